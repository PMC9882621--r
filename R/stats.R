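# Summary-statistics layer: least-squares association scan, fixed-effect
# inverse-variance meta-analysis with Cochran's Q, LD clumping and locus
# definition, effect-size IVW regression, binary-genotype PCA with
# projection, McFadden pseudo-R2, disease odds ratios, CLPP
# colocalization, fine-mapping enrichment, and the gene-assignment ladder.

#' Least-squares association scan
#'
#' Per variant with minor allele count strictly above `mac_min`, fits the
#' least-squares effect of genotype on the phenotype with covariates
#' projected out. Intended for unrelated samples (a stand-in for a
#' mixed-model scan, which this package does not provide).
#'
#' @param genotypes Numeric samples x variants matrix coded 0/1/2 (NA
#'   allowed).
#' @param y Phenotype vector (inverse-rank normalized upstream).
#' @param covariates Optional covariate matrix (no intercept column).
#' @param mac_min Minor-allele-count exclusion bound (strict; default 20).
#' @return data.frame (`assoc_records`): variant_id, beta, se, p, mac, n,
#'   plus a `skipped` attribute listing variants dropped and why.
#' @export
ols_scan <- function(genotypes, y, covariates = NULL, mac_min = 20L) {
  stopifnot(nrow(genotypes) == length(y))
  vids <- colnames(genotypes)
  if (is.null(vids)) vids <- paste0("v", seq_len(ncol(genotypes)))
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    ok <- !is.na(g) & !is.na(y)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    gg <- g[ok]; yy <- y[ok]
    ac <- sum(gg)
    mac <- min(ac, 2 * length(gg) - ac)
    if (mac <= mac_min) { skipped <- c(skipped, paste0(vids[j], ": MAC <= ", mac_min)); next }
    if (stats::var(gg) == 0) { skipped <- c(skipped, paste0(vids[j], ": zero genotype variance")); next }
    if (!is.null(covariates)) {
      C <- as.matrix(covariates)[ok, , drop = FALSE]
      fit <- stats::lm(yy ~ gg + C)
    } else {
      fit <- stats::lm(yy ~ gg)
    }
    sm <- summary(fit)$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = vids[j], beta = sm["gg", 1], se = sm["gg", 2],
      p = sm["gg", 4], mac = mac, n = length(gg), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), beta = numeric(), se = numeric(),
               p = numeric(), mac = integer(), n = integer(),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis for one variant
#'
#' Weights `w_i = 1/se_i^2`; pooled beta is the weighted mean, pooled
#' `se = 1/sqrt(sum(w))`, with a two-sided normal p-value.
#'
#' @param beta,se Per-group effect estimates and standard errors (all
#'   `se > 0`).
#' @return list(beta, se, p, k).
#' @export
ivw_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)), k = length(beta))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (b_i - b_meta)^2)` referred to chi-square with k - 1
#' degrees of freedom.
#' @inheritParams ivw_meta
#' @return list(Q, p_het, df).
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  if (k < 2) stop("Cochran's Q needs at least 2 studies")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bm)^2)
  list(Q = Q, p_het = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
       df = k - 1)
}

#' Greedy LD clumping of association records
#'
#' Repeatedly takes the smallest-p unassigned variant passing `p_index`
#' as an index SNP (p ties broken by lower genomic position) and assigns
#' to it all unassigned variants within `window` bases with
#' `r^2 > r2_threshold` passing `p_clumped`. Missing LD for an in-window
#' pair counts as r^2 = 0 with a warning.
#'
#' @param assoc data.frame with columns `variant_id`, `chrom`, `pos`, `p`.
#' @param ld_lookup Function `(id_a, id_b) -> r^2` (may return NA), or a
#'   symmetric matrix with variant IDs as dimnames.
#' @param r2_threshold LD threshold (default 0.1).
#' @param window Distance threshold in bases (default 5e5).
#' @param p_index,p_clumped Significance thresholds (default 1, i.e. all).
#' @return `assoc` with added columns `clump_index` (the index variant of
#'   each variant's clump) and `is_index`.
#' @export
ld_clump <- function(assoc, ld_lookup, r2_threshold = 0.1, window = 5e5,
                     p_index = 1, p_clumped = 1) {
  if (is.matrix(ld_lookup)) {
    M <- ld_lookup
    ld_lookup <- function(a, b) M[a, b]
  }
  n <- nrow(assoc)
  assigned <- rep(NA_character_, n)
  warned <- FALSE
  repeat {
    cand <- which(is.na(assigned) & assoc$p <= p_index)
    if (length(cand) == 0) break
    i <- cand[order(assoc$p[cand], assoc$pos[cand])][1]
    idx_id <- assoc$variant_id[i]
    assigned[i] <- idx_id
    near <- which(is.na(assigned) &
                    assoc$chrom == assoc$chrom[i] &
                    abs(assoc$pos - assoc$pos[i]) <= window &
                    assoc$p <= p_clumped)
    for (j in near) {
      r2 <- ld_lookup(idx_id, assoc$variant_id[j])
      if (is.na(r2)) {
        if (!warned) { warning("missing LD for an in-window pair; treating r^2 as 0"); warned <- TRUE }
        r2 <- 0
      }
      if (r2 > r2_threshold) assigned[j] <- idx_id
    }
  }
  # variants failing p_index that were never absorbed form singleton clumps
  left <- which(is.na(assigned))
  assigned[left] <- assoc$variant_id[left]
  assoc$clump_index <- assigned
  assoc$is_index <- assoc$variant_id == assigned
  assoc
}

#' Chain lead SNPs into loci and flag replication of prior loci
#'
#' Lead SNPs on a chromosome merge into one locus whenever consecutive
#' leads are within `merge_window`. A prior locus replicates at a
#' threshold iff any new association with p below that threshold lies
#' within `repl_window` of the prior locus's top variant.
#'
#' @param leads data.frame with `chrom`, `pos`, `p` for lead SNPs.
#' @param merge_window Locus merge distance (default 2 Mb).
#' @param prior_loci Optional data.frame with `chrom`, `pos` (top variant)
#'   per previously reported locus.
#' @param new_assoc Associations used to assess replication (defaults to
#'   `leads`).
#' @param p_repl,p_gws Replication thresholds (defaults 5e-5, 5e-8).
#' @param repl_window Replication distance (default 2 Mb).
#' @return list(`loci` = data.frame(chrom, start, end, n_leads, top_p),
#'   `replication` = prior_loci with logical `repl_suggestive` /
#'   `repl_gws` columns, or NULL).
#' @export
define_loci_and_replication <- function(leads, merge_window = 2e6,
                                        prior_loci = NULL,
                                        new_assoc = leads,
                                        p_repl = 5e-5, p_gws = 5e-8,
                                        repl_window = 2e6) {
  loci <- list()
  for (ch in unique(leads$chrom)) {
    d <- leads[leads$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(d$pos) > merge_window))
    for (g in unique(grp)) {
      dd <- d[grp == g, , drop = FALSE]
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, start = min(dd$pos), end = max(dd$pos),
        n_leads = nrow(dd), top_p = min(dd$p), stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, loci)
  replication <- NULL
  if (!is.null(prior_loci)) {
    hit_at <- function(thr) {
      vapply(seq_len(nrow(prior_loci)), function(i) {
        any(new_assoc$chrom == prior_loci$chrom[i] &
              abs(new_assoc$pos - prior_loci$pos[i]) <= repl_window &
              new_assoc$p < thr)
      }, logical(1))
    }
    replication <- prior_loci
    replication$repl_suggestive <- hit_at(p_repl)
    replication$repl_gws <- hit_at(p_gws)
  }
  list(loci = loci, replication = replication)
}

#' Inverse-variance-weighted effect-size regression
#'
#' Weighted least squares of outcome effect sizes on exposure effect
#' sizes with per-point weight `(1/se_x^2) * (1/se_y^2)` -- the
#' summary-level regression used for bidirectional effect-size comparison.
#'
#' @param bx,sex Exposure betas and SEs.
#' @param by,sey Outcome betas and SEs.
#' @return list(slope, se, p, n).
#' @export
effectsize_ivw_regression <- function(bx, sex, by, sey) {
  stopifnot(length(bx) == length(by), length(bx) == length(sex),
            length(by) == length(sey))
  if (length(bx) < 3) stop("insufficient data: need at least 3 points")
  if (any(sex <= 0) || any(sey <= 0)) stop("all SEs must be positive")
  w <- (1 / sex^2) * (1 / sey^2)
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  list(slope = sm["bx", 1], se = sm["bx", 2], p = sm["bx", 4],
       n = length(bx))
}

#' PCA of a binary homoplasmy genotype matrix, with projection
#'
#' Columns are filtered at `maf_min`, centered and scaled on the training
#' rows, and the top-k singular decomposition gives training scores. The
#' returned projector maps held-out rows into the same space using the
#' training centers, scales and loadings.
#'
#' @param M Binary samples x variants matrix (0/1).
#' @param k Number of components (default 50, capped by rank).
#' @param maf_min Minor-allele-frequency filter (default 0.001).
#' @param train Logical or integer index of training rows (default all).
#' @return list(scores, loadings, sdev, project(newdata), kept_variants,
#'   dropped).
#' @export
binary_genotype_pca <- function(M, k = 50L, maf_min = 0.001, train = NULL) {
  M <- as.matrix(M)
  if (is.null(train)) train <- seq_len(nrow(M))
  Mt <- M[train, , drop = FALSE]
  af <- colMeans(Mt)
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min
  ctr <- colMeans(Mt[, keep, drop = FALSE])
  sdv <- apply(Mt[, keep, drop = FALSE], 2, stats::sd)
  nz <- sdv > 0
  dropped <- colnames(M)[keep][!nz]
  keep_names <- colnames(Mt[, keep, drop = FALSE])[nz]
  ctr <- ctr[nz]; sdv <- sdv[nz]
  Z <- scale(Mt[, keep, drop = FALSE][, nz, drop = FALSE],
             center = ctr, scale = sdv)
  k <- min(k, nrow(Z) - 1L, ncol(Z))
  sv <- svd(Z, nu = k, nv = k)
  loadings <- sv$v
  rownames(loadings) <- keep_names
  scores <- Z %*% loadings
  project <- function(newdata) {
    Zn <- scale(as.matrix(newdata)[, keep_names, drop = FALSE],
                center = ctr, scale = sdv)
    Zn %*% loadings
  }
  list(scores = scores, loadings = loadings,
       sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(Z) - 1)),
       project = project, kept_variants = keep_names, dropped = dropped)
}

#' McFadden's pseudo-R-squared
#'
#' `1 - loglik_model / loglik_null`; in `[0, 1)` for non-degenerate fits.
#' @param loglik_model,loglik_null Log-likelihoods (null <= 0 and
#'   model >= null).
#' @return Numeric scalar.
#' @export
mcfadden_pseudo_r2 <- function(loglik_model, loglik_null) {
  if (loglik_null == 0) stop("degenerate null model (single-class response)")
  stopifnot(loglik_null < 0, loglik_model >= loglik_null, loglik_model <= 0)
  1 - loglik_model / loglik_null
}

#' Haplogroup predictive power of genotype PCs
#'
#' Fits a multinomial model of a categorical label on principal-component
#' scores against an intercept-only null and reports McFadden's
#' pseudo-R-squared.
#'
#' @param labels Factor of class labels (e.g. top-level haplogroups).
#' @param scores Numeric matrix of PC scores.
#' @param min_group Exclude classes with fewer members than this
#'   (default 30).
#' @return list(pseudo_r2, loglik_model, loglik_null, n).
#' @export
haplogroup_pseudo_r2 <- function(labels, scores, min_group = 30L) {
  labels <- factor(labels)
  keep <- labels %in% names(table(labels))[table(labels) >= min_group]
  labels <- droplevels(labels[keep])
  scores <- scores[keep, , drop = FALSE]
  if (nlevels(labels) < 2) stop("degenerate response: fewer than 2 classes")
  dat <- data.frame(y = labels, scores)
  cap <- utils::capture.output({
    fit <- nnet::multinom(y ~ ., data = dat, maxit = 500, trace = FALSE)
    null <- nnet::multinom(y ~ 1, data = dat, trace = FALSE)
  })
  ll_m <- as.numeric(stats::logLik(fit))
  ll_0 <- as.numeric(stats::logLik(null))
  list(pseudo_r2 = mcfadden_pseudo_r2(ll_m, ll_0),
       loglik_model = ll_m, loglik_null = ll_0, n = length(labels))
}

#' Logistic odds ratio of disease on a standardized trait
#'
#' Logistic model of disease on the z-scored trait with age, sex, their
#' squares and interactions, population and top-level haplogroup as
#' covariates. OR is `exp(beta_trait)` with a Wald 95% CI.
#'
#' @param disease Binary 0/1 outcome vector.
#' @param trait_z Z-scored trait.
#' @param covars data.frame with columns `age`, `sex`, and optionally
#'   `pop`, `haplogroup`.
#' @param min_group Haplogroup levels below this size are pooled into
#'   `"other"` (default 30).
#' @return list(or, ci_lo, ci_hi, beta, se, p, separation).
#' @export
disease_or <- function(disease, trait_z, covars, min_group = 30L) {
  d <- data.frame(y = disease, trait = trait_z,
                  age = covars$age, sex = factor(covars$sex))
  form <- y ~ trait + age + sex + I(age^2) + I(age^2):sex + age:sex
  if (!is.null(covars$pop)) {
    d$pop <- factor(covars$pop)
    if (nlevels(d$pop) > 1) form <- stats::update(form, . ~ . + pop)
  }
  if (!is.null(covars$haplogroup)) {
    hg <- as.character(covars$haplogroup)
    small <- names(table(hg))[table(hg) < min_group]
    hg[hg %in% small] <- "other"
    d$haplogroup <- factor(hg)
    if (nlevels(d$haplogroup) > 1) form <- stats::update(form, . ~ . + haplogroup)
  }
  fit <- suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (sep) {
    return(list(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                beta = NA_real_, se = NA_real_, p = NA_real_,
                separation = TRUE))
  }
  sm <- summary(fit)$coefficients
  b <- sm["trait", 1]; s <- sm["trait", 2]
  list(or = exp(b), ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
       beta = b, se = s, p = sm["trait", 4], separation = FALSE)
}

#' Colocalization posterior probability (CLPP)
#'
#' The product of the GWAS and cis-eQTL posterior inclusion
#' probabilities for a variant.
#' @param pip_gwas,pip_eqtl PIPs in `[0, 1]`.
#' @return Numeric CLPP.
#' @export
colocalization_clpp <- function(pip_gwas, pip_eqtl) {
  if (any(pip_gwas < 0 | pip_gwas > 1) || any(pip_eqtl < 0 | pip_eqtl > 1)) {
    stop("PIPs must lie in [0, 1]")
  }
  pip_gwas * pip_eqtl
}

#' Functional-category enrichment among fine-mapped variants
#'
#' Relative risk = (share of variants with PIP > `pip_hi` in the
#' annotation) / (share of variants with PIP <= `pip_lo` in the
#' annotation), with a percentile bootstrap CI resampling variants within
#' each PIP stratum.
#'
#' @param pip Per-variant PIPs.
#' @param in_annotation Logical per-variant annotation membership.
#' @param pip_hi,pip_lo Stratum bounds (defaults 0.1, 0.01).
#' @param bootstrap_B Bootstrap replicates (default 5000).
#' @return list(rr, ci_lo, ci_hi, n_hi, n_lo); `rr` is NA when the
#'   low-stratum proportion is zero (undefined ratio).
#' @export
enrichment_rr <- function(pip, in_annotation, pip_hi = 0.1, pip_lo = 0.01,
                          bootstrap_B = 5000L) {
  hi <- pip > pip_hi
  lo <- pip <= pip_lo
  if (!any(hi) || !any(lo)) stop("both PIP strata must be non-empty")
  a_hi <- in_annotation[hi]; a_lo <- in_annotation[lo]
  p_lo <- mean(a_lo)
  if (p_lo == 0) {
    return(list(rr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                n_hi = sum(hi), n_lo = sum(lo)))
  }
  rr <- mean(a_hi) / p_lo
  boots <- vapply(seq_len(bootstrap_B), function(b) {
    ph <- mean(sample(a_hi, replace = TRUE))
    pl <- mean(sample(a_lo, replace = TRUE))
    if (pl == 0) NA_real_ else ph / pl
  }, 0)
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(rr = rr, ci_lo = ci[1], ci_hi = ci[2], n_hi = sum(hi), n_lo = sum(lo))
}

# nearest gene with inside-gene-body counting as distance 0
.nearest_genes <- function(pos, genes, max_dist = Inf) {
  dist <- ifelse(pos >= genes$start & pos <= genes$end, 0,
                 pmin(abs(pos - genes$start), abs(pos - genes$end)))
  if (is.finite(max_dist)) {
    within <- genes$gene[dist <= max_dist]
    if (length(within) > 0) return(within)
  }
  genes$gene[which.min(dist)]
}

#' Gene assignment from fine-mapped credible sets
#'
#' Implements the prioritization ladder: within each credible set, retain
#' variants that are minimal-PIP, coding, or PIP > 0.7; a coding variant
#' with PIP > 0.9 assigns its gene directly; otherwise genes within 3 kb
#' of a retained variant are assigned, falling back to the nearest gene
#' (a variant inside a gene body counts as nearest). When a locus has
#' multiple credible sets and at least one retained variant has
#' PIP > 0.1, only assignments from variants with PIP > 0.1 are kept.
#' A locus without a credible set gets the gene whose boundary is nearest
#' its most significant variant.
#'
#' @param finemap data.frame with columns `variant_id`, `pos`, `pip`,
#'   `cs_id` (NA when not in a credible set), `coding_gene` (NA when
#'   non-coding).
#' @param genes data.frame with columns `gene`, `start`, `end`.
#' @param top_variant_pos Position of the locus's most significant variant
#'   (used when no credible set exists).
#' @param near_kb Proximity window in bases (default 3000).
#' @return data.frame: cs_id, variant_id, pip, gene, evidence.
#' @export
assign_genes <- function(finemap, genes, top_variant_pos = NULL,
                         near_kb = 3000) {
  if (nrow(genes) == 0) stop("empty gene catalog")
  cs_ids <- unique(finemap$cs_id[!is.na(finemap$cs_id)])
  if (length(cs_ids) == 0) {
    if (is.null(top_variant_pos)) stop("no credible set and no top variant given")
    g <- .nearest_genes(top_variant_pos, genes)[1]
    return(data.frame(cs_id = NA_character_, variant_id = NA_character_,
                      pip = NA_real_, gene = g, evidence = "nearest_to_top",
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (cs in cs_ids) {
    d <- finemap[!is.na(finemap$cs_id) & finemap$cs_id == cs, , drop = FALSE]
    keep <- d$pip == min(d$pip) | !is.na(d$coding_gene) | d$pip > 0.7
    d <- d[keep, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (!is.na(d$coding_gene[i]) && d$pip[i] > 0.9) {
        rows[[length(rows) + 1L]] <- data.frame(
          cs_id = cs, variant_id = d$variant_id[i], pip = d$pip[i],
          gene = d$coding_gene[i], evidence = "coding_high_pip",
          stringsAsFactors = FALSE)
      } else {
        gs <- .nearest_genes(d$pos[i], genes, max_dist = near_kb)
        ev <- if (any(d$pos[i] >= genes$start & d$pos[i] <= genes$end) ||
                  min(abs(c(d$pos[i] - genes$start, d$pos[i] - genes$end))) <= near_kb)
          "within_3kb" else "nearest"
        for (g in gs) {
          rows[[length(rows) + 1L]] <- data.frame(
            cs_id = cs, variant_id = d$variant_id[i], pip = d$pip[i],
            gene = g, evidence = ev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (length(cs_ids) > 1 && any(out$pip > 0.1, na.rm = TRUE)) {
    out <- out[out$pip > 0.1, , drop = FALSE]
  }
  rownames(out) <- NULL
  unique(out)
}
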