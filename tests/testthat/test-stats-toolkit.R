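test_that("association scan recovers planted effects and applies the MAC rule", {
  set.seed(51)
  n <- 2000
  maf <- 0.3
  g <- matrix(rbinom(n * 3, 2, maf), n,
              dimnames = list(NULL, c("null1", "causal", "rare")))
  # a variant with MAC exactly 20 must be excluded
  g[, "rare"] <- 0
  g[sample.int(n, 20), "rare"] <- 1
  y <- 0.5 * g[, "causal"] + rnorm(n)
  out <- ols_scan(g, y, mac_min = 20)
  expect_false("rare" %in% out$variant_id)
  expect_true(any(grepl("MAC", attr(out, "skipped"))))
  est <- out[out$variant_id == "causal", ]
  expect_lt(abs(est$beta - 0.5), 2 * est$se)
  expect_gt(out$p[out$variant_id == "null1"], 1e-4)

  # covariate projection: confounded effect removed
  cov_ <- rnorm(n)
  y2 <- 0.8 * cov_ + rnorm(n)
  out2 <- ols_scan(g[, "null1", drop = FALSE], y2,
                   covariates = cbind(cov_))
  expect_gt(out2$p, 0.001)

  # zero-variance variant skipped with reason
  gz <- matrix(1, n, 1, dimnames = list(NULL, "const"))
  oz <- ols_scan(gz, y, mac_min = 20)
  expect_equal(nrow(oz), 0L)
  expect_true(any(grepl("variance", attr(oz, "skipped"))))
})

test_that("IVW meta-analysis matches closed forms and a reference implementation", {
  # k = 1 passes through
  m1 <- ivw_meta(0.4, 0.1)
  expect_equal(m1$beta, 0.4)
  expect_equal(m1$se, 0.1)
  # identical studies: se = s / sqrt(k), beta unchanged
  m2 <- ivw_meta(c(0.3, 0.3), c(0.2, 0.2))
  expect_equal(m2$beta, 0.3)
  expect_equal(m2$se, 0.2 / sqrt(2))
  # order invariance
  b <- c(0.1, -0.2, 0.5); s <- c(0.05, 0.2, 0.11)
  expect_equal(ivw_meta(b, s)$beta, ivw_meta(rev(b), rev(s))$beta)
  # weights scale-invariant in relative terms
  expect_equal(ivw_meta(b, s)$beta, ivw_meta(b, 2 * s)$beta)
  # cross-check against metafor fixed-effect model
  mf <- metafor::rma(yi = b, sei = s, method = "FE")
  got <- ivw_meta(b, s)
  expect_equal(got$beta, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(got$se, mf$se, tolerance = 1e-10)
  expect_error(ivw_meta(b, c(0.1, 0, 0.1)), "positive")
})

test_that("Cochran's Q matches the closed form and is calibrated", {
  expect_equal(cochran_q(c(0.2, 0.2, 0.2), rep(0.1, 3))$Q, 0)
  expect_equal(cochran_q(c(0.2, 0.2, 0.2), rep(0.1, 3))$p_het, 1)
  q <- cochran_q(c(0, 2), c(1, 1))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  # agreement with metafor
  b <- c(0.1, 0.4, -0.1, 0.25); s <- c(0.1, 0.15, 0.12, 0.2)
  mf <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(cochran_q(b, s)$Q, as.numeric(mf$QE), tolerance = 1e-10)
  expect_error(cochran_q(0.2, 0.1), "at least 2")
})

test_that("LD clumping matches a brute-force greedy oracle", {
  # all-zero LD: every variant its own clump
  a0 <- data.frame(variant_id = paste0("v", 1:5), chrom = "chr1",
                   pos = 1:5 * 1000, p = runif(5), stringsAsFactors = FALSE)
  ld0 <- diag(5); dimnames(ld0) <- list(a0$variant_id, a0$variant_id)
  c0 <- ld_clump(a0, ld0)
  expect_true(all(c0$is_index))

  set.seed(61)
  for (rep in 1:5) {
    sim <- simulate_summary_stats(n_blocks = 5, m_per_block = 20,
                                  rho2 = 0.5, seed = 600 + rep)
    a <- sim$assoc[sim$assoc$ancestry == "g1", ]
    got <- ld_clump(a, sim$ld)
    want <- clump_oracle(a, sim$ld)
    expect_equal(got$clump_index, want)
    # clumps partition the variant set
    expect_true(all(!is.na(got$clump_index)))
    expect_true(all(got$clump_index %in% got$variant_id))
  }

  # p-value tie: lower genomic position wins
  at <- data.frame(variant_id = c("a", "b"), chrom = "chr1",
                   pos = c(2000, 1000), p = c(0.5, 0.5),
                   stringsAsFactors = FALSE)
  ldt <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ct <- ld_clump(at, ldt)
  expect_equal(unique(ct$clump_index), "b")

  # missing LD treated as zero with a warning
  ldna <- ldt; ldna["a", "b"] <- NA; ldna["b", "a"] <- NA
  expect_warning(cna <- ld_clump(at, ldna), "missing LD")
  expect_true(all(cna$is_index))
})

test_that("locus chaining and replication thresholds behave as specified", {
  leads <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                      pos = c(1e6, 2.9e6, 1e6, 3.2e6),
                      p = c(1e-9, 1e-10, 1e-8, 1e-9))
  out <- define_loci_and_replication(leads)
  expect_equal(nrow(out$loci), 3L)      # 1.9 Mb apart merge; 2.2 Mb do not
  prior <- data.frame(chrom = "chr1", pos = 2e6)
  out2 <- define_loci_and_replication(
    leads, prior_loci = prior,
    new_assoc = data.frame(chrom = "chr1", pos = 3e6, p = 1e-6))
  expect_true(out2$replication$repl_suggestive)   # p < 5e-5 within 2 Mb
  expect_false(out2$replication$repl_gws)         # but not < 5e-8
})

test_that("effect-size IVW regression weights points by joint precision", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  out <- effectsize_ivw_regression(bx, rep(0.1, 4), 2 * bx, rep(0.1, 4))
  expect_equal(out$slope, 2, tolerance = 1e-10)
  # zero-weight point (huge SE) does not influence the slope
  bx2 <- c(bx, 10); by2 <- c(2 * bx, -50)
  out2 <- effectsize_ivw_regression(bx2, c(rep(0.1, 4), 1e6),
                                    by2, c(rep(0.1, 4), 1e6))
  expect_equal(out2$slope, 2, tolerance = 1e-4)
  # noisy recovery within 2 SE
  set.seed(71)
  bx3 <- rnorm(50, 0, 0.2); sey <- rep(0.05, 50)
  by3 <- bx3 + rnorm(50, 0, 0.05)
  out3 <- effectsize_ivw_regression(bx3, rep(0.01, 50), by3, sey)
  expect_lt(abs(out3$slope - 1), 2 * out3$se)
  expect_error(effectsize_ivw_regression(1:2, c(1, 1), 1:2, c(1, 1)),
               "at least 3")
})

test_that("binary-genotype PCA projects consistently and matches a dense SVD", {
  set.seed(81)
  M <- matrix(rbinom(50 * 30, 1, 0.3), 50, 30,
              dimnames = list(NULL, paste0("v", 1:30)))
  pca <- binary_genotype_pca(M, k = 5, maf_min = 0.001)
  # projecting training rows reproduces their scores
  expect_equal(pca$project(M), pca$scores, tolerance = 1e-8)
  # component variances non-increasing
  expect_true(all(diff(pca$sdev) <= 1e-12))
  # dense decomposition oracle (up to sign)
  Z <- scale(M[, pca$kept_variants])
  sv <- svd(Z)
  or <- Z %*% sv$v[, 1:5]
  for (j in 1:5) {
    expect_equal(abs(cor(pca$scores[, j], or[, j])), 1, tolerance = 1e-8)
  }
  # held-out projection uses training centers/scales
  tr <- 1:40
  p2 <- binary_genotype_pca(M, k = 3, train = tr)
  ho <- p2$project(M[41:50, , drop = FALSE])
  expect_equal(dim(ho), c(10L, 3L))
  # MAF filter removes monomorphic columns
  M2 <- cbind(M, mono = 0L)
  expect_false("mono" %in% binary_genotype_pca(M2, k = 3)$kept_variants)
})

test_that("McFadden pseudo-R2 follows the likelihood-ratio form", {
  expect_equal(mcfadden_pseudo_r2(-100, -100), 0)
  expect_equal(mcfadden_pseudo_r2(0, -100), 1)
  expect_equal(mcfadden_pseudo_r2(-50, -100), 0.5)
  expect_error(mcfadden_pseudo_r2(-1, 0), "degenerate")
  # separable classes give high predictive power on PCs
  set.seed(91)
  lab <- rep(c("H", "U", "L"), each = 40)
  sc <- cbind(rnorm(120, rep(c(0, 3, 6), each = 40), 0.5), rnorm(120))
  out <- haplogroup_pseudo_r2(lab, sc, min_group = 30)
  expect_gt(out$pseudo_r2, 0.8)
  expect_lt(out$pseudo_r2, 1)
})

test_that("disease odds ratios recover planted effects with symmetric CIs", {
  set.seed(101)
  n <- 5000
  tr <- rnorm(n)
  age <- runif(n, 40, 70)
  sex <- sample(c("F", "M"), n, TRUE)
  lp <- -2 + 0.3 * tr
  y <- rbinom(n, 1, plogis(lp))
  out <- disease_or(y, tr, data.frame(age = age, sex = sex))
  expect_lt(abs(out$beta - 0.3), 2 * out$se)
  # CI symmetric on the log scale
  expect_equal(log(out$ci_hi) - out$beta, out$beta - log(out$ci_lo),
               tolerance = 1e-10)
  # complete separation flagged
  ysep <- as.integer(tr > 0)
  osep <- disease_or(ysep, tr, data.frame(age = age, sex = sex))
  expect_true(osep$separation)
})

test_that("CLPP is the product of PIPs", {
  expect_equal(colocalization_clpp(1, 1), 1)
  expect_equal(colocalization_clpp(0.5, 0.2), 0.1)
  expect_equal(colocalization_clpp(0, 0.7), 0)
  expect_error(colocalization_clpp(1.2, 0.5), "0, 1")
})

test_that("PIP enrichment computes relative risks with bootstrap CIs", {
  # annotation in all high-PIP and half of low-PIP variants -> RR = 2
  pip <- c(rep(0.5, 40), rep(0.001, 200))
  ann <- c(rep(TRUE, 40), rep(c(TRUE, FALSE), 100))
  out <- enrichment_rr(pip, ann, bootstrap_B = 500)
  expect_equal(out$rr, 2)
  expect_true(out$ci_lo <= out$rr && out$rr <= out$ci_hi)
  # annotation independent of PIP: CI covers 1
  set.seed(111)
  ann2 <- runif(240) < 0.5
  out2 <- enrichment_rr(pip, ann2, bootstrap_B = 1000)
  expect_true(out2$ci_lo <= 1 && 1 <= out2$ci_hi)
  # zero low-stratum proportion: undefined
  out3 <- enrichment_rr(pip, c(rep(TRUE, 40), rep(FALSE, 200)),
                        bootstrap_B = 100)
  expect_true(is.na(out3$rr))
})

test_that("gene assignment implements the prioritization ladder", {
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      start = c(1000, 50000, 120000),
                      end = c(5000, 60000, 130000), stringsAsFactors = FALSE)
  # coding variant with PIP > 0.9 assigns its gene
  fm <- data.frame(variant_id = "v1", pos = 3000, pip = 0.95, cs_id = "cs1",
                   coding_gene = "G1", stringsAsFactors = FALSE)
  out <- assign_genes(fm, genes)
  expect_equal(out$gene, "G1")
  expect_equal(out$evidence, "coding_high_pip")

  # non-coding CS variant 2.5 kb from a gene boundary -> that gene
  fm2 <- data.frame(variant_id = "v2", pos = 62500, pip = 0.8, cs_id = "cs1",
                    coding_gene = NA_character_, stringsAsFactors = FALSE)
  out2 <- assign_genes(fm2, genes)
  expect_equal(out2$gene, "G2")

  # no credible set: nearest gene to the top variant
  fm3 <- data.frame(variant_id = character(), pos = numeric(),
                    pip = numeric(), cs_id = character(),
                    coding_gene = character(), stringsAsFactors = FALSE)
  out3 <- assign_genes(fm3, genes, top_variant_pos = 118000)
  expect_equal(out3$gene, "G3")
  expect_equal(out3$evidence, "nearest_to_top")

  # inside a gene body counts as nearest even when non-coding
  fm4 <- data.frame(variant_id = "v4", pos = 125000, pip = 0.8, cs_id = "cs1",
                    coding_gene = NA_character_, stringsAsFactors = FALSE)
  expect_equal(assign_genes(fm4, genes)$gene, "G3")

  # multi-CS retention: only PIP > 0.1 assignments kept when any exceed it
  fm5 <- rbind(
    data.frame(variant_id = "a", pos = 3000, pip = 0.5, cs_id = "cs1",
               coding_gene = NA_character_, stringsAsFactors = FALSE),
    data.frame(variant_id = "b", pos = 55000, pip = 0.05, cs_id = "cs2",
               coding_gene = NA_character_, stringsAsFactors = FALSE))
  out5 <- assign_genes(fm5, genes)
  expect_true(all(out5$pip > 0.1))
  expect_error(assign_genes(fm, genes[0, ]), "empty")
})

test_that("the full chain scan -> meta -> clump recovers planted causal loci", {
  set.seed(121)
  n_blocks <- 4L; m_tag <- 8L; n <- 1500L; k_groups <- 3L
  maf <- 0.3; rho <- 0.8; beta <- 0.25
  m <- n_blocks * (m_tag + 1L)
  block <- rep(seq_len(n_blocks), each = m_tag + 1L)
  within_i <- sequence(rep(m_tag + 1L, n_blocks))
  causal <- within_i == (m_tag %/% 2L + 1L)
  pos <- (block - 1L) * 5e6 + within_i * 2e4
  vid <- paste0("b", block, "_v", within_i)
  gen_group <- function() {
    G <- matrix(0L, n, m, dimnames = list(NULL, vid))
    for (bl in seq_len(n_blocks)) {
      idx <- which(block == bl)
      gc_ <- rbinom(n, 2, maf)
      for (j in idx) {
        if (causal[j]) { G[, j] <- gc_; next }
        keep <- runif(n) < rho
        G[, j] <- ifelse(keep, gc_, rbinom(n, 2, maf))
      }
    }
    G
  }
  groups <- lapply(seq_len(k_groups), function(k) {
    G <- gen_group()
    y <- G[, causal, drop = FALSE] %*% rep(beta, n_blocks) + rnorm(n)
    list(G = G, y = as.numeric(y))
  })
  scans <- lapply(groups, function(gr) ols_scan(gr$G, gr$y, mac_min = 20))
  meta <- do.call(rbind, lapply(vid, function(v) {
    b <- vapply(scans, function(s) s$beta[s$variant_id == v], 0)
    s <- vapply(scans, function(s) s$se[s$variant_id == v], 0)
    mm <- ivw_meta(b, s)
    data.frame(variant_id = v, beta = mm$beta, se = mm$se, p = mm$p,
               stringsAsFactors = FALSE)
  }))
  meta$chrom <- "chr1"
  meta$pos <- pos
  ld <- cor(do.call(rbind, lapply(groups, `[[`, "G")))^2
  cl <- ld_clump(meta, ld)
  leads <- cl[cl$is_index & cl$p < 5e-8, , drop = FALSE]
  # every planted causal locus yields a genome-wide significant lead
  # within 100 kb
  for (bl in seq_len(n_blocks)) {
    cp <- pos[causal & block == bl]
    expect_true(any(abs(leads$pos - cp) <= 1e5),
                info = paste("block", bl))
  }
})
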