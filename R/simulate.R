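# Deterministic synthetic-data generators with planted ground truth.
# Every generator is a pure function of (params, seed): fixing the seed
# reproduces the output byte for byte.

#' Build a toy circular mtDNA-like genome with planted features
#'
#' A random circular genome carrying the CSBII-like motif
#' `AA C7 T C5 GC` at the classifier locus, optional extra poly-C tracts,
#' and NUMT decoys copied from the genome with per-base divergence.
#' Region coordinates mirror the packaged mtDNA catalog, scaled so the
#' wrapping regions fit the toy length.
#'
#' @param L Genome length (>= 600 so the packaged region layout fits).
#' @param motif_at Start of the planted CSBII motif (default 300, placing
#'   the first C-run adjacent to position 302).
#' @param polyC Integer vector of extra positions at which to plant a
#'   short C6 tract (may be empty).
#' @param numt List: `n` decoys, `length` bases each, `divergence`
#'   per-base substitution rate.
#' @param seed Integer seed.
#' @return list(genome, catalog, catalog_config, decoys, motif_at).
#' @export
make_toy_genome <- function(L = 3000L, motif_at = 300L, polyC = integer(),
                            numt = list(n = 1L, length = 1200L,
                                        divergence = 0.02),
                            seed = 1L) {
  if (L < 600L) stop("toy genome must be at least 600 bases")
  motif <- paste0("AA", strrep("C", 7), "T", strrep("C", 5), "GC")
  if (motif_at + nchar(motif) - 1L > L) stop("motif does not fit in genome")
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  # keep long accidental C-runs out of the neighborhood of the motif
  splice <- function(s, at, piece) {
    s[at:(at + nchar(piece) - 1L)] <- strsplit(piece, "")[[1]]
    s
  }
  s <- splice(s, motif_at, motif)
  # guard bases around the motif so the classifier regex matches uniquely
  if (motif_at > 2) s[(motif_at - 2):(motif_at - 1)] <- c("G", "G")
  after <- motif_at + nchar(motif)
  if (after + 1 <= L) s[after:(after + 1)] <- c("A", "A")
  for (p in polyC) s <- splice(s, p, strrep("C", 6))
  g <- circular_genome("chrM_toy", paste(s, collapse = ""))
  cfg <- list(
    control_region = c(L - 400L, 576L),
    seven_s_span   = c(L - 300L, 191L)
  )
  catalog <- region_catalog_default(g, cfg)
  decoys <- list()
  if (numt$n > 0) {
    for (i in seq_len(numt$n)) {
      start <- 600L + (i - 1L) * 37L
      seg <- strsplit(genome_seq(g, start, .wrap(start + numt$length - 1L, L)),
                      "")[[1]]
      flip <- which(stats::runif(length(seg)) < numt$divergence)
      seg[flip] <- vapply(seg[flip],
                          function(b) sample(setdiff(bases, b), 1L), "")
      decoys[[paste0("numt", i)]] <-
        circular_genome(paste0("numt", i), paste(seg, collapse = ""),
                        circular = FALSE)
    }
  }
  list(genome = g, catalog = catalog, catalog_config = cfg,
       decoys = decoys, motif_at = motif_at)
}

# run code under a local RNG state; returns a restore function
.with_seed <- function(seed) {
  force(seed)  # evaluate caller-supplied draws before snapshotting the state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a cohort with planted mtDNA phenotype structure
#'
#' Mothers carry indel-like heteroplasmies drawn from a mixture prior;
#' offspring inherit the maternal fraction plus truncated-normal noise.
#' Somatic SNV counts are Poisson with a piecewise-constant age rate that
#' steps up at the changepoint age. log mtCN is baseline plus an age
#' slope, planted blood-covariate effects and noise. Genotypes at nuclear
#' QTL loci shift the case-only heteroplasmy by the planted betas.
#'
#' @param n_families Number of mother-offspring pairs (cohort size is
#'   `2 * n_families`).
#' @param params List overriding any of: `p_carrier` (maternal carrier
#'   probability, 0.6), `het_shape` (Beta(2, 6) fraction prior),
#'   `maternal_sigma` (transmission noise SD, 0.03), `age_slope`
#'   (log-mtCN change per decade, -0.02), `mtcn_baseline` (log copies,
#'   log(60)), `mtcn_sigma` (0.15), `blood_beta` (effect of the first
#'   blood index on log mtCN, 0.05), `n_blood` (14), `qtl_maf` (0.3),
#'   `qtl_beta` (additive genotype effect on heteroplasmy fraction,
#'   0.02), `somatic_rate_young` (0.3), `somatic_rate_old` (1.2),
#'   `changepoint_age` (70), `haplogroup_freqs` (named probabilities).
#' @param seed Integer seed.
#' @return list(samples, pedigree, het_fraction, qtl_genotypes, params):
#'   `samples` holds ages, sexes, haplogroups, covariates, true and
#'   observed mtCN and somatic counts; `het_fraction` the per-sample true
#'   heteroplasmy fraction (NA for non-carriers).
#' @export
simulate_cohort <- function(n_families = 500L, params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    p_carrier = 0.6, het_shape = c(2, 6), maternal_sigma = 0.03,
    age_slope = -0.02, mtcn_baseline = log(60), mtcn_sigma = 0.15,
    blood_beta = 0.05, n_blood = 14L, qtl_maf = 0.3, qtl_beta = 0.02,
    somatic_rate_young = 0.3, somatic_rate_old = 1.2, changepoint_age = 70,
    haplogroup_freqs = c(H = 0.45, U = 0.15, T = 0.1, J = 0.1, K = 0.08,
                         L = 0.07, M = 0.05)
  ), params)
  if (p$p_carrier < 0 || p$p_carrier > 1) stop("invalid probability parameter")
  restore <- .with_seed(seed)
  on.exit(restore())
  n <- 2L * n_families
  id_m <- sprintf("M%04d", seq_len(n_families))
  id_o <- sprintf("O%04d", seq_len(n_families))
  ids <- c(id_m, id_o)
  hap <- sample(names(p$haplogroup_freqs), n_families, replace = TRUE,
                prob = p$haplogroup_freqs)
  age_m <- stats::runif(n_families, 55, 85)
  age_o <- age_m - stats::runif(n_families, 20, 35)
  ages <- c(age_m, age_o)
  sexes <- c(rep("F", n_families),
             sample(c("F", "M"), n_families, replace = TRUE))
  # maternal heteroplasmy and transmission
  carrier <- stats::runif(n_families) < p$p_carrier
  frac_m <- ifelse(carrier,
                   stats::rbeta(n_families, p$het_shape[1], p$het_shape[2]),
                   NA_real_)
  noise <- stats::rnorm(n_families, 0, p$maternal_sigma)
  frac_o <- pmin(pmax(frac_m + noise, 0), 1)
  het <- c(frac_m, frac_o)
  # nuclear QTL shifting the heteroplasmy fraction of carriers
  geno <- stats::rbinom(n, 2, p$qtl_maf)
  het <- pmin(pmax(het + p$qtl_beta * (geno - 2 * p$qtl_maf), 0), 1)
  # somatic SNV counts: piecewise Poisson in age
  rate <- ifelse(ages >= p$changepoint_age, p$somatic_rate_old,
                 p$somatic_rate_young)
  somatic <- stats::rpois(n, rate)
  # covariates and log mtCN
  blood <- matrix(stats::rnorm(n * p$n_blood), n,
                  dimnames = list(ids, paste0("blood", seq_len(p$n_blood))))
  draw_time <- stats::runif(n, 8 * 60, 18 * 60)
  center <- sample(c("C1", "C2", "C3"), n, replace = TRUE)
  dates <- as.Date("2007-07-01") + floor(stats::runif(n, 0, 1095))
  fasting <- sample(0:24, n, replace = TRUE)
  log_mtcn <- p$mtcn_baseline + p$age_slope * (ages - 60) / 10 +
    p$blood_beta * blood[, 1] + stats::rnorm(n, 0, p$mtcn_sigma)
  samples <- data.frame(
    sample_id = ids, role = rep(c("mother", "offspring"), each = n_families),
    age = ages, sex = sexes, haplogroup = rep(hap, 2),
    draw_time = draw_time, assessment_date = dates,
    month = format(dates, "%m"), center = center,
    fasting_hours = fasting, somatic_snvs = somatic,
    log_mtcn = log_mtcn, mtcn = exp(log_mtcn),
    stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(blood))
  pedigree <- data.frame(id1 = id_m, id2 = id_o,
                         relationship = "mother_offspring",
                         stringsAsFactors = FALSE)
  list(samples = samples, pedigree = pedigree,
       het_fraction = stats::setNames(het, ids),
       qtl_genotypes = stats::setNames(geno, ids), params = p)
}

# translate a consensus-coordinate window into a reference-anchored
# alignment (left_pos + CIGAR) through the haplotype's coordinate map
.cigar_from_map <- function(map, cons_start, len) {
  Lc <- map$cons_length
  Lr <- map$ref_length
  cpos <- .wrap(cons_start + 0:(len - 1L), Lc)
  lifted <- lift_position(map, cpos, "cons_to_ref")
  ops <- character(0); lens <- integer(0)
  push <- function(op, k) {
    if (length(ops) > 0 && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + k
    } else {
      ops <<- c(ops, op); lens <<- c(lens, k)
    }
  }
  left_pos <- NA_integer_
  prev_ref <- NA_integer_
  for (i in seq_len(len)) {
    if (lifted$flag[i] == "inside_insertion") {
      push(if (is.na(left_pos)) "S" else "I", 1L)
    } else {
      rp <- lifted$pos[i]
      if (is.na(left_pos)) {
        left_pos <- rp
      } else {
        gap <- (rp - prev_ref - 1L) %% Lr
        if (gap > 0L) push("D", gap)
      }
      push("M", 1L)
      prev_ref <- rp
    }
  }
  if (is.na(left_pos)) return(NULL)  # read entirely inside an insertion
  list(left_pos = left_pos, cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate reads from a mixture of mtDNA haplotypes (and NUMT decoys)
#'
#' Reads are drawn uniformly (or per a depth profile) from the circular
#' haplotypes of a sample's mtDNA mixture, with substitution errors,
#' duplicate flags at the stated rate, optional cell barcodes, and
#' reference-anchored CIGARs derived from each haplotype's coordinate
#' map. In `linear_mode`, reads spanning the reference origin are clipped
#' at the boundary (emulating a linear aligner) which depresses coverage
#' at the linearization breakpoints.
#'
#' @param g Reference [circular_genome()].
#' @param haplotypes List of components `list(edits =, frac =)`; edit
#'   tables may be empty for the reference haplotype. Fractions must sum
#'   to 1.
#' @param depth Target mean depth over the genome.
#' @param read_length Read length (default 100).
#' @param error_rate Per-base substitution error rate in `[0, 0.1]`.
#' @param duplicate_rate Fraction of reads duplicate-flagged.
#' @param numt_reads Optional list `list(genome =, depth =)` adding reads
#'   copied from a NUMT decoy.
#' @param barcode Optional cell barcode applied to all reads.
#' @param linear_mode Clip origin-spanning reads at the boundary?
#' @param prefix Read-name prefix.
#' @param seed Integer seed.
#' @return An [aligned_reads()] table (reference-anchored coordinates for
#'   mtDNA reads; decoy reads carry the decoy contig and gapless CIGARs).
#' @export
simulate_reads <- function(g, haplotypes = list(list(edits = NULL, frac = 1)),
                           depth = 100, read_length = 100L,
                           error_rate = 0.003, duplicate_rate = 0,
                           numt_reads = NULL, barcode = NA_character_,
                           linear_mode = FALSE, prefix = "r", seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  fr <- vapply(haplotypes, function(h) h$frac, 0)
  stopifnot(abs(sum(fr) - 1) < 1e-9)
  if (depth <= 0) stop("zero depth everywhere")
  restore <- .with_seed(seed)
  on.exit(restore())
  haps <- lapply(haplotypes, function(h) {
    ed <- h$edits
    if (is.null(ed) || nrow(ed) == 0) ed <- .empty_edits()
    build_consensus(g, ed)
  })
  n_reads <- as.integer(round(depth * g$length / read_length))
  which_h <- sample(seq_along(haps), n_reads, replace = TRUE, prob = fr)
  bases <- c("A", "C", "G", "T")
  starts <- integer(n_reads)
  seqs <- character(n_reads)
  left <- integer(n_reads)
  cigars <- character(n_reads)
  keep <- rep(TRUE, n_reads)
  for (h in seq_along(haps)) {
    idx <- which(which_h == h)
    if (length(idx) == 0) next
    hp <- haps[[h]]
    Lc <- hp$genome$length
    s <- sample.int(Lc, length(idx), replace = TRUE)
    starts[idx] <- s
    doubled <- paste0(hp$genome$sequence,
                      substr(hp$genome$sequence, 1L, read_length))
    seqs[idx] <- substring(doubled, s, s + read_length - 1L)
    length_preserving <- nrow(hp$map$edits) == 0 ||
      all(nchar(hp$map$edits$ref) == nchar(hp$map$edits$alt))
    if (length_preserving) {
      # consensus and reference coordinates coincide
      left[idx] <- s
      cigars[idx] <- paste0(read_length, "M")
    } else {
      for (i in idx) {
        aln <- .cigar_from_map(hp$map, starts[i], read_length)
        if (is.null(aln)) { keep[i] <- FALSE; next }
        left[i] <- aln$left_pos
        cigars[i] <- aln$cigar
      }
    }
  }
  # substitution errors
  ne <- stats::rbinom(n_reads, read_length, error_rate)
  for (i in which(ne > 0 & keep)) {
    at <- sample.int(read_length, ne[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1L), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  if (linear_mode) {
    for (i in which(keep)) {
      span <- .read_ref_span(cigars[i])
      if (left[i] + span - 1L > g$length) {
        keep_ref <- g$length - left[i] + 1L
        clip <- .clip_cigar_at(cigars[i], keep_ref)
        if (!is.null(clip)) {
          cigars[i] <- clip
        } else if (grepl("^\\d+M$", cigars[i])) {
          # mostly past the edge: emit the wrapped tail anchored at base 1
          cigars[i] <- paste0(keep_ref, "S", read_length - keep_ref, "M")
          left[i] <- 1L
        } else {
          keep[i] <- FALSE
        }
      }
    }
  }
  flag <- ifelse(stats::runif(n_reads) < duplicate_rate, FLAG_DUPLICATE, 0L)
  w <- which(keep)
  reads <- aligned_reads(paste0(prefix, w), g$contig, left[w], cigars[w],
                         seqs[w], flag = flag[w], cell_barcode = barcode)
  if (!is.null(numt_reads)) {
    dg <- numt_reads$genome
    nn <- as.integer(round(numt_reads$depth * dg$length / read_length))
    starts <- sample.int(max(1L, dg$length - read_length + 1L), nn,
                         replace = TRUE)
    sqs <- substring(dg$sequence, starts, starts + read_length - 1L)
    reads <- rbind(reads,
                   aligned_reads(paste0(prefix, "n", seq_len(nn)), dg$contig,
                                 starts, paste0(nchar(sqs), "M"), sqs,
                                 cell_barcode = barcode))
    class(reads) <- c("aligned_reads", "data.frame")
  }
  reads
}

.read_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "=", "X")])
}

# truncate a CIGAR after keep_ref reference bases, soft-clipping the rest
.clip_cigar_at <- function(cigar, keep_ref) {
  ops <- parse_cigar(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  new_ops <- character(0); new_lens <- integer(0)
  ref_used <- 0L; q_used <- 0L
  for (j in seq_len(nrow(ops))) {
    op <- ops$op[j]; len <- ops$len[j]
    consumes_ref <- op %in% c("M", "D", "=", "X")
    consumes_q <- op %in% c("M", "I", "S", "=", "X")
    if (consumes_ref && ref_used + len > keep_ref) {
      part <- keep_ref - ref_used
      if (part > 0) {
        new_ops <- c(new_ops, op); new_lens <- c(new_lens, part)
        if (consumes_q) q_used <- q_used + part
        ref_used <- keep_ref
      }
      break
    }
    new_ops <- c(new_ops, op); new_lens <- c(new_lens, len)
    if (consumes_ref) ref_used <- ref_used + len
    if (consumes_q) q_used <- q_used + len
  }
  if (q_used < qlen %/% 2L) return(NULL)  # drop reads mostly past the edge
  if (q_used < qlen) {
    new_ops <- c(new_ops, "S"); new_lens <- c(new_lens, qlen - q_used)
  }
  paste0(new_lens, new_ops, collapse = "")
}

#' Simulate per-group GWAS summary statistics over LD blocks
#'
#' Each block holds `m_per_block` variants with pairwise within-block
#' `r^2 = rho2` and one causal variant; marginal true effects of tagging
#' variants are attenuated by `sqrt(rho2)`. Per-group observed betas are
#' the truth plus normal noise with `se = 1/sqrt(2 maf (1-maf) n)`.
#'
#' @param n_blocks Number of LD blocks (default 5).
#' @param m_per_block Variants per block (default 20).
#' @param rho2 Within-block r-squared (default 0.5).
#' @param causal_beta True effect at each block's causal variant
#'   (scalar or per-block vector; default 0.15).
#' @param k_groups Number of ancestry groups (default 3).
#' @param n_per_group Sample size per group (default 20000).
#' @param maf Minor allele frequency (default 0.3).
#' @param heterogeneity SD of per-group deviations from the shared causal
#'   effect (default 0, homogeneous).
#' @param seed Integer seed.
#' @return list(assoc = per-group stacked data.frame (variant_id, chrom,
#'   pos, beta, se, p, mac, ancestry), ld = r-squared matrix,
#'   truth = data.frame of causal variants).
#' @export
simulate_summary_stats <- function(n_blocks = 5L, m_per_block = 20L,
                                   rho2 = 0.5, causal_beta = 0.15,
                                   k_groups = 3L, n_per_group = 20000L,
                                   maf = 0.3, heterogeneity = 0,
                                   seed = 1L) {
  restore <- .with_seed(seed)
  on.exit(restore())
  m <- n_blocks * m_per_block
  block <- rep(seq_len(n_blocks), each = m_per_block)
  pos <- rep((seq_len(n_blocks) - 1L) * 5e6L + 1e6L, each = m_per_block) +
    (seq_len(m_per_block) - 1L) * 10e3L
  vid <- paste0("b", block, "_v", rep(seq_len(m_per_block), n_blocks))
  causal_beta <- rep_len(causal_beta, n_blocks)
  causal_idx <- (seq_len(n_blocks) - 1L) * m_per_block + m_per_block %/% 2L + 1L
  truth_beta <- numeric(m)
  truth_beta[causal_idx] <- causal_beta
  tag <- truth_beta == 0
  truth_beta[tag] <- sqrt(rho2) * causal_beta[block[tag]]
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_per_group)
  assoc <- do.call(rbind, lapply(seq_len(k_groups), function(k) {
    shift <- if (heterogeneity > 0)
      stats::rnorm(n_blocks, 0, heterogeneity)[block] else 0
    b <- stats::rnorm(m, truth_beta + shift, se)
    data.frame(variant_id = vid, chrom = paste0("chr", block), pos = pos,
               beta = b, se = se, p = 2 * stats::pnorm(-abs(b / se)),
               mac = as.integer(round(2 * maf * n_per_group)),
               ancestry = paste0("g", k), stringsAsFactors = FALSE)
  }))
  ld <- matrix(0, m, m, dimnames = list(vid, vid))
  for (bl in seq_len(n_blocks)) {
    idx <- which(block == bl)
    ld[idx, idx] <- rho2
  }
  diag(ld) <- 1
  list(assoc = assoc,
       ld = ld,
       truth = data.frame(variant_id = vid[causal_idx],
                          chrom = paste0("chr", seq_len(n_blocks)),
                          pos = pos[causal_idx], beta = causal_beta,
                          stringsAsFactors = FALSE))
}
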