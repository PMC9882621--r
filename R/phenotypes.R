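# Analysis-phenotype construction: case-only / case-control heteroplasmy
# coding, covariate design matrices with F-test-gated residualization,
# rank-based inverse normal transformation, coverage-discrepancy traits,
# transmission pairs, age-accrual summaries, and pathogenic-carrier
# contrasts.

#' Case-only heteroplasmy phenotype
#'
#' Carriers (heteroplasmic state) get their fraction; reference, missing
#' and homoplasmic samples are coded missing, so the trait is the
#' quantitative heteroplasmy level among carriers only.
#'
#' @param matrix A QC'ed `het_matrix`.
#' @param variant Variant ID (`contig:pos:ref,alt`).
#' @return Named numeric vector over all samples in the matrix (NA when
#'   missing).
#' @export
build_case_only <- function(matrix, variant) {
  if (!variant %in% matrix$variant) stop("unknown variant: ", variant)
  samples <- unique(matrix$sample_id)
  out <- stats::setNames(rep(NA_real_, length(samples)), samples)
  rows <- matrix[matrix$variant == variant &
                   matrix$state == "heteroplasmic", , drop = FALSE]
  out[rows$sample_id] <- rows$fraction
  out
}

#' Case-control heteroplasmy phenotype
#'
#' Cases (1) are samples with any detectable heteroplasmy at the variant;
#' controls (0) only those confidently inferred reference (depth-backed
#' reference state); homoplasmic and no-call samples are missing.
#'
#' @inheritParams build_case_only
#' @return Named 0/1/NA vector over all samples.
#' @export
build_case_control <- function(matrix, variant) {
  if (!variant %in% matrix$variant) stop("unknown variant: ", variant)
  samples <- unique(matrix$sample_id)
  out <- stats::setNames(rep(NA_real_, length(samples)), samples)
  rows <- matrix[matrix$variant == variant, , drop = FALSE]
  out[rows$sample_id[rows$state == "heteroplasmic"]] <- 1
  out[rows$sample_id[rows$state == "reference"]] <- 0
  out
}

#' Recode fasting hours to the supported indicator range
#' @param hours Integer fasting hours; values above 18 recode to 18 and 0
#'   recodes to 1.
#' @return Integer vector in `[1, 18]`.
#' @export
recode_fasting <- function(hours) {
  hours <- as.integer(hours)
  hours[!is.na(hours) & hours > 18L] <- 18L
  hours[!is.na(hours) & hours == 0L] <- 1L
  hours
}

#' Quarterly seasonal knots over a date span
#' @param from,to Date bounds (inclusive), default the packaged span
#'   2007-07-01 through 2010-07-01.
#' @return Date vector at 3-month increments.
#' @export
seasonal_knots <- function(from = as.Date("2007-07-01"),
                           to = as.Date("2010-07-01")) {
  seq(from, to, by = "3 months")
}

#' Build a covariate design matrix for mtDNA phenotype correction
#'
#' Technical terms: blood-draw time expanded in a natural cubic spline
#' basis with 5 degrees of freedom; assessment date expanded in a natural
#' spline with fixed seasonal (quarterly) knots; center and month as
#' indicators; fasting hours recoded to `[1, 18]` and entered as
#' indicators. Blood terms: the continuous blood indices with entries at
#' |Z| > 4 masked to NA. Aliased columns are dropped deterministically
#' (last-in first-dropped) and reported.
#'
#' @param table data.frame with any of the columns `draw_time` (minutes of
#'   day), `assessment_date` (Date), `center`, `month`, `fasting_hours`,
#'   plus blood-index columns named in `blood_cols`.
#' @param terms Which blocks to include: `"technical"`, `"blood"` or both.
#' @param blood_cols Character vector naming blood-index columns.
#' @param knots Seasonal knot dates (see [seasonal_knots()]); outermost
#'   two serve as boundary knots.
#' @param z_mask Mask threshold for blood indices (default 4).
#' @return A list with `X` (design matrix without intercept), `dropped`
#'   (aliased column names), `masked` (count of masked blood entries).
#' @export
build_covariate_design <- function(table,
                                   terms = c("technical", "blood"),
                                   blood_cols = character(),
                                   knots = seasonal_knots(),
                                   z_mask = 4) {
  terms <- match.arg(terms, several.ok = TRUE)
  blocks <- list()
  masked <- 0L
  if ("technical" %in% terms) {
    if (!is.null(table$draw_time)) {
      B <- splines::ns(table$draw_time, df = 5)
      colnames(B) <- paste0("draw_time_ns", 1:ncol(B))
      blocks <- c(blocks, list(B))
    }
    if (!is.null(table$assessment_date)) {
      x <- as.numeric(table$assessment_date)
      kn <- as.numeric(knots)
      B <- splines::ns(x, knots = kn[-c(1, length(kn))],
                       Boundary.knots = kn[c(1, length(kn))])
      colnames(B) <- paste0("date_ns", 1:ncol(B))
      blocks <- c(blocks, list(B))
    }
    for (fac in c("center", "month")) {
      if (!is.null(table[[fac]])) {
        f <- factor(table[[fac]])
        if (nlevels(f) > 1) {
          B <- stats::model.matrix(~f)[, -1, drop = FALSE]
          colnames(B) <- paste0(fac, "_", levels(f)[-1])
          blocks <- c(blocks, list(B))
        }
      }
    }
    if (!is.null(table$fasting_hours)) {
      f <- factor(recode_fasting(table$fasting_hours))
      if (nlevels(f) > 1) {
        B <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(B) <- paste0("fasting_", levels(f)[-1])
        blocks <- c(blocks, list(B))
      }
    }
  }
  if ("blood" %in% terms && length(blood_cols) > 0) {
    B <- as.matrix(table[, blood_cols, drop = FALSE])
    z <- scale(B)
    mask <- !is.na(z) & abs(z) > z_mask
    masked <- sum(mask)
    B[mask] <- NA
    blocks <- c(blocks, list(B))
  }
  if (length(blocks) == 0) stop("no design terms available")
  X <- do.call(cbind, blocks)
  # deterministic aliasing removal: keep the earliest independent columns
  cc <- stats::complete.cases(X)
  qrX <- qr(cbind(1, X[cc, , drop = FALSE]))
  keep_idx <- sort(qrX$pivot[seq_len(qrX$rank)])
  keep_idx <- setdiff(keep_idx, 1L) - 1L  # drop intercept slot
  dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
  list(X = X[, keep_idx, drop = FALSE], dropped = dropped, masked = masked)
}

#' Residualize a phenotype on a covariate design with an F-test gate
#'
#' An F-test compares the full covariate model to the intercept-only
#' model; when its p-value is at or above `gate_alpha` the phenotype is
#' returned untouched (no correction warranted). Otherwise residuals are
#' taken (on the log scale when `log_transform`), the pre-correction mean
#' is added back, and in log mode the result is exponentiated back to the
#' absolute scale. Rows with missing phenotype or covariates pass through
#' as missing.
#'
#' @param y Named numeric phenotype vector (NA = missing).
#' @param design Design list from [build_covariate_design()] or a plain
#'   matrix aligned with `y`.
#' @param log_transform Model `log(y)`?
#' @param gate_alpha F-test gate; the Bonferroni level 0.05/40 mirrors a
#'   40-phenotype correction screen (default).
#' @return A list: `y_corr` (corrected vector), `applied` (did the gate
#'   open), `f_p` (gate p-value).
#' @export
residualize_phenotype <- function(y, design, log_transform = FALSE,
                                  gate_alpha = 0.05 / 40) {
  stopifnot(gate_alpha > 0)
  X <- if (is.list(design) && !is.data.frame(design)) design$X else as.matrix(design)
  if (length(y) != nrow(X)) stop("phenotype and design are not aligned")
  resp <- if (log_transform) log(y) else y
  ok <- !is.na(resp) & stats::complete.cases(X)
  if (sum(ok) <= ncol(X) + 1) stop("insufficient data: fewer rows than design columns")
  fit <- stats::lm(resp[ok] ~ X[ok, , drop = FALSE])
  fs <- summary(fit)$fstatistic
  f_p <- if (is.null(fs)) 1 else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  if (f_p >= gate_alpha) {
    return(list(y_corr = y, applied = FALSE, f_p = unname(f_p)))
  }
  out <- rep(NA_real_, length(y))
  names(out) <- names(y)
  corr <- stats::residuals(fit) + mean(resp[ok])
  if (log_transform) corr <- exp(corr)
  out[ok] <- corr
  list(y_corr = out, applied = TRUE, f_p = unname(f_p))
}

#' Rank-based inverse normal transformation (Blom offset)
#'
#' Maps the value at (tie-averaged) rank r among n non-missing values to
#' the standard normal quantile of `(r - 3/8) / (n + 1/4)`.
#'
#' @param values Numeric vector; NAs preserved.
#' @return Transformed vector.
#' @export
inverse_rank_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  if (length(unique(values[ok])) == 1) stop("degenerate input: all values identical")
  r <- rank(values[ok], ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Coverage-discrepancy phenotypes from per-sample coverage vectors
#'
#' Per sample, median coverage is computed over the DNA-primer, RNA-primer
#' and 7S-DNA (first third) regions; samples in haplogroups with fewer
#' than `min_group` members are excluded; the DNA-primer median is then
#' regressed on each alternative predictor with haplogroup main effects
#' and haplogroup-by-predictor interactions, and the residuals are the
#' discrepancy traits.
#'
#' @param coverages Named list (by sample) of reference-coordinate depth
#'   vectors.
#' @param catalog A `region_catalog`.
#' @param haplogroups Named character vector of per-sample haplogroups.
#' @param min_group Minimum haplogroup size (default 30).
#' @return A list with `traits` (data.frame: sample_id, vs_7s_dna,
#'   vs_rna_primer) and `medians` (the per-region medians).
#' @export
coverage_discrepancy_traits <- function(coverages, catalog, haplogroups,
                                        min_group = 30L) {
  L <- NULL
  med_region <- function(cov, iv) {
    stats::median(cov[interval_positions(iv, length(cov))])
  }
  for (nm in c("dna_primer", "rna_primer", "seven_s_first_third")) {
    if (is.null(catalog[[nm]])) stop("region ", nm, " missing from catalog")
  }
  samples <- names(coverages)
  med <- data.frame(
    sample_id = samples,
    dna_primer = vapply(coverages, med_region, 0, iv = catalog$dna_primer),
    rna_primer = vapply(coverages, med_region, 0, iv = catalog$rna_primer),
    seven_s = vapply(coverages, med_region, 0, iv = catalog$seven_s_first_third),
    haplogroup = haplogroups[samples],
    stringsAsFactors = FALSE)
  tab <- table(med$haplogroup)
  med <- med[med$haplogroup %in% names(tab)[tab >= min_group], , drop = FALSE]
  med$haplogroup <- factor(med$haplogroup)
  resid_of <- function(pred) {
    fit <- stats::lm(dna_primer ~ pred * haplogroup,
                     data = cbind(med, pred = med[[pred]]))
    stats::setNames(stats::residuals(fit), med$sample_id)
  }
  traits <- data.frame(sample_id = med$sample_id,
                       vs_7s_dna = resid_of("seven_s"),
                       vs_rna_primer = resid_of("rna_primer"),
                       stringsAsFactors = FALSE)
  rownames(traits) <- NULL
  list(traits = traits, medians = med)
}

#' Paired heteroplasmy fractions across relative pairs
#'
#' For every variant carried by at least `min_samples` samples, emits one
#' row per relative pair per relationship class with both members'
#' fractions; pairs where either member is missing for the variant are
#' dropped.
#'
#' @param matrix A `het_matrix`.
#' @param pedigree data.frame with columns `id1`, `id2`, `relationship`
#'   (e.g. `"mother_offspring"`, `"father_offspring"`, `"siblings"`).
#' @param min_samples Minimum carriers for a variant to be assessed
#'   (default 5).
#' @return data.frame: variant, relationship, id1, id2, frac1, frac2.
#' @export
transmission_pairs <- function(matrix, pedigree, min_samples = 5L) {
  het <- matrix[matrix$state == "heteroplasmic", , drop = FALSE]
  counts <- table(het$variant)
  variants <- names(counts)[counts >= min_samples]
  out <- list()
  for (v in variants) {
    rows <- matrix[matrix$variant == v, , drop = FALSE]
    # fraction lookup: heteroplasmic -> fraction; reference -> 0; else NA
    f <- stats::setNames(rep(NA_real_, nrow(rows)), rows$sample_id)
    f[rows$state == "heteroplasmic"] <- rows$fraction[rows$state == "heteroplasmic"]
    f[rows$state == "reference"] <- 0
    f1 <- f[pedigree$id1]
    f2 <- f[pedigree$id2]
    ok <- !is.na(f1) & !is.na(f2)
    if (any(ok)) {
      out[[v]] <- data.frame(variant = v,
                             relationship = pedigree$relationship[ok],
                             id1 = pedigree$id1[ok], id2 = pedigree$id2[ok],
                             frac1 = unname(f1[ok]), frac2 = unname(f2[ok]),
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = character(), relationship = character(),
               id1 = character(), id2 = character(), frac1 = numeric(),
               frac2 = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Mean variant counts per age bin, zero-inclusive
#'
#' Individuals without any variant of a class contribute zero counts --
#' excluding them would bias the age trend upward.
#'
#' @param counts data.frame with columns `sample_id`, `class`, `count`
#'   (samples absent for a class default to 0).
#' @param ages Named numeric vector of ages over all samples.
#' @param bins Numeric break points for [cut()] (right-open).
#' @return data.frame: class, bin, n, mean, sem (NA rows for empty bins).
#' @export
age_accrual_summary <- function(counts, ages, bins) {
  if (any(is.na(ages))) stop("every sample needs an age")
  samples <- names(ages)
  classes <- unique(counts$class)
  bin_f <- cut(ages, breaks = bins, right = FALSE, include.lowest = TRUE)
  out <- list()
  for (cl in classes) {
    cc <- counts[counts$class == cl, , drop = FALSE]
    full <- stats::setNames(rep(0, length(samples)), samples)
    full[cc$sample_id] <- cc$count
    for (b in levels(bin_f)) {
      v <- full[samples[!is.na(bin_f) & bin_f == b]]
      out[[length(out) + 1L]] <- data.frame(
        class = cl, bin = b, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pathogenic-carrier vs control contrasts on residualized measurements
#'
#' For each (variant, phenotype) pair with more than `min_carriers`
#' defined carrier values, a two-sample t-test compares carriers against
#' the shared control set; q-values come from Benjamini-Hochberg over all
#' performed tests.
#'
#' @param carrier_sets Named list (by variant) of carrier sample IDs.
#' @param measurements Named list (by phenotype) of named residualized
#'   value vectors.
#' @param control_set Character vector of control sample IDs (samples with
#'   none of the tested variants, reference-confirmed at every site).
#' @param min_carriers Skip pairs with carrier n at or below this
#'   (default 10).
#' @return data.frame: variant, phenotype, n_carrier, n_control,
#'   mean_carrier, mean_control, t, p, q.
#' @export
carrier_contrast <- function(carrier_sets, measurements, control_set,
                             min_carriers = 10L) {
  if (length(control_set) == 0) stop("empty control set")
  rows <- list()
  for (v in names(carrier_sets)) {
    for (ph in names(measurements)) {
      m <- measurements[[ph]]
      xc <- m[intersect(carrier_sets[[v]], names(m))]
      xc <- xc[!is.na(xc)]
      x0 <- m[intersect(control_set, names(m))]
      x0 <- x0[!is.na(x0)]
      if (length(xc) <= min_carriers || length(x0) < 2) next
      tt <- stats::t.test(xc, x0)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, phenotype = ph, n_carrier = length(xc),
        n_control = length(x0), mean_carrier = mean(xc),
        mean_control = mean(x0), t = unname(tt$statistic),
        p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), phenotype = character(),
               n_carrier = integer(), n_control = integer(),
               mean_carrier = numeric(), mean_control = numeric(),
               t = numeric(), p = numeric(), stringsAsFactors = FALSE)
  res$q <- if (nrow(res)) stats::p.adjust(res$p, method = "BH") else numeric(0)
  res
}
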