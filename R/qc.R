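# Post-calling variant- and sample-level QC, common-heteroplasmy
# annotation, and the AD-alt sensitivity filter.
#
# Cell states of the sample x variant heteroplasmy matrix:
#   "heteroplasmic" -- fraction in [0.05, homoplasmy threshold)
#   "homoplasmic"   -- fraction >= homoplasmy threshold
#   "reference"     -- confidently reference (stored fraction 0)
#   "missing"       -- no-call / removed / low depth

#' Variant ID string for a call
#' @param calls A [variant_calls()] table.
#' @return Character vector `contig:pos:ref,alt`.
#' @export
variant_id <- function(calls) {
  paste0(calls$contig, ":", calls$pos, ":", calls$ref, ",", calls$alt)
}

#' Variant-level QC for one sample
#'
#' Applies the post-calling recode ladder: caller-flagged calls become
#' missing; fraction below 0.01 is recoded as reference with stored
#' heteroplasmy 0; fraction in `[0.01, 0.05)` is removed (missing, at high
#' risk of NUMT-derived signal); fraction at or above the homoplasmy
#' threshold is homoplasmic. Sites of interest with no call are inferred
#' reference when site depth reaches `min_site_depth` and missing
#' otherwise.
#'
#' @param calls [variant_calls()] for one sample.
#' @param site_depth Numeric per-position depth vector (reference
#'   coordinates) used for no-call inference.
#' @param sites Optional character vector of variant IDs
#'   (`contig:pos:ref,alt`) that must be represented in the output even
#'   when uncalled.
#' @param hom_threshold Homoplasmy threshold (default 0.95).
#' @param min_site_depth Depth needed to infer reference at an uncalled
#'   site (default 100).
#' @return data.frame with columns `variant`, `pos`, `state`, `fraction`.
#' @export
variant_qc <- function(calls, site_depth, sites = NULL,
                       hom_threshold = 0.95, min_site_depth = 100) {
  if (nrow(calls) > 0 && any(calls$af < 0 | calls$af > 1)) {
    stop("heteroplasmy fraction outside [0, 1]")
  }
  out <- list()
  if (nrow(calls) > 0) {
    state <- character(nrow(calls))
    frac <- calls$af
    flagged <- calls$filters != "PASS" & calls$filters != "."
    state[flagged] <- "missing"
    state[!flagged & calls$af < 0.01] <- "reference"
    frac[!flagged & calls$af < 0.01] <- 0
    state[!flagged & calls$af >= 0.01 & calls$af < 0.05] <- "missing"
    state[!flagged & calls$af >= 0.05 & calls$af < hom_threshold] <- "heteroplasmic"
    state[!flagged & calls$af >= hom_threshold] <- "homoplasmic"
    frac[state == "missing"] <- NA_real_
    out[[1]] <- data.frame(variant = variant_id(calls), pos = calls$pos,
                           state = state, fraction = frac,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(sites)) {
    called <- if (nrow(calls) > 0) variant_id(calls) else character(0)
    uncalled <- setdiff(sites, called)
    if (length(uncalled) > 0) {
      pos <- as.integer(vapply(strsplit(uncalled, ":", fixed = TRUE),
                               `[`, "", 2))
      dp <- site_depth[pos]
      out[[length(out) + 1L]] <- data.frame(
        variant = uncalled, pos = pos,
        state = ifelse(dp >= min_site_depth, "reference", "missing"),
        fraction = ifelse(dp >= min_site_depth, 0, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = character(), pos = integer(), state = character(),
               fraction = numeric(), stringsAsFactors = FALSE)
  res <- res[order(res$pos, res$variant), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect overlapping homoplasmic alleles in a sample's calls
#'
#' TRUE when any site carries two distinct non-reference alleles each at a
#' fraction of 0.5 or more -- a signature of sample mixing.
#' @param calls [variant_calls()] for one sample.
#' @param min_fraction Per-allele fraction for the overlap test.
#' @return Logical scalar.
#' @export
homoplasmy_overlap <- function(calls, min_fraction = 0.5) {
  if (nrow(calls) == 0) return(FALSE)
  hi <- calls[calls$af >= min_fraction, , drop = FALSE]
  any(duplicated(hi$pos))
}

#' Sample-level QC
#'
#' Drops samples with mtDNA copy number below `mtcn_floor` (strict),
#' contamination above `contamination_ceiling` (strict), overlapping
#' homoplasmic alleles, or a processing year in the configured exclusion
#' set. All applicable reasons are recorded.
#'
#' @param records data.frame with columns `sample_id`, `mtcn`,
#'   `contamination`, `homoplasmy_overlap`, and optionally
#'   `processing_year`.
#' @param mtcn_floor Copy-number floor (default 50).
#' @param contamination_ceiling Contamination ceiling (default 0.02).
#' @param excluded_years Integer vector of processing years to drop
#'   (cohort-specific; empty by default).
#' @return The records with added `keep` (logical) and `drop_reasons`
#'   (comma-separated string, empty iff kept).
#' @export
sample_qc <- function(records, mtcn_floor = 50, contamination_ceiling = 0.02,
                      excluded_years = integer()) {
  reasons <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- character(0)
    if (is.na(records$mtcn[i]) || is.na(records$contamination[i])) {
      r <- c(r, "incomplete")
    } else {
      if (records$mtcn[i] < mtcn_floor) r <- c(r, "low_mtcn")
      if (records$contamination[i] > contamination_ceiling) r <- c(r, "contamination")
    }
    if (isTRUE(records$homoplasmy_overlap[i])) r <- c(r, "homoplasmy_overlap")
    if ("processing_year" %in% names(records) &&
        !is.na(records$processing_year[i]) &&
        records$processing_year[i] %in% excluded_years) {
      r <- c(r, "processing_year")
    }
    reasons[[i]] <- r
  }
  records$keep <- lengths(reasons) == 0L
  records$drop_reasons <- vapply(reasons, paste, "", collapse = ",")
  records
}

#' Assemble a heteroplasmy matrix from per-sample QC'ed states
#'
#' @param per_sample Named list (by sample ID) of [variant_qc()] outputs.
#' @return A long-format data.frame of class `het_matrix` with columns
#'   `sample_id`, `variant`, `pos`, `state`, `fraction`.
#' @export
het_matrix <- function(per_sample) {
  stopifnot(length(names(per_sample)) == length(per_sample) ||
              length(per_sample) == 0)
  out <- do.call(rbind, lapply(names(per_sample), function(s) {
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE), per_sample[[s]])
  }))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), variant = character(),
                      pos = integer(), state = character(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("het_matrix", "data.frame")
  out
}

#' Annotate "common low heteroplasmy" variants
#'
#' A variant is flagged when the share of filter-passing samples with a
#' heteroplasmy strictly between 0 and 0.5 reaches `min_prop`.
#'
#' @param matrix A `het_matrix` after [variant_qc()] (and sample QC).
#' @param min_prop Flagging proportion (default 0.001, i.e. 0.1%).
#' @return Character vector of flagged variant IDs.
#' @export
annotate_common_low_het <- function(matrix, min_prop = 0.001) {
  if (nrow(matrix) == 0) stop("empty heteroplasmy matrix")
  n_samples <- length(unique(matrix$sample_id))
  low <- matrix$state == "heteroplasmic" &
    matrix$fraction > 0 & matrix$fraction < 0.5
  counts <- table(matrix$variant[low])
  names(counts)[counts / n_samples >= min_prop]
}

#' Define the common-heteroplasmy variant set
#'
#' Restricts the common-low-heteroplasmy annotation to variants carried
#' as heteroplasmies by at least `min_carriers` samples.
#'
#' @param matrix A `het_matrix`.
#' @param flagged Variant IDs from [annotate_common_low_het()].
#' @param min_carriers Minimum heteroplasmic carriers (default 500).
#' @return Character vector of variant IDs.
#' @export
define_common_heteroplasmies <- function(matrix, flagged, min_carriers = 500) {
  het <- matrix$state == "heteroplasmic"
  counts <- table(matrix$variant[het])
  keep <- names(counts)[counts >= min_carriers]
  intersect(flagged, keep)
}

#' AD-alt sensitivity filter
#'
#' Marks calls missing when the alternate-allele depth falls strictly
#' below the sample's mean nuclear coverage -- a guard against NUMT-derived
#' support, since a true mtDNA allele should outnumber reads from any
#' two-copy nuclear segment.
#'
#' @param calls [variant_calls()] with AD present on every call.
#' @param nuc_mean Mean nuclear coverage of the sample.
#' @return The calls with a logical `ad_missing` column.
#' @export
ad_alt_filter <- function(calls, nuc_mean) {
  if (nrow(calls) > 0 && any(is.na(calls$ad))) stop("AD missing on some calls")
  calls$ad_missing <- calls$ad < nuc_mean
  calls
}

#' Write a sample QC report as TSV
#' @param records Output of [sample_qc()].
#' @param path Output path.
#' @export
write_qc_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a heteroplasmy matrix as sparse TSV
#' @param matrix A `het_matrix`.
#' @param path Output path.
#' @export
write_het_matrix <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a heteroplasmy matrix from sparse TSV
#' @param path TSV written by [write_het_matrix()].
#' @return A `het_matrix`.
#' @export
read_het_matrix <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("het_matrix", "data.frame")
  out
}
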