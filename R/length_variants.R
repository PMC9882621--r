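# Poly-C/G length-heteroplasmy genotyping at the CSBII chrM:302 locus.
#
# The reference CSBII motif on the forward strand is AA C7 T C5 GC; the
# "302" tract is the first C-run (adjacent to position 302), which in the
# opposite-strand G_m A G_n nomenclature is the G_n tract. Insertion
# alleles chrM:302:A,AC / A,ACC / A,ACCC extend this run to 8 / 9 / 10.

TRACT_REGEX <- "AA(CCC+[CT]CC+)GC"

#' Map a 302-adjacent tract length to its allele label
#' @param run_302 Length of the C-run adjacent to position 302 (>= 3).
#' @return `"reference"` for 7, `"chrM:302:A,AC"` for 8,
#'   `"chrM:302:A,ACC"` for 9, `"chrM:302:A,ACCC"` for 10, else `"other"`.
#' @export
allele_class_from_tracts <- function(run_302) {
  stopifnot(all(run_302 >= 3))
  lab <- c(`7` = "reference", `8` = "chrM:302:A,AC",
           `9` = "chrM:302:A,ACC", `10` = "chrM:302:A,ACCC")
  out <- lab[as.character(run_302)]
  out[is.na(out)] <- "other"
  unname(out)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Classify the CSBII tract structure of one read
#'
#' Applies the anchored pattern `AA(CCC+[CT]CC+)GC` to the forward-strand
#' read sequence (reverse-strand alignments are reverse-complemented
#' first) and extracts the two poly-C run lengths and the spacer base.
#' Reads that do not match return `NULL` (classified NA upstream). The
#' caller must pre-filter to reads whose alignment completely spans the
#' locus.
#'
#' @param sequence Read sequence (character scalar).
#' @param reverse_strand Reverse-complement before matching?
#' @return `NULL`, or a list with `run_302` (first C-run length), `spacer`
#'   (`"C"` or `"T"`), `run_m` (second C-run length) and `allele_label`.
#' @export
classify_read_tracts <- function(sequence, reverse_strand = FALSE) {
  if (reverse_strand) sequence <- .revcomp(sequence)
  m <- regexec(TRACT_REGEX, sequence)[[1]]
  if (m[1] == -1L) return(NULL)
  inner <- regmatches(sequence, list(m))[[1]][2]
  runs <- regexec("^(C+)([CT])(C+)$", inner)[[1]]
  # the spacer is the single non-run base; with a C spacer the regex engine
  # makes the split ambiguous, so re-derive runs from the T position when
  # present, else treat the whole tract as run lengths split by the engine
  t_at <- as.integer(regexpr("T", inner, fixed = TRUE))
  if (t_at > 0) {
    run_302 <- t_at - 1L
    spacer <- "T"
    run_m <- nchar(inner) - t_at
  } else {
    # all-C tract: regex split per pattern minimums (CCC+ then [CT] then CC+)
    run_302 <- nchar(inner) - 3L
    spacer <- "C"
    run_m <- 2L
  }
  if (run_302 < 3L || run_m < 2L) return(NULL)
  list(run_302 = run_302, spacer = spacer, run_m = run_m,
       allele_label = allele_class_from_tracts(run_302))
}

#' Does a read alignment completely span a locus?
#' @param reads An [aligned_reads()] table.
#' @param locus Single-row [genomic_interval()].
#' @param L Genome length (wrap-aware).
#' @return Logical vector.
#' @export
read_spans_locus <- function(reads, locus, L) {
  n <- nrow(reads)
  out <- logical(n)
  for (i in seq_len(n)) {
    ops <- parse_cigar(reads$cigar[i])
    ref_len <- sum(ops$len[ops$op %in% c("M", "D", "=", "X")])
    covered <- .wrap(reads$left_pos[i] + 0:(ref_len - 1L), L)
    out[i] <- all(interval_positions(locus, L) %in% covered)
  }
  out
}

#' Per-cell length-variant composition profiles
#'
#' Reads with barcodes outside the whitelist are dropped; cells with fewer
#' than `min_reads` locus-spanning reads are excluded. For each retained
#' cell the fractions of the top `n_top` globally most common
#' `(run_m, run_302)` variants are reported, with all remaining reads
#' (including unclassifiable, NA reads) aggregated as `"other"`.
#'
#' @param reads [aligned_reads()] with `cell_barcode` set, pre-filtered to
#'   locus-spanning alignments.
#' @param whitelist Character vector of valid cell barcodes.
#' @param min_reads Minimum spanning reads per retained cell (default 20).
#' @param n_top Number of named variants (default 3).
#' @param top_variants Optional fixed character vector of
#'   `"run_m,run_302"` keys (e.g. `c("6,8", "6,9", "6,10")`) overriding the
#'   data-driven top set.
#' @return data.frame with columns `cell`, `variant`, `fraction`, `count`;
#'   per-cell fractions sum to 1.
#' @export
cell_length_profiles <- function(reads, whitelist, min_reads = 20L,
                                 n_top = 3L, top_variants = NULL) {
  if (length(whitelist) == 0) stop("empty cell whitelist")
  reads <- reads[!is.na(reads$cell_barcode) &
                   reads$cell_barcode %in% whitelist, , drop = FALSE]
  cls <- lapply(reads$sequence, classify_read_tracts)
  key <- vapply(cls, function(x) {
    if (is.null(x)) NA_character_ else paste(x$run_m, x$run_302, sep = ",")
  }, "")
  tab <- data.frame(cell = reads$cell_barcode, key = key,
                    stringsAsFactors = FALSE)
  counts <- table(tab$cell)
  keep_cells <- names(counts)[counts >= min_reads]
  tab <- tab[tab$cell %in% keep_cells, , drop = FALSE]
  if (nrow(tab) == 0) {
    return(data.frame(cell = character(), variant = character(),
                      fraction = numeric(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(top_variants)) {
    glob <- sort(table(tab$key[!is.na(tab$key)]), decreasing = TRUE)
    top_variants <- names(glob)[seq_len(min(n_top, length(glob)))]
  }
  out <- do.call(rbind, lapply(split(tab, tab$cell), function(d) {
    n <- nrow(d)
    cnt <- vapply(top_variants, function(v) sum(!is.na(d$key) & d$key == v),
                  integer(1))
    other <- n - sum(cnt)
    data.frame(cell = d$cell[1],
               variant = c(top_variants, "other"),
               fraction = c(cnt, other) / n,
               count = c(cnt, other),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bulk length-variant profile from per-cell profiles
#'
#' Sums allele counts over retained cells and renormalizes the fractions.
#' @param profiles Output of [cell_length_profiles()].
#' @return data.frame with columns `variant`, `fraction`, `count`.
#' @export
bulk_profile <- function(profiles) {
  if (nrow(profiles) == 0 || sum(profiles$count) == 0) {
    stop("zero total read count; no retained cells")
  }
  agg <- stats::aggregate(count ~ variant, data = profiles, FUN = sum)
  agg$fraction <- agg$count / sum(agg$count)
  agg[order(match(agg$variant, unique(profiles$variant))),
      c("variant", "fraction", "count")]
}

#' Per-sample chrM:302 composition from variant calls
#'
#' The reference fraction is `1 - sum(heteroplasmy of any allele at the
#' locus)`, floored at 0; samples without calls get reference fraction 1;
#' samples with locus depth below `min_depth` are excluded (returns
#' `NULL`); alleles other than the three named insertion alleles pool into
#' `"other"`; missing allele fractions impute as 0.
#'
#' @param sample_calls [variant_calls()] at the chrM:302 site for one
#'   sample (possibly empty).
#' @param locus_depth Depth at chrM:302 after local realignment.
#' @param min_depth Exclusion threshold (default 100).
#' @return Named numeric vector over
#'   `c("reference", "chrM:302:A,AC", "chrM:302:A,ACC", "chrM:302:A,ACCC",
#'   "other")` summing to 1, or `NULL` when the sample is excluded.
#' @export
composition_from_calls <- function(sample_calls, locus_depth,
                                   min_depth = 100) {
  if (locus_depth < min_depth) return(NULL)
  named <- c("chrM:302:A,AC", "chrM:302:A,ACC", "chrM:302:A,ACCC")
  out <- stats::setNames(numeric(5),
                         c("reference", named, "other"))
  if (nrow(sample_calls) > 0) {
    frac <- sample_calls$af
    frac[is.na(frac)] <- 0  # missing allele fractions impute as 0
    tot <- sum(frac)
    if (tot > 1 + 1e-6) stop("allele fractions at locus sum to ", tot, " > 1")
    ids <- variant_id(sample_calls)
    for (v in named) out[v] <- sum(frac[ids == v])
    out["other"] <- sum(frac[!(ids %in% named)])
  }
  out["reference"] <- max(0, 1 - sum(out[-1]))
  s <- sum(out)
  if (abs(s - 1) > 1e-9) out <- out / s  # renormalize after flooring
  out
}

#' Write composition profiles as TSV (unit, variant, fraction, count)
#' @param profiles data.frame from [cell_length_profiles()] or assembled
#'   sample compositions.
#' @param path Output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
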