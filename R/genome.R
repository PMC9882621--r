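#' Circular genome representation
#'
#' A minimal container for a single circular contig (typically the 16,569 bp
#' human mtDNA). Positions are 1-based inclusive; position arithmetic is
#' modular in the genome length, so intervals may wrap across the
#' linearization origin.
#'
#' @param contig Contig name, e.g. `"chrM"`.
#' @param sequence Character scalar over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @param circular Logical; circular contigs support wrap-aware intervals.
#' @return An object of class `circular_genome` with fields `contig`,
#'   `sequence`, `length` and `circular`.
#' @export
circular_genome <- function(contig, sequence, circular = TRUE) {
  stopifnot(is.character(contig), length(contig) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(contig = contig, sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp (%s)\n", x$contig, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.circular_genome <- function(x) x$length

#' Extract bases from a circular genome
#'
#' Wrap-aware subsequence extraction: when `start > end` on a circular
#' genome the interval runs through the origin.
#'
#' @param g A [circular_genome()].
#' @param start,end 1-based inclusive positions.
#' @return Character scalar with the requested bases.
#' @export
genome_seq <- function(g, start, end) {
  stopifnot(inherits(g, "circular_genome"))
  L <- g$length
  if (start < 1 || start > L || end < 1 || end > L) {
    stop("positions out of range [1, ", L, "]")
  }
  if (start <= end) {
    substr(g$sequence, start, end)
  } else {
    if (!g$circular) stop("start > end on a linear contig")
    paste0(substr(g$sequence, start, L), substr(g$sequence, 1, end))
  }
}

#' Genomic intervals with circular wrap semantics
#'
#' @param contig Contig name(s).
#' @param start,end 1-based inclusive bounds. On a circular contig
#'   `start > end` denotes an interval wrapping the origin.
#' @param wraps Logical; inferred as `start > end` when missing.
#' @return A data.frame of class `genomic_intervals` with columns
#'   `contig`, `start`, `end`, `wraps`.
#' @export
genomic_interval <- function(contig, start, end, wraps = NULL) {
  n <- max(length(contig), length(start), length(end))
  contig <- rep_len(as.character(contig), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (is.null(wraps)) wraps <- start > end else wraps <- rep_len(wraps, n)
  out <- data.frame(contig = contig, start = start, end = end, wraps = wraps,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Number of bases covered by a (possibly wrapping) interval
#' @param iv A single-row [genomic_interval()].
#' @param L Contig length, required for wrapping intervals.
#' @return Integer width in bases.
#' @export
interval_width <- function(iv, L = NULL) {
  if (iv$wraps[1]) {
    if (is.null(L)) stop("contig length required for wrapping interval")
    (L - iv$start[1] + 1L) + iv$end[1]
  } else {
    iv$end[1] - iv$start[1] + 1L
  }
}

#' Wrap-aware interval membership
#'
#' @param pos Integer positions to test.
#' @param iv A single-row [genomic_interval()].
#' @return Logical vector: is each position inside the interval?
#' @export
in_interval <- function(pos, iv) {
  if (iv$wraps[1]) pos >= iv$start[1] | pos <= iv$end[1]
  else pos >= iv$start[1] & pos <= iv$end[1]
}

#' Enumerate the positions covered by a (possibly wrapping) interval
#' @inheritParams interval_width
#' @return Integer vector of covered positions in circular order.
#' @export
interval_positions <- function(iv, L = NULL) {
  if (iv$wraps[1]) {
    if (is.null(L)) stop("contig length required for wrapping interval")
    c(seq.int(iv$start[1], L), seq.int(1L, iv$end[1]))
  } else {
    seq.int(iv$start[1], iv$end[1])
  }
}

#' Pad and merge NUMT intervals on linear nuclear contigs
#'
#' Extends each interval by `pad` bases on both sides, clips to the contig
#' bounds, and merges overlapping or touching (gap zero) intervals on the
#' same contig. This is the standard preparation step for a reference-NUMT
#' blocklist: padding absorbs the soft edges of homology tracts so that
#' nuclear reads near a NUMT are handled by the NUMT decoy rather than
#' leaking onto the mtDNA.
#'
#' @param intervals A [genomic_interval()] table on linear contigs.
#' @param pad Non-negative padding in bases applied to both sides.
#' @param contig_lengths Optional named integer vector used to clip the
#'   right edge; the left edge is always clipped at 1.
#' @return A merged, sorted `genomic_intervals` table covering exactly the
#'   union of the padded inputs.
#' @export
prepare_numt_intervals <- function(intervals, pad, contig_lengths = NULL) {
  stopifnot(pad >= 0)
  if (any(intervals$wraps) || any(intervals$start > intervals$end)) {
    stop("malformed interval: start > end on a linear contig")
  }
  if (nrow(intervals) == 0L) return(genomic_interval(character(), integer(), integer()))
  st <- pmax(1L, intervals$start - as.integer(pad))
  en <- intervals$end + as.integer(pad)
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[intervals$contig]
    if (any(is.na(lim))) stop("contig length missing for some intervals")
    en <- pmin(en, as.integer(lim))
  }
  pieces <- lapply(split(seq_len(nrow(intervals)), intervals$contig), function(idx) {
    r <- IRanges::reduce(IRanges::IRanges(start = st[idx], end = en[idx]),
                         min.gapwidth = 1L)
    data.frame(contig = intervals$contig[idx[1]],
               start = IRanges::start(r), end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[order(names(pieces))])
  rownames(out) <- NULL
  genomic_interval(out$contig, out$start, out$end)
}

#' Build a shifted copy of a circular genome
#'
#' Linearizing a circular genome creates artificial breakpoints where read
#' coverage collapses. Calling the control region against a rotated
#' ("shifted") copy of the molecule moves the breakpoint away from the
#' region of interest. The shifted sequence begins at original position
#' `shift + 1`; positions map by modular arithmetic in both directions.
#'
#' @param g A [circular_genome()].
#' @param shift Rotation in bases, `0 <= shift < length(g)`. Default is
#'   `floor(L / 2)`, which maximally separates the two breakpoints.
#' @return A list with `genome` (the rotated [circular_genome()]),
#'   `to_shifted(p)` and `to_original(p)` (vectorized position maps, both
#'   bijections on `[1, L]`), and `shift`.
#' @export
build_shifted_genome <- function(g, shift = floor(g$length / 2)) {
  stopifnot(inherits(g, "circular_genome"))
  L <- g$length
  if (shift < 0 || shift >= L) stop("shift must be in [0, L)")
  shift <- as.integer(shift)
  seq_shifted <- if (shift == 0L) g$sequence else
    paste0(substr(g$sequence, shift + 1L, L), substr(g$sequence, 1L, shift))
  list(
    genome = circular_genome(paste0(g$contig, "_shifted"), seq_shifted,
                             circular = g$circular),
    to_shifted = function(p) ((p - shift - 1L) %% L) + 1L,
    to_original = function(p) ((p + shift - 1L) %% L) + 1L,
    shift = shift
  )
}

# Default rCRS-style control-region annotation. Coordinates follow the
# standard rCRS feature annotations; all are overridable through `config`.
.default_region_coords <- function() {
  list(
    control_region = c(16024L, 576L),   # wraps the origin
    CSBII          = c(299L, 315L),
    CSBIII         = c(346L, 363L),
    LSP            = c(407L, 445L),
    origin_H_zone  = c(110L, 191L),     # heavy-strand replication origin zone
    seven_s_span   = c(16106L, 191L),   # 7S DNA third strand, wraps origin
    locus_302      = c(300L, 318L)      # chrM:302 length-variant classifier locus
  )
}

#' Build the non-coding-region catalog for an mtDNA genome
#'
#' Returns named intervals for the control region, CSBII, CSBIII, the light
#' strand promoter (LSP), the heavy-strand origin zone, the 7S DNA span and
#' its first third, the DNA-primer and RNA-primer regions, and the chrM:302
#' classifier locus. Derived regions follow the D-loop geometry: the
#' DNA-primer region lies between the heavy-strand origin and CSBII, the
#' RNA-primer region between CSBIII and the LSP, and the 7S "first third"
#' is the first third (by base count, rounded down) of the 7S span counted
#' from the boundary nearer the linearization origin.
#'
#' @param g A [circular_genome()] for the mtDNA contig.
#' @param config Optional named list overriding any entry of the packaged
#'   defaults; each value is `c(start, end)` in 1-based inclusive
#'   coordinates (start > end means wrapping).
#' @return A list of class `region_catalog` of single-row
#'   [genomic_interval()] tables.
#' @export
region_catalog_default <- function(g, config = list()) {
  stopifnot(inherits(g, "circular_genome"))
  coords <- utils::modifyList(.default_region_coords(), config)
  L <- g$length
  iv <- function(se) {
    if (any(se < 1) || any(se > L)) stop("region outside genome bounds [1, ", L, "]")
    genomic_interval(g$contig, se[1], se[2])
  }
  cat_ <- lapply(coords, iv)
  # DNA primer: between heavy-strand origin and CSBII
  dna_primer <- genomic_interval(g$contig,
                                 cat_$origin_H_zone$end + 1L,
                                 cat_$CSBII$start - 1L)
  # RNA primer: between CSBIII and LSP
  rna_primer <- genomic_interval(g$contig,
                                 cat_$CSBIII$end + 1L,
                                 cat_$LSP$start - 1L)
  seven_s_third <- region_first_third(cat_$seven_s_span, L)
  out <- c(cat_, list(dna_primer = dna_primer, rna_primer = rna_primer,
                      seven_s_first_third = seven_s_third))
  # primer and 7S regions must not overlap one another
  combos <- utils::combn(c("dna_primer", "rna_primer", "seven_s_span"), 2)
  for (j in seq_len(ncol(combos))) {
    a <- interval_positions(out[[combos[1, j]]], L)
    b <- interval_positions(out[[combos[2, j]]], L)
    if (length(intersect(a, b)) > 0) {
      stop("regions ", combos[1, j], " and ", combos[2, j], " overlap")
    }
  }
  class(out) <- "region_catalog"
  out
}

#' First third of a circular interval, counted from the wrap-proximal end
#'
#' The span is enumerated in circular order and the first `floor(width/3)`
#' positions are taken starting from whichever endpoint lies nearer the
#' linearization origin (position 1).
#'
#' @param iv Single-row [genomic_interval()].
#' @param L Contig length.
#' @return A single-row `genomic_intervals` table.
#' @export
region_first_third <- function(iv, L) {
  w <- interval_width(iv, L)
  k <- w %/% 3L
  pos <- interval_positions(iv, L)
  # circular distance of each endpoint to position 1
  dist1 <- function(p) min((p - 1L) %% L, (1L - p) %% L)
  if (dist1(iv$end[1]) < dist1(iv$start[1])) {
    keep <- rev(pos)[seq_len(k)]
    genomic_interval(iv$contig[1], keep[k], keep[1])
  } else {
    keep <- pos[seq_len(k)]
    genomic_interval(iv$contig[1], keep[1], keep[k])
  }
}

#' @export
print.region_catalog <- function(x, ...) {
  cat("<region_catalog>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s:%d-%d%s\n", nm, x[[nm]]$contig, x[[nm]]$start,
                x[[nm]]$end, if (x[[nm]]$wraps) " (wraps)" else ""))
  }
  invisible(x)
}
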