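# Pileup-based heteroplasmy estimation with NUMT-decoy competitive read
# placement, dual-pass (primary + shifted) calling across the circular
# control region, and the coverage / copy-number formulas.

# SAM flag bits
FLAG_UNMAPPED  <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L

.wrap <- function(p, L) ((p - 1L) %% L) + 1L

#' Parse a CIGAR string into operations
#' @param cigar CIGAR string (ops M, I, D, S, H, =, X supported).
#' @return data.frame with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDSH=X])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDSH=X])", cigar))[[1]]
  if (length(parts) == 0 || sum(nchar(parts)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  data.frame(op = substr(parts, nchar(parts), nchar(parts)),
             len = as.integer(substr(parts, 1, nchar(parts) - 1L)),
             stringsAsFactors = FALSE)
}

.query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])

#' Competitive placement of reads against the mtDNA and NUMT decoys
#'
#' Each read is assigned to the target (one mtDNA consensus plus zero or
#' more NUMT decoy genomes) giving the fewest mismatches under exact k-mer
#' seeding followed by ungapped extension on the circular sequence. Ties
#' are assigned to the NUMT decoy -- the conservative choice against false
#' low-level heteroplasmy. Reads with no seed hit anywhere are flagged
#' unmapped.
#'
#' @param reads An [aligned_reads()] table (sequences used; prior
#'   coordinates ignored).
#' @param mt_genome The mtDNA [circular_genome()] (reference or consensus).
#' @param decoys List of NUMT decoy [circular_genome()]s (possibly empty).
#' @param k Seed length for exact k-mer anchoring.
#' @return The reads with `contig`, `left_pos` and the unmapped flag
#'   updated, plus columns `target` (`"mt"`, decoy name, or `NA`) and
#'   `mismatches`.
#' @export
place_reads <- function(reads, mt_genome, decoys = list(), k = 15L) {
  targets <- c(list(mt = mt_genome), decoys)
  if (length(targets) == 0) stop("empty target set")
  if (is.null(names(targets)) || any(names(targets) == "")) {
    stop("decoys must be named")
  }
  n <- nrow(reads)
  if (n == 0) {
    reads$target <- character(0); reads$mismatches <- integer(0)
    return(reads)
  }
  rlen <- nchar(reads$sequence)
  if (any(rlen < k)) stop("reads shorter than seed length k = ", k)
  # three seeds per read: start, middle, end
  offs <- cbind(1L, pmax(1L, (rlen - k) %/% 2L + 1L), rlen - k + 1L)
  seed_of <- function(j) substr(reads$sequence, offs[, j], offs[, j] + k - 1L)
  seeds <- lapply(1:3, seed_of)

  best_mm <- matrix(NA_integer_, n, length(targets),
                    dimnames = list(NULL, names(targets)))
  best_pos <- matrix(NA_integer_, n, length(targets))
  raw_reads <- lapply(reads$sequence, charToRaw)
  for (t in seq_along(targets)) {
    g <- targets[[t]]
    ext <- if (g$circular) substr(g$sequence, 1L, min(g$length, max(rlen))) else ""
    doubled <- paste0(g$sequence, ext)
    kmers <- substring(doubled, 1:(nchar(doubled) - k + 1L), k:nchar(doubled))
    hit <- lapply(seeds, function(s) match(s, kmers))  # first hit per seed
    for (i in seq_len(n)) {
      cands <- integer(0)
      for (j in 1:3) {
        h <- hit[[j]][i]
        if (!is.na(h)) {
          p <- h - offs[i, j] + 1L
          if (g$circular) p <- .wrap(p, g$length)
          # a placement must fit on a linear contig
          if (p >= 1L && p + rlen[i] - 1L <= nchar(doubled)) cands <- c(cands, p)
        }
      }
      cands <- unique(cands)
      if (length(cands) == 0) next
      mm <- vapply(cands, function(p) {
        tseq <- substr(doubled, p, p + rlen[i] - 1L)
        sum(charToRaw(tseq) != raw_reads[[i]])
      }, integer(1))
      b <- which.min(mm)
      best_mm[i, t] <- mm[b]
      best_pos[i, t] <- cands[b]
    }
  }
  target <- character(n)
  for (i in seq_len(n)) {
    mm <- best_mm[i, ]
    if (all(is.na(mm))) {
      target[i] <- NA_character_
      reads$flag[i] <- bitwOr(reads$flag[i], FLAG_UNMAPPED)
      next
    }
    lowest <- min(mm, na.rm = TRUE)
    winners <- names(targets)[which(!is.na(mm) & mm == lowest)]
    # tie rule: any non-mt winner takes the read
    pick <- if (length(winners) > 1 && any(winners != "mt"))
      winners[winners != "mt"][1] else winners[1]
    target[i] <- pick
    reads$contig[i] <- targets[[pick]]$contig
    reads$left_pos[i] <- best_pos[i, match(pick, names(targets))]
  }
  reads$target <- target
  reads$mismatches <- best_mm[cbind(seq_len(n),
                                    ifelse(is.na(target), 1L,
                                           match(target, names(targets))))]
  reads$mismatches[is.na(target)] <- NA_integer_
  reads
}

#' Pileup reads over a circular genome and call variants
#'
#' Depth excludes duplicate, secondary, and unmapped reads and bases below
#' `min_base_quality`. SNV fraction is alt count over depth; insertions and
#' deletions are parsed from the CIGAR and left-aligned. A call is emitted
#' whenever the alternate count reaches `min_alt_reads`; all fraction
#' thresholds are deferred to post-calling QC.
#'
#' @param reads An [aligned_reads()] table aligned to `g` (coordinates may
#'   run past the origin; they wrap modularly).
#' @param g The target [circular_genome()].
#' @param min_base_quality Minimum Phred base quality contributing to the
#'   pileup (default 20).
#' @param min_alt_reads Minimum alternate reads to emit a call (default 2).
#' @return A list with `coverage` (numeric vector, one depth per genome
#'   position) and `calls` (a [variant_calls()] table).
#' @export
pileup_and_call <- function(reads, g, min_base_quality = 20L,
                            min_alt_reads = 2L) {
  L <- g$length
  depth <- numeric(L)
  snv <- new.env(parent = emptyenv())    # key "pos|base" -> count
  indel <- new.env(parent = emptyenv())  # key "pos|ref|alt" -> count
  bump <- function(env, key) {
    assign(key, (if (exists(key, envir = env)) get(key, envir = env) else 0L) + 1L,
           envir = env)
  }
  excl <- bitwAnd(reads$flag,
                  FLAG_DUPLICATE + FLAG_SECONDARY + FLAG_UNMAPPED) != 0L
  use <- which(!excl)
  ref_raw <- charToRaw(g$sequence)
  # vectorized fast path: gapless reads (single M operation)
  simple <- use[grepl("^\\d+M$", reads$cigar[use])]
  if (length(simple) > 0) {
    lens <- nchar(reads$sequence[simple])
    if (any(lens != as.integer(sub("M$", "", reads$cigar[simple])))) {
      stop("malformed read: CIGAR query length does not match sequence length")
    }
    idx <- .wrap(unlist(lapply(seq_along(simple), function(j) {
      reads$left_pos[simple[j]] + 0:(lens[j] - 1L)
    })), L)
    seq_raw_all <- charToRaw(paste(reads$sequence[simple], collapse = ""))
    qual_all <- charToRaw(paste(reads$qualities[simple], collapse = ""))
    ok <- as.integer(qual_all) - 33L >= min_base_quality
    depth <- depth + tabulate(idx[ok], nbins = L)
    mism <- which(ok & (seq_raw_all != ref_raw[idx]))
    for (w in mism) {
      bump(snv, paste0(idx[w], "|", rawToChar(seq_raw_all[w])))
    }
    use <- setdiff(use, simple)
  }
  for (i in use) {
    ops <- parse_cigar(reads$cigar[i])
    if (.query_len(ops) != nchar(reads$sequence[i])) {
      stop("malformed read ", reads$read_id[i],
           ": CIGAR query length does not match sequence length")
    }
    seq_raw <- charToRaw(reads$sequence[i])
    qual <- utf8ToInt(reads$qualities[i]) - 33L
    rp <- reads$left_pos[i]  # reference cursor (unwrapped)
    qp <- 1L
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        idx <- .wrap(rp:(rp + len - 1L), L)
        q <- qual[qp:(qp + len - 1L)]
        ok <- q >= min_base_quality
        depth[idx[ok]] <- depth[idx[ok]] + 1
        mism <- ok & (seq_raw[qp:(qp + len - 1L)] != ref_raw[idx])
        for (w in which(mism)) {
          bump(snv, paste0(idx[w], "|", rawToChar(seq_raw[qp + w - 1L])))
        }
        rp <- rp + len; qp <- qp + len
      } else if (op == "I") {
        anchor <- .wrap(rp - 1L, L)
        ins <- rawToChar(seq_raw[qp:(qp + len - 1L)])
        anchor_base <- substr(g$sequence, anchor, anchor)
        nm <- normalize_call(anchor, anchor_base, paste0(anchor_base, ins),
                             g$sequence)
        bump(indel, paste(nm$pos, nm$ref, nm$alt, sep = "|"))
        qp <- qp + len
      } else if (op == "D") {
        anchor <- .wrap(rp - 1L, L)
        del <- genome_seq(g, .wrap(rp, L), .wrap(rp + len - 1L, L))
        anchor_base <- substr(g$sequence, anchor, anchor)
        nm <- normalize_call(anchor, paste0(anchor_base, del), anchor_base,
                             g$sequence)
        bump(indel, paste(nm$pos, nm$ref, nm$alt, sep = "|"))
        rp <- rp + len
      } else if (op == "S") {
        qp <- qp + len
      } else if (op == "H") {
        # consumes neither
      }
    }
  }
  calls <- list()
  for (key in ls(snv)) {
    cnt <- get(key, envir = snv)
    if (cnt < min_alt_reads) next
    kv <- strsplit(key, "|", fixed = TRUE)[[1]]
    p <- as.integer(kv[1])
    dp <- depth[p]
    if (dp <= 0) next
    calls[[length(calls) + 1L]] <-
      variant_calls(g$contig, p, substr(g$sequence, p, p), kv[2],
                    min(1, cnt / dp), as.integer(round(dp)), cnt)
  }
  for (key in ls(indel)) {
    cnt <- get(key, envir = indel)
    if (cnt < min_alt_reads) next
    kv <- strsplit(key, "|", fixed = TRUE)[[1]]
    p <- as.integer(kv[1])
    dp <- depth[p]
    if (dp <= 0) next
    calls[[length(calls) + 1L]] <-
      variant_calls(g$contig, p, kv[2], kv[3], min(1, cnt / dp),
                    as.integer(round(dp)), as.integer(min(cnt, dp)))
  }
  calls <- if (length(calls)) do.call(rbind, calls) else variant_calls()
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  list(coverage = depth, calls = calls)
}

#' Merge primary-pass and shifted-pass calls
#'
#' Shifted-pass calls are lifted back to reference coordinates; calls
#' inside the control region are taken exclusively from the shifted pass
#' and all other calls exclusively from the primary pass, so no position is
#' reported from both passes.
#'
#' @param calls_primary [variant_calls()] in reference coordinates.
#' @param calls_shifted [variant_calls()] in shifted coordinates.
#' @param catalog A `region_catalog` supplying the control region.
#' @param shifted A shifted-genome object from [build_shifted_genome()]
#'   (or a bare shift in bases).
#' @param contig Reference contig name for the lifted calls.
#' @param L Genome length (required when `shifted` is a bare shift).
#' @return Merged [variant_calls()] in reference coordinates.
#' @export
dual_pass_merge <- function(calls_primary, calls_shifted, catalog, shifted,
                            contig = "chrM", L = NULL) {
  if (is.numeric(shifted)) {
    if (is.null(L)) stop("L required when passing a bare shift")
    to_original <- function(p) ((p + as.integer(shifted) - 1L) %% L) + 1L
  } else {
    to_original <- shifted$to_original
  }
  cr <- catalog$control_region
  if (nrow(calls_shifted) > 0) {
    calls_shifted$pos <- to_original(calls_shifted$pos)
    calls_shifted$contig <- contig
  }
  keep_s <- calls_shifted[in_interval(calls_shifted$pos, cr), , drop = FALSE]
  keep_p <- calls_primary[!in_interval(calls_primary$pos, cr), , drop = FALSE]
  out <- rbind(keep_p, keep_s)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Merge primary and shifted per-base coverage
#'
#' Control-region positions take the shifted-pass depth (rotated back to
#' reference coordinates); all other positions take the primary depth.
#' @param cov_primary Reference-coordinate depth vector.
#' @param cov_shifted Shifted-coordinate depth vector.
#' @param catalog A `region_catalog`.
#' @param shifted A shifted-genome object from [build_shifted_genome()].
#' @return Reference-coordinate depth vector.
#' @export
dual_pass_coverage <- function(cov_primary, cov_shifted, catalog, shifted) {
  L <- length(cov_primary)
  stopifnot(length(cov_shifted) == L)
  out <- cov_primary
  in_cr <- in_interval(seq_len(L), catalog$control_region)
  out[in_cr] <- cov_shifted[shifted$to_shifted(which(in_cr))]
  out
}

#' Mean nuclear DNA coverage from flag-level read counts
#'
#' `(total_mapped - singletons - mate_discordant - duplicates) *
#'  read_length / genome_length`, clamped at zero (with a warning) if the
#' exclusion counts exceed the mapped total. The count definitions follow
#' samtools flagstat categories and are documented inputs.
#'
#' @param total_mapped,singletons,mate_discordant,duplicates Read counts.
#' @param read_length Read length in bases.
#' @param genome_length Nuclear genome length in bases.
#' @return Mean depth (x coverage).
#' @export
mean_nuc_coverage <- function(total_mapped, singletons, mate_discordant,
                              duplicates, read_length, genome_length) {
  stopifnot(total_mapped >= 0, singletons >= 0, mate_discordant >= 0,
            duplicates >= 0)
  if (genome_length <= 0) stop("genome_length must be positive")
  num <- total_mapped - singletons - mate_discordant - duplicates
  if (num < 0) {
    warning("exclusion counts exceed total mapped reads; clamping coverage at 0")
    num <- 0
  }
  num * read_length / genome_length
}

#' mtDNA copy number per diploid genome
#'
#' `2 * (mean or median mtDNA coverage) / mean nuclear coverage`. The mean
#' is the default numerator.
#'
#' @param mt_coverage_summary List or named vector with `mean` and
#'   `median` mtDNA coverage.
#' @param nuc_mean Mean nuclear DNA coverage (must be positive).
#' @param use_mean Use mean (default) or median mtDNA coverage.
#' @return Copies per diploid genome.
#' @export
compute_mtcn <- function(mt_coverage_summary, nuc_mean, use_mean = TRUE) {
  if (nuc_mean <= 0) stop("nuc_mean must be positive")
  num <- if (use_mean) mt_coverage_summary[["mean"]] else
    mt_coverage_summary[["median"]]
  2 * num / nuc_mean
}
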