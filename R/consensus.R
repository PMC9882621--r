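# Per-sample self-reference construction and liftover.
#
# A sample's consensus ("self-reference") is the canonical mtDNA with the
# sample's homoplasmic mtDNA calls and homozygous nuclear (NUMT) calls
# applied as edits. Variants are then re-called against the consensus and
# everything -- calls and per-base coverage -- is lifted back to reference
# coordinates through an edit-indexed coordinate map.

#' Select consensus edits from a sample's variant calls
#'
#' Homoplasmic mtDNA calls (heteroplasmy at or above `het_threshold`) and
#' homozygous-alternate nuclear calls become edits of the per-sample
#' self-reference. Overlapping candidates are resolved by keeping the
#' higher-fraction call, ties broken leftmost.
#'
#' @param calls A [variant_calls()] table; nuclear homozygous calls are
#'   marked by `source = "nuclear_homozygous"` in an optional `source`
#'   column (absent column means all calls are mtDNA).
#' @param g The reference [circular_genome()] used to validate ref alleles.
#' @param het_threshold Homoplasmy threshold in `(0.5, 1]`; default 0.95.
#' @return A data.frame of class `consensus_edits` with columns `pos`,
#'   `ref`, `alt`, `source`, `source_fraction`, sorted and non-overlapping.
#' @export
select_consensus_edits <- function(calls, g, het_threshold = 0.95) {
  stopifnot(het_threshold > 0.5, het_threshold <= 1)
  src <- if ("source" %in% names(calls)) calls$source else
    rep("mtDNA_homoplasmy", nrow(calls))
  keep <- (src == "nuclear_homozygous") | (calls$af >= het_threshold)
  cand <- calls[keep, , drop = FALSE]
  src <- src[keep]
  if (nrow(cand) == 0) return(.empty_edits())
  # validate against the reference
  for (i in seq_len(nrow(cand))) {
    rl <- nchar(cand$ref[i])
    obs <- genome_seq(g, cand$pos[i], ((cand$pos[i] + rl - 2L) %% g$length) + 1L)
    if (obs != cand$ref[i]) {
      stop("reference mismatch at position ", cand$pos[i], ": call asserts ",
           cand$ref[i], " but reference has ", obs)
    }
  }
  # resolve overlaps: higher fraction wins, then leftmost
  ord <- order(-cand$af, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  src <- src[ord]
  sel <- logical(nrow(cand))
  covered <- integer(0)
  for (i in seq_len(nrow(cand))) {
    span <- cand$pos[i]:(cand$pos[i] + nchar(cand$ref[i]) - 1L)
    if (!any(span %in% covered)) {
      sel[i] <- TRUE
      covered <- c(covered, span)
    }
  }
  cand <- cand[sel, , drop = FALSE]
  src <- src[sel]
  o <- order(cand$pos)
  out <- data.frame(pos = cand$pos[o], ref = cand$ref[o], alt = cand$alt[o],
                    source = src[o], source_fraction = cand$af[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_edits", "data.frame")
  out
}

.empty_edits <- function() {
  out <- data.frame(pos = integer(), ref = character(), alt = character(),
                    source = character(), source_fraction = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_edits", "data.frame")
  out
}

#' Create a consensus-edit table directly
#' @param pos,ref,alt Edit site and alleles (1-based reference position).
#' @param source Edit provenance label.
#' @param source_fraction Heteroplasmy fraction of the originating call.
#' @return A `consensus_edits` data.frame sorted by position.
#' @export
consensus_edits <- function(pos, ref, alt, source = "mtDNA_homoplasmy",
                            source_fraction = 1) {
  n <- length(pos)
  out <- data.frame(pos = as.integer(pos), ref = as.character(ref),
                    alt = as.character(alt),
                    source = rep_len(source, n),
                    source_fraction = rep_len(source_fraction, n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (n > 1) {
    ends <- out$pos + nchar(out$ref) - 1L
    if (any(out$pos[-1] <= ends[-n])) stop("overlapping edits")
  }
  class(out) <- c("consensus_edits", "data.frame")
  out
}

#' Apply edits to build the per-sample consensus genome
#'
#' @param g Reference [circular_genome()].
#' @param edits A `consensus_edits` table (sorted, non-overlapping,
#'   ref alleles matching `g`).
#' @return A list with `genome` (the consensus [circular_genome()]) and
#'   `map` (a `coordinate_map` recording every edit).
#' @export
build_consensus <- function(g, edits) {
  stopifnot(inherits(g, "circular_genome"))
  n <- nrow(edits)
  if (n > 1) {
    ends <- edits$pos + nchar(edits$ref) - 1L
    if (any(edits$pos[-1] <= ends[-n])) stop("overlapping edits")
  }
  pieces <- character(0)
  cursor <- 1L
  cons_start <- integer(n)
  cons_cursor <- 1L
  for (i in seq_len(n)) {
    p <- edits$pos[i]
    rl <- nchar(edits$ref[i])
    if (substr(g$sequence, p, p + rl - 1L) != edits$ref[i]) {
      stop("edit ref allele mismatch at position ", p)
    }
    if (p > cursor) {
      pieces <- c(pieces, substr(g$sequence, cursor, p - 1L))
      cons_cursor <- cons_cursor + (p - cursor)
    }
    pieces <- c(pieces, edits$alt[i])
    cons_start[i] <- cons_cursor
    cons_cursor <- cons_cursor + nchar(edits$alt[i])
    cursor <- p + rl
  }
  pieces <- c(pieces, substr(g$sequence, cursor, g$length))
  seq_cons <- paste(pieces, collapse = "")
  map <- structure(list(
    edits = edits, cons_start = cons_start,
    ref_length = g$length, cons_length = nchar(seq_cons),
    ref_seq = g$sequence, contig = g$contig
  ), class = "coordinate_map")
  stopifnot(map$cons_length ==
              map$ref_length + sum(nchar(edits$alt) - nchar(edits$ref)))
  list(genome = circular_genome(g$contig, seq_cons, circular = g$circular),
       map = map)
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("<coordinate_map> reference %d bp -> consensus %d bp, %d edit(s)\n",
              x$ref_length, x$cons_length, nrow(x$edits)))
  invisible(x)
}

#' Lift positions between reference and consensus coordinates
#'
#' Positions outside edit footprints map exactly. A consensus position
#' inside inserted bases maps to the left-anchoring reference position with
#' flag `"inside_insertion"`; a reference position deleted in the consensus
#' maps to the left-anchoring consensus position with flag
#' `"inside_deletion"`; all other positions get flag `"exact"`.
#'
#' @param map A `coordinate_map` from [build_consensus()].
#' @param pos Integer positions in the source coordinate space.
#' @param direction `"ref_to_cons"` or `"cons_to_ref"`.
#' @return A data.frame with columns `pos` (lifted position) and `flag`.
#' @export
lift_position <- function(map, pos,
                          direction = c("cons_to_ref", "ref_to_cons")) {
  direction <- match.arg(direction)
  src_len <- if (direction == "cons_to_ref") map$cons_length else map$ref_length
  if (any(pos < 1 | pos > src_len)) stop("position out of range [1, ", src_len, "]")
  e <- map$edits
  rl <- nchar(e$ref)
  al <- nchar(e$alt)
  if (direction == "cons_to_ref") {
    src_start <- map$cons_start; src_w <- al
    dst_start <- e$pos; dst_w <- rl
    inside_flag <- "inside_insertion"
  } else {
    src_start <- e$pos; src_w <- rl
    dst_start <- map$cons_start; dst_w <- al
    inside_flag <- "inside_deletion"
  }
  cum_off <- cumsum(dst_w - src_w)  # offset accumulated through each edit
  i <- findInterval(pos, src_start)  # last edit starting at or before pos
  out_pos <- pos
  out_flag <- rep("exact", length(pos))
  hit <- which(i > 0L)
  if (length(hit) > 0) {
    ih <- i[hit]
    within <- pos[hit] <= src_start[ih] + src_w[ih] - 1L
    after <- hit[!within]
    out_pos[after] <- pos[after] + cum_off[i[after]]
    inb <- hit[within]
    if (length(inb) > 0) {
      ii <- i[inb]
      off <- pos[inb] - src_start[ii]
      exact <- off < dst_w[ii]
      out_pos[inb[exact]] <- dst_start[ii[exact]] + off[exact]
      out_pos[inb[!exact]] <- dst_start[ii[!exact]] + dst_w[ii[!exact]] - 1L
      out_flag[inb[!exact]] <- inside_flag
    }
  }
  data.frame(pos = out_pos, flag = out_flag, stringsAsFactors = FALSE)
}

#' Normalize a variant call (parsimony trim + left alignment)
#'
#' Shared suffix then prefix bases are trimmed and indels are shifted to
#' their leftmost representation against the reference sequence, matching
#' standard VCF normalization so that poly-C length alleles are anchored
#' consistently.
#'
#' @param pos,ref,alt The call to normalize (1-based reference position).
#' @param ref_seq Reference sequence string used for left-shifting.
#' @return list(pos, ref, alt).
#' @export
normalize_call <- function(pos, ref, alt, ref_seq) {
  if (nchar(ref) == 0 || nchar(alt) == 0) stop("normalization error: empty allele")
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn > 1 && an > 1 && substr(ref, rn, rn) == substr(alt, an, an)) {
      ref <- substr(ref, 1, rn - 1L); alt <- substr(alt, 1, an - 1L)
    } else if ((rn > 1 || an > 1) &&
               substr(ref, rn, rn) == substr(alt, an, an) && pos > 1) {
      # pure indel whose last bases agree: shift left
      prev <- substr(ref_seq, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1, rn - 1L))
      alt <- paste0(prev, substr(alt, 1, an - 1L))
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Lift a consensus-space variant call to reference coordinates
#'
#' Calls not overlapping any consensus edit are position-shifted only.
#' A call at an edited site is re-expressed against the reference allele by
#' composing the edit with the call (the consensus "reference" allele there
#' is the edit's alt); emitted alleles are normalized via [normalize_call()].
#'
#' @param map A `coordinate_map`.
#' @param call One-row [variant_calls()] table expressed in consensus
#'   coordinates and alleles.
#' @return A [variant_calls()] table in reference coordinates.
#' @export
lift_variant_call <- function(map, call) {
  stopifnot(nrow(call) == 1)
  e <- map$edits
  q <- call$pos
  q_end <- q + nchar(call$ref) - 1L
  rl <- nchar(e$ref); al <- nchar(e$alt)
  ce_start <- map$cons_start; ce_end <- map$cons_start + al - 1L
  hit <- which(ce_start <= q_end & ce_end >= q)
  if (length(hit) == 0) {
    lift <- lift_position(map, q, "cons_to_ref")
    nm <- normalize_call(lift$pos, call$ref, call$alt, map$ref_seq)
    return(variant_calls(call$contig, nm$pos, nm$ref, nm$alt,
                         call$af, call$dp, call$ad, call$filters))
  }
  i <- hit[1]
  # Re-express against the reference: the consensus slice the call replaces
  # corresponds (through edit i) to the reference allele e$ref[i]. The
  # composed call asserts that a fraction af of molecules carry the call's
  # alt in place of the whole edited slice.
  if (q == ce_start[i] && q_end == ce_end[i]) {
    composed_alt <- call$alt
  } else {
    # partial overlap: substitute the call's alt into the edit's alt slice
    rel_s <- q - ce_start[i] + 1L
    rel_e <- q_end - ce_start[i] + 1L
    composed_alt <- paste0(substr(e$alt[i], 1, rel_s - 1L), call$alt,
                           substr(e$alt[i], rel_e + 1L, al[i]))
  }
  nm <- normalize_call(e$pos[i], e$ref[i], composed_alt, map$ref_seq)
  if (nchar(nm$ref) == 0 || nchar(nm$alt) == 0) stop("normalization error")
  variant_calls(call$contig, nm$pos, nm$ref, nm$alt,
                call$af, call$dp, call$ad, call$filters)
}

#' Lift a full consensus-space call set, re-emitting consensus edits
#'
#' In addition to lifting each consensus-space call via
#' [lift_variant_call()], every consensus edit is re-emitted as a
#' reference-coordinate call with heteroplasmy
#' `1 - sum(fractions of lifted calls at that site asserting a different
#' allele)`, floored at 0. A sample homoplasmic for an edit therefore
#' reappears at fraction 1.0 after liftover, and residual heteroplasmy at
#' an edited site is split between the competing alleles.
#'
#' @param map A `coordinate_map`.
#' @param calls [variant_calls()] in consensus coordinates (possibly empty).
#' @param edit_dp Depth to report for re-emitted edit calls; defaults to the
#'   maximum call depth at the site or `NA`.
#' @return [variant_calls()] in reference coordinates, sorted by position.
#' @export
lift_sample_calls <- function(map, calls, edit_dp = NA_integer_) {
  lifted <- if (nrow(calls) == 0) variant_calls() else
    do.call(rbind, lapply(seq_len(nrow(calls)),
                          function(i) lift_variant_call(map, calls[i, ])))
  e <- map$edits
  if (nrow(e) > 0) {
    contig <- if (!is.null(map$contig)) map$contig else
      if (nrow(calls) > 0) calls$contig[1] else "chrM"
    emitted <- lapply(seq_len(nrow(e)), function(i) {
      nm <- normalize_call(e$pos[i], e$ref[i], e$alt[i], map$ref_seq)
      competing <- 0
      if (nrow(lifted) > 0) {
        same_site <- lifted$pos == nm$pos & lifted$ref == nm$ref &
          lifted$alt != nm$alt
        competing <- sum(lifted$af[same_site])
      }
      frac <- max(0, 1 - competing)
      dp <- edit_dp
      if (is.na(dp) && nrow(lifted) > 0) {
        at_site <- lifted$pos == nm$pos
        if (any(at_site)) dp <- max(lifted$dp[at_site], na.rm = TRUE)
      }
      variant_calls(contig, nm$pos, nm$ref, nm$alt, frac, dp,
                    as.integer(round(frac * ifelse(is.na(dp), 0, dp))), "PASS")
    })
    # drop emitted edits whose allele is already asserted by a lifted call
    emitted <- do.call(rbind, emitted)
    if (nrow(lifted) > 0) {
      dup <- paste(emitted$pos, emitted$ref, emitted$alt) %in%
        paste(lifted$pos, lifted$ref, lifted$alt)
      emitted <- emitted[!dup, , drop = FALSE]
    }
    lifted <- rbind(lifted, emitted)
  }
  # composed calls whose alt collapses to the reference allele assert the
  # reference fraction; they feed the remainder computation above but are
  # not variants
  lifted <- lifted[lifted$ref != lifted$alt, , drop = FALSE]
  out <- lifted[order(lifted$pos, lifted$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Lift per-base consensus coverage to reference coordinates
#'
#' Un-edited and substituted positions copy their depth; reference
#' positions deleted in the consensus inherit the depth of the left
#' flanking consensus base; depths at inserted consensus bases are dropped.
#'
#' @param map A `coordinate_map`.
#' @param cov_consensus Numeric depth vector of consensus length.
#' @return Numeric depth vector of reference length.
#' @export
lift_coverage <- function(map, cov_consensus) {
  if (length(cov_consensus) != map$cons_length) {
    stop("coverage length ", length(cov_consensus),
         " does not match consensus length ", map$cons_length)
  }
  out <- numeric(map$ref_length)
  lifted <- lift_position(map, seq_len(map$ref_length), "ref_to_cons")
  out[] <- cov_consensus[lifted$pos]
  out
}

# --- chain-style serialization --------------------------------------------

#' Serialize a coordinate map as chain-style text
#'
#' Blocks of `match`/`sub`/`ins`/`del` lengths describing the alignment of
#' reference to consensus, plus the edit table, in a plain-text format that
#' round-trips through [read_chain()].
#' @param map A `coordinate_map`.
#' @param path Output path.
#' @export
write_chain <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("chain ref_length=%d cons_length=%d",
                     map$ref_length, map$cons_length), con)
  for (i in seq_len(nrow(map$edits))) {
    writeLines(sprintf("edit\t%d\t%s\t%s\t%s\t%.6g", map$edits$pos[i],
                       map$edits$ref[i], map$edits$alt[i],
                       map$edits$source[i], map$edits$source_fraction[i]), con)
  }
  invisible(path)
}

#' Read a chain-style coordinate map written by [write_chain()]
#' @param path Chain file path.
#' @param g The reference [circular_genome()] (for the reference sequence).
#' @return A `coordinate_map`.
#' @export
read_chain <- function(path, g) {
  lines <- readLines(path)
  edits_ln <- lines[startsWith(lines, "edit\t")]
  if (length(edits_ln) == 0) {
    ed <- .empty_edits()
  } else {
    f <- strsplit(edits_ln, "\t", fixed = TRUE)
    ed <- consensus_edits(
      pos = as.integer(vapply(f, `[`, "", 2)),
      ref = vapply(f, `[`, "", 3), alt = vapply(f, `[`, "", 4),
      source = vapply(f, `[`, "", 5),
      source_fraction = as.numeric(vapply(f, `[`, "", 6)))
  }
  build_consensus(g, ed)$map
}
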