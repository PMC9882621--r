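#' Read a single-contig genome from FASTA
#'
#' Circularity is annotated through a `circular=true` token in the FASTA
#' header line.
#'
#' @param path FASTA file path.
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single-contig FASTA, found ", length(ss))
  header <- names(ss)[1]
  circular <- grepl("circular=true", header, fixed = TRUE)
  contig <- strsplit(header, "[ \t]")[[1]][1]
  circular_genome(contig, as.character(ss[[1]]), circular = circular)
}

#' Write a genome to FASTA
#' @param g A [circular_genome()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$sequence)
  names(ss) <- paste0(g$contig, if (g$circular) " circular=true" else "")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read intervals from BED (0-based half-open on disk)
#' @param path BED file path.
#' @return A [genomic_interval()] table in 1-based inclusive coordinates.
#' @export
read_bed <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("contig", "start0", "end0"))[, 1:3]
  genomic_interval(tb$contig, tb$start0 + 1L, tb$end0)
}

#' Write intervals to BED (converted to 0-based half-open)
#' @param intervals A [genomic_interval()] table (non-wrapping).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$wraps)) stop("BED cannot represent wrapping intervals")
  utils::write.table(
    data.frame(intervals$contig, intervals$start - 1L, intervals$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region catalog from a key = contig:start-end config file
#' @param path Config file; `#` comments and blank lines ignored.
#' @return Named list of `c(start, end)` coordinate pairs suitable for
#'   the `config` argument of [region_catalog_default()].
#' @export
read_region_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed region config line: ", ln)
    m <- regmatches(kv[2], regexec("^\\s*\\S+:(\\d+)-(\\d+)\\s*$", kv[2]))[[1]]
    if (length(m) != 3) stop("malformed region value: ", kv[2])
    out[[trimws(kv[1])]] <- c(as.integer(m[2]), as.integer(m[3]))
  }
  out
}

# --- VCF -------------------------------------------------------------------
# A deliberately narrow VCF surface: single-sample records with the
# FORMAT fields AF (allele fraction), DP (site depth), AD (alt depth) and
# FT (per-call filter string). Standard column layout so files round-trip
# through bcftools and vcfR.

#' Construct a variant-call table
#'
#' @param contig,pos,ref,alt Site and alleles (1-based positions).
#' @param af Heteroplasmy / allele fraction in `[0, 1]`.
#' @param dp Site depth (reads).
#' @param ad Alternate-allele depth (reads).
#' @param filters Per-call filter string; `"PASS"` when clean.
#' @return A data.frame of class `variant_calls`.
#' @export
variant_calls <- function(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          af = numeric(), dp = integer(), ad = integer(),
                          filters = rep("PASS", length(pos))) {
  out <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    af = as.numeric(af), dp = as.integer(dp),
                    ad = as.integer(ad), filters = as.character(filters),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0) {
    if (any(out$ad > out$dp, na.rm = TRUE)) stop("AD exceeds DP")
    if (any(out$af < 0 | out$af > 1, na.rm = TRUE)) stop("AF outside [0,1]")
  }
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Write variant calls as a single-sample VCF
#' @param calls A [variant_calls()] table.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @export
write_vcf <- function(calls, path, sample_id = "SAMPLE",
                      contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mitohet",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Allele fraction (heteroplasmy)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="Alternate allele depth">',
    '##FORMAT=<ID=FT,Number=1,Type=String,Description="Per-call filter">'
  ), con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_id), collapse = "\t"), con)
  if (nrow(calls) > 0) {
    gt <- ifelse(calls$af >= 0.95, "1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:AF:DP:AD:FT\t%s:%.6g:%d:%d:%s",
                       calls$contig, calls$pos, calls$ref, calls$alt,
                       calls$filters, gt, calls$af, calls$dp, calls$ad,
                       calls$filters), con)
  }
  invisible(path)
}

#' Read a single-sample VCF written by [write_vcf()] (or any VCF carrying
#' AF/DP/AD in the first sample's FORMAT fields)
#' @param path VCF path.
#' @return A [variant_calls()] table.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(variant_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  get_fmt <- function(row, key) {
    keys <- strsplit(row[9], ":", fixed = TRUE)[[1]]
    vals <- strsplit(row[10], ":", fixed = TRUE)[[1]]
    i <- match(key, keys)
    if (is.na(i)) NA_character_ else vals[i]
  }
  variant_calls(
    contig = vapply(f, `[`, "", 1),
    pos = as.integer(vapply(f, `[`, "", 2)),
    ref = vapply(f, `[`, "", 4),
    alt = vapply(f, `[`, "", 5),
    af = as.numeric(vapply(f, get_fmt, "", key = "AF")),
    dp = as.integer(vapply(f, get_fmt, "", key = "DP")),
    ad = as.integer(vapply(f, get_fmt, "", key = "AD")),
    filters = vapply(f, `[`, "", 7)
  )
}

#' Write per-base coverage as TSV (contig, position, depth)
#' @param cov Numeric depth vector over positions `1..length(cov)`.
#' @param contig Contig name.
#' @param path Output path.
#' @export
write_coverage_tsv <- function(cov, contig, path) {
  utils::write.table(
    data.frame(contig = contig, pos = seq_along(cov), depth = cov),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-base coverage from TSV
#' @param path TSV with columns contig, pos, depth.
#' @return Numeric depth vector ordered by position.
#' @export
read_coverage_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tb$depth[order(tb$pos)]
}

# --- SAM -------------------------------------------------------------------
# Aligned reads live in a plain data.frame ("aligned_reads"): read_id,
# contig, left_pos, cigar, sequence, qualities (Phred+33 string), flag
# (SAM bit flag), cell_barcode (optional, NA when absent).

#' Construct an aligned-read table
#' @param read_id,contig,left_pos,cigar,sequence Core SAM-like fields
#'   (1-based `left_pos`).
#' @param qualities Phred+33 quality strings; defaults to `"I"` (Q40) runs.
#' @param flag SAM bit flags (0x400 duplicate, 0x100 secondary, 0x4
#'   unmapped, 0x800 supplementary); defaults to 0.
#' @param cell_barcode Optional per-read cell barcodes.
#' @return A data.frame of class `aligned_reads`.
#' @export
aligned_reads <- function(read_id, contig, left_pos, cigar, sequence,
                          qualities = strrep("I", nchar(sequence)),
                          flag = 0L, cell_barcode = NA_character_) {
  n <- length(read_id)
  out <- data.frame(read_id = as.character(read_id),
                    contig = rep_len(as.character(contig), n),
                    left_pos = as.integer(left_pos),
                    cigar = as.character(cigar),
                    sequence = as.character(sequence),
                    qualities = rep_len(as.character(qualities), n),
                    flag = rep_len(as.integer(flag), n),
                    cell_barcode = rep_len(as.character(cell_barcode), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Write reads as SAM text
#' @param reads An [aligned_reads()] table.
#' @param path Output path.
#' @param contig_lengths Named integer vector for `@SQ` headers.
#' @export
write_sam <- function(reads, path, contig_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  cb <- ifelse(is.na(reads$cell_barcode), "",
               paste0("\tCB:Z:", reads$cell_barcode))
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s%s",
                     reads$read_id, reads$flag, reads$contig, reads$left_pos,
                     reads$cigar, reads$sequence, reads$qualities, cb), con)
  invisible(path)
}

#' Read SAM text into an aligned-read table
#'
#' Parses the eleven mandatory SAM columns plus the `CB:Z` barcode tag.
#' @param path SAM path.
#' @return An [aligned_reads()] table.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(aligned_reads(character(), character(), integer(), character(),
                         character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  cb <- vapply(f, function(row) {
    tag <- grep("^CB:Z:", row[-(1:11)], value = TRUE)
    if (length(tag)) sub("^CB:Z:", "", tag[1]) else NA_character_
  }, "")
  aligned_reads(
    read_id = vapply(f, `[`, "", 1),
    contig = vapply(f, `[`, "", 3),
    left_pos = as.integer(vapply(f, `[`, "", 4)),
    cigar = vapply(f, `[`, "", 6),
    sequence = vapply(f, `[`, "", 10),
    qualities = vapply(f, `[`, "", 11),
    flag = as.integer(vapply(f, `[`, "", 2)),
    cell_barcode = cb
  )
}
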