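# Per-sample and cohort pipeline orchestration.
#
# Per-sample flow: NUMT-aware read placement -> dual-pass (primary +
# shifted) calling against the canonical reference -> consensus edit
# selection -> self-reference construction -> dual-pass re-calling
# against the consensus -> liftover of calls and coverage back to
# reference coordinates -> copy number and sample QC record.

#' Default pipeline configuration
#' @param L Genome length (used for the default shift).
#' @param ... Overrides for any field: `shift`, `het_threshold`,
#'   `min_base_quality`, `min_alt_reads`, `seed_k`, `min_site_depth`,
#'   `mtcn_floor`, `contamination_ceiling`, `excluded_years`,
#'   `min_carriers`, `use_mean_mtcn`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(L = 16569L, ...) {
  cfg <- utils::modifyList(list(
    shift = as.integer(floor(L / 2)), het_threshold = 0.95,
    min_base_quality = 20L, min_alt_reads = 2L, seed_k = 15L,
    min_site_depth = 100, mtcn_floor = 50, contamination_ceiling = 0.02,
    excluded_years = integer(), min_carriers = 500L, use_mean_mtcn = TRUE
  ), list(...))
  stopifnot(cfg$het_threshold > 0.5, cfg$het_threshold <= 1,
            cfg$shift >= 0, cfg$shift < L)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# one dual-pass calling round against a target genome
.dual_pass_round <- function(reads, target, catalog, cfg) {
  shifted <- build_shifted_genome(target, cfg$shift %% target$length)
  primary <- pileup_and_call(reads, target, cfg$min_base_quality,
                             cfg$min_alt_reads)
  # shifted pass: rotate intact alignments; re-place clipped reads so the
  # soft-clipped bases at the linearization breakpoint are recovered
  sreads <- reads
  sreads$left_pos <- shifted$to_shifted(sreads$left_pos)
  clipped <- grepl("S", sreads$cigar, fixed = TRUE)
  if (any(clipped)) {
    rep_ <- place_reads(reads[clipped, , drop = FALSE], shifted$genome,
                        k = cfg$seed_k)
    placed <- !is.na(rep_$target) & rep_$target == "mt"
    rep_$cigar[placed] <- paste0(nchar(rep_$sequence[placed]), "M")
    sreads[clipped, c("left_pos", "cigar", "flag")] <-
      rep_[, c("left_pos", "cigar", "flag")]
  }
  spass <- pileup_and_call(sreads, shifted$genome, cfg$min_base_quality,
                           cfg$min_alt_reads)
  calls <- dual_pass_merge(primary$calls, spass$calls, catalog, shifted,
                           contig = target$contig)
  coverage <- dual_pass_coverage(primary$coverage, spass$coverage, catalog,
                                 shifted)
  list(calls = calls, coverage = coverage)
}

#' Run the full per-sample pipeline
#'
#' @param reads [aligned_reads()] for one sample, aligned to (or at least
#'   sequenced from) the reference contig.
#' @param reference The canonical mtDNA [circular_genome()].
#' @param decoys Named list of NUMT decoy genomes (possibly empty).
#' @param catalog A `region_catalog` for `reference`.
#' @param config A [pipeline_config()].
#' @param nuc_mean Mean nuclear coverage of the sample (for copy number);
#'   NA skips the mtCN computation.
#' @param contamination Externally estimated contamination fraction
#'   (default 0).
#' @param sample_id Sample label.
#' @return list(calls, coverage, mtcn, qc_record, consensus, log). Calls
#'   and coverage are in reference coordinates.
#' @export
run_sample_pipeline <- function(reads, reference, decoys = list(),
                                catalog, config = pipeline_config(reference$length),
                                nuc_mean = NA_real_, contamination = 0,
                                sample_id = "sample") {
  log <- list(input_reads = nrow(reads))
  placed <- place_reads(reads, reference, decoys, k = config$seed_k)
  is_mt <- !is.na(placed$target) & placed$target == "mt"
  mt <- placed[is_mt, , drop = FALSE]
  # keep the input alignments (they may carry indel CIGARs); placement is
  # only used to split mtDNA reads from NUMT-derived reads
  orig <- reads[match(mt$read_id, reads$read_id), , drop = FALSE]
  same_contig <- orig$contig == reference$contig
  mt$left_pos[same_contig] <- orig$left_pos[same_contig]
  mt$cigar[same_contig] <- orig$cigar[same_contig]
  log$mt_reads <- nrow(mt)
  log$decoy_reads <- sum(!is.na(placed$target) & placed$target != "mt")
  log$unmapped_reads <- sum(is.na(placed$target))

  round1 <- .dual_pass_round(mt, reference, catalog, config)
  log$round1_calls <- nrow(round1$calls)

  edits <- select_consensus_edits(round1$calls, reference,
                                  het_threshold = config$het_threshold)
  log$consensus_edits <- nrow(edits)
  cons <- build_consensus(reference, edits)

  length_preserving <- nrow(edits) == 0 ||
    all(nchar(edits$ref) == nchar(edits$alt))
  mt2 <- mt
  if (!length_preserving) {
    # indel edits change coordinates: re-place reads on the consensus
    rep_ <- place_reads(mt, cons$genome, k = config$seed_k)
    keep <- !is.na(rep_$target) & rep_$target == "mt"
    rep_$cigar[keep] <- paste0(nchar(rep_$sequence[keep]), "M")
    mt2 <- rep_[keep, , drop = FALSE]
  }
  cons_catalog <- catalog
  cons_catalog$control_region$contig <- cons$genome$contig
  round2 <- .dual_pass_round(mt2, cons$genome, cons_catalog, config)
  log$round2_calls <- nrow(round2$calls)

  final_calls <- lift_sample_calls(cons$map, round2$calls)
  if (nrow(final_calls) > 0) final_calls$contig <- reference$contig
  final_cov <- lift_coverage(cons$map, round2$coverage)
  # re-emitted consensus edits with no competing call carry no depth of
  # their own; report the lifted site depth
  na_dp <- is.na(final_calls$dp)
  final_calls$dp[na_dp] <- as.integer(round(final_cov[final_calls$pos[na_dp]]))
  final_calls$ad[na_dp] <- as.integer(round(final_calls$af[na_dp] *
                                              final_calls$dp[na_dp]))
  log$final_calls <- nrow(final_calls)

  mtcn <- NA_real_
  if (!is.na(nuc_mean)) {
    mtcn <- compute_mtcn(list(mean = mean(final_cov),
                              median = stats::median(final_cov)),
                         nuc_mean, use_mean = config$use_mean_mtcn)
  }
  qc_record <- data.frame(
    sample_id = sample_id, mtcn = mtcn, contamination = contamination,
    homoplasmy_overlap = homoplasmy_overlap(final_calls),
    stringsAsFactors = FALSE)
  list(calls = final_calls, coverage = final_cov, mtcn = mtcn,
       qc_record = qc_record, consensus = cons, log = log)
}

#' Write the per-sample pipeline outputs to a directory
#' @param result Output of [run_sample_pipeline()].
#' @param dir Output directory (created if needed).
#' @param sample_id Sample label used in file names.
#' @param reference The reference genome (for headers).
#' @export
write_sample_outputs <- function(result, dir, sample_id, reference) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- stats::setNames(reference$length, reference$contig)
  write_vcf(result$calls, file.path(dir, paste0(sample_id, ".vcf")),
            sample_id = sample_id, contig_lengths = cl)
  write_coverage_tsv(result$coverage, reference$contig,
                     file.path(dir, paste0(sample_id, ".coverage.tsv")))
  write_chain(result$consensus$map,
              file.path(dir, paste0(sample_id, ".chain.txt")))
  write_qc_report(result$qc_record,
                  file.path(dir, paste0(sample_id, ".qc.tsv")))
  invisible(dir)
}

#' Run the cohort aggregation pipeline
#'
#' Builds the heteroplasmy matrix from per-sample calls and coverage,
#' applies sample QC, annotates common heteroplasmies, constructs
#' case-only and case-control phenotypes and the corrected copy-number
#' phenotype, and emits transmission pairs when a pedigree is supplied.
#'
#' @param sample_results Named list (by sample ID) of
#'   [run_sample_pipeline()] outputs (or lists with `calls`, `coverage`,
#'   `qc_record`).
#' @param covariates Optional data.frame with `sample_id` plus covariate
#'   columns for [build_covariate_design()].
#' @param pedigree Optional pedigree for [transmission_pairs()].
#' @param config A [pipeline_config()].
#' @return list(matrix, qc, common_variants, case_only, case_control,
#'   mtcn, mtcn_corr, transmission, log).
#' @export
run_cohort_pipeline <- function(sample_results, covariates = NULL,
                                pedigree = NULL,
                                config = pipeline_config()) {
  if (length(sample_results) < 2) stop("cohort pipeline needs >= 2 samples")
  log <- list(n_samples = length(sample_results))
  qc <- do.call(rbind, lapply(sample_results, `[[`, "qc_record"))
  qc <- sample_qc(qc, mtcn_floor = config$mtcn_floor,
                  contamination_ceiling = config$contamination_ceiling,
                  excluded_years = config$excluded_years)
  kept <- qc$sample_id[qc$keep]
  log$n_kept <- length(kept)
  all_sites <- unique(unlist(lapply(sample_results[kept], function(r)
    variant_id(r$calls))))
  per_sample <- lapply(sample_results[kept], function(r) {
    variant_qc(r$calls, r$coverage, sites = all_sites,
               hom_threshold = config$het_threshold,
               min_site_depth = config$min_site_depth)
  })
  matrix <- het_matrix(per_sample)
  flagged <- if (length(all_sites)) annotate_common_low_het(matrix) else character(0)
  common <- define_common_heteroplasmies(matrix, flagged,
                                         min_carriers = config$min_carriers)
  log$n_common <- length(common)
  case_only <- lapply(common, function(v) build_case_only(matrix, v))
  names(case_only) <- common
  case_control <- lapply(common, function(v) build_case_control(matrix, v))
  names(case_control) <- common
  mtcn <- stats::setNames(qc$mtcn[qc$keep], kept)
  mtcn_corr <- NULL
  if (!is.null(covariates)) {
    cov <- covariates[match(kept, covariates$sample_id), , drop = FALSE]
    design <- build_covariate_design(cov, terms = "technical")
    res <- residualize_phenotype(mtcn, design, log_transform = TRUE)
    mtcn_corr <- res$y_corr
    log$mtcn_correction_applied <- res$applied
  }
  transmission <- if (!is.null(pedigree))
    transmission_pairs(matrix, pedigree) else NULL
  list(matrix = matrix, qc = qc, common_variants = common,
       case_only = case_only, case_control = case_control,
       mtcn = mtcn, mtcn_corr = mtcn_corr, transmission = transmission,
       log = log)
}
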