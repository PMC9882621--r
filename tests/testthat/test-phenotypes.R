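mk_matrix <- function() {
  per <- list(
    carrier = data.frame(variant = "chrM:10:A,G", pos = 10L,
                         state = "heteroplasmic", fraction = 0.2,
                         stringsAsFactors = FALSE),
    refok = data.frame(variant = "chrM:10:A,G", pos = 10L,
                       state = "reference", fraction = 0,
                       stringsAsFactors = FALSE),
    hom = data.frame(variant = "chrM:10:A,G", pos = 10L,
                     state = "homoplasmic", fraction = 0.97,
                     stringsAsFactors = FALSE),
    nocall = data.frame(variant = "chrM:10:A,G", pos = 10L,
                        state = "missing", fraction = NA_real_,
                        stringsAsFactors = FALSE))
  het_matrix(per)
}

test_that("case-only and case-control coding follow the state rules", {
  m <- mk_matrix()
  co <- build_case_only(m, "chrM:10:A,G")
  expect_equal(unname(co["carrier"]), 0.2)
  expect_true(is.na(co["refok"]))     # reference -> missing in case-only
  expect_true(is.na(co["hom"]))       # homoplasmic always missing
  expect_true(is.na(co["nocall"]))

  cc <- build_case_control(m, "chrM:10:A,G")
  expect_equal(unname(cc["carrier"]), 1)
  expect_equal(unname(cc["refok"]), 0)
  expect_true(is.na(cc["hom"]))
  expect_true(is.na(cc["nocall"]))    # low-coverage control invalid

  # consistency: every case-only non-missing sample is a case-control case
  expect_true(all(cc[names(co)[!is.na(co)]] == 1))
  expect_error(build_case_only(m, "chrM:99:A,G"), "unknown")
})

test_that("covariate design applies recodes, knots, masking and aliasing rules", {
  expect_equal(recode_fasting(c(24, 18, 0, 3)), c(18L, 18L, 1L, 3L))
  expect_length(seasonal_knots(), 13L)  # 3 years quarterly inclusive

  set.seed(10)
  n <- 120
  tb <- data.frame(
    draw_time = runif(n, 480, 1080),
    assessment_date = as.Date("2007-07-01") + sample(0:1095, n, TRUE),
    center = sample(c("a", "b"), n, TRUE),
    month = sample(month.abb[1:6], n, TRUE),
    fasting_hours = sample(c(0, 2, 5, 24), n, TRUE),
    b1 = rnorm(n), b2 = rnorm(n))
  tb$b1[1] <- 10  # |Z| > 4 outlier
  d <- build_covariate_design(tb, terms = c("technical", "blood"),
                              blood_cols = c("b1", "b2"))
  expect_equal(d$masked, 1L)
  expect_true(is.na(d$X[1, "b1"]))
  expect_true(any(grepl("^draw_time_ns", colnames(d$X))))
  expect_equal(sum(grepl("^draw_time_ns", colnames(d$X))), 5L)
  expect_true(any(grepl("^fasting_18$", colnames(d$X))))
  # fasting 24h contributed to the "18" level, 0h to "1"
  expect_false(any(grepl("fasting_24", colnames(d$X))))
  # aliased column dropped deterministically and reported
  tb$center2 <- tb$center
  d2 <- build_covariate_design(cbind(tb, dup = as.numeric(factor(tb$center))),
                               terms = "technical")
  expect_true(all(qr(cbind(1, d2$X[stats::complete.cases(d2$X), ]))$rank ==
                    ncol(d2$X) + 1))
})

test_that("residualization is gated, orthogonal and rescaled", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- 2 + 0.8 * x + rnorm(n, 0, 0.5)
  X <- cbind(x = x)
  res <- residualize_phenotype(y, X, gate_alpha = 0.05 / 40)
  expect_true(res$applied)
  # least-squares orthogonality
  expect_lt(abs(cor(res$y_corr, x)), 1e-8)
  # mean restored
  expect_equal(mean(res$y_corr), mean(y))

  # null covariate: gate stays closed, phenotype untouched
  x0 <- rnorm(n)
  res0 <- residualize_phenotype(y - 0.8 * x + rnorm(n, 0, 0.0), cbind(x0),
                                gate_alpha = 1e-6)
  expect_false(res0$applied)

  # log mode with a perfectly explained phenotype returns exp(mean(log y))
  yl <- exp(1 + 0.5 * x)
  resl <- suppressWarnings(  # degenerate zero-residual fit is intended here
    residualize_phenotype(yl, X, log_transform = TRUE, gate_alpha = 0.05))
  expect_true(resl$applied)
  expect_equal(unname(resl$y_corr), rep(exp(mean(log(yl))), n))

  # missing rows pass through as missing
  y[5] <- NA
  resm <- residualize_phenotype(y, X)
  expect_true(is.na(resm$y_corr[5]))
  expect_error(residualize_phenotype(y[1:2], X[1:2, , drop = FALSE]),
               "insufficient")
})

test_that("planted covariate effects on log mtCN are recovered before correction", {
  co <- simulate_cohort(n_families = 500, seed = 41)
  s <- co$samples
  fit <- lm(log_mtcn ~ I((age - 60) / 10) + blood1, data = s)
  sm <- summary(fit)$coefficients
  expect_lt(abs(sm[2, 1] - co$params$age_slope), 2 * sm[2, 2])
  expect_lt(abs(sm[3, 1] - co$params$blood_beta), 2 * sm[3, 2])
  # residuals orthogonal to every design column after correction
  X <- cbind(age10 = (s$age - 60) / 10, blood1 = s$blood1)
  res <- residualize_phenotype(s$log_mtcn, X, gate_alpha = 0.05)
  expect_true(all(abs(crossprod(scale(X), scale(res$y_corr)) /
                        (nrow(X) - 1)) < 1e-8))
})

test_that("inverse rank normalization uses Blom offsets and preserves ranks", {
  # odd-length distinct sample: median maps to 0
  v <- c(3, 1, 7, 5, 9)
  out <- inverse_rank_normalize(v)
  expect_equal(out[v == 5], 0)
  # n = 3 distinct: Blom quantiles
  q3 <- inverse_rank_normalize(c(10, 20, 30))
  expect_equal(q3, qnorm((1:3 - 0.375) / 3.25))
  # monotone-transform invariance
  expect_equal(inverse_rank_normalize(exp(v)), out)
  # ties averaged; NAs preserved
  vt <- c(1, 2, 2, 4, NA)
  ot <- inverse_rank_normalize(vt)
  expect_equal(ot[2], ot[3])
  expect_true(is.na(ot[5]))
  expect_error(inverse_rank_normalize(c(2, 2, 2)), "identical")
  expect_error(inverse_rank_normalize(c(1, NA)), "2 non-missing")
})

test_that("coverage-discrepancy traits vanish under proportional coverage", {
  toy <- toy_fixture()
  L <- toy$genome$length
  set.seed(12)
  base <- runif(L, 80, 120)
  n <- 70
  covs <- lapply(seq_len(n), function(i) base * runif(1, 0.5, 2))
  names(covs) <- paste0("s", seq_len(n))
  hg <- setNames(rep(c("H", "U"), length.out = n), names(covs))
  out <- coverage_discrepancy_traits(covs, toy$catalog, hg, min_group = 30)
  # a shared shape scaled per sample is perfectly fit by the slope terms
  expect_true(all(abs(out$traits$vs_7s_dna) < 1e-9))
  expect_true(all(abs(out$traits$vs_rna_primer) < 1e-9))
  # region medians equal brute-force medians
  s1 <- covs[["s1"]]
  expect_equal(out$medians$dna_primer[1],
               median(s1[interval_positions(toy$catalog$dna_primer, L)]))
  # haplogroups below the floor are excluded
  hg2 <- hg; hg2[1:5] <- "RARE"
  out2 <- coverage_discrepancy_traits(covs, toy$catalog, hg2, min_group = 30)
  expect_false(any(out2$traits$sample_id %in% names(covs)[1:5]))
})

test_that("transmission pairs respect the carrier floor and recover the slope", {
  co <- simulate_cohort(n_families = 400, params = list(qtl_beta = 0),
                        seed = 77)
  ids <- co$samples$sample_id
  per <- lapply(ids, function(s) {
    f <- co$het_fraction[s]
    if (is.na(f) || f < 0.05) {
      data.frame(variant = "chrM:302:A,AC", pos = 302L, state = "reference",
                 fraction = 0, stringsAsFactors = FALSE)
    } else {
      data.frame(variant = "chrM:302:A,AC", pos = 302L,
                 state = "heteroplasmic", fraction = unname(f),
                 stringsAsFactors = FALSE)
    }
  })
  names(per) <- ids
  m <- het_matrix(per)
  pairs <- transmission_pairs(m, co$pedigree)
  expect_gt(nrow(pairs), 100)
  fit <- lm(frac2 ~ frac1, data = pairs)
  sm <- summary(fit)$coefficients
  expect_lt(abs(sm[2, 1] - 1), 3 * sm[2, 2])

  # variants under the floor are omitted
  rare <- lapply(ids[1:4], function(s)
    data.frame(variant = "chrM:55:A,G", pos = 55L, state = "heteroplasmic",
               fraction = 0.3, stringsAsFactors = FALSE))
  names(rare) <- ids[1:4]
  expect_equal(nrow(transmission_pairs(het_matrix(rare), co$pedigree)), 0L)
})

test_that("age-accrual means include zero-count individuals", {
  ages <- setNames(c(50, 60, 72, 75, 80), paste0("s", 1:5))
  counts <- data.frame(sample_id = c("s3", "s4"), class = "CtoT",
                       count = c(2L, 4L), stringsAsFactors = FALSE)
  out <- age_accrual_summary(counts, ages, bins = c(40, 70, 90))
  old <- out[out$bin == "[70,90]", ]
  expect_equal(old$n, 3L)
  expect_equal(old$mean, mean(c(2, 4, 0)))  # zero-count s5 included
  young <- out[out$bin == "[40,70)", ]
  expect_equal(young$mean, 0)
  # excluding zero-count individuals would change the mean
  expect_false(isTRUE(all.equal(old$mean, mean(c(2, 4)))))
  # a planted step increase after the changepoint shows in bin means
  co <- simulate_cohort(n_families = 600, seed = 13)
  cnt <- data.frame(sample_id = co$samples$sample_id, class = "SNV",
                    count = co$samples$somatic_snvs, stringsAsFactors = FALSE)
  acc <- age_accrual_summary(cnt, setNames(co$samples$age,
                                           co$samples$sample_id),
                             bins = c(20, 70, 90))
  m_young <- acc$mean[acc$bin == "[20,70)"]
  m_old <- acc$mean[acc$bin == "[70,90]"]
  expect_gt(m_old, m_young + 0.5)
})

test_that("carrier contrasts skip small carrier sets and BH is monotone", {
  set.seed(21)
  meas <- list(ph1 = setNames(rnorm(300), paste0("s", 1:300)),
               ph2 = setNames(rnorm(300), paste0("s", 1:300)))
  carriers <- list(v_small = paste0("s", 1:10),      # exactly 10 -> skipped
                   v_ok = paste0("s", 11:40),
                   v_eff = paste0("s", 41:80))
  meas$ph1[carriers$v_eff] <- meas$ph1[carriers$v_eff] + 2
  controls <- paste0("s", 101:300)
  out <- carrier_contrast(carriers, meas, controls)
  expect_false("v_small" %in% out$variant)
  expect_lt(out$p[out$variant == "v_eff" & out$phenotype == "ph1"], 1e-6)
  ord <- order(out$p)
  expect_true(all(diff(out$q[ord]) >= -1e-12))
  expect_error(carrier_contrast(carriers, meas, character()), "empty")
})
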