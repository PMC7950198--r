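test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_run(lib_subset("II_12"), site_rt = c(II_12 = 6), seed = 31)
  b <- simulate_run(lib_subset("II_12"), site_rt = c(II_12 = 6), seed = 31)
  expect_identical(a, b)
  c1 <- simulate_cohort(paste0("t", 1:4), seed = 32)
  c2 <- simulate_cohort(paste0("t", 1:4), seed = 32)
  expect_identical(c1, c2)
  s1 <- simulate_stability(paste0("t", 1:4), seed = 33)
  s2 <- simulate_stability(paste0("t", 1:4), seed = 33)
  expect_identical(s1, s2)
})

test_that("simulator input validation", {
  bad <- list(II_12 = c(N4H5S2 = 0.7, N4H5S1 = 0.7))
  expect_error(simulate_run(lib_subset("II_12"), site_fractions = bad,
                            site_rt = c(II_12 = 6)), "sum to")
  expect_error(simulate_cohort("t1", effects = c(zz = 1)), "unknown trait")
  expect_error(simulate_stability("t1", n_subjects = 1), "at least 2")
  expect_error(simulate_stability("t1", inter_sd = -1), "sds must be")
  fr <- default_site_fractions(AGP_LIB)
  expect_equal(unname(vapply(fr, sum, numeric(1))),
               rep(1, length(fr)), tolerance = 1e-12)
})

recovery_errors <- function(ab, truth, keep = NULL) {
  # absolute fraction errors against the ground truth, renormalizing both
  # sides over the compared analytes (QC-dropped glycoforms drop from both)
  if (!is.null(keep)) {
    ab <- ab[paste(ab$site_group, ab$composition) %in% keep, ]
  }
  unlist(lapply(unique(ab$site_group), function(sg) {
    x <- ab[ab$site_group == sg, ]
    tr <- truth[[sg]][x$composition]
    abs(x$fraction / sum(x$fraction) - unname(tr) / sum(tr))
  }))
}

test_that("noiseless runs are recovered within 1% absolute", {
  rig <- two_site_rig(seed = 34, noise_sd = 0, ppm_jitter = 0,
                      ppm_bias = 0, decoy_per_scan = 0)
  recs <- extract_run(rig$run, rig$targets)
  qc <- batch_qc(recs)
  ab <- normalize_per_site(sum_charges(recs, qc))
  truth <- attr(rig$run, "truth")$site_fractions
  # analytes retained at every charge state carry no charge-summation bias
  full <- names(which(tapply(qc$retained, qc$analyte_id, all)))
  expect_gt(length(full), 18)
  expect_lt(max(recovery_errors(ab, truth, keep = full)), 0.01)
  # exact peak positions: mass errors vanish; envelopes deviate only where
  # near-isobaric glycoforms genuinely overlap
  expect_lt(abs(median(recs$ppm_error)), 1e-6)
  expect_lt(median(recs$ipq), 0.01)
})

test_that("a simulated calibration bias is reported as ppm error", {
  rig <- two_site_rig(seed = 35, ppm_bias = 10)
  recs <- extract_run(rig$run, rig$targets)
  expect_equal(mean(recs$ppm_error), 10, tolerance = 1)
})

test_that("signal-to-noise rises as simulated noise falls", {
  snr_at <- function(decoy_int) {
    rig <- two_site_rig(seed = 36, decoy_per_scan = 60,
                        decoy_intensity = decoy_int)
    recs <- extract_run(rig$run, rig$targets)
    median(recs$snr[is.finite(recs$snr)])
  }
  s <- vapply(c(400, 100, 25), snr_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("end-to-end recovery within 2% absolute at default noise", {
  run <- simulate_run(AGP_LIB, seed = 37)
  targets <- make_extraction_targets(AGP_LIB, attr(run, "truth")$site_rt)
  recs <- extract_run(run, targets)
  ab <- normalize_per_site(sum_charges(recs, batch_qc(recs)))
  truth <- attr(run, "truth")$site_fractions
  expect_lt(max(recovery_errors(ab, truth)), 0.02)
  # and the derived traits follow, over the traits whose members were all
  # quantified (QC may remove overlap-affected glycoforms, as designed)
  defs <- enumerate_traits(AGP_LIB)
  tt <- suppressMessages(compute_traits(ab, defs))
  present <- paste(ab$site_group, ab$composition)
  truth_ab <- do.call(rbind, lapply(names(truth), function(sg) {
    keep <- paste(sg, names(truth[[sg]])) %in% present
    fr <- truth[[sg]][keep]
    data.frame(sample = "truth", site_group = sg, composition = names(fr),
               fraction = unname(fr) / sum(fr), stringsAsFactors = FALSE)
  }))
  tt_truth <- suppressMessages(compute_traits(truth_ab, defs))
  ok <- !is.na(unlist(tt[, -1])) & !is.na(unlist(tt_truth[, -1]))
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(unlist(tt[, -1])[ok] - unlist(tt_truth[, -1])[ok])), 0.02)
})

test_that("cohort power: BH recovers most simulated effects", {
  set.seed(38)
  eff <- c("t1" = 0.8, "t2" = 0.9, "t3" = 0.8, "t4" = 0.7, "t5" = 0.9, "t6" = 0.8)
  hits <- replicate(25, {
    sim <- simulate_cohort(paste0("t", 1:20), effects = eff,
                           seed = sample.int(1e6, 1))
    res <- associate_traits(sim$traits, sim$meta)
    sum(res$trait[which(res$p_adj < 0.05)] %in% names(eff))
  })
  expect_gte(mean(hits), 4)
})
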