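corrected_trace <- function(y, rt = seq_along(y) / 100) {
  eoripen:::new_trace(rt, y, stage = "baseline_corrected")
}

test_that("a single triangular peak above threshold is found with its height", {
  y <- c(rep(0, 10), seq(0, 1, by = 0.2), seq(0.8, 0, by = -0.2),
         rep(0, 10))
  tr <- corrected_trace(y)
  det <- detect_peaks(tr, noise_stats(0, 0.1))
  expect_equal(nrow(det), 1)
  expect_equal(det$height, 1)
  expect_equal(det$prominence, 1)
})

test_that("plateaus yield the leftmost apex and detection is threshold-monotone", {
  y <- c(0, 1, 2, 2, 2, 1, 0, 3, 0)
  tr <- corrected_trace(y)
  det <- detect_peaks(tr, noise_stats(0, 0.1))
  expect_equal(det$height, c(2, 3))
  expect_equal(det$rt_apex[1], tr$rt_min[3]) # leftmost point of plateau

  set.seed(8)
  y2 <- rnorm(2000)
  tr2 <- corrected_trace(y2)
  lo <- detect_peaks(tr2, noise_stats(0, 0.3))
  hi <- detect_peaks(tr2, noise_stats(0, 0.6))
  expect_true(all(hi$rt_apex %in% lo$rt_apex))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("false positives on pure noise stay below 1% of grid points", {
  set.seed(15)
  fp <- vapply(1:30, function(i) {
    tr <- corrected_trace(rnorm(3000, 0, 0.02))
    nrow(detect_peaks(tr, estimate_noise(tr)))
  }, numeric(1))
  expect_lt(mean(fp), 0.01 * 3000)
})

test_that("matching keeps identical detections and honors the presence threshold", {
  det_one <- tibble::tibble(rt_apex = c(5, 10, 15),
                            height = c(1, 2, 1.5))
  all_det <- dplyr::bind_rows(lapply(1:10, function(i)
    dplyr::mutate(det_one, sample_id = sprintf("s%02d", i),
                  replicate_id = 1L, class_label = 1L, threshold = 0.1)))
  reg <- match_peaks(all_det)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$consensus_rt, c(5, 10, 15))
  expect_true(all(reg$presence_fraction == 1))

  # drop peak at rt 10 from one trace
  miss <- all_det[!(all_det$sample_id == "s01" & all_det$rt_apex == 10), ]
  strict <- match_peaks(miss, presence_threshold = 1)
  expect_equal(strict$consensus_rt, c(5, 15))
  lax <- match_peaks(miss, presence_threshold = 0.9)
  expect_equal(lax$consensus_rt, c(5, 10, 15))

  expect_error(match_peaks(all_det, rt_tol = 0), "rt_tol")
})

test_that("matching is invariant to trace order and registry RTs increase", {
  set.seed(3)
  study <- preprocess_study(simulate_study(tiny_specs(), quiet_design()))
  det <- detect_study(study)
  reg1 <- match_peaks(det)
  reg2 <- match_peaks(det[sample(nrow(det)), ])
  expect_equal(reg1, reg2, ignore_attr = TRUE)
  expect_true(all(diff(reg1$consensus_rt) > 0))
})

test_that("a noiseless study recovers the spec peaks and their heights", {
  specs <- tiny_specs()
  study <- preprocess_study(simulate_study(specs, quiet_design(), seed = 6))
  det <- detect_study(study)
  reg <- match_peaks(det)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$consensus_rt, specs$rt_min, tolerance = 0.01)

  fm <- build_feature_matrix(det, reg)
  expect_equal(nrow(fm), nrow(study))
  vals <- feature_values(fm)
  for (r in seq_len(nrow(fm))) {
    truth <- unlist(specs[, paste0("logh_", fm$class_label[r])])
    # within 1% relative error on the raw-intensity scale
    expect_lt(max(abs(10^vals[r, ] / 10^truth - 1)), 0.01)
  }
})

test_that("unmatched registry peaks are imputed at the trace threshold", {
  det_one <- tibble::tibble(rt_apex = c(5, 10), height = c(1, 2))
  all_det <- dplyr::bind_rows(lapply(1:5, function(i)
    dplyr::mutate(det_one, sample_id = sprintf("s%02d", i),
                  replicate_id = 1L, class_label = 1L, threshold = 0.25)))
  # trace s01 misses the rt 10 peak
  miss <- all_det[!(all_det$sample_id == "s01" & all_det$rt_apex == 10), ]
  reg <- match_peaks(miss, presence_threshold = 0.5)
  fm <- build_feature_matrix(miss, reg)
  expect_equal(dim(feature_values(fm)), c(5, 2))
  imputed <- attr(fm, "imputed")
  expect_equal(sum(imputed), 1)
  expect_equal(feature_values(fm)[fm$sample_id == "s01", 2], 0.25,
               ignore_attr = TRUE)
})

test_that("the feature matrix is reproducible end to end", {
  specs <- tiny_specs()
  d <- study_design(class_sizes = c(1, 1, 1, 1), replicates = 2,
                    noise_sd = 2, baseline_amplitude = 30)
  run <- function() {
    study <- preprocess_study(simulate_study(specs, d, seed = 17))
    det <- detect_study(study)
    build_feature_matrix(det, match_peaks(det))
  }
  expect_identical(run(), run())
})
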