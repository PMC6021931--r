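test_that("the stratified split reproduces the 19-of-27 worked example", {
  m <- reference_manifest()
  set.seed(1)
  plan <- grouped_stratified_split(m)
  counts <- table(plan$class_label, plan$subset)
  expect_equal(unname(counts["2", "train"]), 19)
  expect_equal(sum(counts), 101)
  expect_equal(unname(rowSums(counts)), c(11, 27, 36, 27))
  # per-class training counts at 70% with round-to-nearest
  expect_equal(unname(counts[, "train"]), c(8, 19, 25, 19))
})

test_that("all replicates of an oil share one subset in every partition", {
  m <- reference_manifest()
  plans <- eoripen:::make_partition_plans(m, R = 10, seed = 99)
  for (plan in plans) {
    subset_of <- setNames(as.character(plan$subset), plan$sample_id)
    per_row <- subset_of[m$sample_id]
    spans <- tapply(per_row, m$sample_id, dplyr::n_distinct)
    expect_true(all(spans == 1))
    expect_setequal(levels(plan$subset),
                    c("train", "internal", "external"))
  }
})

test_that("degenerate classes are refused", {
  m <- tibble::tibble(sample_id = c("a", "b"), class_label = c(1, 1))
  expect_error(grouped_stratified_split(m), "too few samples")
  expect_error(grouped_stratified_split(reference_manifest(),
                                        fractions = c(0.5, 0.3, 0.3)),
               "sum to 1")
})

test_that("standardization uses the training scaler everywhere", {
  set.seed(2)
  x <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  train <- 1:12
  sc <- standardize_features(x, train)
  expect_equal(colMeans(sc$x[train, ]), c(a = 0, b = 0, c = 0),
               tolerance = 1e-8)
  expect_equal(apply(sc$x[train, ], 2, sd), c(a = 1, b = 1, c = 1),
               tolerance = 1e-8)
  # hand-computed oracle for a validation row
  expect_equal(sc$x[15, 2],
               (x[15, 2] - mean(x[train, 2])) / sd(x[train, 2]))

  xc <- cbind(x, const = 7)
  expect_warning(sc2 <- standardize_features(xc, train), "zero-variance")
  expect_true(all(sc2$x[, "const"] == 0))
})

test_that("the perceptron separates blob data and is seed-deterministic", {
  set.seed(10)
  centers <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4), 4, 2, byrow = TRUE)
  x <- centers[rep(1:4, each = 30), ] + matrix(rnorm(240, 0, 0.3), 120, 2)
  y <- rep(1:4, each = 30)
  cfg <- fast_config(2, hidden = 6)
  fit <- train_mlp(x, y, cfg)
  expect_gte(ccr(predict(fit, x), y), 0.99)

  fit2 <- train_mlp(x, y, cfg)
  expect_identical(fit$layers, fit2$layers)
})

test_that("shuffled labels drop external accuracy to the class prior", {
  set.seed(23)
  fm <- simulate_features(default_peak_specs(), study_design(), seed = 12)
  fm$class_label <- sample(fm$class_label) # row-level shuffle: no signal
  cv <- cross_validate(fm, fast_config(22), R = 12, seed = 7)
  prior <- max(table(fm$class_label)) / nrow(fm)
  expect_lt(abs(mean(cv$per_partition$ccr_external) - prior), 0.1)
})

test_that("non-finite losses abort with a diagnostic", {
  x <- matrix(c(NaN, 0.5, -0.5, 1), 4, 1) # corrupt feature entry
  y <- c(1, 2, 3, 4)
  cfg <- mlp_config(1, hidden = 2, max_epochs = 50)
  expect_error(train_mlp(x, y, cfg), "non-finite")
})

test_that("ccr follows Nright over N", {
  expect_equal(ccr(c(1, 2, 3, 3), c(1, 2, 3, 4)), 0.75)
  expect_equal(ccr(1:4, 1:4), 1)
  expect_equal(ccr(c(2, 3), c(3, 2)), 0)
  expect_error(ccr(integer(), integer()), "non-empty")
  expect_error(ccr(1:3, 1:4), "equal length")
})

test_that("averaged confusion matrices are row-stochastic percentages", {
  m1 <- matrix(c(5, 0, 0, 0,
                 1, 4, 0, 0,
                 0, 0, 5, 0,
                 0, 0, 2, 3), 4, 4, byrow = TRUE)
  avg1 <- averaged_confusion(list(m1, m1))
  expect_equal(avg1, averaged_confusion(list(m1)))
  expect_true(all(abs(rowSums(avg1) - 100) < 0.5))

  perfect <- averaged_confusion(list(diag(4) * 7))
  expect_equal(perfect, diag(4) * 100)
})

test_that("architecture search returns single candidates and prefers parsimony", {
  set.seed(5)
  fm <- simulate_features(default_peak_specs(),
                          study_design(class_sizes = c(6, 8, 10, 8),
                                       replicates = 2), seed = 4)
  one <- list(fast_config(22, hidden = 4))
  res <- select_architecture(fm, one, R = 3, seed = 2)
  expect_identical(res$best_config$hidden, 4L)

  # two architectures, identical internal CCR by construction (both hit
  # the ceiling on separable data): the smaller must win
  two <- list(fast_config(22, hidden = 16), fast_config(22, hidden = 4))
  res2 <- select_architecture(fm, two, R = 3, seed = 2)
  cand <- res2$candidates
  if (cand$ccr_internal_mean[1] == cand$ccr_internal_mean[2]) {
    expect_identical(res2$best_config$hidden, 4L)
  }
  expect_gte(max(cand$ccr_internal_mean),
             cand$ccr_internal_mean[res2$winner_index] -
               cand$ccr_internal_sd[res2$winner_index])
})

test_that("cross-validation tidiers expose per-partition and summary views", {
  fm <- simulate_features(default_peak_specs(),
                          study_design(class_sizes = c(6, 8, 10, 8),
                                       replicates = 2), seed = 8)
  cv <- cross_validate(fm, fast_config(22, hidden = 4), R = 4, seed = 3)
  td <- tidy(cv)
  expect_equal(nrow(td), 4)
  expect_true(all(td$ccr_external >= 0 & td$ccr_external <= 1))
  gl <- glance(cv)
  expect_equal(gl$ccr_external_mean, mean(td$ccr_external))
  expect_true(all(abs(rowSums(cv$confusion) - 100) < 0.5))
})
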