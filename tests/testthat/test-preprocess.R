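make_raw_trace <- function(intensity, rt = seq_along(intensity)) {
  eoripen:::new_trace(rt, intensity, stage = "raw")
}

test_that("log transform maps powers of ten and shifts by the offset", {
  tr <- make_raw_trace(c(1, 10, 100))
  expect_equal(log_transform(tr, offset = 0)$intensity, c(0, 1, 2))
  tr2 <- make_raw_trace(c(0, 9))
  expect_equal(log_transform(tr2, offset = 1)$intensity, c(0, 1))

  # a 1e4 max/median raw ratio becomes a difference of 4 decades
  tr3 <- make_raw_trace(c(rep(10, 100), 1e5))
  logged <- log_transform(tr3, offset = 0)$intensity
  expect_equal(max(logged) - stats::median(logged), 4)

  expect_error(log_transform(make_raw_trace(c(1, -2, 3)), offset = 0),
               "index 2")
  expect_equal(eoripen:::trace_stage(log_transform(tr)), "logged")
})

test_that("a constant signal is its own baseline", {
  y <- rep(2.5, 200)
  z <- psalsa_baseline(y)
  expect_lt(max(abs(z - y)), 1e-6)
})

test_that("one fixed-weight iteration matches a dense least-squares oracle", {
  # the banded solve must agree with an explicit dense solution of
  # (W + lambda D'D) z = W y on a small instance
  set.seed(21)
  n <- 50
  y <- cumsum(rnorm(n)) + 3 * dnorm(seq(-3, 3, length.out = n))
  w <- runif(n, 0.1, 1)
  lam <- 50
  D <- diff(diag(n), differences = 2)
  A <- diag(w) + lam * crossprod(D)
  z_oracle <- solve(A, w * y)
  z <- eoripen:::als_solve(y, w, lam)
  expect_lt(max(abs(z - z_oracle)), 1e-8)
})

test_that("the baseline recovers a known drift under Gaussian peaks", {
  t <- seq(0, 10, length.out = 1200)
  drift <- 1 + 0.15 * t
  peaks <- 2.0 * (dnorm(t, 2, 0.06) + dnorm(t, 5, 0.06) +
                    dnorm(t, 8, 0.06)) / dnorm(0, 0, 0.06)
  y <- drift + peaks
  z <- psalsa_baseline(y)
  expect_lt(max(abs(z - drift)), 0.02 * diff(range(drift)))
})

test_that("increasing lambda never increases the curvature energy", {
  set.seed(4)
  t <- seq(0, 10, length.out = 800)
  y <- 1 + 0.2 * t + 0.3 * cos(t) +
    3 * exp(-(t - 5)^2 / 0.02) + rnorm(800, 0, 0.02)
  energy <- vapply(c(1e2, 1e3, 1e4, 1e5, 1e6, 1e7), function(lam) {
    z <- psalsa_baseline(y, psalsa_params(lam = lam))
    sum(diff(z, differences = 2)^2)
  }, numeric(1))
  expect_true(all(diff(energy) <= 1e-10))
})

test_that("the baseline hugs the lower envelope of a peaky trace", {
  set.seed(9)
  study <- simulate_study(tiny_specs(),
                          study_design(class_sizes = c(1, 1, 1, 1),
                                       replicates = 1, noise_sd = 2,
                                       baseline_amplitude = 40))
  for (tr in study$trace) {
    logged <- log_transform(tr)
    z <- psalsa_baseline(logged$intensity)
    expect_gte(stats::median(logged$intensity - z), 0)
  }
})

test_that("baseline subtraction behaves and re-estimation is near zero", {
  y <- rep(1.5, 300)
  tr <- make_raw_trace(10^y - 1)
  logged <- log_transform(tr)
  z <- psalsa_baseline(logged$intensity)
  corrected <- subtract_baseline(logged, z)
  expect_lt(max(abs(corrected$intensity)), 1e-6)
  expect_equal(eoripen:::trace_stage(corrected), "baseline_corrected")
  expect_error(subtract_baseline(logged, z[-1]), "length")
  expect_error(subtract_baseline(tr, z), "logged")

  # idempotence on a realistic trace: a second baseline pass finds
  # almost nothing left (moderate noise, so the residual lower-envelope
  # wiggle stays well under the original baseline range)
  set.seed(2)
  tr2 <- simulate_study(tiny_specs(),
                        study_design(class_sizes = c(1, 1, 1, 1),
                                     replicates = 1, noise_sd = 0.5,
                                     baseline_amplitude = 40))$trace[[1]]
  logged2 <- log_transform(tr2)
  z1 <- psalsa_baseline(logged2$intensity)
  corr <- subtract_baseline(logged2, z1)
  z2 <- psalsa_baseline(corr$intensity)
  expect_lt(max(abs(z2)), 0.05 * diff(range(z1)))
})

test_that("corrected apex heights track the generator log heights", {
  set.seed(31)
  study <- simulate_study(tiny_specs(), quiet_design())
  for (i in seq_len(nrow(study))) {
    corr <- preprocess_trace(study$trace[[i]])
    cls <- study$class_label[i]
    truth <- unname(unlist(tiny_specs()[, paste0("logh_", cls)]))
    for (j in 1:3) {
      idx <- which.min(abs(corr$rt_min - tiny_specs()$rt_min[j]))
      window <- corr$intensity[pmax(1, idx - 3):pmin(nrow(corr), idx + 3)]
      expect_equal(max(window), truth[j], tolerance = 0.005)
    }
  }
})

test_that("noise statistics recover the full noise scale from the quiet region", {
  set.seed(77)
  sigma <- 0.02
  reps <- vapply(1:20, function(i) {
    tr <- eoripen:::new_trace(seq_len(3000), rnorm(3000, 0, sigma),
                              stage = "baseline_corrected")
    estimate_noise(tr)$threshold
  }, numeric(1))
  expect_true(all(reps > 2.5 * sigma & reps < 3.5 * sigma))

  zero <- eoripen:::new_trace(1:100, rep(0, 100),
                              stage = "baseline_corrected")
  ns <- estimate_noise(zero)
  expect_equal(ns$mean, 0)
  expect_equal(ns$sd, 0)
  expect_equal(ns$threshold, 0)

  forced <- noise_stats(0.1, 0.2)
  expect_equal(forced$threshold, 0.7)
})

test_that("the preprocessing chain is deterministic", {
  set.seed(13)
  tr <- simulate_study(tiny_specs(),
                       study_design(class_sizes = c(1, 1, 1, 1),
                                    replicates = 1, noise_sd = 2,
                                    baseline_amplitude = 30))$trace[[1]]
  a <- preprocess_trace(tr)
  b <- preprocess_trace(tr)
  expect_identical(a$intensity, b$intensity)
  expect_identical(attr(a, "noise_stats"), attr(b, "noise_stats"))
})
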