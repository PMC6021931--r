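test_that("sensitivity of a linear toy network matches the closed form", {
  set.seed(44)
  W <- matrix(c(0.5, -1.2, 0, 2,
                0, 0, 0, 0,
                1, 1, -1, 0.3), 3, 4, byrow = TRUE)
  net <- linear_toy_mlp(W)
  x <- matrix(runif(60, -2, 3), 20, 3,
              dimnames = list(NULL, c("peak_01", "peak_02", "peak_03")))
  sens <- sensitivity_analysis(net, x, grid_steps = 50)
  ranges <- apply(x, 2, function(col) diff(range(col)))
  for (j in 1:3) {
    for (cl in 1:4) {
      expected <- abs(W[j, cl]) * unname(ranges[j])
      got <- sens$sensitivity[sens$peak == colnames(x)[j] &
                                sens$class == cl]
      expect_equal(got, expected, tolerance = 1e-6)
    }
  }
  # input 2 is disconnected: zero sensitivity for every class
  expect_true(all(sens$sensitivity[sens$peak == "peak_02"] == 0))

  # row order of the data must not matter
  sens_perm <- sensitivity_analysis(net, x[sample(20), ], grid_steps = 50)
  expect_equal(sens, sens_perm)

  expect_error(sensitivity_analysis(net, x, grid_steps = 2), "grid_steps")
})

test_that("ranking sorts by descending sensitivity with id tie-break", {
  sens <- tibble::tibble(
    peak = rep(c("peak_01", "peak_02", "peak_03"), 2),
    class = rep(1:2, each = 3),
    sensitivity = c(0.5, 0.9, 0.1, 0.2, 0.2, 0.2)
  )
  rk <- rank_inputs(sens)
  expect_equal(rk$peak_id[rk$class == 1], c(2, 1, 3))
  expect_equal(rk$peak_id[rk$class == 2], c(1, 2, 3)) # all-equal: id order
})

test_that("sequential addition reproduces the published worked example", {
  trace <- sequential_rank_addition(bitter_orange_rankings())
  expect_equal(nrow(trace), 13)
  expect_equal(trace$n_cumulative,
               c(3, 5, 7, 8, 9, 11, 13, 15, 16, 17, 19, 21, 22))
  expect_equal(trace$peaks_added[[1]], c(1, 11, 19))
  expect_equal(trace$peaks_added[[2]], c(3, 18))
  expect_equal(trace$peaks_added[[3]], c(10, 15))
  expect_equal(trace$peaks_added[[4]], 20)
  expect_equal(trace$peaks_added[[5]], 4)
  expect_equal(trace$peaks_added[[6]], c(17, 22))
  expect_equal(trace$peaks_added[[7]], c(14, 21))
  expect_equal(trace$peaks_added[[8]], c(5, 13))
  expect_equal(trace$peaks_added[[9]], 9)
  expect_equal(trace$peaks_added[[10]], 12)
  expect_equal(trace$peaks_added[[11]], c(6, 8))
  expect_equal(trace$peaks_added[[12]], c(2, 16))
  expect_equal(trace$peaks_added[[13]], 7)
  expect_setequal(trace$cumulative[[13]], 1:22)
})

test_that("degenerate rankings produce one peak per step", {
  # a single class: every rank level holds exactly one peak
  single <- tibble::tibble(class = 1, rank = 1:6, peak_id = c(3, 1, 6, 2, 5, 4))
  tr <- sequential_rank_addition(single)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$n_added == 1))
  expect_equal(unlist(tr$peaks_added), c(3, 1, 6, 2, 5, 4))

  # four identical rankings behave like one
  same <- dplyr::bind_rows(lapply(1:4, function(cl)
    dplyr::mutate(single, class = cl)))
  tr4 <- sequential_rank_addition(same)
  expect_equal(unlist(tr4$peaks_added), c(3, 1, 6, 2, 5, 4))
})

test_that("sequential addition agrees with the best-rank oracle on random tables", {
  # a peak joins exactly when the pointer reaches its best (minimum) rank
  # over the four classes, so grouping peaks by that minimum and ordering
  # the groups is an independent closed-form account of the procedure
  set.seed(66)
  for (i in 1:200) {
    p <- sample(3:10, 1)
    ranks <- dplyr::bind_rows(lapply(1:4, function(cl)
      tibble::tibble(class = cl, rank = 1:p, peak_id = sample(p))))
    tr <- sequential_rank_addition(ranks)

    best_rank <- vapply(seq_len(p), function(j)
      min(ranks$rank[ranks$peak_id == j]), numeric(1))
    oracle <- split(seq_len(p), best_rank)
    expect_equal(length(tr$peaks_added), length(oracle))
    for (s in seq_along(oracle)) {
      expect_equal(tr$peaks_added[[s]], unname(sort(oracle[[s]])))
    }
    # the steps partition the peak ids
    expect_equal(sort(unlist(tr$peaks_added)), seq_len(p))
    expect_true(all(diff(tr$n_cumulative) > 0))
  }
})

test_that("trace evaluation finds a planted informative subset", {
  specs <- planted_specs(p = 8, planted = c(2, 5))
  fm <- simulate_features(specs, study_design(class_sizes = c(6, 8, 10, 8),
                                              replicates = 2), seed = 9)
  cfg <- fast_config(8, hidden = 6)
  cv <- cross_validate(fm, cfg, R = 6, seed = 21)
  sens <- sensitivity_analysis(cv, fm, grid_steps = 25)
  ranks <- rank_inputs(sens)
  # a planted peak must sit near the top of every class ranking (flat
  # peaks also score, as reference channels for the shared oil-level
  # intensity shift, but cannot all outrank the signal carriers)
  planted_best <- tapply(ranks$rank[ranks$peak_id %in% c(2, 5)],
                         ranks$class[ranks$peak_id %in% c(2, 5)], min)
  expect_true(all(planted_best <= 3))

  trace <- sequential_rank_addition(ranks)
  trace <- evaluate_trace(trace, fm, cfg, R = 6, seed = 22)
  best <- attr(trace, "best_step")
  expect_true(all(c(2, 5) %in% trace$cumulative[[best]]))
  full <- trace$ccr_external[nrow(trace)]
  expect_gte(trace$ccr_external[best], full - 0.02)
  expect_equal(length(trace$ccr_internal), nrow(trace))

  # single-step trace evaluates to itself
  one <- trace[nrow(trace), ]
  one$step <- 1L
  ev <- evaluate_trace(one, fm, cfg, R = 2, seed = 1)
  expect_equal(attr(ev, "best_step"), 1L)
})
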