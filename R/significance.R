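#' Permute class labels at the oil level
#'
#' Randomly reassigns the class labels of the distinct oils (not of the
#' replicate rows), so every replicate of an oil keeps one common permuted
#' label and the class-size multiset is preserved. Uses the current R
#' random-number state.
#'
#' @param manifest A tibble with `sample_id` and `class_label` columns
#'   (replicate rows allowed).
#' @return The manifest with permuted `class_label`.
#' @export
permute_labels <- function(manifest) {
  eos <- dplyr::distinct(manifest, .data$sample_id, .data$class_label)
  perm <- sample(nrow(eos))
  new_label <- stats::setNames(eos$class_label[perm], eos$sample_id)
  out <- manifest
  out$class_label <- unname(new_label[manifest$sample_id])
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. `U` counts the pairs `(a_i, b_j)`
#' with `a_i > b_j` (ties contribute 1/2), computed via midranks. The
#' p-value comes from exact enumeration over all assignments of the
#' pooled values to the two groups when the problem is small
#' (`n_a * n_b <= 400`), otherwise from the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (a shifted
#'   above b, large U) or `"less"`.
#' @return A list: `U`, `p_value`, `method` ("exact" or "normal").
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b,
                           alternative = c("two.sided", "greater",
                                           "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n_a <- length(a)
  n_b <- length(b)
  u_obs <- u_statistic(a, b)
  mu <- n_a * n_b / 2

  if (max(a, b) == min(a, b)) # all values identical across both samples
    return(list(U = u_obs, p_value = 1, method = "degenerate"))

  if (n_a * n_b <= 400 && choose(n_a + n_b, n_a) <= 2e6) {
    pooled <- c(a, b)
    splits <- utils::combn(n_a + n_b, n_a)
    us <- apply(splits, 2, function(idx)
      u_statistic(pooled[idx], pooled[-idx]))
    p <- switch(alternative,
      two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12),
      greater = mean(us >= u_obs - 1e-12),
      less = mean(us <= u_obs + 1e-12)
    )
    return(list(U = u_obs, p_value = min(1, p), method = "exact"))
  }

  n <- n_a + n_b
  ties <- table(c(a, b))
  sigma2 <- n_a * n_b / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0)
    return(list(U = u_obs, p_value = 1, method = "degenerate"))
  z <- u_obs - mu
  cc <- switch(alternative,
               two.sided = sign(z) * 0.5,
               greater = 0.5,
               less = -0.5)
  z <- (z - cc) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z)
  )
  list(U = u_obs, p_value = min(1, p), method = "normal")
}

u_statistic <- function(a, b) {
  r <- rank(c(a, b)) # midranks
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Permutation test of the classification accuracy
#'
#' Builds the null distribution of the external-validation correct
#' classification rate by repeatedly permuting the class labels at the
#' oil level and re-running the cross-validated classifier (architecture
#' fixed by default; pass a `search_space` to repeat the architecture
#' search under every permutation). The observed distribution uses the
#' real labels. The two CCR distributions are compared with the
#' Mann-Whitney U test; an empirical p-value
#' `(1 + #\{null >= mean(observed)\}) / (1 + n_perm)` is reported as well.
#'
#' @param features A feature tibble (typically restricted to the selected
#'   peaks).
#' @param config The fixed [mlp_config()] used for every run.
#' @param n_perm Number of label permutations (>= 1).
#' @param R_observed Partitions for the observed (real-label) runs.
#' @param R_null Partitions per permutation (kept small for
#'   tractability; each permutation contributes its mean external CCR).
#' @param seed Master seed.
#' @param alternative Sidedness of the U test.
#' @param search_space Optional list of configs; when given, each
#'   permutation re-selects the architecture instead of using `config`.
#' @param fractions Train / internal / external fractions.
#' @return An object of class `eo_permtest`: `observed_ccrs`,
#'   `null_ccrs`, `U`, `p_value`, `p_empirical`, `n_permutations`.
#' @export
permutation_test <- function(features, config, n_perm = 99,
                             R_observed = 20, R_null = 5, seed = 1L,
                             alternative = "two.sided",
                             search_space = NULL,
                             fractions = c(0.7, 0.1, 0.2)) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  obs_cv <- cross_validate(features, config, R = R_observed, seed = seed,
                           fractions = fractions)
  observed <- obs_cv$per_partition$ccr_external

  set.seed(seed + 1L)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  null_ccrs <- vapply(seq_len(n_perm), function(b) {
    set.seed(perm_seeds[b])
    permuted <- permute_labels(features)
    stopifnot(identical(
      sort(as.integer(table(dplyr::distinct(
        permuted, .data$sample_id, .data$class_label)$class_label))),
      sort(as.integer(table(dplyr::distinct(
        features, .data$sample_id, .data$class_label)$class_label)))))
    cfg <- if (is.null(search_space)) config
           else select_architecture(permuted, search_space, R = R_null,
                                    seed = perm_seeds[b],
                                    fractions = fractions)$best_config
    cv <- cross_validate(permuted, cfg, R = R_null, seed = perm_seeds[b],
                         fractions = fractions)
    mean(cv$per_partition$ccr_external)
  }, numeric(1))

  mw <- mann_whitney_u(observed, null_ccrs, alternative = alternative)
  p_emp <- (1 + sum(null_ccrs >= mean(observed))) / (1 + n_perm)
  structure(list(observed_ccrs = observed, null_ccrs = null_ccrs,
                 U = mw$U, p_value = mw$p_value, p_empirical = p_emp,
                 n_permutations = n_perm, method = mw$method,
                 observed_cv = obs_cv),
            class = "eo_permtest")
}

#' @export
print.eo_permtest <- function(x, ...) {
  cat("<eo_permtest> ", x$n_permutations, " permutations\n", sep = "")
  cat(sprintf("  observed external CCR %.3f +/- %.3f (n = %d)\n",
              mean(x$observed_ccrs), stats::sd(x$observed_ccrs),
              length(x$observed_ccrs)))
  cat(sprintf("  null external CCR     %.3f +/- %.3f (n = %d)\n",
              mean(x$null_ccrs), stats::sd(x$null_ccrs),
              length(x$null_ccrs)))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g (%s); empirical p = %.3g\n",
              x$U, x$p_value, x$method, x$p_empirical))
  invisible(x)
}
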