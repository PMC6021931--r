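#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x An `eo_cv` object.
#' @param ... Unused.
#' @return The per-partition tibble (`partition`, `ccr_internal`,
#'   `ccr_external`, `ccr_external_eo`).
#' @export
tidy.eo_cv <- function(x, ...) x$per_partition

#' @rdname tidy.eo_cv
#' @export
glance.eo_cv <- function(x, ...) {
  tibble::tibble(
    n_partitions = nrow(x$per_partition),
    architecture = paste(c(x$config$n_inputs, x$config$hidden,
                           x$config$n_outputs), collapse = "-"),
    activation = x$config$activation,
    ccr_internal_mean = mean(x$per_partition$ccr_internal),
    ccr_internal_sd = stats::sd(x$per_partition$ccr_internal),
    ccr_external_mean = mean(x$per_partition$ccr_external),
    ccr_external_sd = stats::sd(x$per_partition$ccr_external),
    ccr_external_eo_mean = mean(x$per_partition$ccr_external_eo)
  )
}

#' Tidy an architecture search
#'
#' @param x An `eo_arch_search` object.
#' @param ... Unused.
#' @return The per-candidate tibble with mean and sd internal CCR.
#' @export
tidy.eo_arch_search <- function(x, ...) x$candidates

#' @rdname tidy.eo_arch_search
#' @export
glance.eo_arch_search <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_candidates = nrow(x$candidates)),
    glance(x$cv)
  )
}

#' Tidy a permutation test
#'
#' @param x An `eo_permtest` object.
#' @param ... Unused.
#' @return A long tibble of the two CCR distributions: `labels`
#'   (observed / permuted), `ccr_external`.
#' @export
tidy.eo_permtest <- function(x, ...) {
  tibble::tibble(
    labels = rep(c("observed", "permuted"),
                 c(length(x$observed_ccrs), length(x$null_ccrs))),
    ccr_external = c(x$observed_ccrs, x$null_ccrs)
  )
}

#' @rdname tidy.eo_permtest
#' @export
glance.eo_permtest <- function(x, ...) {
  tibble::tibble(
    n_permutations = x$n_permutations,
    ccr_observed_mean = mean(x$observed_ccrs),
    ccr_null_mean = mean(x$null_ccrs),
    U = x$U,
    p_value = x$p_value,
    p_empirical = x$p_empirical,
    method = x$method
  )
}
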