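#' Sensitivity analysis of a trained network
#'
#' Probes the response of the classifier to each input: input `j` is swept
#' over `grid_steps` equally spaced values spanning its observed range
#' while every other input is locked at its column mean; the sensitivity
#' of input `j` for class output `c` is the range (max minus min) of
#' output `c` over the sweep. Applied to an `eo_cv` object, the
#' sensitivities of the per-partition models are averaged (or the single
#' model with the best external CCR is used).
#'
#' @param model A trained `eo_mlp`, or an `eo_cv` cross-validation object.
#' @param x Standardized feature matrix the model was trained on (for an
#'   `eo_cv`, pass the raw feature tibble instead — each partition's own
#'   scaler is applied).
#' @param grid_steps Number of sweep points per input (>= 3). Default 50.
#' @param ... Passed on to methods.
#' @return A tibble with one row per input and class: `peak` (column
#'   name), `class`, `sensitivity` (>= 0).
#' @export
sensitivity_analysis <- function(model, x, grid_steps = 50, ...) {
  UseMethod("sensitivity_analysis")
}

#' @export
sensitivity_analysis.eo_mlp <- function(model, x, grid_steps = 50, ...) {
  if (grid_steps < 3) stop("`grid_steps` must be >= 3", call. = FALSE)
  p <- ncol(x)
  mu <- colMeans(x)
  n_out <- model$config$n_outputs
  S <- matrix(0, p, n_out)
  for (j in seq_len(p)) {
    grid <- seq(min(x[, j]), max(x[, j]), length.out = grid_steps)
    probe <- matrix(mu, grid_steps, p, byrow = TRUE)
    probe[, j] <- grid
    out <- predict(model, probe, type = "response")
    S[j, ] <- apply(out, 2, function(o) max(o) - min(o))
  }
  peaks <- colnames(x) %||% peak_col_names(p)
  tibble::tibble(
    peak = rep(peaks, n_out),
    class = rep(seq_len(n_out), each = p),
    sensitivity = as.vector(S)
  )
}

#' @param use For `eo_cv`: `"average"` (mean sensitivity over the
#'   per-partition models) or `"best"` (the single model with the highest
#'   external CCR).
#' @rdname sensitivity_analysis
#' @export
sensitivity_analysis.eo_cv <- function(model, x, grid_steps = 50,
                                       use = c("average", "best"), ...) {
  use <- match.arg(use)
  xmat <- feature_values(x)
  idx <- if (use == "best") {
    which.max(model$per_partition$ccr_external)
  } else {
    seq_along(model$models)
  }
  tabs <- lapply(idx, function(r) {
    sc <- model$scalers[[r]]
    xs <- sweep(sweep(xmat, 2, sc$center), 2, sc$scale, "/")
    sensitivity_analysis(model$models[[r]], xs, grid_steps)
  })
  dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$peak, .data$class) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     .groups = "drop") |>
    dplyr::arrange(.data$class, .data$peak)
}

#' Rank inputs by sensitivity, per class
#'
#' For each class output, peaks are sorted by decreasing sensitivity (rank
#' 1 = most sensitive); ties break towards the smaller peak id.
#'
#' @param sens A sensitivity tibble from [sensitivity_analysis()].
#' @return A rank tibble: `class`, `rank`, `peak_id` — each class's rows
#'   are a permutation of the peak ids.
#' @export
rank_inputs <- function(sens) {
  sens |>
    dplyr::mutate(peak_id = match(.data$peak, sort(unique(.data$peak)))) |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(dplyr::desc(.data$sensitivity), .data$peak_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("class", "rank", "peak_id") |>
    dplyr::arrange(.data$class, .data$rank)
}

#' Published per-class peak rankings of the bitter-orange study
#'
#' The sensitivity-based per-class rankings of the 22 consistently
#' detected peaks reported for the four-stage bitter-orange ripening data
#' set, usable as input to [sequential_rank_addition()] and as a worked
#' example of the rank-based feature search.
#'
#' @return A rank tibble (`class`, `rank`, `peak_id`) with 4 x 22 rows.
#' @export
#' @examples
#' trace <- sequential_rank_addition(bitter_orange_rankings())
#' trace$n_cumulative
bitter_orange_rankings <- function() {
  by_class <- list(
    c(11, 1, 3, 15, 18, 19, 20, 10, 4, 5, 9, 17, 21, 14, 12, 13, 22, 6,
      8, 2, 16, 7),
    c(11, 19, 18, 10, 3, 20, 4, 22, 15, 13, 17, 1, 9, 21, 12, 5, 8, 14,
      2, 6, 16, 7),
    c(19, 1, 11, 10, 18, 20, 15, 17, 14, 5, 4, 22, 3, 21, 13, 12, 9, 8,
      6, 2, 16, 7),
    c(1, 19, 11, 18, 10, 20, 15, 22, 21, 17, 5, 3, 14, 4, 13, 9, 6, 12,
      16, 2, 8, 7)
  )
  tibble::tibble(
    class = rep(1:4, each = 22),
    rank = rep(1:22, times = 4),
    peak_id = unlist(by_class)
  )
}

#' Sequential rank-based feature addition
#'
#' Grows the input set from the per-class rankings: starting from the
#' empty set, the rank pointer advances to the lowest rank whose union of
#' per-class peaks contains at least one peak not yet included; all such
#' new peaks join as one step (ranks contributing nothing new are skipped
#' without producing a step). The procedure ends when every peak is in
#' the set, so the steps partition the peak ids.
#'
#' @param ranks A rank tibble (`class`, `rank`, `peak_id`), e.g. from
#'   [rank_inputs()] or [bitter_orange_rankings()].
#' @return A tibble of class `eo_selection_trace`: `step`, `peaks_added`
#'   (list), `n_added`, `cumulative` (list), `n_cumulative`.
#' @export
sequential_rank_addition <- function(ranks) {
  p <- max(ranks$rank)
  peak_ids <- sort(unique(ranks$peak_id))
  if (!all(vapply(split(ranks$peak_id, ranks$class),
                  function(v) setequal(v, peak_ids) && !anyDuplicated(v),
                  logical(1))))
    stop("each class's ranking must be a permutation of the peak ids",
         call. = FALSE)
  cumulative <- integer()
  steps <- list()
  for (r in seq_len(p)) {
    at_rank <- unique(ranks$peak_id[ranks$rank == r])
    new <- sort(setdiff(at_rank, cumulative))
    if (length(new) == 0) next
    cumulative <- c(cumulative, new)
    n_cum <- length(cumulative)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1L,
      peaks_added = list(new),
      n_added = length(new),
      cumulative = list(sort(cumulative)),
      n_cumulative = n_cum
    )
    if (length(cumulative) == length(peak_ids)) break
  }
  out <- dplyr::bind_rows(steps)
  class(out) <- c("eo_selection_trace", class(out))
  out
}

#' Score every step of a selection trace by cross-validation
#'
#' For each step's cumulative peak set, the winning architecture (with its
#' input layer resized to the subset) is re-evaluated under the
#' replicate-grouped double cross-validation of [cross_validate()]. The
#' best step is the one with the highest mean internal-validation CCR;
#' ties break towards the smaller peak set.
#'
#' @param trace A selection trace from [sequential_rank_addition()].
#' @param features A feature tibble with all peaks.
#' @param config The winning [mlp_config()] (its `n_inputs` is resized
#'   per step).
#' @param R Partitions per step.
#' @param seed Master seed.
#' @param fractions Train / internal / external fractions.
#' @return The trace with `ccr_internal` and `ccr_external` columns
#'   (means over partitions) and attributes `best_step` and `cv_best`
#'   (the `eo_cv` of the best step).
#' @export
evaluate_trace <- function(trace, features, config, R = 20, seed = 1L,
                           fractions = c(0.7, 0.1, 0.2)) {
  meta_cols <- c("sample_id", "replicate_id", "class_label")
  all_peaks <- grep("^peak_", names(features), value = TRUE)
  cvs <- vector("list", nrow(trace))
  for (i in seq_len(nrow(trace))) {
    cols <- all_peaks[trace$cumulative[[i]]]
    sub <- features[c(meta_cols, cols)]
    cfg <- config
    cfg$n_inputs <- length(cols)
    cvs[[i]] <- cross_validate(sub, cfg, R = R, seed = seed,
                               fractions = fractions)
  }
  out <- trace
  out$ccr_internal <- vapply(cvs, function(cv)
    mean(cv$per_partition$ccr_internal), numeric(1))
  out$ccr_external <- vapply(cvs, function(cv)
    mean(cv$per_partition$ccr_external), numeric(1))
  best <- which(out$ccr_internal == max(out$ccr_internal))[1]
  attr(out, "best_step") <- best
  attr(out, "cv_best") <- cvs[[best]]
  class(out) <- c("eo_selection_trace", class(out))
  out
}
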