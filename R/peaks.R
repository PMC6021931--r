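#' Detect peaks above the noise threshold
#'
#' Finds all strict local maxima of a baseline-corrected trace whose apex
#' intensity exceeds the detection threshold (noise mean + 3 sd). A local
#' maximum is a point strictly greater than both neighbours; on a plateau
#' the leftmost point is taken as the apex.
#'
#' @param trace A baseline-corrected chromatogram tibble.
#' @param noise A `noise_stats` object; defaults to the one attached by
#'   [preprocess_trace()].
#' @return A tibble sorted by retention time: `rt_apex` (min), `height`
#'   (corrected logged intensity at the apex) and `prominence` (apex
#'   height above the higher of the two flanking valleys).
#' @export
detect_peaks <- function(trace, noise = attr(trace, "noise_stats")) {
  if (trace_stage(trace) != "baseline_corrected")
    stop("peak detection expects a baseline-corrected trace", call. = FALSE)
  if (is.null(noise))
    stop("no noise statistics: run estimate_noise() first", call. = FALSE)
  y <- trace$intensity
  apex <- local_maxima(y)
  apex <- apex[y[apex] > noise$threshold]
  if (length(apex) == 0)
    return(tibble::tibble(rt_apex = numeric(), height = numeric(),
                          prominence = numeric()))
  tibble::tibble(
    rt_apex = trace$rt_min[apex],
    height = y[apex],
    prominence = vapply(apex, peak_prominence, numeric(1), y = y)
  )
}

# indices of strict local maxima; plateaus contribute their leftmost point
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  s <- sign(diff(y))
  # collapse zero runs: a plateau is an apex iff the last nonzero sign
  # before it is +1 and the first nonzero sign after it is -1
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- integer()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] != 1) next
    # next nonzero run after any plateau
    j <- i + 1L
    while (j <= length(runs$values) && runs$values[j] == 0) j <- j + 1L
    if (j <= length(runs$values) && runs$values[j] == -1) {
      out <- c(out, ends[i] + 1L) # first point after the rise
    }
  }
  out
}

peak_prominence <- function(i, y) {
  h <- y[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1 && y[j] <= h) {
    left_min <- min(left_min, y[j])
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  while (j <= length(y) && y[j] <= h) {
    right_min <- min(right_min, y[j])
    j <- j + 1L
  }
  h - max(left_min, right_min)
}

#' Detect peaks in every trace of a preprocessed study
#'
#' @param study A preprocessed study tibble (see [preprocess_study()]).
#' @return A long tibble of detections with trace metadata: `sample_id`,
#'   `replicate_id`, `class_label`, `threshold`, `rt_apex`, `height`,
#'   `prominence`.
#' @export
detect_study <- function(study) {
  res <- purrr::pmap(study, function(sample_id, replicate_id, class_label,
                                     trace, ...) {
    det <- detect_peaks(trace)
    ns <- attr(trace, "noise_stats")
    dplyr::mutate(det,
                  sample_id = sample_id, replicate_id = replicate_id,
                  class_label = class_label, threshold = ns$threshold,
                  .before = 1)
  })
  dplyr::bind_rows(res)
}

#' Match detected peaks across traces into a consistent registry
#'
#' Clusters apex retention times across all traces by greedy gap
#' clustering at two scales. Apexes are first sorted and split wherever
#' the gap between consecutive apexes exceeds `rt_resolution` (the
#' acquisition-grid scale); groups seen in fewer than
#' `presence_threshold` of the traces are discarded as irreproducible —
#' this removes the scattered false apexes that occasional noise
#' excursions above the detection threshold produce, which would
#' otherwise chain distinct compounds together. The surviving groups are
#' then merged with the same gap rule at the cross-run tolerance
#' `rt_tol`. The consensus retention time of a registry peak is the
#' median apex RT of its cluster.
#'
#' @param detections Long detection tibble from [detect_study()] (needs
#'   `sample_id`, `replicate_id`, `rt_apex`).
#' @param rt_tol Maximum retention-time gap (minutes) between apexes of
#'   the same compound across runs. Default 0.1.
#' @param presence_threshold Minimum fraction of traces in which a peak
#'   must be detected. Default 1 (present in every chromatogram).
#' @param n_traces Total number of traces; defaults to the number of
#'   distinct (sample_id, replicate_id) pairs in `detections`.
#' @param rt_resolution Gap scale (minutes) of the first clustering
#'   stage; about two sampling intervals of a 2 Hz acquisition. Default
#'   0.02.
#' @return A registry tibble: `peak_id`, `consensus_rt`,
#'   `presence_fraction`, with attribute `rt_tol`.
#' @export
match_peaks <- function(detections, rt_tol = 0.1, presence_threshold = 1,
                        n_traces = NULL, rt_resolution = 0.02) {
  if (rt_tol <= 0) stop("`rt_tol` must be > 0", call. = FALSE)
  if (presence_threshold <= 0 || presence_threshold > 1)
    stop("`presence_threshold` must be in (0, 1]", call. = FALSE)
  trace_key <- paste(detections$sample_id, detections$replicate_id)
  if (is.null(n_traces)) n_traces <- dplyr::n_distinct(trace_key)
  ord <- order(detections$rt_apex)
  rt <- detections$rt_apex[ord]
  key <- trace_key[ord]

  # stage 1: grid-scale groups, kept only if reproducible across traces
  fine <- cumsum(c(1, diff(rt) > min(rt_resolution, rt_tol)))
  grp <- tibble::tibble(rt = rt, key = key, fine = fine) |>
    dplyr::group_by(.data$fine) |>
    dplyr::summarise(rts = list(.data$rt), keys = list(.data$key),
                     n_traces_seen = dplyr::n_distinct(.data$key),
                     rt = stats::median(.data$rt),
                     .groups = "drop") |>
    dplyr::filter(.data$n_traces_seen / n_traces >= presence_threshold) |>
    dplyr::arrange(.data$rt)

  # stage 2: merge surviving groups within the cross-run tolerance
  if (nrow(grp) == 0) {
    out <- tibble::tibble(peak_id = integer(), consensus_rt = numeric(),
                          presence_fraction = numeric())
    attr(out, "rt_tol") <- rt_tol
    return(out)
  }
  coarse <- cumsum(c(1, diff(grp$rt) > rt_tol))
  reg <- tibble::tibble(coarse = coarse,
                        rts = grp$rts, keys = grp$keys) |>
    dplyr::group_by(.data$coarse) |>
    dplyr::summarise(
      consensus_rt = stats::median(unlist(.data$rts)),
      presence_fraction =
        dplyr::n_distinct(unlist(.data$keys)) / n_traces,
      .groups = "drop") |>
    dplyr::arrange(.data$consensus_rt)
  out <- tibble::tibble(peak_id = seq_len(nrow(reg)),
                        consensus_rt = reg$consensus_rt,
                        presence_fraction = reg$presence_fraction)
  attr(out, "rt_tol") <- rt_tol
  out
}

#' Assemble the samples-by-peaks feature matrix of log peak heights
#'
#' For every trace and registry peak, takes the height of the detection
#' closest in retention time to the peak's consensus RT (within `rt_tol`).
#' A trace with no matching detection gets that trace's own detection
#' threshold as the imputed height; imputed entries are flagged in the
#' `imputed` attribute.
#'
#' @param detections Long detection tibble from [detect_study()].
#' @param registry Registry tibble from [match_peaks()].
#' @param rt_tol Matching tolerance in minutes; defaults to the registry's.
#' @return A feature tibble: `sample_id`, `replicate_id`, `class_label`,
#'   then one `peak_XX` column per registry peak (logged heights), rows
#'   grouped by sample. Attributes: `registry`, `imputed` (logical
#'   matrix).
#' @export
build_feature_matrix <- function(detections, registry,
                                 rt_tol = attr(registry, "rt_tol") %||% 0.1) {
  if (nrow(registry) == 0) stop("empty peak registry", call. = FALSE)
  meta <- detections |>
    dplyr::distinct(.data$sample_id, .data$replicate_id,
                    .data$class_label, .data$threshold) |>
    dplyr::arrange(.data$sample_id, .data$replicate_id)
  p <- nrow(registry)
  vals <- matrix(NA_real_, nrow(meta), p)
  imputed <- matrix(FALSE, nrow(meta), p)
  det_key <- paste(detections$sample_id, detections$replicate_id)
  meta_key <- paste(meta$sample_id, meta$replicate_id)
  det_split <- split(seq_len(nrow(detections)), det_key)
  for (r in seq_len(nrow(meta))) {
    idx <- det_split[[meta_key[r]]]
    for (j in seq_len(p)) {
      d <- abs(detections$rt_apex[idx] - registry$consensus_rt[j])
      hit <- idx[d <= rt_tol]
      if (length(hit) == 0) {
        vals[r, j] <- meta$threshold[r]
        imputed[r, j] <- TRUE
      } else {
        best <- hit[which.min(abs(detections$rt_apex[hit] -
                                    registry$consensus_rt[j]))]
        vals[r, j] <- detections$height[best]
      }
    }
  }
  colnames(vals) <- peak_col_names(p)
  out <- dplyr::bind_cols(
    meta[c("sample_id", "replicate_id", "class_label")],
    tibble::as_tibble(vals)
  )
  attr(out, "registry") <- registry
  attr(out, "imputed") <- imputed
  out
}

#' Extract the numeric peak-height matrix from a feature tibble
#'
#' @param features A feature tibble (from [build_feature_matrix()] or
#'   [simulate_features()]).
#' @return A numeric matrix (rows = traces, columns = peaks).
#' @export
feature_values <- function(features) {
  cols <- grep("^peak_", names(features), value = TRUE)
  as.matrix(features[cols])
}
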