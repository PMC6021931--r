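#' Reference peak set for the four-stage bitter-orange study
#'
#' Returns the 22-peak registry used throughout the package as the default
#' ground truth for synthetic chromatograms: one row per chromatographic
#' peak, at the retention times of the compounds consistently detected in
#' the headspace of bitter-orange essential oil, with per-class mean log10
#' peak heights encoding how each compound evolves over the four fruit
#' ripening stages (green, yellow, light orange, orange).
#'
#' The limonene-like peak at 10.45 min dominates the profile (its mean
#' log10 height is at least two decades above every other peak) but is
#' deliberately uninformative for ripening stage; the class signal lives in
#' a 15-peak subset whose trajectories are increasing, decreasing or
#' U-shaped (similar at the first and last stage, different in between),
#' mirroring the non-monotone evolution of monoterpene abundances during
#' ripening.
#'
#' @param amplitude Trajectory amplitude in log10 units: half-range of the
#'   between-class excursion of an informative peak. Default 0.25.
#' @param star_amplitude Amplitude for the three most informative peaks
#'   (ids 1, 11, 19). Default 0.35.
#' @return A tibble with columns `peak_id`, `rt_min`, `width_min`,
#'   `compound`, `trajectory` and `logh_1` .. `logh_4` (per-class mean
#'   log10 heights, arbitrary intensity units).
#' @export
#' @examples
#' specs <- default_peak_specs()
#' specs[specs$compound == "limonene", ]
default_peak_specs <- function(amplitude = 0.25, star_amplitude = 0.35) {
  rt <- c(1.99, 5.17, 6.95, 8.27, 8.41, 8.83, 9.43, 9.92, 10.45, 11.30,
          11.82, 12.48, 13.28, 13.80, 15.64, 16.83, 18.16, 19.01, 21.66,
          23.40, 25.70, 26.07)
  compound <- c("ND", "ND", "alpha-pinene", "beta-pinene", "ND",
                "beta-myrcene", "ND", "ND", "limonene", "ocimene",
                "cyclopropane-1,2-dibutyl", "cis-linalool oxide",
                "myrcenol", "linalool", "ND", "ND", "linalyl butyrate",
                "alpha-terpineol", "3-carene", "nerol", "ND", "ND")
  # Widths chosen so every pair of neighbouring peaks stays baseline
  # resolved; the 8.27/8.41 pair (0.14 min apart) forces 0.04 min there.
  width <- c(0.10, 0.10, 0.08, 0.04, 0.04, 0.08, 0.09, 0.09, 0.06, 0.10,
             0.10, 0.10, 0.10, 0.10, 0.12, 0.12, 0.12, 0.10, 0.12, 0.12,
             0.08, 0.08)
  base <- c(3.4, 3.0, 3.6, 3.3, 3.0, 3.7, 3.0, 3.1, 6.3, 3.5,
            3.4, 3.1, 3.2, 3.6, 3.0, 3.1, 3.3, 3.5, 3.4, 3.3,
            3.0, 3.1)
  # 15 informative peaks carry the ripening signal; the rest (including
  # the dominant limonene peak) are flat.
  trajectory <- rep("flat", 22)
  trajectory[c(1, 15, 18, 20)] <- "increasing"
  trajectory[c(3, 5, 11, 21, 22)] <- "decreasing"
  trajectory[c(4, 10, 13, 14, 17, 19)] <- "u_shaped"

  amp <- rep(amplitude, 22)
  amp[c(1, 11, 19)] <- star_amplitude

  shapes <- list(
    increasing = c(-1, -1 / 3, 1 / 3, 1),
    decreasing = c(1, 1 / 3, -1 / 3, -1),
    u_shaped   = c(0.8, -0.8, -0.8, 0.8),
    flat       = c(0, 0, 0, 0)
  )
  logh <- t(vapply(seq_len(22), function(j) {
    base[j] + amp[j] * shapes[[trajectory[j]]]
  }, numeric(4)))
  colnames(logh) <- paste0("logh_", 1:4)

  tibble::tibble(
    peak_id = seq_len(22),
    rt_min = rt,
    width_min = width,
    compound = compound,
    trajectory = trajectory,
    tibble::as_tibble(logh)
  )
}

#' Study design for a synthetic ripening study
#'
#' Bundles the sampling design and noise model of a synthetic
#' chromatographic study: how many essential-oil samples per ripening
#' class, how many replicate injections each, and the magnitudes of the
#' instrumental nuisance terms.
#'
#' The default design reproduces the structure of the bitter-orange study
#' the package emulates: 101 oils split 11/27/36/27 over the four ripening
#' stages, each measured in triplicate (303 traces).
#'
#' @param class_sizes Integer vector of length 4: number of distinct oils
#'   per ripening class.
#' @param replicates Replicate injections per oil.
#' @param noise_sd Standard deviation of the additive detector noise on
#'   the raw intensity scale (arbitrary units); must be strictly positive.
#' @param baseline_amplitude Scale of the smooth drifting baseline (raw
#'   intensity units, >= 0).
#' @param eo_log_sd Between-oil scatter: sd of a per-oil log10 intensity
#'   shift shared by all peaks and replicates of that oil.
#' @param replicate_log_sd Within-oil scatter: sd of a per-trace log10
#'   intensity shift.
#' @param separability Scalar multiplier on the between-class log-height
#'   differences; 0 removes all class signal, 1 is the default study.
#' @param rt_range Retention-time window in minutes.
#' @param points_per_sec Sampling rate of the retention-time grid
#'   (acquisitions per second; the grid is uniform).
#' @param seed Default seed used by [simulate_study()].
#' @return An object of class `eo_design` (a validated list).
#' @export
#' @examples
#' design <- study_design()
#' design$class_sizes
study_design <- function(class_sizes = c(11, 27, 36, 27),
                         replicates = 3,
                         noise_sd = 2,
                         baseline_amplitude = 50,
                         eo_log_sd = 0.15,
                         replicate_log_sd = 0.05,
                         separability = 1,
                         rt_range = c(0.5, 28),
                         points_per_sec = 2,
                         seed = 1L) {
  if (length(class_sizes) != 4 || any(class_sizes < 1))
    stop("`class_sizes` must be 4 positive integers", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("invalid design: `noise_sd` must be > 0", call. = FALSE)
  if (baseline_amplitude < 0)
    stop("invalid design: `baseline_amplitude` must be >= 0", call. = FALSE)
  if (eo_log_sd < 0 || replicate_log_sd < 0)
    stop("invalid design: log-scale sds must be >= 0", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(class_sizes = as.integer(class_sizes),
         replicates = as.integer(replicates),
         noise_sd = noise_sd,
         baseline_amplitude = baseline_amplitude,
         eo_log_sd = eo_log_sd,
         replicate_log_sd = replicate_log_sd,
         separability = separability,
         rt_range = rt_range,
         points_per_sec = points_per_sec,
         seed = as.integer(seed)),
    class = "eo_design"
  )
}

#' @export
print.eo_design <- function(x, ...) {
  cat("<eo_design>\n")
  cat("  oils per class:", paste(x$class_sizes, collapse = "/"),
      " replicates:", x$replicates,
      " (", sum(x$class_sizes) * x$replicates, "traces )\n")
  cat("  noise_sd:", x$noise_sd,
      " baseline_amplitude:", x$baseline_amplitude, "\n")
  cat("  eo_log_sd:", x$eo_log_sd,
      " replicate_log_sd:", x$replicate_log_sd,
      " separability:", x$separability, "\n")
  invisible(x)
}

rt_grid <- function(design) {
  step <- 1 / (60 * design$points_per_sec)
  seq(design$rt_range[1], design$rt_range[2], by = step)
}

# per-class log10 heights after applying the separability multiplier
class_log_heights <- function(specs, separability = 1) {
  h <- as.matrix(specs[paste0("logh_", 1:4)])
  m <- rowMeans(h)
  m + separability * (h - m)
}

new_trace <- function(rt, intensity, sample_id = NA_character_,
                      replicate_id = NA_integer_, class_label = NA_integer_,
                      stage = "raw") {
  out <- tibble::tibble(rt_min = rt, intensity = intensity)
  attr(out, "sample_id") <- sample_id
  attr(out, "replicate_id") <- replicate_id
  attr(out, "class_label") <- class_label
  attr(out, "stage") <- stage
  class(out) <- c("eo_trace", class(out))
  out
}

trace_stage <- function(trace) attr(trace, "stage") %||% "raw"

#' Simulate a single chromatogram
#'
#' Renders one total-ion-chromatogram trace for a sample of a given
#' ripening class: Gaussian peaks at the spec retention times, scaled by
#' `10^(class log height + eo_effect + replicate_effect)`, riding on a
#' smooth strictly positive drifting baseline, plus i.i.d. Gaussian
#' detector noise. Uses the current R random-number state; seed upstream
#' for reproducibility (as [simulate_study()] does).
#'
#' @param specs Peak spec tibble, see [default_peak_specs()].
#' @param class_index Ripening class, 1..4.
#' @param eo_effect,replicate_effect Log10 intensity shifts shared by all
#'   peaks of the trace (between-oil and within-oil nuisance terms).
#' @param design An [study_design()] object.
#' @return A chromatogram tibble (`rt_min`, `intensity`) with stage `"raw"`.
#' @export
simulate_chromatogram <- function(specs, class_index, eo_effect = 0,
                                  replicate_effect = 0,
                                  design = study_design()) {
  stopifnot(inherits(design, "eo_design"))
  if (!class_index %in% 1:4)
    stop("`class_index` must be in 1..4", call. = FALSE)
  t <- rt_grid(design)
  y <- baseline_truth(t, design)
  logh <- class_log_heights(specs, design$separability)[, class_index]
  heights <- 10^(logh + eo_effect + replicate_effect)
  for (j in seq_len(nrow(specs))) {
    y <- y + heights[j] *
      exp(-(t - specs$rt_min[j])^2 / (2 * specs$width_min[j]^2))
  }
  y <- y + stats::rnorm(length(t), 0, design$noise_sd)
  new_trace(t, y, class_label = as.integer(class_index), stage = "raw")
}

# Smooth, slowly varying, strictly positive baseline: linear drift plus one
# broad low-frequency cosine. Kept gentle (about +/-10% of the amplitude)
# so the log-scale noise level is nearly uniform along the trace, as it is
# for a real detector between peaks.
baseline_truth <- function(t, design) {
  u <- (t - design$rt_range[1]) / diff(design$rt_range)
  design$baseline_amplitude * (1 + 0.1 * u + 0.05 * cos(2 * pi * u))
}

#' Simulate a full ripening study
#'
#' Generates every chromatogram of a study design along with its sample
#' manifest. Each oil draws one between-oil intensity shift shared by its
#' replicate injections; each injection adds its own within-oil shift.
#'
#' @param specs Peak spec tibble, see [default_peak_specs()].
#' @param design An [study_design()] object.
#' @param seed Integer seed; defaults to the design's seed.
#' @return A tibble with one row per trace: `sample_id`, `replicate_id`,
#'   `class_label` and a `trace` list-column of chromatogram tibbles.
#' @export
#' @examples
#' small <- study_design(class_sizes = c(1, 1, 1, 1), replicates = 1)
#' study <- simulate_study(default_peak_specs(), small)
#' nrow(study)
simulate_study <- function(specs, design = study_design(),
                           seed = design$seed) {
  stopifnot(inherits(design, "eo_design"))
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  n_eo <- sum(design$class_sizes)
  classes <- rep(1:4, times = design$class_sizes)
  sample_ids <- sprintf("eo_%03d", seq_len(n_eo))
  rows <- vector("list", n_eo * design$replicates)
  k <- 0L
  for (i in seq_len(n_eo)) {
    eo_eff <- stats::rnorm(1, 0, design$eo_log_sd)
    for (r in seq_len(design$replicates)) {
      rep_eff <- stats::rnorm(1, 0, design$replicate_log_sd)
      tr <- simulate_chromatogram(specs, classes[i], eo_eff, rep_eff, design)
      attr(tr, "sample_id") <- sample_ids[i]
      attr(tr, "replicate_id") <- r
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        sample_id = sample_ids[i],
        replicate_id = r,
        class_label = classes[i],
        trace = list(tr)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a feature matrix directly (no chromatogram rendering)
#'
#' Draws the samples-by-peaks matrix of log10 peak heights straight from
#' the generative model of [simulate_study()], bypassing trace rendering,
#' baseline estimation and peak detection. Useful for fast classifier and
#' permutation experiments where the chromatographic stages are not under
#' test. A small i.i.d. log-scale measurement noise stands in for the
#' residual height error of the detection stage.
#'
#' @inheritParams simulate_study
#' @param height_log_sd Per-entry log10 measurement noise (default 0.01,
#'   about the apex-height error of detection on default-noise traces).
#' @return A feature tibble: `sample_id`, `replicate_id`, `class_label`,
#'   then one `peak_XX` column per spec peak.
#' @export
simulate_features <- function(specs, design = study_design(),
                              seed = design$seed, height_log_sd = 0.01) {
  stopifnot(inherits(design, "eo_design"))
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  n_eo <- sum(design$class_sizes)
  classes <- rep(1:4, times = design$class_sizes)
  sample_ids <- sprintf("eo_%03d", seq_len(n_eo))
  logh <- class_log_heights(specs, design$separability)
  p <- nrow(specs)

  rows <- vector("list", n_eo * design$replicates)
  k <- 0L
  for (i in seq_len(n_eo)) {
    eo_eff <- stats::rnorm(1, 0, design$eo_log_sd)
    for (r in seq_len(design$replicates)) {
      rep_eff <- stats::rnorm(1, 0, design$replicate_log_sd)
      vals <- logh[, classes[i]] + eo_eff + rep_eff +
        stats::rnorm(p, 0, height_log_sd)
      k <- k + 1L
      rows[[k]] <- c(list(sample_id = sample_ids[i], replicate_id = r,
                          class_label = classes[i]),
                     stats::setNames(as.list(vals), peak_col_names(p)))
    }
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

peak_col_names <- function(p) sprintf("peak_%02d", seq_len(p))

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a study as plain tabular text
#'
#' Each trace goes to its own two-column file (`rt_min`, `intensity`,
#' header row, '.' decimal separator); the manifest lists
#' `sample_id, replicate_id, class_label, path`.
#'
#' @param study A study tibble from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `write_study()` returns the manifest tibble invisibly;
#'   `read_study()` returns a study tibble.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- sprintf("%s_r%d.tsv", study$sample_id, study$replicate_id)
  for (i in seq_len(nrow(study))) {
    utils::write.table(
      as.data.frame(study$trace[[i]][c("rt_min", "intensity")]),
      file.path(dir, paths[i]),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  manifest <- tibble::tibble(
    sample_id = study$sample_id,
    replicate_id = study$replicate_id,
    class_label = study$class_label,
    path = paths
  )
  utils::write.table(as.data.frame(manifest),
                     file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.table(
    file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
  traces <- purrr::pmap(manifest, function(sample_id, replicate_id,
                                           class_label, path) {
    d <- utils::read.table(file.path(dir, path), header = TRUE, sep = "\t")
    new_trace(d$rt_min, d$intensity, sample_id, replicate_id,
              as.integer(class_label), stage = "raw")
  })
  dplyr::mutate(manifest[c("sample_id", "replicate_id", "class_label")],
                trace = traces)
}
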