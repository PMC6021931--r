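#' Configuration of the full profiling pipeline
#'
#' Collects every stage parameter with its default, so one object (plus a
#' seed) fully determines a pipeline run.
#'
#' @param design An [study_design()] object (the synthetic study to
#'   generate; ignored when a study is passed to [run_pipeline()]).
#' @param psalsa A [psalsa_params()] object.
#' @param log_offset Log-transform offset (raw intensity units).
#' @param quiet_fraction Noise-region fraction for [estimate_noise()].
#' @param rt_tol Peak-matching tolerance in minutes.
#' @param presence_threshold Minimum presence fraction for registry peaks.
#' @param fractions Train / internal / external split fractions.
#' @param R_partitions Partitions for architecture search and selection.
#' @param search_widths Hidden-layer width ladder of the architecture
#'   search.
#' @param two_layer Include two-layer architectures in the search.
#' @param grid_steps Sensitivity-sweep resolution.
#' @param n_perm Label permutations of the significance test.
#' @param R_null Partitions per permutation.
#' @param max_epochs,patience Training schedule passed to every
#'   [mlp_config()].
#' @param seed Master seed of the run.
#' @return A list of class `eo_pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            psalsa = psalsa_params(),
                            log_offset = 1,
                            quiet_fraction = 0.2,
                            rt_tol = 0.1,
                            presence_threshold = 1,
                            fractions = c(0.7, 0.1, 0.2),
                            R_partitions = 20,
                            search_widths = c(4, 8, 13),
                            two_layer = FALSE,
                            grid_steps = 50,
                            n_perm = 50,
                            R_null = 5,
                            max_epochs = 200L,
                            patience = 30L,
                            seed = 1L) {
  structure(list(design = design, psalsa = psalsa,
                 log_offset = log_offset,
                 quiet_fraction = quiet_fraction, rt_tol = rt_tol,
                 presence_threshold = presence_threshold,
                 fractions = fractions, R_partitions = R_partitions,
                 search_widths = search_widths, two_layer = two_layer,
                 grid_steps = grid_steps, n_perm = n_perm,
                 R_null = R_null, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "eo_pipeline_config")
}

#' Run the full profiling pipeline
#'
#' Executes every stage in order: simulate (unless a study is supplied),
#' preprocess, detect and match peaks, build the feature matrix, select
#' the network architecture, rank inputs by sensitivity, run the
#' sequential feature search, score the selected subset on external
#' validation, and assess significance with the label-permutation test.
#' Fully reproducible from the configuration and its seed.
#'
#' @param config An [pipeline_config()] object.
#' @param study Optional study tibble (e.g. from [read_study()]); when
#'   `NULL` the configured synthetic study is generated.
#' @param specs Peak specs used when simulating (default
#'   [default_peak_specs()]).
#' @return A list of class `eo_pipeline` with every stage artifact:
#'   `features`, `registry`, `arch_search`, `sensitivity`, `ranks`,
#'   `trace`, `cv_selected`, `permtest`, and a one-row `summary` tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         specs = default_peak_specs()) {
  stopifnot(inherits(config, "eo_pipeline_config"))
  if (is.null(study))
    study <- simulate_study(specs, config$design, seed = config$seed)

  study <- preprocess_study(study, params = config$psalsa,
                            offset = config$log_offset,
                            quiet_fraction = config$quiet_fraction)
  detections <- detect_study(study)
  registry <- match_peaks(detections, rt_tol = config$rt_tol,
                          presence_threshold = config$presence_threshold)
  if (nrow(registry) == 0)
    stop("peak matching produced an empty registry", call. = FALSE)
  features <- build_feature_matrix(detections, registry)

  space <- mlp_search_space(n_inputs = nrow(registry),
                            widths = config$search_widths,
                            two_layer = config$two_layer,
                            max_epochs = config$max_epochs,
                            patience = config$patience)
  search <- select_architecture(features, space, R = config$R_partitions,
                                seed = config$seed,
                                fractions = config$fractions)

  sens <- sensitivity_analysis(search$cv, features,
                               grid_steps = config$grid_steps)
  ranks <- rank_inputs(sens)
  trace <- sequential_rank_addition(ranks)
  trace <- evaluate_trace(trace, features, search$best_config,
                          R = config$R_partitions, seed = config$seed,
                          fractions = config$fractions)
  best_step <- attr(trace, "best_step")
  selected <- trace$cumulative[[best_step]]

  sel_features <- features[c("sample_id", "replicate_id", "class_label",
                             peak_col_names(nrow(registry))[selected])]
  sel_config <- search$best_config
  sel_config$n_inputs <- length(selected)
  permtest <- permutation_test(sel_features, sel_config,
                               n_perm = config$n_perm,
                               R_observed = config$R_partitions,
                               R_null = config$R_null,
                               seed = config$seed,
                               fractions = config$fractions)
  cv_selected <- permtest$observed_cv

  summary <- tibble::tibble(
    n_traces = nrow(features),
    n_registry_peaks = nrow(registry),
    architecture = paste(c(search$best_config$n_inputs,
                           search$best_config$hidden, 4), collapse = "-"),
    n_selected_peaks = length(selected),
    ccr_external_full = mean(search$cv$per_partition$ccr_external),
    ccr_external_selected = mean(cv_selected$per_partition$ccr_external),
    ccr_external_selected_sd = stats::sd(
      cv_selected$per_partition$ccr_external),
    p_value = permtest$p_value,
    p_empirical = permtest$p_empirical
  )
  structure(list(config = config, registry = registry,
                 features = features, arch_search = search,
                 sensitivity = sens, ranks = ranks, trace = trace,
                 selected_peaks = selected, cv_selected = cv_selected,
                 permtest = permtest, summary = summary),
            class = "eo_pipeline")
}

#' @export
print.eo_pipeline <- function(x, ...) {
  cat("<eo_pipeline>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Exploratory principal component overview of the feature matrix
#'
#' Centered (not scaled) PCA of the log peak heights, for a first look at
#' the inner dimensionality of the profile data.
#'
#' @param features A feature tibble.
#' @return A tibble `component`, `variance_fraction`, `cumulative`
#'   (fractions non-increasing, summing to 1), with the scores of the
#'   first three components in the `scores` attribute.
#' @export
pca_overview <- function(features) {
  x <- feature_values(features)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- v / sum(v)
  out <- tibble::tibble(component = seq_along(frac),
                        variance_fraction = frac,
                        cumulative = cumsum(frac))
  k <- min(3, ncol(pc$x))
  attr(out, "scores") <- dplyr::bind_cols(
    features[intersect(c("sample_id", "replicate_id", "class_label"),
                       names(features))],
    tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  )
  out
}
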