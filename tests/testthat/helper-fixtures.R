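# Small fixtures shared across test files; everything is generated in code.

# a minimal 3-peak spec table with one strong flat peak and two class-
# dependent ones
tiny_specs <- function() {
  tibble::tibble(
    peak_id = 1:3,
    rt_min = c(5, 10, 15),
    width_min = c(0.1, 0.1, 0.1),
    compound = c("a", "b", "c"),
    trajectory = c("increasing", "flat", "decreasing"),
    logh_1 = c(2.8, 4.0, 3.2),
    logh_2 = c(2.9, 4.0, 3.1),
    logh_3 = c(3.1, 4.0, 2.9),
    logh_4 = c(3.2, 4.0, 2.8)
  )
}

# spec table with `p` peaks, all flat except `planted`, which carry a
# strong monotone class trajectory
planted_specs <- function(p = 8, planted = c(2, 5), amplitude = 0.5) {
  shape <- c(-1, -1 / 3, 1 / 3, 1)
  logh <- matrix(3.2, p, 4)
  for (j in planted) logh[j, ] <- 3.2 + amplitude * shape
  tibble::tibble(
    peak_id = seq_len(p),
    rt_min = seq(3, 25, length.out = p),
    width_min = rep(0.1, p),
    compound = sprintf("c%02d", seq_len(p)),
    trajectory = ifelse(seq_len(p) %in% planted, "increasing", "flat"),
    logh_1 = logh[, 1], logh_2 = logh[, 2],
    logh_3 = logh[, 3], logh_4 = logh[, 4]
  )
}

# near-noiseless design on a small class layout. noise_sd is kept small
# enough that peak heights are exact to well under 1%, but large enough
# that the detection threshold sits above the ~1e-3 log-unit ripple the
# smoothness penalty leaves around very tall peaks.
quiet_design <- function(class_sizes = c(2, 2, 2, 2), replicates = 1,
                         ...) {
  study_design(class_sizes = class_sizes, replicates = replicates,
               noise_sd = 0.003, baseline_amplitude = 0,
               eo_log_sd = 0, replicate_log_sd = 0, ...)
}

# a fast training configuration for classifier tests
fast_config <- function(n_inputs, hidden = 8, ...) {
  mlp_config(n_inputs, hidden = hidden, max_epochs = 120L,
             patience = 20L, ...)
}

# one-layer linear "network" (input directly to linear outputs) with a
# given weight matrix; exercised by the closed-form sensitivity oracle
linear_toy_mlp <- function(W) {
  structure(
    list(layers = list(list(W = W, b = rep(0, ncol(W)))),
         config = list(activation = "tanh", n_outputs = ncol(W))),
    class = "eo_mlp"
  )
}

# replicate-level manifest with the reference class layout
reference_manifest <- function(class_sizes = c(11, 27, 36, 27),
                               replicates = 3) {
  n <- sum(class_sizes)
  tibble::tibble(
    sample_id = rep(sprintf("eo_%03d", seq_len(n)), each = replicates),
    replicate_id = rep(seq_len(replicates), n),
    class_label = rep(rep(1:4, times = class_sizes), each = replicates)
  )
}
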