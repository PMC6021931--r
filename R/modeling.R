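#' Replicate-grouped, class-stratified three-way split
#'
#' Assigns every oil (sample) of the manifest to training, internal
#' validation or external validation, stratified by ripening class: per
#' class, `round(f_train * n)` oils go to training and
#' `round(f_val * n)` to internal validation (round half up), the
#' remainder to external validation. All replicates of an oil always share
#' its subset, so replicate identity can never leak across subsets.
#'
#' @param manifest A tibble with at least `sample_id` and `class_label`
#'   (replicate rows are allowed and collapsed).
#' @param fractions Length-3 numeric (train, internal, external), summing
#'   to 1. Default `c(0.70, 0.10, 0.20)`.
#' @return A tibble `sample_id`, `class_label`, `subset` (factor with
#'   levels train / internal / external).
#' @export
#' @examples
#' m <- tibble::tibble(sample_id = sprintf("s%02d", 1:27), class_label = 2)
#' set.seed(1)
#' table(grouped_stratified_split(m)$subset)
grouped_stratified_split <- function(manifest,
                                     fractions = c(0.70, 0.10, 0.20)) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1", call. = FALSE)
  eos <- dplyr::distinct(manifest, .data$sample_id, .data$class_label)
  out <- lapply(split(eos, eos$class_label), function(cl) {
    n <- nrow(cl)
    n_tr <- round_half_up(fractions[1] * n)
    n_iv <- round_half_up(fractions[2] * n)
    while (n_tr + n_iv > n) { # degenerate small classes
      if (n_iv > 0) n_iv <- n_iv - 1L else n_tr <- n_tr - 1L
    }
    n_ex <- n - n_tr - n_iv
    need <- c(train = fractions[1], internal = fractions[2],
              external = fractions[3]) > 0
    got <- c(train = n_tr, internal = n_iv, external = n_ex) > 0
    if (any(need & !got))
      stop("class ", cl$class_label[1],
           " has too few samples for the requested subsets", call. = FALSE)
    subset <- rep(c("train", "internal", "external"),
                  times = c(n_tr, n_iv, n_ex))
    cl$subset <- sample(subset)
    cl
  })
  out <- dplyr::bind_rows(out)
  out$subset <- factor(out$subset,
                       levels = c("train", "internal", "external"))
  dplyr::arrange(out, .data$sample_id)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

# R independent split plans under one master seed
make_partition_plans <- function(manifest, R, fractions = c(0.7, 0.1, 0.2),
                                 seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, R)
  lapply(seq_len(R), function(r) {
    set.seed(seeds[r])
    grouped_stratified_split(manifest, fractions)
  })
}

#' Column-wise z-scoring fitted on the training subset
#'
#' @param x Numeric feature matrix (rows = replicate traces).
#' @param train_rows Logical or integer index of the training rows.
#' @return A list with the transformed matrix `x`, and the `center` and
#'   `scale` vectors estimated from the training rows only. Zero-variance
#'   columns get unit scale (with a warning).
#' @export
standardize_features <- function(x, train_rows) {
  xtr <- x[train_rows, , drop = FALSE]
  center <- colMeans(xtr)
  scale_ <- apply(xtr, 2, stats::sd)
  zero <- !is.finite(scale_) | scale_ == 0
  if (any(zero)) {
    warning("zero-variance feature column(s): ",
            paste(colnames(x)[zero], collapse = ", "),
            "; using unit scale", call. = FALSE)
    scale_[zero] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale_, "/"),
       center = center, scale = scale_)
}

#' Multilayer perceptron configuration
#'
#' Describes the network architecture and training hyper-parameters of the
#' ripening-stage classifier: 1 or 2 sigmoidal hidden layers, a 4-unit
#' linear output layer scored against one-hot class targets with a
#' least-squares objective, trained full-batch by resilient
#' backpropagation (sign-based per-weight step sizes, grow factor 1.2,
#' shrink factor 0.5, steps bounded to [1e-6, 50]).
#'
#' @param n_inputs Number of input features.
#' @param hidden Integer vector of 1 or 2 hidden-layer widths.
#' @param activation Hidden activation: `"tanh"` (hyperbolic tangent
#'   sigmoid) or `"logistic"`.
#' @param n_outputs Output width (one unit per class).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs, judged on the
#'   internal-validation correct classification rate (ignored when no
#'   validation set is supplied).
#' @param seed Seed for weight initialization.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(n_inputs, hidden = 8L,
                       activation = c("tanh", "logistic"),
                       n_outputs = 4L, max_epochs = 200L, patience = 30L,
                       seed = 1L) {
  activation <- match.arg(activation)
  if (length(hidden) < 1 || length(hidden) > 2 || any(hidden < 1))
    stop("`hidden` must be 1 or 2 positive widths", call. = FALSE)
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden = as.integer(hidden),
                 activation = activation,
                 n_outputs = as.integer(n_outputs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' @export
print.mlp_config <- function(x, ...) {
  cat("<mlp_config> ", paste(c(x$n_inputs, x$hidden, x$n_outputs),
                             collapse = "-"),
      " ", x$activation, "/linear, rprop, max ", x$max_epochs,
      " epochs\n", sep = "")
  invisible(x)
}

#' Number of trainable weights of a configuration
#' @param config An [mlp_config()] object.
#' @return Integer count of weights and biases.
#' @export
n_weights <- function(config) {
  widths <- c(config$n_inputs, config$hidden, config$n_outputs)
  sum(widths[-length(widths)] * widths[-1]) + sum(widths[-1])
}

init_layers <- function(config) {
  widths <- c(config$n_inputs, config$hidden, config$n_outputs)
  lapply(seq_len(length(widths) - 1), function(l) {
    fan_in <- widths[l]
    list(W = matrix(stats::rnorm(fan_in * widths[l + 1], 0,
                                 1 / sqrt(fan_in)),
                    fan_in, widths[l + 1]),
         b = rep(0, widths[l + 1]))
  })
}

act_fun <- function(z, type) {
  if (type == "tanh") tanh(z) else 1 / (1 + exp(-z))
}
act_grad <- function(a, type) {
  if (type == "tanh") 1 - a^2 else a * (1 - a)
}

mlp_forward <- function(layers, x, activation) {
  n_layers <- length(layers)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(x), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1]] <- if (l < n_layers) act_fun(z, activation) else z
  }
  acts
}

mlp_backward <- function(layers, acts, y, activation) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  delta <- 2 * (acts[[n_layers + 1]] - y) # d(least squares)/d(output)
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) *
        act_grad(acts[[l]], activation)
    }
  }
  grads
}

#' Train a multilayer perceptron with resilient backpropagation
#'
#' Minimizes the summed squared error between the 4 linear outputs and the
#' one-hot class targets by full-batch Rprop. When a validation set is
#' given, training stops early once the validation correct classification
#' rate has not improved for `patience` epochs and the best-scoring
#' weights are restored.
#'
#' @param x Numeric matrix of (standardized) training features.
#' @param y Integer class labels 1..n_outputs.
#' @param config An [mlp_config()] object.
#' @param x_val,y_val Optional validation set for early stopping.
#' @return An object of class `eo_mlp`: layers, config, `best_epoch`,
#'   `val_ccr` (if validated), final training loss.
#' @export
train_mlp <- function(x, y, config, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(config, "mlp_config"))
  if (nrow(x) < config$n_outputs)
    stop("need at least as many rows as classes", call. = FALSE)
  if (ncol(x) != config$n_inputs)
    stop("feature count does not match `config$n_inputs`", call. = FALSE)
  y_onehot <- diag(config$n_outputs)[y, , drop = FALSE]
  set.seed(config$seed)
  layers <- init_layers(config)
  act <- config$activation

  # rprop state: per-weight step size and previous gradient sign
  steps <- lapply(layers, function(l)
    list(W = matrix(0.1, nrow(l$W), ncol(l$W)), b = rep(0.1, length(l$b))))
  prev <- lapply(layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b))))

  best <- list(ccr = -Inf, layers = layers, epoch = 0L)
  stale <- 0L
  loss <- NA_real_
  trained_epochs <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    acts <- mlp_forward(layers, x, act)
    loss <- sum((acts[[length(acts)]] - y_onehot)^2)
    if (!is.finite(loss))
      stop("non-finite training loss at epoch ", epoch, call. = FALSE)
    grads <- mlp_backward(layers, acts, y_onehot, act)
    for (l in seq_along(layers)) {
      for (part in c("W", "b")) {
        g <- grads[[l]][[part]]
        s <- g * prev[[l]][[part]]
        st <- steps[[l]][[part]]
        st[s > 0] <- pmin(st[s > 0] * 1.2, 50)
        st[s < 0] <- pmax(st[s < 0] * 0.5, 1e-6)
        g[s < 0] <- 0 # iRprop-: forget the sign after a reversal
        layers[[l]][[part]] <- layers[[l]][[part]] - sign(g) * st
        steps[[l]][[part]] <- st
        prev[[l]][[part]] <- g
      }
    }
    if (!is.null(x_val)) {
      pred <- mlp_predict_classes(layers, x_val, act)
      vc <- mean(pred == y_val)
      if (vc > best$ccr) {
        best <- list(ccr = vc, layers = layers, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) {
          trained_epochs <- epoch
          break
        }
      }
    }
  }
  if (!is.null(x_val)) layers <- best$layers
  structure(list(layers = layers, config = config,
                 best_epoch = if (is.null(x_val)) trained_epochs
                              else best$epoch,
                 val_ccr = if (is.null(x_val)) NA_real_ else best$ccr,
                 loss = loss),
            class = "eo_mlp")
}

mlp_predict_classes <- function(layers, x, activation) {
  out <- mlp_forward(layers, x, activation)
  max.col(out[[length(out)]], ties.method = "first")
}

#' Predict from a trained perceptron
#'
#' @param object An `eo_mlp` model.
#' @param newdata Feature matrix on the same (standardized) scale the
#'   model was trained on.
#' @param type `"class"` for hard labels (argmax over the linear outputs)
#'   or `"response"` for the raw output matrix.
#' @param ... Unused.
#' @export
predict.eo_mlp <- function(object, newdata, type = c("class", "response"),
                           ...) {
  type <- match.arg(type)
  acts <- mlp_forward(object$layers, newdata, object$config$activation)
  out <- acts[[length(acts)]]
  if (type == "response") out
  else max.col(out, ties.method = "first")
}

#' Correct classification rate
#'
#' The fraction of rows whose predicted class equals the true class
#' (`Nright / N`).
#'
#' @param predicted,true Equal-length class vectors.
#' @return A number in \[0, 1\].
#' @export
ccr <- function(predicted, true) {
  if (length(predicted) == 0 || length(predicted) != length(true))
    stop("`predicted` and `true` must be non-empty and equal length",
         call. = FALSE)
  mean(predicted == true)
}

#' Average row-normalized confusion matrices, in percent
#'
#' Each matrix is row-normalized (true classes in rows) and converted to
#' percentages before element-wise averaging, so every averaged row sums
#' to 100.
#'
#' @param mats A list of square confusion-count matrices (true x
#'   predicted).
#' @return A percentage matrix of the same dimension.
#' @export
averaged_confusion <- function(mats) {
  if (length(mats) == 0) stop("no confusion matrices", call. = FALSE)
  norm <- lapply(mats, function(m) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    100 * m / rs
  })
  Reduce(`+`, norm) / length(norm)
}

confusion_counts <- function(true, predicted, n_classes = 4) {
  m <- matrix(0, n_classes, n_classes)
  for (i in seq_along(true)) m[true[i], predicted[i]] <-
      m[true[i], predicted[i]] + 1
  m
}

# Train/score one configuration on one split plan.
# Returns internal CCR and (optionally, after refitting on train+internal)
# external CCR, confusion counts and EO-level majority-vote CCR.
eval_config_on_plan <- function(xmat, y, sample_ids, plan, config, seed_r,
                                external = FALSE) {
  subset_of <- stats::setNames(as.character(plan$subset), plan$sample_id)
  row_subset <- subset_of[sample_ids]
  tr <- row_subset == "train"
  iv <- row_subset == "internal"
  ex <- row_subset == "external"

  sc <- standardize_features(xmat, tr)
  cfg <- config
  cfg$seed <- seed_r
  fit <- train_mlp(sc$x[tr, , drop = FALSE], y[tr], cfg,
                   x_val = sc$x[iv, , drop = FALSE], y_val = y[iv])
  ccr_internal <- fit$val_ccr
  res <- list(ccr_internal = ccr_internal)
  if (external) {
    fused <- tr | iv
    cfg2 <- cfg
    cfg2$max_epochs <- max(fit$best_epoch, 1L)
    refit <- train_mlp(sc$x[fused, , drop = FALSE], y[fused], cfg2)
    pred <- predict(refit, sc$x[ex, , drop = FALSE])
    res$ccr_external <- ccr(pred, y[ex])
    res$confusion <- confusion_counts(y[ex], pred, config$n_outputs)
    res$ccr_external_eo <- eo_majority_ccr(sample_ids[ex], pred, y[ex])
    res$model <- refit
    res$scaler <- sc[c("center", "scale")]
  }
  res
}

eo_majority_ccr <- function(sample_ids, pred, true) {
  by_eo <- split(seq_along(pred), sample_ids)
  votes <- vapply(by_eo, function(i) {
    tab <- table(pred[i])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  truth <- vapply(by_eo, function(i) true[i][1], numeric(1))
  mean(votes == truth)
}

#' Fixed-architecture double cross-validation
#'
#' Runs `R` replicate-grouped stratified partitions: per partition the
#' network is trained on the training subset with early stopping on the
#' internal-validation subset, then refit on the fused training +
#' internal data and scored on the untouched external subset.
#'
#' @param features A feature tibble (`sample_id`, `replicate_id`,
#'   `class_label`, `peak_*` columns).
#' @param config An [mlp_config()] object.
#' @param R Number of random partitions.
#' @param seed Master seed; per-partition seeds are derived from it.
#' @param fractions Train / internal / external fractions.
#' @return An object of class `eo_cv`: per-partition tibble (`partition`,
#'   `ccr_internal`, `ccr_external`, `ccr_external_eo`), averaged
#'   percentage confusion matrix, the config, and the per-partition
#'   models.
#' @export
cross_validate <- function(features, config, R = 50, seed = 1L,
                           fractions = c(0.7, 0.1, 0.2)) {
  xmat <- feature_values(features)
  y <- features$class_label
  plans <- make_partition_plans(features, R, fractions, seed)
  set.seed(seed + 1L)
  seeds <- sample.int(.Machine$integer.max - 1L, R)
  res <- lapply(seq_len(R), function(r) {
    eval_config_on_plan(xmat, y, features$sample_id, plans[[r]], config,
                        seeds[r], external = TRUE)
  })
  per_partition <- tibble::tibble(
    partition = seq_len(R),
    ccr_internal = vapply(res, `[[`, numeric(1), "ccr_internal"),
    ccr_external = vapply(res, `[[`, numeric(1), "ccr_external"),
    ccr_external_eo = vapply(res, `[[`, numeric(1), "ccr_external_eo")
  )
  structure(list(per_partition = per_partition,
                 confusion = averaged_confusion(
                   lapply(res, `[[`, "confusion")),
                 config = config,
                 models = lapply(res, `[[`, "model"),
                 scalers = lapply(res, `[[`, "scaler"),
                 plans = plans,
                 seed = seed),
            class = "eo_cv")
}

#' @export
print.eo_cv <- function(x, ...) {
  cat("<eo_cv> ", nrow(x$per_partition), " partitions, architecture ",
      paste(c(x$config$n_inputs, x$config$hidden, x$config$n_outputs),
            collapse = "-"), " (", x$config$activation, ")\n", sep = "")
  cat(sprintf("  internal CCR %.3f +/- %.3f, external CCR %.3f +/- %.3f\n",
              mean(x$per_partition$ccr_internal),
              stats::sd(x$per_partition$ccr_internal),
              mean(x$per_partition$ccr_external),
              stats::sd(x$per_partition$ccr_external)))
  invisible(x)
}

#' Default architecture search space
#'
#' One- and two-hidden-layer perceptrons with widths from a small ladder,
#' under both sigmoidal hidden activations.
#'
#' @param n_inputs Number of input features.
#' @param widths Candidate hidden-layer widths.
#' @param activations Candidate hidden activations.
#' @param two_layer Include all two-layer width pairs.
#' @param ... Passed to [mlp_config()] (epochs, patience).
#' @return A list of [mlp_config()] objects.
#' @export
mlp_search_space <- function(n_inputs, widths = c(2, 4, 8, 13, 16),
                             activations = c("tanh", "logistic"),
                             two_layer = TRUE, ...) {
  hiddens <- as.list(widths)
  if (two_layer) {
    hiddens <- c(hiddens,
                 unlist(lapply(widths, function(a)
                   lapply(widths, function(b) c(a, b))),
                   recursive = FALSE))
  }
  out <- list()
  for (act in activations) {
    for (h in hiddens) {
      out[[length(out) + 1]] <-
        mlp_config(n_inputs, hidden = h, activation = act, ...)
    }
  }
  out
}

#' Architecture selection by internal-validation CCR
#'
#' Scores every candidate architecture on the same set of `R` partitions
#' by its mean internal-validation correct classification rate. The
#' winner is the candidate with the highest mean; any candidate within
#' one standard deviation of the winner's mean is considered equivalent
#' and the tie is broken towards the fewest trainable weights
#' (parsimony). The winner is then refit per partition on the fused
#' training + internal data and assessed on the external subset.
#'
#' @param features A feature tibble.
#' @param search_space A list of [mlp_config()] objects (all with the
#'   same `n_inputs` as `features`).
#' @param R Number of partitions used for the search.
#' @param seed Master seed.
#' @param fractions Train / internal / external fractions.
#' @return A list of class `eo_arch_search`: `best_config`, `cv` (an
#'   `eo_cv` for the winner), and `candidates` (per-config tibble with
#'   mean/sd internal CCR and weight counts).
#' @export
select_architecture <- function(features, search_space, R = 50, seed = 1L,
                                fractions = c(0.7, 0.1, 0.2)) {
  if (length(search_space) == 0) stop("empty search space", call. = FALSE)
  xmat <- feature_values(features)
  y <- features$class_label
  plans <- make_partition_plans(features, R, fractions, seed)
  set.seed(seed + 1L)
  seeds <- sample.int(.Machine$integer.max - 1L, R)

  stats_ <- purrr::map(search_space, function(cfg) {
    ccrs <- vapply(seq_len(R), function(r) {
      eval_config_on_plan(xmat, y, features$sample_id, plans[[r]], cfg,
                          seeds[r])$ccr_internal
    }, numeric(1))
    tibble::tibble(
      architecture = paste(c(cfg$n_inputs, cfg$hidden, cfg$n_outputs),
                           collapse = "-"),
      activation = cfg$activation,
      weights = n_weights(cfg),
      ccr_internal_mean = mean(ccrs),
      ccr_internal_sd = stats::sd(ccrs)
    )
  })
  candidates <- dplyr::bind_rows(stats_)
  best_i <- which.max(candidates$ccr_internal_mean)
  near <- candidates$ccr_internal_mean >=
    candidates$ccr_internal_mean[best_i] -
    (candidates$ccr_internal_sd[best_i] %|na|% 0)
  near_idx <- which(near)
  winner <- near_idx[order(candidates$weights[near_idx],
                           -candidates$ccr_internal_mean[near_idx])][1]
  best_config <- search_space[[winner]]
  cv <- cross_validate(features, best_config, R, seed, fractions)
  structure(list(best_config = best_config, cv = cv,
                 candidates = candidates, winner_index = winner),
            class = "eo_arch_search")
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' @export
print.eo_arch_search <- function(x, ...) {
  cat("<eo_arch_search> ", nrow(x$candidates), " candidates\n", sep = "")
  cat("  winner: ",
      x$candidates$architecture[x$winner_index], " (",
      x$candidates$activation[x$winner_index], ")\n", sep = "")
  print(x$cv)
  invisible(x)
}
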