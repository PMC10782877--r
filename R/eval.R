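#' Percent root-mean-square error
#'
#' RMSE of relative errors, in percent:
#' \eqn{100 \sqrt{mean(((pred - truth)/truth)^2)}}. The relative form is the
#' only one comparable across the two targets' different scales. The
#' alternative normalisation RMSE/mean(truth) x 100 is available via
#' \code{relative = FALSE}.
#'
#' @param pred,truth Equal-length numeric vectors; \code{truth} nonzero.
#' @param relative Use per-sample relative errors (default) or divide the
#'   plain RMSE by mean(truth).
#' @return Nonnegative percentage.
#' @export
#' @examples
#' rmse_percent(1.1, 1.0)            # 10
#' rmse_percent(c(1.1, 0.9), c(1, 1))  # 10
rmse_percent <- function(pred, truth, relative = TRUE) {
  if (length(pred) != length(truth) || length(truth) < 1L)
    stop("pred and truth must have equal, positive length", call. = FALSE)
  if (any(truth == 0)) stop("truth contains zero entries", call. = FALSE)
  if (relative) 100 * sqrt(mean(((pred - truth) / truth)^2))
  else 100 * sqrt(mean((pred - truth)^2)) / mean(truth)
}

#' k-fold cross-validation of an optical-property model
#'
#' Randomly partitions the records into k disjoint folds, fits the model on
#' k-1 folds and predicts the held-out fold, then pools the predictions and
#' reports percent RMSE per target.
#'
#' @param features Feature table (or raw-spectra matrix for the NN).
#' @param labels Data frame with mu_a, mu_s_prime.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param model \code{"wir"}, \code{"nn"} (features input) — the fitting
#'   routine applied per fold.
#' @param ... Passed to the fitting routine.
#' @return List of class \code{"drs_cv"}: \code{rmse} (named vector),
#'   \code{predictions}, \code{folds}.
#' @export
kfold_cv <- function(features, labels, k = 5L, seed = 0L, model = c("wir", "nn"), ...) {
  model <- match.arg(model)
  n <- nrow(features)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k records", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  pred <- data.frame(mu_a = numeric(n), mu_s_prime = numeric(n))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- if (model == "wir") wir(features[tr, , drop = FALSE], labels[tr, ], ...)
           else dense_nn(features[tr, , drop = FALSE], labels[tr, ], ...)
    pred[fold == f, ] <- predict(fit, features[!tr, , drop = FALSE])
  }
  structure(list(
    rmse = c(mu_a = rmse_percent(pred$mu_a, labels$mu_a),
             mu_s_prime = rmse_percent(pred$mu_s_prime, labels$mu_s_prime)),
    predictions = pred, folds = fold),
    class = "drs_cv")
}

#' @export
print.drs_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV percent RMSE: mu_a %.3f%%, mu_s' %.3f%%\n",
              max(x$folds), x$rmse["mu_a"], x$rmse["mu_s_prime"]))
  invisible(x)
}

#' Leave-one-group-out evaluation
#'
#' For each group (e.g. a phantom titration), all of that group's records
#' form the test set and the model trains on every other group plus the
#' (optional) augmentation records. Augmentation records never enter a test
#' fold. The report carries per-group and mean percent RMSE; the mean is the
#' arithmetic mean of the per-group values.
#'
#' @param features,labels,groups Test-pool feature table, labels and group
#'   ids (equal lengths).
#' @param aug_features,aug_labels Optional augmentation pool added to every
#'   training set.
#' @param model,... Passed to \code{\link{kfold_cv}}'s fitting routine.
#' @return List of class \code{"drs_logo"}: \code{per_group} data frame and
#'   \code{mean} named vector.
#' @export
leave_one_group_out <- function(features, labels, groups,
                                aug_features = NULL, aug_labels = NULL,
                                model = c("wir", "nn"), ...) {
  model <- match.arg(model)
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  per <- data.frame(group = gs, n = NA_integer_,
                    mu_a = NA_real_, mu_s_prime = NA_real_)
  for (i in seq_along(gs)) {
    te <- groups == gs[i]
    xtr <- features[!te, , drop = FALSE]
    ytr <- labels[!te, ]
    if (!is.null(aug_features)) {
      xtr <- rbind(xtr, aug_features)
      ytr <- rbind(ytr, aug_labels)
    }
    fit <- if (model == "wir") wir(xtr, ytr, ...) else dense_nn(xtr, ytr, ...)
    p <- predict(fit, features[te, , drop = FALSE])
    per$n[i] <- sum(te)
    per$mu_a[i] <- rmse_percent(p$mu_a, labels$mu_a[te])
    per$mu_s_prime[i] <- rmse_percent(p$mu_s_prime, labels$mu_s_prime[te])
  }
  structure(list(per_group = per,
                 mean = c(mu_a = mean(per$mu_a), mu_s_prime = mean(per$mu_s_prime))),
            class = "drs_logo")
}

#' @export
print.drs_logo <- function(x, ...) {
  print(x$per_group, row.names = FALSE)
  cat(sprintf("mean percent RMSE: mu_a %.3f%%, mu_s' %.3f%%\n",
              x$mean["mu_a"], x$mean["mu_s_prime"]))
  invisible(x)
}

#' Robustness experiment: all models across the seven conditions
#'
#' Generates the perfect dataset and its six corrupted variants, then
#' evaluates the requested models on each condition: the spectral-matching
#' inversion (no training; run directly against the forward model), the WIR
#' via k-fold CV, and the dense NN baselines (engineered features or raw
#' spectra) via k-fold CV. Per-condition prediction wall times are reported
#' for information only (hardware-dependent, never asserted).
#'
#' @param base Perfect \code{drs_dataset}; default generates the standard
#'   40 x 38 grid.
#' @param models Subset of \code{c("mci", "wir", "nn_features", "nn_raw")}.
#' @param config A \code{\link{drs_error_config}}.
#' @param seed Master seed for corruption draws and fold assignment.
#' @param k CV folds.
#' @param mci_n_grid Coarse library resolution for the inversion.
#' @param nn_epochs Cap on NN training epochs.
#' @return Data frame of class \code{"drs_table"}: one row per
#'   condition x model x target with \code{rmse_percent} and
#'   \code{predict_time_s}.
#' @export
robustness_experiment <- function(base = NULL,
                             models = c("mci", "wir", "nn_features", "nn_raw"),
                             config = drs_error_config(), seed = 0L, k = 5L,
                             mci_n_grid = 200L, nn_epochs = 500L) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(base)) base <- generate_grid_dataset()
  suite <- condition_suite(base, config, seed)
  fwd <- forward_closure(probe_geometry(base$probe_id),
                         standard = attr(base, "standard"),
                         wavelength = base$wavelength)
  rows <- list()
  add <- function(condition, model, target, rmse, t) {
    rows[[length(rows) + 1L]] <<- data.frame(
      condition = condition, model = model, target = target,
      rmse_percent = rmse, predict_time_s = t)
  }
  lib <- if ("mci" %in% models) mci_library(fwd, n_grid = mci_n_grid) else NULL
  for (cond in names(suite)) {
    ds <- suite[[cond]]
    labs <- ds$labels
    if ("mci" %in% models) {
      t0 <- proc.time()[3]
      inv <- mci_invert_dataset(ds, fwd, library = lib)
      dt <- proc.time()[3] - t0
      add(cond, "mci", "mu_a", rmse_percent(inv$mu_a, labs$mu_a), dt)
      add(cond, "mci", "mu_s_prime", rmse_percent(inv$mu_s_prime, labs$mu_s_prime), dt)
    }
    if (any(c("wir", "nn_features") %in% models)) feats <- drs_features(ds)
    if ("wir" %in% models) {
      t0 <- proc.time()[3]
      cv <- kfold_cv(feats, labs, k = k, seed = seed, model = "wir")
      dt <- proc.time()[3] - t0
      add(cond, "wir", "mu_a", unname(cv$rmse["mu_a"]), dt)
      add(cond, "wir", "mu_s_prime", unname(cv$rmse["mu_s_prime"]), dt)
    }
    if ("nn_features" %in% models) {
      t0 <- proc.time()[3]
      cv <- kfold_cv(feats, labs, k = k, seed = seed, model = "nn",
                     input_mode = "features", epochs = nn_epochs, seed = seed)
      dt <- proc.time()[3] - t0
      add(cond, "nn_features", "mu_a", unname(cv$rmse["mu_a"]), dt)
      add(cond, "nn_features", "mu_s_prime", unname(cv$rmse["mu_s_prime"]), dt)
    }
    if ("nn_raw" %in% models) {
      raw <- raw_spectra_matrix(ds)
      t0 <- proc.time()[3]
      cv <- kfold_cv(raw, labs, k = k, seed = seed, model = "nn",
                     input_mode = "raw_spectra", epochs = nn_epochs, seed = seed)
      dt <- proc.time()[3] - t0
      add(cond, "nn_raw", "mu_a", unname(cv$rmse["mu_a"]), dt)
      add(cond, "nn_raw", "mu_s_prime", unname(cv$rmse["mu_s_prime"]), dt)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("drs_table", class(out))
  out
}

#' @export
print.drs_table <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x)[, c("condition", "model", "target", "rmse_percent")],
                         idvar = c("model", "target"), timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^rmse_percent\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
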