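#' Fit the wavelength-independent regressor (WIR)
#'
#' The WIR is a pair of gradient-boosted regression-tree ensembles — one for
#' the absorption coefficient mu_a, one for the reduced scattering
#' coefficient mu_s' — fitted to the 35 wavelength-independent features of
#' \code{\link{wir_feature_names}}. Each ensemble uses 200 trees of maximum
#' depth 5 with at least 3 samples per leaf and a fixed random state, so
#' refitting with the same data reproduces the same model bit for bit.
#' Targets are fitted on the log scale (accuracy is assessed as relative
#' error, and log-scale least squares matches the loss to that metric);
#' predictions are exponentiated back and clamped to the training label
#' range, since tree ensembles do not extrapolate.
#'
#' @param x Feature table: data frame or matrix with the 35 columns of
#'   \code{\link{wir_feature_names}} (or a \code{drs_dataset}, from which
#'   features and labels are taken directly).
#' @param y Data frame/matrix with columns \code{mu_a} and \code{mu_s_prime};
#'   ignored when \code{x} is a dataset.
#' @param nrounds Number of boosting iterations per target (default 200).
#' @param max_depth Maximum tree depth (default 5).
#' @param min_samples_leaf Minimum samples per leaf (default 3).
#' @param learning_rate Shrinkage (default 0.1).
#' @param seed Random state (default 0).
#' @param log_target Fit log-scale targets (default TRUE).
#' @return Object of class \code{"wir"} with \code{predict}, \code{print},
#'   \code{summary} and \code{plot} methods.
#' @export
#' @examples
#' ds <- generate_grid_dataset(n_mu_a = 6, n_mu_s = 5)
#' fit <- wir(ds)
#' head(predict(fit, drs_features(ds)))
wir <- function(x, y = NULL, nrounds = 200L, max_depth = 5L,
                min_samples_leaf = 3L, learning_rate = 0.1, seed = 0L,
                log_target = TRUE) {
  if (inherits(x, "drs_dataset")) {
    y <- x$labels
    x <- drs_features(x)
  }
  x <- as.data.frame(x)
  if (!identical(names(x), wir_feature_names()))
    stop("feature layout mismatch: expected the 35 columns of wir_feature_names()",
         call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 training samples", call. = FALSE)
  y <- as.data.frame(y)
  if (!all(c("mu_a", "mu_s_prime") %in% names(y)))
    stop("labels must have columns mu_a and mu_s_prime", call. = FALSE)
  xm <- as.matrix(x)
  fit_one <- function(target) {
    ty <- if (log_target) log(y[[target]]) else y[[target]]
    xgboost::xgboost(xm, ty, nrounds = nrounds, max_depth = max_depth,
                     min_child_weight = min_samples_leaf,
                     learning_rate = learning_rate, tree_method = "exact",
                     nthreads = 1L, seed = seed, verbosity = 0L)
  }
  structure(list(
    boosters = list(mu_a = fit_one("mu_a"), mu_s_prime = fit_one("mu_s_prime")),
    feature_names = wir_feature_names(),
    label_range = list(mu_a = range(y$mu_a), mu_s_prime = range(y$mu_s_prime)),
    log_target = log_target,
    n_train = nrow(x),
    params = list(nrounds = nrounds, max_depth = max_depth,
                  min_samples_leaf = min_samples_leaf,
                  learning_rate = learning_rate, seed = seed)),
    class = "wir")
}

#' Predict optical properties with a fitted WIR model
#'
#' @param object A fitted \code{\link{wir}} model.
#' @param newdata Feature table with the model's 35 columns, or a
#'   \code{drs_dataset}.
#' @param ... Unused.
#' @return Data frame with columns \code{mu_a} and \code{mu_s_prime} (cm^-1),
#'   clamped to the training label ranges.
#' @export
predict.wir <- function(object, newdata, ...) {
  if (inherits(newdata, "drs_dataset")) newdata <- drs_features(newdata)
  newdata <- as.data.frame(newdata)
  if (!identical(names(newdata), object$feature_names))
    stop("feature layout mismatch: refusing to predict", call. = FALSE)
  xm <- as.matrix(newdata)
  one <- function(target) {
    p <- predict(object$boosters[[target]], xm)
    if (object$log_target) p <- exp(p)
    r <- object$label_range[[target]]
    pmin(pmax(p, r[1]), r[2])
  }
  data.frame(mu_a = one("mu_a"), mu_s_prime = one("mu_s_prime"))
}

#' @export
print.wir <- function(x, ...) {
  cat("Wavelength-independent regressor (gradient-boosted trees)\n")
  cat(sprintf("  %d trees, depth %d, >= %d samples/leaf, learning rate %g, seed %d\n",
              x$params$nrounds, x$params$max_depth, x$params$min_samples_leaf,
              x$params$learning_rate, x$params$seed))
  cat(sprintf("  trained on %d samples; mu_a in [%.3f, %.3f], mu_s' in [%.3f, %.3f] cm^-1\n",
              x$n_train, x$label_range$mu_a[1], x$label_range$mu_a[2],
              x$label_range$mu_s_prime[1], x$label_range$mu_s_prime[2]))
  invisible(x)
}

#' Impurity-based feature importances of a WIR model
#'
#' Gain importances per target, normalised to sum to one over all 35
#' features (unused features get 0), sorted descending.
#'
#' @param model A fitted \code{\link{wir}} model.
#' @return Named list of two data frames (\code{mu_a}, \code{mu_s_prime})
#'   with columns \code{feature} and \code{importance}.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "wir"))
  one <- function(target) {
    imp <- xgboost::xgb.importance(model = model$boosters[[target]])
    v <- stats::setNames(rep(0, 35L), model$feature_names)
    v[imp$Feature] <- imp$Gain
    v <- v / sum(v)
    v <- sort(v, decreasing = TRUE)
    data.frame(feature = names(v), importance = as.numeric(v), row.names = NULL)
  }
  list(mu_a = one("mu_a"), mu_s_prime = one("mu_s_prime"))
}

#' @export
summary.wir <- function(object, ...) {
  imp <- feature_importances(object)
  out <- list(model = object, importances = imp)
  class(out) <- "summary.wir"
  out
}

#' @export
print.summary.wir <- function(x, ...) {
  print(x$model)
  cat("\nTop features for mu_a:\n")
  print(utils::head(x$importances$mu_a, 5), row.names = FALSE)
  cat("\nTop features for mu_s':\n")
  print(utils::head(x$importances$mu_s_prime, 5), row.names = FALSE)
  invisible(x)
}

#' Plot WIR feature importances
#'
#' Horizontal bar chart of the top features per target.
#'
#' @param x A fitted \code{\link{wir}} model.
#' @param n_top Number of features to show (default 10).
#' @param ... Passed to \code{barplot}.
#' @export
plot.wir <- function(x, n_top = 10L, ...) {
  imp <- feature_importances(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  for (target in c("mu_a", "mu_s_prime")) {
    d <- utils::head(imp[[target]], n_top)
    graphics::barplot(rev(d$importance), names.arg = rev(d$feature), horiz = TRUE,
                      las = 1, cex.names = 0.7, main = target,
                      xlab = "gain importance", ...)
  }
  invisible(x)
}

#' Save a fitted WIR model as a versioned bundle
#'
#' Writes a directory containing the two boosters (binary JSON) and a
#' manifest recording the format version, feature order, label ranges and
#' hyperparameters. \code{\link{read_wir}} refuses bundles whose feature
#' layout does not match the package's.
#'
#' @param model A fitted \code{\link{wir}} model.
#' @param path Directory to create.
#' @export
write_wir <- function(model, path) {
  stopifnot(inherits(model, "wir"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$boosters$mu_a, file.path(path, "mu_a.ubj"))
  xgboost::xgb.save(model$boosters$mu_s_prime, file.path(path, "mu_s_prime.ubj"))
  jsonlite::write_json(list(format_version = 1L,
                            feature_names = model$feature_names,
                            label_range = model$label_range,
                            log_target = model$log_target,
                            n_train = model$n_train, params = model$params),
                       file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a WIR model bundle
#'
#' @param path Directory written by \code{\link{write_wir}}.
#' @return A \code{"wir"} model.
#' @export
read_wir <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"), simplifyVector = TRUE)
  if (!identical(man$feature_names, wir_feature_names()))
    stop("model bundle has a mismatched feature layout; refusing to load", call. = FALSE)
  structure(list(
    boosters = list(mu_a = xgboost::xgb.load(file.path(path, "mu_a.ubj")),
                    mu_s_prime = xgboost::xgb.load(file.path(path, "mu_s_prime.ubj"))),
    feature_names = man$feature_names,
    label_range = lapply(man$label_range, as.numeric),
    log_target = man$log_target,
    n_train = man$n_train,
    params = man$params),
    class = "wir")
}
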