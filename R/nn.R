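#' Dense neural-network baseline
#'
#' A small fully connected regression network with two hidden layers of 25
#' units (ReLU) and a linear output, trained per target with full-batch Adam
#' on a mean-squared-error loss, early stopping on a 10 percent validation
#' split, and a fixed seed. It is a baseline for comparison with the
#' wavelength-independent regressor: it carries no accuracy contract beyond
#' producing finite, reproducible predictions. Inputs are either the 35
#' engineered features or the raw concatenated spectra (gray, red, green,
#' blue; length 4N).
#'
#' @param x Numeric matrix/data frame of inputs (n x p).
#' @param y Data frame with columns mu_a, mu_s_prime.
#' @param input_mode \code{"features"} or \code{"raw_spectra"} (recorded and
#'   checked at prediction time).
#' @param hidden Hidden layer sizes (fixed default \code{c(25, 25)}).
#' @param epochs Maximum epochs (default 500).
#' @param learning_rate Adam step size.
#' @param val_fraction Validation split for early stopping.
#' @param patience Early-stopping patience in epochs.
#' @param seed Random seed.
#' @return Object of class \code{"dense_nn"}.
#' @export
dense_nn <- function(x, y, input_mode = c("features", "raw_spectra"),
                     hidden = c(25L, 25L), epochs = 500L, learning_rate = 1e-2,
                     val_fraction = 0.1, patience = 25L, seed = 0L) {
  input_mode <- match.arg(input_mode)
  x <- as.matrix(x)
  y <- as.data.frame(y)
  if (!all(c("mu_a", "mu_s_prime") %in% names(y)))
    stop("labels must have columns mu_a and mu_s_prime", call. = FALSE)
  mu_x <- colMeans(x)
  sd_x <- apply(x, 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  xs <- sweep(sweep(x, 2, mu_x), 2, sd_x, `/`)
  nets <- lapply(c(mu_a = "mu_a", mu_s_prime = "mu_s_prime"), function(target) {
    fit_mlp(xs, y[[target]], hidden, epochs, learning_rate, val_fraction,
            patience, seed)
  })
  structure(list(nets = nets, mu_x = mu_x, sd_x = sd_x, input_mode = input_mode,
                 n_input = ncol(x), hidden = hidden, seed = seed),
            class = "dense_nn")
}

fit_mlp <- function(xs, yv, hidden, epochs, lr, val_fraction, patience, seed) {
  set.seed(seed)
  n <- nrow(xs)
  mu_y <- mean(yv); sd_y <- stats::sd(yv); if (sd_y == 0) sd_y <- 1
  ys <- (yv - mu_y) / sd_y
  val <- sample(n, max(1L, round(val_fraction * n)))
  tr <- setdiff(seq_len(n), val)
  sizes <- c(ncol(xs), hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                  sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  forward_pass <- function(X) {
    a <- list(X)
    for (l in seq_along(W)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
      a[[l + 1L]] <- if (l < length(W)) pmax(z, 0) else z
    }
    a
  }
  best <- list(W = W, b = b, loss = Inf, since = 0L)
  Xtr <- xs[tr, , drop = FALSE]; ytr <- ys[tr]
  Xval <- xs[val, , drop = FALSE]; yval <- ys[val]
  for (ep in seq_len(epochs)) {
    a <- forward_pass(Xtr)
    L <- length(W)
    delta <- 2 * (a[[L + 1L]][, 1] - ytr) / length(ytr)
    delta <- matrix(delta, ncol = 1L)
    for (l in L:1) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^ep; corr2 <- 1 - beta2^ep
      W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
    }
    pv <- forward_pass(Xval)[[L + 1L]][, 1]
    vloss <- mean((pv - yval)^2)
    if (vloss < best$loss - 1e-9) {
      best <- list(W = W, b = b, loss = vloss, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
  }
  list(W = best$W, b = best$b, mu_y = mu_y, sd_y = sd_y, val_loss = best$loss)
}

#' Predict with the dense NN baseline
#'
#' @param object A fitted \code{\link{dense_nn}}.
#' @param newdata Input matrix with the same number of columns as training.
#' @param ... Unused.
#' @return Data frame with columns mu_a and mu_s_prime.
#' @export
predict.dense_nn <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_input)
    stop("input shape mismatch: expected ", object$n_input, " columns", call. = FALSE)
  xs <- sweep(sweep(x, 2, object$mu_x), 2, object$sd_x, `/`)
  one <- function(net) {
    a <- xs
    L <- length(net$W)
    for (l in seq_len(L)) {
      z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], `+`)
      a <- if (l < L) pmax(z, 0) else z
    }
    a[, 1] * net$sd_y + net$mu_y
  }
  data.frame(mu_a = one(object$nets$mu_a), mu_s_prime = one(object$nets$mu_s_prime))
}

#' @export
print.dense_nn <- function(x, ...) {
  cat(sprintf("Dense NN baseline: %d inputs -> %s -> 1 per target (%s mode)\n",
              x$n_input, paste(x$hidden, collapse = " -> "), x$input_mode))
  invisible(x)
}

#' Raw-spectra input matrix for the dense NN
#'
#' Concatenates the gray, red, green and blue spectra of each record into one
#' vector of length 4N.
#'
#' @param dataset A \code{drs_dataset}.
#' @return Numeric matrix n x 4N.
#' @export
raw_spectra_matrix <- function(dataset) {
  ch <- dataset_channels(dataset)
  cbind(dataset$gray, ch$red, ch$green, ch$blue)
}
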