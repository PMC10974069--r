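#' Fit a PLS1 regression model by NIPALS
#'
#' Classic NIPALS partial least squares with X-deflation per component, on
#' autoscaled data (columns centred and scaled to unit variance, response
#' likewise). Channels with zero variance are dropped with a warning before
#' scaling and receive a zero regression coefficient. The returned
#' `regression_vector`/`intercept` map a raw (unscaled) spectrum directly to a
#' raw response prediction.
#'
#' @param X numeric matrix, samples by channels.
#' @param y numeric response vector.
#' @param ncomp number of latent components, `<= min(n - 1, p)`.
#' @return An object of class `plsr_model` with elements `x_mean`, `x_sd`,
#'   `y_mean`, `y_sd`, `weights` (W), `x_loadings` (P), `y_loadings` (q),
#'   `scores` (training T), `regression_vector`, `intercept`, `ncomp`,
#'   `kept` (logical channel mask after the zero-variance drop).
#' @export
fit_plsr <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p_all <- ncol(X)
  if (length(y) != n) stop("length of y must match rows of X")
  if (n < 3) stop("need at least 3 samples")
  if (stats::sd(y) < 1e-12) stop("y is constant; nothing to regress")
  x_mean_all <- colMeans(X)
  x_sd_all <- apply(X, 2L, stats::sd)
  kept <- x_sd_all > 1e-12
  if (!all(kept))
    warning(sprintf("dropping %d zero-variance channel(s) before scaling",
                    sum(!kept)))
  Xk <- X[, kept, drop = FALSE]
  p <- ncol(Xk)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop(sprintf("ncomp must lie in [1, min(n - 1, p)] = [1, %d]", min(n - 1, p)))

  x_mean <- x_mean_all[kept]; x_sd <- x_sd_all[kept]
  y_mean <- mean(y); y_sd <- stats::sd(y)
  Xc <- sweep(sweep(Xk, 2, x_mean), 2, x_sd, "/")
  yc <- (y - y_mean) / y_sd

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      ncomp <- k - 1L
      if (ncomp == 0L) stop("X carries no covariance with y")
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      break
    }
    w <- w / wn
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(Xc, t)) / tt
    qk <- sum(yc * t) / tt
    W[, k] <- w; P[, k] <- pl; q[k] <- qk; Tm[, k] <- t
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qk * t
  }

  # b_scaled = W (P'W)^-1 q ; back-transform to raw units
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b_raw <- numeric(p_all)
  b_raw[kept] <- b_scaled * y_sd / x_sd
  intercept <- y_mean - sum(b_raw[kept] * x_mean)

  structure(
    list(x_mean = x_mean_all, x_sd = x_sd_all, y_mean = y_mean, y_sd = y_sd,
         weights = W, x_loadings = P, y_loadings = q, scores = Tm,
         regression_vector = b_raw, intercept = intercept,
         ncomp = as.integer(ncomp), kept = kept, n_train = n),
    class = "plsr_model"
  )
}

#' Predict from a fitted PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata numeric matrix (or vector for a single spectrum) with the
#'   same channel count as the training matrix.
#' @param ... unused.
#' @return Numeric vector of predictions in raw response units.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$regression_vector))
    stop("channel count of newdata does not match the model")
  drop(newdata %*% object$regression_vector) + object$intercept
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d channels (%d kept), n = %d\n",
              x$ncomp, length(x$regression_vector), sum(x$kept), x$n_train))
  invisible(x)
}

#' Cross-validation fold assignment
#'
#' @param n number of samples.
#' @param scheme `"loo"` (leave-one-out, the default used throughout) or
#'   `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param seed optional seed for the k-fold shuffle; `NULL` assigns folds in
#'   sample order (deterministic).
#' @return Integer vector of 1-based fold labels, one per sample.
#' @export
cv_folds <- function(n, scheme = c("loo", "kfold"), k = 5, seed = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") return(seq_len(n))
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  fold <- rep(seq_len(k), length.out = n)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    fold <- sample(fold)
  }
  fold
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cross-validate PLSR over component counts
#'
#' For each component count `1..max_ncomp`, refits the model on every training
#' fold, predicts its held-out fold, and pools all held-out predictions.
#' `RMSEcv` is the root mean squared pooled error and `R2cv` is
#' `1 - SSE_pooled / SST(y)`. The chosen component count is the first
#' minimizer of `RMSEcv` (ties resolved toward fewer components).
#'
#' @param X numeric matrix, samples by channels.
#' @param y numeric response.
#' @param max_ncomp largest component count to consider; capped at
#'   `min(n_train_min - 1, p)` where `n_train_min` is the smallest training
#'   fold. Default `min(10, n - 2)`.
#' @param folds integer fold labels from [cv_folds()]; default leave-one-out.
#' @return A list of class `plsr_cv` with `rmse_cv_by_ncomp`, `chosen_ncomp`,
#'   `rmse_cv`, `r2_cv`, and the pooled `predictions` matrix.
#' @export
cross_validate <- function(X, y, max_ncomp = NULL, folds = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(folds)) folds <- cv_folds(n, "loo")
  if (length(folds) != n) stop("folds must label every sample")
  n_train_min <- n - max(tabulate(folds))
  cap <- min(n_train_min - 1L, ncol(X))
  if (is.null(max_ncomp)) max_ncomp <- min(10L, n - 2L)
  if (max_ncomp < 1L) stop("max_ncomp must be >= 1")
  if (max_ncomp > cap)
    stop(sprintf("max_ncomp = %d infeasible for the smallest training fold (cap %d)",
                 max_ncomp, cap))
  pred <- .plsr_cv_predictions(X, y, as.integer(folds), as.integer(max_ncomp))
  err2 <- colMeans((pred - y)^2)
  rmse_by <- sqrt(err2)
  chosen <- which.min(rmse_by)  # which.min takes the first minimum
  sst <- sum((y - mean(y))^2)
  structure(
    list(rmse_cv_by_ncomp = rmse_by,
         chosen_ncomp = as.integer(chosen),
         rmse_cv = rmse_by[chosen],
         r2_cv = 1 - sum((pred[, chosen] - y)^2) / sst,
         predictions = pred),
    class = "plsr_cv"
  )
}

#' Serialize / restore a PLSR model as JSON
#'
#' @param model a `plsr_model`.
#' @param path output path (`plsr_to_json`) / input path (`plsr_from_json`).
#' @return `plsr_from_json()` returns the restored `plsr_model`.
#' @export
plsr_to_json <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  jsonlite::write_json(
    list(x_mean = model$x_mean, x_sd = model$x_sd,
         y_mean = model$y_mean, y_sd = model$y_sd,
         regression_vector = model$regression_vector,
         intercept = model$intercept, ncomp = model$ncomp,
         kept = model$kept,
         weights = model$weights, x_loadings = model$x_loadings,
         y_loadings = model$y_loadings),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname plsr_to_json
#' @export
plsr_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$weights <- as.matrix(j$weights)
  j$x_loadings <- as.matrix(j$x_loadings)
  j$ncomp <- as.integer(j$ncomp)
  j$n_train <- NA_integer_
  class(j) <- "plsr_model"
  j
}
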