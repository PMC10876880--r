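#' Fit a single-response PLS model by NIPALS
#'
#' Partial least squares regression extracts orthogonal latent variables that
#' maximize covariance with the response, making it the method of choice for
#' p >> n collinear instrumental profiles. This is the classical NIPALS
#' sequence for one response: at each step the weight vector is the
#' normalized covariance `X'y`, scores/loadings are extracted and both blocks
#' deflated. Predictors and response are mean-centered (no autoscaling, so
#' relative peak magnitudes are preserved); centering can be disabled.
#'
#' The model stores the quantities needed downstream: unit-norm weights `W`,
#' x-loadings `P`, y-loadings `q`, per-latent-variable explained response
#' sum-of-squares `SS` (used by [vip_scores()] and for the cumulative
#' contribution rate), scores `T`, and the regression vector `b` so that
#' `prediction = (x - x_mean) b + y_mean`.
#'
#' If the response is fully deflated before `ncomp` components (exactly
#' collinear data), the fit stops early with a warning and `ncomp` is
#' truncated.
#'
#' @param X predictor matrix (n x p), e.g. a [dtg_matrix()].
#' @param y numeric response vector of length n.
#' @param ncomp number of latent variables A, `1 <= A <= min(n - 1, p)`.
#' @param center logical; mean-center `X` and `y` (default TRUE).
#' @return object of class `pls_model`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 8), 40); y <- X %*% rnorm(8) + rnorm(40, 0, 0.1)
#' m <- fit_pls(X, y, ncomp = 4)
#' r_squared(y, predict(m, X))
#' @export
fit_pls <- function(X, y, ncomp, center = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, p >= 1)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be between 1 and min(n - 1, p) = ", min(n - 1, p))
  x_mean <- if (center) colMeans(X) else rep(0, p)
  y_mean <- if (center) mean(y) else 0
  Xd <- sweep(X, 2, x_mean); yd <- y - y_mean
  sstot <- sum(yd^2)

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- SS <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sstot))) {
      warning("response fully deflated after ", a_used,
              " latent variables; ncomp truncated")
      break
    }
    w <- w / nw
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    if (t2 <= 0) break
    pp <- drop(crossprod(Xd, tt)) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt
    q[a] <- qa; SS[a] <- qa^2 * t2
    a_used <- a
  }
  if (a_used == 0L) stop("no latent variable could be extracted (X'y is zero)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]; SS <- SS[seq_len(a_used)]

  structure(list(ncomp = a_used, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, SS = SS, sstot = sstot,
                 scores = Tm, b = pls_coefficients_raw(W, P, q, a_used),
                 y_residual = yd, center = center),
            class = "pls_model")
}

pls_coefficients_raw <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' Regression vector of a PLS model
#'
#' @param model a `pls_model`.
#' @param ncomp number of latent variables to use (default all fitted).
#' @return numeric vector of length p.
#' @export
pls_coefficients <- function(model, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"), ncomp >= 1, ncomp <= model$ncomp)
  if (ncomp == model$ncomp) return(model$b)
  pls_coefficients_raw(model$W, model$P, model$q, ncomp)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata predictor matrix with the same columns as the training `X`.
#' @param ncomp number of latent variables to use.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  b <- pls_coefficients(object, ncomp)
  drop(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), p = %d, cumulative y-variance %.1f%%\n",
              x$ncomp, nrow(x$W), 100 * sum(x$SS) / x$sstot))
  invisible(x)
}

#' Cumulative explained response variance per latent variable
#'
#' @param model a `pls_model`.
#' @return numeric vector: `cumsum(SS) / SStot`.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  cumsum(model$SS) / model$sstot
}

#' Choose the number of PLS latent variables
#'
#' Combines the cumulative-contribution criterion with cross-validated error:
#' candidate counts are those whose cumulative explained response variance on
#' the full data reaches `contribution` (default 90%) *and* whose k-fold
#' RMSECV lies within one standard error of the minimum RMSECV over
#' `1..max_A`; the smallest such count is returned. If no count satisfies
#' both, the RMSECV-minimizing count is used. The one-standard-error rule
#' operationalizes "relatively small RMSECV" with a conventional, scale-free
#' tolerance.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param max_A largest count to consider (capped at `min(n - n/k - 1, p)`).
#' @param cv_folds number of CV folds k (default 10).
#' @param contribution cumulative-contribution threshold (default 0.90).
#' @param seed optional seed for the fold assignment.
#' @return selected count (integer) with attributes `rmsecv` (per candidate
#'   count) and `contribution` (cumulative explained variance per count).
#' @export
select_n_latent <- function(X, y, max_A = 20, cv_folds = 10,
                            contribution = 0.90, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(max_A >= 1, cv_folds >= 2, n >= cv_folds)
  max_A <- max(1, min(max_A, ncol(X), n - ceiling(n / cv_folds) - 1))
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))

  sse <- matrix(NA_real_, cv_folds, max_A)
  cnt <- integer(cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    m <- suppressWarnings(fit_pls(X[tr, , drop = FALSE], y[tr], max_A))
    for (a in seq_len(max_A)) {
      pred <- predict(m, X[!tr, , drop = FALSE], ncomp = min(a, m$ncomp))
      sse[f, a] <- sum((y[!tr] - pred)^2)
    }
    cnt[f] <- sum(!tr)
  }
  rmsecv <- sqrt(colSums(sse) / n)
  fold_rmse <- sqrt(sweep(sse, 1, cnt, `/`))
  best <- which.min(rmsecv)
  se_best <- stats::sd(fold_rmse[, best]) / sqrt(cv_folds)

  full <- suppressWarnings(fit_pls(X, y, max_A))
  contrib <- rep(1, max_A)
  contrib[seq_len(full$ncomp)] <- explained_variance(full)
  cand <- which(contrib >= contribution & rmsecv <= rmsecv[best] + se_best)
  a_sel <- if (length(cand)) min(cand) else best
  structure(as.integer(a_sel), rmsecv = rmsecv, contribution = contrib)
}
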