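#' Seeded train/test split
#'
#' Shuffle split with `round(test_fraction * n)` test samples (clamped so
#' both parts are non-empty), reproducible for a fixed seed.
#'
#' @param n number of samples (>= 4).
#' @param test_fraction fraction held out, strictly between 0 and 1
#'   (default 0.25).
#' @param seed integer seed.
#' @return object of class `split_spec` with integer index vectors `train`
#'   and `test` (disjoint, exhaustive).
#' @examples
#' s <- split_dataset(157, 0.25, seed = 1)
#' length(s$train); length(s$test)  # 118 / 39
#' @export
split_dataset <- function(n, test_fraction = 0.25, seed = 1L) {
  stopifnot(n >= 4)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be strictly between 0 and 1")
  n_test <- min(max(round(test_fraction * n), 1), n - 1)
  set.seed(seed)
  idx <- sample.int(n)
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 test = sort(idx[seq_len(n_test)]),
                 train = sort(idx[-seq_len(n_test)])),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train), length(x$test), x$test_fraction, x$seed))
  invisible(x)
}

#' Ordinary least squares baseline (minimum-norm when p > n)
#'
#' Multiple linear regression on the centered predictors via the SVD
#' pseudoinverse, which gives the usual OLS solution when `n > p` and the
#' minimum-norm interpolating solution when `p >= n`. On high-dimensional
#' collinear profiles the latter badly overfits -- the expected negative
#' out-of-sample R-squared is the motivating failure for latent-variable
#' methods.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @return object of class `mlr_model`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  x_mean <- colMeans(X); y_mean <- mean(y)
  sv <- svd(sweep(X, 2, x_mean))
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  b <- sv$v[, keep, drop = FALSE] %*%
    (drop(crossprod(sv$u[, keep, drop = FALSE], y - y_mean)) / sv$d[keep])
  structure(list(b = drop(b), x_mean = x_mean, y_mean = y_mean,
                 rank = sum(keep)),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  drop(sweep(as.matrix(newdata), 2, object$x_mean) %*% object$b) + object$y_mean
}

#' RBF-kernel support vector regression with cross-validated tuning
#'
#' Grid search over the penalty parameter (cost), kernel width (gamma) and
#' epsilon, minimizing k-fold cross-validation loss; the chosen grid and the
#' winning parameters are recorded in the returned object.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param cv_folds folds for the tuning CV (default 5).
#' @param cost,gamma,epsilon numeric grids; `gamma` defaults to a logarithmic
#'   grid around the `1/p` heuristic.
#' @param seed seed for the CV partition.
#' @return object of class `svr_model` with elements `fit` (the tuned
#'   [e1071::svm] model), `params`, `grid` and `cv_rmse`.
#' @export
fit_svr <- function(X, y, cv_folds = 5,
                    cost = 10^(0:2),
                    gamma = NULL,
                    epsilon = c(0.05, 0.1),
                    seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(cv_folds >= 2)
  if (is.null(gamma)) gamma <- 10^(-1:1) / ncol(X)
  set.seed(seed)
  tuned <- e1071::tune.svm(X, y, cost = cost, gamma = gamma, epsilon = epsilon,
                           tunecontrol = e1071::tune.control(cross = cv_folds))
  structure(list(fit = tuned$best.model,
                 params = as.list(tuned$best.parameters),
                 grid = list(cost = cost, gamma = gamma, epsilon = epsilon),
                 cv_rmse = sqrt(tuned$best.performance)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, as.matrix(newdata)))
}

rq_kernel <- function(sigma, alpha = 2) {
  k <- function(x, y) {
    d2 <- sum((x - y)^2)
    (1 + sigma * d2 / (2 * alpha))^(-alpha)
  }
  class(k) <- "kernel"
  k
}

#' Gaussian process regression with a three-kernel ensemble
#'
#' Fits three independent GP regressions with the squared-exponential (SE),
#' exponential (Exp) and rational-quadratic (RQ) kernels; downstream
#' evaluation reports the arithmetic mean of the three models' metrics. The
#' shared inverse-width hyperparameter is set from the median pairwise
#' distance heuristic ([kernlab::sigest]); the noise variance defaults to 1%
#' of `var(y)`. A kernel whose fit fails is dropped with a warning and the
#' ensemble continues with the remaining kernels.
#'
#' @param X predictor matrix.
#' @param y response vector (n >= 5).
#' @param noise_var observation noise variance passed to [kernlab::gausspr];
#'   default `0.01 * var(y)`, floored at kernlab's minimum of just above
#'   1e-3.
#' @param seed seed (sigest subsamples for large n).
#' @return object of class `gpr_ensemble` with element `models`, a named list
#'   of fitted [kernlab::gausspr] models (subset of SE/Exp/RQ).
#' @export
fit_gpr_ensemble <- function(X, y, noise_var = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) >= 5)
  # kernlab rejects var <= 1e-3, so the nugget is floored there
  if (is.null(noise_var)) noise_var <- 0.01 * stats::var(y)
  noise_var <- max(noise_var, 0.0011)
  set.seed(seed)
  sigma <- unname(stats::median(kernlab::sigest(X, scaled = FALSE)))
  kernels <- list(SE = kernlab::rbfdot(sigma = sigma),
                  Exp = kernlab::laplacedot(sigma = sqrt(sigma)),
                  RQ = rq_kernel(sigma = sigma, alpha = 2))
  models <- list()
  for (nm in names(kernels)) {
    fit <- tryCatch(
      kernlab::gausspr(X, y, kernel = kernels[[nm]], var = noise_var,
                       scaled = FALSE),
      error = function(e) {
        warning("GPR kernel ", nm, " failed (", conditionMessage(e),
                "); continuing with remaining kernels")
        NULL
      })
    if (!is.null(fit)) models[[nm]] <- fit
  }
  if (!length(models)) stop("all GPR kernels failed")
  structure(list(models = models, sigma = sigma, noise_var = noise_var),
            class = "gpr_ensemble")
}

#' @export
predict.gpr_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$models,
                  function(m) as.numeric(kernlab::predict(m, newdata)),
                  numeric(nrow(newdata)))
  matrix(preds, nrow = nrow(newdata),
         dimnames = list(NULL, names(object$models)))
}

#' Average per-kernel metrics of a GPR ensemble
#'
#' @param object a `gpr_ensemble`.
#' @param X predictor matrix.
#' @param y observed response.
#' @return list with `r2` and `rmse`, each the arithmetic mean over kernels.
#' @export
gpr_average_metrics <- function(object, X, y) {
  preds <- predict(object, X)
  list(r2 = mean(apply(preds, 2, function(p) r_squared(y, p))),
       rmse = mean(apply(preds, 2, function(p) rmse(y, p))))
}

#' Baseline model families
#'
#' Dispatches to the reference implementations used for comparison with the
#' main calibrations: `MLR` ([fit_mlr()]), `RF` (a seeded
#' [randomForest::randomForest] of regression trees) and `SNN` (a seeded
#' single-hidden-layer [nnet::nnet] with linear output and weight decay;
#' 32 hidden units, reduced on wide predictor blocks so the weight count
#' stays within nnet's practical optimizer limit).
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param kind one of `"MLR"`, `"RF"`, `"SNN"`.
#' @param seed seed for the stochastic fits.
#' @param ... passed to the underlying fitter.
#' @return object of class `baseline_model` with elements `kind`, `fit` and
#'   `params`.
#' @export
fit_baseline <- function(X, y, kind = c("MLR", "RF", "SNN"), seed = 1L, ...) {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as.numeric(y)
  set.seed(seed)
  if (kind == "MLR") {
    fit <- fit_mlr(X, y)
    params <- list(rank = fit$rank)
  } else if (kind == "RF") {
    fit <- randomForest::randomForest(X, y, ntree = 300, ...)
    params <- list(ntree = 300, mtry = fit$mtry)
  } else {
    # nnet's BFGS keeps a dense inverse-Hessian, so the weight count
    # (p + 2) * size must stay in the few-thousand range to be tractable;
    # width 32 applies to narrow inputs, wide profiles get fewer units
    size <- min(32L, max(2L, 4000L %/% (ncol(X) + 2L)))
    fit <- nnet::nnet(X, y, size = size, linout = TRUE, decay = 0.01,
                      maxit = 200, trace = FALSE,
                      MaxNWts = (ncol(X) + 1) * size + size + 1, ...)
    params <- list(size = size, decay = 0.01, maxit = 200)
  }
  structure(list(kind = kind, fit = fit, params = params, seed = seed),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "MLR") predict(object$fit, newdata)
  else as.numeric(stats::predict(object$fit, newdata))
}

#' Evaluate all calibration models for a set of components
#'
#' For each component column and each requested model family, fits on the
#' training split and reports train/test R-squared and RMSE -- the package's
#' model-comparison table. PLS selects its latent-variable count by
#' [select_n_latent()]; GPR reports the mean metrics of its kernel ensemble;
#' all stochastic fits are seeded.
#'
#' @param X predictor matrix (samples x grid points), rows aligned with
#'   `table`.
#' @param table composition table with the component columns.
#' @param components character vector of component columns to model
#'   (default: all non-`sample_id` columns). Missing columns are skipped
#'   with a warning.
#' @param models subset of `c("PLS", "SVR", "GPR", "MLR", "RF", "SNN")`.
#' @param split a [split_dataset()] result for `nrow(X)` samples.
#' @param max_A,cv_folds PLS latent-variable selection settings.
#' @param seed seed for the stochastic fits.
#' @return data frame with one row per (component, model): columns
#'   `component`, `model`, `r2_train`, `rmse_train`, `r2_test`, `rmse_test`,
#'   `n_latent` (PLS only) and `hyperparameters` (compact record).
#' @export
evaluate_all <- function(X, table, components = NULL,
                         models = c("PLS", "SVR", "GPR", "MLR", "RF", "SNN"),
                         split, max_A = 30, cv_folds = 10, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(inherits(split, "split_spec"),
            max(c(split$train, split$test)) <= nrow(X))
  all_models <- c("PLS", "SVR", "GPR", "MLR", "RF", "SNN")
  if (!length(models) || !all(models %in% all_models))
    stop("models must be a non-empty subset of: ",
         paste(all_models, collapse = ", "))
  if (is.null(components)) components <- setdiff(names(table), "sample_id")
  missing <- setdiff(components, names(table))
  if (length(missing)) {
    warning("component column(s) not in table, skipped: ",
            paste(missing, collapse = ", "))
    components <- setdiff(components, missing)
  }
  tr <- split$train; te <- split$test
  rows <- list()
  for (comp in components) {
    y <- table[[comp]]
    for (mod in models) {
      res <- tryCatch(
        eval_one_model(X[tr, , drop = FALSE], y[tr],
                       X[te, , drop = FALSE], y[te],
                       mod, max_A, cv_folds, seed),
        error = function(e) {
          warning("model ", mod, " failed for ", comp, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <-
        data.frame(component = comp, model = mod, res,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

eval_one_model <- function(Xtr, ytr, Xte, yte, model, max_A, cv_folds, seed) {
  n_latent <- NA_integer_
  if (model == "PLS") {
    A <- select_n_latent(Xtr, ytr, max_A = max_A, cv_folds = cv_folds,
                         seed = seed)
    fit <- fit_pls(Xtr, ytr, ncomp = A)
    n_latent <- fit$ncomp
    hyper <- sprintf("A=%d", n_latent)
    ptr <- predict(fit, Xtr); pte <- predict(fit, Xte)
  } else if (model == "SVR") {
    fit <- fit_svr(Xtr, ytr, cv_folds = min(cv_folds, 5), seed = seed)
    hyper <- sprintf("cost=%g,gamma=%g,eps=%g", fit$params$cost,
                     fit$params$gamma, fit$params$epsilon)
    ptr <- predict(fit, Xtr); pte <- predict(fit, Xte)
  } else if (model == "GPR") {
    fit <- fit_gpr_ensemble(Xtr, ytr, seed = seed)
    hyper <- sprintf("kernels=%s,sigma=%.3g",
                     paste(names(fit$models), collapse = "+"), fit$sigma)
    mtr <- gpr_average_metrics(fit, Xtr, ytr)
    mte <- gpr_average_metrics(fit, Xte, yte)
    return(data.frame(r2_train = mtr$r2, rmse_train = mtr$rmse,
                      r2_test = mte$r2, rmse_test = mte$rmse,
                      n_latent = n_latent, hyperparameters = hyper))
  } else {
    fit <- fit_baseline(Xtr, ytr, kind = model, seed = seed)
    hyper <- paste(names(fit$params), unlist(fit$params),
                   sep = "=", collapse = ",")
    ptr <- predict(fit, Xtr); pte <- predict(fit, Xte)
  }
  data.frame(r2_train = r_squared(ytr, ptr), rmse_train = rmse(ytr, ptr),
             r2_test = r_squared(yte, pte), rmse_test = rmse(yte, pte),
             n_latent = n_latent, hyperparameters = hyper)
}
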