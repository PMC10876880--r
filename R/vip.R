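#' VIP scores of a fitted PLS model
#'
#' Variable importance in projection, the standard chemometric summary of
#' each predictor's weighted contribution across latent variables:
#' \deqn{VIP_j = \sqrt{p \, \sum_a SS_a w_{ja}^2 / \sum_a SS_a}}
#' with unit-norm weight vectors \eqn{w_a} and \eqn{SS_a} the response
#' sum-of-squares explained by latent variable \eqn{a}. The mean squared VIP
#' equals 1 by construction, so a score above 1 marks a predictor of
#' above-average importance.
#'
#' @param model a [fit_pls()] model.
#' @param temperatures numeric vector labelling the predictors (grid
#'   temperatures), length p.
#' @return object of class `vip_profile`: list with `temperature` and `vip`.
#' @export
vip_scores <- function(model, temperatures) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) != p)
    stop("temperatures length ", length(temperatures), " != p = ", p)
  ss <- model$SS
  if (sum(ss) <= 0) stop("all latent variables explain zero response variance (degenerate fit)")
  vip <- sqrt(p * drop(model$W^2 %*% ss) / sum(ss))
  structure(list(temperature = temperatures, vip = vip, ncomp = model$ncomp),
            class = "vip_profile")
}

#' @export
print.vip_profile <- function(x, ...) {
  cat(sprintf("<vip_profile> %d temperatures, %d LV(s), %d with VIP > 1\n",
              length(x$vip), x$ncomp, sum(x$vip > 1)))
  invisible(x)
}

#' Extract characteristic temperature intervals from a VIP profile
#'
#' Finds maximal runs of consecutive grid points whose VIP exceeds the
#' threshold, merges runs separated by less than `merge_gap`, and drops runs
#' shorter than `min_run` -- pointwise thresholding at fine grid resolution
#' fragments otherwise; the merge/min-run defaults (5 and 2 degC) keep the
#' output at the granularity at which characteristic ranges are reported.
#' The result is always a sorted set of disjoint closed intervals with
#' endpoints at grid temperatures.
#'
#' @param profile a [vip_scores()] profile.
#' @param threshold VIP cutoff (> 0), default 1 (above-average importance).
#' @param min_run minimum interval width in degC (runs narrower than this
#'   are discarded); default 2.
#' @param merge_gap gaps narrower than this (degC) between adjacent runs are
#'   bridged; default 5.
#' @return object of class `interval_set`: data frame with columns `t_lo`,
#'   `t_hi`.
#' @export
extract_intervals <- function(profile, threshold = 1, min_run = 2,
                              merge_gap = 5) {
  stopifnot(inherits(profile, "vip_profile"), threshold > 0,
            min_run >= 0, merge_gap >= 0)
  sel <- profile$vip > threshold
  if (!any(sel)) return(interval_set(numeric(0), numeric(0)))
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lo <- profile$temperature[starts[r$values]]
  hi <- profile$temperature[ends[r$values]]
  # merge runs separated by less than merge_gap
  if (length(lo) > 1) {
    out_lo <- c(); out_hi <- c()
    cur_lo <- lo[1]; cur_hi <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] - cur_hi < merge_gap) {
        cur_hi <- hi[i]
      } else {
        out_lo <- c(out_lo, cur_lo); out_hi <- c(out_hi, cur_hi)
        cur_lo <- lo[i]; cur_hi <- hi[i]
      }
    }
    lo <- c(out_lo, cur_lo); hi <- c(out_hi, cur_hi)
  }
  wide <- (hi - lo) >= min_run | min_run == 0
  interval_set(lo[wide], hi[wide])
}

#' Construct an interval set
#'
#' @param t_lo,t_hi interval endpoints in degC (`t_lo <= t_hi` pairwise).
#'   Intervals are sorted and must be disjoint.
#' @return object of class `interval_set`.
#' @export
interval_set <- function(t_lo, t_hi) {
  stopifnot(length(t_lo) == length(t_hi), all(t_lo <= t_hi))
  ord <- order(t_lo)
  t_lo <- t_lo[ord]; t_hi <- t_hi[ord]
  if (length(t_lo) > 1 && any(t_lo[-1] <= t_hi[-length(t_hi)]))
    stop("intervals must be pairwise disjoint")
  structure(data.frame(t_lo = t_lo, t_hi = t_hi),
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set> ", if (nrow(x)) format_intervals(x) else "(empty)", "\n")
  invisible(x)
}

#' Compact "lo-hi,lo-hi" rendering of an interval set
#'
#' @param intervals an [interval_set()].
#' @param digits decimal places for the endpoints (default 0).
#' @return single string, e.g. `"150-390,510-520,688-701"`.
#' @export
format_intervals <- function(intervals, digits = 0) {
  paste(sprintf("%.*f-%.*f", digits, intervals$t_lo, digits, intervals$t_hi),
        collapse = ",")
}

#' Jaccard overlap of two interval sets
#'
#' Length of the intersection of the two unions divided by the length of
#' their union, on the continuous temperature axis; 1 means identical
#' coverage. Used to validate that VIP-selected intervals recover known
#' signal windows.
#'
#' @param a,b `interval_set`s.
#' @return scalar in `[0, 1]` (0 if both are empty).
#' @export
interval_jaccard <- function(a, b) {
  len <- function(s) if (nrow(s)) sum(s$t_hi - s$t_lo) else 0
  inter <- 0
  if (nrow(a) && nrow(b)) {
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      lo <- max(a$t_lo[i], b$t_lo[j]); hi <- min(a$t_hi[i], b$t_hi[j])
      if (hi > lo) inter <- inter + (hi - lo)
    }
  }
  uni <- len(a) + len(b) - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Restrict a DTG matrix to selected temperature intervals
#'
#' Keeps the columns whose temperature lies inside any of the (closed)
#' intervals, preserving order and the column-to-temperature mapping.
#'
#' @param X DTG matrix with a numeric `"temperature"` attribute or numeric
#'   column names.
#' @param intervals a non-empty [interval_set()].
#' @return the column-subset matrix, `"temperature"` attribute updated.
#' @export
restrict_to_intervals <- function(X, intervals) {
  stopifnot(is.matrix(X), inherits(intervals, "interval_set"))
  if (!nrow(intervals)) stop("empty interval set: nothing to fit")
  temps <- attr(X, "temperature") %||% as.numeric(colnames(X))
  if (anyNA(temps)) stop("X must carry temperatures (attribute or column names)")
  keep <- rep(FALSE, length(temps))
  for (i in seq_len(nrow(intervals)))
    keep <- keep | (temps >= intervals$t_lo[i] - 1e-9 &
                      temps <= intervals$t_hi[i] + 1e-9)
  if (!any(keep)) stop("no grid point falls inside the intervals")
  out <- X[, keep, drop = FALSE]
  attr(out, "temperature") <- temps[keep]
  out
}

#' Refit PLS on selected intervals and compare with the full-grid model
#'
#' Fits the full-grid PLS calibration and an interval-restricted refit on the
#' same train/test split, re-selecting the latent-variable count for the
#' restricted predictor block (whose rank differs), and reports both models'
#' train/test metrics together with the R-squared reduction caused by the
#' restriction -- the validation that selected characteristic intervals
#' retain the curve's predictive information.
#'
#' @param X full DTG matrix (with temperatures).
#' @param y response vector.
#' @param intervals [interval_set()] of characteristic temperature ranges.
#' @param split a [split_dataset()] result.
#' @param max_A,cv_folds,seed latent-variable selection settings.
#' @return list with `comparison` (two-row data frame, full vs restricted)
#'   and `delta` (list `r2_train`, `r2_test`: full minus restricted).
#' @export
refit_and_compare <- function(X, y, intervals, split, max_A = 30,
                              cv_folds = 10, seed = 1L) {
  stopifnot(inherits(split, "split_spec"))
  Xr <- restrict_to_intervals(X, intervals)
  tr <- split$train; te <- split$test
  fit_one <- function(Xs) {
    A <- select_n_latent(Xs[tr, , drop = FALSE], y[tr], max_A = max_A,
                         cv_folds = cv_folds, seed = seed)
    m <- fit_pls(Xs[tr, , drop = FALSE], y[tr], ncomp = A)
    ptr <- predict(m, Xs[tr, , drop = FALSE])
    pte <- predict(m, Xs[te, , drop = FALSE])
    data.frame(n_latent = m$ncomp,
               r2_train = r_squared(y[tr], ptr), rmse_train = rmse(y[tr], ptr),
               r2_test = r_squared(y[te], pte), rmse_test = rmse(y[te], pte))
  }
  full <- fit_one(X)
  restricted <- fit_one(Xr)
  comparison <- cbind(data.frame(fit = c("full", "restricted"),
                                 n_predictors = c(ncol(X), ncol(Xr))),
                      rbind(full, restricted))
  list(comparison = comparison,
       delta = list(r2_train = full$r2_train - restricted$r2_train,
                    r2_test = full$r2_test - restricted$r2_test))
}
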