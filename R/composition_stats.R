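#' Per-component density distributions
#'
#' For each component, spans `[min, max]` with `n_bins` equal-width bins,
#' counts samples per bin and converts to probabilities -- the construction
#' behind content-distribution density plots. A constant column yields one
#' degenerate bin carrying probability 1.
#'
#' @param table composition table (data frame; a `sample_id` column, if
#'   present, is ignored).
#' @param n_bins number of bins (>= 1), default 20.
#' @return named list; per component a list with `breaks` (length bins + 1)
#'   and `probability` (summing to 1).
#' @export
density_distribution <- function(table, n_bins = 20) {
  stopifnot(is.data.frame(table), n_bins >= 1)
  vals <- composition_values(table)
  if (nrow(vals) < 1) stop("need at least one sample")
  out <- lapply(colnames(vals), function(nm) {
    x <- vals[, nm]
    lo <- min(x); hi <- max(x)
    if (hi == lo)
      return(list(breaks = c(lo, hi), probability = 1))
    breaks <- seq(lo, hi, length.out = n_bins + 1)
    counts <- graphics::hist(x, breaks = breaks, include.lowest = TRUE,
                             right = TRUE, plot = FALSE)$counts
    list(breaks = breaks, probability = counts / length(x))
  })
  names(out) <- colnames(vals)
  out
}

#' Inter-component correlation matrix
#'
#' Pairwise linear (Pearson) correlation between all component columns; the
#' descriptive analysis used to judge whether components must be modelled
#' independently. Spearman rank correlation is available behind the `method`
#' flag.
#'
#' @param table composition table.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal. Constant columns
#'   are flagged with a warning and their correlations reported as `NA`.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- composition_values(table)
  if (nrow(vals) < 3) stop("need at least 3 samples for a correlation matrix")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    warning("constant column(s), correlations undefined: ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
  cm <- suppressWarnings(stats::cor(vals, method = method))
  diag(cm) <- 1
  cm
}

#' Strongly correlated component pairs
#'
#' Off-diagonal pairs with `|r|` above a threshold, each pair reported once,
#' strongest first.
#'
#' @param matrix correlation matrix as from [correlation_matrix()].
#' @param threshold absolute-correlation cutoff in `[0, 1)`, default 0.9.
#' @return data frame with columns `component_a`, `component_b`, `r`.
#' @export
high_correlation_pairs <- function(matrix, threshold = 0.9) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            threshold >= 0, threshold < 1)
  nms <- colnames(matrix)
  idx <- which(upper.tri(matrix) & !is.na(matrix) &
                 abs(matrix) > threshold, arr.ind = TRUE)
  out <- data.frame(component_a = nms[idx[, 1]],
                    component_b = nms[idx[, 2]],
                    r = matrix[idx])
  out[order(-abs(out$r)), , drop = FALSE]
}

composition_values <- function(table) {
  cols <- setdiff(names(table), "sample_id")
  vals <- as.matrix(table[, cols, drop = FALSE])
  if (!is.numeric(vals)) stop("composition columns must be numeric")
  if (anyNA(vals)) stop("missing values among modelled components")
  vals
}
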