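## Accuracy, error and uncertainty metrics.
##
## State labels 1..K are ordered along the conformational transition
## (guaranteed by the PC1 ordering of the state model), so the magnitude of
## the label deviation |predicted - true| is structurally meaningful and
## tolerance-band accuracies are well defined.

#' Shannon entropy of a class-probability vector
#'
#' H(P) = -sum_i p_i ln p_i, with 0 ln 0 = 0. Natural log by default; the
#' result lies in [0, log(K)].
#'
#' @param p probability vector (non-negative, sums to 1).
#' @param base logarithm base (default e).
#' @return entropy (nats for the default base).
#' @examples
#' shannonEntropy(rep(1 / 19, 19))  # log(19)
#' @export
shannonEntropy <- function(p, base = exp(1)) {
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("p must be a probability vector summing to 1")
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Tolerance-band classification accuracy
#'
#' Fraction of predictions within k ordered states of the truth;
#' \code{k = 0} is exact-match accuracy.
#'
#' @param yTrue,yHat integer state labels of equal length.
#' @param k allowed absolute deviation in states.
#' @return fraction in [0, 1].
#' @export
toleranceAccuracy <- function(yTrue, yHat, k = 0L) {
  stopifnot(length(yTrue) == length(yHat))
  mean(abs(yHat - yTrue) <= k)
}

#' Histogram of state deviations
#'
#' Counts of |predicted - true| over 0..K-1, plus the tail count of
#' deviations >= \code{tailFrom} (large deviations correspond to substantial
#' conformational misassignment).
#'
#' @param yTrue,yHat integer state labels.
#' @param K number of states (default: max observed label).
#' @param tailFrom tail threshold in states.
#' @return list with \code{counts} (named 0..K-1) and \code{tail}.
#' @export
deviationHistogram <- function(yTrue, yHat, K = max(yTrue, yHat),
                               tailFrom = 4L) {
  stopifnot(length(yTrue) == length(yHat))
  dev <- abs(yHat - yTrue)
  counts <- vapply(0:(K - 1L), function(d) sum(dev == d), integer(1))
  names(counts) <- 0:(K - 1L)
  list(counts = counts, tail = sum(dev >= tailFrom))
}

#' Pixelwise image errors
#'
#' @param a,b \linkS4class{HeightImage}s on one grid.
#' @return named numeric: \code{mae} (nm) and \code{mse} (nm^2).
#' @export
imageErrors <- function(a, b) {
  stopifnot(identical(dim(a@values), dim(b@values)))
  d <- a@values - b@values
  c(mae = mean(abs(d)), mse = mean(d^2))
}

#' Mean of class-probability vectors
#'
#' Elementwise mean over a list (or row-matrix) of probability vectors;
#' the result is again a probability vector.
#'
#' @param preds list of probability vectors, or a matrix with one row each.
#' @return numeric probability vector.
#' @export
meanProbs <- function(preds) {
  if (is.list(preds)) preds <- do.call(rbind, preds)
  stopifnot(nrow(preds) >= 1L)
  colMeans(preds)
}
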