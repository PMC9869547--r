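# Biweight midcorrelation ---------------------------------------------------

# Transform one observation vector into biweight midcovariance scores.
# Returns the centered, Tukey-biweighted values; NOT normalized.
# MAD = 0 with positive variance falls back to plain mean-centering
# (Pearson-style scores) for that vector; a constant vector is an error.
.bicor_scores <- function(x, label = "vector") {
  med <- stats::median(x)
  mad <- stats::median(abs(x - med))  # no consistency scaling: cancels in u
  if (mad > 0) {
    u <- (x - med) / (9 * mad)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (x - med) * w
  } else if (stats::var(x) > 0) {
    x - mean(x)
  } else {
    stop("undefined correlation: '", label, "' is constant")
  }
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation using Tukey biweights with the standard tuning
#' constant 9: observations further than 9 MADs from the median get zero
#' weight, and weights decay smoothly in between. Falls back to Pearson
#' behaviour for a vector whose MAD is zero but whose variance is positive;
#' a constant vector is an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  a <- .bicor_scores(x, "x")
  b <- .bicor_scores(y, "y")
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' All pairwise biweight midcorrelations of the rows of a matrix
#'
#' @param x Numeric matrix (variables in rows, observations in columns),
#'   at least 3 columns.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(x) {
  if (ncol(x) < 3) stop("need at least 3 observations (columns)")
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  scores <- x
  for (i in seq_len(nrow(x))) {
    scores[i, ] <- .bicor_scores(x[i, ], labels[i])
  }
  norms <- sqrt(rowSums(scores^2))
  scores <- scores / norms
  r <- tcrossprod(scores)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}
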