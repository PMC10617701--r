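#' Weighted mean and covariance (population form)
#'
#' Small numerical helpers used throughout the package.  The covariance
#' uses the population denominator \eqn{W = \sum_i w_i} (not
#' \eqn{W - 1}): with that convention the Erreygers identity
#' \eqn{E = 8\,\mathrm{cov}_w(h, r)} holds exactly and all results are
#' invariant to rescaling the weights.
#'
#' @param x,y numeric vectors.
#' @param w positive weights, recycled to \code{length(x)} if scalar.
#' @return A single number.
#' @examples
#' wtd_mean(c(0, 1), c(1, 3))   # 0.75
#' wtd_cov(c(0, 1), c(0, 1), c(1, 1))  # 0.25
#' @export
wtd_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep.int(1, length(x))
  check_weights(w, length(x))
  sum(w * x) / sum(w)
}

#' @rdname wtd_mean
#' @export
wtd_cov <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep.int(1, length(x))
  check_weights(w, length(x))
  if (length(y) != length(x)) stop("'x' and 'y' must have equal length")
  W <- sum(w)
  mx <- sum(w * x) / W
  my <- sum(w * y) / W
  sum(w * (x - mx) * (y - my)) / W
}

# weighted variance, population form
wtd_var <- function(x, w) wtd_cov(x, x, w)

check_weights <- function(w, n) {
  if (length(w) != n) stop("weights must have length ", n)
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0))
    stop("all weights must be finite and > 0")
  invisible(w)
}

check_binary <- function(h, what = "outcome") {
  if (anyNA(h) || !all(h %in% c(0, 1)))
    stop(sprintf("%s must be coded 0/1 with no missing values", what))
  invisible(h)
}
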