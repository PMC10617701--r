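#' Trend of an inequality index across survey rounds
#'
#' Ordinary least-squares line of the index on calendar year, plus the
#' Pearson correlation of the (year, index) pairs.  Calendar year (not
#' round number) is the regressor, so the slope is in index units per
#' year.  With only two rounds the correlation is necessarily +/-1; no
#' inference is attempted (few points).
#'
#' @param years numeric survey years; at least two distinct values.
#' @param index index value per year (e.g. Erreygers indices).
#' @return A list of class \code{"ci_trend"}: \code{slope},
#'   \code{intercept}, \code{pearson_r}, and \code{points} (data frame
#'   of the input pairs, sorted by year).
#' @examples
#' tr <- fit_trend(c(2005, 2011, 2016), c(0.251, 0.239, 0.201))
#' round(tr$pearson_r, 2)   # -0.94
#' @export
fit_trend <- function(years, index) {
  years <- as.numeric(years)
  index <- as.numeric(index)
  if (length(years) != length(index)) stop("'years' and 'index' must have equal length")
  if (anyNA(years) || anyNA(index)) stop("missing values in trend input")
  if (length(unique(years)) < 2) stop("at least two distinct years required")
  fit <- stats::lm(index ~ years)
  r <- if (stats::sd(index) == 0) 0 else stats::cor(years, index)
  o <- order(years)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r,
                 points = data.frame(year = years[o], index = index[o])),
            class = "ci_trend")
}

#' @export
print.ci_trend <- function(x, digits = 4, ...) {
  cat("Trend of inequality index across survey rounds\n")
  cat("  slope     :", format(x$slope, digits = digits), "per year\n")
  cat("  intercept :", format(x$intercept, digits = digits), "\n")
  cat("  Pearson r :", format(x$pearson_r, digits = digits), "\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}
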