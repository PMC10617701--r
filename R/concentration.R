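#' Weighted fractional ranks
#'
#' Ranks respondents by a living-standards score and returns the
#' weighted fractional rank used by concentration indices: after sorting
#' ascending by score, respondent \eqn{i} receives
#' \eqn{r_i = (\sum_{j<i} w_j + w_i/2)/W}, the midpoint of its weight
#' interval on the cumulative-weight scale.  All members of a tie block
#' receive the midpoint rank of the block's combined interval, so the
#' weighted mean of the ranks is exactly 0.5 and ranking by a coarse
#' score (e.g. quintile group) remains well defined.
#'
#' @param scores numeric vector of finite living-standards scores.
#' @param weights positive sampling weights (default: equal).
#' @return Numeric vector of ranks in (0, 1), in the original order.
#' @examples
#' fractional_rank(c(10, 20, 30, 40))        # 0.125 0.375 0.625 0.875
#' fractional_rank(c(1, 2), weights = c(1, 3)) # 0.125 0.625
#' @seealso \code{\link{erreygers_index}}, \code{\link{concentration_curve}}
#' @export
fractional_rank <- function(scores, weights = NULL) {
  n <- length(scores)
  if (n == 0L) stop("empty score vector")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(weights)) weights <- rep.int(1, n)
  check_weights(weights, n)

  o <- order(scores)
  w <- weights[o]
  s <- scores[o]
  W <- sum(w)
  cw <- cumsum(w)
  blk <- cumsum(!duplicated(s))          # tie-block id along sorted order
  block_start <- ave(cw - w, blk, FUN = min)   # cumulative weight before block
  block_w <- ave(w, blk, FUN = sum)
  r <- (block_start + block_w / 2) / W
  out <- numeric(n)
  out[o] <- r
  out
}

#' Concentration curve of a binary outcome
#'
#' Cumulative weighted share of the outcome plotted against the
#' cumulative weighted population share, respondents ranked from poorest
#' to richest.  One point is emitted per distinct score block and the
#' origin (0, 0) is prepended; the final point is (1, 1).  A curve lying
#' below the diagonal indicates concentration of the outcome among the
#' rich (pro-rich inequality).
#'
#' @param h binary outcome vector (0/1); at least one 1 is required.
#' @param scores ranking variable (wealth score).
#' @param weights positive sampling weights (default: equal).
#' @return A data frame of class \code{"concentration_curve"} with
#'   columns \code{p} (population share) and \code{L} (outcome share),
#'   both nondecreasing from 0 to 1.
#' @examples
#' cc <- concentration_curve(c(0, 0, 0, 1), 1:4)
#' cc$L   # 0 0 0 0 1
#' @export
concentration_curve <- function(h, scores, weights = NULL) {
  n <- length(h)
  check_binary(h)
  if (length(scores) != n) stop("'h' and 'scores' must have equal length")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(weights)) weights <- rep.int(1, n)
  check_weights(weights, n)
  if (sum(h) == 0) stop("concentration curve undefined: outcome is 0 for every respondent")

  o <- order(scores)
  w <- weights[o]
  s <- scores[o]
  hw <- w * h[o]
  last <- !duplicated(s, fromLast = TRUE)  # block ends in sorted order
  p <- cumsum(w)[last] / sum(w)
  L <- cumsum(hw)[last] / sum(hw)
  out <- data.frame(p = c(0, p), L = c(0, L))
  class(out) <- c("concentration_curve", "data.frame")
  out
}

#' @export
plot.concentration_curve <- function(x, ...,
                                     xlab = "Cumulative population share (poorest to richest)",
                                     ylab = "Cumulative outcome share",
                                     main = "Concentration curve") {
  graphics::plot(x$p, x$L, type = "l", xlab = xlab, ylab = ylab,
                 main = main, xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Standard and Erreygers concentration indices
#'
#' For a binary outcome \eqn{h} with weighted mean \eqn{\mu} and
#' fractional wealth ranks \eqn{r}, the standard concentration index is
#' \eqn{C = 2\,\mathrm{cov}_w(h, r)/\mu} (twice the area between the
#' concentration curve and the diagonal) and the Erreygers index is its
#' bounded-outcome correction \eqn{E = 8\,\mathrm{cov}_w(h, r) = 4\mu C},
#' ranging over \eqn{[-1, 1]}.  Positive values indicate concentration
#' of the outcome among richer respondents.
#'
#' @param h binary outcome vector (0/1).
#' @param ranks fractional ranks from \code{\link{fractional_rank}},
#'   computed with the same weights.
#' @param weights positive sampling weights (default: equal).
#' @return A list of class \code{"conc_index"} with elements \code{mu},
#'   \code{C}, \code{E}, \code{n} and \code{ranks}.  When \eqn{\mu = 0}
#'   the standard index is undefined: \code{C} is \code{NA} (with a
#'   warning) and \code{E} is 0.
#' @examples
#' r <- fractional_rank(1:4)
#' erreygers_index(c(0, 0, 0, 1), r)$E   # 0.75
#' @export
erreygers_index <- function(h, ranks, weights = NULL) {
  n <- length(h)
  check_binary(h)
  if (length(ranks) != n) stop("'h' and 'ranks' must have equal length")
  if (any(ranks <= 0) || any(ranks >= 1)) stop("ranks must lie strictly in (0, 1)")
  if (is.null(weights)) weights <- rep.int(1, n)
  check_weights(weights, n)

  mu <- wtd_mean(h, weights)
  cv <- wtd_cov(h, ranks, weights)
  E <- 8 * cv
  if (mu == 0) {
    warning("weighted prevalence is zero: standard concentration index undefined")
    C <- NA_real_
  } else {
    C <- 2 * cv / mu
  }
  structure(list(mu = mu, C = C, E = E, n = n, ranks = ranks),
            class = "conc_index")
}

#' @export
print.conc_index <- function(x, digits = 4, ...) {
  cat("Concentration of a binary outcome (n = ", x$n, ")\n", sep = "")
  cat("  weighted prevalence mu :", format(x$mu, digits = digits), "\n")
  cat("  standard index C       :", format(x$C, digits = digits), "\n")
  cat("  Erreygers index E      :", format(x$E, digits = digits), "\n")
  if (!is.null(x$se_E))
    cat("  bootstrap SE(E)        :", format(x$se_E, digits = digits), "\n")
  invisible(x)
}

#' Stratified cluster bootstrap
#'
#' Resamples primary sampling units (clusters) with replacement within
#' strata and recomputes a statistic, the standard way to attach
#' uncertainty to design-based estimates without survey-linearization
#' algebra.  Within each stratum the same number of clusters is drawn as
#' observed; all rows of a drawn cluster enter the replicate (weights
#' travel with the rows).
#'
#' @param data data frame with one row per respondent.
#' @param statistic function mapping a data frame like \code{data} to a
#'   single number.
#' @param cluster name of the cluster (PSU) column in \code{data}.
#' @param strata optional name of the stratum column; \code{NULL} treats
#'   the sample as one stratum.
#' @param B number of bootstrap replicates (at least 100).
#' @param seed integer seed; fixed seed gives identical results.
#' @param level confidence level for the percentile interval.
#' @return List with \code{se}, percentile interval \code{ci}
#'   (length 2), the replicate values \code{replicates}, and \code{B}.
#' @export
bootstrap_se <- function(data, statistic, cluster, strata = NULL,
                         B = 200, seed = 1, level = 0.95) {
  stopifnot(is.data.frame(data), is.function(statistic))
  if (B < 100) stop("B must be at least 100")
  if (!cluster %in% names(data)) stop("no column '", cluster, "' in data")
  cl <- as.character(data[[cluster]])
  st <- if (is.null(strata)) rep("all", nrow(data)) else {
    if (!strata %in% names(data)) stop("no column '", strata, "' in data")
    as.character(data[[strata]])
  }
  # cluster ids must not straddle strata; qualify by stratum
  key <- paste(st, cl, sep = "\r")
  if (length(unique(key)) < 2)
    stop("cluster bootstrap needs at least 2 clusters")
  idx_by_cluster <- split(seq_len(nrow(data)), key)
  clusters_by_stratum <- split(names(idx_by_cluster),
                               sub("\r.*$", "", names(idx_by_cluster)))

  reps <- numeric(B)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    take <- unlist(lapply(clusters_by_stratum, function(cls) {
      drawn <- cls[sample.int(length(cls), length(cls), replace = TRUE)]
      unlist(idx_by_cluster[drawn], use.names = FALSE)
    }), use.names = FALSE)
    reps[b] <- statistic(data[take, , drop = FALSE])
  }
  alpha <- (1 - level) / 2
  list(se = stats::sd(reps),
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7)),
       replicates = reps,
       B = B)
}
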