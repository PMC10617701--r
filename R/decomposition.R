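#' Weighted logit fit
#'
#' Maximizes the weight-scaled binomial log-likelihood
#' \eqn{\sum_i w_i [h_i \log p_i + (1-h_i)\log(1-p_i)]} with
#' \eqn{p_i = \mathrm{logit}^{-1}(\beta_0 + x_i'\beta)} by iteratively
#' reweighted least squares (the \code{\link[stats]{glm.fit}} engine
#' with a quasi-binomial family, so non-integer sampling weights are
#' accepted silently).  Collinear columns are dropped with a warning
#' rather than failing; coefficients larger than 15 in absolute value
#' trigger a separation warning.  At convergence the weighted mean of
#' the fitted probabilities equals the weighted prevalence of \code{h}
#' (intercept score equation).
#'
#' @param h binary outcome (0/1), not constant.
#' @param design numeric matrix of covariate columns (no intercept; the
#'   fit adds one), e.g. from \code{\link{encode_design}}.
#' @param weights positive sampling weights (default: equal).
#' @param tol IRLS convergence tolerance (relative deviance change).
#' @param maxit maximum IRLS iterations.
#' @return A list of class \code{"logit_fit"}: \code{coefficients}
#'   (intercept first), \code{fitted} probabilities, \code{converged},
#'   \code{iterations}, \code{loglik}, \code{dropped} (collinear
#'   columns), and the retained \code{design}.
#' @examples
#' h <- c(0, 0, 1, 1); x <- cbind(x = c(0, 1, 0, 1))
#' coef(fit_logit(h, x))
#' @export
fit_logit <- function(h, design, weights = NULL, tol = 1e-10, maxit = 100) {
  check_binary(h)
  n <- length(h)
  if (stats::var(h) == 0) stop("outcome is constant; logit model undefined")
  X <- as.matrix(design)
  if (nrow(X) != n) stop("design matrix must have one row per outcome value")
  if (is.null(weights)) weights <- rep.int(1, n)
  check_weights(weights, n)

  Xf <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xf * sqrt(weights))
  dropped <- character(0)
  if (qrX$rank < ncol(Xf)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(Xf)[-keep]
    warning("dropping collinear design column(s): ",
            paste(dropped, collapse = ", "))
    Xf <- Xf[, sort(keep), drop = FALSE]
  }

  fit <- stats::glm.fit(Xf, h, weights = weights,
                        family = stats::quasibinomial(),
                        control = stats::glm.control(epsilon = tol, maxit = maxit))
  if (!fit$converged)
    stop("logit fit did not converge within ", maxit,
         " iterations (deviance ", format(fit$deviance), ")")
  beta <- fit$coefficients
  if (any(abs(beta) > 15))
    warning("possible separation: |coefficient| > 15 for ",
            paste(names(beta)[abs(beta) > 15], collapse = ", "))
  p <- fit$fitted.values
  ll <- sum(weights * (h * log(p) + (1 - h) * log1p(-p)))
  design_out <- Xf[, -1, drop = FALSE]
  smap <- attr(design, "spec_map")
  if (!is.null(smap))
    attr(design_out, "spec_map") <- smap[smap$column %in% colnames(design_out), , drop = FALSE]
  structure(list(coefficients = beta, fitted = as.numeric(p),
                 converged = fit$converged, iterations = fit$iter,
                 loglik = ll, dropped = dropped,
                 design = design_out, weights = weights, h = h),
            class = "logit_fit")
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
print.logit_fit <- function(x, digits = 4, ...) {
  cat("Weighted logit fit (", x$iterations, " IRLS iterations, logLik ",
      format(x$loglik, digits = digits), ")\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Average marginal effects on the probability scale
#'
#' For an indicator column \eqn{x_k} the average marginal effect is the
#' weighted mean discrete change
#' \eqn{\beta^m_k = \mathrm{E}_w[p(x_k{=}1) - p(x_k{=}0)]}, holding all
#' other columns at their observed values; for a continuous column it is
#' the weighted mean derivative \eqn{\mathrm{E}_w[p_i(1-p_i)]\,\beta_k}.
#' Columns whose observed values are all 0/1 are treated as indicators
#' unless \code{kinds} says otherwise.
#'
#' @param fit a \code{\link{fit_logit}} object.
#' @param kinds optional character vector (\code{"indicator"} or
#'   \code{"continuous"}) named by design column.
#' @return Named numeric vector of AMEs, one per retained design column.
#' @examples
#' h <- c(0, 0, 1, 1, 0, 1); x <- cbind(x = c(0, 1, 0, 1, 0, 1))
#' average_marginal_effects(fit_logit(h, x))
#' @export
average_marginal_effects <- function(fit, kinds = NULL) {
  stopifnot(inherits(fit, "logit_fit"))
  X <- fit$design
  w <- fit$weights
  beta <- fit$coefficients
  eta <- as.numeric(cbind(1, X) %*% beta)
  cn <- colnames(X)
  out <- stats::setNames(numeric(length(cn)), cn)
  for (k in seq_along(cn)) {
    bk <- beta[[cn[k]]]
    xk <- X[, k]
    kind <- if (!is.null(kinds) && cn[k] %in% names(kinds)) kinds[[cn[k]]]
            else if (all(xk %in% c(0, 1))) "indicator" else "continuous"
    if (kind == "indicator") {
      p1 <- stats::plogis(eta + (1 - xk) * bk)
      p0 <- stats::plogis(eta - xk * bk)
      out[k] <- wtd_mean(p1 - p0, w)
    } else {
      p <- stats::plogis(eta)
      out[k] <- wtd_mean(p * (1 - p), w) * bk
    }
  }
  out
}

#' Decompose the Erreygers index into covariate contributions
#'
#' Wagstaff-type decomposition for a binary outcome: each design column
#' \eqn{x_k} contributes \eqn{a_k = e_k C_k}, where
#' \eqn{e_k = 4\beta^m_k \bar x_k} is the Erreygers-scale elasticity
#' (\eqn{\beta^m_k} the average marginal effect, \eqn{\bar x_k} the
#' weighted mean) and \eqn{C_k = 2\,\mathrm{cov}_w(x_k, r)/\bar x_k} the
#' covariate's standard concentration index over the wealth ranks
#' \eqn{r}.  Equivalently \eqn{a_k = 8\beta^m_k\,\mathrm{cov}_w(x_k,r)}.
#' The unexplained residual (the generalized-concentration error term)
#' is \eqn{E - \sum_k a_k}, so contributions and residual add up to the
#' total index by construction.  Percentage contributions use the total
#' index \eqn{E} as denominator.
#'
#' @param E total Erreygers index of the outcome (from
#'   \code{\link{erreygers_index}}); \eqn{|E|} must exceed \code{1e-6}
#'   for percentages to be defined.
#' @param fit a \code{\link{fit_logit}} object for the same respondents.
#' @param ranks fractional wealth ranks (same weights as the fit).
#' @param kinds passed to \code{\link{average_marginal_effects}}.
#' @return A list of class \code{"ci_decomposition"}: \code{table}
#'   (data frame with columns \code{column}, \code{covariate},
#'   \code{level}, \code{beta_m}, \code{xbar}, \code{elasticity},
#'   \code{conc_index}, \code{contribution}, \code{percent}),
#'   \code{group_percent} (summed percentage per covariate), \code{E},
#'   \code{residual} and \code{total_percent_explained}.
#' @export
decompose_index <- function(E, fit, ranks, kinds = NULL) {
  stopifnot(inherits(fit, "logit_fit"))
  X <- fit$design
  w <- fit$weights
  if (length(ranks) != nrow(X)) stop("'ranks' must have one value per respondent")
  if (abs(E) < 1e-6)
    stop("total index is numerically zero; percentage contributions undefined")

  beta_m <- average_marginal_effects(fit, kinds = kinds)
  cn <- colnames(X)
  xbar <- apply(X, 2, wtd_mean, w = w)
  covr <- apply(X, 2, function(x) wtd_cov(x, ranks, w))
  ci_k <- ifelse(xbar == 0, NA_real_, 2 * covr / xbar)
  elastic <- 4 * beta_m * xbar
  contrib <- 8 * beta_m * covr            # = elastic * ci_k, exactly
  pct <- 100 * contrib / E

  smap <- attr(X, "spec_map")
  if (is.null(smap)) {
    covariate <- sub(":.*$", "", cn)
    level <- ifelse(grepl(":", cn), sub("^[^:]*:", "", cn), NA_character_)
  } else {
    m <- match(cn, smap$column)
    covariate <- smap$covariate[m]
    level <- smap$level[m]
  }
  tab <- data.frame(column = cn, covariate = covariate, level = level,
                    beta_m = unname(beta_m), xbar = unname(xbar),
                    elasticity = unname(elastic), conc_index = unname(ci_k),
                    contribution = unname(contrib), percent = unname(pct),
                    stringsAsFactors = FALSE)
  residual <- E - sum(contrib)
  grp <- tapply(tab$percent, tab$covariate, sum)
  structure(list(table = tab,
                 group_percent = grp[unique(tab$covariate)],
                 E = E, residual = residual,
                 total_percent_explained = sum(pct)),
            class = "ci_decomposition")
}

#' @export
print.ci_decomposition <- function(x, digits = 3, ...) {
  cat("Decomposition of the Erreygers concentration index\n")
  cat("  total index E      :", format(x$E, digits = digits), "\n")
  cat("  explained          :", format(x$E - x$residual, digits = digits),
      sprintf("(%.1f%%)\n", x$total_percent_explained))
  cat("  residual           :", format(x$residual, digits = digits), "\n\n")
  tab <- x$table
  tab$beta_m <- round(tab$beta_m, 3)
  tab$xbar <- round(tab$xbar, 3)
  tab$elasticity <- round(tab$elasticity, 3)
  tab$conc_index <- round(tab$conc_index, 3)
  tab$contribution <- round(tab$contribution, 4)
  tab$percent <- round(tab$percent, 1)
  print(tab[, c("covariate", "level", "beta_m", "xbar", "elasticity",
                "conc_index", "percent")], row.names = FALSE)
  cat("\nSummed percentage contribution by covariate:\n")
  print(round(x$group_percent, 1))
  invisible(x)
}

#' Percentage contribution from elasticity and covariate index
#'
#' The share of the total index attributable to one covariate:
#' \eqn{100\, e_k C_k / E}.  Useful for reproducing published
#' decomposition tables from their printed elasticities and covariate
#' concentration indices.
#'
#' @param elasticity Erreygers-scale elasticity \eqn{e_k}.
#' @param conc_index covariate concentration index \eqn{C_k}.
#' @param E total Erreygers index.
#' @return Percentage contribution(s), vectorized.
#' @examples
#' contribution_percent(0.096, 0.507, 0.201)  # about 24.2
#' @export
contribution_percent <- function(elasticity, conc_index, E) {
  if (any(abs(E) < 1e-6)) stop("total index is numerically zero")
  100 * elasticity * conc_index / E
}
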