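#' Fit a concentration-index decomposition model
#'
#' One-stop interface for the wealth-related inequality analysis of a
#' binary health indicator.  The left-hand side of the formula is the
#' 0/1 outcome; the right-hand side lists the covariates of the
#' decomposition model (factors and character columns are dummy-coded
#' against their first/reference level, numeric 0/1 columns are
#' indicators, other numeric columns enter linearly).  Respondents are
#' ranked by \code{rank_by} (a wealth score or quintile) converted to
#' weighted fractional ranks.  The function estimates the weighted
#' prevalence, standard and Erreygers concentration indices, fits the
#' weighted logit model, computes average marginal effects, and
#' decomposes the index into covariate contributions plus a residual.
#' With \code{~ 1} only the indices are estimated.
#'
#' @param formula model formula, e.g. \code{know ~ sex + education + tv}.
#' @param data data frame with one row per respondent.
#' @param weights sampling weights: a column name (bare or quoted) in
#'   \code{data}, or a numeric vector.  Default: equal weights.
#' @param rank_by ranking variable: column name in \code{data} or a
#'   numeric vector (higher = richer).
#' @param cluster,strata optional column names used by the bootstrap.
#' @param boot number of stratified cluster-bootstrap replicates for
#'   the SE of the Erreygers index (0 = none); requires \code{cluster}.
#' @param seed seed for the bootstrap.
#' @return An object of class \code{"cidecomp"}; see
#'   \code{\link{summary.cidecomp}}, \code{\link{plot.cidecomp}}.
#' @examples
#' sim <- generate_survey(synthetic_config(clusters_per_stratum = 10,
#'                                         households_per_cluster = 20), seed = 7)
#' d <- sim$table
#' d$know <- build_knowledge_indicator(d[paste0("q", 1:5)], d$heard)
#' wi <- compute_wealth_scores(d[grep("^asset", names(d))], d$weight)
#' d$wealth_score <- wi$scores
#' fit <- cidecomp(know ~ sex + education + tv, data = d,
#'                 weights = weight, rank_by = wealth_score)
#' fit$index$E
#' @export
cidecomp <- function(formula, data, weights = NULL, rank_by,
                     cluster = NULL, strata = NULL, boot = 0, seed = 1) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  resolve <- function(expr) {
    if (is.null(expr)) return(NULL)
    if (is.character(expr) && length(expr) == 1 && expr %in% names(data))
      return(data[[expr]])
    if (is.name(expr) && as.character(expr) %in% names(data))
      return(data[[as.character(expr)]])
    eval(expr, envir = parent.frame(2))
  }
  if (missing(rank_by)) stop("'rank_by' is required")
  w <- resolve(substitute(weights))
  rk <- resolve(substitute(rank_by))
  if (is.null(rk)) stop("'rank_by' is required")
  if (is.factor(rk) || is.ordered(rk)) rk <- as.numeric(rk)
  n <- nrow(data)
  if (is.null(w)) w <- rep.int(1, n)
  check_weights(w, n)

  lhs <- all.vars(formula[[2]])
  if (length(lhs) != 1 || !lhs %in% names(data))
    stop("the formula must name one outcome column present in 'data'")
  h <- data[[lhs]]
  if (is.logical(h)) h <- as.integer(h)
  check_binary(h, what = paste0("outcome '", lhs, "'"))

  rhs_vars <- all.vars(formula[[3]])
  missing_rhs <- setdiff(rhs_vars, names(data))
  if (length(missing_rhs))
    stop("covariate(s) not in data: ", paste(missing_rhs, collapse = ", "))
  specs <- lapply(rhs_vars, function(v) spec_from_column(v, data[[v]]))
  X <- encode_design(data, specs)

  ranks <- fractional_rank(rk, w)
  index <- erreygers_index(h, ranks, w)
  curve <- concentration_curve(h, rk, w)

  fit <- NULL
  decomp <- NULL
  if (ncol(X) > 0) {
    fit <- fit_logit(h, X, w)
    decomp <- decompose_index(index$E, fit, ranks)
  }

  if (boot > 0) {
    cl_nm <- substitute(cluster); st_nm <- substitute(strata)
    cl_nm <- if (is.name(cl_nm)) as.character(cl_nm) else cluster
    st_nm <- if (is.name(st_nm)) as.character(st_nm) else strata
    if (is.null(cl_nm)) stop("bootstrap requires a 'cluster' column name")
    bd <- data
    bd$.h <- h; bd$.w <- w; bd$.rk <- rk
    bs <- bootstrap_se(bd, function(df) {
      r <- fractional_rank(df$.rk, df$.w)
      8 * wtd_cov(df$.h, r, df$.w)
    }, cluster = cl_nm, strata = st_nm, B = boot, seed = seed)
    index$se_E <- bs$se
    index$ci_E <- bs$ci
    index$B <- boot
  }

  structure(list(call = match.call(), outcome = lhs, n = n,
                 index = index, curve = curve, ranks = ranks,
                 fit = fit, decomposition = decomp,
                 specs = specs, weights = w, h = h),
            class = "cidecomp")
}

# derive a covariate_spec from an observed column
spec_from_column <- function(name, v) {
  if (is.factor(v))
    covariate_spec(name, if (nlevels(v) == 2) "binary" else "categorical",
                   levels = levels(v))
  else if (is.character(v)) {
    lev <- unique(normalize_label(v))
    covariate_spec(name, if (length(lev) == 2) "binary" else "categorical",
                   levels = sort(lev))
  } else if (is.numeric(v) && all(v %in% c(0, 1)))
    covariate_spec(name, "binary", levels = c("0", "1"))
  else covariate_spec(name, "continuous")
}

#' @export
print.cidecomp <- function(x, digits = 4, ...) {
  cat("Wealth-related inequality in '", x$outcome, "' (n = ", x$n, ")\n",
      sep = "")
  cat("  weighted prevalence :", format(x$index$mu, digits = digits), "\n")
  cat("  Erreygers index E   :", format(x$index$E, digits = digits))
  if (!is.null(x$index$se_E))
    cat("  (bootstrap SE ", format(x$index$se_E, digits = 3), ", 95% CI ",
        format(x$index$ci_E[1], digits = 3), " to ",
        format(x$index$ci_E[2], digits = 3), ")", sep = "")
  cat("\n")
  if (!is.null(x$decomposition))
    cat("  explained by model  : ",
        sprintf("%.1f%%", x$decomposition$total_percent_explained),
        " (residual ", format(x$decomposition$residual, digits = 3), ")\n",
        sep = "")
  invisible(x)
}

#' Summary of a concentration-index decomposition
#'
#' @param object a \code{\link{cidecomp}} fit.
#' @param ... unused.
#' @return The object, invisibly, after printing indices, logit
#'   coefficients, and the full decomposition table.
#' @export
summary.cidecomp <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\n")
    print(object$fit)
    cat("\n")
    print(object$decomposition)
  }
  invisible(object)
}

#' @export
coef.cidecomp <- function(object, type = c("ame", "logit"), ...) {
  type <- match.arg(type)
  if (is.null(object$fit)) return(numeric(0))
  if (type == "logit") object$fit$coefficients
  else stats::setNames(object$decomposition$table$beta_m,
                       object$decomposition$table$column)
}

#' @export
predict.cidecomp <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(object$fit)) stop("no covariate model in this fit")
  if (is.null(newdata)) {
    eta <- as.numeric(cbind(1, object$fit$design) %*% object$fit$coefficients)
  } else {
    X <- encode_design(newdata, object$specs)
    X <- X[, colnames(object$fit$design), drop = FALSE]
    eta <- as.numeric(cbind(1, X) %*% object$fit$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.cidecomp <- function(object, ...) {
  if (is.null(object$fit)) stop("no covariate model in this fit")
  object$h - object$fit$fitted
}

#' @export
fitted.cidecomp <- function(object, ...) {
  if (is.null(object$fit)) stop("no covariate model in this fit")
  object$fit$fitted
}

#' @export
plot.cidecomp <- function(x, ...) {
  plot(x$curve, main = paste0("Concentration curve of '", x$outcome,
                              "' (E = ", round(x$index$E, 3), ")"), ...)
}

#' @export
simulate.cidecomp <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fit)) stop("no covariate model in this fit")
  if (!is.null(seed)) set.seed(seed)
  p <- object$fit$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
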