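#' Asset-based wealth scores (weighted first principal component)
#'
#' Computes a living-standards score as the first principal component of
#' the asset-ownership matrix, the standard DHS-style wealth index.
#' Each asset is standardized by its weighted mean and SD, the weighted
#' correlation matrix is eigen-decomposed, and scores are the first
#' component.  The loading vector has unit Euclidean norm and its
#' orientation is fixed so that the sum of loadings is positive, i.e.
#' owning assets raises the score (richer means higher).
#'
#' @param assets numeric matrix/data frame of asset indicators (rows =
#'   respondents); at least two columns with nonzero weighted variance.
#'   Constant columns are dropped with a warning.
#' @param weights positive sampling weights (default: equal).
#' @return A list of class \code{"wealth_index"}: \code{scores} (one per
#'   respondent), \code{loadings} (one per retained asset),
#'   \code{explained_share} (share of total variance carried by the
#'   first component), and \code{dropped} (names of constant columns).
#' @examples
#' a <- cbind(radio = c(0, 0, 1, 1), tv = c(0, 1, 0, 1))
#' compute_wealth_scores(a)$explained_share
#' @export
compute_wealth_scores <- function(assets, weights = NULL) {
  A <- as.matrix(assets)
  storage.mode(A) <- "double"
  if (anyNA(A)) stop("asset matrix contains missing values")
  n <- nrow(A)
  if (is.null(weights)) weights <- rep.int(1, n)
  check_weights(weights, n)

  v <- apply(A, 2, wtd_var, w = weights)
  dropped <- colnames(A)[v <= 0] %||% character(0)
  if (any(v <= 0)) {
    if (all(v <= 0)) stop("every asset column is constant; wealth score undefined")
    warning("dropping constant asset column(s): ", paste(dropped, collapse = ", "))
    A <- A[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  if (ncol(A) < 2) stop("at least two non-constant asset columns required")

  wn <- weights / sum(weights)
  mu <- colSums(wn * A)
  Z <- sweep(sweep(A, 2, mu, `-`), 2, sqrt(v), `/`)
  R <- crossprod(Z * sqrt(wn), Z * sqrt(wn))      # weighted correlation matrix
  eig <- eigen(R, symmetric = TRUE)
  load <- eig$vectors[, 1]
  if (sum(load) < 0) load <- -load                # richer -> higher score
  structure(list(scores = as.numeric(Z %*% load),
                 loadings = stats::setNames(load, colnames(A)),
                 explained_share = eig$values[1] / sum(eig$values),
                 dropped = dropped),
            class = "wealth_index")
}

#' @export
print.wealth_index <- function(x, digits = 3, ...) {
  cat("Asset-based wealth index (first principal component)\n")
  cat("  assets retained :", length(x$loadings), "\n")
  cat("  variance share  :", format(x$explained_share, digits = digits), "\n")
  cat("  loadings        :",
      paste(format(x$loadings, digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' Weighted wealth quintile groups
#'
#' Assigns each respondent to one of five weighted quintile groups
#' (poorest, poorer, middle, richer, richest).  Respondents are sorted
#' by score; a tie block is assigned to the quintile in which its
#' cumulative-weight interval begins (the lowest quintile its mass
#' overlaps), so ties always share a group and a block ending exactly on
#' a quintile boundary stays on the lower side of the boundary.  Each
#' group's weighted share is 20\% up to the granularity of one
#' respondent's weight.
#'
#' @param scores numeric wealth scores (finite).
#' @param weights positive sampling weights (default: equal).
#' @return Factor with levels poorest < poorer < middle < richer <
#'   richest, in the original respondent order.
#' @examples
#' table(assign_quintiles(1:10))   # two per group
#' @export
assign_quintiles <- function(scores, weights = NULL) {
  n <- length(scores)
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(weights)) weights <- rep.int(1, n)
  check_weights(weights, n)
  labels <- c("poorest", "poorer", "middle", "richer", "richest")

  o <- order(scores)
  w <- weights[o]
  s <- scores[o]
  W <- sum(w)
  cw <- cumsum(w)
  blk <- cumsum(!duplicated(s))
  start_share <- ave(cw - w, blk, FUN = min) / W   # weight share below the block
  g <- pmin(findInterval(start_share, c(0.2, 0.4, 0.6, 0.8)) + 1L, 5L)
  out <- integer(n)
  out[o] <- g
  factor(labels[out], levels = labels, ordered = TRUE)
}
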