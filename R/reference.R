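#' Published Ethiopian reference estimates
#'
#' Published estimates from the national analysis of wealth-related
#' inequality in comprehensive HIV/AIDS knowledge among Ethiopian adults
#' (DHS rounds 2005, 2011, 2016), shipped as plain-text tables.
#' \code{ethiopia_reference()} returns the per-covariate decomposition
#' estimates: weighted covariate mean share (\code{xbar}), average
#' marginal effect (\code{beta}), Erreygers-scale elasticity,
#' covariate concentration index, and printed percentage contribution.
#' \code{ethiopia_index_by_round()} returns the round-level Erreygers
#' index and prevalence (in percent).
#'
#' The \code{consistent} column flags rows whose printed elasticity is
#' arithmetically irreconcilable with the printed marginal effect and
#' mean share beyond what printed precision can explain (half-ulp
#' rounding of the inputs can move \eqn{4\beta\bar x} by at most about
#' 0.0013).  Three 2016 rows are flagged: the men row, whose printed
#' elasticity 0.210 implies a mean share of about 0.449 against the
#' printed 0.425; the Muslim row, whose printed elasticity has the
#' opposite sign to the printed marginal effect; and the primary
#' education row, whose residual 0.0021 exceeds the rounding bound.
#' These are treated as typographical and excluded from
#' arithmetic-identity checks.
#'
#' @return A data frame.
#' @examples
#' head(ethiopia_reference())
#' ethiopia_index_by_round()
#' @export
ethiopia_reference <- function() {
  utils::read.csv(system.file("extdata", "ethiopia_published_estimates.csv",
                              package = "hcindex"),
                  stringsAsFactors = FALSE)
}

#' @rdname ethiopia_reference
#' @export
ethiopia_index_by_round <- function() {
  utils::read.csv(system.file("extdata", "ethiopia_index_by_round.csv",
                              package = "hcindex"),
                  stringsAsFactors = FALSE)
}
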