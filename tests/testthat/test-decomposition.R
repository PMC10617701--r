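test_that("intercept-only logit recovers the weighted prevalence", {
  h <- c(0, 1, 1, 0, 1)
  w <- c(1, 2, 1, 3, 1)
  fit <- fit_logit(h, matrix(numeric(0), 5, 0), weights = w)
  expect_equal(unname(coef(fit)), qlogis(wtd_mean(h, w)), tolerance = 1e-10)
  expect_equal(wtd_mean(fit$fitted, w), wtd_mean(h, w), tolerance = 1e-10)
})

test_that("single binary covariate recovers the weighted log odds ratio", {
  set.seed(21)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  h <- rbinom(n, 1, plogis(-1 + 1.3 * x))
  w <- runif(n, 0.5, 2)
  fit <- fit_logit(h, cbind(x = x), weights = w)
  # closed form from the weighted 2x2 table
  p1 <- wtd_mean(h[x == 1], w[x == 1])
  p0 <- wtd_mean(h[x == 0], w[x == 0])
  expect_equal(unname(coef(fit)["x"]), qlogis(p1) - qlogis(p0), tolerance = 1e-8)
  # weighted score equation for the intercept
  expect_equal(wtd_mean(fit$fitted, w), wtd_mean(h, w), tolerance = 1e-8)

  # AME equals the weighted prevalence difference in the saturated model
  ame <- average_marginal_effects(fit)
  expect_equal(unname(ame["x"]), p1 - p0, tolerance = 1e-8)
})

test_that("integer weights are equivalent to duplicated rows", {
  set.seed(33)
  n <- 60
  x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  h <- rbinom(n, 1, plogis(-0.3 + 0.8 * x[, "a"] + 0.5 * x[, "b"]))
  w <- sample(1:3, n, replace = TRUE)
  fit_w <- fit_logit(h, x, weights = w)
  idx <- rep(seq_len(n), w)
  fit_d <- fit_logit(h[idx], x[idx, ], weights = NULL)
  expect_equal(coef(fit_w), coef(fit_d), tolerance = 1e-7)
})

test_that("collinear columns are dropped with a warning; separation warns", {
  h <- c(0, 1, 0, 1, 1, 0, 1, 0)
  x <- cbind(a = c(0, 1, 0, 1, 1, 0, 1, 0) * 0 + rep(c(0, 1), 4))
  X <- cbind(x, twice = 2 * x[, 1])
  expect_warning(fit <- fit_logit(h, X), "collinear")
  expect_false("twice" %in% names(coef(fit)))

  hs <- c(0, 0, 0, 0, 1, 1, 1, 1)
  xs <- cbind(s = hs)   # perfect separation
  expect_warning(try(fit_logit(hs, xs), silent = TRUE), "separation")
})

test_that("AME is zero when a coefficient is zero and uses the derivative for continuous columns", {
  set.seed(8)
  n <- 200
  X <- cbind(d = rbinom(n, 1, 0.5), z = rnorm(n))
  h <- rbinom(n, 1, plogis(0.2 + 0.8 * X[, "z"]))
  fit <- fit_logit(h, X)
  fit$coefficients["d"] <- 0
  ame <- average_marginal_effects(fit)
  expect_equal(unname(ame["d"]), 0, tolerance = 1e-12)
  # continuous column: weighted mean of p(1-p) times beta
  eta <- as.numeric(cbind(1, fit$design) %*% fit$coefficients)
  p <- plogis(eta)
  expect_equal(unname(ame["z"]),
               mean(p * (1 - p)) * unname(fit$coefficients["z"]),
               tolerance = 1e-12)
})

test_that("decomposition adds up exactly and matches the covariance identity", {
  for (seed in 1:5) {
    s <- small_sim(seed = seed)
    d <- s$data
    d$wealth_quintile <- assign_quintiles(d$wealth_score, d$weight)
    specs <- list(
      covariate_spec("sex", "binary", c("women", "men")),
      covariate_spec("education", "categorical",
                     c("none", "primary", "secondary", "higher")),
      covariate_spec("tv", "binary", c("no", "yes")),
      covariate_spec("wealth_quintile", "categorical",
                     c("poorest", "poorer", "middle", "richer", "richest")))
    X <- encode_design(d, specs)
    r <- fractional_rank(d$wealth_score, d$weight)
    E <- erreygers_index(d$know, r, d$weight)$E
    fit <- fit_logit(d$know, X, d$weight)
    dec <- decompose_index(E, fit, r)

    # adding up: contributions + residual = E
    expect_equal(sum(dec$table$contribution) + dec$residual, E,
                 tolerance = 1e-12)
    # a_k = 8 beta_m cov_w(x_k, r), computed through the e_k * C_k route
    for (k in seq_len(nrow(dec$table))) {
      xk <- X[, dec$table$column[k]]
      expect_equal(dec$table$contribution[k],
                   dec$table$elasticity[k] * dec$table$conc_index[k],
                   tolerance = 1e-10)
      expect_equal(dec$table$contribution[k],
                   8 * dec$table$beta_m[k] * wtd_cov(xk, r, d$weight),
                   tolerance = 1e-10)
    }
    expect_equal(sum(dec$table$percent), dec$total_percent_explained,
                 tolerance = 1e-10)
    # grouped percentages sum the member columns
    edu <- dec$table$covariate == "education"
    expect_equal(unname(dec$group_percent["education"]),
                 sum(dec$table$percent[edu]), tolerance = 1e-12)
  }
})

test_that("a covariate uncorrelated with rank contributes nothing", {
  # symmetric design: x = 1 on the two extremes, cov(x, r) = 0 exactly
  h <- c(0, 1, 0, 1)
  x <- cbind(sym = c(1, 0, 0, 1))
  r <- fractional_rank(1:4)
  fit <- fit_logit(h, x)
  E <- erreygers_index(h, r)$E
  dec <- decompose_index(E, fit, r)
  expect_equal(dec$table$contribution[1], 0, tolerance = 1e-12)
  expect_equal(dec$residual, E, tolerance = 1e-12)
})

test_that("percentage contribution helper reproduces the printed arithmetic", {
  expect_equal(round(contribution_percent(0.096, 0.507, 0.201), 1), 24.2)
  expect_error(contribution_percent(0.1, 0.5, 0), "zero")
})

test_that("near-zero total index refuses percentages", {
  h <- c(0, 1, 0, 1)
  x <- cbind(a = c(0, 1, 1, 0))
  fit <- fit_logit(h, x)
  expect_error(decompose_index(1e-9, fit, fractional_rank(1:4)), "zero")
})
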