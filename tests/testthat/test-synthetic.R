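test_that("generation is reproducible: same config and seed, identical table", {
  cfg <- synthetic_config(clusters_per_stratum = 5, households_per_cluster = 8)
  s1 <- generate_survey(cfg, seed = 123)
  s2 <- generate_survey(cfg, seed = 123)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$latent_ses, s2$truth$latent_ses)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(s1$table, f1, row.names = FALSE)
  write.csv(s2$table, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))

  s3 <- generate_survey(cfg, seed = 124)
  expect_false(identical(s1$table$q1, s3$table$q1))
})

test_that("the composite indicator reconstructs the drawn outcome exactly", {
  s <- generate_survey(synthetic_config(clusters_per_stratum = 10,
                                        households_per_cluster = 10), seed = 2)
  know <- build_knowledge_indicator(s$table[paste0("q", 1:5)], s$table$heard)
  expect_identical(know, s$truth$h)
  expect_true(all(know[s$table$heard == "no"] == 0))
})

test_that("SES-independent outcome shows no wealth concentration", {
  cfg <- synthetic_config(
    clusters_per_stratum = 100, households_per_cluster = 125,  # n = 50,000
    outcome = list(intercept = qlogis(0.25), z = 0,
                   coefficients = c("sex:men" = 0)))
  s <- generate_survey(cfg, seed = 31)
  d <- s$table
  sc <- compute_wealth_scores(d[grep("^asset", names(d))], d$weight)$scores
  r <- fractional_rank(sc, d$weight)
  E <- erreygers_index(s$truth$h, r, d$weight)$E
  expect_lt(abs(E), 0.02)
})

test_that("a pro-rich configuration hits its prevalence and is pro-rich", {
  cfg <- round_config("2016")
  cfg$clusters_per_stratum <- 100
  cfg$households_per_cluster <- 125                            # n = 50,000
  s <- generate_survey(cfg, seed = 17)
  d <- s$table
  sc <- compute_wealth_scores(d[grep("^asset", names(d))], d$weight)$scores
  r <- fractional_rank(sc, d$weight)
  idx <- erreygers_index(s$truth$h, r, d$weight)
  expect_lt(abs(idx$mu - 0.28), 0.01)
  expect_gt(idx$E, 0)
})

test_that("full pipeline closes over generated data without missing values", {
  s <- small_sim(seed = 11)
  d <- s$data
  d$wealth_quintile <- assign_quintiles(d$wealth_score, d$weight)
  fit <- cidecomp(know ~ sex + residence + education + radio + tv +
                    newspaper + tested + wealth_quintile,
                  data = d, weights = weight, rank_by = wealth_score)
  expect_s3_class(fit, "cidecomp")
  expect_false(anyNA(fit$decomposition$table$contribution))
  expect_equal(sum(fit$decomposition$table$contribution) +
                 fit$decomposition$residual,
               fit$index$E, tolerance = 1e-12)
})

test_that("invalid configurations fail with informative messages", {
  expect_error(synthetic_config(n_strata = 0), "positive")
  expect_error(synthetic_config(selection_prob = c(-1, 1, 1, 1)), "positive")
  expect_error(synthetic_config(covariates = list(
    bad = list(kind = "binary", levels = c("a", "b"), prob = 1.4))),
    "invalid probability")
  expect_error(synthetic_config(covariates = list(
    edu = list(kind = "ordinal", levels = c("a", "b", "c"),
               slope = 1, cutpoints = c(1, 0)))),
    "increasing")
  # heard share cannot be below the knowledge prevalence
  cfg <- synthetic_config(clusters_per_stratum = 5, households_per_cluster = 10,
                          heard_rate = 0.05)
  expect_error(generate_survey(cfg, seed = 1), "heard_rate")
})

test_that("the most SES-entangled covariate dominates the decomposition", {
  cfg <- synthetic_config(
    covariates = list(
      sex = list(kind = "binary", levels = c("women", "men"), prob = 0.5),
      radio = list(kind = "binary", levels = c("no", "yes"),
                   intercept = -0.2, slope = 0.25),
      tv = list(kind = "binary", levels = c("no", "yes"),
                intercept = -0.5, slope = 1.8)),
    outcome = list(intercept = -1.6, z = 0,
                   coefficients = c("sex:men" = 0.2, "radio:yes" = 0.2,
                                    "tv:yes" = 1.2)))
  wins <- 0L
  for (seed in 1:10) {
    cfg$clusters_per_stratum <- 40          # n = 4,000
    sim <- generate_survey(cfg, seed = seed)
    d <- sim$table
    d$know <- build_knowledge_indicator(d[paste0("q", 1:5)], d$heard)
    d$wealth_score <- compute_wealth_scores(d[grep("^asset", names(d))],
                                            d$weight)$scores
    fit <- cidecomp(know ~ sex + radio + tv, data = d,
                    weights = weight, rank_by = wealth_score)
    gp <- fit$decomposition$group_percent
    if (names(which.max(gp)) == "tv") wins <- wins + 1L
  }
  expect_identical(wins, 10L)
})

test_that("ground truth targets are internally consistent", {
  cfg <- synthetic_config()
  gt <- ground_truth(cfg, n = 50000, seed = 4)
  expect_true(abs(gt$target_E) <= 1)
  expect_true(gt$prevalence > 0 && gt$prevalence < 1)
  expect_true(all(c("sex:men", "latent_ses") %in% names(gt$ame)))
  # positive coefficients must yield positive AMEs
  expect_gt(gt$ame[["education:higher"]], 0)
})
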