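# Shared fixtures, all generated in code.

# random small survey-like table for property tests: ties in scores,
# unequal weights, binary outcome with at least one positive
random_small_table <- function(n, seed) {
  set.seed(seed)
  scores <- sample(seq_len(max(2, n %/% 2)), n, replace = TRUE) / 2
  w <- stats::runif(n, 0.2, 3)
  h <- stats::rbinom(n, 1, 0.4)
  if (sum(h) == 0) h[sample.int(n, 1)] <- 1
  list(h = h, scores = scores, w = w)
}

# standard concentration index via trapezoid integration of the
# concentration curve: C = 1 - 2 * area under L(p)
area_based_C <- function(h, scores, w) {
  cc <- concentration_curve(h, scores, w)
  p <- cc$p
  L <- cc$L
  auc <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  1 - 2 * auc
}

# tiny generated survey used by several files
small_sim <- function(seed = 42, clusters = 8, hh = 15) {
  sim <- generate_survey(synthetic_config(clusters_per_stratum = clusters,
                                          households_per_cluster = hh),
                         seed = seed)
  d <- sim$table
  d$know <- build_knowledge_indicator(d[paste0("q", 1:5)], d$heard)
  acols <- grep("^asset", names(d), value = TRUE)
  d$wealth_score <- compute_wealth_scores(d[acols], d$weight)$scores
  list(data = d, truth = sim$truth)
}

# write a 4-respondent fixture CSV + YAML config; know = (0,0,0,1)
# poorest-to-richest, equal weights, so E = 0.75
write_tiny_fixture <- function(dir) {
  csv <- file.path(dir, "tiny.csv")
  yml <- file.path(dir, "tiny.yaml")
  d <- data.frame(
    q1 = c("no", "yes", "no", "yes"), q2 = c("yes", "no", "yes", "yes"),
    q3 = c("yes", "yes", "dont_know", "yes"),
    q4 = c("no", "no", "no", "no"), q5 = c("no", "no", "yes", "no"),
    heard = c("yes", "yes", "yes", "yes"),
    wt = 1, psu = c("c1", "c1", "c2", "c2"), str = "all",
    wealth = c(1, 2, 3, 4))
  utils::write.csv(d, csv, row.names = FALSE)
  yaml::write_yaml(list(columns = list(
    item1 = "q1", item2 = "q2", item3 = "q3", item4 = "q4", item5 = "q5",
    heard = "heard", weight = "wt", cluster = "psu", stratum = "str",
    wealth_score = "wealth")), yml)
  list(csv = csv, yaml = yml)
}

# run the CLI silencing its stderr log lines
quiet_cli <- function(args) suppressWarnings(suppressMessages(run_cli(args)))
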