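test_that("composite knowledge indicator requires all five correct answers", {
  items <- data.frame(q1 = c("yes", "yes", "yes", "no", "yes"),
                      q2 = c("yes", "yes", "yes", "yes", "yes"),
                      q3 = c("yes", "yes", "dont_know", "yes", "yes"),
                      q4 = c("no", "yes", "no", "no", "no"),
                      q5 = c("no", "no", "no", "no", "no"))
  heard <- c("yes", "yes", "yes", "yes", "no")
  # row 1: fully correct; row 2: misconception not rejected; row 3:
  # dont_know counts as incorrect; row 4: item 1 wrong; row 5: correct
  # pattern but never heard of AIDS
  expect_identical(build_knowledge_indicator(items, heard), c(1L, 0L, 0L, 0L, 0L))
})

test_that("labels are normalized and malformed responses are rejected by name", {
  items <- data.frame(q1 = " YES ", q2 = "Yes", q3 = "yes",
                      q4 = "No", q5 = "Don't know")
  expect_identical(build_knowledge_indicator(items, "YES"), 0L)
  items$q5 <- "no"
  expect_identical(build_knowledge_indicator(items, " yes"), 1L)
  items$q3 <- "maybe"
  expect_error(build_knowledge_indicator(items, "yes"),
               "item column 3, record 1")
  items$q3 <- "yes"
  expect_error(build_knowledge_indicator(items, "dunno"), "'heard'")
  expect_error(build_knowledge_indicator(items[, 1:4], "yes"), "five columns")
})

test_that("complete-case filter drops rows with missing required fields", {
  d <- data.frame(a = 1:3, w = c(1, NA, 2), s = c("x", "y", ""))
  out <- complete_case_filter(d, c("a"))
  expect_identical(out$a, 1:3)
  expect_identical(attr(out, "dropped"), 0L)

  out <- complete_case_filter(d, c("a", "w"))
  expect_identical(out$a, c(1L, 3L))
  expect_identical(attr(out, "dropped"), 1L)

  # empty strings count as missing in character columns
  out <- complete_case_filter(d, c("w", "s"))
  expect_identical(out$a, 1L)
  expect_identical(attr(out, "dropped"), 2L)

  d$all_na <- NA_real_
  expect_error(complete_case_filter(d, "all_na"), "every row")
  expect_error(complete_case_filter(d, "nope"), "not present")
})

test_that("complete-case filter reproduces survey-scale row accounting", {
  # same shape as a national round: 19,541 interviewed, 723 incomplete
  n <- 19541
  d <- data.frame(h = rep.int(1L, n), edu = rep.int("primary", n))
  d$edu[seq_len(723)] <- NA
  out <- complete_case_filter(d, "edu")
  expect_identical(nrow(out), 18818L)
  expect_identical(attr(out, "dropped"), 723L)
})

test_that("design encoding dummy-codes against the reference level", {
  d <- data.frame(tv = c("no", "yes", "no"),
                  edu = c("none", "secondary", "higher"),
                  age = c(20, 30, 40))
  X <- encode_design(d, list(
    covariate_spec("tv", "binary", c("no", "yes")),
    covariate_spec("edu", "categorical",
                   c("none", "primary", "secondary", "higher")),
    covariate_spec("age", "continuous")))
  expect_identical(colnames(X),
                   c("tv:yes", "edu:primary", "edu:secondary", "edu:higher", "age"))
  expect_equal(X[, "tv:yes"], c(0, 1, 0))
  expect_equal(X[, "edu:secondary"], c(0, 1, 0))
  expect_equal(X[, "edu:higher"], c(0, 0, 1))
  expect_equal(X[, "age"], d$age)
  smap <- attr(X, "spec_map")
  expect_identical(smap$covariate, c("tv", "edu", "edu", "edu", "age"))

  expect_identical(ncol(encode_design(d, list())), 0L)
  d$tv[2] <- "sometimes"
  expect_error(encode_design(d, list(covariate_spec("tv", "binary", c("no", "yes")))),
               "unknown category label 'sometimes'")
})

test_that("covariate_spec validates its inputs", {
  expect_error(covariate_spec("x", "binary", c("a", "b", "c")), "exactly two")
  expect_error(covariate_spec("x", "categorical", c("a", "a", "b")), "duplicate")
  expect_error(covariate_spec("x", "categorical", c("a", "b"), reference = "z"),
               "reference")
  expect_identical(covariate_spec("x", "categorical", c("a", "b"))$reference, "a")
})

test_that("prevalence factorizes over ever-heard when never-heard are coded zero", {
  d <- small_sim(seed = 3)$data
  w <- d$weight
  heard <- d$heard == "yes"
  lhs <- wtd_mean(d$know, w)
  rhs <- wtd_mean(d$know[heard], w[heard]) * wtd_mean(heard, w)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_true(all(d$know[!heard] == 0))
})

test_that("filtering and encoding commute on complete columns", {
  d <- small_sim(seed = 4)$data
  d$aux <- 1
  d$aux[seq(1, nrow(d), by = 7)] <- NA
  specs <- list(covariate_spec("tv", "binary", c("no", "yes")),
                covariate_spec("education", "categorical",
                               c("none", "primary", "secondary", "higher")))
  X_then_filter <- encode_design(d, specs)[!is.na(d$aux), , drop = FALSE]
  filter_then_X <- encode_design(complete_case_filter(d, "aux"), specs)
  expect_equal(unclass(X_then_filter), unclass(filter_then_X),
               ignore_attr = TRUE)
})

test_that("read_survey binds columns via config and reports filtering meta", {
  dir <- withr::local_tempdir()
  fx <- write_tiny_fixture(dir)
  tab <- read_survey(fx$csv, fx$yaml)
  expect_identical(tab$know, c(0L, 0L, 0L, 1L))
  expect_identical(attr(tab, "meta")$rows_in, 4L)
  expect_identical(attr(tab, "meta")$dropped, 0L)
  expect_match(attr(tab, "meta")$never_heard_coding, "coded 0")

  sidecar <- write_clean_survey(tab, file.path(dir, "clean.csv"))
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_identical(meta$rows_kept, 4L)
})
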