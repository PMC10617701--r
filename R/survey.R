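#' Build the comprehensive-knowledge indicator
#'
#' The composite binary indicator of comprehensive HIV/AIDS knowledge is
#' built from five ternary items asked of respondents who have ever
#' heard of AIDS: affirming that consistent condom use and having one
#' uninfected partner prevent HIV and that a healthy-looking person can
#' have HIV (items 1-3, correct answer "yes"), and rejecting the
#' misconceptions that HIV is transmitted by mosquito bites or by
#' sharing food (items 4-5, correct answer "no").  "Don't know" counts
#' as an incorrect answer.  Respondents who have never heard of AIDS
#' cannot hold comprehensive knowledge and are coded 0, so the indicator
#' is defined for every respondent.
#'
#' @param items data frame or matrix with five columns, values among
#'   \code{"yes"}, \code{"no"}, \code{"dont_know"} (case-insensitive,
#'   surrounding whitespace ignored).
#' @param heard vector with values \code{"yes"}/\code{"no"} (same
#'   normalization), or logical.
#' @return Integer vector of 0/1, one per row of \code{items}.
#' @examples
#' build_knowledge_indicator(
#'   data.frame(q1 = "yes", q2 = "yes", q3 = "yes", q4 = "no", q5 = "no"),
#'   heard = "yes")   # 1
#' @export
build_knowledge_indicator <- function(items, heard) {
  items <- as.data.frame(items)
  if (ncol(items) != 5L)
    stop("'items' must have exactly five columns, got ", ncol(items))
  n <- nrow(items)
  if (length(heard) != n) stop("'heard' must have one value per row of 'items'")

  itm <- lapply(seq_len(5L), function(j) {
    v <- normalize_label(items[[j]])
    bad <- !v %in% c("yes", "no", "dont_know")
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("malformed response %s in item column %d, record %d (expected yes/no/dont_know)",
                   dQuote(as.character(items[[j]][i])), j, i))
    }
    v
  })
  if (is.logical(heard)) {
    if (anyNA(heard)) stop("missing value in 'heard'")
    hrd <- heard
  } else {
    v <- normalize_label(heard)
    bad <- !v %in% c("yes", "no")
    if (any(bad))
      stop(sprintf("malformed response %s in 'heard', record %d (expected yes/no)",
                   dQuote(as.character(heard[which(bad)[1]])), which(bad)[1]))
    hrd <- v == "yes"
  }
  correct <- itm[[1]] == "yes" & itm[[2]] == "yes" & itm[[3]] == "yes" &
    itm[[4]] == "no" & itm[[5]] == "no"
  as.integer(correct & hrd)
}

# trim + lower-case; harmonize common don't-know spellings
normalize_label <- function(x) {
  v <- tolower(trimws(as.character(x)))
  v[v %in% c("don't know", "dont know", "dk", "don't_know")] <- "dont_know"
  v
}

#' Complete-case filter
#'
#' Drops every row with a missing value in any of the required columns
#' (listwise deletion), the standard treatment when missingness is
#' assumed completely at random.  Row order is preserved.
#'
#' @param data data frame.
#' @param required character vector of column names that must be
#'   non-missing.  Empty strings are treated as missing in character
#'   columns.
#' @return The filtered data frame, with attribute \code{"dropped"}
#'   giving the number of removed rows.  Dropping every row is an error.
#' @examples
#' d <- data.frame(x = c(1, NA, 3), w = c(1, 1, 1))
#' nrow(complete_case_filter(d, "x"))                 # 2
#' attr(complete_case_filter(d, "x"), "dropped")      # 1
#' @export
complete_case_filter <- function(data, required) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("required column(s) not present: ", paste(missing_cols, collapse = ", "))
  if (length(required) == 0L) {
    attr(data, "dropped") <- 0L
    return(data)
  }
  miss <- Reduce(`|`, lapply(required, function(cn) {
    v <- data[[cn]]
    is.na(v) | (is.character(v) & trimws(as.character(v)) == "")
  }))
  out <- data[!miss, , drop = FALSE]
  if (nrow(out) == 0L) stop("complete-case filter removed every row")
  attr(out, "dropped") <- sum(miss)
  out
}

#' Covariate specification
#'
#' Describes how one covariate enters the design matrix: binary and
#' categorical covariates are dummy-coded with one indicator column per
#' non-reference level (in the declared level order); continuous
#' covariates pass through unchanged.
#'
#' @param name column name in the survey table.
#' @param kind one of \code{"binary"}, \code{"categorical"},
#'   \code{"continuous"}.
#' @param levels ordered unique category labels (ignored for
#'   continuous).
#' @param reference reference level; defaults to the first level.
#' @return A list of class \code{"covariate_spec"}.
#' @examples
#' covariate_spec("education", "categorical",
#'                levels = c("none", "primary", "secondary", "higher"))
#' @export
covariate_spec <- function(name, kind = c("binary", "categorical", "continuous"),
                           levels = NULL, reference = NULL) {
  kind <- match.arg(kind)
  if (kind != "continuous") {
    if (is.null(levels) || length(levels) < 2L)
      stop("covariate '", name, "': at least two levels required")
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("covariate '", name, "': duplicate levels")
    if (kind == "binary" && length(levels) != 2L)
      stop("covariate '", name, "': binary covariates need exactly two levels")
    if (is.null(reference)) reference <- levels[1]
    if (!reference %in% levels)
      stop("covariate '", name, "': reference level '", reference,
           "' is not among the declared levels")
  } else {
    levels <- NULL
    reference <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference),
            class = "covariate_spec")
}

#' Encode a dummy-coded design matrix
#'
#' Builds the covariate design matrix used by the decomposition: one 0/1
#' indicator column per non-reference level of each binary/categorical
#' covariate (named \code{<name>:<level>}) and one pass-through column
#' per continuous covariate, in specification order.  No intercept
#' column is included (the model fit adds its own).
#'
#' @param data data frame holding the covariate columns.
#' @param specs list of \code{\link{covariate_spec}} objects.
#' @return Numeric matrix with \code{nrow(data)} rows; the attribute
#'   \code{"spec_map"} maps each column to its covariate name and level.
#' @examples
#' d <- data.frame(tv = c("no", "yes", "no"))
#' encode_design(d, list(covariate_spec("tv", "binary", c("no", "yes"))))
#' @export
encode_design <- function(data, specs) {
  stopifnot(is.data.frame(data))
  if (inherits(specs, "covariate_spec")) specs <- list(specs)
  cols <- list()
  map_name <- character(0)
  map_level <- character(0)
  for (sp in specs) {
    if (!inherits(sp, "covariate_spec")) stop("'specs' must contain covariate_spec objects")
    if (!sp$name %in% names(data)) stop("no column '", sp$name, "' in data")
    v <- data[[sp$name]]
    if (sp$kind == "continuous") {
      x <- as.numeric(v)
      if (anyNA(x)) stop("covariate '", sp$name, "': missing or non-numeric values")
      cols[[sp$name]] <- x
      map_name <- c(map_name, sp$name)
      map_level <- c(map_level, NA_character_)
    } else {
      lab <- normalize_label(v)
      lev <- normalize_label(sp$levels)
      unseen <- setdiff(unique(lab), lev)
      if (length(unseen))
        stop("covariate '", sp$name, "': unknown category label '",
             unseen[1], "'")
      for (j in seq_along(sp$levels)) {
        if (normalize_label(sp$reference) == lev[j]) next
        cols[[paste0(sp$name, ":", sp$levels[j])]] <- as.numeric(lab == lev[j])
        map_name <- c(map_name, sp$name)
        map_level <- c(map_level, sp$levels[j])
      }
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  rownames(X) <- NULL
  attr(X, "spec_map") <- data.frame(column = colnames(X) %||% character(0),
                                    covariate = map_name, level = map_level,
                                    stringsAsFactors = FALSE)
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a survey table and its column-mapping configuration
#'
#' Loads a respondent-level CSV and a YAML configuration that binds file
#' columns to semantic roles, so arbitrary survey exports can be
#' analysed without code changes.  The configuration has two sections:
#' \code{columns:} mapping roles (\code{item1}..\code{item5},
#' \code{heard}, \code{weight}, \code{cluster}, \code{stratum}, and
#' optionally \code{wealth_score} or \code{assets} as a list of column
#' names) to CSV column names, and \code{covariates:}, a list of entries
#' with \code{name}, \code{kind}, \code{levels}, \code{reference}.
#'
#' The returned table carries a derived 0/1 \code{know} column (from
#' \code{\link{build_knowledge_indicator}}) and has been complete-case
#' filtered on all mapped columns; the attribute \code{"meta"} records
#' row counts before/after filtering and the never-heard coding
#' convention.
#'
#' @param csv_path path to the respondent CSV (header row mandatory).
#' @param config path to a YAML file, or an already-parsed list.
#' @return A data frame with standardized columns \code{know},
#'   \code{weight}, \code{cluster}, \code{stratum}, optional
#'   \code{wealth_score}/asset columns, and the covariate columns;
#'   attributes \code{"meta"} (list) and \code{"specs"} (list of
#'   \code{\link{covariate_spec}}).
#' @export
read_survey <- function(csv_path, config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$columns)) stop("config: missing 'columns' section")
  cm <- cfg$columns
  need <- c("item1", "item2", "item3", "item4", "item5", "heard",
            "weight", "cluster", "stratum")
  absent <- setdiff(need, names(cm))
  if (length(absent))
    stop("config: 'columns' must map roles: ", paste(absent, collapse = ", "))
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE)

  specs <- lapply(cfg$covariates %||% list(), function(cv)
    covariate_spec(cv$name, cv$kind, levels = unlist(cv$levels),
                   reference = cv$reference))
  asset_cols <- unlist(cm$assets)
  used <- c(unlist(cm[need]), cm$wealth_score, asset_cols,
            vapply(specs, `[[`, "", "name"))
  missing_cols <- setdiff(used, names(raw))
  if (length(missing_cols))
    stop("CSV is missing mapped column(s): ", paste(missing_cols, collapse = ", "))

  n_before <- nrow(raw)
  raw <- complete_case_filter(raw, used)
  dropped <- attr(raw, "dropped")

  out <- data.frame(
    know = build_knowledge_indicator(raw[unlist(cm[paste0("item", 1:5)])],
                                     raw[[cm$heard]]),
    weight = as.numeric(raw[[cm$weight]]),
    cluster = raw[[cm$cluster]],
    stratum = raw[[cm$stratum]],
    stringsAsFactors = FALSE)
  if (any(out$weight <= 0)) stop("all sampling weights must be positive")
  if (length(unique(out$cluster)) < 2) stop("at least 2 distinct clusters required")
  if (!is.null(cm$wealth_score)) out$wealth_score <- as.numeric(raw[[cm$wealth_score]])
  for (ac in asset_cols) out[[ac]] <- as.numeric(raw[[ac]])
  for (sp in specs) out[[sp$name]] <- raw[[sp$name]]

  attr(out, "meta") <- list(rows_in = n_before, rows_kept = nrow(out),
                            dropped = dropped,
                            never_heard_coding = "coded 0 (not excluded)",
                            asset_columns = asset_cols)
  attr(out, "specs") <- specs
  out
}

#' Write a cleaned survey table with a JSON sidecar
#'
#' Writes the table as CSV and a \code{<path>.meta.json} sidecar holding
#' the row counts before/after complete-case filtering and the
#' never-heard coding convention.
#'
#' @param data a table from \code{\link{read_survey}} (or any data frame
#'   with a \code{"meta"} attribute).
#' @param path output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_clean_survey <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  meta <- attr(data, "meta") %||% list(rows_in = nrow(data),
                                       rows_kept = nrow(data), dropped = 0L)
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
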