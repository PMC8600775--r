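#' Canonical QLQ-C30 covariate columns
#'
#' The fifteen QLQ-C30 scale/item scores used as mapping covariates: global
#' health status, the five functional scales, and the nine symptom scales
#' and single items (financial difficulties included). All are on 0-100;
#' higher functional/global scores mean better quality of life, higher
#' symptom scores mean worse symptoms.
#'
#' @return Character vector of 15 column names.
#' @export
qlq_scales <- function() {
  c("global_health", "physical_f", "role_f", "emotional_f", "cognitive_f",
    "social_f", "fatigue", "nausea_vomiting", "pain", "dyspnoea",
    "insomnia", "appetite_loss", "constipation", "diarrhoea", "financial")
}

required_columns <- function(has_responses = FALSE) {
  base <- c("patient_id", "age", qlq_scales())
  if (has_responses) c(base, eq5d_dimensions()) else c(base, "eq5d")
}

#' Read a QLQ-C30 / EQ-5D mapping dataset from delimited text
#'
#' Expects one row per patient-visit with a header. Mandatory columns are
#' `patient_id`, `age`, the fifteen [qlq_scales()], and either an `eq5d`
#' utility column or the five EQ-5D dimension responses (`covariates_only =
#' TRUE` waives the outcome). Column names in the file can differ from the
#' canonical ones via `column_map`.
#'
#' @param path Path to a delimited text file (comma or tab separated).
#' @param column_map Optional named character vector mapping canonical name
#'   -> file column name, or path to a plain-text `key: value` file with
#'   one mapping per line.
#' @param has_responses If `TRUE` the outcome is the five dimension-response
#'   columns (levels 1-3) rather than a utility column.
#' @param covariates_only If `TRUE` no outcome column is required.
#' @param missing_codes Strings treated as missing in addition to empty
#'   fields (default `c("NA", ".")`).
#' @return A tibble with canonical column names; score columns checked to be
#'   within \[0, 100\] (missing values are kept as `NA`), plus a
#'   `visit_index` column (order of appearance within patient) if absent.
#' @export
read_mapping_data <- function(path, column_map = NULL, has_responses = FALSE,
                              covariates_only = FALSE,
                              missing_codes = c("NA", ".")) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map) && is.null(names(column_map))) {
    column_map <- read_column_map(column_map)
  }
  dat <- readr::read_delim(path, delim = guess_delim(path),
                           na = c("", missing_codes),
                           show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(dat)) {
        stop("column_map refers to missing column '", src, "'", call. = FALSE)
      }
      names(dat)[names(dat) == src] <- canon
    }
  }
  need <- if (covariates_only) {
    c("patient_id", "age", qlq_scales())
  } else {
    required_columns(has_responses)
  }
  absent <- setdiff(need, names(dat))
  if (length(absent) > 0L) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(need, "patient_id")
  for (cl in num_cols) {
    v <- dat[[cl]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(v2))) {
        stop("non-numeric value in column '", cl, "'", call. = FALSE)
      }
      dat[[cl]] <- v2
    }
  }
  for (cl in qlq_scales()) {
    bad <- !is.na(dat[[cl]]) & (dat[[cl]] < 0 | dat[[cl]] > 100)
    if (any(bad)) {
      stop("score out of [0, 100] in column '", cl, "' (row ",
           which(bad)[1], ")", call. = FALSE)
    }
  }
  if (any(!is.na(dat$age) & dat$age <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  if (!covariates_only && !has_responses) {
    u <- dat$eq5d
    bad <- !is.na(u) & !is_feasible_utility(u)
    if (any(bad)) {
      stop("eq5d utility outside the feasible zone (row ", which(bad)[1], ")",
           call. = FALSE)
    }
  }
  if (!covariates_only && has_responses) {
    for (cl in eq5d_dimensions()) {
      bad <- !is.na(dat[[cl]]) & !dat[[cl]] %in% 1:3
      if (any(bad)) {
        stop("response level outside {1,2,3} in column '", cl, "'",
             call. = FALSE)
      }
    }
  }
  if (!"visit_index" %in% names(dat)) {
    dat <- dat |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(visit_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  tibble::as_tibble(dat)
}

guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_column_map <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed column map line: ", lines[bad][1],
                     call. = FALSE)
  stats::setNames(trimws(vapply(kv, `[[`, "", 2L)),
                  trimws(vapply(kv, `[[`, "", 1L)))
}

#' Write a mapping dataset back to delimited text
#'
#' @param data A tibble as returned by [read_mapping_data()].
#' @param path Output file path; delimiter chosen from the extension
#'   (`.tsv` -> tab, otherwise comma).
#' @return `path`, invisibly.
#' @export
write_mapping_data <- function(data, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(data, path, delim = delim, na = "")
  invisible(path)
}

#' Drop rows with missing outcome or covariates
#'
#' Removes every row with a missing EQ-5D outcome (utility or any of the
#' five dimension responses, whichever the dataset carries) or any missing
#' QLQ-C30 covariate or age. Retained rows are untouched.
#'
#' @param data A mapping tibble.
#' @return A list with `data` (the complete-case tibble) and `report`, a
#'   one-row tibble with `n_total`, `n_dropped`, `n_kept` and `pct_dropped`.
#' @export
filter_complete_cases <- function(data) {
  outcome_cols <- intersect(c("eq5d", eq5d_dimensions()), names(data))
  check_cols <- c("age", qlq_scales(), outcome_cols)
  check_cols <- intersect(check_cols, names(data))
  keep <- stats::complete.cases(data[, check_cols])
  kept <- data[keep, , drop = FALSE]
  n_total <- nrow(data)
  n_dropped <- n_total - nrow(kept)
  if (nrow(kept) == 0L) {
    warning("no complete cases remain after filtering", call. = FALSE)
  }
  list(
    data = kept,
    report = tibble::tibble(
      n_total = n_total, n_dropped = n_dropped, n_kept = nrow(kept),
      pct_dropped = if (n_total > 0) 100 * n_dropped / n_total else 0
    )
  )
}

#' Build model design matrices from a mapping dataset
#'
#' All QLQ-C30 scores enter rescaled by 100 so coefficients are per full
#' scale range. Three blocks are produced:
#' \describe{
#'   \item{X}{component covariates: intercept, global health, the five
#'     functional scales, the nine symptom scales/items (all /100), and age
#'     in raw years. Used inside ALDVMM mixture components.}
#'   \item{Z}{membership covariates: intercept, global health/100 and its
#'     square. Drives mixture component probabilities.}
#'   \item{X2}{comparator design: X plus age squared, used by the linear
#'     random-effects model and the ordered-probit response mapping.}
#' }
#'
#' @param data A complete-case mapping tibble.
#' @return A list with matrices `X`, `Z`, `X2`, plus `cluster` (patient ids)
#'   and outcome vectors `y` (utilities) and/or `responses` (matrix of the
#'   five dimension levels) when present.
#' @export
build_design <- function(data) {
  scales <- qlq_scales()
  if (!all(scales %in% names(data))) {
    stop("dataset lacks QLQ-C30 covariate columns", call. = FALSE)
  }
  S <- as.matrix(data[, scales]) / 100
  X <- cbind(intercept = 1, S, age = data$age)
  gh <- S[, "global_health"]
  Z <- cbind(intercept = 1, global_health = gh, global_health_sq = gh^2)
  X2 <- cbind(X, age_sq = data$age^2)
  for (M in list(X, Z, X2)) {
    sds <- apply(M[, -1, drop = FALSE], 2, stats::sd)
    if (nrow(M) > 1 && any(sds == 0)) {
      warning("constant covariate column(s): ",
              paste(colnames(M[, -1, drop = FALSE])[sds == 0],
                    collapse = ", "), call. = FALSE)
    }
    break # warn once, on X
  }
  out <- list(X = X, Z = Z, X2 = X2, cluster = data$patient_id)
  if ("eq5d" %in% names(data)) out$y <- data$eq5d
  if (all(eq5d_dimensions() %in% names(data))) {
    out$responses <- as.matrix(data[, eq5d_dimensions()])
  }
  out
}
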