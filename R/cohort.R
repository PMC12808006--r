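#' Construct and validate a person-level cohort
#'
#' The analysis input: one row per person, binary flags for the 33 chronic
#' conditions, non-negative counts for the 7 utilization variables, and
#' categorical sociodemographics used only for profiling. When
#' `enforce_multimorbidity` is `TRUE` (the default, matching the study
#' population definition) every person must carry at least two conditions.
#'
#' @param person_id Vector of unique person identifiers.
#' @param conditions n x 33 numeric matrix of 0/1 flags; columns must be
#'   named after `catalog$name` (any order; they are reordered internally).
#' @param utilization n x 7 non-negative numeric matrix named after
#'   `util_schema` (any order).
#' @param sociodemo Data frame with the columns of [sociodemo_fields()]
#'   (missing values are mapped to category `"unknown"`); an optional
#'   numeric `age` column is carried through for the mean-age profile row.
#' @param catalog Condition catalog, see [condition_catalog()].
#' @param util_schema Utilization schema, see [utilization_schema()].
#' @param enforce_multimorbidity Require >= 2 conditions per person.
#' @return An object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(person_id, conditions, utilization, sociodemo,
                          catalog = condition_catalog(),
                          util_schema = utilization_schema(),
                          enforce_multimorbidity = TRUE) {
  n <- length(person_id)
  conditions <- as.matrix(conditions)
  utilization <- as.matrix(utilization)
  if (anyDuplicated(person_id)) {
    stop("person_id values must be unique; duplicated: ",
         paste(utils::head(person_id[duplicated(person_id)], 5L), collapse = ", "))
  }
  if (nrow(conditions) != n || nrow(utilization) != n || nrow(sociodemo) != n) {
    stop("person_id, conditions, utilization and sociodemo must have the same number of rows")
  }

  conditions <- reorder_block(conditions, catalog$name, "condition")
  utilization <- reorder_block(utilization, util_schema, "utilization")

  bad <- which(!(conditions %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad)) {
    rows <- sort(unique(((bad - 1L) %% n) + 1L))
    stop("non-binary condition value at row(s): ",
         paste(utils::head(rows, 10L), collapse = ", "))
  }
  if (anyNA(utilization) || any(utilization < 0)) {
    rows <- sort(unique(which(is.na(utilization) | utilization < 0, arr.ind = TRUE)[, 1L]))
    stop("negative or missing utilization value at row(s): ",
         paste(utils::head(rows, 10L), collapse = ", "))
  }

  sd_cols <- sociodemo_fields()
  missing_sd <- setdiff(sd_cols, names(sociodemo))
  if (length(missing_sd)) {
    stop("missing sociodemographic column(s): ", paste(missing_sd, collapse = ", "))
  }
  keep <- c(sd_cols, intersect("age", names(sociodemo)))
  sociodemo <- sociodemo[, keep, drop = FALSE]
  for (f in sd_cols) {
    v <- as.character(sociodemo[[f]])
    v[is.na(v) | v == ""] <- "unknown"
    sociodemo[[f]] <- v
  }

  if (isTRUE(enforce_multimorbidity)) {
    csum <- rowSums(conditions)
    if (any(csum < 2)) {
      offenders <- person_id[csum < 2]
      stop("multimorbidity violated (fewer than 2 conditions) for person_id(s): ",
           paste(utils::head(offenders, 10L), collapse = ", "))
    }
  }

  structure(
    list(person_id = person_id, conditions = conditions,
         utilization = utilization, sociodemo = sociodemo,
         catalog = catalog, util_schema = util_schema,
         enforce_multimorbidity = isTRUE(enforce_multimorbidity)),
    class = "cohort_matrix"
  )
}

reorder_block <- function(m, wanted, what) {
  if (is.null(colnames(m))) {
    if (ncol(m) != length(wanted)) {
      stop(sprintf("expected %d %s columns, got %d", length(wanted), what, ncol(m)))
    }
    colnames(m) <- wanted
    return(m)
  }
  missing <- setdiff(wanted, colnames(m))
  extra <- setdiff(colnames(m), wanted)
  if (length(missing)) {
    stop(sprintf("missing %s column(s): %s", what, paste(missing, collapse = ", ")))
  }
  if (length(extra)) {
    stop(sprintf("unexpected %s column(s): %s", what, paste(extra, collapse = ", ")))
  }
  m[, wanted, drop = FALSE]
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d persons, %d conditions, %d utilization variables\n",
              length(x$person_id), ncol(x$conditions), ncol(x$utilization)))
  cat(sprintf("  multimorbidity enforced: %s; mean conditions per person: %.2f\n",
              x$enforce_multimorbidity, mean(rowSums(x$conditions))))
  invisible(x)
}

#' Number of persons in a cohort
#' @param cohort A `cohort_matrix`.
#' @return Integer cohort size.
#' @export
cohort_size <- function(cohort) length(cohort$person_id)

#' Read a cohort from a delimited text file
#'
#' Expects a UTF-8 CSV with a header row and one row per person: `person_id`,
#' the 33 condition columns, the 7 utilization columns and the 7
#' sociodemographic columns (plus an optional numeric `age`). Condition and
#' utilization columns may appear in any order as long as the names match;
#' they are reordered to the canonical catalog/schema order internally.
#'
#' @inheritParams cohort_matrix
#' @param path Path to a cohort CSV.
#' @return A validated `cohort_matrix`; row order is preserved.
#' @export
read_cohort <- function(path, catalog = condition_catalog(),
                        util_schema = utilization_schema(),
                        enforce_multimorbidity = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"person_id" %in% names(df)) stop("missing column: person_id")
  known <- c("person_id", catalog$name, util_schema, sociodemo_fields(), "age")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    stop("unexpected column(s) in cohort file: ", paste(unknown, collapse = ", "))
  }
  cond_cols <- intersect(names(df), catalog$name)
  util_cols <- intersect(names(df), util_schema)
  sd_present <- intersect(names(df), c(sociodemo_fields(), "age"))
  if (nrow(df) == 0L) {
    return(cohort_matrix(
      person_id = character(0),
      conditions = matrix(numeric(0), 0L, 33L, dimnames = list(NULL, catalog$name)),
      utilization = matrix(numeric(0), 0L, 7L, dimnames = list(NULL, util_schema)),
      sociodemo = as.data.frame(stats::setNames(
        rep(list(character(0)), length(sociodemo_fields())), sociodemo_fields())),
      catalog = catalog, util_schema = util_schema,
      enforce_multimorbidity = enforce_multimorbidity
    ))
  }
  cond <- as.matrix(df[, cond_cols, drop = FALSE])
  if (anyNA(cond)) {
    stop("missing condition value at row(s): ",
         paste(utils::head(which(rowSums(is.na(cond)) > 0), 10L), collapse = ", "))
  }
  cohort_matrix(
    person_id = df$person_id,
    conditions = cond,
    utilization = as.matrix(df[, util_cols, drop = FALSE]),
    sociodemo = df[, sd_present, drop = FALSE],
    catalog = catalog, util_schema = util_schema,
    enforce_multimorbidity = enforce_multimorbidity
  )
}

#' Write a cohort to a delimited text file
#'
#' Column order is documented and fixed: `person_id`, the 33 conditions in
#' catalog order, the 7 utilization variables in schema order, the
#' sociodemographic fields (and `age` when present). `read_cohort()` applied
#' to the output reproduces the cohort field-for-field.
#'
#' @param cohort A `cohort_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cbind(
    data.frame(person_id = cohort$person_id, stringsAsFactors = FALSE),
    as.data.frame(cohort$conditions),
    as.data.frame(cohort$utilization),
    cohort$sociodemo
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
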