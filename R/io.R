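#' Validate a long-format PK dataset
#'
#' The dataset dialect is one row per record with columns `id`, `group`,
#' `type` (`dose`, `plasma` or `urine`), `time` (hr), `value` (mg/kg for
#' dose rows, ng/mL for plasma rows, fraction of dose for urine rows) and
#' an optional `flag` column (`""`, `"truncated"` or `"excluded"`).
#' Validation enforces: exactly one dose row per subject, observation
#' times at or after the dose time, nonnegative plasma values, urine
#' fractions in `[0, 1]`, and no unknown record types. Errors name the
#' offending subject or row.
#'
#' @param data A data frame in the dialect above.
#'
#' @return The validated data as a tibble (with a `flag` column added when
#'   absent), invisibly usable in a pipe.
#' @export
validate_pk_dataset <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("id", "group", "type", "time", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"flag" %in% names(data)) data$flag <- ""
  data$flag[is.na(data$flag)] <- ""

  bad_type <- !data$type %in% c("dose", "plasma", "urine")
  if (any(bad_type)) {
    stop("unknown record type(s) in row(s) ",
         paste(utils::head(which(bad_type), 5), collapse = ", "),
         ": ", paste(unique(data$type[bad_type]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(data$time)) || any(!is.finite(data$value))) {
    bad <- which(!is.finite(data$time) | !is.finite(data$value))
    stop("non-finite time or value in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  dose_n <- table(data$id[data$type == "dose"])
  no_dose <- setdiff(unique(data$id), names(dose_n))
  if (length(no_dose) > 0) {
    stop("no dose row for subject(s): ",
         paste(no_dose, collapse = ", "), call. = FALSE)
  }
  multi <- names(dose_n)[dose_n > 1]
  if (length(multi) > 0) {
    stop("duplicate dose rows for subject(s): ",
         paste(multi, collapse = ", "), call. = FALSE)
  }

  neg_plasma <- data$type == "plasma" & data$value < 0
  if (any(neg_plasma)) {
    stop("negative plasma value(s) in row(s) ",
         paste(utils::head(which(neg_plasma), 5), collapse = ", "),
         call. = FALSE)
  }
  bad_urine <- data$type == "urine" & (data$value < 0 | data$value > 1)
  if (any(bad_urine)) {
    stop("urine fraction outside [0, 1] in row(s) ",
         paste(utils::head(which(bad_urine), 5), collapse = ", "),
         call. = FALSE)
  }
  nonpos_dose <- data$type == "dose" & data$value <= 0
  if (any(nonpos_dose)) {
    stop("nonpositive dose in row(s) ",
         paste(utils::head(which(nonpos_dose), 5), collapse = ", "),
         call. = FALSE)
  }

  dose_time <- data |>
    dplyr::filter(.data$type == "dose") |>
    dplyr::select(id = "id", dose_time = "time")
  chk <- data |>
    dplyr::left_join(dose_time, by = "id") |>
    dplyr::filter(.data$type != "dose", .data$time < .data$dose_time)
  if (nrow(chk) > 0) {
    stop("observation before dose time for subject(s): ",
         paste(unique(chk$id), collapse = ", "), call. = FALSE)
  }

  grp <- data |> dplyr::distinct(.data$id, .data$group)
  if (anyDuplicated(grp$id)) {
    stop("subject(s) assigned to multiple groups: ",
         paste(grp$id[duplicated(grp$id)], collapse = ", "), call. = FALSE)
  }
  data
}

# Canonical row order used by write_pk_dataset(), so write/read round-trips
# are bit-identical regardless of input ordering.
.canonical_order <- function(data) {
  data |>
    dplyr::mutate(.type_rank = match(.data$type, c("dose", "plasma", "urine"))) |>
    dplyr::arrange(.data$id, .data$.type_rank, .data$time) |>
    dplyr::select(-".type_rank")
}

#' Read / write the long-format PK dataset
#'
#' CSV serialization of the dataset dialect described in
#' [validate_pk_dataset()]. `write_pk_dataset()` writes rows in canonical
#' order (subject, then dose/plasma/urine, then time); `read_pk_dataset()`
#' parses with fixed column types and validates, so `write` followed by
#' `read` is the identity on canonical form.
#'
#' @param path File path.
#' @param data Dataset tibble.
#'
#' @return `read_pk_dataset()` returns the validated tibble;
#'   `write_pk_dataset()` returns `data` (canonicalized) invisibly.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # base read.csv: strtod parsing is correctly rounded, so the shortest
  # round-trippable doubles written by write_pk_dataset() re-read exactly
  data <- utils::read.csv(
    path, colClasses = c(id = "character", group = "character",
                         type = "character", time = "numeric",
                         value = "numeric", flag = "character"),
    na.strings = "NA"
  )
  data$flag[is.na(data$flag)] <- ""
  validate_pk_dataset(tibble::as_tibble(data))
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  data <- validate_pk_dataset(data) |> .canonical_order()
  attr(data, "true_params") <- NULL  # simulation oracle never serialized
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

# Split a validated dataset into per-subject records used by the NCA and
# population estimators. Subjects come back sorted by id so downstream
# results do not depend on input row order.
.split_subjects <- function(data, drop_excluded = TRUE) {
  data <- validate_pk_dataset(data)
  if (drop_excluded) data <- dplyr::filter(data, .data$flag != "excluded")
  ids <- sort(unique(data$id))
  lapply(ids, function(i) {
    d <- data[data$id == i, ]
    dose_row <- d[d$type == "dose", ]
    pl <- d[d$type == "plasma", ]
    pl <- pl[order(pl$time), ]
    ur <- d[d$type == "urine", ]
    list(
      id = i,
      group = d$group[[1]],
      dose_amount = dose_row$value[[1]],
      dose_time = dose_row$time[[1]],
      times = pl$time,
      conc = pl$value,
      urine_frac = if (nrow(ur) > 0) ur$value[[1]] else NA_real_,
      urine_time = if (nrow(ur) > 0) ur$time[[1]] else NA_real_
    )
  })
}
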