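#' @keywords internal
"_PACKAGE"

# Column contract for long-format stability tables. One dialect only:
# comma-separated, period decimal, UTF-8.
STABILITY_COLUMNS <- c("batch_id", "molecular_type", "container",
                       "temperature_C", "time_months", "potency")
CONTAINER_LEVELS <- c("vial", "syringe")

#' Construct a stability dataset
#'
#' A `stability_dataset` is a long-format table of potency measurements, one
#' row per (batch, molecular type, container, temperature, time) observation,
#' with dataset-level metadata: the ordered set of molecular-type labels, the
#' declared storage-temperature set, and an optional lower specification
#' limit. Potency is stored normalized to percent of label claim; because of
#' assay noise it may exceed 100.
#'
#' Replicate measurements at the same (batch, type, container, temperature,
#' time) key are allowed; they are flagged (see [replicate_keys()]), never
#' averaged, and the models treat them as independent observations.
#'
#' @param records data.frame with columns `batch_id`, `molecular_type`,
#'   `container`, `temperature_C`, `time_months`, `potency`.
#' @param type_labels ordered character vector of molecular-type labels;
#'   defaults to the sorted labels present in `records`.
#' @param temperature_set ordered numeric vector of declared storage
#'   temperatures (degrees Celsius); defaults to the sorted temperatures
#'   present.
#' @param spec_limit optional lower specification limit (normalized percent).
#' @return object of class `stability_dataset` (a data.frame subclass).
#' @export
stability_dataset <- function(records, type_labels = NULL,
                              temperature_set = NULL, spec_limit = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STABILITY_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[STABILITY_COLUMNS]
  records$batch_id <- as.character(records$batch_id)
  records$molecular_type <- as.character(records$molecular_type)
  records$container <- as.character(records$container)
  records$temperature_C <- as.numeric(records$temperature_C)
  records$time_months <- as.numeric(records$time_months)
  records$potency <- as.numeric(records$potency)
  rownames(records) <- NULL

  if (is.null(type_labels)) type_labels <- sort(unique(records$molecular_type))
  if (is.null(temperature_set)) {
    temperature_set <- sort(unique(records$temperature_C))
  }
  structure(records,
            type_labels = as.character(type_labels),
            temperature_set = as.numeric(temperature_set),
            spec_limit = spec_limit,
            class = c("stability_dataset", "data.frame")) |>
    validate_stability_dataset()
}

#' Validate a stability dataset
#'
#' Checks record-level invariants (finite non-negative times, finite positive
#' potency, declared containers and temperatures) and dataset-level
#' invariants (each batch in exactly one container; every batch assayed for
#' the same molecular-type set). Violations raise errors naming the
#' offending rows.
#'
#' @param ds a `stability_dataset`.
#' @return `ds`, invisibly unchanged, if valid.
#' @export
validate_stability_dataset <- function(ds) {
  rec <- as.data.frame(ds)
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop(what, " in row(s): ", paste(utils::head(idx, 5L), collapse = ", "),
           if (length(idx) > 5L) sprintf(" (and %d more)", length(idx) - 5L),
           call. = FALSE)
    }
  }
  if (nrow(rec) > 0L) {
    bad_row(!is.finite(rec$time_months) | rec$time_months < 0,
            "time_months must be finite and >= 0")
    bad_row(!is.finite(rec$potency) | rec$potency <= 0,
            "potency must be finite and > 0")
    bad_row(!(rec$container %in% CONTAINER_LEVELS),
            paste0("container must be one of {",
                   paste(CONTAINER_LEVELS, collapse = ", "), "}"))
    bad_row(!(rec$temperature_C %in% attr(ds, "temperature_set")),
            "temperature_C outside the declared temperature set")
    bad_row(!(rec$molecular_type %in% attr(ds, "type_labels")),
            "molecular_type outside the declared type labels")

    n_cont <- tapply(rec$container, rec$batch_id,
                     function(x) length(unique(x)))
    if (any(n_cont > 1L)) {
      stop("batch(es) mapped to more than one container: ",
           paste(names(n_cont)[n_cont > 1L], collapse = ", "), call. = FALSE)
    }
    type_sets <- tapply(rec$molecular_type, rec$batch_id,
                        function(x) paste(sort(unique(x)), collapse = "|"))
    if (length(unique(type_sets)) > 1L) {
      stop("molecular-type set differs across batches; every batch must ",
           "carry the same types", call. = FALSE)
    }
  }
  sl <- attr(ds, "spec_limit")
  if (!is.null(sl) && (!is.numeric(sl) || length(sl) != 1L || !is.finite(sl) ||
                       sl <= 0)) {
    stop("spec_limit must be a single positive number", call. = FALSE)
  }
  invisible(ds)
}

#' Replicate keys of a dataset
#'
#' Identifies (batch, type, container, temperature, time) keys carrying more
#' than one measurement. Replicates are legitimate (repeat assays) and are
#' modelled as independent observations.
#'
#' @param ds a `stability_dataset`.
#' @return data.frame of duplicated keys with their multiplicity (possibly
#'   zero rows).
#' @export
replicate_keys <- function(ds) {
  rec <- as.data.frame(ds)
  key <- interaction(rec$batch_id, rec$molecular_type, rec$container,
                     rec$temperature_C, rec$time_months, drop = TRUE)
  tab <- table(key)
  dup <- names(tab)[tab > 1L]
  out <- unique(rec[key %in% dup,
                    c("batch_id", "molecular_type", "container",
                      "temperature_C", "time_months")])
  out$n_replicates <- as.integer(tab[match(
    interaction(out$batch_id, out$molecular_type, out$container,
                out$temperature_C, out$time_months, drop = TRUE),
    names(tab))])
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.stability_dataset <- function(x, ...) {
  out <- x
  attr(out, "type_labels") <- NULL
  attr(out, "temperature_set") <- NULL
  attr(out, "spec_limit") <- NULL
  attr(out, "true_means") <- NULL
  attr(out, "true_parameters") <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.stability_dataset <- function(x, ...) {
  cat(sprintf(
    "<stability_dataset> %d records | %d batches | %d types | temps {%s} C\n",
    nrow(x), length(unique(x$batch_id)), length(attr(x, "type_labels")),
    paste(attr(x, "temperature_set"), collapse = ", ")))
  if (!is.null(attr(x, "spec_limit"))) {
    cat(sprintf("  lower specification limit: %.1f%%\n",
                attr(x, "spec_limit")))
  }
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a long-format stability table from CSV
#'
#' Expects the exact header
#' `batch_id,molecular_type,container,temperature_C,time_months,potency`.
#' Rows violating record invariants are rejected with row-numbered
#' diagnostics (row numbers count data rows, header excluded).
#'
#' @param path path to a CSV file.
#' @param spec_limit optional lower specification limit attached to the
#'   returned dataset.
#' @return a [stability_dataset()].
#' @export
read_stability_table <- function(path, spec_limit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), STABILITY_COLUMNS)) {
    stop("schema error: expected header '",
         paste(STABILITY_COLUMNS, collapse = ","), "' but found '",
         paste(header, collapse = ","), "'", call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  for (col in c("temperature_C", "time_months", "potency")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("parse error: non-numeric %s in row(s): %s", col,
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    raw[[col]] <- num
  }
  unknown <- which(!(raw$container %in% CONTAINER_LEVELS))
  if (length(unknown) > 0L) {
    stop(sprintf("value error: unknown container token in row(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")),
         call. = FALSE)
  }
  stability_dataset(raw, spec_limit = spec_limit)
}

#' Write a stability dataset to CSV
#'
#' Inverse of [read_stability_table()]: writing then reading reproduces the
#' dataset exactly (up to float formatting, which uses R's full `%.15g`
#' precision so numeric round-trips are lossless in practice).
#'
#' @param ds a `stability_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_table <- function(ds, path) {
  validate_stability_dataset(ds)
  rec <- as.data.frame(ds)
  for (col in c("temperature_C", "time_months", "potency")) {
    rec[[col]] <- sprintf("%.15g", rec[[col]])
  }
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset by time for time-split validation
#'
#' Training on early time points and testing predictions on later ones. The
#' training split keeps records at all temperatures with
#' `time <= cutoff_months`; the test split keeps records with
#' `time > cutoff_months`, optionally restricted to a single hold-out
#' temperature (the long-term storage condition, typically 5 degrees C).
#'
#' @param ds a `stability_dataset`.
#' @param cutoff_months non-negative cutoff in months.
#' @param holdout_temperature optional temperature (degrees C) restricting
#'   the test split.
#' @return list with elements `train` and `test`, both `stability_dataset`s
#'   sharing `ds`'s metadata.
#' @export
split_by_time <- function(ds, cutoff_months, holdout_temperature = NULL) {
  stopifnot(is.numeric(cutoff_months), length(cutoff_months) == 1L,
            cutoff_months >= 0)
  rec <- as.data.frame(ds)
  train_idx <- rec$time_months <= cutoff_months
  if (!any(train_idx)) {
    stop("empty-train error: cutoff ", cutoff_months,
         " months excludes all data", call. = FALSE)
  }
  test_idx <- !train_idx
  if (!is.null(holdout_temperature)) {
    test_idx <- test_idx & rec$temperature_C == holdout_temperature
  }
  subset_ds <- function(idx) {
    structure(rec[idx, , drop = FALSE] |> `rownames<-`(NULL),
              type_labels = attr(ds, "type_labels"),
              temperature_set = attr(ds, "temperature_set"),
              spec_limit = attr(ds, "spec_limit"),
              class = c("stability_dataset", "data.frame"))
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}
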