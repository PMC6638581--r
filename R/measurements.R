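#' Read a long-format measurement table
#'
#' Reads a comma-delimited, UTF-8 measurement file with one row per blinded
#' reading of one diameter from one acquired ultrasound image. The header
#' must name the seven canonical columns (`patient_id`, `image_id`,
#' `acquirer`, `diameter_type`, `reader_id`, `repeat_index`, `value_mm`),
#' in any order; `col_map` renames non-standard headers. The table is
#' validated on load and the function stops on any validation error.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(value_mm = "diameter")`.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with the seven canonical columns, one row per reading.
#'   Row order carries no meaning: all downstream estimates are invariant
#'   to it.
#' @seealso [validate_measurements()], [write_measurements()]
#' @export
read_measurements <- function(path, col_map = NULL, delim = ",") {
  if (!file.exists(path)) {
    stop("measurement file not found: ", path, call. = FALSE)
  }
  dat <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(dat)) {
        names(dat)[names(dat) == col_map[[canon]]] <- canon
      }
    }
  }
  required <- c("patient_id", "image_id", "acquirer", "diameter_type",
                "reader_id", "repeat_index", "value_mm")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0) {
    stop("measurement file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) == 0) {
    stop("measurement file contains a header but no records", call. = FALSE)
  }
  value_num <- suppressWarnings(as.numeric(dat$value_mm))
  bad <- which(is.na(value_num) | !is.finite(value_num) | value_num <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-numeric value_mm at data row(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = dat$patient_id,
    image_id = dat$image_id,
    acquirer = dat$acquirer,
    diameter_type = dat$diameter_type,
    reader_id = dat$reader_id,
    repeat_index = as.integer(dat$repeat_index),
    value_mm = value_num
  )
  rep <- validate_measurements(out)
  errs <- dplyr::filter(rep$findings, .data$severity == "error")
  if (nrow(errs) > 0) {
    stop("invalid measurement table:\n  ",
         paste(errs$message, collapse = "\n  "), call. = FALSE)
  }
  out
}

#' Write a measurement table to CSV
#'
#' @param data Measurement tibble (see [read_measurements()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  readr::write_csv(data[, c("patient_id", "image_id", "acquirer",
                            "diameter_type", "reader_id", "repeat_index",
                            "value_mm")], path, progress = FALSE)
  invisible(path)
}

#' Validate a measurement table
#'
#' Checks the structural invariants of the hierarchical design and returns a
#' report rather than failing: each finding is an error (an invariant
#' violation that downstream fitting cannot tolerate) or a warning (an
#' analysable but noteworthy condition). Warnings include fewer than 12
#' distinct patients for a diameter type — the minimum this design needs for
#' unbiased variance estimation — and operator-by-patient cells with no
#' image (an unbalanced but permitted design).
#'
#' @param data Measurement tibble.
#' @return An object of class `acq_validation`: a list with `findings`
#'   (tibble with columns `severity`, `code`, `message`) and `n_records`.
#'   Serialize with [jsonlite::toJSON()] on `findings`, or `as_json()`.
#' @export
validate_measurements <- function(data) {
  f <- list()
  add <- function(severity, code, message) {
    f[[length(f) + 1]] <<- tibble::tibble(
      severity = severity, code = code, message = message
    )
  }

  bad_val <- which(!is.finite(data$value_mm) | data$value_mm <= 0)
  if (length(bad_val) > 0) {
    add("error", "nonpositive_value",
        paste0("value_mm must be finite and > 0; violated at row(s) ",
               paste(head(bad_val, 5), collapse = ", ")))
  }
  bad_diam <- setdiff(unique(data$diameter_type), diameter_types())
  if (length(bad_diam) > 0) {
    add("error", "unknown_diameter",
        paste0("unknown diameter_type: ", paste(bad_diam, collapse = ", ")))
  }

  key <- paste(data$image_id, data$diameter_type, data$reader_id,
               data$repeat_index, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    add("error", "duplicate_key",
        paste0(length(dup), " duplicated (image_id, diameter_type, ",
               "reader_id, repeat_index) key(s), e.g. image_id ",
               strsplit(dup[1], "\r")[[1]][1]))
  }

  img_pat <- dplyr::distinct(data, .data$image_id, .data$patient_id)
  multi_pat <- img_pat$image_id[duplicated(img_pat$image_id)]
  if (length(multi_pat) > 0) {
    add("error", "image_multiple_patients",
        paste0("image_id appears under more than one patient_id: ",
               paste(unique(multi_pat), collapse = ", ")))
  }
  img_acq <- dplyr::distinct(data, .data$image_id, .data$acquirer)
  multi_acq <- img_acq$image_id[duplicated(img_acq$image_id)]
  if (length(multi_acq) > 0) {
    add("error", "image_multiple_acquirers",
        paste0("image_id appears under more than one acquirer: ",
               paste(unique(multi_acq), collapse = ", ")))
  }

  for (d in intersect(diameter_types(), unique(data$diameter_type))) {
    dd <- data[data$diameter_type == d, ]
    n_pat <- dplyr::n_distinct(dd$patient_id)
    if (n_pat < 12) {
      add("warning", "small_sample",
          paste0(d, ": only ", n_pat, " distinct patient(s); at least 12 ",
                 "patients are needed for unbiased variance estimation"))
    }
    cells <- dplyr::distinct(dd, .data$patient_id, .data$acquirer)
    ops <- unique(dd$acquirer)
    pats <- unique(dd$patient_id)
    n_missing <- length(ops) * length(pats) - nrow(cells)
    if (n_missing > 0) {
      add("warning", "unbalanced_design",
          paste0(d, ": ", n_missing, " operator-by-patient cell(s) have no ",
                 "image (unbalanced design, handled by the model)"))
    }
  }

  findings <- if (length(f) > 0) {
    dplyr::bind_rows(f)
  } else {
    tibble::tibble(severity = character(), code = character(),
                   message = character())
  }
  structure(
    list(findings = findings, n_records = nrow(data)),
    class = "acq_validation"
  )
}

#' @export
print.acq_validation <- function(x, ...) {
  n_err <- sum(x$findings$severity == "error")
  n_warn <- sum(x$findings$severity == "warning")
  cat("Measurement validation: ", x$n_records, " records, ",
      n_err, " error(s), ", n_warn, " warning(s)\n", sep = "")
  if (nrow(x$findings) > 0) {
    for (i in seq_len(nrow(x$findings))) {
      cat("  [", x$findings$severity[i], "] ",
          x$findings$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Per-diameter design summary
#'
#' Counts patients, images, and readings per diameter type, plus the mean
#' number of images per patient (rounded to one decimal, half away from
#' zero, the convention used when reporting examinations per participant).
#'
#' @param data Measurement tibble.
#' @return A tibble with one row per diameter type: `diameter_type`,
#'   `n_patients`, `n_images`, `n_records`, `mean_images_per_patient`.
#' @export
#' @examples
#' cfg <- default_study_config(seed = 1)
#' count_summary(simulate_measurements(cfg))
count_summary <- function(data) {
  data |>
    dplyr::group_by(.data$diameter_type) |>
    dplyr::summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      n_images = dplyr::n_distinct(.data$image_id),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_images_per_patient =
        round_half_up(.data$n_images / .data$n_patients, 1)
    )
}
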