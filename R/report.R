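#' Render a human-readable assessment report
#'
#' Renders the per-trainee verdict table as markdown and, for every
#' non-GREEN verdict, appends the catalogue of candidate technique
#' deficiencies ([candidate_deficiencies()]) that could explain the error,
#' as remediation hints.
#'
#' @param x An `acq_assessment`, or the path to a result JSON written by
#'   [as_json()] / [cmd_assess()].
#' @return Character vector of markdown lines (invisibly printable with
#'   `cat(report, sep = "\n")`).
#' @export
render_report <- function(x) {
  if (is.character(x)) {
    x <- read_assessment_json(x)
  }
  v <- x$verdicts
  if (is.null(v) || nrow(v) == 0) {
    stop("assessment result is empty", call. = FALSE)
  }
  lines <- c(
    "# Image-acquisition competence report",
    "",
    sprintf("Instructor reference: `%s`; %d%% intervals.",
            x$instructor, x$level),
    "",
    "| Trainee | Diameter | Systematic (mm) | 90% CI | Zone (mm) | Verdict | Sporadic (mm2) | 90% UB | Zone upper (mm2) | Verdict |",
    "|---|---|---|---|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %.1f | (%.1f, %.1f) | ±%.1f | %s | %.1f | %.1f | %.1f | %s |",
      r$trainee, r$diameter_type, r$sys_estimate, r$sys_lower, r$sys_upper,
      r$sys_margin, r$sys_color, r$spo_estimate, r$spo_upper,
      r$spo_zone_upper, r$spo_color
    ))
  }

  if (!is.null(x$icc) && nrow(x$icc) > 0) {
    lines <- c(lines, "", "## Consistency ICCs (instructor images)", "")
    for (i in seq_len(nrow(x$icc))) {
      lines <- c(lines, sprintf("- %s: %.2f (95%% CI %.2f-%.2f)",
                                x$icc$diameter_type[i], x$icc$estimate[i],
                                x$icc$conf.low[i], x$icc$conf.high[i]))
    }
  }

  hints <- character()
  for (tr in unique(v$trainee)) {
    for (cls in c("systematic", "sporadic")) {
      col <- if (cls == "systematic") "sys_color" else "spo_color"
      affected <- v$diameter_type[v$trainee == tr & v[[col]] != "GREEN"]
      if (length(affected) == 0) next
      cand <- candidate_deficiencies(cls, affected)
      if (nrow(cand) == 0) next
      hints <- c(hints, "",
                 sprintf("### Trainee %s - %s error on %s", tr, cls,
                         paste(affected, collapse = ", ")),
                 "", "Candidate technique deficiencies to review:")
      hints <- c(hints, sprintf("- %s (%s): %s", cand$deficiency,
                                cand$domain, cand$impact))
    }
  }
  if (length(hints) > 0) {
    lines <- c(lines, "", "## Remediation hints", hints)
  }
  lines
}

# rebuild the pieces of an assessment that the report needs from its JSON
read_assessment_json <- function(path) {
  if (!file.exists(path)) {
    stop("result file not found: ", path, call. = FALSE)
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed result JSON: ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (is.null(obj$trainees) || length(obj$trainees) == 0) {
    stop("assessment result is empty", call. = FALSE)
  }
  rows <- list()
  for (tr in names(obj$trainees)) {
    for (d in names(obj$trainees[[tr]])) {
      e <- obj$trainees[[tr]][[d]]
      rows[[paste(tr, d)]] <- tibble::tibble(
        diameter_type = d, trainee = tr,
        sys_estimate = e$systematic$estimate_mm,
        sys_lower = e$systematic$ci90[[1]],
        sys_upper = e$systematic$ci90[[2]],
        sys_margin = e$systematic$zone[[2]],
        sys_color = e$systematic$color,
        spo_estimate = e$sporadic$estimate_mm2,
        spo_upper = e$sporadic$ci90_upper,
        spo_margin = NA_real_,
        spo_zone_upper = e$sporadic$zone[[2]],
        spo_color = e$sporadic$color
      )
    }
  }
  icc <- NULL
  if (!is.null(obj$icc)) {
    icc <- purrr::map_dfr(names(obj$icc), function(d) {
      tibble::tibble(diameter_type = d,
                     estimate = obj$icc[[d]]$estimate,
                     conf.low = obj$icc[[d]]$ci95[[1]],
                     conf.high = obj$icc[[d]]$ci95[[2]])
    })
  }
  structure(
    list(verdicts = dplyr::bind_rows(rows), icc = icc,
         instructor = obj$instructor %||% "instructor",
         level = obj$level %||% 90),
    class = "acq_assessment"
  )
}
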