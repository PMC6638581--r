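#' Assess trainee image-acquisition competence
#'
#' End-to-end assessment: for each requested diameter type the three-level
#' model is fitted ([fit_acquisition_model()]), equivalence and
#' noninferiority zones are built from the instructor's observed
#' measurements ([equivalence_margin()], [noninferiority_margin()]), and
#' each trainee receives a traffic-light verdict for the systematic error
#' (posterior median of the trainee contrast with its two-sided 90%
#' interval, against the +/- margin zone) and for the sporadic error
#' (posterior median of the trainee's image-level variance with its
#' one-sided 90% upper bound, against `[0, instructor image variance +
#' margin]`), together with the consistency ICC and the instructor's
#' adjusted mean (95% interval).
#'
#' Zones are plug-in sample statistics of the instructor's data, not
#' posterior functionals: they stay fixed while trainee posteriors vary.
#'
#' @param data Measurement tibble.
#' @param diameters Diameter types to assess; default all present in
#'   `data`.
#' @param instructor Instructor's acquirer label.
#' @param level Interval level in percent for the verdicts, default 90.
#' @param ... MCMC settings passed to [fit_acquisition_model()]
#'   (`n_iter`, `burn_in`, `thin`, `n_chains`, `seed`, priors).
#' @return An object of class `acq_assessment`: a list with
#'   * `verdicts` — tibble, one row per (trainee, diameter):
#'     `diameter_type`, `trainee`, systematic `sys_estimate`/`sys_lower`/
#'     `sys_upper`/`sys_margin`/`sys_color` (mm) and sporadic
#'     `spo_estimate`/`spo_upper`/`spo_margin`/`spo_zone_upper`/`spo_color`
#'     (mm²);
#'   * `instructor_means` — adjusted mean and 95% interval per diameter;
#'   * `icc` — consistency ICC per diameter (median, 95% interval);
#'   * `diagnostics` — MCMC diagnostics per diameter;
#'   * `fits` — the underlying `acq_fit` objects.
#' @export
#' @examples
#' cfg <- default_study_config(seed = 5)
#' dat <- simulate_measurements(cfg)
#' a <- assess_acquisition(dat, diameters = "IVC_MAX",
#'                         n_iter = 600, burn_in = 100, seed = 2)
#' a$verdicts
assess_acquisition <- function(data, diameters = NULL,
                               instructor = "instructor", level = 90, ...) {
  if (is.null(diameters)) {
    diameters <- intersect(diameter_types(), unique(data$diameter_type))
  }
  rep <- validate_measurements(data)
  errs <- rep$findings[rep$findings$severity == "error", ]
  if (nrow(errs) > 0) {
    stop("invalid measurement table:\n  ",
         paste(errs$message, collapse = "\n  "), call. = FALSE)
  }
  for (w in rep$findings$message[rep$findings$severity == "warning"]) {
    warning(w, call. = FALSE)
  }

  fits <- list()
  verdicts <- list()
  instr_means <- list()
  iccs <- list()
  diags <- list()
  for (d in diameters) {
    fit <- fit_acquisition_model(data, d, instructor = instructor, ...)
    fits[[d]] <- fit

    eq_margin <- equivalence_margin(data, d, instructor)
    ni_margin <- noninferiority_margin(data, d, instructor)
    instr_col <- paste0("sigma2_image_", instructor)
    s2v_instr_med <- median(fit$draws[[instr_col]])
    zone_upper <- s2v_instr_med + ni_margin

    mu_s <- posterior_summary(fit$draws$mu, level = 95)
    instr_means[[d]] <- tibble::tibble(
      diameter_type = d, estimate = mu_s$estimate,
      conf.low = mu_s$lower, conf.high = mu_s$upper
    )
    iccs[[d]] <- compute_icc(fit)
    dg <- fit$diagnostics
    dg$diameter_type <- d
    diags[[d]] <- dg

    for (tr in fit$trainees) {
      bs <- posterior_summary(fit$draws[[paste0("beta_", tr)]],
                              level = level, sidedness = "two_sided")
      vs <- posterior_summary(fit$draws[[paste0("sigma2_image_", tr)]],
                              level = level, sidedness = "one_sided_upper")
      verdicts[[paste(d, tr)]] <- tibble::tibble(
        diameter_type = d,
        trainee = tr,
        sys_estimate = bs$estimate,
        sys_lower = bs$lower,
        sys_upper = bs$upper,
        sys_margin = eq_margin,
        sys_color = classify_systematic(bs$estimate, bs$lower, bs$upper,
                                        eq_margin),
        spo_estimate = vs$estimate,
        spo_upper = vs$upper,
        spo_margin = ni_margin,
        spo_zone_upper = zone_upper,
        spo_color = classify_sporadic(vs$estimate, vs$upper, zone_upper)
      )
    }
  }

  structure(
    list(
      verdicts = dplyr::bind_rows(verdicts),
      instructor_means = dplyr::bind_rows(instr_means),
      icc = dplyr::bind_rows(iccs),
      diagnostics = dplyr::bind_rows(diags),
      fits = fits,
      instructor = instructor,
      level = level
    ),
    class = "acq_assessment"
  )
}

#' @export
print.acq_assessment <- function(x, ...) {
  cat("Acquisition-competence assessment (", x$level,
      "% intervals, instructor: ", x$instructor, ")\n", sep = "")
  print(x$verdicts[, c("diameter_type", "trainee", "sys_estimate",
                       "sys_color", "spo_estimate", "spo_color")])
  invisible(x)
}

#' @export
tidy.acq_assessment <- function(x, ...) {
  x$verdicts
}

#' @export
glance.acq_assessment <- function(x, ...) {
  tibble::tibble(
    n_diameters = dplyr::n_distinct(x$verdicts$diameter_type),
    n_trainees = dplyr::n_distinct(x$verdicts$trainee),
    n_green = sum(x$verdicts$sys_color == "GREEN") +
      sum(x$verdicts$spo_color == "GREEN"),
    n_yellow = sum(x$verdicts$sys_color == "YELLOW") +
      sum(x$verdicts$spo_color == "YELLOW"),
    n_red = sum(x$verdicts$sys_color == "RED") +
      sum(x$verdicts$spo_color == "RED"),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = min(x$diagnostics$ess)
  )
}

#' Serialize an assessment (or validation report) to JSON
#'
#' @param x An `acq_assessment` or `acq_validation`.
#' @param path Optional file path; if given, JSON is written there.
#' @param ... Unused.
#' @return JSON string (invisibly if `path` is given).
#' @export
as_json <- function(x, path = NULL, ...) {
  UseMethod("as_json")
}

#' @export
as_json.acq_validation <- function(x, path = NULL, ...) {
  obj <- list(schema_version = "1.0", n_records = x$n_records,
              findings = x$findings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
as_json.acq_assessment <- function(x, path = NULL, ...) {
  per_trainee <- list()
  for (i in seq_len(nrow(x$verdicts))) {
    r <- x$verdicts[i, ]
    per_trainee[[r$trainee]][[r$diameter_type]] <- list(
      systematic = list(
        estimate_mm = r$sys_estimate,
        ci90 = c(r$sys_lower, r$sys_upper),
        zone = c(-r$sys_margin, r$sys_margin),
        color = r$sys_color
      ),
      sporadic = list(
        estimate_mm2 = r$spo_estimate,
        ci90_upper = r$spo_upper,
        zone = c(0, r$spo_zone_upper),
        color = r$spo_color
      )
    )
  }
  icc <- lapply(seq_len(nrow(x$icc)), function(i) {
    list(estimate = x$icc$estimate[i],
         ci95 = c(x$icc$conf.low[i], x$icc$conf.high[i]))
  })
  names(icc) <- x$icc$diameter_type
  instr <- lapply(seq_len(nrow(x$instructor_means)), function(i) {
    list(estimate_mm = x$instructor_means$estimate[i],
         ci95 = c(x$instructor_means$conf.low[i],
                  x$instructor_means$conf.high[i]))
  })
  names(instr) <- x$instructor_means$diameter_type
  obj <- list(
    schema_version = "1.0",
    instructor = x$instructor,
    level = x$level,
    trainees = per_trainee,
    icc = icc,
    instructor_adjusted_means = instr,
    diagnostics = x$diagnostics
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
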