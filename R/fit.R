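#' Fit the three-level acquisition model for one diameter type
#'
#' Fits, by Gibbs sampling, the Bayesian mixed-effects model
#'
#' \deqn{y_{ijk} = \mu + \beta_{op(j)} + u_i + v_j + e_{ijk}}
#'
#' for readings \eqn{k} nested in images \eqn{j} nested in patients \eqn{i}:
#' a grand mean \eqn{\mu}, one fixed effect \eqn{\beta_t} per trainee (the
#' instructor is the reference, \eqn{\beta = 0}), patient random intercepts
#' \eqn{u_i \sim N(0, \sigma_u^2)}, image-level random effects with an
#' operator-specific variance \eqn{v_j \sim N(0, \sigma_{v,op}^2)} (random
#' coefficients — each operator's image variance is estimated from that
#' operator's images only), and a common reading residual \eqn{e \sim N(0,
#' \sigma_e^2)}. \eqn{\beta_t} is directly the instructor-referenced
#' contrast: the systematic acquisition error of trainee \eqn{t}, in mm.
#' \eqn{\sigma_{v,t}^2} carries the trainee's sporadic acquisition error,
#' in mm².
#'
#' Priors are diffuse: improper flat on \eqn{\mu} and each \eqn{\beta_t},
#' inverse-gamma(`prior_shape`, `prior_rate`) on every variance. All full
#' conditionals are conjugate; the update order is fixed effects, patient
#' effects, image effects, variances. Split-chain R-hat and effective
#' sample size are computed for every reported quantity; the fit is flagged
#' (with an R warning, and in `$diagnostics`) if R-hat exceeds 1.05 or ESS
#' falls below 400.
#'
#' @param data Measurement tibble (see [read_measurements()]).
#' @param diameter One of [diameter_types()].
#' @param instructor Acquirer label of the instructor (reference standard).
#' @param n_iter,burn_in,thin,n_chains MCMC settings; defaults 11000 / 1000
#'   / 1 / 2.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters for every
#'   variance component; default 0.001 / 0.001 (a conventional diffuse
#'   choice).
#' @param fix_variances Optional named list fixing the variance components
#'   instead of sampling them: `sigma2_patient`, `sigma2_image` (named by
#'   operator), `sigma2_reading`. Used for conjugate-oracle checks.
#' @return An object of class `acq_fit`: a list with `draws` (tibble, one
#'   row per retained draw, columns `.chain`, `.iteration`, `mu`,
#'   `beta_<trainee>`, `sigma2_patient`, `sigma2_image_<operator>`,
#'   `sigma2_reading`), `diagnostics` (tibble with `parameter`, `rhat`,
#'   `ess`, `flagged`), `diameter`, `instructor`, `trainees`, and the MCMC
#'   settings. Variance draws are strictly positive; the number of retained
#'   draws per chain is `(n_iter - burn_in) / thin`.
#' @seealso [tidy.acq_fit()], [glance.acq_fit()], [compute_icc()],
#'   [posterior_summary()]
#' @export
#' @examples
#' cfg <- default_study_config(seed = 3)
#' dat <- simulate_measurements(cfg)
#' fit <- fit_acquisition_model(dat, "IVC_MAX", n_iter = 600, burn_in = 100,
#'                              seed = 1)
#' tidy(fit)
fit_acquisition_model <- function(data, diameter,
                                  instructor = "instructor",
                                  n_iter = 11000, burn_in = 1000, thin = 1,
                                  n_chains = 2, seed = 1L,
                                  prior_shape = 0.001, prior_rate = 0.001,
                                  fix_variances = NULL) {
  if (!diameter %in% diameter_types()) {
    stop("unknown diameter type: ", diameter, call. = FALSE)
  }
  if (n_iter <= burn_in || burn_in < 0 || thin < 1) {
    stop("require n_iter > burn_in >= 0 and thin >= 1", call. = FALSE)
  }
  dd <- data[data$diameter_type == diameter, ]
  if (nrow(dd) == 0) {
    stop("no records for diameter type ", diameter, call. = FALSE)
  }
  if (!instructor %in% dd$acquirer) {
    stop("fit error: operator '", instructor,
         "' (instructor) has no images for ", diameter, call. = FALSE)
  }
  trainees <- sort(setdiff(unique(data$acquirer), instructor))
  missing_ops <- setdiff(trainees, unique(dd$acquirer))
  if (length(missing_ops) > 0) {
    stop("fit error: trainee '", missing_ops[1],
         "' has no images for ", diameter, call. = FALSE)
  }
  if (dplyr::n_distinct(dd$patient_id) < 2) {
    stop("fit error: need >= 2 patients for ", diameter, call. = FALSE)
  }

  operators <- c(instructor, trainees)
  # index maps (sorted for label-order stability)
  pat_levels <- sort(unique(dd$patient_id))
  img_levels <- sort(unique(dd$image_id))
  pat_idx <- match(dd$patient_id, pat_levels) - 1L
  img_idx <- match(dd$image_id, img_levels) - 1L
  img_acq <- dd$acquirer[match(img_levels, dd$image_id)]
  img_op <- match(img_acq, operators) - 1L

  n_ops <- length(operators)
  fixed <- !is.null(fix_variances)
  fixed_var <- if (fixed) {
    c(fix_variances$sigma2_patient,
      unname(fix_variances$sigma2_image[operators]),
      fix_variances$sigma2_reading)
  } else {
    rep(1, n_ops + 2)
  }
  if (fixed && (length(fixed_var) != n_ops + 2 || any(!is.finite(fixed_var)) ||
                any(fixed_var <= 0))) {
    stop("fix_variances must give positive sigma2_patient, sigma2_image for ",
         "every operator, and sigma2_reading", call. = FALSE)
  }

  # order the data once so draws are reproducible regardless of row order
  ord <- order(img_idx, pat_idx, dd$reader_id, dd$repeat_index, dd$value_mm)
  y <- dd$value_mm[ord]
  pat_idx <- pat_idx[ord]
  img_idx <- img_idx[ord]

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    chains[[ch]] <- gibbs_chain(
      y, pat_idx, img_idx, img_op, n_ops,
      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
      prior_shape, prior_rate, fixed, fixed_var
    )
  }

  par_names <- c("mu",
                 if (length(trainees) > 0) paste0("beta_", trainees),
                 "sigma2_patient",
                 paste0("sigma2_image_", operators),
                 "sigma2_reading")
  draws <- purrr::map2_dfr(chains, seq_len(n_chains), function(m, ch) {
    colnames(m) <- par_names
    out <- tibble::as_tibble(m)
    out$.chain <- ch
    out$.iteration <- seq_len(nrow(m))
    out[, c(".chain", ".iteration", par_names)]
  })

  monitored <- if (fixed) c("mu", paste0("beta_", trainees)) else par_names
  diagnostics <- purrr::map_dfr(monitored, function(pn) {
    mat <- matrix(draws[[pn]], ncol = n_chains)
    tibble::tibble(
      parameter = pn,
      rhat = split_rhat(mat),
      ess = total_ess(mat)
    )
  })
  diagnostics$flagged <- (is.finite(diagnostics$rhat) &
                            diagnostics$rhat > 1.05) |
    diagnostics$ess < 400
  if (any(diagnostics$flagged)) {
    warning("possible non-convergence for ", diameter, ": ",
            paste(diagnostics$parameter[diagnostics$flagged],
                  collapse = ", "),
            " (split R-hat > 1.05 or ESS < 400)", call. = FALSE)
  }

  structure(
    list(draws = draws, diagnostics = diagnostics, diameter = diameter,
         instructor = instructor, trainees = trainees,
         operators = operators,
         mcmc = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                     n_chains = n_chains, seed = seed,
                     prior_shape = prior_shape, prior_rate = prior_rate,
                     fix_variances = fix_variances),
         n_records = nrow(dd),
         n_patients = length(pat_levels),
         n_images = length(img_levels)),
    class = "acq_fit"
  )
}

# split-chain R-hat: each chain split in half, between/within variance ratio
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[(n - half + 1):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# total effective sample size across chains
total_ess <- function(mat) {
  sum(apply(mat, 2, function(x) {
    if (var(x) == 0) return(length(x))
    as.numeric(coda::effectiveSize(coda::mcmc(x)))
  }))
}

#' Summarise a posterior sample vector
#'
#' Point estimate is the posterior median (less biased than the mean for
#' variance components); intervals use type-7 quantiles (linear
#' interpolation between order statistics) throughout. Systematic errors
#' are reported with two-sided intervals, sporadic (variance) errors with
#' one-sided upper intervals.
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @param level Interval level in percent, default 90.
#' @param sidedness `"two_sided"` (central interval) or `"one_sided_upper"`
#'   (upper bound at `level`; the lower bound is 0 for nonnegative
#'   quantities, `-Inf` otherwise).
#' @return A tibble with columns `estimate`, `lower`, `upper`, `level`,
#'   `sidedness`.
#' @export
#' @examples
#' posterior_summary(1:100, level = 90)
posterior_summary <- function(draws, level = 90,
                              sidedness = c("two_sided",
                                            "one_sided_upper")) {
  sidedness <- match.arg(sidedness)
  if (length(draws) < 2 || any(!is.finite(draws))) {
    stop("need >= 2 finite draws", call. = FALSE)
  }
  alpha <- 1 - level / 100
  if (sidedness == "two_sided") {
    q <- quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                  type = 7)
    lower <- q[1]
    upper <- q[2]
  } else {
    upper <- quantile(draws, 1 - alpha, names = FALSE, type = 7)
    lower <- if (all(draws >= 0)) 0 else -Inf
  }
  tibble::tibble(estimate = median(draws), lower = lower, upper = upper,
                 level = level, sidedness = sidedness)
}

#' Consistency intraclass correlation coefficient
#'
#' The proportion of total measurement variance attributable to differences
#' between patients when the instructor acquires the images, computed per
#' posterior draw as
#' \deqn{ICC = \sigma_u^2 / (\sigma_u^2 + \sigma_{v,instr}^2 + \sigma_e^2)}
#' and summarised by its posterior median and central 95% interval. Because
#' the model adjusts for trainee fixed effects, this is a consistency ICC.
#'
#' @param fit An [fit_acquisition_model()] result.
#' @return A tibble with `diameter_type`, `estimate`, `conf.low`,
#'   `conf.high` (95% central interval). Every ICC draw lies in (0, 1).
#' @export
compute_icc <- function(fit) {
  stopifnot(inherits(fit, "acq_fit"))
  instr_col <- paste0("sigma2_image_", fit$instructor)
  if (!instr_col %in% names(fit$draws)) {
    stop("fit carries no instructor image-level variance", call. = FALSE)
  }
  s2u <- fit$draws$sigma2_patient
  s2v <- fit$draws[[instr_col]]
  s2e <- fit$draws$sigma2_reading
  icc <- s2u / (s2u + s2v + s2e)
  q <- quantile(icc, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(diameter_type = fit$diameter, estimate = median(icc),
                 conf.low = q[1], conf.high = q[2])
}

#' @export
print.acq_fit <- function(x, ...) {
  cat("Three-level acquisition model fit (", x$diameter, ")\n", sep = "")
  cat("  ", x$n_records, " readings, ", x$n_images, " images, ",
      x$n_patients, " patients\n", sep = "")
  cat("  instructor: ", x$instructor, "; trainees: ",
      paste(x$trainees, collapse = ", "), "\n", sep = "")
  cat("  ", x$mcmc$n_chains, " chain(s) x ", x$mcmc$n_iter,
      " iterations (burn-in ", x$mcmc$burn_in, ", thin ", x$mcmc$thin,
      ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of an acquisition-model fit
#'
#' @param x An `acq_fit`.
#' @param level Interval level in percent (default 90: the level used for
#'   the equivalence/noninferiority assessment).
#' @param ... Unused.
#' @return One row per model parameter: `term`, `estimate` (posterior
#'   median), `conf.low`, `conf.high` (two-sided for `mu` and the trainee
#'   contrasts, one-sided upper for variance components), `rhat`, `ess`.
#' @export
tidy.acq_fit <- function(x, level = 90, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iteration"))
  purrr::map_dfr(pars, function(pn) {
    two_sided <- !startsWith(pn, "sigma2")
    s <- posterior_summary(x$draws[[pn]], level = level,
                           sidedness = if (two_sided) "two_sided"
                                       else "one_sided_upper")
    d <- x$diagnostics[x$diagnostics$parameter == pn, ]
    tibble::tibble(term = pn, estimate = s$estimate, conf.low = s$lower,
                   conf.high = s$upper,
                   rhat = if (nrow(d)) d$rhat else NA_real_,
                   ess = if (nrow(d)) d$ess else NA_real_)
  })
}

#' One-row fit summary
#'
#' @param x An `acq_fit`.
#' @param ... Unused.
#' @return A one-row tibble: diameter, data sizes, draw count, worst R-hat,
#'   smallest ESS, consistency ICC (posterior median).
#' @export
glance.acq_fit <- function(x, ...) {
  tibble::tibble(
    diameter_type = x$diameter,
    n_records = x$n_records,
    n_images = x$n_images,
    n_patients = x$n_patients,
    n_draws = nrow(x$draws),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = min(x$diagnostics$ess),
    icc = compute_icc(x)$estimate
  )
}
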