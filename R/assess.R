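#' Equivalence margin for systematic errors
#'
#' Half a standard deviation of the mean diameter measurements obtained
#' from the instructor's ultrasound images: each patient's instructor
#' readings (all images, readers, repeats) are averaged first, and the
#' margin is 0.5 times the sample SD (n - 1 denominator) of those
#' per-patient means. The equivalence zone for a trainee's systematic
#' error is then (-margin, +margin) around zero, in mm. A systematic shift
#' of this size misclassifies about 1 in 15 diameters against a mean ± 2 SD
#' reference range (see [reference_rule_check()]).
#'
#' @param data Measurement tibble.
#' @param diameter One of [diameter_types()].
#' @param instructor Instructor's acquirer label.
#' @return Margin in mm (single numeric).
#' @export
equivalence_margin <- function(data, diameter, instructor = "instructor") {
  dd <- data[data$diameter_type == diameter &
               data$acquirer == instructor, ]
  means <- dd |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(m = mean(.data$value_mm), .groups = "drop")
  if (nrow(means) < 2) {
    stop("need >= 2 patients with instructor images for ", diameter,
         call. = FALSE)
  }
  0.5 * sd(means$m)
}

#' Noninferiority margin for sporadic errors
#'
#' A quarter of the sample variance (n - 1 denominator) of all instructor
#' readings for this diameter, pooled across patients and images. The
#' sporadic-error zone of noninferiority runs from 0 up to the instructor's
#' image-level variance plus this margin, in mm²: a trainee's excess
#' image-to-image variance must stay under a quarter of the instructor's
#' overall measurement variance.
#'
#' @inheritParams equivalence_margin
#' @return Margin in mm² (single numeric).
#' @export
noninferiority_margin <- function(data, diameter,
                                  instructor = "instructor") {
  v <- data$value_mm[data$diameter_type == diameter &
                       data$acquirer == instructor]
  if (length(v) < 2) {
    stop("need >= 2 instructor readings for ", diameter, call. = FALSE)
  }
  0.25 * var(v)
}

#' Traffic-light verdict for a systematic error
#'
#' Classifies a trainee's systematic acquisition error (posterior median
#' and two-sided 90% interval, mm) against the symmetric equivalence zone
#' (-margin, +margin): `GREEN` if the whole interval lies within the zone,
#' `RED` if the point estimate itself lies outside, `YELLOW` otherwise
#' (interval crosses the margin but the point estimate is inside).
#' Endpoints exactly on a margin count as inside.
#'
#' @param estimate Posterior median, mm.
#' @param lower,upper Two-sided interval bounds, mm.
#' @param margin Equivalence margin, mm (zone is `c(-margin, margin)`).
#' @return One of `"GREEN"`, `"YELLOW"`, `"RED"`.
#' @export
#' @examples
#' classify_systematic(-3.8, -5.4, -2.3, margin = 3) # "RED"
classify_systematic <- function(estimate, lower, upper, margin) {
  if (any(lower > upper)) {
    stop("malformed interval: lower > upper", call. = FALSE)
  }
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  dplyr::case_when(
    lower >= -margin & upper <= margin ~ "GREEN",
    estimate < -margin | estimate > margin ~ "RED",
    TRUE ~ "YELLOW"
  )
}

#' Traffic-light verdict for a sporadic error
#'
#' Classifies a trainee's image-level variance (posterior median and
#' one-sided 90% upper bound, mm²) against the noninferiority zone
#' `[0, zone_upper]`: `GREEN` if the upper bound is within the zone, `RED`
#' if the point estimate exceeds it, `YELLOW` otherwise. Ties on the bound
#' count as inside.
#'
#' @param estimate Posterior median of the trainee's image-level variance,
#'   mm².
#' @param upper One-sided 90% upper bound, mm².
#' @param zone_upper Upper bound of the noninferiority zone, mm²
#'   (instructor's image-level variance plus the [noninferiority_margin()]).
#' @return One of `"GREEN"`, `"YELLOW"`, `"RED"`.
#' @export
classify_sporadic <- function(estimate, upper, zone_upper) {
  if (any(estimate < 0) || any(upper < 0)) {
    stop("variance summaries must be >= 0", call. = FALSE)
  }
  if (zone_upper < 0) stop("zone_upper must be >= 0", call. = FALSE)
  dplyr::case_when(
    upper <= zone_upper ~ "GREEN",
    estimate > zone_upper ~ "RED",
    TRUE ~ "YELLOW"
  )
}

#' Misclassification rate induced by a downward systematic bias
#'
#' For diameters distributed Normal(`pop_mean`, `pop_sd`²) in a patient
#' population, a systematic downward measurement shift of `bias` mm makes
#' every diameter truly in `(cutoff, cutoff + bias]` appear at or below the
#' clinical cutoff. This returns that probability,
#' \eqn{P(cutoff < X \le cutoff + bias)} — the fraction of all images that
#' would be misclassified from above to below the cutoff. (The study's
#' discussion rounds this figure for its worked example; the exact normal
#' computation is returned here.)
#'
#' @param pop_mean Population mean diameter, mm.
#' @param pop_sd Population SD, mm (> 0).
#' @param cutoff Clinical decision cutoff, mm.
#' @param bias Downward measurement shift, mm (>= 0).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' misclassification_rate(22, 6, 20, 1.8)
misclassification_rate <- function(pop_mean, pop_sd, cutoff, bias) {
  if (pop_sd <= 0) stop("pop_sd must be > 0", call. = FALSE)
  if (bias < 0) stop("bias must be >= 0", call. = FALSE)
  pnorm(cutoff + bias, pop_mean, pop_sd) - pnorm(cutoff, pop_mean, pop_sd)
}

#' The "1 in N" rule behind the half-SD equivalence threshold
#'
#' Against a reference range of mean ± `k` SD, a downward systematic bias
#' of `bias_sd` standard deviations misclassifies the fraction
#' \eqn{P(Z > k - bias\_sd)} of diameters near the upper limit (standard
#' normal Z). Returns the rounded reciprocal N such that the rate is about
#' 1 in N. The default half-SD bias against a 2-SD limit gives
#' \eqn{P(Z > 1.5) = 0.0668}, i.e. 1 out of 15.
#'
#' @param bias_sd Bias in SD units, default 0.5.
#' @param k Reference-limit width in SD units, default 2.
#' @return Integer N (`round(1 / P)`).
#' @export
#' @examples
#' reference_rule_check()      # 15
#' reference_rule_check(0)     # 44 (the nominal 2.5% tail)
reference_rule_check <- function(bias_sd = 0.5, k = 2) {
  p <- pnorm(k - bias_sd, lower.tail = FALSE)
  as.integer(round(1 / p))
}

# static lookup of instructor-observed technique deficiencies, their likely
# impact on the depicted vein dimensions, the diameters affected, and the
# acquisition-level error class each one produces
deficiency_table <- function() {
  ivc <- c("IVC_MAX", "IVC_MIN")
  all4 <- diameter_types()
  tibble::tribble(
    ~domain, ~deficiency, ~impact, ~affected, ~error_class,
    "Placing transducer", "Off-axis",
    "Smaller due to oblique plane", list(ivc), "systematic",
    "Placing transducer", "Full exhalation not recorded",
    "Not fully enlarged", list(all4), "systematic",
    "Placing transducer", "Too much pressure",
    "Compressed", list("RIJ_AP"), "systematic",
    "Placing transducer", "Liver not included for acoustic enhancement",
    "Lumen edges indistinct", list(ivc), "sporadic",
    "Placing transducer", "Acoustic 'rib shadows' at target",
    "Lumen edges indistinct", list(ivc), "sporadic",
    "Placing transducer", "Not perpendicular to skin of the neck",
    "Lateral lumen edge indistinct", list("RIJ_ML"), "sporadic",
    "Placing transducer", "Not 'anchored' during patient movement",
    "Measurement target moving", list(all4), "sporadic",
    "Confirming visualization",
    "Incomplete recovery after confirmatory compression",
    "Compressed", list("RIJ_AP"), "systematic",
    "Confirming visualization", "Orientation landmarks not included",
    "Measurement target unknown", list(ivc), "sporadic",
    "Optimizing quality", "Far-field gain too high",
    "Smaller due to far wall artifacts",
    list(c("IVC_MAX", "IVC_MIN", "RIJ_AP")), "systematic",
    "Optimizing quality", "Overall gain too high",
    "Lumen edges indistinct", list(all4), "sporadic",
    "Optimizing quality", "Target not centered on screen",
    "Lumen edges indistinct", list(all4), "sporadic"
  )
}

#' Candidate technique deficiencies for an observed error profile
#'
#' Maps a model-derived acquisition error back to the catalogue of
#' instructor-observable technique deficiencies that could produce it:
#' returns every deficiency whose error class matches and whose set of
#' affected diameter types intersects `affected`. Intended to guide
#' remediation, not to diagnose.
#'
#' @param error_class `"systematic"` or `"sporadic"`.
#' @param affected Character vector of diameter codes showing the error
#'   (subset of [diameter_types()]); an empty vector returns zero rows.
#' @return A tibble with `domain`, `deficiency`, `impact`, `affected`
#'   (list-column of diameter codes), `error_class`.
#' @export
#' @examples
#' candidate_deficiencies("systematic", "RIJ_AP")$deficiency
candidate_deficiencies <- function(error_class = c("systematic",
                                                   "sporadic"),
                                   affected) {
  error_class <- match.arg(error_class)
  tab <- deficiency_table()
  hit <- tab$error_class == error_class &
    purrr::map_lgl(tab$affected, ~ length(intersect(.x, affected)) > 0)
  tab[hit, ]
}
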