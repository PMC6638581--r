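test_that("equivalence margin is half the SD of per-patient instructor means", {
  # two patients with means 10 and 14: SD = 2*sqrt(2), margin = sqrt(2)
  dat <- dplyr::bind_rows(
    make_complete_table(1, 1),
    make_complete_table(1, 1) |>
      dplyr::mutate(patient_id = "P02", image_id = "I002")
  )
  dat$value_mm <- ifelse(dat$patient_id == "P01", 10, 14)
  expect_equal(equivalence_margin(dat, "IVC_MAX"), sqrt(2))

  # zero dispersion -> zero margin
  dat$value_mm <- 10
  expect_equal(equivalence_margin(dat, "IVC_MAX"), 0)

  # fewer than two instructor patients is an error
  one <- make_complete_table(2, 1)
  expect_error(equivalence_margin(one, "IVC_MAX"), ">= 2 patients")
})

test_that("noninferiority margin is a quarter of the pooled instructor variance", {
  dat <- make_complete_table(4, 4)
  dat$value_mm <- rep(c(4, 8, 12, 16), length.out = nrow(dat)) # var known
  expect_equal(noninferiority_margin(dat, "IVC_MAX"),
               0.25 * var(dat$value_mm))
  dat$value_mm <- 7
  expect_equal(noninferiority_margin(dat, "IVC_MAX"), 0)
  expect_error(noninferiority_margin(dat[1, ], "IVC_MAX"), ">= 2")
})

test_that("margins scale with the measurement unit", {
  dat <- simulate_measurements(tiny_study_config(seed = 6, n_patients = 8))
  scaled <- dat |> dplyr::mutate(value_mm = value_mm * 2.5)
  expect_equal(equivalence_margin(scaled, "IVC_MAX"),
               2.5 * equivalence_margin(dat, "IVC_MAX"))
  expect_equal(noninferiority_margin(scaled, "IVC_MAX"),
               2.5^2 * noninferiority_margin(dat, "IVC_MAX"))
})

test_that("systematic verdicts partition every case into exactly one colour", {
  margin <- 3
  for (est in seq(-6, 6, by = 0.5)) {
    for (hw in c(0, 0.5, 2, 4, 8)) {
      col <- classify_systematic(est, est - hw, est + hw, margin)
      expect_true(col %in% c("GREEN", "YELLOW", "RED"))
      inside_int <- (est - hw) >= -margin && (est + hw) <= margin
      outside_pt <- est < -margin || est > margin
      expect_equal(col, if (inside_int) "GREEN"
                        else if (outside_pt) "RED" else "YELLOW")
      # the three clauses are mutually exclusive here because the point
      # estimate lies inside its own interval
      expect_false(inside_int && outside_pt)
    }
  }
})

test_that("the published trainee-A anteroposterior case is RED", {
  expect_equal(classify_systematic(-3.8, -5.4, -2.3, margin = 3), "RED")
  expect_equal(classify_systematic(0, -1, 1, margin = 3), "GREEN")
  expect_equal(classify_systematic(0, -4, 4, margin = 3), "YELLOW")
  # boundary ties count as inside
  expect_equal(classify_systematic(0, -3, 3, margin = 3), "GREEN")
  expect_error(classify_systematic(0, 2, -2, margin = 3), "malformed")
})

test_that("sporadic verdicts follow the noninferiority rule", {
  expect_equal(classify_sporadic(5, 8, zone_upper = 10), "GREEN")
  expect_equal(classify_sporadic(8, 12, zone_upper = 10), "YELLOW")
  expect_equal(classify_sporadic(12, 15, zone_upper = 10), "RED")
  expect_equal(classify_sporadic(10, 10, zone_upper = 10), "GREEN") # tie
  expect_error(classify_sporadic(-1, 2, 10), ">= 0")
})

test_that("misclassification arithmetic matches the normal model", {
  expect_equal(misclassification_rate(22, 6, 20, 0), 0)
  # a 1.8 mm downward bias in a N(22, 6^2) population against a 20 mm
  # cutoff: the exact figure behind the study's rounded 10%
  expect_equal(misclassification_rate(22, 6, 20, 1.8), 0.1173, # oracle below
               tolerance = 1e-3)
  # independent numeric-integration oracle
  oracle <- integrate(function(x) dnorm(x, 22, 6), 20, 21.8)$value
  expect_equal(misclassification_rate(22, 6, 20, 1.8), oracle,
               tolerance = 1e-8)
  # monotone nondecreasing in bias, -> 0 as bias -> 0
  rates <- vapply(seq(0, 4, 0.5), function(b)
    misclassification_rate(22, 6, 20, b), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(misclassification_rate(22, 6, 20, 1e-8), 1e-8)
  expect_error(misclassification_rate(22, 0, 20, 1), "pop_sd")
  expect_error(misclassification_rate(22, 6, 20, -1), "bias")
})

test_that("the half-SD bias misclassifies about 1 in 15 near a 2-SD limit", {
  expect_equal(reference_rule_check(), 15L)
  # tail oracle: 1 / (1 - Phi(1.5)) = 14.96...
  expect_equal(1 / pnorm(1.5, lower.tail = FALSE), 14.96, tolerance = 1e-3)
  expect_equal(reference_rule_check(0), 44L)   # nominal 2.5% tail
  expect_equal(reference_rule_check(2), 2L)    # bias of 2 SD: half the mass
})

test_that("deficiency lookup maps error profiles to technique candidates", {
  ap <- candidate_deficiencies("systematic", "RIJ_AP")
  expect_true(all(c("Too much pressure",
                    "Incomplete recovery after confirmatory compression")
                  %in% ap$deficiency))
  ml <- candidate_deficiencies("sporadic", "RIJ_ML")
  expect_true("Not perpendicular to skin of the neck" %in% ml$deficiency)
  expect_equal(nrow(candidate_deficiencies("systematic", character(0))), 0)
  # error classes never bleed into each other
  expect_false("Too much pressure" %in%
                 candidate_deficiencies("sporadic", "RIJ_AP")$deficiency)
})

test_that("end-to-end: biased and ideal trainees get the expected verdicts", {
  # at the default study design: trainee A's bias set to 3x the expected
  # IVC-max equivalence margin (3 mm), keeping A's inflated image variance;
  # trainee B unbiased with no sporadic excess. Verdicts are stochastic, so
  # the property is checked as proportions over replicates: RED systematic
  # for A in >= 95% of replicates, GREEN for B in >= 80%.
  n_rep <- 20
  res <- purrr::map_dfr(seq_len(n_rep), function(r) {
    cfg <- default_study_config(seed = 700 + r)
    cfg$params <- cfg$params["IVC_MAX"]
    cfg$params$IVC_MAX$beta[["A"]] <- -9  # 3 x the 3 mm margin
    dat <- simulate_measurements(cfg)
    a <- suppressWarnings(assess_acquisition(
      dat, n_iter = 1200, burn_in = 300, n_chains = 1, seed = r
    ))
    if (r == 1) {
      # every trainee x fitted diameter appears exactly once, ICC in range
      expect_equal(nrow(a$verdicts), 2)
      expect_true(all(a$icc$estimate > 0 & a$icc$estimate < 1))
    }
    a$verdicts[, c("trainee", "sys_color", "spo_color")]
  })
  expect_gte(sum(res$sys_color[res$trainee == "A"] == "RED"), 19)
  expect_gte(sum(res$spo_color[res$trainee == "A"] != "GREEN"), 16)
  expect_gte(sum(res$sys_color[res$trainee == "B"] == "GREEN"), 16)
  expect_gte(sum(res$spo_color[res$trainee == "B"] == "GREEN"), 16)
})
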