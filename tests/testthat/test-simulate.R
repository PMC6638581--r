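test_that("degenerate noise yields the population mean exactly", {
  prm <- sim_params(mu = 10, sigma_patient = 0,
                    beta = c(A = 0, B = 0),
                    sigma_image = c(instructor = 0, A = 0, B = 0),
                    sigma_meas = 0)
  cfg <- sim_config(n_patients = 3, params = list(IVC_MAX = prm), seed = 1)
  dat <- simulate_measurements(cfg)
  expect_true(all(dat$value_mm == 10))
})

test_that("complete designs have the constructed counts", {
  cfg <- tiny_study_config(seed = 2, n_patients = 16)
  dat <- simulate_measurements(cfg)
  cs <- count_summary(dat)
  expect_equal(cs$n_images, 16L * 3L)        # 3 operators, no missingness
  expect_equal(cs$n_records, 16L * 3L * 9L)  # 9 readings per image
  # count conservation holds per diameter for every complete design
  expect_equal(cs$n_records, cs$n_images * 9L)
})

test_that("simulation is seed-deterministic and patient-extensible", {
  cfg <- tiny_study_config(seed = 33, n_patients = 6)
  expect_identical(simulate_measurements(cfg)$value_mm,
                   simulate_measurements(cfg)$value_mm)

  # adding patients must not perturb earlier patients' draws
  big <- tiny_study_config(seed = 33, n_patients = 9)
  d6 <- simulate_measurements(cfg)
  d9 <- simulate_measurements(big)
  first6 <- d9[d9$patient_id %in% sprintf("P%02d", 1:6), ]
  expect_equal(dplyr::arrange(first6, image_id, reader_id, repeat_index),
               dplyr::arrange(d6, image_id, reader_id, repeat_index),
               ignore_attr = TRUE)
})

test_that("a simulated systematic bias appears in the image means", {
  # law-of-large-numbers check on the trainee-minus-instructor contrast
  cfg <- tiny_study_config(seed = 5, n_patients = 500, beta_A = -3.8)
  dat <- simulate_measurements(cfg)
  img <- dat |>
    dplyr::group_by(image_id, patient_id, acquirer) |>
    dplyr::summarise(m = mean(value_mm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = acquirer, values_from = m,
                       id_cols = patient_id,
                       values_fn = mean)
  contrast <- mean(img$A - img$instructor)
  # paired contrast SE ~ sqrt(2 * (1 + 0.25/9)) / sqrt(500) ~ 0.064
  expect_lt(abs(contrast - (-3.8)), 3 * 0.064)
})

test_that("invalid configurations are rejected", {
  prm_ok <- sim_params(mu = 10, sigma_patient = 1,
                       beta = c(A = 0, B = 0),
                       sigma_image = c(instructor = 1, A = 1, B = 1),
                       sigma_meas = 0.5)
  expect_error(sim_params(10, -1, c(A = 0), c(instructor = 1, A = 1), 0.5),
               ">= 0")
  expect_error(sim_config(0, params = list(IVC_MAX = prm_ok)),
               "n_patients")
  expect_error(sim_config(5, params = list(IVC_MAX = prm_ok),
                          p_missing_image = 1.5), "probability")
  expect_error(sim_config(5, params = list(BAD = prm_ok)),
               "unknown diameter")
})

test_that("the default study config encodes the published anchors", {
  cfg <- default_study_config()
  expect_equal(cfg$n_patients, 21L)
  expect_equal(cfg$n_readers * cfg$n_repeats, 9L)  # nine readings per image
  mus <- vapply(cfg$params, `[[`, numeric(1), "mu")
  expect_equal(unname(mus[diameter_types()]), c(16.2, 10.3, 14.4, 11.6))

  # the variance components must imply the published instructor ICCs
  implied_icc <- vapply(cfg$params, function(p) {
    s2u <- p$sigma_patient^2
    s2v <- p$sigma_image[["instructor"]]^2
    s2u / (s2u + s2v + p$sigma_meas^2)
  }, numeric(1))
  expect_equal(unname(implied_icc[diameter_types()]),
               c(0.88, 0.69, 0.83, 0.63), tolerance = 1e-10)

  # trainee A carries the published biases; trainee B none
  expect_equal(cfg$params$IVC_MAX$beta[["A"]], -1.8)
  expect_equal(cfg$params$RIJ_AP$beta[["A"]], -3.8)
  expect_true(all(vapply(cfg$params, function(p) p$beta[["B"]] == 0,
                         logical(1))))
  # with no bias and no extra spread, B is generatively identical to the
  # instructor
  expect_true(all(vapply(cfg$params, function(p) {
    p$sigma_image[["B"]] == p$sigma_image[["instructor"]]
  }, logical(1))))
})

test_that("instructor per-patient mean variance matches the generative sum", {
  # var of per-patient instructor means -> s2u + s2v + s2e/9 at large n
  cfg <- tiny_study_config(seed = 8, n_patients = 2000)
  dat <- simulate_measurements(cfg)
  m <- dat |>
    dplyr::filter(acquirer == "instructor") |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(m = mean(value_mm), .groups = "drop")
  expected <- 2^2 + 1^2 + 0.5^2 / 9
  # chi-square MC tolerance: sd of sample var ~ expected * sqrt(2/n)
  expect_lt(abs(var(m$m) - expected), 4 * expected * sqrt(2 / 2000))
})

test_that("simulated truth is echoed and recoverable", {
  cfg <- tiny_study_config(seed = 3, n_patients = 4)
  dat <- simulate_measurements(cfg)
  expect_identical(sim_truth(dat), cfg$params)
  expect_error(sim_truth(tibble::tibble(a = 1)), "truth")
})
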