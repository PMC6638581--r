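# fixtures are built in code; nothing is read from disk

# a complete single-acquirer measurement table: n_images spread round-robin
# over n_patients, each image read n_repeats times by each of n_readers
make_complete_table <- function(n_images, n_patients,
                                n_readers = 3, n_repeats = 3,
                                diameter = "IVC_MAX",
                                acquirer = "instructor") {
  imgs <- tibble::tibble(
    image_id = sprintf("I%03d", seq_len(n_images)),
    patient_id = sprintf("P%02d", ((seq_len(n_images) - 1) %% n_patients) + 1)
  )
  tidyr::expand_grid(
    image_id = imgs$image_id,
    reader_id = sprintf("R%d", seq_len(n_readers)),
    repeat_index = seq_len(n_repeats)
  ) |>
    dplyr::left_join(imgs, by = "image_id") |>
    dplyr::mutate(
      acquirer = acquirer,
      diameter_type = diameter,
      value_mm = 10 + (seq_along(image_id) %% 7) * 0.3
    ) |>
    dplyr::select(patient_id, image_id, acquirer, diameter_type,
                  reader_id, repeat_index, value_mm)
}

# a small well-separated config for fast fitting tests (large mu keeps all
# draws far from zero)
tiny_study_config <- function(seed = 1, n_patients = 8,
                              beta_A = 0, sigma_image_A = 1,
                              p_missing_image = 0,
                              diameters = "IVC_MAX") {
  prm <- lapply(setNames(diameters, diameters), function(d) {
    sim_params(
      mu = 20, sigma_patient = 2,
      beta = c(A = beta_A, B = 0),
      sigma_image = c(instructor = 1, A = sigma_image_A, B = 1),
      sigma_meas = 0.5
    )
  })
  sim_config(n_patients = n_patients, params = prm,
             p_missing_image = p_missing_image, seed = seed)
}

quiet_fit <- function(...) suppressWarnings(fit_acquisition_model(...))

# independent closed-form GLS posterior for (mu, beta) given known variance
# components, via dense linear algebra on per-image means: the oracle the
# collapsed Gibbs update is checked against
gls_posterior <- function(data, diameter, instructor,
                          sigma2_patient, sigma2_image, sigma2_reading) {
  dd <- data[data$diameter_type == diameter, ]
  imgs <- dd |>
    dplyr::group_by(image_id, patient_id, acquirer) |>
    dplyr::summarise(m = mean(value_mm), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(image_id)
  ops <- c(instructor, sort(setdiff(unique(dd$acquirer), instructor)))
  V <- diag(sigma2_image[imgs$acquirer] + sigma2_reading / imgs$n) +
    sigma2_patient * outer(imgs$patient_id, imgs$patient_id, "==")
  X <- cbind(1, sapply(ops[-1], function(o) as.numeric(imgs$acquirer == o)))
  W <- solve(V)
  A <- t(X) %*% W %*% X
  list(mean = drop(solve(A, t(X) %*% W %*% imgs$m)), cov = solve(A))
}

# fabricate an acq_fit carrying given variance draws (for ICC arithmetic)
fake_fit <- function(s2u, s2v_instr, s2e, n = 50) {
  structure(
    list(
      draws = tibble::tibble(
        .chain = 1L, .iteration = seq_len(n),
        mu = 0, sigma2_patient = rep(s2u, n),
        sigma2_image_instructor = rep(s2v_instr, n),
        sigma2_reading = rep(s2e, n)
      ),
      diagnostics = tibble::tibble(parameter = character(),
                                   rhat = numeric(), ess = numeric(),
                                   flagged = logical()),
      diameter = "IVC_MAX", instructor = "instructor",
      trainees = character(0)
    ),
    class = "acq_fit"
  )
}
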