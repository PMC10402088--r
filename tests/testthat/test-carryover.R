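test_that("carry-over covariates enumerate prior-by-subsequent pairs", {
  sch <- fx_schedules()
  for (cls in c("achromatic", "chromatic")) {
    cov <- build_carryover_covariates(sch, cls)
    expect_equal(ncol(cov), 49)
    # every ordered pair has support (counterbalance + rotation guarantee)
    expect_true(all(colSums(cov != 0) > 0))
    # total unconvolved support: 12 s x (trials per class - acquisitions)
    n_acq_cls <- if (cls == "achromatic") 12 else 24
    expect_equal(sum(cov), 12 * (n_acq_cls * 28 - n_acq_cls))
    # full rank after convolution
    kern <- double_gamma_hrf(0:27)
    covk <- build_carryover_covariates(sch, cls, kern)
    expect_equal(qr(highpass_project(covk,
                                     acquisition_length = 336))$rank, 49)
  }
  # a single 2-trial acquisition supports only its one ordered pair
  toy <- toy_schedule(c(8, 16))
  cov <- build_carryover_covariates(list(toy), "achromatic")
  lab <- attr(cov, "labels")
  supp <- which(colSums(cov != 0) > 0)
  expect_identical(lab$prior_hz[supp], 8)
  expect_identical(lab$subsequent_hz[supp], 16)
})

test_that("residuals vanish without carry-over and are orthogonal to the design", {
  nl <- fx_noiseless_fit()
  resid <- residual_signal(nl$bold, nl$fit)
  expect_lt(max(abs(resid)), 1e-6)
  # orthogonality for a noisy single vertex
  sch <- fx_schedules()
  basis <- fx_basis()
  geom <- make_vertex_geometry(1, seed = 8)
  truth <- ground_truth(geom, seed = 3, pattern_sd = 0, noise_sd = 0.4,
                        drift_amplitude = 0)
  bold <- simulate_bold(sch, truth, basis, seed = 9)
  fit <- fit_timeseries(bold, basis)
  r <- residual_signal(bold, fit)
  w <- fit$hrf_weights[1, ]
  for (a in c(1, 17, 36)) {
    X <- flickerfit:::.combine_block(fit$prep, a, w)
    rows <- (a - 1) * 336 + 1:336
    expect_lt(max(abs(crossprod(X, r[rows]))) / sqrt(sum(r^2)), 1e-6)
  }
  # zero residual -> all-zero carry-over matrix
  cov <- build_carryover_covariates(sch, "achromatic",
                                    double_gamma_hrf(0:27))
  cm0 <- fit_carryover(numeric(36 * 336), cov)
  expect_true(all(abs(cm0$values) < 1e-12))
})

test_that("injected suppression after 64 Hz is recovered against a generative oracle", {
  sch <- fx_schedules()
  basis <- fx_basis()
  geom <- make_vertex_geometry(2, seed = 2)
  gain <- matrix(1, 7, 7); gain[7, ] <- 0.7
  cg <- list(achromatic = gain, chromatic = gain)
  truth <- quiet_truth(geom, carryover_gain = cg)
  truth0 <- quiet_truth(geom)
  bold <- simulate_bold(sch, truth, basis, seed = 4, keep_signal = TRUE)
  bold0 <- simulate_bold(sch, truth0, basis, seed = 4, keep_signal = TRUE)
  # injected carry-over increases residual variance vs. the free case
  fit <- fit_timeseries(bold, basis)
  fit0 <- fit_timeseries(bold0, basis)
  r <- residual_signal(bold, fit)
  r0 <- residual_signal(bold0, fit0)
  expect_gt(sum(r^2), sum(r0^2))
  hrfk <- kernel_from_params(basis, colMeans(fit$hrf_weights))
  cov <- build_carryover_covariates(sch, "achromatic", hrfk)
  cm <- fit_carryover(r, cov)
  # generative oracle: regress the known injected component (residualized
  # against the same main design) on the same covariates
  inj <- colMeans(bold$signal - bold0$signal)
  dm <- build_design_matrix(sch, hrf_kernel = flickerfit:::.unit_response_kernel(
    kernel_from_params(basis, canonical_hrf_params(basis))))
  Xf <- highpass_project(dm$matrix, acquisition_length = 336)
  injf <- highpass_project(inj, acquisition_length = 336)
  injr <- drop(injf - Xf %*% qr.solve(Xf, injf))
  cmo <- fit_carryover(injr, cov)
  m_imp <- mean(cm$values["64", -1])
  m_or <- mean(cmo$values["64", -1])
  expect_lt(m_imp, 0)
  expect_lt(m_or, 0)
  expect_lt(abs(m_imp - m_or) / abs(m_or), 0.25)
})

test_that("null carry-over yields matrices consistent with zero", {
  # with all-ones gains and noise, cell t-statistics across seeds stay small
  sch <- fx_schedules()
  basis <- fx_basis()
  geom <- make_vertex_geometry(1, seed = 3)
  kern <- kernel_from_params(basis, canonical_hrf_params(basis))
  cov <- build_carryover_covariates(sch, "achromatic", kern)
  Xf <- highpass_project(cov, acquisition_length = 336)
  vals <- withr::with_seed(31, {
    sapply(1:50, function(i) {
      # null residual: white noise filtered like the analysis residual
      r <- highpass_project(rnorm(36 * 336, sd = 0.1),
                            acquisition_length = 336)
      fit_carryover(r, cov)$values
    })
  })
  tstat <- rowMeans(vals) / (apply(vals, 1, sd) / sqrt(ncol(vals)))
  expect_true(all(abs(tstat) < 4))
})

test_that("across-participant flags mark cells beyond twice the SEM", {
  m1 <- matrix(0.5, 7, 7); m2 <- m1; m3 <- m1
  fl <- flag_cells(list(m1, m2, m3))
  expect_true(all(fl$flags))          # SEM 0, |mean| > 0
  fl2 <- flag_cells(list(m1, -m1))
  expect_false(any(fl2$flags))        # mean 0
  # matches a direct recomputation on random stacks
  mats <- withr::with_seed(5, lapply(1:4, function(i) matrix(rnorm(49), 7)))
  fl3 <- flag_cells(mats)
  arr <- simplify2array(mats)
  mu <- apply(arr, c(1, 2), mean)
  sem <- apply(arr, c(1, 2), sd) / 2
  expect_identical(fl3$flags, abs(mu) > 2 * sem)
})
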