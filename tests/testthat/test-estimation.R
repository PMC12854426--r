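test_that("likelihood ratio test reproduces the stepwise thresholds", {
  expect_equal(lrt(3.84, 1), 0.050, tolerance = 1e-2)
  expect_equal(lrt(7.88, 1), 0.005, tolerance = 1e-2)
  expect_equal(lrt(0, 1), 1.0)
  expect_equal(qchisq(0.95, 1), 3.84, tolerance = 1e-3)
  expect_equal(qchisq(0.995, 1), 7.88, tolerance = 1e-3)
  expect_error(lrt(-1, 1), "non-negative")
  expect_error(lrt(3, 0), "df")
})

test_that("eta-shrinkage follows the (1 - SD/omega) formula", {
  expect_equal(eta_shrinkage(c(-0.1, 0.1), 0.2), 29.3, tolerance = 1e-2)
  expect_equal(eta_shrinkage(c(-0.1, 0.1), sd(c(-0.1, 0.1))), 0)
  expect_equal(eta_shrinkage(rep(0, 10), 0.3), 100)
  set.seed(501)
  x <- rnorm(50, 0, 0.2)
  expect_equal(eta_shrinkage(x, 0.2), (1 - sd(x) / 0.2) * 100)
  expect_error(eta_shrinkage(c(-0.1, 0.1), 0), "omega")
})

test_that("Laplace per-subject -2LL matches 21-node adaptive quadrature", {
  m <- pza_model()
  fixtures <- list(
    mk_subject(c(1, 4, 12), c(25, 20, 11)),
    mk_subject(c(2, 8), c(30, 18), eth = "korean", dm = 1, olddm = 1, lbw = 40, dose = 1500),
    mk_subject(c(6), c(15), lbw = 50),
    mk_subject(c(0.5, 3, 10, 22), c(14, 33, 20, 7), lbw = 38, dm = 1, dose = 1000)
  )
  for (s in fixtures) {
    lap <- subject_neg2ll(m, s)$value
    expect_lt(abs(lap - agq_neg2ll(m, s)), 0.05)
  }
})

test_that("conditional mode is zero when data sit on the population prediction", {
  m <- pza_model()
  p <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  times <- c(2, 10)
  dv <- conc_ss(p, dose_regimen(1200), times)
  sol <- subject_neg2ll(m, mk_subject(times, dv))
  expect_equal(unname(sol$eta_hat), c(0, 0), tolerance = 1e-4)
})

test_that("vanishing IIV reduces the marginal to the fixed-effect density", {
  m <- pza_model(omega2 = c(cl_ind = 1e-12, cl_kor = 1e-12, v = 1e-12, ka = 0))
  s <- mk_subject(c(2, 10), c(25, 14))
  p <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  f <- conc_ss(p, dose_regimen(1200), c(2, 10))
  direct <- sum((c(25, 14) - f)^2) / m$sigma_add^2 + 2 * log(2 * pi * m$sigma_add^2)
  expect_equal(subject_neg2ll(m, s)$value, direct, tolerance = 1e-4)
  # exactly zero variances take the dimension-reduced path to the same value
  m0 <- pza_model(omega2 = c(cl_ind = 0, cl_kor = 0, v = 0, ka = 0))
  expect_equal(subject_neg2ll(m0, s)$value, direct, tolerance = 1e-8)
})

test_that("OFV is additive over subjects and invariant to ordering", {
  m <- pza_model()
  cov <- sample_covariates(cohort_spec(), n = 24, seed = 502)
  ds <- apply_blloq_policy(simulate_trial(m, cov, seed = 503))
  o1 <- ofv(m, ds)
  # duplicating every subject under fresh ids doubles the OFV
  dup <- ds
  dup$ID <- paste0(dup$ID, "_copy")
  both <- rbind(as.data.frame(ds), as.data.frame(dup))
  both <- as_nm_dataset(both)
  expect_equal(ofv(m, both), 2 * o1, tolerance = 1e-6)
  # subject ordering and within-subject record shuffles do not matter
  perm <- as.data.frame(ds)[rev(seq_len(nrow(ds))), ]
  expect_equal(ofv(m, as_nm_dataset(perm)), o1, tolerance = 1e-6)
  # sum of per-subject contributions equals the dataset OFV
  # (subjects whose observations were all discarded contribute nothing)
  ids <- unique(ds$ID[ds$EVID == 0 & ds$MDV == 0])
  per <- vapply(
    ids,
    function(id) subject_neg2ll(m, ds[ds$ID == id, ])$value,
    numeric(1)
  )
  expect_equal(sum(per), o1, tolerance = 1e-6)
})

test_that("dataset OFV at the truth agrees with the quadrature oracle", {
  m <- pza_model()
  cov <- sample_covariates(cohort_spec(), n = 30, seed = 504)
  ds <- apply_blloq_policy(simulate_trial(m, cov, seed = 505))
  ids <- unique(ds$ID[ds$EVID == 0 & ds$MDV == 0])
  agq <- sum(vapply(ids, function(id) agq_neg2ll(m, ds[ds$ID == id, ]), numeric(1)))
  expect_lt(abs(ofv(m, ds) - agq) / abs(agq), 0.03)
})

test_that("noise-free rich data identify the structural parameters to 0.1%", {
  truth <- pza_model(
    omega2 = c(cl_ind = 0, cl_kor = 0, v = 0, ka = 0),
    sigma_add = 1e-6
  )
  times <- c(0.5, 1, 1.5, 2, 3, 6, 10, 16, 22)
  p <- individual_params(truth, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  subjects <- lapply(1:3, function(i) {
    mk_subject(times + i * 0.05, conc_ss(p, dose_regimen(1200), times + i * 0.05),
      id = paste0("R", i)
    )
  })
  ds <- as_nm_dataset(do.call(rbind, lapply(subjects, as.data.frame)))
  init <- truth
  init$theta[["cl_ind"]] <- 2.5
  init$theta[["v"]] <- 70
  init$theta[["ka"]] <- 1.2
  f <- fit(init, ds,
    fixed = c(
      "cl_kor", "eff_dm_indonesian", "eff_olddm_korean",
      "omega2_cl_ind", "omega2_cl_kor", "omega2_v", "sigma_add"
    ),
    se = FALSE
  )
  expect_lt(abs(f$estimates[["cl_ind"]] - 3.18) / 3.18, 1e-3)
  expect_lt(abs(f$estimates[["v"]] - 52.8) / 52.8, 1e-3)
  expect_lt(abs(f$estimates[["ka"]] - 2.0) / 2.0, 1e-3)
})

test_that("the full sparse-design fit recovers the generating fixed effects", {
  f <- shared_fit()
  expect_true(f$convergence)
  truth <- model_to_par_truth <- pzapk:::model_to_par(pza_model())
  for (nm in c("cl_ind", "cl_kor", "v", "ka")) {
    expect_lt(
      abs(f$estimates[[nm]] - truth[[nm]]) / truth[[nm]], 0.15,
      label = paste("relative error of", nm)
    )
  }
  # reported uncertainty is self-consistent
  expect_equal(f$rse[["cl_ind"]], 100 * f$se[["cl_ind"]] / f$estimates[["cl_ind"]])
  expect_true(all(f$shrinkage <= 100, na.rm = TRUE))
  # EBEs exist for every subject in the filtered dataset
  expect_equal(nrow(f$ebes), f$n_subjects)
})

test_that("refits from perturbed initials reach the same optimum", {
  m <- pza_model()
  cov <- sample_covariates(cohort_spec(), n = 40, seed = 506)
  ds <- apply_blloq_policy(simulate_trial(m, cov, seed = 507))
  fixed <- c("omega2_cl_kor", "ka") # weakly informed at this size
  f0 <- fit(m, ds, fixed = fixed, se = FALSE)
  pert <- m
  pert$theta[["cl_ind"]] <- m$theta[["cl_ind"]] * 1.3
  pert$theta[["cl_kor"]] <- m$theta[["cl_kor"]] * 0.7
  pert$theta[["v"]] <- m$theta[["v"]] * 1.3
  pert$covariates$dm_indonesian$value <- 0.05
  pert$sigma_add <- m$sigma_add * 1.3
  f1 <- fit(pert, ds, fixed = fixed, se = FALSE)
  expect_lt(abs(f0$ofv - f1$ofv), 0.5)
})

test_that("fit rejects unknown fixed-parameter names and bad initials", {
  m <- pza_model()
  ds <- shared_dataset()
  expect_error(fit(m, ds, fixed = "not_a_parameter"), "unknown parameter")
  bad <- m
  bad$sigma_add <- 0
  expect_error(fit(bad, ds), "positive")
})
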