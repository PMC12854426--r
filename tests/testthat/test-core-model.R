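test_that("individual parameters reproduce the final-model typical values", {
  m <- pza_model()
  ref_ind <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  expect_equal(ref_ind$cl_f, 3.18)
  expect_equal(ref_ind$v_f, 52.8)
  expect_equal(ref_ind$ka, 2.0)
  expect_equal(ref_ind$ke, 3.18 / 52.8, tolerance = 1e-12)
  kor_olddm <- individual_params(m, list(ethnicity = "korean", lbw = 45, dm = 1, old_dm = 1))
  expect_equal(kor_olddm$cl_f, 3.5 * 1.252)
  ind_dm <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 1, old_dm = 0))
  expect_equal(ind_dm$cl_f, 3.18 * 1.226)
  # the old-DM shift applies to the Korean stratum only
  ind_olddm <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 1, old_dm = 1))
  expect_equal(ind_olddm$cl_f, 3.18 * 1.226)
  # allometric scaling with fixed exponents 0.75 / 1
  low <- individual_params(m, list(ethnicity = "indonesian", lbw = 36, dm = 0, old_dm = 0))
  expect_equal(low$cl_f, 3.18 * (36 / 45)^0.75)
  expect_equal(low$v_f, 52.8 * 36 / 45)
  # log-normal IIV: eta_cl = log 2 doubles clearance
  dbl <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0),
    eta = c(log(2), 0)
  )
  expect_equal(dbl$cl_f, 2 * ref_ind$cl_f)
  expect_error(
    individual_params(m, list(ethnicity = "thai", lbw = 45, dm = 0, old_dm = 0)),
    "ethnicity"
  )
})

test_that("steady-state concentration matches brute-force superposition", {
  m <- pza_model()
  p <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  reg <- dose_regimen(1200)
  # frozen value from the superposition oracle (>= 100 accumulated doses)
  expect_equal(conc_ss(p, reg, 2), 26.7487, tolerance = 1e-4)
  for (t in c(0.25, 1, 2, 6, 12, 23.5)) {
    expect_equal(
      conc_ss(p, reg, t),
      conc_superposition(p$cl_f, p$v_f, p$ka, 1200, 24, t),
      tolerance = 1e-10
    )
  }
  # periodicity, positivity, dose linearity
  expect_equal(conc_ss(p, reg, 0), conc_ss(p, reg, 24), tolerance = 1e-10)
  tt <- seq(0, 24, by = 0.25)
  expect_true(all(conc_ss(p, reg, tt) >= 0))
  expect_equal(
    conc_ss(p, dose_regimen(2400), tt), 2 * conc_ss(p, reg, tt),
    tolerance = 1e-12
  )
  expect_error(conc_ss(p, reg, 25), "within")
  expect_error(conc_ss(p, reg, -0.1), "within")
})

test_that("the ka ~ ke degenerate case uses the analytic limit", {
  # parameters tuned so ka == ke exactly
  p_deg <- list(cl_f = 2, v_f = 40, ka = 0.05)
  reg <- dose_regimen(1000)
  for (t in c(0.5, 3, 12, 20)) {
    expect_equal(
      conc_ss(p_deg, reg, t),
      conc_superposition(2, 40, 0.05 + 1e-11, 1000, 24, t, n_doses = 5000),
      tolerance = 1e-5
    )
  }
  # continuity across the branch switch
  near <- list(cl_f = 2, v_f = 40, ka = 0.05 * (1 + 1e-7))
  expect_equal(conc_ss(p_deg, reg, 6), conc_ss(near, reg, 6), tolerance = 1e-5)
})

test_that("steady-state AUC equals dose/CL and the quadrature of conc_ss", {
  m <- pza_model()
  p <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  expect_equal(auc_ss(p, dose_regimen(1250)), 1250 / 3.18)
  expect_equal(auc_ss(list(cl_f = 4.382, v_f = 52.8, ka = 2), dose_regimen(1200)),
    273.9,
    tolerance = 1e-3
  )
  # AUC is independent of ka and V: quadrature oracle over random parameters
  set.seed(401)
  for (i in 1:100) {
    cl <- runif(1, 1, 8)
    v <- runif(1, 20, 90)
    ka <- runif(1, 0.3, 4)
    d <- runif(1, 500, 3000)
    p_i <- list(cl_f = cl, v_f = v, ka = ka)
    q <- stats::integrate(function(x) conc_ss(p_i, dose_regimen(d), x),
      0, 24,
      rel.tol = 1e-9, subdivisions = 400
    )$value
    expect_equal(auc_ss(p_i, dose_regimen(d)), q, tolerance = 1e-4)
  }
})

test_that("Cmax/Tmax agree with a dense-grid search and scale linearly in dose", {
  m <- pza_model()
  p <- individual_params(m, list(ethnicity = "indonesian", lbw = 45, dm = 0, old_dm = 0))
  reg <- dose_regimen(1200)
  cm <- cmax_tmax_ss(p, reg)
  # frozen from a 1e5-point grid search
  expect_equal(cm$cmax, 26.893, tolerance = 1e-4)
  expect_equal(cm$tmax, 1.667, tolerance = 1e-3)
  grid <- seq(0, 24, length.out = 100001)
  cg <- conc_ss(p, reg, grid)
  expect_true(cm$cmax >= max(cg) - 1e-8)
  expect_equal(cm$tmax, grid[which.max(cg)], tolerance = 1e-3)
  cm2 <- cmax_tmax_ss(p, dose_regimen(2400))
  expect_equal(cm2$cmax, 2 * cm$cmax, tolerance = 1e-10)
  expect_equal(cm2$tmax, cm$tmax, tolerance = 1e-10)
  # vectorized Cmax agrees with the scalar version across random parameters
  set.seed(402)
  cl <- runif(20, 1, 8); v <- runif(20, 20, 90); ka <- runif(20, 0.3, 4)
  vec <- pzapk:::cmax_ss_vec(cl, v, ka, 1500, 24)
  sc <- vapply(
    seq_len(20),
    function(i) cmax_tmax_ss(list(cl_f = cl[i], v_f = v[i], ka = ka[i]), dose_regimen(1500))$cmax,
    numeric(1)
  )
  expect_equal(vec, sc, tolerance = 1e-8)
})

test_that("model constructor validates its inputs", {
  expect_error(pza_model(theta = c(cl_ind = -1, cl_kor = 3.5, v = 52.8, ka = 2)), "positive")
  expect_error(
    pza_model(omega2 = c(cl_ind = -0.1, cl_kor = 0.0025, v = 0.05, ka = 0)),
    "non-negative"
  )
  expect_equal(omega2_from_cv(20.5), 0.042025)
  expect_equal(cv_from_omega2(omega2_from_cv(23.6)), 23.6)
  tg <- therapeutic_targets()
  expect_true(all(unlist(tg) > 0))
})
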