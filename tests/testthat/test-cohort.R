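test_that("sampled covariates match the cohort spec and are reproducible", {
  spec <- cohort_spec()
  cov <- sample_covariates(spec, n = 320, seed = 101)
  expect_equal(nrow(cov), 320)
  # summary statistics within sampling error of the study cohort
  expect_lt(abs(median(cov$weight) - 55), 3)
  expect_lt(abs(mean(cov$sex == "male") - 0.616), 0.06)
  expect_lt(abs(mean(cov$dm) - 0.241), 0.06)
  # LBW is always the Boer transform of sex/weight/height, never free-standing
  expect_equal(cov$lbw, lbw_boer(cov$sex, cov$weight, cov$height))
  expect_equal(cov$egfr, egfr_ckdepi(cov$sex, cov$scr, cov$age))
  # old_dm consistent with age and dm by construction
  expect_true(all(cov$old_dm <= cov$dm))
  expect_true(all(cov$age[cov$old_dm == 1] >= 60))
  expect_true(all(cov$age >= 18))
  # determinism
  expect_identical(cov, sample_covariates(spec, n = 320, seed = 101))
  expect_false(identical(cov, sample_covariates(spec, n = 320, seed = 102)))
})

test_that("cohort quantiles track the spec at large n", {
  spec <- cohort_spec()
  cov <- sample_covariates(spec, n = 10000, seed = 103)
  ind <- cov[cov$ethnicity == "indonesian", ]
  kor <- cov[cov$ethnicity == "korean", ]
  expect_lt(abs(median(ind$weight) - 50), 1.5)
  expect_lt(abs(median(kor$weight) - 56), 1.5)
  expect_lt(abs(quantile(kor$weight, 0.75) - 63), 2.5)
  expect_lt(abs(median(ind$age) - 45), 2)
  expect_lt(abs(mean(ind$dm) - 55 / 160), 0.02)
  expect_lt(abs(mean(kor$old_dm) - 13 / 160), 0.02)
  # overall LBW near the study median
  expect_lt(abs(median(cov$lbw) - 45.5), 2.5)
})

test_that("degenerate prevalence specs behave", {
  spec <- cohort_spec()
  spec$indonesian$dm_prev <- 0
  spec$indonesian$olddm_prev <- 0
  spec$korean$dm_prev <- 0
  spec$korean$olddm_prev <- 0
  cov <- sample_covariates(spec, n = 200, seed = 104)
  expect_true(all(cov$dm == 0) && all(cov$old_dm == 0))
  spec$korean$olddm_prev <- 0.5
  expect_error(sample_covariates(spec, n = 50, seed = 1), "prevalence")
})

test_that("cohort specs round-trip through YAML", {
  spec <- cohort_spec(n_per_stratum = 40)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(back, spec)
  # an equivalent cohort is drawn from the round-tripped spec
  expect_identical(
    sample_covariates(back, n = 40, seed = 9),
    sample_covariates(spec, n = 40, seed = 9)
  )
  # invalid prevalence combinations are rejected on read
  bad <- spec
  bad$korean$olddm_prev <- 0.9
  write_cohort_spec(bad, path)
  expect_error(read_cohort_spec(path), "prevalence")
})

test_that("caliper matching picks the nearest admissible candidate", {
  ref <- data.frame(subject_id = "r1", weight = 50, age = 30)
  pool <- data.frame(subject_id = c("p1", "p2"), weight = c(52, 58), age = c(33, 30))
  res <- match_cohorts(ref, pool)
  expect_equal(res$pairs$pool_id, "p1") # p2 violates the 5 kg weight caliper
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$unmatched, character(0))
  # both calipers violated: no pairs
  res2 <- match_cohorts(ref, data.frame(subject_id = "p3", weight = 56, age = 36))
  expect_equal(nrow(res2$pairs), 0)
  expect_equal(res2$unmatched, "r1")
  # empty inputs give empty results
  res3 <- match_cohorts(ref[0, ], pool)
  expect_equal(nrow(res3$pairs), 0)
})

test_that("matching is 1:1, caliper-safe, and bounded by the smaller cohort", {
  spec <- cohort_spec()
  cov <- sample_covariates(spec, n = 240, seed = 105)
  ref <- cov[cov$ethnicity == "indonesian", ]
  pool <- cov[cov$ethnicity == "korean", ]
  res <- match_cohorts(ref, pool)
  expect_lte(nrow(res$pairs), min(nrow(ref), nrow(pool)))
  # without replacement: every pool subject used at most once
  expect_false(any(duplicated(res$pairs$pool_id)))
  expect_false(any(duplicated(res$pairs$ref_id)))
  # exhaustive caliper check on every emitted pair
  expect_true(all(res$pairs$dweight <= 5))
  expect_true(all(res$pairs$dage <= 5))
  expect_equal(nrow(res$pairs) + length(res$unmatched), nrow(ref))
})

test_that("simulated trials reduce to the model in the noise-free limit", {
  m <- pza_model(
    omega2 = c(cl_ind = 0, cl_kor = 0, v = 0, ka = 0),
    sigma_add = 1e-12
  )
  cohort <- data.frame(
    subject_id = "X1", ethnicity = "indonesian", sex = "male", age = 45,
    weight = 55, height = 165, lbw = 45, dm = 0, old_dm = 0, scr = 0.7,
    egfr = 113, albumin = 3.5, ast = 25, alt = 20, bilirubin = 0.5,
    bun = 10, dose = 1200, stringsAsFactors = FALSE
  )
  design <- sampling_design(
    two_sample_frac = c(indonesian = 1, korean = 0),
    blloq_artifact_rate = 0
  )
  ds <- simulate_trial(m, cohort, design, seed = 42)
  obs <- ds[ds$EVID == 0, ]
  p <- individual_params(m, cohort)
  expect_equal(obs$DV, conc_ss(p, dose_regimen(1200), obs$TIME), tolerance = 1e-6)
  expect_equal(nrow(obs), 2) # hospitalized stratum: two samples
})

test_that("trial simulation is seed-reproducible and flags the BLLoQ artifact rate", {
  m <- pza_model()
  cov <- sample_covariates(cohort_spec(), n = 320, seed = 106)
  ds1 <- simulate_trial(m, cov, seed = 7)
  ds2 <- simulate_trial(m, cov, seed = 7)
  ds3 <- simulate_trial(m, cov, seed = 8)
  expect_identical(ds1, ds2)
  expect_false(identical(ds1, ds3))
  # the pre-analytical degradation artifact drives essentially all BLLoQ
  # records; its empirical rate matches the 11% design value
  blq_frac <- mean(ds1$BLQ[ds1$EVID == 0])
  expect_lt(abs(blq_frac - 0.11), 0.04)
  # sampling times respect the design window
  expect_true(all(ds1$TIME[ds1$EVID == 0] >= 0.5 & ds1$TIME[ds1$EVID == 0] <= 24))
})

test_that("simulated concentrations converge to the eta-integrated expectation", {
  # Monte Carlo mean at a fixed time vs 2-d Gauss-Hermite integration over
  # the random effects (independent oracle)
  m <- pza_model()
  n <- 10000
  cohort <- data.frame(
    subject_id = sprintf("X%05d", 1:n), ethnicity = "indonesian", sex = "male",
    age = 45, weight = 55, height = 165, lbw = 45, dm = 0, old_dm = 0,
    scr = 0.7, egfr = 113, albumin = 3.5, ast = 25, alt = 20, bilirubin = 0.5,
    bun = 10, dose = 1200, stringsAsFactors = FALSE
  )
  m0 <- m
  m0$sigma_add <- 1e-9 # isolate the eta integral
  design <- sampling_design(
    two_sample_frac = c(indonesian = 0, korean = 0),
    window = c(6, 6.000001), blloq_artifact_rate = 0
  )
  ds <- simulate_trial(m0, cohort, design, seed = 44)
  mc_mean <- mean(ds$DV[ds$EVID == 0])
  gh <- pracma::gaussHermite(41)
  s_cl <- sqrt(m$omega2[["cl_ind"]])
  s_v <- sqrt(m$omega2[["v"]])
  p0 <- individual_params(m, cohort[1, ])
  expc <- 0
  for (i in seq_along(gh$x)) {
    for (j in seq_along(gh$x)) {
      eta <- sqrt(2) * c(s_cl * gh$x[i], s_v * gh$x[j])
      ci <- conc_ss(
        list(cl_f = p0$cl_f * exp(eta[1]), v_f = p0$v_f * exp(eta[2]), ka = p0$ka),
        dose_regimen(1200), 6
      )
      expc <- expc + gh$w[i] * gh$w[j] * ci / pi
    }
  }
  expect_lt(abs(mc_mean - expc) / expc, 0.02)
})
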