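# candidate descriptors used across selection tests
cand_dm_ind <- list(
  name = "dm_indonesian", param = "cl", type = "categorical",
  column = "dm", ethnicity = "indonesian", value = 0
)
cand_olddm_kor <- list(
  name = "olddm_korean", param = "cl", type = "categorical",
  column = "old_dm", ethnicity = "korean", value = 0
)
cand_null_sex <- list(
  name = "male_cl", param = "cl", type = "categorical",
  column = "is_male", ethnicity = NA, value = 0
)

# the selection fits hold the variance components and Ka at their generating
# values so each candidate evaluation stays fast
sel_fixed <- c("ka", "v", "omega2_cl_ind", "omega2_cl_kor", "omega2_v", "sigma_add")

test_that("a strong simulated DM effect is retained by stepwise selection", {
  truth <- pza_model() # carries the two diabetes effects
  cov <- sample_covariates(cohort_spec(), n = 150, seed = 601)
  cov$is_male <- as.integer(cov$sex == "male")
  design <- sampling_design(
    two_sample_frac = c(indonesian = 1, korean = 1),
    blloq_artifact_rate = 0
  )
  ds <- simulate_trial(truth, cov, design, seed = 602)
  ds$IS_MALE <- as.integer(ds$SEX == "male")
  base <- pza_model(covariates = list())
  # expose the helper covariate column under the lower-case name the
  # descriptors use
  ds$is_male <- ds$IS_MALE
  sel <- stepwise_selection(
    base, list(
      dm_indonesian = cand_dm_ind,
      olddm_korean = cand_olddm_kor,
      male_cl = cand_null_sex
    ),
    ds,
    fixed = sel_fixed
  )
  expect_true("dm_indonesian" %in% names(sel$model$covariates))
  expect_false("male_cl" %in% names(sel$model$covariates))
  # recovered effect size near the generating +22.6% shift
  expect_lt(abs(sel$model$covariates$dm_indonesian$value - 0.226), 0.15)
  # trace bookkeeping: forward additions met their thresholds
  added <- sel$trace[sel$trace$decision == "added", ]
  expect_true(all(added$delta_ofv[1] >= qchisq(0.95, 1)))
  if (nrow(added) > 1) expect_true(all(added$delta_ofv[-1] >= qchisq(0.99, 1)))
  kept <- sel$trace[sel$trace$stage == "backward" & sel$trace$decision == "kept", ]
  expect_true(all(kept$delta_ofv > qchisq(0.995, 1)))
})

test_that("an empty candidate set returns the refitted base model unchanged", {
  base <- pza_model(covariates = list())
  ds <- shared_dataset()
  sel <- stepwise_selection(base, list(), ds, fixed = sel_fixed)
  expect_equal(length(sel$model$covariates), 0)
  expect_equal(nrow(sel$trace), 0)
})

test_that("null-covariate OFV drops follow a chi-square(1) law", {
  # data simulated WITHOUT any covariate effect; the OFV drop from adding a
  # spurious DM effect should be ~ chi-square with 1 df
  m0 <- pza_model(covariates = list())
  n_rep <- 60
  dofv <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cov <- sample_covariates(cohort_spec(), n = 40, seed = 7000 + r)
    design <- sampling_design(blloq_artifact_rate = 0)
    ds <- simulate_trial(m0, cov, design, seed = 7500 + r)
    free_fixed <- c(
      "cl_kor", "v", "ka",
      "omega2_cl_ind", "omega2_cl_kor", "omega2_v", "sigma_add"
    )
    f_base <- fit(m0, ds, fixed = free_fixed, se = FALSE)
    m1 <- m0
    m1$covariates <- pzapk:::validate_covariate_effects(list(dm_indonesian = cand_dm_ind))
    f_ext <- fit(m1, ds, fixed = free_fixed, se = FALSE)
    dofv[r] <- max(0, f_base$ofv - f_ext$ofv)
  }
  q95 <- unname(quantile(dofv, 0.95))
  expect_gt(q95, 1.8)
  expect_lt(q95, 6.5)
  # type-I retention at the forward threshold stays near its nominal 5%
  expect_lte(mean(dofv >= qchisq(0.95, 1)), 0.15)
})

test_that("bootstrap is seed-stable and brackets the generating parameters", {
  m <- pza_model()
  cov <- sample_covariates(cohort_spec(), n = 60, seed = 603)
  ds <- apply_blloq_policy(simulate_trial(m, cov, seed = 604))
  bfixed <- c("ka", "omega2_cl_ind", "omega2_cl_kor", "omega2_v", "sigma_add")
  bs <- bootstrap(m, ds, n_resamples = 20, seed = 605, fixed = bfixed)
  bs2 <- bootstrap(m, ds, n_resamples = 20, seed = 605, fixed = bfixed)
  expect_identical(bs$summary, bs2$summary)
  expect_true(all(bs$summary$lower <= bs$summary$median))
  expect_true(all(bs$summary$median <= bs$summary$upper))
  # percentile CIs of the freely estimated fixed effects cover the truth for
  # most parameters (small-sample run; the generating values are the truth)
  truth <- pzapk:::model_to_par(m)
  free <- c("cl_ind", "cl_kor", "v", "eff_dm_indonesian", "eff_olddm_korean")
  s <- bs$summary[match(free, bs$summary$parameter), ]
  covered <- truth[free] >= s$lower & truth[free] <= s$upper
  expect_gte(sum(covered), 4)
  # resampling is stratified: per-replicate subject count is preserved
  expect_lte(bs$n_failed, 5)
})

test_that("a single forced resample collapses the interval to a point", {
  m <- pza_model()
  cov <- sample_covariates(cohort_spec(), n = 20, seed = 606)
  ds <- apply_blloq_policy(simulate_trial(m, cov, seed = 607))
  bs <- bootstrap(m, ds,
    n_resamples = 1, seed = 608,
    fixed = c("ka", "omega2_cl_ind", "omega2_cl_kor", "omega2_v", "sigma_add")
  )
  expect_equal(bs$summary$lower, bs$summary$upper, tolerance = 1e-12)
  expect_equal(bs$summary$lower, bs$summary$median, tolerance = 1e-12)
})
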