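# shared fixtures and independent oracles for the test suite

# single-subject NONMEM-style dataset at steady state
mk_subject <- function(times, dvs, id = "T1", eth = "indonesian", dm = 0,
                       olddm = 0, lbw = 45, dose = 1200, sex = "male") {
  n <- length(times)
  as_nm_dataset(data.frame(
    ID = id, TIME = c(0, times), EVID = c(1L, rep(0L, n)),
    AMT = c(dose, rep(NA_real_, n)), DV = c(NA_real_, dvs),
    MDV = c(1L, rep(0L, n)), BLQ = 0L,
    ETH = eth, SEX = sex, AGE = 45, WT = 55, HT = 165, LBW = lbw,
    DM = dm, OLDDM = olddm, stringsAsFactors = FALSE
  ))
}

# brute-force steady-state oracle: superposition of many single oral doses
conc_superposition <- function(cl, v, ka, dose, tau, t, n_doses = 400) {
  ke <- cl / v
  single <- function(tt) {
    dose * ka / (v * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt))
  }
  sum(single(t + tau * (0:(n_doses - 1))))
}

# adaptive Gauss-Hermite quadrature oracle for the per-subject marginal
# -2 log likelihood (tensor nq x nq nodes centered at the conditional mode)
agq_neg2ll <- function(model, records, nq = 21) {
  sol <- subject_neg2ll(model, records)
  mode <- sol$eta_hat
  S <- solve(sol$hessian)
  L <- t(chol(S))
  gh <- pracma::gaussHermite(nq)
  prep <- pzapk:::prepare_nm(records)
  st <- pzapk:::engine_state(model, prep)
  tot <- 0
  for (i in seq_len(nq)) {
    for (j in seq_len(nq)) {
      z <- sqrt(2) * c(gh$x[i], gh$x[j])
      eta <- mode + as.vector(L %*% z)
      g <- pzapk:::engine_g(st, eta[1], eta[2])
      tot <- tot + gh$w[i] * gh$w[j] * exp(-g / 2 + sum(z^2) / 2)
    }
  }
  -2 * log(2 * det(L) * tot)
}

# moderate simulated trial + fit, shared (memoized) across test files
.shared <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    m <- pza_model()
    cov <- sample_covariates(cohort_spec(), n = 120, seed = 2024)
    .shared$cohort <- cov
    .shared$ds <- apply_blloq_policy(simulate_trial(m, cov, seed = 2025))
  }
  .shared$ds
}

shared_fit <- function() {
  if (is.null(.shared$fit)) {
    .shared$fit <- fit(pza_model(), shared_dataset())
  }
  .shared$fit
}
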