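#' Population pharmacokinetic model object
#'
#' Constructs the population PK model for once-daily oral pyrazinamide: a
#' one-compartment disposition model with first-order absorption and
#' elimination, lean-body-weight (LBW) allometric scaling of apparent
#' clearance (exponent 0.75) and volume (exponent 1), ethnicity-specific
#' typical clearances, fractional-shift diabetes covariate effects on
#' clearance, log-normal inter-individual variability (IIV) on CL/F and Vd/F,
#' and an additive residual error.
#'
#' The defaults are the final-model estimates of the interethnic
#' (Indonesian/Korean) adult TB cohort this package emulates: typical CL/F
#' 3.18 L/h (Indonesian) and 3.5 L/h (Korean) at the 45 kg LBW reference,
#' a +22.6\% clearance shift for Indonesian diabetic patients, a +25.2\% shift
#' for Korean diabetic patients aged 60 or older, Vd/F 52.8 L, Ka 2.0 1/h,
#' IIV CVs of 20.5\% / 5\% (CL/F by ethnicity) and 23.6\% (Vd/F), and an
#' additive residual SD of 1.29 mg/L.
#'
#' @param theta named numeric vector of fixed effects: `cl_ind`, `cl_kor`
#'   (L/h at the LBW reference), `v` (L), `ka` (1/h).
#' @param covariates list of covariate-effect descriptors. Each element is a
#'   list with fields `param` (`"cl"` or `"v"`), `type` (`"categorical"` or
#'   `"power"`), `column` (covariate column name), `ethnicity`
#'   (`"indonesian"`, `"korean"` or `NA` for both), `value` (fractional shift
#'   or power exponent) and, for power effects, `median` (reference value).
#' @param omega2 named numeric vector of IIV variances (log scale):
#'   `cl_ind`, `cl_kor`, `v`, `ka`. `ka` is fixed at 0 (no IIV on absorption).
#' @param sigma_add additive residual SD, mg/L.
#' @param lbw_ref allometric reference LBW, kg.
#' @param allo_cl,allo_v fixed allometric exponents for CL/F and Vd/F.
#' @return an object of class `pza_model`.
#' @examples
#' m <- pza_model()
#' m$theta[["cl_ind"]]
#' @export
pza_model <- function(theta = c(cl_ind = 3.18, cl_kor = 3.5, v = 52.8, ka = 2.0),
                      covariates = default_covariate_effects(),
                      omega2 = c(
                        cl_ind = omega2_from_cv(20.5),
                        cl_kor = omega2_from_cv(5),
                        v = omega2_from_cv(23.6),
                        ka = 0
                      ),
                      sigma_add = 1.29,
                      lbw_ref = 45,
                      allo_cl = 0.75,
                      allo_v = 1) {
  need <- c("cl_ind", "cl_kor", "v", "ka")
  if (!all(need %in% names(theta))) {
    stop("`theta` must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(theta[need] <= 0)) stop("fixed effects must be positive", call. = FALSE)
  om_need <- c("cl_ind", "cl_kor", "v", "ka")
  if (!all(om_need %in% names(omega2))) {
    stop("`omega2` must contain ", paste(om_need, collapse = ", "), call. = FALSE)
  }
  if (any(omega2[om_need] < 0)) stop("variances must be non-negative", call. = FALSE)
  if (sigma_add < 0) stop("`sigma_add` must be non-negative", call. = FALSE)
  if (lbw_ref <= 0) stop("`lbw_ref` must be positive", call. = FALSE)
  covariates <- validate_covariate_effects(covariates)
  structure(
    list(
      theta = theta[need], covariates = covariates, omega2 = omega2[om_need],
      sigma_add = sigma_add, lbw_ref = lbw_ref,
      allo_cl = allo_cl, allo_v = allo_v
    ),
    class = "pza_model"
  )
}

#' @export
print.pza_model <- function(x, ...) {
  cat("Population PK model (1-cpt oral, LBW allometry)\n")
  cat(sprintf(
    "  theta: CL/F ind %.3g, kor %.3g L/h; Vd/F %.3g L; Ka %.3g 1/h (LBW ref %g kg)\n",
    x$theta[["cl_ind"]], x$theta[["cl_kor"]], x$theta[["v"]], x$theta[["ka"]],
    x$lbw_ref
  ))
  for (ef in x$covariates) {
    cat(sprintf(
      "  covariate %s: %s on %s [%s] value %.4g\n",
      ef$name, ef$type, ef$param,
      if (is.na(ef$ethnicity)) "both" else ef$ethnicity, ef$value
    ))
  }
  cat(sprintf(
    "  omega2: CL ind %.4g, CL kor %.4g, V %.4g, Ka %g; sigma_add %.3g mg/L\n",
    x$omega2[["cl_ind"]], x$omega2[["cl_kor"]], x$omega2[["v"]],
    x$omega2[["ka"]], x$sigma_add
  ))
  invisible(x)
}

#' Final-model covariate effects: diabetes on clearance
#'
#' Diabetes raises apparent clearance by 22.6\% in the Indonesian stratum; in
#' the Korean stratum the shift (25.2\%) applies to diabetic patients aged
#' 60 or older.
#'
#' @return list of covariate-effect descriptors (see [pza_model()]).
#' @export
default_covariate_effects <- function() {
  list(
    dm_indonesian = list(
      name = "dm_indonesian", param = "cl", type = "categorical",
      column = "dm", ethnicity = "indonesian", value = 0.226
    ),
    olddm_korean = list(
      name = "olddm_korean", param = "cl", type = "categorical",
      column = "old_dm", ethnicity = "korean", value = 0.252
    )
  )
}

validate_covariate_effects <- function(covariates) {
  if (length(covariates) == 0) return(list())
  out <- list()
  for (i in seq_along(covariates)) {
    ef <- covariates[[i]]
    nm <- if (!is.null(ef$name)) ef$name else names(covariates)[i]
    if (is.null(nm) || !nzchar(nm)) stop("covariate effects must be named", call. = FALSE)
    ef$name <- nm
    if (is.null(ef$ethnicity)) ef$ethnicity <- NA_character_
    if (!ef$param %in% c("cl", "v")) stop("effect `param` must be 'cl' or 'v'", call. = FALSE)
    if (!ef$type %in% c("categorical", "power")) {
      stop("effect `type` must be 'categorical' or 'power'", call. = FALSE)
    }
    if (ef$type == "power" && is.null(ef$median)) {
      stop("power effects need a `median` reference value", call. = FALSE)
    }
    out[[nm]] <- ef
  }
  out
}

#' Convert a reported IIV CV\% to a log-normal variance (and back)
#'
#' IIV magnitudes are reported as approximate coefficients of variation,
#' `CV\% = 100 * sqrt(omega2)`; internally the log-scale variance is used.
#'
#' @param cv_pct coefficient of variation in percent.
#' @return variance of the log-normal random effect.
#' @export
omega2_from_cv <- function(cv_pct) (cv_pct / 100)^2

#' @rdname omega2_from_cv
#' @param omega2 log-scale variance.
#' @export
cv_from_omega2 <- function(omega2) 100 * sqrt(omega2)

#' Therapeutic target constants for pyrazinamide exposure
#'
#' @return list with `auc_target` (363 mg.h/L efficacy target),
#'   `cmax_toxicity_limit` (60 mg/L), `cmax_efficacy_ref` (35 mg/L),
#'   `lloq` (2.0 mg/L) and `pta_criterion` (0.90).
#' @export
therapeutic_targets <- function() {
  list(
    auc_target = 363, cmax_toxicity_limit = 60, cmax_efficacy_ref = 35,
    lloq = 2.0, pta_criterion = 0.90
  )
}

#' Once-daily dosing regimen
#'
#' @param dose dose in mg (> 0).
#' @param tau dosing interval in h, default 24.
#' @return list with `dose`, `tau`, `f` (bioavailability fraction, fixed 1 and
#'   absorbed into the apparent parameters).
#' @export
dose_regimen <- function(dose, tau = 24) {
  if (any(dose <= 0) || any(tau <= 0)) stop("dose and tau must be positive", call. = FALSE)
  list(dose = dose, tau = tau, f = 1)
}

# --- typical and individual parameters -------------------------------------

# vectorized typical parameters for a covariate data frame
# covs needs: ethnicity, lbw, plus any effect columns (dm, old_dm, ...)
typical_params <- function(model, covs) {
  eth <- tolower(as.character(covs$ethnicity))
  if (any(!eth %in% c("indonesian", "korean"))) {
    stop("ethnicity must be 'indonesian' or 'korean'", call. = FALSE)
  }
  lbw <- covs$lbw
  if (any(!is.finite(lbw)) || any(lbw <= 0)) stop("lbw must be positive", call. = FALSE)
  size_cl <- (lbw / model$lbw_ref)^model$allo_cl
  size_v <- (lbw / model$lbw_ref)^model$allo_v
  cl <- ifelse(eth == "indonesian", model$theta[["cl_ind"]], model$theta[["cl_kor"]]) * size_cl
  v <- model$theta[["v"]] * size_v
  for (ef in model$covariates) {
    x <- covs[[ef$column]]
    if (is.null(x)) stop("covariate column '", ef$column, "' missing", call. = FALSE)
    sel <- if (is.na(ef$ethnicity)) rep(TRUE, length(eth)) else eth == ef$ethnicity
    fac <- if (ef$type == "categorical") {
      1 + ef$value * (as.numeric(x) * sel)
    } else {
      ifelse(sel, (x / ef$median)^ef$value, 1)
    }
    if (ef$param == "cl") cl <- cl * fac else v <- v * fac
  }
  data.frame(cl = cl, v = v, ka = rep(model$theta[["ka"]], length(cl)))
}

#' Individual structural PK parameters
#'
#' Combines the typical (covariate-determined) parameter values with a
#' subject's log-normal random effects: `CL/F = TVCL * exp(eta_cl)`,
#' `Vd/F = TVV * exp(eta_v)`; Ka carries no IIV.
#'
#' @param model a [pza_model()].
#' @param covs a one-row data frame (or list) with at least `ethnicity`,
#'   `lbw`, and the covariate columns the model's effects reference
#'   (`dm`, `old_dm` for the default model).
#' @param eta numeric vector `c(eta_cl, eta_v)` of random effects; default 0.
#' @return list of class `pza_params` with `cl_f` (L/h), `v_f` (L),
#'   `ka` (1/h) and `ke = cl_f / v_f` (1/h).
#' @examples
#' m <- pza_model()
#' individual_params(m, list(ethnicity = "korean", lbw = 45, dm = 1, old_dm = 1))
#' @export
individual_params <- function(model, covs, eta = c(0, 0)) {
  covs <- as.data.frame(covs, stringsAsFactors = FALSE)
  if (nrow(covs) != 1) stop("`covs` must describe a single subject", call. = FALSE)
  if (length(eta) != 2) stop("`eta` must be c(eta_cl, eta_v)", call. = FALSE)
  tv <- typical_params(model, covs)
  cl <- tv$cl * exp(eta[1])
  v <- tv$v * exp(eta[2])
  structure(
    list(cl_f = cl, v_f = v, ka = tv$ka, ke = cl / v),
    class = "pza_params"
  )
}

# --- steady-state concentration, AUC, Cmax ---------------------------------

# fully vectorized steady-state concentration; handles the ka ~ ke
# degenerate case by the analytic limit to avoid catastrophic cancellation
conc_ss_vec <- function(cl, v, ka, dose, tau, t) {
  n <- max(length(cl), length(v), length(ka), length(dose), length(tau), length(t))
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  dose <- rep_len(dose, n); tau <- rep_len(tau, n); t <- rep_len(t, n)
  ke <- cl / v
  out <- numeric(n)
  deg <- is.finite(ke) & abs(ka - ke) < 1e-8 * ka
  if (any(!deg)) {
    i <- !deg
    eke <- exp(-ke[i] * tau[i]); eka <- exp(-ka[i] * tau[i])
    out[i] <- dose[i] * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) / (1 - eke) - exp(-ka[i] * t[i]) / (1 - eka))
  }
  if (any(deg)) {
    i <- deg
    k <- ka[i]
    e <- exp(-k * tau[i])
    out[i] <- dose[i] * k / v[i] * exp(-k * t[i]) *
      (t[i] / (1 - e) + tau[i] * e / (1 - e)^2)
  }
  pmax(out, 0)
}

#' Steady-state plasma concentration
#'
#' Closed-form steady-state concentration of the one-compartment first-order
#' absorption model under repeated dosing every `tau` hours (superposition of
#' the single-dose solution).
#'
#' @param params structural parameters ([individual_params()] result, or any
#'   list with `cl_f`, `v_f`, `ka`).
#' @param regimen a [dose_regimen()].
#' @param t time after the last dose, h; vectorized; must lie in `[0, tau]`.
#' @return concentration in mg/L.
#' @export
conc_ss <- function(params, regimen, t) {
  if (any(t < 0) || any(t > regimen$tau)) {
    stop("`t` must lie within [0, tau]", call. = FALSE)
  }
  conc_ss_vec(params$cl_f, params$v_f, params$ka, regimen$dose, regimen$tau, t)
}

#' Steady-state AUC over one dosing interval
#'
#' At steady state the area under the curve over a dosing interval equals
#' `dose / (CL/F)`, independent of Ka and Vd/F.
#'
#' @inheritParams conc_ss
#' @return AUC over `[0, tau]` in mg.h/L.
#' @export
auc_ss <- function(params, regimen) {
  regimen$dose / params$cl_f
}

#' Steady-state Cmax and Tmax
#'
#' Location of the within-interval maximum. For `ka != ke` the root of
#' `dC/dt = 0` has the closed form
#' `tmax = log(ka (1 - exp(-ke tau)) / (ke (1 - exp(-ka tau)))) / (ka - ke)`;
#' in the degenerate `ka ~ ke` case, or if the root falls outside the
#' interval, a dense-grid + local refinement fallback is used.
#'
#' @inheritParams conc_ss
#' @return list with `cmax` (mg/L) and `tmax` (h).
#' @export
cmax_tmax_ss <- function(params, regimen) {
  ka <- params$ka; ke <- params$cl_f / params$v_f; tau <- regimen$tau
  if (abs(ka - ke) >= 1e-8 * ka) {
    tmax <- log(ka * (1 - exp(-ke * tau)) / (ke * (1 - exp(-ka * tau)))) / (ka - ke)
  } else {
    tmax <- NA_real_
  }
  if (!is.finite(tmax) || tmax < 0 || tmax > tau) {
    grid <- seq(0, tau, length.out = 2001)
    cg <- conc_ss(params, regimen, grid)
    i <- which.max(cg)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(x) conc_ss(params, regimen, x),
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-10
    )
    tmax <- opt$maximum
  }
  list(cmax = conc_ss(params, regimen, tmax), tmax = tmax)
}

# vectorized Cmax for Monte Carlo simulation (non-degenerate branch with
# per-element grid fallback only where needed)
cmax_ss_vec <- function(cl, v, ka, dose, tau) {
  n <- max(length(cl), length(v), length(ka), length(dose), length(tau))
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  dose <- rep_len(dose, n); tau <- rep_len(tau, n)
  ke <- cl / v
  ok <- abs(ka - ke) >= 1e-8 * ka
  tmax <- rep(NA_real_, n)
  tmax[ok] <- log(ka[ok] * (1 - exp(-ke[ok] * tau[ok])) /
    (ke[ok] * (1 - exp(-ka[ok] * tau[ok])))) / (ka[ok] - ke[ok])
  bad <- !ok | !is.finite(tmax) | tmax < 0 | tmax > tau
  out <- numeric(n)
  if (any(!bad)) {
    i <- !bad
    out[i] <- conc_ss_vec(cl[i], v[i], ka[i], dose[i], tau[i], tmax[i])
  }
  for (j in which(bad)) {
    p <- list(cl_f = cl[j], v_f = v[j], ka = ka[j])
    out[j] <- cmax_tmax_ss(p, dose_regimen(dose[j], tau[j]))$cmax
  }
  out
}
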