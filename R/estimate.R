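# --- dataset preparation ----------------------------------------------------

# flatten an nm_dataset into the structures the likelihood engine needs:
# usable observations (EVID 0, MDV 0, not BLQ) and per-subject covariates
prepare_nm <- function(ds) {
  obs <- ds[ds$EVID == 0 & ds$MDV == 0 & (is.na(ds$BLQ) | ds$BLQ == 0), , drop = FALSE]
  if (nrow(obs) == 0) stop("dataset has no usable observations", call. = FALSE)
  covs <- nm_covariates(ds)
  covs <- covs[covs$subject_id %in% unique(obs$ID), , drop = FALSE]
  rownames(covs) <- NULL
  isubj <- match(obs$ID, covs$subject_id)
  if (any(is.na(covs$dose))) {
    stop("subject(s) without a dose record: ",
      paste(covs$subject_id[is.na(covs$dose)], collapse = ", "),
      call. = FALSE
    )
  }
  n_obs <- tabulate(isubj, nbins = nrow(covs))
  list(
    y = obs$DV, t = obs$TIME, isubj = isubj,
    dose_obs = covs$dose[isubj],
    covs = covs, n_subj = nrow(covs), n_obs = n_obs,
    eth = tolower(covs$ethnicity)
  )
}

# per-subject joint -2 log density ("g") at the given random effects;
# st carries the prepared data plus current model-derived quantities
engine_g <- function(st, eta_cl, eta_v) {
  cl <- st$cl_tv * exp(eta_cl)
  v <- st$v_tv * exp(eta_v)
  f <- conc_ss_vec(cl[st$isubj], v[st$isubj], st$ka[st$isubj], st$dose_obs, 24, st$t)
  # extreme random effects explored by the line search can overflow the
  # closed form; a huge-but-finite penalty makes backtracking reject them
  f[!is.finite(f)] <- 1e10
  rss <- rowsum_by((st$y - f)^2, st$isubj, st$n_subj)
  rss / st$sigma2 + st$n_obs * log(2 * pi * st$sigma2) +
    st$a_cl * eta_cl^2 / st$om_cl1 + st$a_v * eta_v^2 / st$om_v1 +
    st$a_cl * log(2 * pi * st$om_cl1) + st$a_v * log(2 * pi * st$om_v1)
}

rowsum_by <- function(x, g, n) {
  rs <- rowsum(x, g)
  out <- numeric(n)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# vectorized-across-subjects damped Newton for the inner (conditional-mode)
# problem; finite-difference gradients/Hessians with a 9-point stencil
inner_solve <- function(st, eta_cl, eta_v, tol = 1e-8, maxit = 100L) {
  h <- 5e-4
  # start each subject from the better of the supplied (warm-start) point
  # and the prior mode: a stale warm start after an extreme outer-optimizer
  # excursion must not strand the Newton iteration on the wrong mode
  if (any(eta_cl != 0) || any(eta_v != 0)) {
    g_warm <- engine_g(st, eta_cl, eta_v)
    g_zero <- engine_g(st, numeric(st$n_subj), numeric(st$n_subj))
    use_zero <- !is.finite(g_warm) | g_zero < g_warm
    eta_cl[use_zero] <- 0
    eta_v[use_zero] <- 0
  }
  g0 <- engine_g(st, eta_cl, eta_v)
  active <- rep(TRUE, st$n_subj)
  d1 <- d2 <- h11 <- h22 <- h12 <- numeric(st$n_subj)
  for (it in seq_len(maxit)) {
    gpc <- engine_g(st, eta_cl + h, eta_v)
    gmc <- engine_g(st, eta_cl - h, eta_v)
    gpv <- engine_g(st, eta_cl, eta_v + h)
    gmv <- engine_g(st, eta_cl, eta_v - h)
    gpp <- engine_g(st, eta_cl + h, eta_v + h)
    gpm <- engine_g(st, eta_cl + h, eta_v - h)
    gmp <- engine_g(st, eta_cl - h, eta_v + h)
    gmm <- engine_g(st, eta_cl - h, eta_v - h)
    d1 <- (gpc - gmc) / (2 * h) * st$a_cl
    d2 <- (gpv - gmv) / (2 * h) * st$a_v
    h11 <- (gpc - 2 * g0 + gmc) / h^2
    h22 <- (gpv - 2 * g0 + gmv) / h^2
    h12 <- (gpp - gpm - gmp + gmm) / (4 * h^2) * st$a_cl * st$a_v
    # regularize to a positive-definite 2x2 where needed
    lam <- pmax(0, -0.5 * (h11 + h22 - sqrt(pmax((h11 - h22)^2 + 4 * h12^2, 0)))) + 1e-8
    h11r <- h11 + lam
    h22r <- h22 + lam
    det <- pmax(h11r * h22r - h12^2, 1e-12)
    s_cl <- -(h22r * d1 - h12 * d2) / det * st$a_cl
    s_v <- -(h11r * d2 - h12 * d1) / det * st$a_v
    # trust region: random effects live on the log scale, steps beyond ~3
    # are never useful and can overflow the structural model
    snorm <- sqrt(s_cl^2 + s_v^2)
    capf <- ifelse(snorm > 3, 3 / snorm, 1)
    s_cl <- s_cl * capf
    s_v <- s_v * capf
    gnorm <- pmax(abs(d1), abs(d2))
    active <- gnorm > tol
    if (!any(active)) break
    # backtracking line search, vectorized over subjects; steps that never
    # achieve a decrease are rejected outright
    step <- ifelse(active, 1, 0)
    for (ls in 1:25) {
      g1 <- engine_g(st, eta_cl + step * s_cl, eta_v + step * s_v)
      worse <- active & (!is.finite(g1) | g1 > g0 + 1e-12)
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    step[worse] <- 0
    eta_cl <- eta_cl + step * s_cl
    eta_v <- eta_v + step * s_v
    g0 <- engine_g(st, eta_cl, eta_v)
  }
  # Laplace per-subject -2 log marginal likelihood; the Hessian used is the
  # curvature of g/2 (i.e., of -log joint density)
  d <- st$a_cl + st$a_v
  det_g <- h11 * h22 - h12^2
  corr <- ifelse(d == 2, log(pmax(det_g, 1e-300) / 4) - 2 * log(2 * pi),
    ifelse(d == 1 & st$a_cl == 1, log(pmax(h11, 1e-300) / 2) - log(2 * pi),
      ifelse(d == 1, log(pmax(h22, 1e-300) / 2) - log(2 * pi), 0)
    )
  )
  list(
    eta_cl = eta_cl, eta_v = eta_v, g = g0, neg2ll = g0 + corr,
    h11 = h11, h12 = h12, h22 = h22, grad_max = max(abs(c(d1, d2)))
  )
}

# assemble engine state from a model and prepared data
engine_state <- function(model, prep) {
  if (model$sigma_add <= 0) {
    stop("additive residual SD must be positive for likelihood evaluation",
      call. = FALSE
    )
  }
  tv <- typical_params(model, prep$covs)
  om_cl <- ifelse(prep$eth == "indonesian", model$omega2[["cl_ind"]], model$omega2[["cl_kor"]])
  om_v <- rep(model$omega2[["v"]], prep$n_subj)
  st <- prep
  st$cl_tv <- tv$cl
  st$v_tv <- tv$v
  st$ka <- tv$ka
  st$sigma2 <- model$sigma_add^2
  st$a_cl <- as.numeric(om_cl > 0)
  st$a_v <- as.numeric(om_v > 0)
  st$om_cl1 <- ifelse(om_cl > 0, om_cl, 1)
  st$om_v1 <- ifelse(om_v > 0, om_v, 1)
  st
}

#' Per-subject Laplace -2 log marginal likelihood
#'
#' Optimizes the joint density over the subject's random effects (Newton with
#' line search) and applies the Laplace approximation to the marginal
#' likelihood. With a purely additive residual error the interaction term of
#' the FOCE-I objective is constant in the random effects, so this Laplace
#' objective coincides with FOCE-I up to curvature terms.
#'
#' @param model a [pza_model()].
#' @param records `nm_dataset` rows for one subject (dose + observations).
#' @param method approximation method; only `"laplace"`.
#' @return list with `value` (-2 log marginal likelihood contribution,
#'   n log(2 pi) constant included), `eta_hat` (conditional mode, c(cl, v)),
#'   and `hessian` (2x2 curvature of the negative log joint density at the
#'   mode).
#' @export
subject_neg2ll <- function(model, records, method = c("laplace")) {
  method <- match.arg(method)
  prep <- prepare_nm(records)
  if (prep$n_subj != 1) stop("`records` must describe a single subject", call. = FALSE)
  st <- engine_state(model, prep)
  sol <- tryCatch(
    inner_solve(st, 0, 0),
    error = function(e) {
      stop("likelihood evaluation failed for subject ", prep$covs$subject_id[1],
        ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (!is.finite(sol$neg2ll)) {
    stop("non-finite likelihood for subject ", prep$covs$subject_id[1], call. = FALSE)
  }
  list(
    value = sol$neg2ll,
    eta_hat = c(cl = sol$eta_cl, v = sol$eta_v),
    hessian = matrix(c(sol$h11, sol$h12, sol$h12, sol$h22) / 2, 2, 2)
  )
}

#' Objective function value of a model on a dataset
#'
#' Sum of the per-subject Laplace -2 log marginal likelihoods. The additive
#' `n log(2 pi)` constant is included, so absolute OFVs are comparable only
#' within this package; differences between nested models are convention-free.
#'
#' @param model a [pza_model()].
#' @param dataset an `nm_dataset`.
#' @return the OFV (dimensionless).
#' @export
ofv <- function(model, dataset) {
  prep <- prepare_nm(dataset)
  st <- engine_state(model, prep)
  sol <- inner_solve(st, numeric(prep$n_subj), numeric(prep$n_subj))
  sum(sol$neg2ll)
}

#' Likelihood ratio test p-value
#'
#' Upper-tail chi-square probability for a drop in OFV between nested models.
#'
#' @param delta_ofv OFV decrease (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return p-value.
#' @examples
#' lrt(3.84, 1) # ~0.05, the forward-inclusion threshold
#' lrt(7.88, 1) # ~0.005, the backward-elimination threshold
#' @export
lrt <- function(delta_ofv, df = 1) {
  if (any(delta_ofv < 0)) stop("`delta_ofv` must be non-negative", call. = FALSE)
  if (any(df < 1)) stop("`df` must be >= 1", call. = FALSE)
  stats::pchisq(delta_ofv, df = df, lower.tail = FALSE)
}

#' Shrinkage of empirical Bayes estimates
#'
#' `(1 - SD(eta_hat) / omega) * 100` percent, with the SD computed with
#' denominator n - 1. Values near 100\% indicate uninformative individual
#' data.
#'
#' @param ebes vector of empirical Bayes estimates for one random effect.
#' @param omega population SD of the random effect (> 0).
#' @return shrinkage in percent.
#' @export
eta_shrinkage <- function(ebes, omega) {
  if (!is.finite(omega) || omega <= 0) {
    stop("`omega` must be positive; shrinkage is undefined at omega = 0",
      call. = FALSE
    )
  }
  (1 - stats::sd(ebes) / omega) * 100
}

# --- parameter vector mapping ----------------------------------------------

par_names <- function(model) {
  c(
    "cl_ind", "cl_kor", "v", "ka",
    if (length(model$covariates)) paste0("eff_", names(model$covariates)),
    "omega2_cl_ind", "omega2_cl_kor", "omega2_v", "sigma_add"
  )
}

model_to_par <- function(model) {
  p <- c(
    cl_ind = unname(model$theta[["cl_ind"]]),
    cl_kor = unname(model$theta[["cl_kor"]]),
    v = unname(model$theta[["v"]]),
    ka = unname(model$theta[["ka"]])
  )
  for (nm in names(model$covariates)) {
    p[paste0("eff_", nm)] <- model$covariates[[nm]]$value
  }
  p["omega2_cl_ind"] <- unname(model$omega2[["cl_ind"]])
  p["omega2_cl_kor"] <- unname(model$omega2[["cl_kor"]])
  p["omega2_v"] <- unname(model$omega2[["v"]])
  p["sigma_add"] <- model$sigma_add
  p
}

par_to_model <- function(p, template) {
  m <- template
  m$theta[["cl_ind"]] <- p[["cl_ind"]]
  m$theta[["cl_kor"]] <- p[["cl_kor"]]
  m$theta[["v"]] <- p[["v"]]
  m$theta[["ka"]] <- p[["ka"]]
  for (nm in names(m$covariates)) {
    m$covariates[[nm]]$value <- p[[paste0("eff_", nm)]]
  }
  m$omega2[["cl_ind"]] <- p[["omega2_cl_ind"]]
  m$omega2[["cl_kor"]] <- p[["omega2_cl_kor"]]
  m$omega2[["v"]] <- p[["omega2_v"]]
  m$sigma_add <- p[["sigma_add"]]
  m
}

# positivity-constrained parameters are estimated on the log scale;
# categorical effects and power exponents are estimated untransformed
is_log_scale <- function(nms) !grepl("^eff_", nms)

#' Fit the population model by Laplace marginal likelihood
#'
#' Maximizes the Laplace-approximated marginal likelihood over the model's
#' fixed effects, covariate effects, IIV variances and residual SD. Positive
#' parameters are estimated on the log scale; covariate effects (which may be
#' negative) untransformed. The allometric exponents and the absent Ka IIV
#' are structural constants and are never estimated. Standard errors come
#' from a finite-difference Hessian of OFV/2 in the natural parameter space.
#'
#' @param model0 a [pza_model()] providing the structure and initial values.
#' @param dataset an `nm_dataset` (BLLoQ records should already be discarded;
#'   any remaining flagged records are ignored).
#' @param fixed character vector of parameter names to hold at their initial
#'   values (see the `estimates` names of the result); e.g.
#'   `c("ka", "omega2_v")`.
#' @param se compute standard errors (default TRUE; skipping them speeds up
#'   bootstrap and selection loops).
#' @param control list: `rel.tol` (outer relative OFV tolerance, default
#'   1e-8), `iter.max`, `eval.max`.
#' @return an object of class `pza_fit`: `model` (updated [pza_model()]),
#'   `estimates`, `se`, `rse` (percent), `ofv`, `ebes` (per-subject
#'   conditional modes), `shrinkage` (percent, per random effect),
#'   `convergence` (logical), `n_subjects`, `n_obs`, `fixed`, `trace`.
#' @export
fit <- function(model0, dataset, fixed = character(), se = TRUE,
                control = list()) {
  ctl <- utils::modifyList(
    list(rel.tol = 1e-8, iter.max = 300L, eval.max = 1500L), control
  )
  prep <- prepare_nm(dataset)
  p0 <- model_to_par(model0)
  nms <- names(p0)
  bad <- setdiff(fixed, nms)
  if (length(bad)) stop("unknown parameter(s) in `fixed`: ", paste(bad, collapse = ", "), call. = FALSE)
  free <- setdiff(nms, fixed)
  logs <- is_log_scale(free)
  if (any(p0[free][logs] <= 0)) {
    stop("initial values for log-scale parameters must be positive", call. = FALSE)
  }
  # warm-started conditional modes persist across outer iterations
  cache <- new.env(parent = emptyenv())
  cache$eta_cl <- numeric(prep$n_subj)
  cache$eta_v <- numeric(prep$n_subj)
  n_eval <- 0L

  ofv_at <- function(p_nat, warm = TRUE) {
    p <- p0
    p[free] <- p_nat
    m <- par_to_model(p, model0)
    st <- engine_state(m, prep)
    sol <- inner_solve(
      st,
      if (warm) cache$eta_cl else numeric(prep$n_subj),
      if (warm) cache$eta_v else numeric(prep$n_subj)
    )
    if (all(is.finite(sol$neg2ll))) {
      cache$eta_cl <- sol$eta_cl
      cache$eta_v <- sol$eta_v
    }
    sum(sol$neg2ll)
  }
  obj <- function(x) {
    p_nat <- ifelse(logs, exp(x), x)
    n_eval <<- n_eval + 1L
    val <- tryCatch(ofv_at(p_nat), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  if (length(free)) {
    x0 <- ifelse(logs, log(p0[free]), p0[free])
    # explicit central-difference gradient: the inner solver's adaptive
    # termination leaves ~1e-9 noise on the OFV, so the optimizer's own
    # ~1e-8 forward steps are unreliable
    grad <- function(x) {
      h <- 1e-5
      vapply(seq_along(x), function(j) {
        xp <- x; xp[j] <- x[j] + h
        xm <- x; xm[j] <- x[j] - h
        (obj(xp) - obj(xm)) / (2 * h)
      }, numeric(1))
    }
    opt <- stats::nlminb(x0, obj,
      gradient = grad,
      control = list(
        rel.tol = ctl$rel.tol, iter.max = ctl$iter.max, eval.max = ctl$eval.max
      )
    )
  } else {
    # evaluation-only "fit": every parameter held fixed; still produces the
    # OFV, conditional modes and shrinkage at the supplied values
    opt <- list(par = numeric(0), convergence = 0L, message = "all parameters fixed", iterations = 0L)
  }
  p_hat <- p0
  p_hat[free] <- ifelse(logs, exp(opt$par), opt$par)
  m_hat <- par_to_model(p_hat, model0)
  st <- engine_state(m_hat, prep)
  sol <- inner_solve(st, cache$eta_cl, cache$eta_v)
  ofv_hat <- sum(sol$neg2ll)

  se_vec <- rse_vec <- stats::setNames(rep(NA_real_, length(nms)), nms)
  if (se && length(free)) {
    H <- tryCatch(
      pracma::hessian(function(p_nat) ofv_at(p_nat) / 2, p_hat[free]),
      error = function(e) NULL
    )
    if (!is.null(H)) {
      cov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(cov)) {
        dg <- diag(cov)
        dg[dg < 0] <- NA_real_
        se_vec[free] <- sqrt(dg)
        rse_vec[free] <- 100 * se_vec[free] / abs(p_hat[free])
      }
    }
  }
  ebes <- data.frame(
    subject_id = prep$covs$subject_id,
    ethnicity = prep$eth,
    eta_cl = sol$eta_cl, eta_v = sol$eta_v,
    stringsAsFactors = FALSE
  )
  shr <- c(
    cl_ind = if (m_hat$omega2[["cl_ind"]] > 0 && any(prep$eth == "indonesian")) {
      eta_shrinkage(sol$eta_cl[prep$eth == "indonesian"], sqrt(m_hat$omega2[["cl_ind"]]))
    } else {
      NA_real_
    },
    cl_kor = if (m_hat$omega2[["cl_kor"]] > 0 && any(prep$eth == "korean")) {
      eta_shrinkage(sol$eta_cl[prep$eth == "korean"], sqrt(m_hat$omega2[["cl_kor"]]))
    } else {
      NA_real_
    },
    v = if (m_hat$omega2[["v"]] > 0) eta_shrinkage(sol$eta_v, sqrt(m_hat$omega2[["v"]])) else NA_real_
  )
  structure(
    list(
      model = m_hat, estimates = p_hat, se = se_vec, rse = rse_vec,
      ofv = ofv_hat, ebes = ebes, shrinkage = shr,
      convergence = opt$convergence == 0, message = opt$message,
      n_subjects = prep$n_subj, n_obs = length(prep$y),
      fixed = fixed,
      trace = list(iterations = opt$iterations, evaluations = n_eval)
    ),
    class = "pza_fit"
  )
}

#' @export
print.pza_fit <- function(x, ...) {
  cat(sprintf(
    "Population PK fit: OFV %.3f, %d subjects / %d observations, %s\n",
    x$ofv, x$n_subjects, x$n_obs,
    if (x$convergence) "converged" else "NOT CONVERGED"
  ))
  tab <- data.frame(
    estimate = signif(x$estimates, 4),
    rse_pct = signif(x$rse, 3)
  )
  print(tab)
  cat(
    "eta-shrinkage (%):",
    paste(names(x$shrinkage), signif(x$shrinkage, 3), sep = "=", collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' Write a fit summary as structured, diffable text
#'
#' @param fit a `pza_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ofv: %.6f", fit$ofv),
    sprintf("converged: %s", fit$convergence),
    sprintf("n_subjects: %d", fit$n_subjects),
    sprintf("n_obs: %d", fit$n_obs),
    "",
    "parameter\testimate\tse\trse_pct"
  ), con)
  for (nm in names(fit$estimates)) {
    writeLines(sprintf(
      "%s\t%.8g\t%.8g\t%.6g",
      nm, fit$estimates[[nm]], fit$se[[nm]], fit$rse[[nm]]
    ), con)
  }
  writeLines(c("", "shrinkage_pct:"), con)
  for (nm in names(fit$shrinkage)) {
    writeLines(sprintf("  %s: %.6g", nm, fit$shrinkage[[nm]]), con)
  }
  invisible(path)
}

# --- stepwise covariate selection ------------------------------------------

#' Stepwise covariate selection (forward inclusion, backward elimination)
#'
#' Forward pass: candidate effects are added one at a time, the most
#' significant first; the first addition requires an OFV drop of at least
#' 3.84 (p < 0.05, 1 df), subsequent additions 6.63 (p < 0.01). Backward
#' pass: each retained covariate is deleted in turn and kept only if its
#' deletion raises the OFV by more than 7.88 (p < 0.005). Candidates whose
#' fit fails are skipped and logged in the trace.
#'
#' @param base_model a [pza_model()] without the candidate effects.
#' @param candidates list of covariate-effect descriptors (as in
#'   [pza_model()]'s `covariates`), with `value` the initial effect size.
#' @param dataset an `nm_dataset`.
#' @param fixed parameters held fixed in every fit (passed to [fit()]).
#' @param control passed to [fit()].
#' @return list with `model` (final fitted model), `fit` (final `pza_fit`),
#'   and `trace` (data frame: stage, candidate, delta_ofv, p_value, decision).
#' @export
stepwise_selection <- function(base_model, candidates, dataset,
                               fixed = character(), control = list()) {
  trace <- data.frame(
    stage = character(), candidate = character(), delta_ofv = numeric(),
    p_value = numeric(), decision = character(), stringsAsFactors = FALSE
  )
  log_row <- function(stage, cand, dofv, p, dec) {
    trace[nrow(trace) + 1L, ] <<- list(stage, cand, dofv, p, dec)
  }
  candidates <- validate_covariate_effects(candidates)
  cur_model <- base_model
  cur_fit <- fit(cur_model, dataset, fixed = fixed, se = FALSE, control = control)
  cur_model <- cur_fit$model
  if (length(candidates) == 0) {
    return(list(model = cur_model, fit = cur_fit, trace = trace))
  }
  remaining <- candidates
  n_added <- 0L
  # forward inclusion
  repeat {
    thr <- if (n_added == 0) stats::qchisq(0.95, 1) else stats::qchisq(0.99, 1)
    best <- NULL
    results <- list()
    for (nm in names(remaining)) {
      cand_model <- cur_model
      cand_model$covariates <- validate_covariate_effects(
        c(cur_model$covariates, remaining[nm])
      )
      cand_fit <- tryCatch(
        fit(cand_model, dataset, fixed = fixed, se = FALSE, control = control),
        error = function(e) NULL
      )
      if (is.null(cand_fit) || !is.finite(cand_fit$ofv)) {
        log_row("forward", nm, NA_real_, NA_real_, "skipped (fit failed)")
        next
      }
      dofv <- cur_fit$ofv - cand_fit$ofv
      results[[nm]] <- list(fit = cand_fit, dofv = dofv)
    }
    if (length(results) == 0) break
    dofvs <- vapply(results, function(r) r$dofv, numeric(1))
    bi <- which.max(dofvs)
    for (nm in names(results)) {
      if (nm == names(results)[bi]) next
      log_row(
        "forward", nm, dofvs[[nm]], lrt(max(dofvs[[nm]], 0), 1),
        "not selected this step"
      )
    }
    best_nm <- names(results)[bi]
    best_dofv <- dofvs[[bi]]
    if (best_dofv >= thr) {
      log_row("forward", best_nm, best_dofv, lrt(max(best_dofv, 0), 1), "added")
      cur_fit <- results[[bi]]$fit
      cur_model <- cur_fit$model
      remaining[[best_nm]] <- NULL
      n_added <- n_added + 1L
      if (length(remaining) == 0) break
    } else {
      log_row(
        "forward", best_nm, best_dofv, lrt(max(best_dofv, 0), 1),
        "rejected (below threshold)"
      )
      break
    }
  }
  # backward elimination
  added_names <- intersect(names(candidates), names(cur_model$covariates))
  thr_back <- stats::qchisq(0.995, 1)
  for (nm in added_names) {
    red_model <- cur_model
    red_model$covariates[[nm]] <- NULL
    red_fit <- tryCatch(
      fit(red_model, dataset, fixed = fixed, se = FALSE, control = control),
      error = function(e) NULL
    )
    if (is.null(red_fit)) {
      log_row("backward", nm, NA_real_, NA_real_, "kept (reduced fit failed)")
      next
    }
    dofv <- red_fit$ofv - cur_fit$ofv # OFV increase on deletion
    if (dofv > thr_back) {
      log_row("backward", nm, dofv, lrt(max(dofv, 0), 1), "kept")
    } else {
      log_row("backward", nm, dofv, lrt(max(dofv, 0), 1), "removed")
      cur_fit <- red_fit
      cur_model <- red_fit$model
    }
  }
  final_fit <- fit(cur_model, dataset, fixed = fixed, se = TRUE, control = control)
  list(model = final_fit$model, fit = final_fit, trace = trace)
}

# --- bootstrap --------------------------------------------------------------

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement, stratified by ethnicity (preserving
#' the per-stratum subject counts), refits the model on each resample, and
#' returns percentile confidence intervals. Non-converged or failed
#' replicates are counted and excluded.
#'
#' @param model a fitted [pza_model()] (used as structure and initial values).
#' @param dataset an `nm_dataset`.
#' @param n_resamples number of bootstrap replicates.
#' @param seed integer seed.
#' @param fixed,control passed to [fit()].
#' @return list with `summary` (data frame: parameter, median, lower 2.5\%,
#'   upper 97.5\%), `estimates` (replicate x parameter matrix), `n_failed`.
#' @export
bootstrap <- function(model, dataset, n_resamples = 200, seed = 1L,
                      fixed = character(), control = list()) {
  stopifnot(n_resamples >= 1)
  covs <- nm_covariates(dataset)
  eth <- tolower(covs$ethnicity)
  strata <- split(covs$subject_id, eth)
  p_names <- names(model_to_par(model))
  est <- matrix(NA_real_, n_resamples, length(p_names),
    dimnames = list(NULL, p_names)
  )
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      ids <- unlist(lapply(strata, function(s) sample(s, length(s), replace = TRUE)))
      parts <- lapply(seq_along(ids), function(i) {
        rows <- dataset[dataset$ID == ids[i], , drop = FALSE]
        rows$ID <- sprintf("B%04d", i)
        rows
      })
      bds <- do.call(rbind, parts)
      class(bds) <- class(dataset)
      attr(bds, "lloq") <- attr(dataset, "lloq")
      bfit <- tryCatch(
        fit(model, bds, fixed = fixed, se = FALSE, control = control),
        error = function(e) NULL
      )
      if (is.null(bfit) || !bfit$convergence) {
        n_failed <- n_failed + 1L
        next
      }
      est[b, ] <- bfit$estimates[p_names]
    }
  })
  ok <- stats::complete.cases(est)
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
    probs = c(0.5, 0.025, 0.975), names = FALSE
  )
  summary <- data.frame(
    parameter = p_names,
    median = qs[1, ], lower = qs[2, ], upper = qs[3, ],
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(summary = summary, estimates = est[ok, , drop = FALSE], n_failed = n_failed)
}
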