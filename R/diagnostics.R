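# finite-difference Jacobian of per-observation predictions wrt (eta_cl, eta_v)
pred_jacobian <- function(st, eta_cl, eta_v, h = 1e-5) {
  pr <- function(ec, ev) {
    conc_ss_vec(
      st$cl_tv[st$isubj] * exp(ec[st$isubj]),
      st$v_tv[st$isubj] * exp(ev[st$isubj]),
      st$ka[st$isubj], st$dose_obs, 24, st$t
    )
  }
  g1 <- (pr(eta_cl + h, eta_v) - pr(eta_cl - h, eta_v)) / (2 * h)
  g2 <- (pr(eta_cl, eta_v + h) - pr(eta_cl, eta_v - h)) / (2 * h)
  cbind(g1, g2)
}

#' Goodness-of-fit table
#'
#' Per-observation population predictions (PRED, at zero random effects),
#' individual predictions (IPRED, at the conditional modes), individual
#' weighted residuals `IWRES = (DV - IPRED) / sigma`, and conditional
#' weighted residuals (CWRES) from the first-order expansion of the model
#' about the conditional modes, using each subject's marginal covariance
#' `G Omega G' + sigma^2 I`.
#'
#' @param model the fitted [pza_model()].
#' @param fit the corresponding `pza_fit` (source of the conditional modes).
#' @param dataset the `nm_dataset` that was fitted.
#' @return data frame: `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `IWRES`, `CWRES`.
#' @export
gof_table <- function(model, fit, dataset) {
  prep <- prepare_nm(dataset)
  st <- engine_state(model, prep)
  i <- match(prep$covs$subject_id, fit$ebes$subject_id)
  if (any(is.na(i))) {
    stop("subject(s) missing empirical Bayes estimates: ",
      paste(prep$covs$subject_id[is.na(i)], collapse = ", "),
      call. = FALSE
    )
  }
  eta_cl <- fit$ebes$eta_cl[i]
  eta_v <- fit$ebes$eta_v[i]
  zero <- numeric(prep$n_subj)
  pred <- conc_ss_vec(
    st$cl_tv[st$isubj], st$v_tv[st$isubj], st$ka[st$isubj],
    st$dose_obs, 24, st$t
  )
  ipred <- conc_ss_vec(
    (st$cl_tv * exp(eta_cl))[st$isubj], (st$v_tv * exp(eta_v))[st$isubj],
    st$ka[st$isubj], st$dose_obs, 24, st$t
  )
  iwres <- (st$y - ipred) / model$sigma_add
  G <- pred_jacobian(st, eta_cl, eta_v)
  om_cl <- ifelse(prep$eth == "indonesian", model$omega2[["cl_ind"]], model$omega2[["cl_kor"]])
  cwres <- numeric(length(st$y))
  for (s in seq_len(prep$n_subj)) {
    rows <- which(st$isubj == s)
    Gs <- G[rows, , drop = FALSE]
    Om <- diag(c(om_cl[s], model$omega2[["v"]]), 2)
    V <- Gs %*% Om %*% t(Gs) + diag(model$sigma_add^2, length(rows))
    r <- st$y[rows] - ipred[rows] + Gs %*% c(eta_cl[s], eta_v[s])
    cwres[rows] <- backsolve(chol(V), r, transpose = TRUE)
  }
  data.frame(
    ID = prep$covs$subject_id[st$isubj], TIME = st$t, DV = st$y,
    PRED = pred, IPRED = ipred, IWRES = iwres, CWRES = cwres,
    stringsAsFactors = FALSE
  )
}

# equal-count time bins; bins with fewer than min_n observations are merged
# with their neighbor
make_bins <- function(t, n_bins, min_n = 5) {
  qs <- unique(stats::quantile(t, probs = seq(0, 1, length.out = n_bins + 1)))
  qs[1] <- min(t) - 1e-9
  qs[length(qs)] <- max(t) + 1e-9
  repeat {
    bin <- cut(t, qs, labels = FALSE)
    cnt <- tabulate(bin, nbins = length(qs) - 1)
    small <- which(cnt < min_n)
    if (length(small) == 0 || length(qs) <= 2) break
    j <- small[1]
    drop <- if (j == 1) 2 else j
    qs <- qs[-drop]
  }
  list(breaks = qs, bin = cut(t, qs, labels = FALSE))
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under its own design (same
#' subjects, covariates, doses and sampling times), prediction-corrects
#' observed and simulated concentrations bin-wise
#' (`pcY = Y * median(PRED_bin) / PRED`), and summarizes the observed 5th /
#' 50th / 95th percentiles per time bin together with the simulated 90\%
#' prediction interval of each percentile.
#'
#' @param model the fitted [pza_model()].
#' @param dataset the `nm_dataset`.
#' @param n_sim number of simulated replicates (>= 100).
#' @param bins number of equal-count time bins (default 8; bins with < 5
#'   observations are merged with a neighbor).
#' @param strata `"none"`, `"dm"` (split by DM flag) or `"olddm"` (split by
#'   the age>=60-with-DM flag).
#' @param seed integer seed.
#' @return list of class `pza_vpc`: one element per stratum, each a data
#'   frame with bin boundaries/midpoints, number of observations, observed
#'   percentiles and simulated lower/upper band per percentile; attribute
#'   `binning` records the bin placement.
#' @export
pc_vpc <- function(model, dataset, n_sim = 500, bins = 8,
                   strata = c("none", "dm", "olddm"), seed = 1L) {
  strata <- match.arg(strata)
  if (n_sim < 100) stop("`n_sim` must be at least 100", call. = FALSE)
  prep <- prepare_nm(dataset)
  st <- engine_state(model, prep)
  pred <- conc_ss_vec(
    st$cl_tv[st$isubj], st$v_tv[st$isubj], st$ka[st$isubj],
    st$dose_obs, 24, st$t
  )
  om_cl <- ifelse(prep$eth == "indonesian", model$omega2[["cl_ind"]], model$omega2[["cl_kor"]])
  n_obs_tot <- length(st$y)
  sims <- with_seed(seed, {
    out <- matrix(0, n_obs_tot, n_sim)
    for (k in seq_len(n_sim)) {
      ec <- stats::rnorm(prep$n_subj, 0, sqrt(om_cl))
      ev <- stats::rnorm(prep$n_subj, 0, sqrt(model$omega2[["v"]]))
      f <- conc_ss_vec(
        (st$cl_tv * exp(ec))[st$isubj], (st$v_tv * exp(ev))[st$isubj],
        st$ka[st$isubj], st$dose_obs, 24, st$t
      )
      out[, k] <- f + stats::rnorm(n_obs_tot, 0, model$sigma_add)
    }
    out
  })
  grp <- switch(strata,
    none = rep("all", n_obs_tot),
    dm = ifelse(prep$covs$dm[st$isubj] == 1, "dm", "non_dm"),
    olddm = ifelse(prep$covs$old_dm[st$isubj] == 1, "old_dm", "other")
  )
  probs <- c(0.05, 0.5, 0.95)
  res <- list()
  for (g in unique(grp)) {
    rows <- which(grp == g)
    bb <- make_bins(st$t[rows], bins)
    bin <- bb$bin
    pc_obs <- st$y[rows]
    pc_sim <- sims[rows, , drop = FALSE]
    med_pred <- stats::ave(pred[rows], bin, FUN = stats::median)
    corr <- med_pred / pred[rows]
    pc_obs <- pc_obs * corr
    pc_sim <- pc_sim * corr
    tab <- lapply(sort(unique(bin)), function(b) {
      in_b <- bin == b
      obs_q <- stats::quantile(pc_obs[in_b], probs, names = FALSE)
      sim_q <- apply(pc_sim[in_b, , drop = FALSE], 2, stats::quantile,
        probs = probs, names = FALSE
      )
      band <- apply(sim_q, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
      data.frame(
        bin = b,
        t_lo = bb$breaks[b], t_hi = bb$breaks[b + 1],
        t_mid = stats::median(st$t[rows][in_b]),
        n = sum(in_b),
        obs_p5 = obs_q[1], obs_p50 = obs_q[2], obs_p95 = obs_q[3],
        sim_p5_lo = band[1, 1], sim_p5_hi = band[2, 1],
        sim_p50_lo = band[1, 2], sim_p50_hi = band[2, 2],
        sim_p95_lo = band[1, 3], sim_p95_hi = band[2, 3]
      )
    })
    res[[g]] <- do.call(rbind, tab)
  }
  structure(res,
    class = "pza_vpc",
    n_sim = n_sim, strata = strata,
    binning = "equal-count bins on observation times, small bins merged"
  )
}
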