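#' MAP empirical Bayes estimate of a subject's random effects
#'
#' Maximizes the joint posterior density of the random effects given the
#' fixed population model and the subject's observed concentrations. This is
#' exactly the inner problem of the marginal-likelihood estimation
#' ([subject_neg2ll()]); the shared conditional-mode solver guarantees the
#' identity. With no usable observations the prior mode (zero) is returned
#' with attribute `no_observations = TRUE`.
#'
#' @param model a [pza_model()].
#' @param records `nm_dataset` rows for one subject.
#' @return named vector `c(cl = eta_cl, v = eta_v)`.
#' @export
map_eta <- function(model, records) {
  usable <- records$EVID == 0 & records$MDV == 0 &
    (is.na(records$BLQ) | records$BLQ == 0)
  if (!any(usable)) {
    out <- c(cl = 0, v = 0)
    attr(out, "no_observations") <- TRUE
    return(out)
  }
  sol <- subject_neg2ll(model, records)
  sol$eta_hat
}

#' Individual steady-state exposure metrics
#'
#' Individual CL/F and Vd/F from the covariates and MAP random effects, the
#' AUC over one dosing interval (`dose / CL`) and the steady-state Cmax at
#' the actual dose, plus the same metrics linearly normalized to a 1200 mg
#' dose for between-subject comparison.
#'
#' @param model a [pza_model()].
#' @param covs one-row covariate data frame (see [individual_params()]).
#' @param eta MAP random effects `c(eta_cl, eta_v)`.
#' @param dose actual once-daily dose, mg.
#' @param ref_dose normalization dose, mg (default 1200).
#' @return one-row data frame: `cl_f`, `v_f`, `auc`, `cmax`, `auc_norm`,
#'   `cmax_norm`, `dose`.
#' @export
individual_exposure <- function(model, covs, eta = c(0, 0), dose, ref_dose = 1200) {
  p <- individual_params(model, covs, eta)
  reg <- dose_regimen(dose)
  auc <- auc_ss(p, reg)
  cmax <- cmax_tmax_ss(p, reg)$cmax
  data.frame(
    cl_f = p$cl_f, v_f = p$v_f, auc = auc, cmax = cmax,
    auc_norm = auc * ref_dose / dose, cmax_norm = cmax * ref_dose / dose,
    dose = dose
  )
}

#' Exposure table for every subject in a dataset
#'
#' Runs MAP estimation per subject and derives exposure metrics at each
#' subject's actual dose.
#'
#' @param model a [pza_model()].
#' @param dataset an `nm_dataset`.
#' @param ref_dose normalization dose, mg.
#' @return data frame, one row per subject: identifiers, covariate flags,
#'   `eta_cl`, `eta_v` and the [individual_exposure()] columns.
#' @export
exposure_table <- function(model, dataset, ref_dose = 1200) {
  covs <- nm_covariates(dataset)
  rows <- lapply(seq_len(nrow(covs)), function(i) {
    rec <- dataset[dataset$ID == covs$subject_id[i], , drop = FALSE]
    eta <- map_eta(model, rec)
    exp_i <- individual_exposure(model, covs[i, , drop = FALSE], eta,
      dose = covs$dose[i], ref_dose = ref_dose
    )
    cbind(
      covs[i, c("subject_id", "ethnicity", "dm", "old_dm"), drop = FALSE],
      data.frame(eta_cl = eta[["cl"]], eta_v = eta[["v"]]),
      exp_i
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subgroup summary of exposure metrics
#'
#' Median and IQR of an exposure metric per group, plus a Welch two-sample
#' t-test on the metric when exactly two non-degenerate groups are present.
#'
#' @param exposures data frame (e.g. from [exposure_table()]).
#' @param grouping name of the grouping column (coerced to factor).
#' @param metric name of the metric column (default `"auc_norm"`).
#' @return list with `summary` (group, n, median, q25, q75) and `test`
#'   (`htest` from [stats::t.test()], or `NULL` if not applicable).
#' @export
subgroup_summary <- function(exposures, grouping, metric = "auc_norm") {
  g <- factor(exposures[[grouping]])
  x <- exposures[[metric]]
  tab <- do.call(rbind, lapply(levels(g), function(lv) {
    xi <- x[g == lv]
    data.frame(
      group = lv, n = length(xi),
      median = stats::median(xi),
      q25 = unname(stats::quantile(xi, 0.25)),
      q75 = unname(stats::quantile(xi, 0.75)),
      stringsAsFactors = FALSE
    )
  }))
  test <- NULL
  if (nlevels(g) == 2 && all(tab$n >= 2) &&
    all(tapply(x, g, function(v) stats::sd(v) > 0))) {
    test <- stats::t.test(x ~ g) # Welch by default
  }
  list(summary = tab, test = test)
}
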