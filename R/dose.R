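#' WHO weight bands and dose grids
#'
#' The four WHO weight bands for first-line TB dosing, their recommended
#' once-daily pyrazinamide doses, and the feasible candidate doses explored
#' for optimization.
#'
#' @return data frame: `label`, `lower` (kg, inclusive), `upper` (kg,
#'   exclusive), `who_dose` (mg).
#' @export
weight_bands <- function() {
  data.frame(
    label = c("<40", "40-54", "55-70", ">70"),
    lower = c(0, 40, 55, 70),
    upper = c(40, 55, 70, Inf),
    who_dose = c(800, 1200, 1600, 2000),
    stringsAsFactors = FALSE
  )
}

#' @rdname weight_bands
#' @export
candidate_doses <- function() c(1000, 1250, 1500, 2000, 2500, 3000)

pta_subgroups <- function() {
  c("indonesian_dm", "indonesian_nondm", "korean_olddm", "korean_other", "mixed")
}

#' Virtual patients for one weight band and covariate subgroup
#'
#' Weights are uniform within the band (open bands truncated to plausible
#' adult limits of 30 and 100 kg); sex and height come from the cohort
#' specification of the relevant ethnicity so lean body weight varies
#' realistically within a band; covariate flags are fixed by the subgroup.
#' Subgroups: `"indonesian_dm"`, `"indonesian_nondm"`, `"korean_olddm"`
#' (every patient diabetic and aged >= 60), `"korean_other"`, or `"mixed"`
#' (both ethnicities with the study's DM / old-DM prevalences).
#'
#' @param spec a [cohort_spec()].
#' @param band one row of [weight_bands()] (or a list with `lower`, `upper`).
#' @param subgroup one of the five subgroup labels.
#' @param n number of virtual patients.
#' @param seed integer seed.
#' @return covariate data frame as from [sample_covariates()] (without labs).
#' @export
band_population <- function(spec = cohort_spec(), band, subgroup, n = 1000, seed = 1L) {
  subgroup <- match.arg(subgroup, pta_subgroups())
  lo <- max(band$lower, 30)
  hi <- min(band$upper, 100)
  if (!(lo < hi)) stop("empty weight band after truncation", call. = FALSE)
  with_seed(seed, {
    eth <- switch(subgroup,
      indonesian_dm = ,
      indonesian_nondm = rep("indonesian", n),
      korean_olddm = ,
      korean_other = rep("korean", n),
      mixed = sample(rep(c("indonesian", "korean"), length.out = n))
    )
    weight <- stats::runif(n, lo, hi)
    sex <- character(n)
    height <- numeric(n)
    age <- numeric(n)
    for (e in unique(eth)) {
      s <- spec[[e]]
      i <- which(eth == e)
      sex[i] <- ifelse(stats::runif(length(i)) < s$male_prop, "male", "female")
      hm <- s$height_male; hf <- s$height_female
      height[i] <- ifelse(sex[i] == "male",
        stats::rnorm(length(i), hm["mean"], hm["sd"]),
        stats::rnorm(length(i), hf["mean"], hf["sd"])
      )
      age[i] <- rlnorm_iqr(length(i), s$age["med"], s$age["q25"], s$age["q75"])
      while (any(age[i] < 18)) {
        j <- i[age[i] < 18]
        age[j] <- rlnorm_iqr(length(j), s$age["med"], s$age["q25"], s$age["q75"])
      }
    }
    dm <- old_dm <- integer(n)
    if (subgroup == "indonesian_dm") {
      dm[] <- 1L
      old_dm <- as.integer(age >= 60)
    } else if (subgroup == "korean_olddm") {
      dm[] <- 1L
      age <- 60 + (age - 18) %% 25 # shift into the >= 60 stratum
      old_dm[] <- 1L
    } else if (subgroup == "mixed") {
      for (e in unique(eth)) {
        s <- spec[[e]]
        i <- which(eth == e)
        old <- age[i] >= 60
        p_old <- if (any(old)) min(1, s$olddm_prev * length(i) / sum(old)) else 0
        p_young <- if (any(!old)) {
          min(1, max(0, s$dm_prev - s$olddm_prev) * length(i) / sum(!old))
        } else {
          0
        }
        dmi <- ifelse(old, stats::runif(length(i)) < p_old, stats::runif(length(i)) < p_young)
        dm[i] <- as.integer(dmi)
        old_dm[i] <- as.integer(dmi & old)
      }
    } else if (subgroup == "korean_other") {
      # diabetic-but-young patients share the reference clearance; keep all
      # patients below the old-DM stratum
      old_dm[] <- 0L
      dm <- as.integer(stats::runif(n) < max(0, spec$korean$dm_prev - spec$korean$olddm_prev))
      age <- pmin(age, 59.5)
    }
    data.frame(
      subject_id = sprintf("V%05d", seq_len(n)),
      ethnicity = eth, sex = sex, age = age, weight = weight, height = height,
      lbw = lbw_boer(sex, weight, height),
      dm = dm, old_dm = old_dm,
      stringsAsFactors = FALSE
    )
  })
}

#' Monte Carlo probability of target attainment for one dose
#'
#' For each replicate, draws log-normal random effects for every virtual
#' patient, computes the steady-state AUC (`dose / CL`) and Cmax
#' analytically, and tallies the fraction attaining the efficacy target
#' (`AUC >= auc_target`) and the fraction crossing the toxicity limit
#' (`Cmax > cmax_toxicity_limit`). Both are evaluated on the same draws so
#' joint probabilities are computable.
#'
#' @param model a [pza_model()].
#' @param population virtual patients from [band_population()].
#' @param dose once-daily dose, mg.
#' @param targets list from [therapeutic_targets()].
#' @param n_rep number of Monte Carlo replicates.
#' @param seed integer seed.
#' @return one-row data frame: `dose`, `pta` (efficacy), `tox_prob`,
#'   `mc_se` (binomial Monte Carlo standard error of `pta`), `n_patients`,
#'   `n_rep`.
#' @export
pta <- function(model, population, dose, targets = therapeutic_targets(),
                n_rep = 200, seed = 1L) {
  stopifnot(n_rep >= 1)
  tv <- typical_params(model, population)
  n <- nrow(population)
  eth <- tolower(population$ethnicity)
  om_cl <- ifelse(eth == "indonesian", model$omega2[["cl_ind"]], model$omega2[["cl_kor"]])
  om_v <- model$omega2[["v"]]
  with_seed(seed, {
    total <- n * n_rep
    eta_cl <- stats::rnorm(total, 0, sqrt(rep(om_cl, n_rep)))
    eta_v <- stats::rnorm(total, 0, sqrt(om_v))
    cl <- rep(tv$cl, n_rep) * exp(eta_cl)
    v <- rep(tv$v, n_rep) * exp(eta_v)
    auc <- dose / cl
    cmax <- cmax_ss_vec(cl, v, rep(tv$ka, n_rep), dose, 24)
    p_eff <- mean(auc >= targets$auc_target)
    p_tox <- mean(cmax > targets$cmax_toxicity_limit)
    data.frame(
      dose = dose, pta = p_eff, tox_prob = p_tox,
      mc_se = sqrt(p_eff * (1 - p_eff) / total),
      n_patients = n, n_rep = n_rep
    )
  })
}

#' Smallest dose attaining the PTA criterion
#'
#' Scans a sorted dose grid and returns the smallest dose whose efficacy PTA
#' meets the criterion (default 90\%).
#'
#' @param model a [pza_model()].
#' @param band one row of [weight_bands()].
#' @param subgroup subgroup label (see [band_population()]).
#' @param dose_grid sorted vector of candidate doses, mg.
#' @param criterion required PTA (default 0.90).
#' @param spec a [cohort_spec()].
#' @param n_patients,n_rep,seed Monte Carlo settings.
#' @return list with `dose` (mg, or `NA` if unattainable), `attained`
#'   (logical), and `grid` (the PTA at every dose).
#' @export
optimal_dose <- function(model, band, subgroup, dose_grid = candidate_doses(),
                         criterion = 0.90, spec = cohort_spec(),
                         n_patients = 1000, n_rep = 200, seed = 1L) {
  if (length(dose_grid) == 0) stop("`dose_grid` must be nonempty", call. = FALSE)
  if (is.unsorted(dose_grid)) stop("`dose_grid` must be sorted", call. = FALSE)
  pop <- band_population(spec, band, subgroup, n = n_patients, seed = seed)
  grid <- do.call(rbind, lapply(seq_along(dose_grid), function(i) {
    pta(model, pop, dose_grid[i], n_rep = n_rep, seed = seed + i)
  }))
  hit <- which(grid$pta >= criterion)
  list(
    dose = if (length(hit)) dose_grid[hit[1]] else NA_real_,
    attained = length(hit) > 0,
    grid = grid
  )
}

#' Full PTA grid across bands, subgroups and doses
#'
#' @param model a [pza_model()].
#' @param bands data frame from [weight_bands()].
#' @param subgroups character vector of subgroup labels.
#' @param doses doses to evaluate (default: candidate doses plus the WHO
#'   band doses).
#' @param spec a [cohort_spec()].
#' @param n_patients,n_rep,seed Monte Carlo settings.
#' @return long data frame: `band`, `subgroup`, `dose`, `pta`, `tox_prob`,
#'   `mc_se`, `n_patients`, `n_rep`, `who_dose` (flag).
#' @export
pta_grid <- function(model, bands = weight_bands(),
                     subgroups = setdiff(pta_subgroups(), "mixed"),
                     doses = NULL, spec = cohort_spec(),
                     n_patients = 1000, n_rep = 200, seed = 1L) {
  all_doses <- if (is.null(doses)) {
    sort(unique(c(candidate_doses(), bands$who_dose)))
  } else {
    sort(unique(doses))
  }
  out <- list()
  k <- 0L
  for (b in seq_len(nrow(bands))) {
    for (sg in subgroups) {
      pop <- band_population(spec, bands[b, ], sg,
        n = n_patients,
        seed = seed + 1000L * b + k
      )
      for (d in all_doses) {
        k <- k + 1L
        row <- pta(model, pop, d, n_rep = n_rep, seed = seed + k)
        row$band <- bands$label[b]
        row$subgroup <- sg
        row$who_dose <- d == bands$who_dose[b]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  res[, c(
    "band", "subgroup", "dose", "pta", "tox_prob", "mc_se",
    "n_patients", "n_rep", "who_dose"
  )]
}
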