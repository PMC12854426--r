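#' Cohort specification for the virtual two-ethnicity TB population
#'
#' Describes the covariate distributions used to generate virtual patients
#' emulating the study cohort: per-ethnicity log-normal age/weight
#' distributions and sex-conditional normal heights (parameterized from the
#' reported medians and interquartile ranges), sex proportion, diabetes (DM)
#' prevalence, prevalence of the age>=60-with-DM stratum, laboratory covariate
#' distributions, and the empirical once-daily dose frequency table.
#'
#' @param n_per_stratum virtual subjects per ethnicity stratum (default 160).
#' @return list of class `cohort_spec` with one entry per ethnicity.
#' @export
cohort_spec <- function(n_per_stratum = 160) {
  lab <- function(med, q25, q75) c(med = med, q25 = q25, q75 = q75)
  spec <- list(
    indonesian = list(
      male_prop = 107 / 160,
      dm_prev = 55 / 160,
      olddm_prev = 12 / 160,
      age = lab(45, 30, 54),
      weight = lab(50, 45, 56.75),
      height_male = c(mean = 168, sd = 6),
      height_female = c(mean = 156, sd = 6),
      scr = lab(0.7, 0.6, 0.9),
      albumin = lab(3.0, 2.7, 3.4),
      ast = lab(29, 24, 44),
      alt = lab(26, 21, 38.25),
      bilirubin = lab(0.4, 0.39, 0.63),
      bun = lab(10, 8, 15),
      dose_table = c(
        `750` = 7, `800` = 1, `1000` = 60, `1200` = 17, `1250` = 30,
        `1275` = 2, `1500` = 32, `1600` = 9, `2000` = 2
      ),
      n = n_per_stratum
    ),
    korean = list(
      male_prop = 90 / 160,
      dm_prev = 22 / 160,
      olddm_prev = 13 / 160,
      age = lab(47, 31, 59),
      weight = lab(56, 51, 63),
      height_male = c(mean = 169, sd = 6),
      height_female = c(mean = 157, sd = 6),
      scr = lab(0.67, 0.61, 0.79),
      albumin = lab(4.1, 4.1, 4.4),
      ast = lab(24, 21.7, 30),
      alt = lab(19, 15, 28),
      bilirubin = lab(0.5, 0.48, 0.73),
      bun = lab(10.4, 9.3, 12.8),
      dose_table = c(
        `500` = 2, `1000` = 23, `1200` = 5, `1250` = 9, `1500` = 105,
        `1600` = 15, `2000` = 1
      ),
      n = n_per_stratum
    )
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Sparse-sampling trial design
#'
#' One steady-state sample per outpatient and two per hospitalized patient,
#' drawn at random times within the dosing interval. A small fraction of
#' samples is degraded below the assay's lower limit of quantification
#' (LLOQ), emulating the pre-analytical workflow artifact observed in the
#' study's early recruitment batch; those records are flagged and later
#' discarded by [apply_blloq_policy()].
#'
#' @param two_sample_frac named fractions of two-sample (hospitalized)
#'   subjects per ethnicity.
#' @param window sampling-time window, h after the last dose.
#' @param lloq lower limit of quantification, mg/L.
#' @param blloq_artifact_rate fraction of samples degraded below the LLOQ.
#' @return list of class `sampling_design`.
#' @export
sampling_design <- function(two_sample_frac = c(indonesian = 0.75, korean = 0.05),
                            window = c(0.5, 24),
                            lloq = 2.0,
                            blloq_artifact_rate = 0.11) {
  stopifnot(
    all(two_sample_frac >= 0 & two_sample_frac <= 1),
    window[1] >= 0, window[2] <= 24, window[1] < window[2],
    lloq >= 0, blloq_artifact_rate >= 0, blloq_artifact_rate <= 1
  )
  structure(
    list(
      two_sample_frac = two_sample_frac, window = window, lloq = lloq,
      blloq_artifact_rate = blloq_artifact_rate
    ),
    class = "sampling_design"
  )
}

#' Read or write a cohort specification as YAML
#'
#' The YAML layout mirrors the [cohort_spec()] field names: one top-level
#' key per ethnicity, scalar keys for proportions, `med`/`q25`/`q75` maps
#' for the median-IQR distributions, `mean`/`sd` maps for heights, and a
#' dose-frequency map.
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  yaml::write_yaml(lapply(unclass(spec), function(s) {
    lapply(s, function(x) if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  }), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- lapply(raw, function(s) {
    lapply(s, function(x) if (is.list(x)) unlist(x) else x)
  })
  for (eth in names(spec)) {
    s <- spec[[eth]]
    if (s$olddm_prev > s$dm_prev) {
      stop("old-DM prevalence cannot exceed DM prevalence (", eth, ")", call. = FALSE)
    }
  }
  class(spec) <- "cohort_spec"
  spec
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# lognormal parameterized by median and IQR
rlnorm_iqr <- function(n, med, q25, q75) {
  sdlog <- (log(q75) - log(q25)) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

#' Sample virtual patient covariates
#'
#' Draws `n` virtual patients (split evenly across the spec's ethnicity
#' strata) with demographics and laboratory covariates matching the cohort
#' specification. Lean body weight is always derived from the sampled sex,
#' weight and height via [lbw_boer()], never sampled independently; eGFR is
#' derived via [egfr_ckdepi()]. DM flags are allocated conditionally on age
#' so that both the overall DM prevalence and the prevalence of the
#' age>=60-with-DM stratum are matched in expectation, and `old_dm` is
#' consistent with `age` and `dm` by construction.
#'
#' @param spec a [cohort_spec()].
#' @param n total number of subjects (default: sum of stratum sizes).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data frame with one row per subject: `subject_id`, `ethnicity`,
#'   `sex`, `age`, `weight`, `height`, `lbw`, `dm`, `old_dm`, `scr`, `egfr`,
#'   `albumin`, `ast`, `alt`, `bilirubin`, `bun`, `dose`.
#' @export
sample_covariates <- function(spec = cohort_spec(), n = NULL, seed = 1L) {
  if (is.null(n)) n <- sum(vapply(spec, function(s) s$n, numeric(1)))
  n_eth <- c(
    indonesian = floor(n / 2),
    korean = n - floor(n / 2)
  )
  with_seed(seed, {
    out <- lapply(names(n_eth), function(eth) {
      s <- spec[[eth]]
      m <- n_eth[[eth]]
      if (m == 0) return(NULL)
      if (s$olddm_prev > s$dm_prev) {
        stop("old-DM prevalence cannot exceed DM prevalence", call. = FALSE)
      }
      sex <- ifelse(stats::runif(m) < s$male_prop, "male", "female")
      age <- rlnorm_iqr(m, s$age["med"], s$age["q25"], s$age["q75"])
      # adult cohort: resample the rare draws below 18 y
      while (any(age < 18)) {
        i <- age < 18
        age[i] <- rlnorm_iqr(sum(i), s$age["med"], s$age["q25"], s$age["q75"])
      }
      weight <- rlnorm_iqr(m, s$weight["med"], s$weight["q25"], s$weight["q75"])
      hm <- s$height_male; hf <- s$height_female
      height <- ifelse(sex == "male",
        stats::rnorm(m, hm["mean"], hm["sd"]),
        stats::rnorm(m, hf["mean"], hf["sd"])
      )
      # DM allocated conditionally on age>=60 so both the overall and the
      # old-DM prevalence are hit in expectation
      old <- age >= 60
      p_old <- if (any(old)) min(1, s$olddm_prev * m / sum(old)) else 0
      p_young <- if (any(!old)) {
        min(1, max(0, (s$dm_prev - s$olddm_prev)) * m / sum(!old))
      } else {
        0
      }
      dm <- ifelse(old, stats::runif(m) < p_old, stats::runif(m) < p_young)
      scr <- rlnorm_iqr(m, s$scr["med"], s$scr["q25"], s$scr["q75"])
      doses <- as.numeric(names(s$dose_table))
      dose <- sample(doses, m, replace = TRUE, prob = s$dose_table)
      data.frame(
        ethnicity = eth, sex = sex, age = age, weight = weight,
        height = height, lbw = lbw_boer(sex, weight, height),
        dm = as.integer(dm), old_dm = as.integer(dm & old),
        scr = scr, egfr = egfr_ckdepi(sex, scr, age),
        albumin = rlnorm_iqr(m, s$albumin["med"], s$albumin["q25"], s$albumin["q75"]),
        ast = rlnorm_iqr(m, s$ast["med"], s$ast["q25"], s$ast["q75"]),
        alt = rlnorm_iqr(m, s$alt["med"], s$alt["q25"], s$alt["q75"]),
        bilirubin = rlnorm_iqr(m, s$bilirubin["med"], s$bilirubin["q25"], s$bilirubin["q75"]),
        bun = rlnorm_iqr(m, s$bun["med"], s$bun["q25"], s$bun["q75"]),
        dose = dose,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, c(
      "subject_id", "ethnicity", "sex", "age", "weight", "height", "lbw",
      "dm", "old_dm", "scr", "egfr", "albumin", "ast", "alt", "bilirubin",
      "bun", "dose"
    )]
  })
}

#' Greedy 1:1 caliper matching of two cohorts
#'
#' Matches each reference subject to the nearest unused pool subject within
#' both a body-weight and an age caliper (nearest by Euclidean distance on
#' the two matching variables), without replacement. Reference subjects with
#' no admissible pool candidate remain unmatched.
#'
#' @param reference,pool data frames with `subject_id`, `weight`, `age`.
#' @param weight_caliper maximum absolute weight difference, kg.
#' @param age_caliper maximum absolute age difference, years.
#' @return list with `pairs` (data frame: `ref_id`, `pool_id`, `dweight`,
#'   `dage`) and `unmatched` (reference ids with no match).
#' @export
match_cohorts <- function(reference, pool, weight_caliper = 5, age_caliper = 5) {
  empty <- data.frame(
    ref_id = character(), pool_id = character(),
    dweight = numeric(), dage = numeric(), stringsAsFactors = FALSE
  )
  if (is.null(reference) || nrow(reference) == 0 || is.null(pool) || nrow(pool) == 0) {
    un <- if (!is.null(reference) && nrow(reference)) reference$subject_id else character()
    return(list(pairs = empty, unmatched = un))
  }
  if (any(reference$subject_id %in% pool$subject_id)) {
    stop("reference and pool must be disjoint", call. = FALSE)
  }
  used <- rep(FALSE, nrow(pool))
  rows <- vector("list", nrow(reference))
  unmatched <- character()
  for (i in seq_len(nrow(reference))) {
    dw <- abs(pool$weight - reference$weight[i])
    da <- abs(pool$age - reference$age[i])
    ok <- !used & dw <= weight_caliper & da <= age_caliper
    if (!any(ok)) {
      unmatched <- c(unmatched, reference$subject_id[i])
      next
    }
    d <- sqrt(dw^2 + da^2)
    d[!ok] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    rows[[i]] <- data.frame(
      ref_id = reference$subject_id[i], pool_id = pool$subject_id[j],
      dweight = dw[j], dage = da[j], stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs)) pairs <- empty
  list(pairs = pairs, unmatched = unmatched)
}

#' Simulate a sparse-sampling steady-state trial
#'
#' For every subject in the cohort, draws log-normal random effects on CL/F
#' and Vd/F (ethnicity-specific variance on CL/F), samples 1 or 2 observation
#' times within the design window, evaluates the steady-state concentration at
#' the subject's own dose, adds additive residual noise, optionally degrades a
#' fraction of samples below the LLOQ (the pre-analytical artifact; see
#' [sampling_design()]), and assembles a NONMEM-style event dataset.
#'
#' @param model a [pza_model()].
#' @param cohort covariate data frame from [sample_covariates()].
#' @param design a [sampling_design()].
#' @param seed integer seed.
#' @return an `nm_dataset` (see [read_nm_csv()] for the layout).
#' @export
simulate_trial <- function(model, cohort, design = sampling_design(), seed = 1L) {
  n <- nrow(cohort)
  tv <- typical_params(model, cohort)
  with_seed(seed, {
    eth <- tolower(cohort$ethnicity)
    om_cl <- ifelse(eth == "indonesian", model$omega2[["cl_ind"]], model$omega2[["cl_kor"]])
    eta_cl <- stats::rnorm(n, 0, sqrt(om_cl))
    eta_v <- stats::rnorm(n, 0, sqrt(model$omega2[["v"]]))
    two <- stats::runif(n) < design$two_sample_frac[eth]
    nsamp <- ifelse(two, 2L, 1L)
    idx <- rep(seq_len(n), nsamp)
    t_obs <- stats::runif(length(idx), design$window[1], design$window[2])
    conc <- conc_ss_vec(
      tv$cl[idx] * exp(eta_cl[idx]), tv$v[idx] * exp(eta_v[idx]), tv$ka[idx],
      cohort$dose[idx], 24, t_obs
    )
    dv <- conc + stats::rnorm(length(idx), 0, model$sigma_add)
    if (design$blloq_artifact_rate > 0) {
      degraded <- stats::runif(length(idx)) < design$blloq_artifact_rate
      dv[degraded] <- stats::runif(sum(degraded), 0, design$lloq)
    }
    obs <- data.frame(
      ID = cohort$subject_id[idx], TIME = t_obs, EVID = 0L,
      AMT = NA_real_, DV = dv, MDV = 0L,
      BLQ = as.integer(dv < design$lloq), stringsAsFactors = FALSE
    )
    dosing <- data.frame(
      ID = cohort$subject_id, TIME = 0, EVID = 1L,
      AMT = cohort$dose, DV = NA_real_, MDV = 1L, BLQ = 0L,
      stringsAsFactors = FALSE
    )
    ev <- rbind(dosing, obs)
    cov_cols <- cohort[match(ev$ID, cohort$subject_id), c(
      "ethnicity", "sex", "age", "weight", "height", "lbw", "dm", "old_dm",
      "scr", "egfr", "albumin", "ast", "alt", "bilirubin", "bun"
    )]
    names(cov_cols) <- c(
      "ETH", "SEX", "AGE", "WT", "HT", "LBW", "DM", "OLDDM",
      "SCR", "EGFR", "ALB", "AST", "ALT", "BILI", "BUN"
    )
    ds <- cbind(ev, cov_cols)
    ds <- ds[order(match(ds$ID, cohort$subject_id), ds$EVID != 1, ds$TIME), ]
    rownames(ds) <- NULL
    as_nm_dataset(ds, lloq = design$lloq)
  })
}
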