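#' Lean body weight by the Boer formula
#'
#' Computes lean body weight (LBW, kg) from sex, total body weight and height.
#' LBW is the body-size descriptor used for allometric scaling of the PK
#' parameters in this package.
#'
#' @param sex character vector, `"male"` or `"female"`.
#' @param weight total body weight in kg (> 0).
#' @param height height in cm (> 0).
#' @return lean body weight in kg.
#' @examples
#' lbw_boer("male", 55, 165)
#' lbw_boer("female", 50, 160)
#' @export
lbw_boer <- function(sex, weight, height) {
  sex <- match_sex(sex)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("`height` must be positive and finite", call. = FALSE)
  }
  ifelse(sex == "male",
    0.407 * weight + 0.267 * height - 19.2,
    0.252 * weight + 0.473 * height - 48.3
  )
}

#' Estimated glomerular filtration rate (CKD-EPI 2009)
#'
#' Four-branch CKD-EPI 2009 creatinine equation (sex x creatinine knot),
#' without the race coefficient.
#'
#' @param sex character vector, `"male"` or `"female"`.
#' @param scr serum creatinine in mg/dL (> 0).
#' @param age age in years (> 0).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckdepi("male", 0.7, 46)
#' @export
egfr_ckdepi <- function(sex, scr, age) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("`scr` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be positive and finite", call. = FALSE)
  }
  kappa <- ifelse(sex == "male", 0.9, 0.7)
  alpha <- ifelse(sex == "male", -0.411, -0.329)
  sexmul <- ifelse(sex == "male", 1, 1.018)
  r <- scr / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age * sexmul
}

#' Power covariate effect on a typical parameter value
#'
#' `theta_tv * (cov_value / cov_median) ^ exponent`, the standard continuous
#' covariate submodel for PK parameters.
#'
#' @param theta_tv typical parameter value at the covariate median.
#' @param cov_value individual covariate value (> 0).
#' @param cov_median reference (median) covariate value (> 0).
#' @param exponent power exponent.
#' @return adjusted parameter value.
#' @export
covariate_power <- function(theta_tv, cov_value, cov_median, exponent) {
  if (any(!is.finite(cov_value)) || any(cov_value <= 0)) {
    stop("`cov_value` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(cov_median)) || any(cov_median <= 0)) {
    stop("`cov_median` must be positive and finite", call. = FALSE)
  }
  theta_tv * (cov_value / cov_median)^exponent
}

#' Categorical (fractional-shift) covariate effect
#'
#' `theta_base * (1 + effect * flag)`: the parameter is shifted by a fraction
#' `effect` when the binary covariate is present.
#'
#' @param theta_base parameter value with the covariate absent.
#' @param effect fractional shift when the covariate is present.
#' @param flag 0/1 (or logical) covariate indicator.
#' @return adjusted parameter value.
#' @examples
#' covariate_categorical(3.5, 0.252, 1) # typical CL/F, older diabetic stratum
#' @export
covariate_categorical <- function(theta_base, effect, flag) {
  flag <- as.numeric(flag)
  if (any(!flag %in% c(0, 1))) {
    stop("`flag` must be 0 or 1", call. = FALSE)
  }
  theta_base * (1 + effect * flag)
}

# normalize sex coding; accepts "male"/"female" (any case) or "M"/"F"
match_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  if (any(!s %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  s
}
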