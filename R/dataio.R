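#' NONMEM-style event dataset
#'
#' The package's dataset container is a plain data frame of ordered event
#' records carrying the class `nm_dataset`. Mandatory columns: `ID`
#' (opaque subject identifier), `TIME` (hours after the most recent dose;
#' the steady-state convention, no dosing-history expansion), `EVID`
#' (1 = dose, 0 = observation), `AMT` (dose amount, mg), `DV` (observed
#' concentration, mg/L), `MDV` (1 = DV missing). Optional: `BLQ` (1 = below
#' the LLOQ; derived from `DV < lloq` when absent) plus any covariate
#' columns, which are carried through unchanged.
#'
#' @param x data frame of event records.
#' @param lloq LLOQ (mg/L) used to derive the `BLQ` flag when absent.
#' @return `x` with class `nm_dataset` and attribute `lloq`.
#' @export
as_nm_dataset <- function(x, lloq = 2.0) {
  need <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("dataset is missing mandatory column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"BLQ" %in% names(x)) {
    x$BLQ <- as.integer(x$EVID == 0 & !is.na(x$DV) & x$DV < lloq)
  }
  if (any(x$TIME < 0 | x$TIME > 24)) {
    stop("TIME must lie within [0, 24] h after the last dose", call. = FALSE)
  }
  dup <- duplicated(x[, c("ID", "TIME", "EVID")])
  if (any(dup)) {
    stop("duplicate (ID, TIME, EVID) records at row(s) ",
      paste(which(dup), collapse = ", "),
      call. = FALSE
    )
  }
  x$ID <- as.character(x$ID)
  class(x) <- c("nm_dataset", "data.frame")
  attr(x, "lloq") <- lloq
  x
}

#' Read a NONMEM-style CSV dataset
#'
#' Comma-separated, period decimal separator, UTF-8. Column names are
#' recognized case-insensitively and in any order; the NONMEM missing token
#' `"."` in `DV` is mapped to `NA` with `MDV = 1`. Unrecognized columns are
#' kept as covariates and reported via a message. Malformed numeric fields
#' are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param lloq LLOQ (mg/L) used to flag below-quantification observations.
#' @return an `nm_dataset`.
#' @export
read_nm_csv <- function(path, lloq = 2.0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path,
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character", fileEncoding = "UTF-8"
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("empty dataset: ", path, call. = FALSE)
  }
  canon <- c(
    ID = "ID", TIME = "TIME", EVID = "EVID", AMT = "AMT", DV = "DV",
    MDV = "MDV", BLQ = "BLQ"
  )
  up <- toupper(names(raw))
  names(raw) <- ifelse(up %in% names(canon), canon[up], toupper(names(raw)))
  for (col in c("ID", "TIME", "DV")) {
    if (!col %in% names(raw)) {
      stop("mandatory column missing from ", path, ": ", col, call. = FALSE)
    }
  }
  known <- c(
    names(canon), "ETH", "SEX", "AGE", "WT", "HT", "LBW", "DM", "OLDDM",
    "SCR", "EGFR", "ALB", "AST", "ALT", "BILI", "BUN", "DOSE", "TAU"
  )
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    message(
      "read_nm_csv: carrying unrecognized covariate column(s): ",
      paste(extra, collapse = ", ")
    )
  }
  num <- function(col) {
    if (!col %in% names(raw)) return(NULL)
    v <- trimws(raw[[col]])
    v[v == "." | v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(
        "malformed numeric value(s) in column ", col, " at data line(s) ",
        paste(bad + 1L, collapse = ", "), " of ", path,
        call. = FALSE
      )
    }
    out
  }
  ds <- data.frame(ID = raw$ID, stringsAsFactors = FALSE)
  ds$TIME <- num("TIME")
  ds$EVID <- if ("EVID" %in% names(raw)) as.integer(num("EVID")) else {
    as.integer(!is.na(num_or_na(raw, "AMT")) & num_or_na(raw, "AMT") > 0)
  }
  ds$AMT <- if ("AMT" %in% names(raw)) num("AMT") else NA_real_
  ds$DV <- num("DV")
  ds$MDV <- if ("MDV" %in% names(raw)) as.integer(num("MDV")) else {
    as.integer(is.na(ds$DV))
  }
  ds$MDV[is.na(ds$DV) & ds$EVID == 0] <- 1L
  if ("BLQ" %in% names(raw)) ds$BLQ <- as.integer(num("BLQ"))
  for (col in setdiff(names(raw), c(names(ds), "BLQ"))) {
    v <- raw[[col]]
    nv <- suppressWarnings(as.numeric(v))
    ds[[col]] <- if (all(is.na(nv) == (is.na(v) | v == "." | v == ""))) nv else v
  }
  as_nm_dataset(ds, lloq = lloq)
}

num_or_na <- function(raw, col) {
  if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
  suppressWarnings(as.numeric(raw[[col]]))
}

#' Write a NONMEM-style CSV dataset
#'
#' Inverse of [read_nm_csv()]: numeric columns are written with full
#' precision (17 significant digits) so a write/read round trip is
#' bit-exact; missing `DV`/`AMT` are written as the NONMEM `"."` token.
#'
#' @param ds an `nm_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nm_csv <- function(ds, path) {
  out <- as.data.frame(ds)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "."
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the below-LLOQ handling policy
#'
#' The shipped policy is `"discard"` (the M1 method): observation records
#' flagged below the LLOQ are removed before estimation; including them led
#' to underprediction in the study this package emulates. The function is
#' idempotent and reports the number of records removed and any subjects
#' left without observations.
#'
#' @param ds an `nm_dataset`.
#' @param policy currently only `"discard"`.
#' @return the filtered `nm_dataset`, with attributes `n_removed` (count of
#'   discarded records) and `subjects_without_obs` (ids of subjects left with
#'   zero observation records).
#' @export
apply_blloq_policy <- function(ds, policy = c("discard")) {
  policy <- match.arg(policy)
  drop <- ds$EVID == 0 & !is.na(ds$BLQ) & ds$BLQ == 1
  out <- ds[!drop, , drop = FALSE]
  rownames(out) <- NULL
  obs_left <- unique(out$ID[out$EVID == 0 & out$MDV == 0])
  lost <- setdiff(unique(ds$ID), obs_left)
  class(out) <- class(ds)
  attr(out, "lloq") <- attr(ds, "lloq")
  attr(out, "n_removed") <- sum(drop)
  attr(out, "subjects_without_obs") <- lost
  out
}

# one row per subject with lower-case covariate names, as used by the model
# layer; dose taken from the subject's dose record
nm_covariates <- function(ds) {
  ids <- unique(ds$ID)
  first <- ds[match(ids, ds$ID), , drop = FALSE]
  map <- c(
    ETH = "ethnicity", SEX = "sex", AGE = "age", WT = "weight", HT = "height",
    LBW = "lbw", DM = "dm", OLDDM = "old_dm", SCR = "scr", EGFR = "egfr",
    ALB = "albumin", AST = "ast", ALT = "alt", BILI = "bilirubin", BUN = "bun"
  )
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (col in names(map)) {
    if (col %in% names(first)) out[[map[[col]]]] <- first[[col]]
  }
  # any further column is an ad-hoc covariate (e.g. a candidate effect
  # column added by the analyst); carry it through under its own name
  event_cols <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "BLQ")
  for (col in setdiff(names(first), c(event_cols, names(map)))) {
    out[[col]] <- first[[col]]
  }
  doses <- ds[ds$EVID == 1, , drop = FALSE]
  out$dose <- doses$AMT[match(ids, doses$ID)]
  out
}
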