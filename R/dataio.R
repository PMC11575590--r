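## Tabular data interfaces and the vapor-liquid-equilibrium pipeline.
##
## Canonical internal units: temperature K, pressure kPa, natural-log
## activity coefficients.  Antoine parameter sets declare their own units
## and log base and are converted on evaluation -- no default guessing.

GAMMA_COLS <- c("smiles_1", "smiles_2", "T_K", "x_1",
                "ln_gamma_1", "ln_gamma_2", "source")
VLE_COLS <- c("smiles_1", "smiles_2", "T_K", "p_kPa", "x_1", "y_1")

#' Antoine vapor-pressure parameter set
#'
#' @param A,B,C Antoine coefficients for `log(pS) = A - B / (C + T)`.
#' @param T_unit Temperature unit of the correlation: `"K"` or `"C"`.
#' @param p_unit Pressure unit the correlation returns: `"kPa"`, `"Pa"`,
#'   `"bar"`, `"mmHg"` or `"atm"`.
#' @param log_base Base of the logarithm (10 or `exp(1)`).
#' @param T_min,T_max Validity range in Kelvin (optional; evaluation outside
#'   it raises a `range_warning`).
#' @param smiles Optional component tag.
#' @return An object of class `antoine_params`.
#' @export
antoine_params <- function(A, B, C, T_unit = "K", p_unit = "kPa",
                           log_base = 10, T_min = NA_real_, T_max = NA_real_,
                           smiles = NA_character_) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C),
            T_unit %in% c("K", "C"), log_base > 0)
  p_fac <- switch(p_unit, kPa = 1, Pa = 1e-3, bar = 100, mmHg = 0.1333224,
                  atm = 101.325,
                  stop_hanna("bad_input", paste("unknown p_unit:", p_unit)))
  structure(list(A = A, B = B, C = C, T_unit = T_unit, p_unit = p_unit,
                 p_factor_kPa = p_fac, log_base = log_base,
                 T_min = T_min, T_max = T_max, smiles = smiles),
            class = "antoine_params")
}

#' Pure-component vapor pressure from the Antoine equation
#'
#' `pS = base^(A - B/(C + T'))` with `T'` in the parameter set's declared
#' unit, converted to kPa.
#'
#' @param params An [antoine_params()].
#' @param T_K Temperature(s) in Kelvin.
#' @return Vapor pressure(s) in kPa.
#' @examples
#' p <- antoine_params(A = 7, B = 1500, C = -50)
#' antoine_vapor_pressure(p, 350)  # 10^(7 - 1500/300) = 100 kPa
#' @export
antoine_vapor_pressure <- function(params, T_K) {
  stopifnot(inherits(params, "antoine_params"), all(T_K > 0))
  if ((!is.na(params$T_min) && any(T_K < params$T_min)) ||
      (!is.na(params$T_max) && any(T_K > params$T_max)))
    warn_hanna("range_warning", sprintf(
      "temperature outside the Antoine validity range [%s, %s] K",
      format(params$T_min), format(params$T_max)))
  Tp <- if (params$T_unit == "C") T_K - 273.15 else T_K
  p <- params$log_base^(params$A - params$B / (params$C + Tp)) *
    params$p_factor_kPa
  if (any(!is.finite(p) | p <= 0))
    stop_hanna("non_positive_pressure",
               "Antoine evaluation gave a non-positive or non-finite pressure")
  p
}

#' Read an Antoine parameter table
#'
#' Schema: `smiles, A, B, C, T_unit, p_unit, log_base, T_min, T_max` (units
#' are mandatory -- there is no default Antoine dialect).
#'
#' @param path CSV file path.
#' @return Named list of [antoine_params()], keyed by `smiles`.
#' @export
read_antoine_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smiles", "A", "B", "C", "T_unit", "p_unit", "log_base")
  if (!all(need %in% names(df)))
    stop_hanna("schema_error", sprintf(
      "missing Antoine column(s): %s",
      paste(setdiff(need, names(df)), collapse = ", ")))
  if (!"T_min" %in% names(df)) df$T_min <- NA_real_
  if (!"T_max" %in% names(df)) df$T_max <- NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    antoine_params(df$A[i], df$B[i], df$C[i], df$T_unit[i], df$p_unit[i],
                   df$log_base[i], df$T_min[i], df$T_max[i], df$smiles[i])
  })
  names(out) <- df$smiles
  out
}

#' Convert VLE measurements to activity coefficients
#'
#' Extended Raoult's law with an ideal-gas vapor phase:
#' `gamma_i = y_i p / (x_i pS_i)`.  The pressure dependence of the liquid
#' chemical potential (Poynting correction) is neglected.  Records with a
#' composition endpoint yield one-sided results (the dissolved component at
#' `x_i = 0` has no defined gamma); non-positive gammas (inconsistent raw
#' data) are dropped with a warning.
#'
#' @param records Data frame in the VLE schema (`smiles_1, smiles_2, T_K,
#'   p_kPa, x_1, y_1`).
#' @param p_sat_1,p_sat_2 Pure-component vapor pressures in kPa, scalars or
#'   vectors matching `records`.
#' @return Data frame in the gamma schema with `source = "vle"`; rows whose
#'   both gammas are undefined are dropped.
#' @examples
#' rec <- data.frame(smiles_1 = "CCO", smiles_2 = "O", T_K = 350,
#'                   p_kPa = 100, x_1 = 0.5, y_1 = 0.6)
#' vle_to_gamma(rec, p_sat_1 = 80, p_sat_2 = 100)
#' @export
vle_to_gamma <- function(records, p_sat_1, p_sat_2) {
  stopifnot(all(VLE_COLS %in% names(records)))
  with(records, stopifnot(all(x_1 >= 0 & x_1 <= 1), all(y_1 >= 0 & y_1 <= 1),
                          all(p_kPa > 0), all(T_K > 0)))
  n <- nrow(records)
  p_sat_1 <- rep_len(p_sat_1, n)
  p_sat_2 <- rep_len(p_sat_2, n)
  stopifnot(all(p_sat_1 > 0), all(p_sat_2 > 0))
  x1 <- records$x_1; y1 <- records$y_1
  g1 <- ifelse(x1 > 0, y1 * records$p_kPa / (x1 * p_sat_1), NA_real_)
  g2 <- ifelse(x1 < 1,
               (1 - y1) * records$p_kPa / ((1 - x1) * p_sat_2), NA_real_)
  bad1 <- !is.na(g1) & g1 <= 0
  bad2 <- !is.na(g2) & g2 <= 0
  g1[bad1] <- NA_real_
  g2[bad2] <- NA_real_
  out <- data.frame(smiles_1 = records$smiles_1, smiles_2 = records$smiles_2,
                    T_K = records$T_K, x_1 = x1,
                    ln_gamma_1 = log(g1), ln_gamma_2 = log(g2),
                    source = "vle", stringsAsFactors = FALSE)
  empty <- is.na(out$ln_gamma_1) & is.na(out$ln_gamma_2)
  if (any(bad1 | bad2))
    warn_hanna("non_positive_gamma", sprintf(
      "%d activity coefficient(s) were non-positive and dropped",
      sum(bad1) + sum(bad2)))
  out[!empty, , drop = FALSE]
}

#' Preprocessing filters for mixture records
#'
#' Drops (in this order of attribution): rows above the pressure ceiling
#' (default 1000 kPa = 10 bar, only if a `p_kPa` column exists), rows flagged
#' by a boolean `poor_quality`/`quality_flag` column, and rows whose SMILES
#' cannot be canonicalized (kept rows get the canonical form written back).
#'
#' @param records Data frame with `smiles_1`, `smiles_2` and optionally
#'   `p_kPa` and a quality column.
#' @param max_p_kPa Pressure ceiling in kPa.
#' @param canonicalize Canonicalize/validate SMILES (requires ChemmineOB)?
#'   Set `FALSE` for synthetic component tags.
#' @return List with `kept` (filtered data frame) and `report` (named drop
#'   counts; `sum(report)` plus `nrow(kept)` equals the input row count).
#' @export
apply_filters <- function(records, max_p_kPa = 1000, canonicalize = TRUE) {
  stopifnot(is.data.frame(records))
  n0 <- nrow(records)
  report <- c(pressure_gt_10bar = 0L, poor_quality = 0L, invalid_smiles = 0L)
  if ("p_kPa" %in% names(records)) {
    drop <- records$p_kPa > max_p_kPa
    report[["pressure_gt_10bar"]] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  qcol <- intersect(c("poor_quality", "quality_flag"), names(records))
  if (length(qcol)) {
    drop <- as.logical(records[[qcol[1]]])
    drop[is.na(drop)] <- FALSE
    report[["poor_quality"]] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  if (canonicalize && nrow(records)) {
    ok1 <- is_valid_smiles(records$smiles_1)
    ok2 <- is_valid_smiles(records$smiles_2)
    keep <- ok1 & ok2
    report[["invalid_smiles"]] <- sum(!keep)
    if (any(!keep))
      warn_hanna("invalid_smiles", sprintf(
        "%d record(s) dropped: SMILES failed canonicalization", sum(!keep)))
    records <- records[keep, , drop = FALSE]
    if (nrow(records)) {
      records$smiles_1 <- canonicalize_smiles(records$smiles_1)
      records$smiles_2 <- canonicalize_smiles(records$smiles_2)
    }
  }
  stopifnot(sum(report) + nrow(records) == n0)
  list(kept = records, report = report)
}

## shared schema validation for gamma records
validate_gamma <- function(df, where = "gamma data") {
  need <- c("smiles_1", "smiles_2", "T_K", "x_1")
  if (!all(need %in% names(df)))
    stop_hanna("schema_error", sprintf(
      "%s: missing column(s): %s", where,
      paste(setdiff(need, names(df)), collapse = ", ")))
  if (!any(c("ln_gamma_1", "ln_gamma_2") %in% names(df)))
    stop_hanna("schema_error",
               sprintf("%s: needs ln_gamma_1 and/or ln_gamma_2", where))
  if (!"ln_gamma_1" %in% names(df)) df$ln_gamma_1 <- NA_real_
  if (!"ln_gamma_2" %in% names(df)) df$ln_gamma_2 <- NA_real_
  if (!"source" %in% names(df)) df$source <- "unknown"
  if (any(df$x_1 < 0 | df$x_1 > 1))
    stop_hanna("schema_error", sprintf("%s: x_1 outside [0, 1]", where))
  empty <- is.na(df$ln_gamma_1) & is.na(df$ln_gamma_2)
  if (any(empty)) {
    warn_hanna("schema_error", sprintf(
      "%s: row(s) %s have no ln gamma value and were rejected", where,
      paste(which(empty), collapse = ", ")))
    df <- df[!empty, , drop = FALSE]
  }
  df[GAMMA_COLS]
}

#' Read / write activity-coefficient tables
#'
#' Schema: `smiles_1, smiles_2, T_K, x_1, ln_gamma_1, ln_gamma_2, source`.
#' Either ln-gamma field may be blank (one-sided records, e.g. infinite
#' dilution), but not both; offending rows are rejected with their position.
#' The write/read round trip is lossless for finite values.
#'
#' @param path CSV file path.
#' @param records Data frame in the gamma schema.
#' @return `read_gamma_csv()`: validated data frame.  `write_gamma_csv()`:
#'   `path`, invisibly.
#' @export
read_gamma_csv <- function(path) {
  validate_gamma(utils::read.csv(path, stringsAsFactors = FALSE),
                 where = path)
}

#' @rdname read_gamma_csv
#' @export
write_gamma_csv <- function(records, path) {
  records <- validate_gamma(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a VLE measurement table
#'
#' Schema: `smiles_1, smiles_2, T_K, p_kPa, x_1, y_1`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_vle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(VLE_COLS %in% names(df)))
    stop_hanna("schema_error", sprintf(
      "%s: missing column(s): %s", path,
      paste(setdiff(VLE_COLS, names(df)), collapse = ", ")))
  df
}
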