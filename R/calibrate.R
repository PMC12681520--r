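# Matrix-matched calibration on internal-standard response ratios,
# LOD/LOQ estimation, back-calculation with dilution selection, and
# extract -> specimen unit conversion.

#' Specimen-preparation constants
#'
#' Extraction arithmetic: 250 mg feces into 2 mL solvent, 100 uL plasma
#' into 900 uL solvent (1 mL total extract).
#'
#' @return Nested list with extract volumes (L), specimen mass (g) or
#'   volume (L) per matrix.
#' @export
default_prep <- function() {
  list(
    plasma = list(extract_volume = 0.001, specimen_volume = 0.0001),
    feces = list(extract_volume = 0.002, specimen_mass = 0.25)
  )
}

# extract-to-specimen multiplier: specimen conc = extract conc * factor
prep_factor <- function(matrix, prep = default_prep()) {
  p <- prep[[matrix]]
  if (is.null(p)) stop("unknown matrix: ", matrix)
  if (matrix == "plasma") {
    p$extract_volume / p$specimen_volume          # 10
  } else {
    p$extract_volume / p$specimen_mass            # 0.008 umol/g per uM
  }
}

#' Convert extract concentration to specimen units
#'
#' Plasma: uM extract -> uM plasma (x10, from 100 uL plasma in 1 mL
#' extract). Feces: uM extract -> umol/g feces (x0.008, from 250 mg in
#' 2 mL).
#'
#' @param extract_conc Numeric vector, uM in the extract.
#' @param matrix `"plasma"` or `"feces"`.
#' @param prep Preparation constants, see [default_prep()].
#' @return Specimen concentration (plasma uM or feces umol/g).
#' @examples
#' to_specimen_units(1, "feces")   # 0.008 umol/g
#' to_specimen_units(1, "plasma")  # 10 uM
#' @export
to_specimen_units <- function(extract_conc, matrix, prep = default_prep()) {
  p <- prep[[matrix]]
  if (is.null(p) || any(unlist(p) <= 0)) {
    if (is.null(p)) stop("unknown matrix: ", matrix)
    stop("preparation constants must be positive")
  }
  extract_conc * prep_factor(matrix, prep)
}

failed_curve <- function(analyte_id, matrix, reason) {
  data.frame(analyte_id = analyte_id, matrix = matrix,
             slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
             lod = NA_real_, loq = NA_real_, n_points = 0L,
             weighting = NA_character_, cal_low = NA_real_, cal_high = NA_real_,
             failed = TRUE, flag = reason, stringsAsFactors = FALSE)
}

#' Fit a matrix-matched calibration curve
#'
#' Weighted least squares of the response ratio (analyte area /
#' internal-standard area) on nominal concentration. Curves with fewer than
#' five usable (non-censored) distinct levels are returned as failures
#' rather than raising; curves with R-squared below 0.99 are retained but
#' flagged `low_r_squared`.
#'
#' @param standards Peak-table rows (`role == "standard"`) for one
#'   analyte x matrix.
#' @param weighting `"1/x"` (default, appropriate for a wide calibration
#'   range), `"none"` or `"1/x^2"`.
#' @return One-row data frame: slope, intercept, r_squared, lod, loq,
#'   n_points, weighting, calibration range, `failed`, `flag`.
#' @examples
#' std <- data.frame(sample_id = "s", analyte_id = "IS", matrix = "plasma",
#'                   dilution_factor = 1,
#'                   analyte_area = 2 * c(0.1, 1, 5, 10, 20),
#'                   intstd_area = 1, batch = "cal", day = "day1",
#'                   role = "standard", nominal_conc = c(0.1, 1, 5, 10, 20))
#' fit_calibration(std)  # slope 2, intercept 0, R-squared 1
#' @export
fit_calibration <- function(standards, weighting = c("1/x", "none", "1/x^2")) {
  weighting <- match.arg(weighting)
  analyte_id <- unique(standards$analyte_id)
  matrix <- unique(standards$matrix)
  if (length(analyte_id) != 1L || length(matrix) != 1L)
    stop("fit_calibration expects rows for a single analyte x matrix")
  ok <- !is.na(standards$analyte_area) & !is.na(standards$intstd_area) &
    standards$intstd_area > 0 & !is.na(standards$nominal_conc)
  std <- standards[ok, , drop = FALSE]
  if (length(unique(std$nominal_conc)) < 5L)
    return(failed_curve(analyte_id, matrix, "insufficient_levels"))
  ratio <- std$analyte_area / std$intstd_area
  conc <- std$nominal_conc
  w <- switch(weighting, "1/x" = 1 / conc, "none" = rep(1, length(conc)),
              "1/x^2" = 1 / conc^2)
  fit <- stats::lm(ratio ~ conc, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # weighted R^2 on the fitted scale (as summary.lm defines it, computed
  # directly so noise-free curves do not trip the perfect-fit warning)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(w * res^2) / sum(w * (ratio - stats::weighted.mean(ratio, w))^2)
  ll <- estimate_lod_loq(fit, std)
  flag <- if (!is.na(r2) && r2 < 0.99) "low_r_squared" else ""
  if (!is.na(slope) && slope <= 0) flag <- paste0(flag, ";nonpositive_slope")
  data.frame(analyte_id = analyte_id, matrix = matrix,
             slope = slope, intercept = intercept, r_squared = r2,
             lod = ll[["lod"]], loq = ll[["loq"]],
             n_points = nrow(std), weighting = weighting,
             cal_low = min(conc), cal_high = max(conc),
             failed = FALSE, flag = flag, stringsAsFactors = FALSE)
}

#' Estimate LOD and LOQ from low-level calibration residuals
#'
#' Default estimator: `LOD = 3.3 * s / |slope|`, `LOQ = 10 * s / |slope|`,
#' with `s` the residual standard deviation of the low-concentration region
#' (points at the lowest six distinct levels). Their ratio is therefore
#' exactly 10/3.3. A perfect line gives LOD = LOQ = 0.
#'
#' @param fit An `lm` of response ratio on concentration (or a list with
#'   elements usable by [stats::residuals()] and [stats::coef()]).
#' @param standards The standards the curve was fitted on (data frame with
#'   `nominal_conc`).
#' @param n_low_levels Number of lowest distinct levels defining the
#'   low-concentration region (default 6).
#' @return Named numeric `c(lod =, loq =)` in uM; both NA (flagged) when the
#'   slope is zero.
#' @export
estimate_lod_loq <- function(fit, standards, n_low_levels = 6L) {
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope == 0) {
    warning("zero slope: LOD/LOQ undefined")
    return(c(lod = NA_real_, loq = NA_real_))
  }
  lev <- sort(unique(standards$nominal_conc))
  low <- lev[seq_len(min(n_low_levels, length(lev)))]
  res <- stats::residuals(fit)[standards$nominal_conc %in% low]
  s <- if (length(res) >= 2) stats::sd(res) else 0
  c(lod = 3.3 * s / abs(slope), loq = 10 * s / abs(slope))
}

#' Fit calibration curves for every analyte of a panel
#'
#' @param standards A peak table of standards (one matrix).
#' @param panel A `panel_config`.
#' @param weighting Passed to [fit_calibration()].
#' @return Data frame of curves (class `calibration_set`), one row per
#'   target analyte.
#' @export
fit_panel_calibrations <- function(standards, panel,
                                   weighting = c("1/x", "none", "1/x^2")) {
  weighting <- match.arg(weighting)
  out <- lapply(panel_targets(panel), function(a) {
    rows <- standards[standards$analyte_id == a, , drop = FALSE]
    if (nrow(rows) == 0) return(failed_curve(a, unique(standards$matrix), "no_standards"))
    fit_calibration(rows, weighting)
  })
  out <- do.call(rbind, out)
  class(out) <- c("calibration_set", class(out))
  out
}

#' Back-calculate extract concentrations from peak records
#'
#' `conc = (ratio - intercept) / slope * dilution_factor`, on the extract
#' scale of the undiluted vial. Results below `loq * dilution_factor` are
#' marked `below_loq` (the value is retained for inspection but treated as
#' censored downstream); missing analyte areas are `not_detected`; a failed
#' curve yields `no_curve`.
#'
#' @param records Peak-table rows for one analyte x matrix (any roles).
#' @param curve One-row curve from [fit_calibration()].
#' @return `records` with added columns `extract_conc` and `status`
#'   (one of `measured`, `below_loq`, `not_detected`, `no_curve`).
#' @export
back_calculate <- function(records, curve) {
  if (nrow(curve) != 1L) stop("curve must be a single row")
  if (!all(records$analyte_id == curve$analyte_id) ||
      !all(records$matrix == curve$matrix))
    stop("records and curve must share analyte and matrix")
  out <- records
  if (isTRUE(curve$failed)) {
    out$extract_conc <- NA_real_
    out$status <- "no_curve"
    return(out)
  }
  ratio <- out$analyte_area / out$intstd_area
  conc <- (ratio - curve$intercept) / curve$slope * out$dilution_factor
  status <- rep("measured", nrow(out))
  status[!is.na(conc) & conc < curve$loq * out$dilution_factor] <- "below_loq"
  nd <- is.na(out$analyte_area) | is.na(out$intstd_area)
  conc[nd] <- NA_real_
  status[nd] <- "not_detected"
  out$extract_conc <- conc
  out$status <- status
  out
}

#' Select the reported value across a dilution series
#'
#' The rule: take the least-diluted record whose undiluted (vial-scale)
#' response falls within the calibration range; if every quantifiable
#' record exceeds the range, take the most-diluted one; if nothing is
#' quantifiable, report a censored marker (`below_loq` when any record was
#' below LOQ, otherwise `not_detected`).
#'
#' @param candidates Rows from [back_calculate()] for one sample x analyte
#'   across its dilution series.
#' @param curve The analyte's calibration curve row.
#' @return One-row data frame `extract_conc`, `status`, `dilution_factor`.
#' @export
select_dilution <- function(candidates, curve) {
  if (nrow(candidates) == 0) stop("no candidates")
  cand <- candidates[order(candidates$dilution_factor), , drop = FALSE]
  vial <- cand$extract_conc / cand$dilution_factor   # concentration seen by the detector
  measured <- cand$status == "measured"
  in_range <- measured & !is.na(vial) &
    vial >= curve$cal_low & vial <= curve$cal_high
  pick <- function(i) data.frame(extract_conc = cand$extract_conc[i],
                                 status = cand$status[i],
                                 dilution_factor = cand$dilution_factor[i],
                                 stringsAsFactors = FALSE)
  if (any(in_range)) return(pick(which(in_range)[1]))
  if (any(measured)) {
    above <- measured & !is.na(vial) & vial > curve$cal_high
    if (any(above) && all(above[measured])) return(pick(max(which(above))))
    return(pick(which(measured)[1]))  # below range but quantifiable: least diluted
  }
  status <- if (any(cand$status == "below_loq")) "below_loq" else "not_detected"
  data.frame(extract_conc = NA_real_, status = status,
             dilution_factor = NA_real_, stringsAsFactors = FALSE)
}

#' Quantify cohort samples into a QuantMatrix
#'
#' Back-calculates every cohort record against its analyte's curve, applies
#' the dilution-selection rule per sample x analyte, and converts extract
#' concentrations to specimen units. Cell provenance is `measured`,
#' `censored` (quantifiable signal below LOQ) or `absent` (no peak / failed
#' curve).
#'
#' @param peaks Cohort peak table for one matrix.
#' @param curves A `calibration_set` for the same matrix.
#' @param panel A `panel_config`.
#' @param subjects Cohort table (`subject_id`, `group`, ...).
#' @param prep Preparation constants.
#' @return A [quant_matrix()].
#' @export
quantify_samples <- function(peaks, curves, panel, subjects,
                             prep = default_prep()) {
  mat <- unique(peaks$matrix)
  if (length(mat) != 1L) stop("peak table must hold a single matrix")
  peaks <- peaks[peaks$role == "cohort", , drop = FALSE]
  targets <- panel_targets(panel)
  values <- base::matrix(NA_real_, nrow = nrow(subjects), ncol = length(targets),
                         dimnames = list(subjects$subject_id, targets))
  prov <- base::matrix("absent", nrow = nrow(subjects), ncol = length(targets),
                       dimnames = list(subjects$subject_id, targets))
  pf <- prep_factor(mat, prep)
  for (a in targets) {
    curve <- curves[curves$analyte_id == a, , drop = FALSE]
    rows <- peaks[peaks$analyte_id == a, , drop = FALSE]
    if (nrow(rows) == 0 || nrow(curve) == 0) next
    bc <- back_calculate(rows, curve)
    for (s in unique(bc$sample_id)) {
      sel <- select_dilution(bc[bc$sample_id == s, , drop = FALSE], curve)
      values[s, a] <- sel$extract_conc * pf
      prov[s, a] <- switch(sel$status,
                           measured = "measured",
                           below_loq = "censored",
                           "absent")
      if (prov[s, a] != "measured") values[s, a] <- NA_real_
    }
  }
  quant_matrix(values, prov, subjects, mat,
               audit = list(list(step = "quantify",
                                 note = sprintf("%d samples x %d analytes back-calculated",
                                                nrow(subjects), length(targets)))))
}
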