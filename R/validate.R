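# Method-validation metrics: precision (%RSD), spike recovery, matrix
# effect, and the assembled per-analyte validation report with pass/fail
# flags at the bioanalytical acceptance thresholds (<= 20 %RSD, recovery
# within the closed interval [80, 120]%).

#' Percent relative standard deviation of replicate measurements
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Scale
#' invariant: multiplying all replicates by a positive constant leaves it
#' unchanged. Flagged (NA with a warning) when the mean is zero.
#'
#' @param values Numeric vector of at least two replicates.
#' @return %RSD.
#' @examples
#' precision_rsd(c(8, 10, 12))  # 20
#' @export
precision_rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("precision requires at least two replicates")
  m <- mean(values)
  if (m == 0) {
    warning("mean of replicates is zero; %RSD undefined")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Spike recovery percentage
#'
#' `100 * pre_spiked / post_spiked`; values outside the closed interval
#' [80, 120]% fail the accuracy criterion (checked by
#' [build_validation_report()]).
#'
#' @param pre_spiked Measured concentration of the sample spiked before
#'   extraction (uM).
#' @param post_spiked Measured concentration of the sample spiked after
#'   extraction (uM); must be positive.
#' @return Recovery in percent (NA with a warning when `post_spiked <= 0`).
#' @examples
#' recovery_percent(8, 10)  # 80
#' @export
recovery_percent <- function(pre_spiked, post_spiked) {
  out <- 100 * pre_spiked / post_spiked
  bad <- !is.na(post_spiked) & post_spiked <= 0
  if (any(bad)) {
    warning("non-positive post-spiked concentration; recovery undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Percent matrix effect from calibration slopes
#'
#' `100 * slope_matrix / slope_neat`: the ratio of the matrix-matched
#' calibration slope to the neat-solvent slope. Values below 100% indicate
#' ion suppression, above 100% enhancement.
#'
#' @param slope_matrix Slope of the matrix-matched curve.
#' @param slope_neat Slope of the neat-solvent curve; must be positive.
#' @return %ME (NA with a warning when `slope_neat <= 0`).
#' @examples
#' matrix_effect_percent(1.2, 1.0)  # 120
#' @export
matrix_effect_percent <- function(slope_matrix, slope_neat) {
  out <- 100 * slope_matrix / slope_neat
  bad <- !is.na(slope_neat) & slope_neat <= 0
  if (any(bad)) {
    warning("non-positive neat slope; matrix effect undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Assemble the method-validation report
#'
#' One row per analyte x matrix with intra-/inter-day peak-area %RSD
#' (intra-day: mean of within-day %RSDs; inter-day: %RSD over all
#' injections across days), spike recovery, matrix effect, LOD/LOQ from the
#' matrix-matched curve, and flags: `precision_fail` (%RSD > 20),
#' `recovery_out_of_range` (outside [80, 120], boundaries passing),
#' `curve_fail` (calibration failed or R-squared < 0.99), `no_coverage`
#' (no replicate data for the analyte).
#'
#' @param standards Matrix-matched calibration peak table.
#' @param spike_experiments Output of [simulate_spike_experiment()] or a
#'   data frame with measured `pre_spiked_conc` / `post_spiked_conc`.
#' @param replicate_runs Precision peak table
#'   ([simulate_precision_runs()] design: 10 injections/day over 3 days).
#' @param panel A `panel_config`.
#' @param neat_standards Optional neat-solvent calibration peak table for
#'   matrix effects.
#' @param rsd_limit,recovery_limits Acceptance thresholds.
#' @return Data frame, one row per retained analyte.
#' @export
build_validation_report <- function(standards, spike_experiments,
                                    replicate_runs, panel,
                                    neat_standards = NULL,
                                    rsd_limit = 20,
                                    recovery_limits = c(80, 120)) {
  curves <- fit_panel_calibrations(standards, panel)
  neat_curves <- if (!is.null(neat_standards))
    fit_panel_calibrations(neat_standards, panel)
  mat <- unique(standards$matrix)
  rows <- lapply(panel_targets(panel), function(a) {
    runs <- replicate_runs[replicate_runs$analyte_id == a &
                             !is.na(replicate_runs$analyte_area), , drop = FALSE]
    flags <- character()
    if (nrow(runs) >= 2L) {
      per_day <- split(runs$analyte_area, runs$day)
      per_day <- per_day[lengths(per_day) >= 2L]
      intra <- if (length(per_day)) {
        mean(vapply(per_day, precision_rsd, numeric(1)))
      } else NA_real_
      inter <- precision_rsd(runs$analyte_area)
    } else {
      intra <- inter <- NA_real_
      flags <- c(flags, "no_coverage")
    }
    sp <- spike_experiments[spike_experiments$analyte_id == a, , drop = FALSE]
    recovery <- if (nrow(sp)) {
      recovery_percent(mean(sp$pre_spiked_conc), mean(sp$post_spiked_conc))
    } else NA_real_
    cv <- curves[curves$analyte_id == a, , drop = FALSE]
    me <- if (!is.null(neat_curves)) {
      nt <- neat_curves[neat_curves$analyte_id == a, , drop = FALSE]
      if (!isTRUE(cv$failed) && !isTRUE(nt$failed))
        matrix_effect_percent(cv$slope, nt$slope) else NA_real_
    } else NA_real_
    if (!is.na(intra) && intra > rsd_limit) flags <- c(flags, "precision_fail")
    if (!is.na(inter) && inter > rsd_limit) flags <- c(flags, "precision_fail")
    if (!is.na(recovery) &&
        (recovery < recovery_limits[1] || recovery > recovery_limits[2]))
      flags <- c(flags, "recovery_out_of_range")
    if (isTRUE(cv$failed) || (!is.na(cv$r_squared) && cv$r_squared < 0.99))
      flags <- c(flags, "curve_fail")
    data.frame(analyte_id = a, matrix = mat,
               intra_day_rsd_area = intra, inter_day_rsd_area = inter,
               recovery = recovery, matrix_effect = me,
               lod = cv$lod, loq = cv$loq, r_squared = cv$r_squared,
               flags = paste(unique(flags), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "panel_arithmetic") <- panel_arithmetic(panel)
  out
}
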