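# Synthetic cohort, concentration and instrument-response generators.
# Everything downstream (calibration, validation, QC cascade, statistics) is
# exercised on data from this module, so its defaults encode the study
# conditions: 60 healthy controls vs 31 dialysis patients, log-normal
# concentrations with configurable fold-changes, linear MRM response with
# per-analyte matrix effects, intra-/inter-day variance components,
# area censoring, serial dilutions and occasional whole-sample suppression.

#' Cohort specification
#'
#' @param n_hc,n_pd Group sizes (defaults 60 healthy controls, 31 dialysis
#'   patients).
#' @param age_model Per-group list `list(min, max, shape1, shape2)`: ages are
#'   drawn as `min + (max - min) * rbeta(shape1, shape2)`, so support is the
#'   closed age range. Defaults give medians near 22 (HC, range 19-57) and
#'   58 (PD, range 29-82).
#' @param sex_proportion Per-group probability that a subject is female.
#' @param comorbidity_model Probabilities over `DM_only`, `DM_and_or_CVD`,
#'   `neither` for dialysis patients; must sum to 1.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_hc = 60L, n_pd = 31L,
                        age_model = list(
                          HC = list(min = 19, max = 57, shape1 = 1, shape2 = 8),
                          PD = list(min = 29, max = 82, shape1 = 2.2, shape2 = 1.8)),
                        sex_proportion = c(HC = 0.561, PD = 0.25),
                        comorbidity_model = c(DM_only = 0.357,
                                              DM_and_or_CVD = 0.571,
                                              neither = 0.072)) {
  if (n_hc <= 0 || n_pd <= 0) stop("group sizes must be positive")
  for (g in c("HC", "PD")) {
    am <- age_model[[g]]
    if (is.null(am) || am$min >= am$max || am$shape1 <= 0 || am$shape2 <= 0)
      stop("degenerate age model for group ", g)
  }
  if (any(sex_proportion < 0 | sex_proportion > 1))
    stop("sex proportions must lie in [0, 1]")
  if (any(comorbidity_model < 0) || abs(sum(comorbidity_model) - 1) > 1e-8)
    stop("comorbidity probabilities must be non-negative and sum to 1")
  structure(list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
                 age_model = age_model, sex_proportion = sex_proportion,
                 comorbidity_model = comorbidity_model),
            class = "cohort_spec")
}

#' Simulate a cohort table
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Data frame with `subject_id`, `group` (HC/PD), `age`, `sex`
#'   (female/male) and `comorbidity` (none for HC).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_hc + spec$n_pd
    group <- c(rep("HC", spec$n_hc), rep("PD", spec$n_pd))
    age <- numeric(n)
    sex <- character(n)
    for (g in c("HC", "PD")) {
      idx <- which(group == g)
      am <- spec$age_model[[g]]
      age[idx] <- round(am$min + (am$max - am$min) *
                          stats::rbeta(length(idx), am$shape1, am$shape2), 1)
      sex[idx] <- ifelse(stats::runif(length(idx)) < spec$sex_proportion[[g]],
                         "female", "male")
    }
    comorbidity <- rep("none", n)
    pd_idx <- which(group == "PD")
    comorbidity[pd_idx] <- sample(names(spec$comorbidity_model), length(pd_idx),
                                  replace = TRUE, prob = spec$comorbidity_model)
    data.frame(
      subject_id = sprintf("%s%02d", ifelse(group == "HC", "HC", "PD"),
                           c(seq_len(spec$n_hc), seq_len(spec$n_pd))),
      group = group, age = age, sex = sex, comorbidity = comorbidity,
      stringsAsFactors = FALSE
    )
  })
}

# Default per-analyte x matrix concentration table. Medians are in specimen
# units (plasma uM, feces umol/g) and are stylized: placed so detected
# analytes fall inside the calibration window at one of the assay's dilutions
# and so group composition shares match the cohort findings (healthy plasma
# dominated by LCA at ~94%, dialysis plasma by phenyl sulfate at ~44%, a
# ten-fold indoxyl sulfate elevation). det_prob is the chance the analyte is
# truly present in a sample of that matrix; fold_change multiplies the PD
# median.
default_concentration_table <- function() {
  row <- function(analyte, matrix, median_hc, fold) {
    data.frame(analyte_id = analyte, matrix = matrix, median_hc = median_hc,
               gcv = 0.5, det_prob = 1, fold_change = fold,
               stringsAsFactors = FALSE)
  }
  plasma <- rbind(
    row("LCA",   "plasma", 1200, 0.4),
    row("PS",    "plasma",   20, 28),
    row("IS",    "plasma",   10, 10),
    row("HA",    "plasma",    8, 4),
    row("ImP",   "plasma",    5, 4),
    row("CMG",   "plasma",    5, 4),
    row("HHA",   "plasma",    5, 4),
    row("PAG",   "plasma",    5, 4),
    row("PAGlu", "plasma",    6, 4),
    row("p-CS",  "plasma",    5, 1),
    row("TMAO",  "plasma",    6, 1),
    row("DCA",   "plasma",    5, 1)
  )
  feces <- rbind(
    row("LCA",       "feces", 0.300, 3),
    row("DCA",       "feces", 0.350, 1),
    row("UDCA",      "feces", 0.050, 3),
    row("CA",        "feces", 0.080, 3),
    row("omega-MCA", "feces", 0.040, 3),
    row("TCA",       "feces", 0.020, 3),
    row("TCDCA",     "feces", 0.015, 3),
    row("TDCA",      "feces", 0.020, 3),
    row("TUDCA",     "feces", 0.012, 3),
    row("GCDCA",     "feces", 0.020, 1),
    row("GDCA",      "feces", 0.025, 1),
    row("GUDCA",     "feces", 0.015, 1),
    row("HA",        "feces", 0.030, 3),
    row("HHA",       "feces", 0.012, 3),
    row("PAGlu",     "feces", 0.015, 3),
    row("p-CS",      "feces", 0.150, 1),
    row("IS",        "feces", 0.050, 1),
    row("PS",        "feces", 0.040, 1),
    row("DG",        "feces", 0.020, 3),
    row("DMG",       "feces", 0.030, 3)
  )
  rbind(plasma, feces)
}

#' Concentration model
#'
#' True concentrations are log-normal per analyte x matrix x group: the PD
#' median is the HC median times `fold_change`, the log-scale SD is
#' `sqrt(log(1 + gcv^2))`, and a cell is truly present with probability
#' `det_prob`. Optional covariate effects add linear age and sex terms on the
#' log scale.
#'
#' @param panel A `panel_config`; analytes of the panel absent from `table`
#'   are treated as never present (det_prob 0).
#' @param table Data frame with columns `analyte_id`, `matrix`, `median_hc`,
#'   `gcv`, `det_prob`, `fold_change`. Defaults encode the study's cohort
#'   structure; see the vignette.
#' @param covariate_effects List with `age_slope` (per year, log scale) and
#'   `sex_female` (log-scale offset); both default to 0.
#' @return A `concentration_model`.
#' @export
concentration_model <- function(panel = default_panel(),
                                table = default_concentration_table(),
                                covariate_effects = list(age_slope = 0,
                                                         sex_female = 0)) {
  needed <- c("analyte_id", "matrix", "median_hc", "gcv", "det_prob", "fold_change")
  if (!all(needed %in% names(table))) stop("concentration table missing columns")
  if (any(table$gcv < 0)) stop("geometric CV must be >= 0")
  if (any(table$det_prob < 0 | table$det_prob > 1))
    stop("detection probabilities must lie in [0, 1]")
  if (any(table$fold_change <= 0)) stop("fold changes must be positive")
  unknown <- setdiff(table$analyte_id, panel$analytes$id)
  if (length(unknown)) stop("concentration table names analytes not in panel: ",
                            paste(unknown, collapse = ", "))
  structure(list(table = table, covariate_effects = covariate_effects,
                 panel = panel),
            class = "concentration_model")
}

#' Draw true specimen concentrations for a cohort
#'
#' @param subjects Cohort table from [simulate_cohort()].
#' @param model A [concentration_model()].
#' @param matrix `"plasma"` or `"feces"`.
#' @param seed Integer seed.
#' @return Long data frame `subject_id`, `analyte_id`, `matrix`,
#'   `true_conc` (specimen units; NA when absent), `present`.
#' @export
sample_true_concentrations <- function(subjects, model, matrix, seed = 1L) {
  stopifnot(inherits(model, "concentration_model"))
  if (!matrix %in% model$panel$matrices) stop("unknown matrix: ", matrix)
  tab <- model$table[model$table$matrix == matrix, , drop = FALSE]
  targets <- panel_targets(model$panel)
  missing <- setdiff(targets, tab$analyte_id)
  # analytes not modelled in this matrix: truly absent
  if (length(missing)) {
    tab <- rbind(tab, data.frame(analyte_id = missing, matrix = matrix,
                                 median_hc = NA_real_, gcv = 0, det_prob = 0,
                                 fold_change = 1, stringsAsFactors = FALSE))
  }
  ce <- model$covariate_effects
  withr::with_seed(seed, {
    grid <- expand.grid(subject_id = subjects$subject_id,
                        analyte_id = tab$analyte_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$matrix <- matrix
    si <- match(grid$subject_id, subjects$subject_id)
    ai <- match(grid$analyte_id, tab$analyte_id)
    sdlog <- sqrt(log(1 + tab$gcv[ai]^2))
    mu <- log(tab$median_hc[ai]) +
      log(tab$fold_change[ai]) * (subjects$group[si] == "PD") +
      ce$age_slope * (subjects$age[si] - mean(subjects$age)) +
      ce$sex_female * (subjects$sex[si] == "female")
    grid$present <- stats::runif(nrow(grid)) < tab$det_prob[ai]
    grid$true_conc <- ifelse(grid$present, exp(mu + stats::rnorm(nrow(grid), 0, sdlog)),
                             NA_real_)
    grid
  })
}

#' Instrument response model
#'
#' MRM areas are generated as
#' `area = slope * ME * conc * (1 + eps_intra) * exp(day) * f_inj * f_sup + intercept`
#' where `ME` is the per-analyte matrix-effect multiplier on the slope,
#' `eps_intra` is within-day analyte noise, `day` a day-level random effect
#' shared by all injections of a day, `f_inj` an injection factor shared by
#' analyte and internal-standard areas of the same injection, and `f_sup` an
#' occasional whole-sample suppression factor that drags both areas down and
#' violates the 80-120% internal-standard recovery window. Areas below
#' `censor_threshold` are reported missing.
#'
#' @param panel A `panel_config`.
#' @param slope,intercept Per-analyte response; recycled. Default slopes are
#'   spread over [0.6, 1.8] ratio units per uM.
#' @param matrix_effect Named list per matrix of per-analyte multipliers
#'   (recycled). Neat solvent is fixed at 1. Defaults span [0.4, 1.35],
#'   inside the admissible [0.004, 1.419] envelope.
#' @param cv_intra,cv_inter,cv_injection Variance components (fractional).
#' @param censor_fraction Censor threshold as a fraction of each analyte's
#'   slope (area units); 5e-4 by default.
#' @param suppression_prob,suppression_range Probability that a cohort
#'   sample suffers whole-sample suppression and the uniform range of the
#'   suppression factor.
#' @param recovery Per-analyte true extraction recovery (fraction) used by
#'   the spike-experiment generator; defaults spread over [0.79, 1.17].
#' @return An `instrument_model`.
#' @export
instrument_model <- function(panel = default_panel(),
                             slope = NULL, intercept = 0,
                             matrix_effect = NULL,
                             cv_intra = 0.05, cv_inter = 0.08,
                             cv_injection = 0.02,
                             censor_fraction = 5e-4,
                             suppression_prob = 0.04,
                             suppression_range = c(0.3, 0.7),
                             recovery = NULL) {
  ids <- panel$analytes$id
  n <- length(ids)
  if (is.null(slope)) slope <- seq(0.6, 1.8, length.out = n)
  slope <- rep_len(slope, n)
  intercept <- rep_len(intercept, n)
  if (any(slope <= 0)) stop("response slopes must be positive")
  if (any(c(cv_intra, cv_inter, cv_injection) < 0)) stop("CVs must be >= 0")
  if (suppression_prob < 0 || suppression_prob > 1)
    stop("suppression probability must lie in [0, 1]")
  if (is.null(matrix_effect)) {
    matrix_effect <- list(
      plasma = seq(0.5, 1.30, length.out = n),
      feces = rev(seq(0.40, 1.35, length.out = n))
    )
  }
  matrix_effect <- lapply(matrix_effect, rep_len, n)
  matrix_effect$neat <- rep(1, n)
  if (is.null(recovery)) recovery <- seq(0.79, 1.17, length.out = n)
  recovery <- rep_len(recovery, n)
  structure(list(
    analyte_id = ids, slope = slope, intercept = intercept,
    matrix_effect = matrix_effect,
    cv_intra = cv_intra, cv_inter = cv_inter, cv_injection = cv_injection,
    censor_threshold = censor_fraction * slope,
    suppression_prob = suppression_prob,
    suppression_range = suppression_range,
    recovery = recovery
  ), class = "instrument_model")
}

#' Noise-free variant of an instrument model
#'
#' Zero variance components, zero intercepts, no censoring and no
#' suppression: under this model the full simulate -> calibrate ->
#' back-calculate -> unit-convert chain is an exact identity.
#'
#' @param instrument An `instrument_model`.
#' @return The modified model.
#' @export
noise_free <- function(instrument = instrument_model()) {
  instrument$cv_intra <- 0
  instrument$cv_inter <- 0
  instrument$cv_injection <- 0
  instrument$intercept <- rep(0, length(instrument$intercept))
  instrument$censor_threshold <- rep(0, length(instrument$censor_threshold))
  instrument$suppression_prob <- 0
  instrument
}

im_field <- function(instrument, field, ids) {
  v <- instrument[[field]]
  v[match(ids, instrument$analyte_id)]
}

im_me <- function(instrument, matrix, ids) {
  me <- instrument$matrix_effect[[matrix]]
  if (is.null(me)) stop("instrument model has no matrix-effect entry for ", matrix)
  me[match(ids, instrument$analyte_id)]
}

#' Geometric calibration-level series
#'
#' Serial dilution from `high` down to `low` in `n` points.
#'
#' @param n Number of levels (10 for routine quantification, 12 for the
#'   validation design).
#' @param low,high Range in uM.
#' @return Increasing numeric vector of length `n`.
#' @export
cal_levels <- function(n = 10L, low = 0.005, high = 20) {
  if (n < 2 || low <= 0 || high <= low) stop("invalid level specification")
  exp(seq(log(low), log(high), length.out = n))
}

# Generate analyte + internal-standard areas for a set of vials.
# `vials` has one row per injection with columns: sample_id, dilution_factor,
# day, batch, role, nominal_conc (optional) and a column per analyte holding
# the extract concentration in the vial (uM). Suppression factors, if any,
# are supplied per row.
generate_areas <- function(vials, extract_conc, analyte_ids, panel, instrument,
                           matrix, suppression = NULL) {
  n_vial <- nrow(vials)
  n_an <- length(analyte_ids)
  is_id <- panel$analytes$internal_standard[match(analyte_ids, panel$analytes$id)]
  mode <- panel$analytes$esi_mode[match(analyte_ids, panel$analytes$id)]
  nominal_is <- panel$intstd_nominal[mode]

  slope <- im_field(instrument, "slope", analyte_ids)
  intercept <- im_field(instrument, "intercept", analyte_ids)
  thr <- im_field(instrument, "censor_threshold", analyte_ids)
  me <- im_me(instrument, matrix, analyte_ids)
  slope_is <- im_field(instrument, "slope", is_id)
  intercept_is <- im_field(instrument, "intercept", is_id)
  me_is <- im_me(instrument, matrix, is_id)

  day_ids <- unique(vials$day)
  day_eff <- stats::rnorm(length(day_ids), 0, instrument$cv_inter)
  names(day_eff) <- day_ids
  f_day <- exp(day_eff[vials$day])
  f_inj <- exp(stats::rnorm(n_vial, 0, instrument$cv_injection))
  f_sup <- if (is.null(suppression)) rep(1, n_vial) else suppression

  rows <- vector("list", n_an)
  for (j in seq_len(n_an)) {
    conc <- extract_conc[, j]
    eps_a <- stats::rnorm(n_vial, 0, instrument$cv_intra)
    eps_i <- stats::rnorm(n_vial, 0, instrument$cv_intra)
    area <- slope[j] * me[j] * conc * (1 + eps_a) * f_day * f_inj * f_sup +
      intercept[j]
    area_is <- slope_is[j] * me_is[j] * nominal_is[j] * (1 + eps_i) *
      f_day * f_inj * f_sup + intercept_is[j]
    area[is.na(conc)] <- NA_real_             # analyte truly absent: no peak
    area[!is.na(area) & area < thr[j]] <- NA_real_  # censored below threshold
    rows[[j]] <- data.frame(
      sample_id = vials$sample_id, analyte_id = analyte_ids[j],
      matrix = matrix, dilution_factor = vials$dilution_factor,
      analyte_area = area, intstd_area = area_is,
      batch = vials$batch, day = vials$day, role = vials$role,
      nominal_conc = if ("nominal_conc" %in% names(vials)) vials$nominal_conc else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a matrix-matched calibration series
#'
#' One record per analyte x level x replicate, with the analyte spiked at
#' the nominal level into pooled matrix extract and the internal standard at
#' its nominal mode-specific spike.
#'
#' @param panel A `panel_config`.
#' @param instrument An [instrument_model()].
#' @param matrix `"plasma"`, `"feces"` or `"neat"` (neat solvent, used for
#'   matrix-effect evaluation).
#' @param levels Increasing standard concentrations in (0, 100] uM.
#' @param replicates Injections per level (default 3).
#' @param days Number of acquisition days over which replicates are spread.
#' @param seed Integer seed.
#' @return A peak table (`data.frame`) with `role = "standard"` and
#'   `nominal_conc` set.
#' @export
simulate_calibration_series <- function(panel, instrument, matrix,
                                        levels = cal_levels(10L),
                                        replicates = 3L, days = 1L, seed = 1L) {
  if (length(levels) == 0) stop("empty calibration levels")
  if (any(levels <= 0) || any(levels > 100) || is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing within (0, 100]")
  analyte_ids <- panel_targets(panel)
  withr::with_seed(seed, {
    vials <- expand.grid(level = levels, rep = seq_len(replicates),
                         KEEP.OUT.ATTRS = FALSE)
    vials$day <- sprintf("day%d", ((vials$rep - 1L) %% days) + 1L)
    vials$batch <- "cal"
    vials$role <- "standard"
    vials$sample_id <- sprintf("std_L%02d_r%d", match(vials$level, levels), vials$rep)
    vials$dilution_factor <- 1
    vials$nominal_conc <- vials$level
    conc <- base::matrix(rep(vials$level, length(analyte_ids)),
                         ncol = length(analyte_ids))
    generate_areas(vials, conc, analyte_ids, panel, instrument, matrix)
  })
}

#' Simulate the cohort peak table
#'
#' One record per subject x analyte x dilution of the matrix's scheme. The
#' vial extract concentration is `true_conc / (prep_factor * dilution)`,
#' where `prep_factor` converts extract to specimen units (see
#' [to_specimen_units()]); the internal standard sits at its nominal spike
#' in every vial because dilutions are made with spiked solvent.
#' Whole-sample suppression, when drawn, multiplies analyte and
#' internal-standard areas in every vial of the affected sample.
#'
#' @param subjects Cohort table.
#' @param true_conc Output of [sample_true_concentrations()].
#' @param panel,instrument Panel and instrument models.
#' @param matrix `"plasma"` or `"feces"`.
#' @param days Number of acquisition days (samples assigned round-robin).
#' @param seed Integer seed.
#' @return A peak table with `role = "cohort"`.
#' @export
simulate_peak_table <- function(subjects, true_conc, panel, instrument,
                                matrix, days = 3L, seed = 1L) {
  if (!matrix %in% panel$matrices) stop("unknown matrix: ", matrix)
  scheme <- panel$dilution_schemes[[matrix]]
  prep <- prep_factor(matrix)
  analyte_ids <- panel_targets(panel)
  wide <- base::matrix(NA_real_, nrow = nrow(subjects),
                       ncol = length(analyte_ids),
                       dimnames = list(subjects$subject_id, analyte_ids))
  idx <- cbind(match(true_conc$subject_id, subjects$subject_id),
               match(true_conc$analyte_id, analyte_ids))
  keep <- !is.na(idx[, 2])
  wide[idx[keep, , drop = FALSE]] <- true_conc$true_conc[keep]

  withr::with_seed(seed, {
    sup_sample <- ifelse(
      stats::runif(nrow(subjects)) < instrument$suppression_prob,
      stats::runif(nrow(subjects), instrument$suppression_range[1],
                   instrument$suppression_range[2]),
      1
    )
    names(sup_sample) <- subjects$subject_id
    day_of <- sprintf("day%d", ((seq_len(nrow(subjects)) - 1L) %% days) + 1L)
    names(day_of) <- subjects$subject_id

    out <- lapply(scheme, function(d) {
      vials <- data.frame(sample_id = subjects$subject_id,
                          dilution_factor = d,
                          day = day_of[subjects$subject_id],
                          batch = day_of[subjects$subject_id],
                          role = "cohort", stringsAsFactors = FALSE)
      extract <- wide / (prep * d)
      generate_areas(vials, extract, analyte_ids, panel, instrument, matrix,
                     suppression = sup_sample[vials$sample_id])
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate precision runs (repeatability design)
#'
#' Mixed standards at one concentration injected `n_per_day` times within a
#' day over `days` consecutive days, the design used for intra-/inter-day
#' precision.
#'
#' @param panel,instrument,matrix As elsewhere.
#' @param conc Standard concentration (uM), default 10.
#' @param n_per_day Replicates within each day (default 10).
#' @param days Number of days (default 3).
#' @param seed Integer seed.
#' @return A peak table with `role = "qc_pool"`.
#' @export
simulate_precision_runs <- function(panel, instrument, matrix, conc = 10,
                                    n_per_day = 10L, days = 3L, seed = 1L) {
  analyte_ids <- panel_targets(panel)
  withr::with_seed(seed, {
    vials <- expand.grid(rep = seq_len(n_per_day), dayn = seq_len(days),
                         KEEP.OUT.ATTRS = FALSE)
    vials$day <- sprintf("day%d", vials$dayn)
    vials$batch <- vials$day
    vials$role <- "qc_pool"
    vials$sample_id <- sprintf("prec_d%d_r%02d", vials$dayn, vials$rep)
    vials$dilution_factor <- 1
    vials$nominal_conc <- conc
    cmat <- base::matrix(conc, nrow = nrow(vials), ncol = length(analyte_ids))
    generate_areas(vials, cmat, analyte_ids, panel, instrument, matrix)
  })
}

#' Simulate a pre-/post-spike recovery experiment
#'
#' Pre-spiked samples receive the standard before extraction, so their
#' measured concentration carries the analyte's true extraction recovery;
#' post-spiked samples receive it after extraction.
#'
#' @param panel,instrument,matrix As elsewhere.
#' @param spike Spike concentration (uM), default 10.
#' @param n Replicates (default 3).
#' @param seed Integer seed.
#' @return Data frame `analyte_id`, `matrix`, `replicate`,
#'   `pre_spiked_conc`, `post_spiked_conc` (measured, uM).
#' @export
simulate_spike_experiment <- function(panel, instrument, matrix, spike = 10,
                                      n = 3L, seed = 1L) {
  ids <- panel_targets(panel)
  rec <- im_field(instrument, "recovery", ids)
  withr::with_seed(seed, {
    grid <- expand.grid(analyte_id = ids, replicate = seq_len(n),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(grid$analyte_id, ids)
    grid$matrix <- matrix
    grid$pre_spiked_conc <- spike * rec[i] *
      (1 + stats::rnorm(nrow(grid), 0, instrument$cv_intra))
    grid$post_spiked_conc <- spike *
      (1 + stats::rnorm(nrow(grid), 0, instrument$cv_intra))
    grid[, c("analyte_id", "matrix", "replicate",
             "pre_spiked_conc", "post_spiked_conc")]
  })
}
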