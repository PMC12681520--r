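# Readers/writers for the delimited-text interchange formats and the
# end-to-end pipeline driver (simulate -> calibrate -> validate -> QC ->
# stats -> report).

peak_table_columns <- c("sample_id", "analyte_id", "matrix", "dilution_factor",
                        "analyte_area", "intstd_area", "batch", "day", "role",
                        "nominal_conc")

#' Write a peak table as CSV
#'
#' @param peaks Peak-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks[, peak_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a peak table from CSV
#'
#' Expects the documented header (one row per sample x analyte x dilution
#' with integrated areas, batch/day labels, role and, for standards, the
#' nominal concentration). Missing areas stay missing — they are never
#' coerced to zero. Unknown analyte ids and negative areas are rejected
#' with the offending value/line.
#'
#' @param path CSV path.
#' @param panel A `panel_config` used to validate analyte ids and dilution
#'   factors.
#' @return A typed peak-table data frame.
#' @export
read_peak_table <- function(path, panel) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(peak_table_columns, names(raw))
  if (length(missing_cols))
    stop("peak table is missing column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[, peak_table_columns]
  for (col in c("sample_id", "analyte_id", "matrix", "batch", "day", "role")) {
    raw[[col]] <- trimws(as.character(raw[[col]]))  # tolerate quoted padding
  }
  for (col in c("dilution_factor", "analyte_area", "intstd_area", "nominal_conc")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(v))
    if (length(bad))
      stop("malformed numeric value in column ", col, " at line ", bad[1] + 1L)
    raw[[col]] <- v
  }
  unknown <- setdiff(unique(raw$analyte_id), panel$analytes$id)
  if (length(unknown))
    stop("unknown analyte id(s): ", paste(unknown, collapse = ", "))
  neg <- which(!is.na(raw$analyte_area) & raw$analyte_area < 0 |
                 !is.na(raw$intstd_area) & raw$intstd_area < 0)
  if (length(neg)) stop("negative peak area at line ", neg[1] + 1L)
  bad_role <- setdiff(unique(raw$role), c("standard", "qc_pool", "cohort"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  if (any(raw$role == "standard" & is.na(raw$nominal_conc)))
    stop("standards must carry nominal_conc")
  raw
}

#' Write a cohort table as CSV
#' @param subjects Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV path.
#' @return Cohort data frame with `subject_id`, `group`, `age`, `sex`.
#' @export
read_cohort_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  needed <- c("subject_id", "group", "age", "sex")
  if (!all(needed %in% names(x)))
    stop("cohort table is missing column(s): ",
         paste(setdiff(needed, names(x)), collapse = ", "))
  bad <- setdiff(unique(x$group), c("HC", "PD"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  x
}

#' Pipeline run configuration
#'
#' @param seed Master integer seed; all per-stage seeds derive from it.
#' @param matrices Matrices to process (subset of the panel's).
#' @param panel A `panel_config`.
#' @param input `"synthetic"` (default) or `"peak_table"`.
#' @param peak_paths,cohort_path In `peak_table` mode, named list of peak
#'   CSV paths per matrix and the cohort CSV path.
#' @param cohort,conc_model,instrument Generator settings for synthetic
#'   mode.
#' @param detection_threshold Detection-rate threshold for the QC cascade.
#' @param significance Raw-p threshold used to call entities significant in
#'   the cross-matrix partition (default 0.01).
#' @param out_dir Optional output directory; when given, every result table
#'   plus the audit log and the configuration used are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       matrices = c("plasma", "feces"),
                       panel = default_panel(),
                       input = c("synthetic", "peak_table"),
                       peak_paths = NULL, cohort_path = NULL,
                       cohort = cohort_spec(),
                       conc_model = NULL,
                       instrument = NULL,
                       detection_threshold = 0.8,
                       significance = 0.01,
                       out_dir = NULL) {
  input <- match.arg(input)
  unknown <- setdiff(matrices, panel$matrices)
  if (length(unknown)) stop("unknown matrix: ", paste(unknown, collapse = ", "))
  if (input == "peak_table") {
    if (is.null(peak_paths) || is.null(cohort_path))
      stop("peak_table mode needs peak_paths and cohort_path")
    for (m in matrices) {
      if (is.null(peak_paths[[m]]) || !file.exists(peak_paths[[m]]))
        stop("peak table for ", m, " not found")
    }
    if (!file.exists(cohort_path)) stop("cohort table not found: ", cohort_path)
  }
  if (is.null(conc_model)) conc_model <- concentration_model(panel)
  if (is.null(instrument)) instrument <- instrument_model(panel)
  structure(list(seed = as.integer(seed), matrices = matrices, panel = panel,
                 input = input, peak_paths = peak_paths,
                 cohort_path = cohort_path, cohort = cohort,
                 conc_model = conc_model, instrument = instrument,
                 detection_threshold = detection_threshold,
                 significance = significance, out_dir = out_dir),
            class = "run_config")
}

stage_seed <- function(master, offset) (master * 131L + offset) %% 2147483647L

#' Run the full quantification pipeline
#'
#' Per matrix: simulate (or read) the calibration series, precision runs,
#' spike experiments and cohort peak table; fit matrix-matched curves;
#' build the validation report; back-calculate and QC-filter the
#' concentration matrix; run the covariate-adjusted group tests and
#' composition profile. Across matrices, partition significant entities
#' into fecal-only / shared / plasma-only. Deterministic under the
#' configured seed; when `out_dir` is set all tables, the audit log and the
#' configuration are written as delimited text.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, per-matrix results (`curves`, `validation`,
#'   `quant`, `stats`, `composition`, `intstd_gate`) and `venn`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  panel <- config$panel
  seed <- config$seed
  cohort <- if (config$input == "synthetic") {
    simulate_cohort(config$cohort, seed = stage_seed(seed, 1L))
  } else {
    read_cohort_table(config$cohort_path)
  }
  results <- list(cohort = cohort, matrices = list())
  significant <- list()
  for (k in seq_along(config$matrices)) {
    m <- config$matrices[k]
    if (config$input == "synthetic") {
      truth <- sample_true_concentrations(cohort, config$conc_model, m,
                                          seed = stage_seed(seed, 10L + k))
      standards <- simulate_calibration_series(panel, config$instrument, m,
                                               seed = stage_seed(seed, 20L + k))
      neat <- simulate_calibration_series(panel, config$instrument, "neat",
                                          seed = stage_seed(seed, 30L + k))
      runs <- simulate_precision_runs(panel, config$instrument, m,
                                      seed = stage_seed(seed, 40L + k))
      spikes <- simulate_spike_experiment(panel, config$instrument, m,
                                          seed = stage_seed(seed, 50L + k))
      peaks <- simulate_peak_table(cohort, truth, panel, config$instrument, m,
                                   seed = stage_seed(seed, 60L + k))
    } else {
      tab <- read_peak_table(config$peak_paths[[m]], panel)
      tab <- tab[tab$matrix == m, , drop = FALSE]
      standards <- tab[tab$role == "standard", , drop = FALSE]
      runs <- tab[tab$role == "qc_pool", , drop = FALSE]
      peaks <- tab[tab$role == "cohort", , drop = FALSE]
      neat <- NULL
      spikes <- data.frame(analyte_id = character(), matrix = character(),
                           replicate = integer(), pre_spiked_conc = numeric(),
                           post_spiked_conc = numeric())
    }
    curves <- fit_panel_calibrations(standards, panel)
    validation <- build_validation_report(standards, spikes, runs, panel,
                                          neat_standards = neat)
    qm <- quantify_samples(peaks, curves, panel, cohort)
    gate <- gate_internal_standard(peaks, panel, intstd_reference(standards, panel))
    flagged <- unique(gate$sample_id[gate$flagged])
    qm <- run_qc_cascade(qm, panel, flagged, config$detection_threshold)
    stats_res <- adjusted_group_test(qm, cohort)
    composition <- composition_profile(qm)
    significant[[m]] <- stats_res$entity[!is.na(stats_res$p_raw) &
                                           stats_res$p_raw < config$significance]
    results$matrices[[m]] <- list(curves = curves, validation = validation,
                                  quant = qm, stats = stats_res,
                                  composition = composition,
                                  intstd_gate = gate)
  }
  if (all(c("plasma", "feces") %in% names(significant))) {
    results$venn <- venn_partition(significant$feces, significant$plasma)
  }
  if (!is.null(config$out_dir)) write_run_outputs(results, config)
  invisible(results)
}

write_run_outputs <- function(results, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  write_cohort_table(results$cohort, file.path(od, "cohort.csv"))
  audit <- character()
  for (m in names(results$matrices)) {
    r <- results$matrices[[m]]
    utils::write.csv(r$curves, file.path(od, paste0("curves_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$validation, file.path(od, paste0("validation_", m, ".csv")),
                     row.names = FALSE)
    dfs <- qm_as_data_frames(r$quant)
    utils::write.csv(dfs$values, file.path(od, paste0("quant_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(dfs$provenance,
                     file.path(od, paste0("provenance_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$stats, file.path(od, paste0("stats_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$composition, file.path(od, paste0("composition_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$intstd_gate, file.path(od, paste0("intstd_gate_", m, ".csv")),
                     row.names = FALSE)
    audit <- c(audit, paste0("[", m, "] ", audit_log(r$quant)))
  }
  if (!is.null(results$venn)) {
    venn_df <- data.frame(partition = c("fecal_only", "shared", "plasma_only"),
                          entities = c(paste(results$venn$fecal_only, collapse = ";"),
                                       paste(results$venn$shared, collapse = ";"),
                                       paste(results$venn$plasma_only, collapse = ";")),
                          n = unname(results$venn$counts))
    utils::write.csv(venn_df, file.path(od, "venn.csv"), row.names = FALSE)
  }
  writeLines(audit, file.path(od, "audit.txt"))
  writeLines(c(
    paste("seed:", config$seed),
    paste("input:", config$input),
    paste("matrices:", paste(config$matrices, collapse = ", ")),
    paste("detection_threshold:", config$detection_threshold),
    paste("significance:", config$significance)
  ), file.path(od, "config.txt"))
  invisible(od)
}
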