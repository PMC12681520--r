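# Quality-control cascade: exclusions -> conjugate collapse -> detection-rate
# filter -> group-minimum imputation -> internal-standard recovery gate ->
# group-median imputation. The order is fixed and every rule is logged in the
# quant matrix audit trail; re-running the cascade on its own output is a
# no-op.

prov_strength <- c(absent = 0, censored = 1, imputed_min = 2,
                   imputed_median = 3, measured = 4)

#' Drop panel-excluded analytes
#'
#' @param qm A `quant_matrix`.
#' @param panel A `panel_config`.
#' @return The quant matrix without columns for excluded analytes.
#' @export
apply_exclusions <- function(qm, panel) {
  excl <- intersect(qm_entities(qm), panel$analytes$id[panel$analytes$excluded])
  keep <- setdiff(qm_entities(qm), excl)
  qm$values <- qm$values[, keep, drop = FALSE]
  qm$provenance <- qm$provenance[, keep, drop = FALSE]
  qm_add_audit(qm, "exclusions",
               sprintf("%d excluded analyte(s) removed%s", length(excl),
                       if (length(excl)) paste0(": ", paste(excl, collapse = ", ")) else ""))
}

#' Collapse co-eluting conjugates into summed group columns
#'
#' Member columns are replaced by a single column holding their sum over
#' quantified members. The group cell is `measured` only when every member
#' is measured; otherwise it takes the weakest member's provenance
#' (absent < censored < imputed_min < imputed_median < measured), and when
#' no member carries a number the cell is censored/absent accordingly.
#'
#' @param qm A `quant_matrix`.
#' @param groups Mapping from [resolve_quant_groups()].
#' @return The collapsed quant matrix.
#' @export
collapse_conjugates <- function(qm, groups) {
  multi <- groups[lengths(groups) > 1L]
  n_collapsed <- 0L
  for (g in names(multi)) {
    members <- multi[[g]]
    if (g %in% qm_entities(qm) && !any(members %in% qm_entities(qm)))
      next  # already collapsed (idempotent re-run)
    present <- intersect(members, qm_entities(qm))
    if (length(present) == 0L) next
    if (length(present) < length(members))
      warning("conjugate group ", g, " only partially present (",
              paste(present, collapse = ", "), "); summing present members")
    vals <- qm$values[, present, drop = FALSE]
    provs <- qm$provenance[, present, drop = FALSE]
    sums <- apply(vals, 1, function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    weakest <- apply(provs, 1, function(p) p[which.min(prov_strength[p])])
    gval <- ifelse(is.na(sums), NA_real_, sums)
    gprov <- weakest
    # a cell with no numeric member cannot be better than censored
    gprov[is.na(gval) & prov_strength[gprov] > prov_strength["censored"]] <- "censored"
    keep <- setdiff(qm_entities(qm), present)
    qm$values <- cbind(qm$values[, keep, drop = FALSE], gval)
    qm$provenance <- cbind(qm$provenance[, keep, drop = FALSE], gprov)
    colnames(qm$values)[ncol(qm$values)] <- g
    colnames(qm$provenance)[ncol(qm$provenance)] <- g
    n_collapsed <- n_collapsed + 1L
  }
  qm_add_audit(qm, "collapse",
               sprintf("%d conjugate group(s) collapsed", n_collapsed))
}

#' Detection-rate filter
#'
#' A reporting entity is retained only when its detection rate is at least
#' `threshold` in every group. "Fewer than 80%" excludes, so a rate of
#' exactly 80% is retained. A cell counts as detected when it holds a
#' quantifiable observation: provenance `measured`, or `imputed_median`
#' (a detected sample whose value was replaced by the IntStd gate) —
#' `censored`, `absent` and `imputed_min` cells are non-detections, which
#' keeps the cascade idempotent.
#'
#' @param qm A `quant_matrix`.
#' @param threshold Minimum per-group detection fraction (default 0.8).
#' @return The filtered quant matrix.
#' @export
detection_rate_filter <- function(qm, threshold = 0.8) {
  groups <- split(seq_len(nrow(qm$values)), qm$samples$group)
  if (any(lengths(groups) == 0)) stop("empty group")
  retained <- vapply(qm_entities(qm), function(e) {
    all(vapply(groups, function(idx) {
      mean(qm$provenance[idx, e] %in% c("measured", "imputed_median")) >= threshold
    }, logical(1)))
  }, logical(1))
  dropped <- qm_entities(qm)[!retained]
  qm$values <- qm$values[, retained, drop = FALSE]
  qm$provenance <- qm$provenance[, retained, drop = FALSE]
  qm_add_audit(qm, "detection_filter",
               sprintf("threshold %.0f%%: %d entity(ies) dropped%s",
                       100 * threshold, length(dropped),
                       if (length(dropped)) paste0(": ", paste(dropped, collapse = ", ")) else ""))
}

#' Impute missing cells with the group minimum
#'
#' Each censored/absent cell of a retained entity receives the minimum
#' measured value of its own clinical group for that entity; provenance
#' becomes `imputed_min`.
#'
#' @param qm A `quant_matrix` (after the detection filter).
#' @return The imputed quant matrix; no missing cells remain for retained
#'   entities.
#' @export
impute_group_minimum <- function(qm) {
  groups <- split(seq_len(nrow(qm$values)), qm$samples$group)
  n_imp <- 0L
  for (e in qm_entities(qm)) {
    for (idx in groups) {
      cells <- qm$provenance[idx, e]
      todo <- idx[cells %in% c("censored", "absent")]
      if (!length(todo)) next
      donors <- qm$values[idx[cells == "measured"], e]
      if (!length(donors))
        stop("no measured donor values for entity ", e,
             " in one group; cannot impute")
      qm$values[todo, e] <- min(donors)
      qm$provenance[todo, e] <- "imputed_min"
      n_imp <- n_imp + length(todo)
    }
  }
  qm_add_audit(qm, "impute_min", sprintf("%d cell(s) imputed with group minimum", n_imp))
}

#' Reference internal-standard response from calibration standards
#'
#' The internal standard sits at a single nominal level in every standard
#' vial, so its reference response is the mean internal-standard area over
#' the calibration series; a sample's back-calculated IntStd concentration
#' is `nominal * area / reference_area` (a through-origin matrix-matched
#' curve).
#'
#' @param standards Calibration peak table for one matrix.
#' @param panel A `panel_config`.
#' @return Data frame `intstd_id`, `matrix`, `ref_area`, `nominal`.
#' @export
intstd_reference <- function(standards, panel) {
  an <- panel$analytes
  is_of <- an$internal_standard[match(standards$analyte_id, an$id)]
  mat <- unique(standards$matrix)
  out <- lapply(unique(is_of), function(i) {
    mode <- an$esi_mode[an$id == i]
    data.frame(intstd_id = i, matrix = mat,
               ref_area = mean(standards$intstd_area[is_of == i], na.rm = TRUE),
               nominal = unname(panel$intstd_nominal[mode]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gate samples on back-calculated internal-standard recovery
#'
#' Per sample and internal standard (one per ESI mode), the back-calculated
#' IntStd concentration is compared with the nominal spike; recovery
#' strictly below 80% or strictly above 120% flags the sample as affected
#' by matrix effects. Samples with no IntStd area are flagged with reason
#' `missing_intstd`.
#'
#' @param peaks Cohort peak table for one matrix.
#' @param panel A `panel_config`.
#' @param reference Output of [intstd_reference()].
#' @return Data frame `sample_id`, `intstd_id`, `esi_mode`,
#'   `back_calc_conc`, `recovery`, `flagged`, `reason`.
#' @export
gate_internal_standard <- function(peaks, panel, reference) {
  an <- panel$analytes
  peaks <- peaks[peaks$role == "cohort", , drop = FALSE]
  peaks$intstd_id <- an$internal_standard[match(peaks$analyte_id, an$id)]
  out <- list()
  for (i in unique(peaks$intstd_id)) {
    ref <- reference[reference$intstd_id == i, , drop = FALSE]
    if (nrow(ref) != 1L) stop("no reference response for internal standard ", i)
    sub <- peaks[peaks$intstd_id == i, , drop = FALSE]
    agg <- stats::aggregate(intstd_area ~ sample_id, data = sub,
                            FUN = function(x) mean(x, na.rm = TRUE),
                            na.action = stats::na.pass)
    conc <- ref$nominal * agg$intstd_area / ref$ref_area
    recovery <- 100 * conc / ref$nominal
    missing <- !is.finite(recovery)
    flagged <- missing | recovery < 80 | recovery > 120
    out[[i]] <- data.frame(
      sample_id = agg$sample_id, intstd_id = i,
      esi_mode = an$esi_mode[an$id == i],
      back_calc_conc = conc, recovery = recovery, flagged = flagged,
      reason = ifelse(missing, "missing_intstd",
                      ifelse(flagged, "recovery_out_of_range", "")),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Impute flagged samples with the group median
#'
#' Every cell of a flagged sample is replaced by the median of measured
#' values from non-flagged samples of the same clinical group (the donor
#' pool excludes other flagged samples); provenance becomes
#' `imputed_median`.
#'
#' @param qm A `quant_matrix`.
#' @param flagged Character vector of flagged sample ids (e.g. from
#'   [gate_internal_standard()]).
#' @return The imputed quant matrix.
#' @export
impute_group_median_flagged <- function(qm, flagged) {
  flagged <- intersect(unique(flagged), rownames(qm$values))
  if (!length(flagged))
    return(qm_add_audit(qm, "impute_median", "0 flagged sample(s)"))
  groups <- split(seq_len(nrow(qm$values)), qm$samples$group)
  n_cells <- 0L
  for (idx in groups) {
    ids <- rownames(qm$values)[idx]
    bad <- idx[ids %in% flagged]
    if (!length(bad)) next
    donors_idx <- setdiff(idx, bad)
    if (!length(donors_idx))
      stop("all samples of a group are flagged; no donor values")
    for (e in qm_entities(qm)) {
      donors <- qm$values[donors_idx, e][qm$provenance[donors_idx, e] == "measured"]
      if (!length(donors))
        donors <- qm$values[donors_idx, e][!is.na(qm$values[donors_idx, e])]
      if (!length(donors))
        stop("no donor values for entity ", e, " in one group")
      qm$values[bad, e] <- stats::median(donors)
      qm$provenance[bad, e] <- "imputed_median"
      n_cells <- n_cells + length(bad)
    }
  }
  qm_add_audit(qm, "impute_median",
               sprintf("%d flagged sample(s), %d cell(s) imputed with group median",
                       length(flagged), n_cells))
}

#' Run the full quality-control cascade
#'
#' Fixed order: exclusions, conjugate collapse, detection-rate filter,
#' group-minimum imputation, group-median imputation of IntStd-flagged
#' samples. Idempotent: applying it to its own output changes nothing
#' (already-imputed cells are not re-imputed; flagged samples' cells are
#' already `imputed_median`).
#'
#' @param qm A `quant_matrix` fresh from [quantify_samples()].
#' @param panel A `panel_config`.
#' @param flagged Flagged sample ids from [gate_internal_standard()].
#' @param threshold Detection-rate threshold (default 0.8).
#' @return The analysis-ready quant matrix: no missing cells remain.
#' @export
run_qc_cascade <- function(qm, panel, flagged = character(), threshold = 0.8) {
  qm <- apply_exclusions(qm, panel)
  qm <- collapse_conjugates(qm, resolve_quant_groups(panel))
  qm <- detection_rate_filter(qm, threshold)
  qm <- impute_group_minimum(qm)
  qm <- impute_group_median_flagged(qm, flagged)
  qm
}
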