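#' Samples-by-entities concentration container with per-cell provenance
#'
#' A `quant_matrix` couples a numeric samples x reporting-entities matrix
#' (specimen units) with a parallel character matrix of cell provenances —
#' one of `measured`, `imputed_min`, `imputed_median`, `censored`, `absent`
#' — plus the sample annotations and an ordered audit log of the
#' quality-control rules applied to it.
#'
#' @param values Numeric matrix, rownames = sample ids.
#' @param provenance Character matrix of identical shape.
#' @param samples Data frame with at least `subject_id` and `group`,
#'   aligned with the rows.
#' @param matrix_label The specimen matrix (`"plasma"` or `"feces"`).
#' @param audit List of audit entries (each a list with `step` and `note`).
#' @return A `quant_matrix` object.
#' @export
quant_matrix <- function(values, provenance, samples, matrix_label,
                         audit = list()) {
  if (!is.matrix(values) || !is.matrix(provenance) ||
      !identical(dim(values), dim(provenance)))
    stop("values and provenance must be matrices of identical shape")
  if (nrow(values) != nrow(samples) ||
      !identical(rownames(values), samples$subject_id))
    stop("rows must align with samples$subject_id")
  bad <- setdiff(unique(as.vector(provenance)),
                 c("measured", "imputed_min", "imputed_median", "censored", "absent"))
  if (length(bad)) stop("unknown provenance value(s): ", paste(bad, collapse = ", "))
  if (any(is.na(values) & provenance %in% c("measured", "imputed_min", "imputed_median")))
    stop("measured/imputed cells must carry a value")
  structure(list(values = values, provenance = provenance, samples = samples,
                 matrix = matrix_label, audit = audit),
            class = "quant_matrix")
}

qm_add_audit <- function(qm, step, note) {
  qm$audit <- c(qm$audit, list(list(step = step, note = note)))
  qm
}

#' Entity names of a quant matrix
#' @param qm A `quant_matrix`.
#' @return Character vector of column (reporting-entity) names.
#' @export
qm_entities <- function(qm) colnames(qm$values)

#' Audit log of a quant matrix
#' @param qm A `quant_matrix`.
#' @return Character vector, one line per applied rule.
#' @export
audit_log <- function(qm) {
  vapply(qm$audit, function(e) paste0(e$step, ": ", e$note), character(1))
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("<quant_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " entities (", x$matrix, ")\n", sep = "")
  tab <- table(factor(x$provenance,
                      levels = c("measured", "imputed_min", "imputed_median",
                                 "censored", "absent")))
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  for (line in audit_log(x)) cat("  - ", line, "\n", sep = "")
  invisible(x)
}

#' Export a quant matrix as data frames
#'
#' @param qm A `quant_matrix`.
#' @return List of two data frames, `values` and `provenance`, each with
#'   `subject_id` and `group` leading columns.
#' @export
qm_as_data_frames <- function(qm) {
  base <- qm$samples[, c("subject_id", "group")]
  list(values = cbind(base, as.data.frame(qm$values, check.names = FALSE)),
       provenance = cbind(base, as.data.frame(qm$provenance, check.names = FALSE)))
}
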