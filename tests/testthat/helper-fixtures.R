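# Shared fixtures: a miniature panel and hand-built peak/quant objects used
# across the module tests. Everything is constructed in code.

tiny_panel_list <- function() {
  an <- function(id, mode, intstd, group = "none", excluded = FALSE,
                 reason = NULL, is_std = FALSE) {
    e <- list(id = id, name = id, class = "uremic_toxin", esi_mode = mode,
              internal_standard = intstd, conjugate_group = group,
              calibration_range = c(0.005, 20), excluded = excluded)
    if (!is.null(reason)) e$exclusion_reason <- reason
    if (is_std) e$internal_standard_flag <- TRUE
    e
  }
  list(
    intstd_nominal = list(negative = 10, positive = 1),
    matrices = c("plasma", "feces"),
    dilution_schemes = list(plasma = c(1, 2, 50), feces = c(1, 2, 10)),
    analytes = list(
      an("STD-neg", "negative", "STD-neg", is_std = TRUE),
      an("STD-pos", "positive", "STD-pos", is_std = TRUE),
      an("A", "negative", "STD-neg"),
      an("B", "positive", "STD-pos"),
      an("C1", "positive", "STD-pos", group = "taurine_conjugates"),
      an("C2", "positive", "STD-pos", group = "taurine_conjugates"),
      an("X", "negative", "STD-neg", excluded = TRUE, reason = "column carryover")
    )
  )
}

tiny_panel <- function() load_panel(tiny_panel_list())

# hand-built quant matrix: groups of size n_hc/n_pd, one value vector per
# entity given as list(HC = ..., PD = ...); NA value means provenance `prov_na`
make_qm <- function(entities, n_hc, n_pd, prov_na = "absent",
                    matrix_label = "plasma") {
  ids <- c(sprintf("HC%02d", seq_len(n_hc)), sprintf("PD%02d", seq_len(n_pd)))
  samples <- data.frame(subject_id = ids,
                        group = rep(c("HC", "PD"), c(n_hc, n_pd)),
                        stringsAsFactors = FALSE)
  vals <- sapply(entities, function(e) c(e$HC, e$PD))
  vals <- base::matrix(vals, nrow = n_hc + n_pd,
                       dimnames = list(ids, names(entities)))
  prov <- ifelse(is.na(vals), prov_na, "measured")
  quant_matrix(vals, prov, samples, matrix_label)
}

# standards peak table for one analyte from exact response ratios
exact_standards <- function(analyte = "A", matrix = "plasma", slope = 2,
                            intercept = 0,
                            levels = c(0.1, 1, 5, 10, 20), reps = 1) {
  grid <- expand.grid(level = levels, rep = seq_len(reps))
  data.frame(sample_id = sprintf("s%d_%d", seq_len(nrow(grid)), grid$rep),
             analyte_id = analyte, matrix = matrix, dilution_factor = 1,
             analyte_area = slope * grid$level + intercept, intstd_area = 1,
             batch = "cal", day = "day1", role = "standard",
             nominal_conc = grid$level, stringsAsFactors = FALSE)
}

# brute-force multiple-testing oracles, written directly from the step
# definitions (independent of the package implementations)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * ps[j] / j, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m); out[o] <- adj; out
}

holm_sidak_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(1:i, function(j) 1 - (1 - ps[j])^(m - j + 1), numeric(1))
    adj[i] <- min(1, max(cand))
  }
  out <- numeric(m); out[o] <- adj; out
}
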