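# Cohort statistics: covariate-adjusted group tests, exact Mann-Whitney with
# Holm-Sidak correction, Pearson 2x2 chi-square (no continuity correction),
# Spearman correlations with Benjamini-Hochberg adjustment, composition
# profiles, PCA, median +/- MAD summaries and the fecal/plasma Venn
# partition. The multiple-testing adjustments, the exact U test and the 2x2
# chi-square are implemented here from their definitions (they are the
# primitives this layer exists for) and are cross-checked against
# stats::p.adjust / wilcox.test / chisq.test in the test suite.

#' Holm-Sidak step-down adjusted p-values
#'
#' Sort raw p ascending; adjusted p_i = max over j <= i of
#' `1 - (1 - p_(j))^(m - j + 1)`, clipped to 1 — monotone non-decreasing in
#' the sorted order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sort raw p ascending; adjusted p_i = min over j >= i of
#' `m * p_(j) / j`, clipped to 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.06))  # 0.03, 0.03, 0.06
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# U statistic of sample a vs b: wins + half-ties
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided. For groups of at most `exact_max` observations each, the
#' permutation distribution of U is enumerated over all
#' `choose(n_a + n_b, n_a)` arrangements of the observed values (ties
#' handled naturally by half-counting); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return List with `u`, `p`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by full enumeration
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  u <- u_statistic(a, b)
  if (na <= exact_max && nb <= exact_max) {
    pool <- c(a, b)
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2, function(idx) u_statistic(pool[idx], pool[-idx]))
    center <- na * nb / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-12)
    return(list(u = u, p = p, method = "exact"))
  }
  # normal approximation with tie correction
  n <- na + nb
  r <- rank(c(a, b))
  ties <- table(r)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal_approx")
}

#' Family of Mann-Whitney tests with Holm-Sidak correction
#'
#' @param pairs Named list; each element is a list/pair of two numeric
#'   vectors to compare.
#' @param exact_max Passed to [mann_whitney_u()].
#' @return Data frame `test`, `u`, `p_raw`, `p_adjusted`, `method`.
#' @export
subgroup_mannwhitney <- function(pairs, exact_max = 8L) {
  res <- lapply(pairs, function(pr) mann_whitney_u(pr[[1]], pr[[2]], exact_max))
  out <- data.frame(
    test = if (is.null(names(pairs))) as.character(seq_along(pairs)) else names(pairs),
    u = vapply(res, `[[`, numeric(1), "u"),
    p_raw = vapply(res, `[[`, numeric(1), "p"),
    method = vapply(res, `[[`, character(1), "method"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- holm_sidak_adjust(out$p_raw)
  out[, c("test", "u", "p_raw", "p_adjusted", "method")]
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' `X^2 = N (ad - bc)^2 / (row1 row2 col1 col2)`, df = 1. The continuity
#' correction is deliberately omitted (the convention needed to reproduce a
#' printed p-value from a sex-distribution table of this kind).
#'
#' @param table 2x2 numeric matrix of counts.
#' @return List with `statistic`, `p`, `df`.
#' @examples
#' chi_square_2x2(matrix(c(32, 7, 25, 21), 2))$p  # ~0.00677
#' @export
chi_square_2x2 <- function(table) {
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- n * (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])^2 /
    prod(rowSums(table), colSums(table))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Covariate-adjusted group comparison per entity
#'
#' Ordinary least squares of (by default log-transformed) concentration on
#' group + age + sex per reporting entity; the reported effect is the PD
#' offset (HC is the reference level) with its two-sided p-value, adjusted
#' across entities.
#'
#' @param qm An analysis-ready `quant_matrix` (no missing cells).
#' @param covariates Subject table with `subject_id`, `age`, `sex`.
#' @param log_transform Model log concentration (default TRUE; concentration
#'   data are right-skewed).
#' @param adjust_method Adjustment across entities: `"BH"` (default),
#'   `"holm_sidak"` or `"none"`.
#' @return Data frame (class `stats_result`), ranked by raw p: `entity`,
#'   `effect` (group coefficient on the analysis scale), `p_raw`,
#'   `p_adjusted`, `adjust_method`, `test`, `covariates`, `n_hc`, `n_pd`,
#'   `flag` (`constant_entity` when the test is undefined).
#' @export
adjusted_group_test <- function(qm, covariates,
                                log_transform = TRUE,
                                adjust_method = c("BH", "holm_sidak", "none")) {
  adjust_method <- match.arg(adjust_method)
  if (any(is.na(qm$values)))
    stop("quant matrix still has missing cells; run the QC cascade first")
  cv <- covariates[match(qm$samples$subject_id, covariates$subject_id), , drop = FALSE]
  if (any(is.na(cv$age)) || any(is.na(cv$sex))) stop("covariates incomplete")
  group <- factor(qm$samples$group, levels = c("HC", "PD"))
  sex <- factor(cv$sex)
  age <- cv$age
  rows <- lapply(qm_entities(qm), function(e) {
    y <- qm$values[, e]
    if (log_transform) y <- log(y)
    if (stats::sd(y) == 0) {
      return(data.frame(entity = e, effect = NA_real_, p_raw = NA_real_,
                        flag = "constant_entity", stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ group + age + sex)
    sm <- summary(fit)$coefficients
    data.frame(entity = e, effect = sm["groupPD", "Estimate"],
               p_raw = sm["groupPD", "Pr(>|t|)"], flag = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(adjust_method,
                           BH = bh_adjust(out$p_raw),
                           holm_sidak = holm_sidak_adjust(out$p_raw),
                           none = out$p_raw)
  out$adjust_method <- adjust_method
  out$test <- if (log_transform) "lm_log" else "lm"
  out$covariates <- "age+sex"
  out$n_hc <- sum(group == "HC")
  out$n_pd <- sum(group == "PD")
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  class(out) <- c("stats_result", class(out))
  out
}

#' Spearman correlations with Benjamini-Hochberg adjustment
#'
#' Rank correlation (average ranks for ties) of every reporting entity
#' against every clinical variable, with pairwise deletion of incomplete
#' observations; p-values from the tie-corrected approximation of
#' [stats::cor.test()], adjusted by [bh_adjust()] across the full pair
#' family; significance at adjusted p < 0.05.
#'
#' @param qm A `quant_matrix`.
#' @param variables Data frame of clinical variables, rows aligned with
#'   `qm$samples` (a `subject_id` column, if present, is used to align).
#' @param min_pairs Minimum complete pairs per correlation (default 3);
#'   pairs below it are skipped.
#' @return Data frame `entity`, `variable`, `n`, `rho`, `p_raw`, `p_bh`,
#'   `significant`.
#' @export
spearman_bh <- function(qm, variables, min_pairs = 3L) {
  if ("subject_id" %in% names(variables)) {
    variables <- variables[match(qm$samples$subject_id, variables$subject_id), ,
                           drop = FALSE]
    variables$subject_id <- NULL
  }
  rows <- list()
  for (e in qm_entities(qm)) {
    for (v in names(variables)) {
      x <- qm$values[, e]
      y <- variables[[v]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_pairs) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[paste(e, v)]] <- data.frame(
        entity = e, variable = v, n = sum(ok),
        rho = unname(ct$estimate), p_raw = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bh <- bh_adjust(out$p_raw)
  out$significant <- !is.na(out$p_bh) & out$p_bh < 0.05
  out
}

#' Per-group composition profile
#'
#' The percentage each entity contributes to the summed per-group central
#' concentration; percentages sum to 100 within each group.
#'
#' @param qm A `quant_matrix`.
#' @param center `"mean"` (default) or `"median"`.
#' @return Data frame `group`, `entity`, `percent`.
#' @export
composition_profile <- function(qm, center = c("mean", "median")) {
  center <- match.arg(center)
  fn <- if (center == "mean") mean else stats::median
  rows <- list()
  for (g in unique(qm$samples$group)) {
    idx <- qm$samples$group == g
    centers <- apply(qm$values[idx, , drop = FALSE], 2, fn, na.rm = TRUE)
    if (any(centers < 0, na.rm = TRUE)) stop("negative concentrations")
    tot <- sum(centers, na.rm = TRUE)
    if (!is.finite(tot) || tot == 0) {
      warning("all-zero group ", g, "; composition undefined")
      next
    }
    rows[[g]] <- data.frame(group = g, entity = names(centers),
                            percent = 100 * centers / tot,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal component analysis of a quant matrix
#'
#' Column-centred (and unit-variance scaled by default) singular value
#' decomposition via [stats::prcomp()]. Zero-variance columns are dropped
#' with a warning under unit scaling.
#'
#' @param qm A `quant_matrix` (at least 2 entities, 3 samples).
#' @param scaling `"unit_variance"` (default) or `"center_only"`.
#' @param log_transform Log-transform values first (default TRUE).
#' @return List with `scores`, `loadings`, `explained` (variance fractions
#'   summing to 1 over all components) and `samples`.
#' @export
pca_scores <- function(qm, scaling = c("unit_variance", "center_only"),
                       log_transform = TRUE) {
  scaling <- match.arg(scaling)
  x <- qm$values
  if (ncol(x) < 2L || nrow(x) < 3L) stop("need at least 2 entities and 3 samples")
  if (log_transform) x <- log(x)
  if (scaling == "unit_variance") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scaling == "unit_variance")
  list(scores = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       samples = qm$samples)
}

#' Median and raw median absolute deviation
#'
#' The MAD is reported raw (no 1.4826 consistency factor), the convention
#' used for clinical summary tables of the form "median +/- MAD".
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric `c(median =, mad =)`.
#' @examples
#' median_mad_summary(c(65, 80, 50, 65, 95, 35))  # 65, 15
#' @export
median_mad_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  c(median = stats::median(values), mad = stats::mad(values, constant = 1))
}

#' Partition significant entities across the two matrices
#'
#' @param significant_fecal,significant_plasma Character vectors of
#'   reporting-entity ids.
#' @return List `fecal_only`, `shared`, `plasma_only` plus `counts`.
#' @export
venn_partition <- function(significant_fecal, significant_plasma) {
  fecal_only <- setdiff(significant_fecal, significant_plasma)
  shared <- intersect(significant_fecal, significant_plasma)
  plasma_only <- setdiff(significant_plasma, significant_fecal)
  list(fecal_only = fecal_only, shared = shared, plasma_only = plasma_only,
       counts = c(fecal_only = length(fecal_only), shared = length(shared),
                  plasma_only = length(plasma_only)))
}

#' Percentage of a printed count
#'
#' Cohort-table convenience: `100 * n / total` rounded to `digits`.
#'
#' @param n,total Counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' percent_of(32, 57)  # 56.1
#' @export
percent_of <- function(n, total, digits = 1) {
  if (total <= 0) stop("total must be positive")
  round(100 * n / total, digits)
}

#' Significance label for a p-value
#'
#' Maps p to the conventional star labels: `****` < 0.0001, `***` < 0.001,
#' `**` < 0.01, `*` < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
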