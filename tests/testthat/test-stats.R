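test_that("Holm-Sidak and BH match worked examples and increase raw p", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.06)), c(0.03, 0.03, 0.06))
  withr::with_seed(51, {
    for (i in 1:50) {
      p <- runif(sample(1:10, 1))
      hs <- holm_sidak_adjust(p)
      bh <- bh_adjust(p)
      expect_true(all(hs >= p - 1e-15))
      expect_true(all(bh >= p - 1e-15))
      # monotone in the raw ordering
      o <- order(p)
      expect_true(all(diff(hs[o]) >= -1e-15))
      expect_true(all(diff(bh[o]) >= -1e-15))
      # BH agrees with the reference implementation
      expect_equal(bh, p.adjust(p, "BH"), tolerance = 1e-12)
    }
  })
})

test_that("the exact Mann-Whitney test agrees with enumeration and wilcox.test", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)      # 2 of the 20 arrangements are as extreme
  expect_equal(res$method, "exact")
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  withr::with_seed(52, {
    for (i in 1:20) {
      a <- rnorm(sample(3:6, 1))
      b <- rnorm(sample(3:6, 1))
      mine <- mann_whitney_u(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
    # large-sample path against the reference normal approximation
    a <- rnorm(30); b <- rnorm(25) + 0.5
    mine <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$method, "normal_approx")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  })
})

test_that("subgroup test families are Holm-Sidak corrected", {
  out <- subgroup_mannwhitney(list(
    ps = list(c(1, 2, 3), c(4, 5, 6)),
    imp = list(c(1, 3, 5), c(2, 4, 6))
  ))
  expect_equal(out$p_adjusted, holm_sidak_adjust(out$p_raw))
  expect_true(all(out$p_adjusted >= out$p_raw))
})

test_that("2x2 chi-square matches the closed form and the reference", {
  res <- chi_square_2x2(matrix(c(32, 7, 25, 21), 2))
  ref <- chisq.test(matrix(c(32, 7, 25, 21), 2), correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # proportional table: statistic 0, p 1
  res0 <- chi_square_2x2(matrix(c(10, 20, 5, 10), 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # closed form N(ad-bc)^2 / product of margins
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 10), 2)), "margin")
})

test_that("the adjusted group test recovers an exact group offset", {
  n <- 20
  samples <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        group = rep(c("HC", "PD"), each = n / 2),
                        stringsAsFactors = FALSE)
  cov <- data.frame(subject_id = samples$subject_id,
                    age = rep(c(30, 40), n / 2),      # balanced covariates
                    sex = rep(c("female", "male"), n / 2))
  y <- exp(2 * (samples$group == "PD"))
  qm <- quant_matrix(base::matrix(y, ncol = 1,
                                  dimnames = list(samples$subject_id, "e")),
                     base::matrix("measured", n, 1,
                                  dimnames = list(samples$subject_id, "e")),
                     samples, "plasma")
  res <- suppressWarnings(adjusted_group_test(qm, cov))  # zero residuals by design
  expect_equal(res$effect, 2, tolerance = 1e-10)
  # constant entity is flagged, not an error
  qm$values[, 1] <- 1
  res2 <- adjusted_group_test(qm, cov)
  expect_equal(res2$flag, "constant_entity")
  expect_true(is.na(res2$p_raw))
})

test_that("the adjusted group test holds its nominal size under the null", {
  withr::with_seed(53, {
    cohort <- simulate_cohort(cohort_spec(), seed = 54)
    k <- 200
    vals <- base::matrix(exp(rnorm(nrow(cohort) * k, 0, 0.5)), ncol = k,
                         dimnames = list(cohort$subject_id, paste0("e", 1:k)))
    qm <- quant_matrix(vals,
                       base::matrix("measured", nrow(cohort), k,
                                    dimnames = dimnames(vals)),
                       cohort, "plasma")
    res <- adjusted_group_test(qm, cohort)
    alpha_hat <- mean(res$p_raw < 0.05)
    expect_lt(alpha_hat, 0.05 + 2 * sqrt(0.05 * 0.95 / k))
  })
})

test_that("designed fold-changes are recovered with high power at study size", {
  # power for a 3-fold effect at n = 60/31 with the default biological CV,
  # age/sex-adjusted; reduced replication
  withr::with_seed(55, {
    hits <- replicate(60, {
      cohort <- simulate_cohort(cohort_spec(), seed = sample.int(1e6, 1))
      y <- exp(rnorm(nrow(cohort), 0, 0.5) + log(3) * (cohort$group == "PD"))
      vals <- base::matrix(y, ncol = 1,
                           dimnames = list(cohort$subject_id, "e"))
      qm <- quant_matrix(vals, base::matrix("measured", nrow(cohort), 1,
                                            dimnames = dimnames(vals)),
                         cohort, "plasma")
      adjusted_group_test(qm, cohort)$p_raw < 0.05
    })
    expect_gt(mean(hits), 0.9)
  })
})

test_that("Spearman correlations use pairwise deletion and BH adjustment", {
  n <- 30
  samples <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        group = rep(c("HC", "PD"), each = n / 2))
  withr::with_seed(56, {
    x <- rlnorm(n)
    vals <- base::matrix(c(x, exp(rnorm(n))), ncol = 2,
                         dimnames = list(samples$subject_id, c("mono", "noise")))
  })
  qm <- quant_matrix(vals, base::matrix("measured", n, 2,
                                        dimnames = dimnames(vals)),
                     samples, "plasma")
  clin <- data.frame(v1 = vals[, "mono"]^2,            # perfectly monotone
                     v2 = c(NA, NA, rnorm(n - 2)))
  out <- spearman_bh(qm, clin)
  expect_equal(out$rho[out$entity == "mono" & out$variable == "v1"], 1)
  expect_equal(out$n[out$entity == "mono" & out$variable == "v2"], n - 2L)
  expect_equal(out$p_bh, bh_adjust(out$p_raw))
  # too few pairs: skipped
  clin$v3 <- c(rnorm(2), rep(NA, n - 2))
  out2 <- spearman_bh(qm, clin)
  expect_false("v3" %in% out2$variable)
})

test_that("independent pairs rarely pass the BH threshold", {
  withr::with_seed(57, {
    fp <- replicate(200, {
      p <- vapply(1:8, function(i) {
        suppressWarnings(cor.test(rnorm(20), rnorm(20),
                                  method = "spearman", exact = FALSE)$p.value)
      }, numeric(1))
      any(bh_adjust(p) < 0.05)
    })
    expect_lt(mean(fp), 0.1)  # FDR control: family-level false positives ~5%
  })
})

test_that("composition percentages are normalized per group", {
  qm <- make_qm(list(a = list(HC = c(94, 94), PD = c(50, 50)),
                     b = list(HC = c(6, 6), PD = c(50, 50))), 2, 2)
  comp <- composition_profile(qm)
  expect_equal(comp$percent[comp$group == "HC" & comp$entity == "a"], 94)
  expect_equal(comp$percent[comp$group == "HC" & comp$entity == "b"], 6)
  for (g in c("HC", "PD"))
    expect_equal(sum(comp$percent[comp$group == g]), 100, tolerance = 1e-9)
  # single entity: 100%
  qm1 <- make_qm(list(a = list(HC = c(1, 2), PD = c(3, 4))), 2, 2)
  expect_true(all(composition_profile(qm1)$percent == 100))
})

test_that("PCA explains one-dimensional data on PC1 and conserves variance", {
  n <- 10
  samples <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        group = rep(c("HC", "PD"), each = n / 2))
  t_axis <- seq_len(n)
  vals <- base::matrix(exp(cbind(t_axis, 2 * t_axis, -t_axis)), ncol = 3,
                       dimnames = list(samples$subject_id, c("a", "b", "c")))
  qm <- quant_matrix(vals, base::matrix("measured", n, 3,
                                        dimnames = dimnames(vals)),
                     samples, "plasma")
  pc <- pca_scores(qm)
  expect_equal(pc$explained[1], 1, tolerance = 1e-10)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-10)
  # orthogonal score components
  cp <- crossprod(pc$scores)
  expect_equal(cp[1, 2], 0, tolerance = 1e-8)
  # separated groups land apart on PC1 (plasma defaults); nulls do not
  res <- run_pipeline(run_config(seed = 58, matrices = "plasma"))
  pc2 <- pca_scores(res$matrices$plasma$quant)
  s1 <- pc2$scores[, 1]
  centers <- tapply(s1, pc2$samples$group, mean)
  spread <- tapply(s1, pc2$samples$group, sd)
  expect_gt(abs(diff(centers)), max(spread))
})

test_that("median and raw MAD follow the clinical-summary convention", {
  expect_equal(median_mad_summary(c(1, 2, 3)), c(median = 2, mad = 1))
  expect_equal(median_mad_summary(rep(7, 5)), c(median = 7, mad = 0))
  expect_equal(median_mad_summary(c(65, 80, 50, 65, 95, 35)),
               c(median = 65, mad = 15))
  expect_error(median_mad_summary(numeric(0)), "empty")
})

test_that("the Venn partition is plain set arithmetic", {
  v <- venn_partition(c("a", "b", "c"), c("c", "d"))
  expect_setequal(v$fecal_only, c("a", "b"))
  expect_equal(v$shared, "c")
  expect_equal(v$plasma_only, "d")
  expect_equal(unname(v$counts), c(2L, 1L, 1L))
  expect_equal(venn_partition(c("a"), c("b"))$shared, character(0))
  expect_equal(venn_partition(c("a"), c("a"))$counts[["shared"]], 1L)
})

test_that("significance labels map the conventional thresholds", {
  expect_equal(significance_label(c(5e-5, 5e-4, 5e-3, 0.03, 0.2)),
               c("****", "***", "**", "*", "ns"))
})
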