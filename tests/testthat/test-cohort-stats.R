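# Descriptives, correlation structure, median split and Mann-Whitney.

test_that("descriptives follow the mean +/- sd (range) convention", {
  d <- data.frame(v = c(1, 2, 3), w = c(5, 5, 5), u = c(NA, NA, NA))
  s <- summarize_cohort(d, c("v", "w", "u"))
  expect_equal(s$mean[1], 2)
  expect_equal(s$sd[1], 1) # sample (n - 1) standard deviation
  expect_equal(c(s$min[1], s$max[1]), c(1, 3))
  expect_equal(s$sd[2], 0)
  expect_true(s$all_missing[3])

  coh <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 17))
  sc <- summarize_cohort(coh, "r_ec")
  expect_equal(sc$mean, 0.035, tolerance = 0.03)
})

test_that("correlation matrix is exact, symmetric and affine-invariant", {
  x <- c(0.2, 1.5, 2.2, 3.9, 5.1)
  d <- data.frame(x = x, y = 2 * x + 1, z = -x,
                  r = c(0.5, 2.5, 1.5, 4.5, 3.5))
  m <- correlation_matrix(d)
  expect_equal(m["x", "y"], 1)
  expect_equal(m["x", "z"], -1)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(1, 4), colnames(m)))
  # direct covariance-formula oracle
  oracle <- sum((x - mean(x)) * (d$r - mean(d$r))) /
    sqrt(sum((x - mean(x))^2) * sum((d$r - mean(d$r))^2))
  expect_equal(m["x", "r"], oracle, tolerance = 1e-12)
  # affine transforms preserve |r| and flip sign with the slope
  d2 <- transform(d, r = -3 * r + 10)
  m2 <- correlation_matrix(d2)
  expect_equal(m2["x", "r"], -m["x", "r"], tolerance = 1e-12)
  # zero-variance variable gives NA cells, not an error
  d$c <- 1
  mc <- correlation_matrix(d)
  expect_true(is.na(mc["c", "x"]))
})

test_that("median split sends ties to the low group and halves even cohorts", {
  coh <- generate_cohort(cohort_spec(seed = 2)) # 22 distinct Lc values
  sp <- median_split(coh, "lc_mm")
  expect_equal(nrow(sp$low), 11)
  expect_equal(nrow(sp$high), 11)
  expect_true(max(sp$low$lc_mm) < min(sp$high$lc_mm))

  d <- data.frame(lc_mm = c(1, 2, 3))
  sp3 <- median_split(d)
  expect_equal(sp3$low$lc_mm, c(1, 2)) # the median itself goes low
  expect_equal(sp3$high$lc_mm, 3)

  expect_warning(median_split(data.frame(lc_mm = rep(2, 5))),
                 "degenerate")
})

test_that("random median splits are monotone in the split key", {
  for (i in 1:20) {
    coh <- generate_cohort(cohort_spec(n_subjects = 10 + i, seed = 100 + i))
    sp <- median_split(coh, "lc_mm")
    expect_true(all(outer(sp$low$lc_mm, sp$high$lc_mm, `<`)))
  }
})

test_that("Mann-Whitney exact enumeration matches known cases", {
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$u_statistic, 0)
  expect_equal(sep$p_value, 2 / 20) # 2 of the C(6,3) = 20 assignments

  expect_error(mann_whitney(numeric(0), 1:3),
               class = "skinmorph_validation_error")
})

test_that("exact p-values match permutation and wilcox.test oracles", {
  set.seed(5)
  for (i in 1:12) {
    n1 <- sample(3:5, 1)
    n2 <- sample(3:5, 1)
    lo <- round(rnorm(n1, 0, 2), 2)
    hi <- round(rnorm(n2, 1, 2), 2)
    got <- mann_whitney(lo, hi)$p_value
    expect_equal(got, mw_permutation_oracle(lo, hi), tolerance = 1e-12)
    if (!any(duplicated(c(lo, hi)))) {
      ref <- stats::wilcox.test(lo, hi, exact = TRUE)$p.value
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("large-sample approximation tracks wilcox.test", {
  set.seed(8)
  lo <- rnorm(15)
  hi <- rnorm(15, 0.8)
  got <- mann_whitney(lo, hi)$p_value
  ref <- stats::wilcox.test(lo, hi, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("the low/high-Lc table flags the planted effect and only it", {
  coh <- generate_cohort(cohort_spec(latent_corr = 0.9, seed = 6))
  tab <- table2_report(coh)
  expect_equal(nrow(tab), 13)
  expect_true(tab$significant[tab$variable == "r_ec"])
  # R_EC is higher in the high-Lc group
  expect_gt(tab$mean_high[tab$variable == "r_ec"],
            tab$mean_low[tab$variable == "r_ec"])
  # the split key itself is always significant for distinct values
  expect_true(tab$significant[tab$variable == "lc_mm"])
  covs <- c("age_years", "weight_kg", "height_cm", "bmi_kg_m2")
  expect_true(all(tab$label[tab$variable %in% covs] == "N.S.D" |
                    tab$p_value[tab$variable %in% covs] >= 0.01))
})
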