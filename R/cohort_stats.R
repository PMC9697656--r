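# Cohort-level statistics: descriptives, correlation structure, median
# split on the characteristic length, and Mann-Whitney U group
# comparisons.

#' Per-variable descriptive statistics of a cohort
#'
#' Mean, sample standard deviation (n - 1), and range for each requested
#' numeric variable, matching the usual "mean +/- sd (range)"
#' presentation.  Variables with fewer than 2 non-missing values are
#' flagged rather than failed.
#'
#' @param records cohort data frame.
#' @param variables character vector of column names (default: all
#'   numeric columns).
#' @return data frame with columns `variable`, `n`, `mean`, `sd`, `min`,
#'   `max`, `all_missing`.
#' @export
summarize_cohort <- function(records, variables = NULL) {
  check(is.data.frame(records), "records must be a data frame")
  if (is.null(variables))
    variables <- names(records)[vapply(records, is.numeric, logical(1))]
  rows <- lapply(variables, function(v) {
    check(v %in% names(records), paste("unknown variable:", v))
    x <- records[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 2)
      return(data.frame(variable = v, n = length(x), mean = NA_real_,
                        sd = NA_real_, min = NA_real_, max = NA_real_,
                        all_missing = length(x) == 0))
    data.frame(variable = v, n = length(x), mean = mean(x), sd = sd(x),
               min = min(x), max = max(x), all_missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix of cohort variables
#'
#' Symmetric matrix of pairwise-complete Pearson correlations, the data
#' behind the usual correlation heatmap.  Zero-variance variables yield
#' `NA` cells (reported, not an error).
#'
#' @param records cohort data frame.
#' @param variables character vector of numeric column names.
#' @return correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(records, variables = NULL) {
  check(is.data.frame(records), "records must be a data frame")
  if (is.null(variables))
    variables <- names(records)[vapply(records, is.numeric, logical(1))]
  check(all(variables %in% names(records)), "unknown variable requested")
  m <- as.matrix(records[variables])
  check(nrow(m) >= 3, "need at least 3 records")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r)[colSums(!is.na(m)) > 0] <- 1
  r
}

#' Median split of a cohort on one variable
#'
#' Records with the key at or below the median go to the low group,
#' records above the median to the high group; ties at the median are
#' assigned to the low group so the split is deterministic.  An even
#' number of distinct values therefore yields equal halves.
#'
#' @param records cohort data frame.
#' @param key column to split on (default `"lc_mm"`).
#' @return list with `low`, `high` (data frames), `median` and
#'   `n_ties_at_median`; degenerate splits (all values identical) carry a
#'   `degenerate` flag and a warning.
#' @export
median_split <- function(records, key = "lc_mm") {
  check(is.data.frame(records) && key %in% names(records),
        paste("records must contain column", key))
  v <- records[[key]]
  keep <- !is.na(v)
  check(sum(keep) >= 2, "need >= 2 non-missing key values")
  med <- median(v[keep])
  low <- records[keep & v <= med, , drop = FALSE]
  high <- records[keep & v > med, , drop = FALSE]
  degenerate <- nrow(high) == 0
  if (degenerate)
    warning("median split is degenerate: all key values at the median")
  list(low = low, high = high, median = med,
       n_ties_at_median = sum(v[keep] == med), degenerate = degenerate)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided test of a location difference between independent samples.
#' For combined sample sizes up to `exact_max_n` the p-value is computed
#' by complete enumeration of all group assignments of the pooled
#' (tie-averaged) ranks, which remains exact in the presence of ties.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param low,high numeric value vectors of the two groups (both
#'   non-empty).
#' @param variable optional variable name carried into the output.
#' @param alpha significance level for the `significant` flag.
#' @param exact_max_n largest combined n for exact enumeration.
#' @return object of class `group_comparison`: list with `variable`,
#'   `mean_low`, `sd_low`, `mean_high`, `sd_high`, `u_statistic`
#'   (U of the low group), `p_value`, `method`, `significant`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))$p_value # 0.1 (exact)
#' @export
mann_whitney <- function(low, high, variable = NA_character_, alpha = 0.05,
                         exact_max_n = 20L) {
  low <- low[!is.na(low)]
  high <- high[!is.na(high)]
  check(length(low) >= 1 && length(high) >= 1,
        "both groups must be non-empty")
  n1 <- length(low)
  n2 <- length(high)
  pooled <- c(low, high)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 + n2 <= exact_max_n) {
    method <- "exact enumeration"
    combs <- combn(n1 + n2, n1)
    rsums <- colSums(matrix(rk[combs], nrow = n1))
    u_all <- rsums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    method <- "normal approximation (tie-corrected)"
    nt <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }
  structure(
    list(variable = variable, mean_low = mean(low), sd_low = sd(low),
         mean_high = mean(high), sd_high = sd(high), u_statistic = u_obs,
         p_value = p, method = method, significant = p < alpha,
         alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: low %.4g +/- %.4g vs high %.4g +/- %.4g, U = %.4g, p = %.3g%s\n",
              ifelse(is.na(x$variable), "comparison", x$variable),
              x$mean_low, x$sd_low, x$mean_high, x$sd_high,
              x$u_statistic, x$p_value,
              ifelse(x$significant, " *", " (N.S.D)")))
  invisible(x)
}

# standard comparison variables: experimental measurements plus patient
# covariates
table2_variables <- function() {
  c("r_ec", "lc_mm", "np_per_mm2", "mean_area_mm2", "mean_perimeter_mm",
    "mean_major_mm", "mean_minor_mm", "mean_aspect_ratio", "ra_um",
    "age_years", "weight_kg", "height_cm", "bmi_kg_m2")
}

#' Low-Lc versus high-Lc group comparison table
#'
#' Splits the cohort at the median of `split_key` and compares every
#' experimental and demographic variable between the two groups with
#' [mann_whitney()], reproducing the structure of the classical low/high
#' characteristic-length comparison table (one row per variable, "N.S.D"
#' when p >= alpha).
#'
#' @param records cohort data frame (see [generate_cohort()] for the
#'   expected columns).
#' @param split_key grouping variable (default `"lc_mm"`).
#' @param alpha significance level.
#' @param variables variables to compare (default: the 13 standard rows).
#' @param exact_max_n passed to [mann_whitney()].
#' @return data frame with one row per variable: `variable`, `mean_low`,
#'   `sd_low`, `mean_high`, `sd_high`, `u_statistic`, `p_value`,
#'   `significant`, `label` ("p" formatted or "N.S.D").
#' @export
table2_report <- function(records, split_key = "lc_mm", alpha = 0.05,
                          variables = table2_variables(),
                          exact_max_n = 20L) {
  variables <- intersect(variables, names(records))
  check(length(variables) > 0, "no requested variable present in records")
  sp <- median_split(records, split_key)
  rows <- lapply(variables, function(v) {
    cmp <- mann_whitney(sp$low[[v]], sp$high[[v]], variable = v,
                        alpha = alpha, exact_max_n = exact_max_n)
    data.frame(variable = v, mean_low = cmp$mean_low, sd_low = cmp$sd_low,
               mean_high = cmp$mean_high, sd_high = cmp$sd_high,
               u_statistic = cmp$u_statistic, p_value = cmp$p_value,
               significant = cmp$significant,
               label = if (cmp$significant)
                 sprintf("p = %.3g", cmp$p_value) else "N.S.D")
  })
  do.call(rbind, rows)
}
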