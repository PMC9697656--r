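# Shared oracles and fixtures, all generated in code.

# Exhaustive-restart Lloyd oracle for k = 2 on raw 1-D values: runs Lloyd
# from every pair of distinct observed values (vectorised across
# restarts) and returns the centroids of the lowest-WCSS solution.
lloyd_restart_oracle_k2 <- function(values, max_iter = 200) {
  x <- sort(unique(values))
  w <- tabulate(match(values, x))
  cw <- cumsum(w)
  cwx <- cumsum(w * x)
  tot_w <- cw[length(x)]
  tot_wx <- cwx[length(x)]
  pairs <- t(combn(length(x), 2))
  c1 <- x[pairs[, 1]]
  c2 <- x[pairs[, 2]]
  for (it in seq_len(max_iter)) {
    i <- findInterval((c1 + c2) / 2, x)
    i[i < 1] <- 1
    i[i >= length(x)] <- length(x) - 1
    n1 <- cw[i]
    new1 <- cwx[i] / n1
    new2 <- (tot_wx - cwx[i]) / (tot_w - n1)
    if (max(abs(new1 - c1)) < 1e-12 && max(abs(new2 - c2)) < 1e-12) {
      c1 <- new1
      c2 <- new2
      break
    }
    c1 <- new1
    c2 <- new2
  }
  i <- findInterval((c1 + c2) / 2, x)
  cwxx <- cumsum(w * x^2)
  tot_wxx <- cwxx[length(x)]
  wcss <- (cwxx[i] - cwx[i]^2 / cw[i]) +
    ((tot_wxx - cwxx[i]) - (tot_wx - cwx[i])^2 / (tot_w - cw[i]))
  best <- which.min(wcss)
  sort(c(c1[best], c2[best]))
}

# Match recovered watershed regions to true tessellation cells by looking
# up the recovered label at each true seed position.
match_regions_to_truth <- function(labels, truth, mm_per_pixel, npx) {
  px_of <- function(mm) pmin(pmax(round(mm / mm_per_pixel + 0.5), 1), npx)
  labels[cbind(px_of(truth$seed_y_mm), px_of(truth$seed_x_mm))]
}

# Interior polygon-count recovery, independent of border-flag
# conventions: the number of distinct watershed regions claimed by the
# true interior seeds, plus any leftover non-border regions not claimed
# by any seed (splits and noise regions count against recovery, merges
# collapse matched labels).
interior_recovery_counts <- function(labels, truth, features, mm_per_pixel,
                                     npx, min_area = 0.01) {
  px_of <- function(mm) pmin(pmax(round(mm / mm_per_pixel + 0.5), 1), npx)
  seed_lab <- labels[cbind(px_of(truth$seed_y_mm), px_of(truth$seed_x_mm))]
  interior <- !truth$touches_border
  matched <- unique(seed_lab[interior & seed_lab > 0])
  unmatched <- setdiff(
    features$label[features$area_mm2 >= min_area & !features$touches_border],
    seed_lab)
  c(n_rec = length(matched) + length(unmatched), n_true = sum(interior))
}

# Brute-force two-sided Mann-Whitney p-value by permutation enumeration
# on the raw values (independent of the package's rank-based route).
mw_permutation_oracle <- function(low, high) {
  n1 <- length(low)
  pooled <- c(low, high)
  stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- stat(seq_len(n1))
  mu <- n1 * (length(pooled) - n1) / 2
  combs <- combn(length(pooled), n1)
  u_all <- apply(combs, 2, stat)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
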