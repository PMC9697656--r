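#' One-dimensional k-means on a grey-level multiset
#'
#' Clusters a 1-D multiset of grey levels into `k` groups by minimising the
#' within-cluster sum of squares.  The computation runs on the value
#' histogram (distinct value, count pairs), which is equivalent to
#' clustering the raw values.  Two methods are available:
#'
#' * `"exact"` (default): dynamic programming over the sorted histogram.
#'   Optimal 1-D k-means clusters are contiguous intervals of the sorted
#'   values, so the DP returns the exact global optimum deterministically,
#'   with no dependence on initialisation.  Inputs with more than
#'   `max_support` distinct values are first binned to `max_support`
#'   equal-width bins (bin width is then far below the grey-level noise).
#' * `"lloyd"`: classical Lloyd iterations on the weighted histogram,
#'   started from the 100*(j + 1/2)/k mass percentiles, stopping when no
#'   centroid moves by more than `tol` or after `max_iter` sweeps.
#'   Optional extra random restarts (controlled by `seed`) keep the best
#'   solution by within-cluster sum of squares.
#'
#' @param values numeric vector of grey levels (raw voxel values).
#' @param k number of clusters.
#' @param method `"exact"` or `"lloyd"`.
#' @param seed integer; only used to draw random restarts for
#'   `method = "lloyd"`.
#' @param restarts number of additional random restarts for Lloyd.
#' @param tol,max_iter Lloyd convergence controls.
#' @param max_support maximum number of distinct values passed to the exact
#'   DP before histogram binning kicks in.
#' @return an object of class `threshold_result`: list with `centroids`
#'   (ascending), `threshold` (`NA` here; set by the channel-specific
#'   wrappers), `k`, `cluster_sizes` and `wcss`.
#' @examples
#' km <- kmeans_1d(c(rep(10, 1000), rep(200, 1000)), k = 2)
#' km$centroids # 10, 200
#' @export
kmeans_1d <- function(values, k, method = c("exact", "lloyd"), seed = NULL,
                      restarts = 0L, tol = 1e-6, max_iter = 300L,
                      max_support = 4096L) {
  method <- match.arg(method)
  check(is_count(k), "k must be a positive integer")
  values <- values[is.finite(values)]
  check(length(values) > 0, "no finite values supplied")

  tab <- sorted_histogram(values, max_support)
  x <- tab$x
  w <- tab$w
  if (length(x) < k)
    degenerate_error(sprintf(
      "need at least k = %d distinct grey levels, found %d", k, length(x)))

  if (method == "exact") {
    starts <- cpp_kmeans_dp(x, w, as.integer(k))
    bounds <- c(starts, length(x) + 1L)
    assign_id <- rep.int(seq_len(k), diff(bounds))
  } else {
    fit <- lloyd_histogram(x, w, k, quantile_init(x, w, k), tol, max_iter)
    if (restarts > 0) {
      fit <- with_seed(seed, {
        best <- fit
        for (i in seq_len(restarts)) {
          init <- sort(sample(x, k, prob = w))
          cand <- lloyd_histogram(x, w, k, init, tol, max_iter)
          if (cand$wcss < best$wcss) best <- cand
        }
        best
      })
    }
    assign_id <- fit$assign
  }

  centroids <- as.numeric(tapply(x * w, assign_id, sum) /
                            tapply(w, assign_id, sum))
  sizes <- as.numeric(tapply(w, assign_id, sum))
  wcss <- sum(w * (x - centroids[assign_id])^2)
  structure(
    list(centroids = centroids, threshold = NA_real_, k = k,
         cluster_sizes = sizes, wcss = wcss, method = method),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("1-D k-means thresholding (k = %d, %s)\n", x$k, x$method))
  cat("  centroids:", paste(signif(x$centroids, 6), collapse = ", "), "\n")
  if (!is.na(x$threshold))
    cat("  threshold:", signif(x$threshold, 6), "\n")
  invisible(x)
}

# distinct sorted values with counts; optionally binned to max_support bins
sorted_histogram <- function(values, max_support) {
  ux <- sort(unique(values))
  if (length(ux) > max_support) {
    rng <- range(values)
    width <- diff(rng) / max_support
    bin <- pmin(floor((values - rng[1]) / width), max_support - 1)
    w <- tabulate(bin + 1L, nbins = max_support)
    keep <- w > 0
    # represent each occupied bin by its mean value (rowsum sorts by bin)
    sums <- rowsum(values, bin)
    list(x = as.numeric(sums) / w[keep], w = as.numeric(w[keep]))
  } else {
    cnt <- tabulate(match(values, ux), nbins = length(ux))
    list(x = ux, w = as.numeric(cnt))
  }
}

quantile_init <- function(x, w, k) {
  cw <- cumsum(w) / sum(w)
  probs <- (seq_len(k) - 0.5) / k
  init <- x[vapply(probs, function(p) which(cw >= p)[1], integer(1))]
  # nudge duplicates apart so every cluster starts distinct
  if (anyDuplicated(init)) init <- init + seq_len(k) * 1e-9 * max(abs(x), 1)
  sort(init)
}

lloyd_histogram <- function(x, w, k, centroids, tol, max_iter) {
  centroids <- sort(centroids)
  for (iter in seq_len(max_iter)) {
    cuts <- (centroids[-1] + centroids[-k]) / 2
    assign_id <- findInterval(x, cuts) + 1L
    new <- centroids
    for (j in seq_len(k)) {
      sel <- assign_id == j
      if (any(sel)) {
        new[j] <- sum(x[sel] * w[sel]) / sum(w[sel])
      } else {
        # empty cluster: relocate to the value farthest from its centroid
        far <- which.max(abs(x - centroids[pmin(assign_id, k)]))
        new[j] <- x[far]
      }
    }
    new <- sort(new)
    if (max(abs(new - centroids)) <= tol) {
      centroids <- new
      break
    }
    centroids <- new
  }
  cuts <- (centroids[-1] + centroids[-k]) / 2
  assign_id <- findInterval(x, cuts) + 1L
  mu <- vapply(seq_len(k), function(j) {
    sel <- assign_id == j
    if (any(sel)) sum(x[sel] * w[sel]) / sum(w[sel]) else centroids[j]
  }, numeric(1))
  list(assign = assign_id, centroids = mu,
       wcss = sum(w * (x - mu[assign_id])^2))
}
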