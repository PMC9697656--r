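#' Collagen grey-level threshold from the SHG channel
#'
#' Runs k = 2 k-means on the SHG channel grey levels (collagen versus
#' background) and takes the centroid of the upper (collagen) cluster as
#' the collagen threshold.  Voxels with grey level greater than or equal
#' to the threshold are counted as collagen.
#'
#' @param stack an [image_stack()].
#' @param ... passed to [kmeans_1d()].
#' @return a `threshold_result` with `threshold` set to the collagen
#'   cluster centroid.
#' @export
collagen_threshold <- function(stack, ...) {
  check(inherits(stack, "image_stack"), "stack must be an image_stack")
  res <- kmeans_1d(as.numeric(stack$shg), k = 2, ...)
  res$threshold <- res$centroids[2]
  res$channel <- "shg"
  res
}

#' Elastin grey-level threshold from the AF channel
#'
#' Runs k = 3 k-means on the AF channel (background, collagen
#' bleed-through, elastin) and takes the centroid of the highest cluster
#' as the elastin threshold, so bleed-through voxels are excluded from the
#' elastin count.
#'
#' @inheritParams collagen_threshold
#' @return a `threshold_result` with `threshold` set to the elastin
#'   cluster centroid.
#' @export
elastin_threshold <- function(stack, ...) {
  check(inherits(stack, "image_stack"), "stack must be an image_stack")
  res <- kmeans_1d(as.numeric(stack$af), k = 3, ...)
  res$threshold <- res$centroids[3]
  res$channel <- "af"
  res
}

#' Elastin-to-Collagen ratio of a two-channel stack
#'
#' Thresholds each channel automatically ([collagen_threshold()],
#' [elastin_threshold()]) and returns the number of elastin voxels divided
#' by the number of collagen voxels, counted over the entire 3-D stack.
#' A voxel counts as signal when its grey level is greater than or equal
#' to the channel threshold.
#'
#' @inheritParams collagen_threshold
#' @return object of class `ec_result`: list with `r_ec`, `n_elastin_px`,
#'   `n_collagen_px` and the two `threshold_result`s.
#' @examples
#' out <- generate_stack(stack_spec(shape = c(48, 48, 6), seed = 2))
#' compute_rec(out$stack)$r_ec
#' @export
compute_rec <- function(stack, ...) {
  col <- collagen_threshold(stack, ...)
  ela <- elastin_threshold(stack, ...)
  n_col <- sum(stack$shg >= col$threshold)
  n_ela <- sum(stack$af >= ela$threshold)
  if (n_col == 0)
    undefined_error("no collagen voxels above threshold; R_EC undefined")
  structure(
    list(r_ec = n_ela / n_col, n_elastin_px = n_ela, n_collagen_px = n_col,
         collagen = col, elastin = ela),
    class = "ec_result")
}

#' @export
print.ec_result <- function(x, ...) {
  cat(sprintf("R_EC = %.4g  (%d elastin / %d collagen voxels)\n",
              x$r_ec, x$n_elastin_px, x$n_collagen_px))
  cat(sprintf("  thresholds: collagen %.4g, elastin %.4g\n",
              x$collagen$threshold, x$elastin$threshold))
  invisible(x)
}

#' SHG-to-AF ageing index of the dermis (SAAID)
#'
#' Literature comparison metric based on mean channel intensities:
#' `SAAID = (I_SHG - I_AF) / (I_SHG + I_AF)`, in `[-1, 1]`.
#'
#' @param i_shg,i_af mean channel intensities (non-negative, not both 0).
#' @return numeric score in `[-1, 1]`.
#' @export
saaid <- function(i_shg, i_af) {
  check(is_number(i_shg) && is_number(i_af) && i_shg >= 0 && i_af >= 0,
        "intensities must be non-negative numbers")
  if (i_shg + i_af <= 0)
    undefined_error("both intensities are zero; SAAID undefined")
  (i_shg - i_af) / (i_shg + i_af)
}

#' Elastin-to-Collagen ratio bounds implied by dermis composition
#'
#' The dry weight of the dermis is roughly 70--80% collagen and 2--4%
#' elastin; the mass-ratio bounds implied by those ranges bracket the
#' plausible R_EC values: lower bound = min elastin / max collagen,
#' upper bound = max elastin / min collagen.
#'
#' @param elastin_frac,collagen_frac two-element ranges of dry-weight
#'   fractions.
#' @return named numeric vector `c(lower, upper)` (defaults: 0.025 and
#'   0.04/0.70 ~= 0.057).
#' @export
composition_rec_bounds <- function(elastin_frac = c(0.02, 0.04),
                                   collagen_frac = c(0.70, 0.80)) {
  check(length(elastin_frac) == 2 && length(collagen_frac) == 2 &&
          all(elastin_frac > 0) && all(collagen_frac > 0),
        "fraction ranges must be two positive numbers each")
  c(lower = min(elastin_frac) / max(collagen_frac),
    upper = max(elastin_frac) / min(collagen_frac))
}
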