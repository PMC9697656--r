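#' Specification of a synthetic two-channel microscopy stack
#'
#' Describes a planted-fibre two-channel 3-D stack emulating two-photon
#' imaging of the upper dermis: a collagen-specific SHG channel containing
#' thick curvilinear fibre bundles, and an AF channel containing sparse
#' thin elastin fibres plus a bleed-through copy of the collagen signal.
#'
#' Signal levels must satisfy the separability assumption of k = 3
#' clustering on the AF channel: elastin strictly above the bleed-through
#' level, which is at or above background (`bleed_level = background +
#' bleed_fraction * (collagen_level - background)`).
#'
#' @param shape integer vector (nx, ny, nz) of voxel counts.
#' @param um_per_pixel lateral calibration in micrometres per pixel.
#' @param z_step_um axial step in micrometres.
#' @param n_collagen_fibres,n_elastin_fibres planted fibre counts.
#' @param bleed_fraction fraction in `[0, 1)` of the collagen signal that
#'   leaks into the AF channel.
#' @param background_level,collagen_level,elastin_level mean grey levels.
#' @param noise_sd additive Gaussian noise, grey levels.
#' @param collagen_radius_px dilation radius of collagen bundles (voxels).
#' @param collagen_steps,elastin_steps random-walk length per fibre.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return an object of class `stack_spec`.
#' @export
stack_spec <- function(shape = c(128L, 128L, 16L), um_per_pixel = 0.5,
                       z_step_um = 1, n_collagen_fibres = 20L,
                       n_elastin_fibres = 6L, bleed_fraction = 0.3,
                       background_level = 10, collagen_level = 180,
                       elastin_level = 220, noise_sd = 5,
                       collagen_radius_px = 2L, collagen_steps = 320L,
                       elastin_steps = 320L, seed = 1L) {
  check(length(shape) == 3 && all(shape >= 4) && all(shape == floor(shape)),
        "shape must be three positive voxel counts (>= 4)")
  check(is_number(bleed_fraction) && bleed_fraction >= 0 && bleed_fraction < 1,
        "bleed_fraction must lie in [0, 1)")
  check(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  check(um_per_pixel > 0 && z_step_um > 0, "calibrations must be positive")
  check(n_collagen_fibres >= 0 && n_elastin_fibres >= 0,
        "fibre counts must be non-negative")
  bleed_level <- background_level +
    bleed_fraction * (collagen_level - background_level)
  check(collagen_level > background_level,
        "collagen_level must exceed background_level")
  check(elastin_level > bleed_level,
        "elastin_level must strictly exceed the bleed-through level")
  structure(
    list(shape = as.integer(shape), um_per_pixel = um_per_pixel,
         z_step_um = z_step_um,
         n_collagen_fibres = as.integer(n_collagen_fibres),
         n_elastin_fibres = as.integer(n_elastin_fibres),
         bleed_fraction = bleed_fraction,
         background_level = background_level,
         collagen_level = collagen_level, elastin_level = elastin_level,
         bleed_level = bleed_level, noise_sd = noise_sd,
         collagen_radius_px = as.integer(collagen_radius_px),
         collagen_steps = as.integer(collagen_steps),
         elastin_steps = as.integer(elastin_steps),
         seed = as.integer(seed)),
    class = "stack_spec")
}

#' Generate a planted-fibre two-channel stack with ground-truth masks
#'
#' Renders collagen fibres as dilated random-walk polylines (thick
#' bundles) and elastin fibres as thin (single-voxel-wide) walks.  Any
#' elastin voxel falling on a collagen voxel is dropped, so the two
#' ground-truth masks are disjoint by construction.  The SHG channel
#' carries the collagen signal; the AF channel carries elastin plus
#' `bleed_fraction` of the collagen signal above background.  Grey levels
#' are continuous (16-bit-like), floored at zero after noise.
#'
#' @param spec a [stack_spec()].
#' @return list with `stack` (an `image_stack`: `shg` and `af` arrays plus
#'   calibration) and `masks` (logical arrays `collagen`, `elastin`).
#' @examples
#' sp <- stack_spec(shape = c(32, 32, 4), noise_sd = 0, seed = 7)
#' out <- generate_stack(sp)
#' true_ratio <- sum(out$masks$elastin) / sum(out$masks$collagen)
#' @export
generate_stack <- function(spec) {
  check(inherits(spec, "stack_spec"), "spec must be a stack_spec")
  with_seed(spec$seed, {
    dims <- spec$shape
    col_mask <- render_fibres(dims, spec$n_collagen_fibres,
                              spec$collagen_steps, spec$collagen_radius_px)
    ela_mask <- render_fibres(dims, spec$n_elastin_fibres,
                              spec$elastin_steps, 0L)
    ela_mask <- ela_mask & !col_mask  # masks disjoint

    shg <- array(spec$background_level, dims)
    shg[col_mask] <- spec$collagen_level
    af <- array(spec$background_level, dims)
    af[col_mask] <- spec$bleed_level
    af[ela_mask] <- spec$elastin_level
    if (spec$noise_sd > 0) {
      shg <- shg + rnorm(length(shg), 0, spec$noise_sd)
      af <- af + rnorm(length(af), 0, spec$noise_sd)
    }
    shg[shg < 0] <- 0
    af[af < 0] <- 0
    list(stack = image_stack(shg, af, spec$um_per_pixel, spec$z_step_um),
         masks = list(collagen = col_mask, elastin = ela_mask))
  })
}

#' Two-channel image stack container
#'
#' @param shg,af 3-D numeric arrays of identical shape with non-negative
#'   grey levels (SHG/collagen channel, AF/elastin channel).
#' @param um_per_pixel,z_step_um physical calibration.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(shg, af, um_per_pixel = 0.5, z_step_um = 1) {
  check(is.array(shg) && is.array(af) && length(dim(shg)) == 3,
        "channels must be 3-D arrays")
  check(identical(dim(shg), dim(af)),
        "both channels must have the same shape")
  check(min(shg) >= 0 && min(af) >= 0, "grey levels must be >= 0")
  check(um_per_pixel > 0 && z_step_um > 0, "calibrations must be positive")
  structure(list(shg = shg, af = af, um_per_pixel = um_per_pixel,
                 z_step_um = z_step_um), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$shg)
  cat(sprintf(
    "two-channel image stack: %d x %d x %d voxels, %.3g um/px, %.3g um z-step\n",
    d[1], d[2], d[3], x$um_per_pixel, x$z_step_um))
  invisible(x)
}

# Random-walk fibre renderer.  Walks are mostly in-plane with slow
# curvature and gentle axial wander, reflected at the volume faces, then
# dilated by a Euclidean ball of the given radius.
render_fibres <- function(dims, n_fibres, steps, radius) {
  mask <- array(FALSE, dims)
  if (n_fibres == 0 || steps == 0) return(mask)
  offs <- ball_offsets(radius)
  for (f in seq_len(n_fibres)) {
    start <- runif(3) * dims
    ang <- runif(1, 0, 2 * pi) + cumsum(rnorm(steps, 0, 0.15))
    x <- start[1] + cumsum(cos(ang))
    y <- start[2] + cumsum(sin(ang))
    z <- start[3] + cumsum(rnorm(steps, 0, 0.2))
    i <- reflect_index(round(x), dims[1])
    j <- reflect_index(round(y), dims[2])
    k <- reflect_index(round(z), dims[3])
    ii <- outer(i, offs[, 1], `+`)
    jj <- outer(j, offs[, 2], `+`)
    kk <- outer(k, offs[, 3], `+`)
    keep <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] &
      kk >= 1 & kk <= dims[3]
    idx <- cbind(ii[keep], jj[keep], kk[keep])
    mask[idx] <- TRUE
  }
  mask
}

ball_offsets <- function(radius) {
  if (radius <= 0) return(matrix(0L, 1, 3))
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# reflect 1-based indices into [1, n] (triangle-wave folding)
reflect_index <- function(v, n) {
  if (n == 1) return(rep(1L, length(v)))
  p <- (v - 1) %% (2 * (n - 1))
  as.integer(ifelse(p > (n - 1), 2 * (n - 1) - p, p) + 1)
}
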