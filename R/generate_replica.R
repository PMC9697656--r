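#' Specification of a synthetic skin-replica texture
#'
#' Describes a grey-level replica image built from a Voronoi tessellation:
#' dark polygonal basins (the skin polygons) separated by bright ridges
#' (furrows/wrinkles), optionally elongated along the x axis to mimic the
#' anisotropy of skin tension lines.
#'
#' @param side_mm side length of the square analysis crop (mm).
#' @param mm_per_pixel calibration.
#' @param n_seeds number of Voronoi seeds (>= 1).
#' @param anisotropy vertical stretch factor >= 1 applied to the metric
#'   before tessellation; values > 1 elongate cells along x.
#' @param ridge_width_mm nominal ridge (furrow) width.
#' @param ridge_level,basin_level grey levels (ridges bright, basins dark).
#' @param noise_sd additive Gaussian grey-level noise.
#' @param seed integer seed.
#' @return object of class `replica_spec`.
#' @export
replica_spec <- function(side_mm = 15, mm_per_pixel = 0.05, n_seeds = 36L,
                         anisotropy = 1, ridge_width_mm = 0.15,
                         ridge_level = 220, basin_level = 30,
                         noise_sd = 8, seed = 1L) {
  check(is_number(side_mm) && side_mm > 0, "side_mm must be positive")
  check(is_number(mm_per_pixel) && mm_per_pixel > 0,
        "mm_per_pixel must be positive")
  check(is_count(n_seeds), "n_seeds must be a positive integer")
  check(is_number(anisotropy) && anisotropy >= 1, "anisotropy must be >= 1")
  check(basin_level < ridge_level, "basin_level must be below ridge_level")
  check(ridge_width_mm >= 0, "ridge_width_mm must be >= 0")
  check(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  # seeds denser than the raster or the ridges can resolve are rejected
  mean_diam <- side_mm / sqrt(n_seeds)
  check(mean_diam >= 8 * mm_per_pixel,
        "n_seeds too dense for the pixel resolution (cells < 8 px across)")
  check(ridge_width_mm < mean_diam / 3,
        "n_seeds too dense for the ridge width (basins would vanish)")
  structure(
    list(side_mm = side_mm, mm_per_pixel = mm_per_pixel,
         n_seeds = as.integer(n_seeds), anisotropy = anisotropy,
         ridge_width_mm = ridge_width_mm, ridge_level = ridge_level,
         basin_level = basin_level, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "replica_spec")
}

#' Grey-level replica image container
#'
#' @param pixels numeric matrix of grey levels in `[0, 255]`, basins dark.
#' @param mm_per_pixel calibration (> 0).
#' @return object of class `replica_image`.
#' @export
replica_image <- function(pixels, mm_per_pixel) {
  check(is.matrix(pixels) && nrow(pixels) >= 2 && ncol(pixels) >= 2,
        "pixels must be a matrix")
  check(is_number(mm_per_pixel) && mm_per_pixel > 0,
        "mm_per_pixel must be positive")
  structure(list(pixels = pixels, mm_per_pixel = mm_per_pixel,
                 crop_side_mm = ncol(pixels) * mm_per_pixel),
            class = "replica_image")
}

#' @export
print.replica_image <- function(x, ...) {
  cat(sprintf("replica image: %d x %d px, %.4g mm/px (%.4g mm crop)\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel,
              x$crop_side_mm))
  invisible(x)
}

#' Generate a Voronoi replica texture with exact ground-truth polygons
#'
#' Seeds are placed uniformly in the (metric-stretched) square and the
#' image renders each pixel as basin or ridge according to its exact
#' distance to the Voronoi cell boundary.  The ground truth is the exact
#' tessellation: each cell polygon is obtained by clipping the crop square
#' with the perpendicular bisectors against every other seed, giving exact
#' areas, perimeters and border flags.  With `anisotropy = a > 1` the
#' tessellation is computed in a space stretched vertically by `a` and
#' mapped back, so cells elongate along x.
#'
#' @param spec a [replica_spec()].
#' @param compute_truth set `FALSE` to skip the exact polygon ground truth
#'   (cheaper when only the image is needed).
#' @param seed_points optional n x 2 matrix of seed coordinates in real mm
#'   (overrides random placement; useful for regular test patterns).
#' @return list with `image` (a [replica_image()]), `labels` (the true
#'   nearest-seed label matrix), and `polygons`: data frame with one row
#'   per seed (`label`, `area_mm2`, `perimeter_mm`, `touches_border`,
#'   `seed_x_mm`, `seed_y_mm`); `NULL` when `compute_truth = FALSE`.
#' @examples
#' out <- generate_replica(replica_spec(n_seeds = 9, seed = 3))
#' sum(out$polygons$area_mm2) # equals side_mm^2
#' @export
generate_replica <- function(spec, compute_truth = TRUE, seed_points = NULL) {
  check(inherits(spec, "replica_spec"), "spec must be a replica_spec")
  with_seed(spec$seed, {
    s <- spec$side_mm
    a <- spec$anisotropy
    if (is.null(seed_points)) {
      # hard-core placement: skin polygons have a minimum size, and seeds
      # closer than the ridge width would create unresolvable slivers
      r_min <- max(2 * spec$ridge_width_mm, 4 * spec$mm_per_pixel,
                   0.3 * s / sqrt(spec$n_seeds))
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(pts) < spec$n_seeds) {
        cand <- runif(2, 0, s)
        if (nrow(pts) == 0 ||
            min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r_min^2)
          pts <- rbind(pts, cand)
        tries <- tries + 1L
        if (tries > 400L * spec$n_seeds)
          validation_error(
            "n_seeds too dense for the ridge width / resolution")
      }
      sx <- pts[, 1]
      sy <- pts[, 2] * a  # stretched-space ordinate
    } else {
      check(is.matrix(seed_points) && ncol(seed_points) == 2 &&
              nrow(seed_points) == spec$n_seeds,
            "seed_points must be an n_seeds x 2 matrix (mm)")
      sx <- seed_points[, 1]
      sy <- seed_points[, 2] * a
    }

    npx <- round(s / spec$mm_per_pixel)
    ren <- cpp_voronoi_render(sx, sy, npx, npx, spec$mm_per_pixel, a)
    ridge <- ren$boundary_dist < spec$ridge_width_mm / 2
    px <- matrix(spec$basin_level, npx, npx)
    px[ridge] <- spec$ridge_level
    if (spec$noise_sd > 0)
      px <- px + rnorm(length(px), 0, spec$noise_sd)
    px[px < 0] <- 0
    px[px > 255] <- 255

    polygons <- if (compute_truth)
      voronoi_truth(sx, sy, s, a) else NULL
    list(image = replica_image(px, spec$mm_per_pixel),
         labels = ren$labels, polygons = polygons)
  })
}

# Exact cell polygons by iterated half-plane clipping of the crop square
# (Voronoi cells are convex).  Coordinates live in the stretched space and
# are mapped back by y / a before measuring.
voronoi_truth <- function(sx, sy, side, aniso) {
  n <- length(sx)
  out <- vector("list", n)
  square <- cbind(c(0, side, side, 0), c(0, 0, side * aniso, side * aniso))
  for (i in seq_len(n)) {
    poly <- square
    for (j in seq_len(n)) {
      if (j == i || nrow(poly) == 0) next
      # keep points closer to seed i than to seed j:
      # 2 (sj - si) . p <= |sj|^2 - |si|^2
      aa <- 2 * (sx[j] - sx[i])
      bb <- 2 * (sy[j] - sy[i])
      cc <- (sx[j]^2 + sy[j]^2) - (sx[i]^2 + sy[i]^2)
      poly <- clip_halfplane(poly, aa, bb, cc)
    }
    out[[i]] <- poly
  }
  eps <- 1e-9 * side
  rows <- lapply(seq_len(n), function(i) {
    p <- out[[i]]
    if (is.null(p) || nrow(p) < 3)
      return(data.frame(label = i, area_mm2 = 0, perimeter_mm = 0,
                        touches_border = NA, seed_x_mm = sx[i],
                        seed_y_mm = sy[i] / aniso))
    xs <- p[, 1]
    ys <- p[, 2] / aniso  # back to real space
    area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    per <- sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
    border <- any(xs < eps | xs > side - eps |
                    p[, 2] < eps | p[, 2] > side * aniso - eps)
    data.frame(label = i, area_mm2 = area, perimeter_mm = per,
               touches_border = border, seed_x_mm = sx[i],
               seed_y_mm = sy[i] / aniso)
  })
  do.call(rbind, rows)
}

# Sutherland-Hodgman clip of a convex polygon by a*x + b*y <= c
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- a * poly[, 1] + b * poly[, 2] - c
  inside <- val <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p1 <- poly[i, ]; p2 <- poly[j, ]
    in1 <- inside[i]; in2 <- inside[j]
    if (in1) out <- rbind(out, p1)
    if (xor(in1, in2)) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}
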