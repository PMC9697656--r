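#' H-minima transform of a grey-level image
#'
#' Suppresses every regional minimum shallower than depth `h` by greyscale
#' reconstruction-by-erosion of `image + h` above `image` (computed by
#' duality through reconstruction-by-dilation).  The extended regional
#' minima -- the regional minima of the transformed image -- are the
#' standard stable markers for marker-controlled watershed segmentation.
#'
#' @param pixels numeric matrix of grey levels.
#' @param h minimum depth (grey levels, >= 1).
#' @return numeric matrix of the same shape.
#' @export
hmin_transform <- function(pixels, h) {
  check(is.matrix(pixels), "pixels must be a matrix")
  check(is_number(h) && h >= 1, "h must be >= 1")
  -cpp_reconstruct_dilate(-(pixels + h), -pixels)
}

#' Segment a replica image into skin polygons
#'
#' Marker-controlled watershed segmentation of the microrelief: the image
#' is (optionally) smoothed, markers are taken as the 8-connected
#' components of the extended regional minima after an H-minima transform
#' of depth `h`, and the watershed then floods the smoothed topography
#' from those markers on a 4-connected grid with a deterministic queue.
#' Basins are dark, ridges bright.  By default flooded basins meet at
#' zero-width boundaries so every pixel belongs to a region; set
#' `watershed_lines = TRUE` to keep classical one-pixel watershed lines
#' (label 0) instead.
#'
#' A uniform (constant) image yields zero markers and an all-zero label
#' map, reported via the `n_markers` attribute rather than an error.
#'
#' @param image a [replica_image()] or a plain numeric matrix.
#' @param h H-minima depth in grey levels (default 10).
#' @param connectivity marker connectivity, 4 or 8 (default 8; flooding is
#'   always 4-connected).
#' @param smooth_sigma Gaussian pre-smoothing in pixels (0 disables).
#' @param watershed_lines keep 1-px watershed lines as label 0.
#' @return integer label matrix with attributes `n_markers` and
#'   `mm_per_pixel` (when available).
#' @examples
#' rep <- generate_replica(replica_spec(n_seeds = 16, seed = 1))
#' lab <- segment_replica(rep$image)
#' attr(lab, "n_markers")
#' @export
segment_replica <- function(image, h = 10, connectivity = 8,
                            smooth_sigma = 1, watershed_lines = FALSE) {
  px <- if (inherits(image, "replica_image")) image$pixels else image
  check(is.matrix(px) && is.numeric(px), "image must be numeric matrix data")
  check(is_number(h) && h >= 1, "h must be >= 1")
  check(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  sm <- if (smooth_sigma > 0) gaussian_smooth(px, smooth_sigma) else px
  if (diff(range(sm)) < .Machine$double.eps * 100) {
    lab <- matrix(0L, nrow(px), ncol(px))
    attr(lab, "n_markers") <- 0L
    return(lab)
  }
  hm <- hmin_transform(sm, h)
  minima <- cpp_regional_minima(hm, 8L)
  markers <- cpp_label(minima, as.integer(connectivity))
  n_markers <- max(markers)
  lab <- cpp_watershed(sm, markers, 4L, watershed_lines)
  attr(lab, "n_markers") <- as.integer(n_markers)
  if (inherits(image, "replica_image"))
    attr(lab, "mm_per_pixel") <- image$mm_per_pixel
  lab
}

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(px, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(m) {  # filter along rows (dim 1)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r)
      out <- out + k[o + r + 1] * padded[(1 + r + o):(nrow(m) + r + o), ,
                                         drop = FALSE]
    out
  }
  t(smooth_1d(t(smooth_1d(px))))
}

#' Per-polygon morphometric features of a segmentation
#'
#' For every labelled region: area (pixel count), perimeter (sub-pixel
#' marching-squares boundary length, so staircase edges are not
#' overcounted), the major/minor axis lengths and orientation of the
#' ellipse with identical normalised second central moments, the aspect
#' ratio `M/m`, and a border flag for regions touching the crop edge.
#' Orientation is measured counter-clockwise from the image x axis
#' (columns), in `(-90, 90]` degrees.  All lengths are calibrated to mm.
#'
#' @param labels integer label matrix (e.g. from [segment_replica()]).
#' @param mm_per_pixel calibration; taken from the `labels` attribute when
#'   omitted.
#' @param border_margin_px regions reaching within this many pixels of the
#'   image edge are flagged `touches_border`; the default of 2 absorbs the
#'   boundary-placement uncertainty of the watershed, so a polygon whose
#'   true contact with the crop edge is thinner than a pixel is still
#'   classified consistently.
#' @return data frame with columns `label`, `area_mm2`, `perimeter_mm`,
#'   `major_mm`, `minor_mm`, `orientation_deg`, `aspect_ratio`,
#'   `touches_border` (one row per region; empty for an empty
#'   segmentation).
#' @export
extract_features <- function(labels, mm_per_pixel = NULL,
                             border_margin_px = 2L) {
  if (is.null(mm_per_pixel)) mm_per_pixel <- attr(labels, "mm_per_pixel")
  check(is_number(mm_per_pixel) && mm_per_pixel > 0,
        "mm_per_pixel must be a positive number")
  nlab <- max(labels)
  empty <- data.frame(label = integer(0), area_mm2 = numeric(0),
                      perimeter_mm = numeric(0), major_mm = numeric(0),
                      minor_mm = numeric(0), orientation_deg = numeric(0),
                      aspect_ratio = numeric(0), touches_border = logical(0))
  if (nlab < 1) return(empty)

  idx <- which(labels > 0)
  lab <- labels[idx]
  nr <- nrow(labels)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  x <- col - 0.5           # pixel centres, px units, x along columns
  y <- -(row - 0.5)        # y grows upward so orientation is CCW

  n <- tabulate(lab, nbins = nlab)
  sums <- rowsum(cbind(x, y, x * x, y * y, x * y), lab)
  present <- sort(unique(lab))
  S <- matrix(0, nlab, 5)
  S[present, ] <- sums
  xb <- S[, 1] / n
  yb <- S[, 2] / n
  # + 1/12: second moment of the unit pixel itself, keeps minor axis > 0
  mu20 <- S[, 3] / n - xb^2 + 1 / 12
  mu02 <- S[, 4] / n - yb^2 + 1 / 12
  mu11 <- S[, 5] / n - xb * yb
  common <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- common + delta
  l2 <- pmax(common - delta, 1e-12)
  major <- 4 * sqrt(l1) * mm_per_pixel
  minor <- 4 * sqrt(l2) * mm_per_pixel
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta[theta <= -90] <- theta[theta <= -90] + 180
  theta[theta > 90] <- theta[theta > 90] - 180

  per <- cpp_region_perimeters(labels, nlab) * mm_per_pixel
  bm <- max(1L, as.integer(border_margin_px))
  rsel <- c(seq_len(min(bm, nr)), seq(max(1L, nr - bm + 1L), nr))
  csel <- c(seq_len(min(bm, ncol(labels))),
            seq(max(1L, ncol(labels) - bm + 1L), ncol(labels)))
  border_labels <- unique(c(labels[rsel, ], labels[, csel]))
  out <- data.frame(
    label = seq_len(nlab), area_mm2 = n * mm_per_pixel^2,
    perimeter_mm = per, major_mm = major, minor_mm = minor,
    orientation_deg = theta, aspect_ratio = major / minor,
    touches_border = seq_len(nlab) %in% border_labels)
  out[n > 0, , drop = FALSE]
}

#' Characteristic length Lc of a set of skin polygons
#'
#' The proposed surface biomarker of dermal ageing: the per-polygon
#' average of equivalent diameter plus equivalent side,
#' `Lc = (1/N) * sum_i (sqrt(A_i) + P_i / 4)`.
#' The average is taken over the per-polygon sums, not over the two
#' cohort means, which matters because `sqrt` is concave.
#'
#' @param features data frame from [extract_features()] (needs `area_mm2`
#'   and `perimeter_mm`).
#' @return Lc in mm.
#' @examples
#' characteristic_length(data.frame(area_mm2 = 1, perimeter_mm = 4)) # 2
#' @export
characteristic_length <- function(features) {
  if (is.null(features) || nrow(features) == 0)
    undefined_error("characteristic length needs at least one polygon")
  check(all(c("area_mm2", "perimeter_mm") %in% names(features)),
        "features must have area_mm2 and perimeter_mm columns")
  mean(sqrt(features$area_mm2) + features$perimeter_mm / 4)
}

#' Morphometric summary of a segmented replica
#'
#' Filters the polygon set to the usable polygons (by default: interior
#' regions not touching the crop border, larger than `min_area_mm2`) and
#' summarises them as one row of cohort-level morphometry: polygon
#' density NP, mean area, mean perimeter, characteristic length Lc and
#' mean aspect ratio.
#'
#' @param features data frame from [extract_features()].
#' @param analysed_area_mm2 area of the analysis crop in mm^2.
#' @param exclude_border drop polygons touching the crop border
#'   (truncated polygons bias area and perimeter low).
#' @param min_area_mm2 speckle filter; regions smaller than this are
#'   treated as noise (default 0.01 mm^2).
#' @return object of class `morphometric_summary`: list with
#'   `np_per_mm2`, `mean_area_mm2`, `mean_perimeter_mm`, `lc_mm`,
#'   `mean_aspect_ratio`, `n_polygons_used`.  With zero usable polygons
#'   the statistics are `NA` and `n_polygons_used` is 0.
#' @export
summarize_morphometry <- function(features, analysed_area_mm2,
                                  exclude_border = TRUE,
                                  min_area_mm2 = 0.01) {
  check(is_number(analysed_area_mm2) && analysed_area_mm2 > 0,
        "analysed_area_mm2 must be positive")
  usable <- features
  if (nrow(usable) > 0) {
    keep <- usable$area_mm2 >= min_area_mm2
    if (exclude_border) keep <- keep & !usable$touches_border
    usable <- usable[keep, , drop = FALSE]
  }
  n <- nrow(usable)
  if (n == 0) {
    return(structure(
      list(np_per_mm2 = 0, mean_area_mm2 = NA_real_,
           mean_perimeter_mm = NA_real_, lc_mm = NA_real_,
           mean_aspect_ratio = NA_real_, n_polygons_used = 0L),
      class = "morphometric_summary"))
  }
  structure(
    list(np_per_mm2 = n / analysed_area_mm2,
         mean_area_mm2 = mean(usable$area_mm2),
         mean_perimeter_mm = mean(usable$perimeter_mm),
         lc_mm = characteristic_length(usable),
         mean_aspect_ratio = mean(usable$aspect_ratio),
         n_polygons_used = n),
    class = "morphometric_summary")
}

#' @export
print.morphometric_summary <- function(x, ...) {
  cat(sprintf(
    "morphometry: NP %.3g /mm2, area %.3g mm2, perimeter %.3g mm, Lc %.3g mm, aspect %.3g (n = %d)\n",
    x$np_per_mm2, x$mean_area_mm2, x$mean_perimeter_mm, x$lc_mm,
    x$mean_aspect_ratio, x$n_polygons_used))
  invisible(x)
}
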