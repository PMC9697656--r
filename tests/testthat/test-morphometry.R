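# H-minima markers, watershed segmentation and polygon features.

test_that("H-minima suppresses shallow minima and drives region merging", {
  m <- matrix(255, 40, 40)
  m[5:15, 5:35] <- 0
  m[25:35, 5:35] <- 0
  m[16:24, 5:35] <- 10 # ridge only 10 grey levels above the basins
  merged <- segment_replica(m, h = 20, smooth_sigma = 0)
  split <- segment_replica(m, h = 5, smooth_sigma = 0)
  expect_equal(attr(merged, "n_markers"), 1L)
  expect_equal(attr(split, "n_markers"), 2L)
  # label conservation: every marker yields exactly one region
  expect_equal(length(setdiff(unique(c(split)), 0L)), 2L)

  single <- matrix(255, 30, 30)
  single[10:20, 10:20] <- 0
  lab1 <- segment_replica(single, h = 20, smooth_sigma = 0)
  expect_equal(attr(lab1, "n_markers"), 1L)

  flat <- matrix(42, 25, 25)
  lab0 <- segment_replica(flat, h = 10)
  expect_equal(attr(lab0, "n_markers"), 0L)
  expect_true(all(lab0 == 0))
})

test_that("hmin_transform raises minima by at most h and keeps deep ones", {
  m <- matrix(200, 20, 20)
  m[5:8, 5:8] <- 0      # deep basin
  m[14:16, 14:16] <- 195 # 5-deep dimple
  hm <- hmin_transform(m, 10)
  expect_equal(hm[6, 6], 10)     # deep basin floor raised by h
  expect_equal(hm[15, 15], 200)  # shallow dimple filled completely
  expect_true(all(hm >= m - 1e-12))
})

test_that("watershed recovers a known Voronoi tessellation", {
  sp <- replica_spec(n_seeds = 25, seed = 5)
  out <- generate_replica(sp)
  lab <- segment_replica(out$image)
  expect_equal(attr(lab, "n_markers"), 25L)
  expect_equal(length(setdiff(unique(c(lab)), 0L)), 25L)
  expect_identical(segment_replica(out$image), lab) # deterministic
})

test_that("region features match exact geometry for simple shapes", {
  lab <- matrix(0L, 120, 120)
  lab[11:110, 11:110] <- 1L # 100 x 100 px square at 0.1 mm/px
  f <- extract_features(lab, 0.1)
  expect_equal(f$area_mm2, 1 * 100) # 10 mm x 10 mm
  expect_equal(f$aspect_ratio, 1, tolerance = 1e-6)
  expect_equal(f$perimeter_mm, 40, tolerance = 0.01)
  expect_false(f$touches_border)

  rect <- matrix(0L, 120, 260)
  rect[11:60, 31:230] <- 1L # 50 rows x 200 cols
  fr <- extract_features(rect, 0.1)
  expect_equal(fr$aspect_ratio, 4, tolerance = 1e-3)
  expect_equal(fr$orientation_deg, 0, tolerance = 1e-6)
  expect_equal(fr$major_mm / fr$minor_mm, fr$aspect_ratio)

  # a vertical rectangle is oriented at 90 degrees
  fv <- extract_features(t(rect), 0.1)
  expect_equal(abs(fv$orientation_deg), 90, tolerance = 1e-6)
})

test_that("recovered cell areas match the exact tessellation", {
  sp <- replica_spec(n_seeds = 36, seed = 3, mm_per_pixel = 0.05)
  out <- generate_replica(sp)
  lab <- segment_replica(out$image)
  f <- extract_features(lab, sp$mm_per_pixel)
  npx <- round(sp$side_mm / sp$mm_per_pixel)
  rec_lab <- match_regions_to_truth(lab, out$polygons, sp$mm_per_pixel, npx)
  fm <- f[match(rec_lab, f$label), ]
  big_interior <- !out$polygons$touches_border &
    out$polygons$area_mm2 / sp$mm_per_pixel^2 >= 1000
  rel <- abs(fm$area_mm2 - out$polygons$area_mm2) / out$polygons$area_mm2
  expect_true(all(rel[big_interior] < 0.02))
  relp <- abs(fm$perimeter_mm - out$polygons$perimeter_mm) /
    out$polygons$perimeter_mm
  expect_true(all(relp[big_interior] < 0.10))
})

test_that("features agree with an independent image-analysis toolkit",
  {
  skip_if_not_installed("EBImage")
  out <- generate_replica(replica_spec(n_seeds = 16, seed = 4))
  lab <- segment_replica(out$image)
  f <- extract_features(lab, 0.05)
  fs <- EBImage::computeFeatures.shape(lab)
  fm <- EBImage::computeFeatures.moment(lab)
  expect_equal(as.numeric(fs[, "s.area"]) * 0.05^2, f$area_mm2)
  maj <- as.numeric(fm[, "m.majoraxis"]) * 0.05
  minr <- maj * sqrt(1 - as.numeric(fm[, "m.eccentricity"])^2)
  expect_equal(maj, f$major_mm, tolerance = 0.01)
  expect_equal(minr, f$minor_mm, tolerance = 0.01)
})

test_that("characteristic length averages the per-polygon sums", {
  one <- data.frame(area_mm2 = 1, perimeter_mm = 4)
  expect_equal(characteristic_length(one), 2)
  two <- data.frame(area_mm2 = c(1, 4), perimeter_mm = c(4, 8))
  expect_equal(characteristic_length(two), (2 + 4) / 2)

  set.seed(31)
  a <- runif(50, 0.5, 4)
  b <- runif(50, 0.5, 4)
  rects <- data.frame(area_mm2 = a * b, perimeter_mm = 2 * (a + b))
  oracle <- sum(sqrt(a * b) + 2 * (a + b) / 4) / 50
  expect_equal(characteristic_length(rects), oracle, tolerance = 1e-12)

  expect_error(characteristic_length(rects[0, ]),
               class = "skinmorph_undefined_error")
})

test_that("morphometric summary applies the usable-polygon rules", {
  # nine unit squares in a 9 mm^2 crop
  f <- data.frame(area_mm2 = rep(1, 9), perimeter_mm = rep(4, 9),
                  major_mm = 1.1, minor_mm = 1.1, orientation_deg = 0,
                  aspect_ratio = 1, touches_border = FALSE)
  s <- summarize_morphometry(f, 9, exclude_border = TRUE)
  expect_equal(s$np_per_mm2, 1)
  expect_equal(s$mean_area_mm2, 1)
  expect_equal(s$lc_mm, 2)
  expect_equal(s$n_polygons_used, 9L)

  # border and speckle filtering
  f$touches_border[1:3] <- TRUE
  f$area_mm2[4] <- 0.004
  s2 <- summarize_morphometry(f, 9)
  expect_equal(s2$n_polygons_used, 5L)

  s0 <- summarize_morphometry(f[0, ], 9)
  expect_equal(s0$n_polygons_used, 0L)
  expect_true(is.na(s0$lc_mm))
})

test_that("aspect ratio and isoperimetric inequality hold for all regions", {
  out <- generate_replica(replica_spec(n_seeds = 36, seed = 8))
  f <- extract_features(segment_replica(out$image), 0.05)
  expect_true(all(f$aspect_ratio >= 1))
  expect_true(all(f$major_mm >= f$minor_mm))
  expect_true(all(f$minor_mm > 0))
  # P^2 >= 4 pi A within discretisation tolerance
  expect_true(all(f$perimeter_mm^2 >= 4 * pi * f$area_mm2 * 0.95))
})

test_that("morphometry is stable under resampling and physical scaling", {
  pts <- as.matrix(expand.grid(seq(1.5, 13.5, by = 3), seq(1.5, 13.5, by = 3)))
  base <- replica_spec(n_seeds = 25, seed = 2, mm_per_pixel = 0.05,
                       noise_sd = 0)
  fine <- replica_spec(n_seeds = 25, seed = 2, mm_per_pixel = 0.025,
                       noise_sd = 0)
  sum_of <- function(sp) {
    out <- generate_replica(sp, seed_points = pts)
    f <- extract_features(segment_replica(out$image), sp$mm_per_pixel)
    summarize_morphometry(f, sp$side_mm^2)
  }
  s1 <- sum_of(base)
  s2 <- sum_of(fine)
  # upsampling x2 leaves the physical measurements invariant within 2%
  expect_equal(s2$mean_area_mm2, s1$mean_area_mm2, tolerance = 0.02)
  expect_equal(s2$mean_perimeter_mm, s1$mean_perimeter_mm, tolerance = 0.02)
  expect_equal(s2$lc_mm, s1$lc_mm, tolerance = 0.02)
  expect_equal(s2$np_per_mm2, s1$np_per_mm2, tolerance = 0.02)

  # stretching the scene by c scales Lc by c and NP by 1/c^2
  cfac <- 2
  big <- replica_spec(side_mm = 30, n_seeds = 25, seed = 2,
                      mm_per_pixel = 0.1, noise_sd = 0,
                      ridge_width_mm = 0.3)
  s3 <- {
    out <- generate_replica(big, seed_points = pts * cfac)
    f <- extract_features(segment_replica(out$image), big$mm_per_pixel)
    summarize_morphometry(f, big$side_mm^2)
  }
  expect_equal(s3$lc_mm, cfac * s1$lc_mm, tolerance = 0.02)
  expect_equal(s3$np_per_mm2, s1$np_per_mm2 / cfac^2, tolerance = 0.02)
})

test_that("anisotropic textures yield elongated, axis-aligned polygons", {
  iso <- generate_replica(replica_spec(n_seeds = 25, seed = 6))
  ani <- generate_replica(replica_spec(n_seeds = 25, seed = 6,
                                       anisotropy = 1.8))
  fi <- extract_features(segment_replica(iso$image), 0.05)
  fa <- extract_features(segment_replica(ani$image), 0.05)
  fi <- fi[!fi$touches_border, ]
  fa <- fa[!fa$touches_border, ]
  expect_gt(mean(fa$aspect_ratio), mean(fi$aspect_ratio))
  # elongation is along x: orientations concentrate near 0
  expect_lt(median(abs(fa$orientation_deg)), 30)
})

test_that("replica images round-trip through PNG", {
  out <- generate_replica(replica_spec(n_seeds = 9, seed = 1))
  f <- tempfile(fileext = ".png")
  write_replica_png(out$image, f)
  back <- read_replica_png(f, 0.05)
  expect_equal(back$pixels, out$image$pixels, tolerance = 0.5)
  unlink(f)
})
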