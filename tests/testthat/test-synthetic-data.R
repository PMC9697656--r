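# Synthetic generators: determinism, ground-truth consistency and the
# analytic roughness oracles.

test_that("stack generator is deterministic and masks are disjoint", {
  sp <- stack_spec(shape = c(48, 48, 6), seed = 11)
  a <- generate_stack(sp)
  b <- generate_stack(sp)
  expect_identical(a, b)
  expect_false(any(a$masks$collagen & a$masks$elastin))
  # different seed changes the stack
  c <- generate_stack(stack_spec(shape = c(48, 48, 6), seed = 12))
  expect_false(identical(a$stack$shg, c$stack$shg))
})

test_that("noise-free AF channel without elastin or bleed is uniform background", {
  sp <- stack_spec(shape = c(32, 32, 4), noise_sd = 0, bleed_fraction = 0,
                   n_elastin_fibres = 0, seed = 1)
  out <- generate_stack(sp)
  expect_true(all(out$stack$af == sp$background_level))
})

test_that("noiseless pipeline estimate equals the mask-derived true ratio", {
  sp <- stack_spec(shape = c(64, 64, 8), noise_sd = 0, seed = 5)
  out <- generate_stack(sp)
  truth <- sum(out$masks$elastin) / sum(out$masks$collagen)
  expect_equal(compute_rec(out$stack)$r_ec, truth)
})

test_that("stack spec validation rejects inseparable signal levels", {
  expect_error(stack_spec(bleed_fraction = 1.2), class = "skinmorph_validation_error")
  expect_error(stack_spec(elastin_level = 50, bleed_fraction = 0.5),
               class = "skinmorph_validation_error")
  expect_error(stack_spec(collagen_level = 5, background_level = 10),
               class = "skinmorph_validation_error")
})

test_that("analytic profiles carry their closed-form roughness", {
  flat <- generate_profile("flat", amplitude_um = 0)
  expect_equal(roughness_ra(flat), 0)

  sq <- generate_profile("square", amplitude_um = 15, wavelength_um = 500)
  expect_equal(roughness_ra(sq), 15)

  sine <- generate_profile("sine", amplitude_um = 10, wavelength_um = 100)
  expect_equal(roughness_ra(sine), 2 * 10 / pi, tolerance = 1e-3)

  saw <- generate_profile("sawtooth", amplitude_um = 12, wavelength_um = 500)
  expect_equal(roughness_ra(detrend_profile(saw, order = 0)), 6,
               tolerance = 5e-3)

  expect_error(generate_profile("sine", spacing_um = 0),
               class = "skinmorph_validation_error")
  expect_error(generate_profile("sine", wavelength_um = 333),
               class = "skinmorph_validation_error")
})

test_that("replica generator is deterministic with exact tessellation truth", {
  sp <- replica_spec(n_seeds = 25, seed = 5)
  a <- generate_replica(sp)
  b <- generate_replica(sp)
  expect_identical(a, b)
  expect_equal(nrow(a$polygons), 25)
  # exact cells tile the crop square
  expect_equal(sum(a$polygons$area_mm2), sp$side_mm^2, tolerance = 1e-9)
  # rendered pixel accounting: basins + ridges = crop, within a pixel row
  npx <- round(sp$side_mm / sp$mm_per_pixel)
  expect_equal(sum(a$image$pixels > 120) + sum(a$image$pixels <= 120),
               npx^2)
})

test_that("single-seed replica yields one crop-bounded polygon", {
  sp <- replica_spec(n_seeds = 1, ridge_width_mm = 0, noise_sd = 0, seed = 2)
  out <- generate_replica(sp)
  expect_equal(nrow(out$polygons), 1)
  expect_equal(out$polygons$area_mm2, sp$side_mm^2)
  expect_true(out$polygons$touches_border)
})

test_that("a regular seed lattice produces exact square interior cells", {
  s <- 3 # lattice pitch, mm
  centres <- seq(s / 2, 15 - s / 2, by = s)
  pts <- as.matrix(expand.grid(centres, centres))
  sp <- replica_spec(n_seeds = nrow(pts), seed = 1)
  out <- generate_replica(sp, seed_points = pts)
  interior <- out$polygons[!out$polygons$touches_border, ]
  expect_equal(nrow(interior), 9)
  expect_equal(interior$area_mm2, rep(s^2, 9), tolerance = 1e-9)
  expect_equal(interior$perimeter_mm, rep(4 * s, 9), tolerance = 1e-9)
  # true Lc of s x s squares is sqrt(s^2) + 4s/4 = 2s
  expect_equal(characteristic_length(interior), 2 * s, tolerance = 1e-9)
})

test_that("replica spec rejects unresolvable seed densities", {
  expect_error(replica_spec(n_seeds = 10000, mm_per_pixel = 0.05),
               class = "skinmorph_validation_error")
  expect_error(replica_spec(ridge_level = 10, basin_level = 30),
               class = "skinmorph_validation_error")
})

test_that("cohort generator plants the requested correlation structure", {
  # exact r = 1 when the drivers are perfectly coupled and never censored
  coh1 <- generate_cohort(cohort_spec(latent_corr = 1, rec_mean = 0.5,
                                      rec_sd = 0.05, seed = 3))
  expect_equal(cor(coh1$lc_mm, coh1$r_ec), 1)

  # independence at rho = 0, large n
  coh0 <- generate_cohort(cohort_spec(n_subjects = 10000, latent_corr = 0,
                                      seed = 9))
  expect_lt(abs(cor(coh0$lc_mm, coh0$r_ec)), 0.05)
  # descriptives recovered
  expect_equal(mean(coh0$r_ec), 0.035, tolerance = 0.03)
  expect_equal(mean(coh0$bmi_kg_m2),
               mean(coh0$weight_kg / (coh0$height_cm / 100)^2))

  expect_error(cohort_spec(latent_corr = 1.4),
               class = "skinmorph_validation_error")
  expect_error(cohort_spec(n_subjects = 2),
               class = "skinmorph_validation_error")

  d1 <- generate_cohort(cohort_spec(seed = 21))
  d2 <- generate_cohort(cohort_spec(seed = 21))
  expect_identical(d1, d2)
})

test_that("planted correlation is recovered within the sampling bound", {
  for (rho in c(0, 0.5, 0.92)) {
    rs <- vapply(1:40, function(i) {
      coh <- generate_cohort(cohort_spec(latent_corr = rho,
                                         seed = round(1000 * rho) + i))
      cor(coh$lc_mm, coh$r_ec)
    }, numeric(1))
    bound <- max(3 * (1 - rho^2) / sqrt(22), 0.02)
    expect_lt(abs(mean(rs) - rho), bound)
  }
})
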