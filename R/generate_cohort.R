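#' Specification of a synthetic study cohort
#'
#' Describes a cohort in which a latent skin-quality factor jointly drives
#' the characteristic length Lc and the Elastin-to-Collagen ratio R_EC
#' with a target Pearson correlation, while demographic covariates (age,
#' height, weight, BMI) are independent of both.  Defaults reproduce the
#' study conditions: 22 elderly women, R_EC ~ 0.035 +/- 0.02, Lc spanning
#' 0.90--2.62 mm, and a planted Lc--R_EC correlation of 0.92.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param latent_corr target Pearson correlation between the Lc and R_EC
#'   drivers, in `[-1, 1]`.
#' @param rec_mean,rec_sd distribution of R_EC (Gaussian, floored at 0).
#' @param lc_range central ~95% band `(min, max)` of the Lc driver (mm).
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   covariate distributions (years, cm, kg); BMI is derived from weight
#'   and height so the record stays internally consistent.
#' @param ra_mean,ra_sd roughness distribution (um), independent of the
#'   latent factor.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 22L, latent_corr = 0.92,
                        rec_mean = 0.035, rec_sd = 0.02,
                        lc_range = c(0.90, 2.62),
                        age_mean = 82.6, age_sd = 9.2,
                        height_mean = 160.8, height_sd = 6.0,
                        weight_mean = 60.8, weight_sd = 9.1,
                        ra_mean = 38.4, ra_sd = 20.2, seed = 1L) {
  check(is_count(n_subjects) && n_subjects >= 4, "n_subjects must be >= 4")
  check(is_number(latent_corr) && abs(latent_corr) <= 1,
        "|latent_corr| must be <= 1")
  check(is_number(rec_sd) && rec_sd > 0, "rec_sd must be > 0")
  check(length(lc_range) == 2 && lc_range[1] > 0 && lc_range[2] > lc_range[1],
        "lc_range must be an increasing positive pair")
  structure(
    list(n_subjects = as.integer(n_subjects), latent_corr = latent_corr,
         rec_mean = rec_mean, rec_sd = rec_sd, lc_range = lc_range,
         age_mean = age_mean, age_sd = age_sd, height_mean = height_mean,
         height_sd = height_sd, weight_mean = weight_mean,
         weight_sd = weight_sd, ra_mean = ra_mean, ra_sd = ra_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a cohort with a planted Lc--R_EC correlation
#'
#' Draws a bivariate standard normal pair `(z1, z2)` with correlation
#' `latent_corr`; R_EC is `rec_mean + rec_sd * z1` floored at 0, and the
#' Lc driver maps `z2` linearly onto `lc_range` (range midpoint, quarter
#' range as standard deviation, floored at 0.05 mm).  Covariates are
#' drawn independently.  Replica-derived morphometry columns (NP, mean
#' area/perimeter/axes, aspect ratio) are emulated from the Lc driver
#' through the square-lattice scaling relations `NP ~ (2/Lc)^2`,
#' `A ~ (Lc/2)^2`, `P ~ 2 Lc` with lognormal scatter, and the minor axis
#' depends only weakly on Lc -- mirroring how these quantities co-vary in
#' real replicas.  Use [run_pipeline()] with `mode = "replica"` to obtain
#' them from actual rendered images instead.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with one row per subject: `subject_id`,
#'   `age_years`, `height_cm`, `weight_kg`, `bmi_kg_m2`, `ra_um`,
#'   `lc_mm`, `r_ec`, `np_per_mm2`, `mean_area_mm2`, `mean_perimeter_mm`,
#'   `mean_major_mm`, `mean_minor_mm`, `mean_aspect_ratio`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 11))
#' cor(coh$lc_mm, coh$r_ec)
#' @export
generate_cohort <- function(spec) {
  check(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  with_seed(spec$seed, {
    n <- spec$n_subjects
    rho <- spec$latent_corr
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    r_ec <- pmax(spec$rec_mean + spec$rec_sd * z1, 0)
    lc_mid <- mean(spec$lc_range)
    lc_sd <- diff(spec$lc_range) / 4
    lc <- pmax(lc_mid + lc_sd * z2, 0.05)

    age <- rnorm(n, spec$age_mean, spec$age_sd)
    height <- rnorm(n, spec$height_mean, spec$height_sd)
    weight <- rnorm(n, spec$weight_mean, spec$weight_sd)
    ra <- pmax(rnorm(n, spec$ra_mean, spec$ra_sd), 1)

    scatter <- function(sd) exp(rnorm(n, 0, sd))
    np <- (2 / lc)^2 * scatter(0.15)
    area <- (lc / 2)^2 * scatter(0.10)
    perim <- 2 * lc * scatter(0.10)
    major <- 0.9 * lc * scatter(0.10)
    minor <- 0.45 * (lc / 1.64)^0.25 * scatter(0.10)

    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      age_years = age, height_cm = height, weight_kg = weight,
      bmi_kg_m2 = weight / (height / 100)^2,
      ra_um = ra, lc_mm = lc, r_ec = r_ec,
      np_per_mm2 = np, mean_area_mm2 = area, mean_perimeter_mm = perim,
      mean_major_mm = major, mean_minor_mm = minor,
      mean_aspect_ratio = major / minor)
  })
}
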