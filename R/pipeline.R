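#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the simulate -> measure -> statistics chain in
#' one validated object so a run is fully reproducible from (config,
#' seed).
#'
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output and returns results only.
#' @param seed master seed for the run.
#' @param mode `"driver"` simulates per-subject measurements at the
#'   latent-driver level (fast); `"replica"` additionally renders one
#'   Voronoi replica and one profile pair per subject from the drivers
#'   and runs the full image pipeline (watershed morphometry, detrended
#'   roughness) on them.
#' @param cohort a [cohort_spec()] describing the simulated study
#'   population (its `seed` is overridden by `seed`).
#' @param replica_side_mm,mm_per_pixel replica rendering geometry used in
#'   `"replica"` mode.
#' @param h_minima H-minima depth for segmentation.
#' @param min_area_mm2,exclude_border morphometry filters.
#' @param detrend_order baseline order for roughness profiles.
#' @param alpha significance level of the group comparisons.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = NULL, seed = 1L,
                       mode = c("driver", "replica"),
                       cohort = cohort_spec(),
                       replica_side_mm = 8, mm_per_pixel = 0.03,
                       h_minima = 10, min_area_mm2 = 0.01,
                       exclude_border = TRUE, detrend_order = 1L,
                       alpha = 0.05) {
  mode <- match.arg(mode)
  check(inherits(cohort, "cohort_spec"), "cohort must be a cohort_spec")
  check(is_number(mm_per_pixel) && mm_per_pixel > 0,
        "mm_per_pixel must be positive")
  check(is_number(replica_side_mm) && replica_side_mm > 0,
        "replica_side_mm must be positive")
  check(is_number(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  check(is_number(h_minima) && h_minima >= 1, "h_minima must be >= 1")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
              cohort = unclass(cohort), replica_side_mm = replica_side_mm,
              mm_per_pixel = mm_per_pixel, h_minima = h_minima,
              min_area_mm2 = min_area_mm2, exclude_border = exclude_border,
              detrend_order = as.integer(detrend_order), alpha = alpha)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

# cells per mm^2 implied by a target characteristic length; the constant
# is the square-lattice relation Lc = 2 / sqrt(density), adjusted for the
# sub-polygon scatter of random tessellations (see the methods vignette).
lc_to_density <- function(lc_mm) (2.0 / lc_mm)^2

#' Run the full simulate -> measure -> statistics pipeline
#'
#' Generates a cohort with a planted Lc--R_EC correlation, obtains
#' per-subject measurements (either directly from the latent drivers or,
#' in `"replica"` mode, by rendering and segmenting one replica image and
#' measuring one detrended profile pair per subject), and computes the
#' cohort statistics: descriptives, the low/high-Lc comparison table and
#' the Pearson correlation matrix.  When `out_dir` is set, writes
#' `cohort.csv`, `table2.csv`, `correlation.csv` and one JSON record per
#' subject under `subjects/`; every artefact carries the config hash, and
#' a rerun with the same config is byte-identical.  Subjects for which an
#' imaging stage fails are excluded from the statistics (complete-case)
#' and listed with a reason.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `cohort`, `table2`, `correlation`,
#'   `descriptives`, `excluded`, `config_hash`.
#' @examples
#' res <- run_pipeline(run_config(seed = 4,
#'   cohort = cohort_spec(n_subjects = 8)))
#' res$table2[res$table2$variable == "r_ec", "label"]
#' @export
run_pipeline <- function(config) {
  check(inherits(config, "run_config"), "config must be a run_config")
  hash <- config_hash(config)
  cspec <- do.call(cohort_spec, c(config$cohort[setdiff(names(config$cohort),
                                                        "seed")],
                                  list(seed = config$seed)))
  cohort <- generate_cohort(cspec)
  excluded <- data.frame(subject_id = character(0), reason = character(0))

  if (config$mode == "replica") {
    measured <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      m <- tryCatch(
        measure_subject(cohort$lc_mm[i], cohort$ra_um[i], config,
                        seed = config$seed * 1000L + i),
        error = function(e) e)
      if (inherits(m, "error")) {
        excluded <- rbind(excluded, data.frame(
          subject_id = cohort$subject_id[i], reason = conditionMessage(m)))
        measured[[i]] <- NULL
      } else {
        measured[[i]] <- m
      }
    }
    ok <- !vapply(measured, is.null, logical(1))
    cohort <- cohort[ok, , drop = FALSE]
    md <- do.call(rbind, measured[ok])
    for (v in names(md)) cohort[[v]] <- md[[v]]
  }

  vars <- table2_variables()
  tab2 <- table2_report(cohort, alpha = config$alpha)
  corr <- correlation_matrix(cohort, intersect(vars, names(cohort)))
  desc <- summarize_cohort(cohort, intersect(vars, names(cohort)))
  res <- list(cohort = cohort, table2 = tab2, correlation = corr,
              descriptives = desc, excluded = excluded, config_hash = hash)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    coh_out <- cohort
    coh_out$config_hash <- hash
    write_cohort_csv(coh_out, file.path(config$out_dir, "cohort.csv"))
    tab_out <- tab2
    tab_out$config_hash <- hash
    write.csv(tab_out, file.path(config$out_dir, "table2.csv"),
              row.names = FALSE)
    write.csv(cbind(data.frame(variable = rownames(corr)), corr),
              file.path(config$out_dir, "correlation.csv"),
              row.names = FALSE)
    sdir <- file.path(config$out_dir, "subjects")
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort))) {
      rec <- c(as.list(cohort[i, ]), list(config_hash = hash))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE),
                 file.path(sdir, paste0(cohort$subject_id[i], ".json")))
    }
  }
  invisible(res)
}

# Render one subject's replica from the Lc driver and measure it with the
# image pipeline; simulate a matching profile pair for the Ra driver.
measure_subject <- function(lc_driver, ra_driver, config, seed) {
  side <- config$replica_side_mm
  n_seeds <- max(9L, round(lc_to_density(lc_driver) * side^2))
  rspec <- replica_spec(side_mm = side, mm_per_pixel = config$mm_per_pixel,
                        n_seeds = n_seeds, ridge_width_mm = 0.1,
                        noise_sd = 8, seed = seed)
  rep <- generate_replica(rspec, compute_truth = FALSE)
  lab <- segment_replica(rep$image, h = config$h_minima)
  feats <- extract_features(lab, config$mm_per_pixel)
  ms <- summarize_morphometry(feats, side^2,
                              exclude_border = config$exclude_border,
                              min_area_mm2 = config$min_area_mm2)
  if (ms$n_polygons_used < 3)
    sm_stop("skinmorph_stage_error", "too few interior polygons recovered")

  # Gaussian roughness profile: |N(0, s)| has mean s * sqrt(2/pi), so
  # s = ra * sqrt(pi/2) gives the target Ra after detrending
  prof <- with_seed(seed + 1L, {
    x <- seq(0, 10, by = 0.005)
    lapply(1:2, function(i)
      surface_profile(x, rnorm(length(x), 0, ra_driver * sqrt(pi / 2))))
  })
  ra <- ra_pair(prof[[1]], prof[[2]], order = config$detrend_order)

  usable <- feats[!feats$touches_border & feats$area_mm2 >=
                    config$min_area_mm2, , drop = FALSE]
  data.frame(
    lc_mm = ms$lc_mm, np_per_mm2 = ms$np_per_mm2,
    mean_area_mm2 = ms$mean_area_mm2,
    mean_perimeter_mm = ms$mean_perimeter_mm,
    mean_major_mm = mean(usable$major_mm),
    mean_minor_mm = mean(usable$minor_mm),
    mean_aspect_ratio = ms$mean_aspect_ratio,
    ra_um = ra$ra_um)
}
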