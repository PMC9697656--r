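# Readers and writers for the standard on-disk formats: multi-page TIFF
# stacks (one file per channel, page = z-slice), 8-bit PNG replica
# images, 2-column CSV height profiles and cohort CSV tables.

#' Write / read one channel of an image stack as multi-page TIFF
#'
#' Grey levels are stored as 16-bit samples scaled by 1/255, so the
#' nominal 0--255 grey scale round-trips with a quantisation error of
#' 1/257 grey level.  Values above 255 are clipped on write.
#'
#' @param channel 3-D numeric array (x, y, z).
#' @param path output file.
#' @return `read_stack_tiff()` returns the 3-D array.
#' @export
write_stack_tiff <- function(channel, path) {
  check(is.array(channel) && length(dim(channel)) == 3,
        "channel must be a 3-D array")
  pages <- lapply(seq_len(dim(channel)[3]), function(k) {
    m <- t(channel[, , k]) / 255
    m[m > 1] <- 1
    m[m < 0] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(m) t(m) * 255,
                matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  arr
}

#' Write / read a replica image as 8-bit PNG
#'
#' @param image a [replica_image()].
#' @param path file path.
#' @param mm_per_pixel calibration to attach on read (PNG carries none).
#' @return `read_replica_png()` returns a [replica_image()].
#' @export
write_replica_png <- function(image, path) {
  check(inherits(image, "replica_image"), "image must be a replica_image")
  m <- image$pixels / 255
  m[m > 1] <- 1
  m[m < 0] <- 0
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_replica_png
#' @export
read_replica_png <- function(path, mm_per_pixel) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) {
    # standard luminance weighting for colour photographs
    m <- 0.2126 * m[, , 1] + 0.7152 * m[, , 2] + 0.0722 * m[, , 3]
  }
  replica_image(m * 255, mm_per_pixel)
}

#' Write / read a height profile as 2-column CSV (x_mm, z_um)
#'
#' @param profile a [surface_profile()].
#' @param path file path.
#' @return `read_profile_csv()` returns a [surface_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  check(inherits(profile, "surface_profile"),
        "profile must be a surface_profile")
  write.csv(data.frame(x_mm = profile$x_mm, z_um = profile$z_um),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- read.csv(path)
  check(all(c("x_mm", "z_um") %in% names(d)),
        "profile CSV needs x_mm and z_um columns")
  surface_profile(d$x_mm, d$z_um)
}

#' Write / read a cohort table as CSV
#'
#' @param records cohort data frame.
#' @param path file path.
#' @return `read_cohort_csv()` returns the data frame.
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
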