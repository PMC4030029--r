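# Chromophore band aggregation: per-pixel sums of the corrected cube over
# the melanin (450-600 nm) and haemoglobin (397-500 nm) wavelength ranges,
# and the red/green composite rendering of the two maps.

#' Aggregate a wavelength range into a chromophore map
#'
#' Per-pixel sum of all bands whose wavelength lies in the closed interval
#' `[lo, hi]`; on the camera's 0.79 nm grid from 397 nm the default melanin
#' range selects 189 bands. With `normalized = TRUE` the summed map is
#' additionally min-max rescaled to `[0, 1]` (the form the area tables
#' report).
#'
#' @param cube the corrected [spectral_cube()] (L_P*).
#' @param lo,hi wavelength bounds in nm.
#' @param normalized rescale the sum to `[0, 1]`?
#' @return an object of class `chromophore_map` with fields `values`,
#'   `band_lo`, `band_hi`, `n_bands`, `normalized`.
#' @export
aggregate_band <- function(cube, lo, hi, normalized = FALSE) {
  idx <- band_indices(cube$wavelengths_nm, lo, hi)
  if (length(idx) == 0L) {
    stop("no bands inside [", lo, ", ", hi, "] nm")
  }
  vals <- sum_bands(cube, idx)
  if (normalized) vals <- normalize(vals)
  structure(list(values = vals, band_lo = lo, band_hi = hi,
                 n_bands = length(idx), normalized = normalized),
            class = "chromophore_map")
}

#' @export
print.chromophore_map <- function(x, ...) {
  cat(sprintf("<chromophore_map> %d x %d px, sum of %d bands in [%g, %g] nm%s\n",
              nrow(x$values), ncol(x$values), x$n_bands, x$band_lo,
              x$band_hi, if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Compose melanin and haemoglobin maps into an RGB image
#'
#' Red = melanin map, green = haemoglobin map, blue extinguished. Both maps
#' must be normalized and share dimensions.
#'
#' @param melanin,haemoglobin normalized `chromophore_map`s.
#' @return an `rows x cols x 3` array in `[0, 1]`.
#' @export
composite_rgb <- function(melanin, haemoglobin) {
  stopifnot(inherits(melanin, "chromophore_map"),
            inherits(haemoglobin, "chromophore_map"))
  if (!identical(dim(melanin$values), dim(haemoglobin$values))) {
    stop("melanin and haemoglobin maps must share dimensions")
  }
  if (!melanin$normalized || !haemoglobin$normalized) {
    stop("composite requires normalized maps")
  }
  out <- array(0, dim = c(dim(melanin$values), 3L))
  out[, , 1] <- melanin$values
  out[, , 2] <- haemoglobin$values
  out
}

#' Export a chromophore map
#'
#' Writes a single-band ENVI file (`<path>.dat`/`.hdr`) holding the exact
#' values and, optionally, a grayscale PNG preview of the normalized map.
#'
#' @param map a `chromophore_map`.
#' @param path output base path (no extension).
#' @param png also write `<path>.png`? Default `TRUE`.
#' @return invisibly, the paths written.
#' @export
export_chromophore_map <- function(map, path, png = TRUE) {
  mid <- (map$band_lo + map$band_hi) / 2
  cube1 <- spectral_cube(array(map$values, dim = c(dim(map$values), 1L)),
                         mid, 0L)
  write_envi_cube(cube1, path, interleave = "bsq")
  written <- c(paste0(path, ".dat"), paste0(path, ".hdr"))
  if (png) {
    v <- if (map$normalized) map$values else normalize(map$values)
    png::writePNG(v, paste0(path, ".png"), dpi = NULL)
    written <- c(written, paste0(path, ".png"))
  }
  invisible(written)
}
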