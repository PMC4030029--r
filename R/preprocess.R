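# Preprocessing: white-reference calibration from in-frame reference rows,
# 3x3 median filtering against impulse noise, min-max normalization to
# [0, 1] (value 1 = 100% emission because the reference area is included),
# and flat-fielding by subtracting a 30x30 moving average.

#' Spatial filter configuration
#'
#' @param median_size odd median mask size, default 3.
#' @param mean_size moving-average mask size for illumination removal,
#'   default 30 (twice the largest structure the flattened image should
#'   retain).
#' @param border_mode `"replicate"` (default), `"zero"`, or `"valid-only"`
#'   (border pixels passed through unfiltered).
#' @return a `filter_config` list.
#' @export
filter_config <- function(median_size = 3L, mean_size = 30L,
                          border_mode = c("replicate", "zero", "valid-only")) {
  border_mode <- match.arg(border_mode)
  if (median_size < 1L || median_size %% 2L == 0L) {
    stop("median_size must be odd and >= 1")
  }
  if (mean_size < 2L) stop("mean_size must be >= 2")
  structure(list(median_size = as.integer(median_size),
                 mean_size = as.integer(mean_size),
                 border_mode = border_mode),
            class = "filter_config")
}

#' Calibrate a cube against its in-frame white reference rows
#'
#' Each band is divided, column by column, by the mean of that band's
#' leading reference rows (per-column white reference; dark reference
#' assumed zero, standard push-broom practice). Reference rows are retained
#' in the frame and stay flagged via `calib_rows`. Near-zero reference
#' values are floored at `eps` before division.
#'
#' @param cube a [spectral_cube()] with `calib_rows >= 1`; with
#'   `calib_rows == 0` calibration is skipped with a warning.
#' @param eps reference floor guarding division.
#' @return the calibrated cube.
#' @export
calibrate <- function(cube, eps = 1e-6) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$calib_rows == 0L) {
    warning("cube has no reference rows; calibration skipped")
    return(cube)
  }
  cr <- seq_len(cube$calib_rows)
  v <- cube$values
  for (k in seq_len(dim(v)[3])) {
    band <- v[, , k]
    ref <- pmax(colMeans(band[cr, , drop = FALSE]), eps)
    v[, , k] <- sweep(band, 2L, ref, `/`)
  }
  out <- spectral_cube(v, cube$wavelengths_nm, cube$calib_rows)
  attr(out, "calibrated") <- TRUE
  out
}

#' Median filter an image
#'
#' Each pixel is replaced by the median of its `size x size` neighbourhood.
#' Borders are handled per `border_mode`; the default replicates edge
#' pixels. The 3x3 case runs through a vectorized comparator network.
#'
#' @param image numeric matrix.
#' @param size odd window size.
#' @param border_mode see [filter_config()].
#' @return the filtered matrix.
#' @export
median_filter <- function(image, size = 3L,
                          border_mode = c("replicate", "zero",
                                          "valid-only")) {
  border_mode <- match.arg(border_mode)
  stopifnot(is.matrix(image))
  if (size %% 2L == 0L || size < 1L) stop("median mask size must be odd")
  if (size == 1L) return(image)
  h <- (size - 1L) %/% 2L
  M <- nrow(image); N <- ncol(image)
  pad <- switch(border_mode,
    replicate = pad_replicate(image, h, h, h, h),
    zero = {
      p <- matrix(0, M + 2L * h, N + 2L * h)
      p[h + seq_len(M), h + seq_len(N)] <- image
      p
    },
    `valid-only` = pad_replicate(image, h, h, h, h)  # interior identical
  )
  rr <- h + seq_len(M); cc <- h + seq_len(N)
  if (size == 3L) {
    nb <- vector("list", 9L)
    t <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      t <- t + 1L
      nb[[t]] <- as.vector(pad[rr + dr, cc + dc])
    }
    out <- matrix(med9(nb), M, N)
  } else {
    k2 <- size * size
    X <- matrix(0, M * N, k2)
    t <- 0L
    for (dr in -h:h) for (dc in -h:h) {
      t <- t + 1L
      X[, t] <- as.vector(pad[rr + dr, cc + dc])
    }
    out <- matrix(apply(X, 1L, stats::median), M, N)
  }
  if (border_mode == "valid-only") {
    keep <- out
    out <- image
    ri <- (h + 1L):(M - h); ci <- (h + 1L):(N - h)
    if (length(ri) > 0L && length(ci) > 0L) out[ri, ci] <- keep[ri, ci]
  }
  out
}

#' Min-max normalize an image to [0, 1]
#'
#' `(x - min) / (max - min)`. Because the reference (100% emission) area is
#' part of the frame, value 1 after normalization corresponds to full
#' emission at that band. A constant image is a degenerate input (a dead
#' band) and raises an error rather than silently producing zeros.
#'
#' @param image numeric matrix with `max > min`.
#' @return normalized matrix spanning exactly `[0, 1]`.
#' @export
normalize <- function(image) {
  mn <- min(image); mx <- max(image)
  if (mx <= mn) stop("degenerate input: image is constant, cannot normalize")
  (image - mn) / (mx - mn)
}

#' Remove uneven illumination
#'
#' Subtracts the `mean_size x mean_size` moving average from the image.
#' The full frame is returned (replicate padding); the attribute `"valid"`
#' gives the row/column ranges where the result exactly equals the padless
#' double-sum (the even mask is anchored with centre offset `mean_size/2`,
#' i.e. offsets `-14..15` for the default 30).
#'
#' @param image numeric matrix strictly larger than the mask in both dims.
#' @param config a [filter_config()] (or an integer mask size).
#' @return the flattened image with a `"valid"` attribute.
#' @export
remove_illumination <- function(image, config = filter_config()) {
  size <- if (inherits(config, "filter_config")) config$mean_size
          else as.integer(config)
  if (nrow(image) <= size || ncol(image) <= size) {
    stop("image (", nrow(image), "x", ncol(image),
         ") must be larger than the mean mask (", size, ")")
  }
  bm <- box_mean(image, size)
  out <- image - bm
  attr(out, "valid") <- attr(bm, "valid")
  out
}

# --- cube-level wrappers -----------------------------------------------

#' Median-filter every band of a cube
#' @param cube a [spectral_cube()].
#' @param config a [filter_config()].
#' @return the filtered cube.
#' @export
median_filter_cube <- function(cube, config = filter_config()) {
  v <- cube$values
  for (k in seq_len(dim(v)[3])) {
    v[, , k] <- median_filter(v[, , k], config$median_size,
                              config$border_mode)
  }
  spectral_cube(v, cube$wavelengths_nm, cube$calib_rows)
}

#' Normalize every band of a cube to [0, 1]
#' @inheritParams median_filter_cube
#' @return the normalized cube (the measurable image L_P).
#' @export
normalize_cube <- function(cube) {
  v <- cube$values
  for (k in seq_len(dim(v)[3])) v[, , k] <- normalize(v[, , k])
  spectral_cube(v, cube$wavelengths_nm, cube$calib_rows)
}

#' Remove uneven illumination from every band of a cube
#' @inheritParams median_filter_cube
#' @return the flattened cube (the segmentation image L_C).
#' @export
remove_illumination_cube <- function(cube, config = filter_config()) {
  v <- cube$values
  for (k in seq_len(dim(v)[3])) {
    b <- remove_illumination(v[, , k], config)
    attr(b, "valid") <- NULL
    v[, , k] <- b
  }
  spectral_cube(v, cube$wavelengths_nm, cube$calib_rows)
}

#' Run the full preprocessing chain on a cube
#'
#' calibrate (when reference rows exist) -> median filter -> normalize
#' (the measurable image `LP`) -> illumination removal (the segmentation
#' image `LC`).
#'
#' @param cube a [spectral_cube()].
#' @param config a [filter_config()].
#' @return `list(LP = ..., LC = ...)`, both spectral cubes.
#' @export
preprocess_cube <- function(cube, config = filter_config()) {
  calibrated <- if (cube$calib_rows > 0L) calibrate(cube) else cube
  lm <- median_filter_cube(calibrated, config)
  lp <- normalize_cube(lm)
  lc <- remove_illumination_cube(lp, config)
  list(LP = lp, LC = lc)
}
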