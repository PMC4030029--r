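# Per-finger region analysis: each matched finger is cut into 12 areas
# (6 along-axis segments x 2 sides), per-area mean/SD tables are computed
# from the chromophore maps, and spectral / along-finger profiles are
# extracted. In the corrected frame fingers run along rows (tips towards
# row 1), so the finger axis is vertical and the two sides split by column:
# side A is the smaller-column side.

#' Partition a finger into 12 areas
#'
#' The finger region is delimited from its tip landmark towards the palm by
#' the template's scaled finger length, within a column window of the
#' template finger width (plus a 1 px guard) around the tip column. Six
#' equal-length half-open segments along the axis (A1/B1 at the tip) times
#' the two sides of the per-row centreline give 12 labelled areas; pixels
#' exactly on the centreline join side A.
#'
#' @param mask 0/1 matrix of the corrected frame.
#' @param landmarks landmark set in the corrected frame (`point`, `row`,
#'   `col`, `visible`); fingertips V1..V5.
#' @param template a [hand_template()] (finger lengths/widths).
#' @param finger finger index 1..5 (or name "V1".."V5").
#' @return an object of class `area_partition`: `list(finger, labels,
#'   label_matrix, axis, segment_bounds, n_pixels)`, or `NULL` (with a
#'   warning) when the finger is not visible.
#' @export
partition_finger <- function(mask, landmarks, template, finger) {
  if (is.character(finger)) finger <- as.integer(sub("^V", "", finger))
  stopifnot(finger >= 1L, finger <= 5L)
  lm <- as.data.frame(landmarks)
  row_i <- match(paste0("V", finger), lm$point)
  if (is.na(row_i) || !isTRUE(lm$visible[row_i]) || is.na(lm$row[row_i])) {
    warning("finger V", finger, " not visible; partition skipped")
    return(NULL)
  }
  tip_r <- lm$row[row_i]; tip_c <- lm$col[row_i]
  len <- template$finger_lengths[finger]
  wid <- template$finger_widths[finger]
  M <- nrow(mask); N <- ncol(mask)

  half_w <- wid / 2 + 1
  cols <- max(1L, ceiling(tip_c - half_w)):min(N, floor(tip_c + half_w))
  bounds <- round(tip_r + seq(0, 6) * len / 6)
  bounds <- pmin(pmax(bounds, 1L), M + 1L)

  labels <- c(paste0("A", 1:6), paste0("B", 1:6))
  label_matrix <- matrix(0L, M, N)
  last_row <- min(M, bounds[7] - 1L)
  if (last_row < bounds[1]) {
    warning("finger V", finger, " region is empty; partition skipped")
    return(NULL)
  }
  rows_all <- seq.int(bounds[1], last_row)
  axis <- data.frame(row = integer(0), centre_col = numeric(0))
  for (r in rows_all) {
    inr <- cols[mask[r, cols] > 0L]
    if (length(inr) == 0L) next
    centre <- mean(inr)
    axis <- rbind(axis, data.frame(row = r, centre_col = centre))
    seg <- findInterval(r, bounds, rightmost.closed = FALSE)
    if (seg < 1L || seg > 6L) next
    side_a <- inr[inr <= centre]
    side_b <- inr[inr > centre]
    label_matrix[r, side_a] <- seg           # A1..A6 -> 1..6
    label_matrix[r, side_b] <- seg + 6L      # B1..B6 -> 7..12
  }
  if (all(label_matrix == 0L)) {
    warning("finger V", finger, " region is empty; partition skipped")
    return(NULL)
  }
  structure(list(
    finger = finger, labels = labels, label_matrix = label_matrix,
    axis = axis, segment_bounds = bounds,
    n_pixels = tabulate(label_matrix[label_matrix > 0L], 12L)
  ), class = "area_partition")
}

#' Per-area statistics of a chromophore map
#'
#' Mean, population standard deviation (the "STD" the area tables print),
#' standard error of the mean and pixel count for each of the 12 areas,
#' ordered A1..A6, B1..B6. Empty areas are recorded as missing (`NA`),
#' not zero.
#'
#' @param map a `chromophore_map` (or plain matrix).
#' @param partition an `area_partition`.
#' @return a data.frame (`area`, `mean`, `sd`, `sem`, `n`) of class
#'   `area_stats`.
#' @export
area_stats <- function(map, partition) {
  stopifnot(inherits(partition, "area_partition"))
  vals <- if (inherits(map, "chromophore_map")) map$values else map
  out <- do.call(rbind, lapply(seq_along(partition$labels), function(l) {
    px <- vals[partition$label_matrix == l]
    n <- length(px)
    if (n == 0L) {
      data.frame(area = partition$labels[l], mean = NA_real_,
                 sd = NA_real_, sem = NA_real_, n = 0L,
                 stringsAsFactors = FALSE)
    } else {
      mu <- mean(px)
      sd_pop <- sqrt(mean((px - mu)^2))
      data.frame(area = partition$labels[l], mean = mu, sd = sd_pop,
                 sem = sd_pop / sqrt(n), n = n, stringsAsFactors = FALSE)
    }
  }))
  class(out) <- c("area_stats", "data.frame")
  out
}

#' Spectral profile along a finger
#'
#' For every along-axis position (row) of the finger region, the mean
#' across the finger width, for every band; positions of degenerate
#' (zero-width) extent are skipped with a warning. Also returns the
#' band-restricted mean curve over a chosen range (melanin by default).
#'
#' @param cube the corrected [spectral_cube()] (L_P*).
#' @param partition an `area_partition`.
#' @param band_lo,band_hi range for the band-mean curve, nm.
#' @return `list(positions, wavelengths_nm, profile, band_mean)` of class
#'   `spectral_profile`; `profile` is positions x bands.
#' @export
spectral_profile <- function(cube, partition, band_lo = 450,
                             band_hi = 600) {
  stopifnot(inherits(partition, "area_partition"))
  region <- partition$label_matrix > 0L
  rows <- sort(unique(which(region, arr.ind = TRUE)[, 1]))
  wl <- cube$wavelengths_nm
  L <- length(wl)
  prof <- matrix(NA_real_, length(rows), L)
  keep <- rep(TRUE, length(rows))
  for (i in seq_along(rows)) {
    cc <- which(region[rows[i], ])
    if (length(cc) == 0L) {
      warning("degenerate width at row ", rows[i], "; position skipped")
      keep[i] <- FALSE
      next
    }
    block <- cube$values[rows[i], cc, , drop = FALSE]
    prof[i, ] <- apply(block, 3L, mean)
  }
  rows <- rows[keep]; prof <- prof[keep, , drop = FALSE]
  idx <- band_indices(wl, band_lo, band_hi)
  structure(list(
    positions = rows, wavelengths_nm = wl, profile = prof,
    band_mean = if (length(idx) > 0L) rowMeans(prof[, idx, drop = FALSE])
                else rep(NA_real_, length(rows))
  ), class = "spectral_profile")
}

#' Along-finger intensity trend and wrist/tip ratio
#'
#' Per finger, the mean map value at every along-axis position, and the
#' ratio of the wrist-end to the tip-end mean (each end averaged over the
#' outermost 5% of positions, at least one row). A constant map yields
#' ratio 1; a programmed wrist-ward gain of `g` yields approximately
#' `1 + g`.
#'
#' @param map a `chromophore_map` (or plain matrix), typically the raw
#'   (unnormalized) melanin sum.
#' @param partitions list of `area_partition`s (one per finger).
#' @return `list(curves, ratios)`: per-finger data.frames
#'   (`position`, `mean`) and the named wrist/tip ratio vector.
#' @export
along_finger_trend <- function(map, partitions) {
  partitions <- Filter(Negate(is.null), partitions)
  if (length(partitions) == 0L) stop("no partitioned fingers")
  vals <- if (inherits(map, "chromophore_map")) map$values else map
  curves <- list()
  ratios <- numeric(0)
  for (p in partitions) {
    region <- p$label_matrix > 0L
    rows <- sort(unique(which(region, arr.ind = TRUE)[, 1]))
    mu <- vapply(rows, function(r) mean(vals[r, region[r, ]]), numeric(1))
    nm <- paste0("V", p$finger)
    curves[[nm]] <- data.frame(position = rows, mean = mu)
    k <- max(1L, ceiling(0.05 * length(rows)))
    ratios[nm] <- mean(utils::tail(mu, k)) / mean(utils::head(mu, k))
  }
  list(curves = curves, ratios = ratios)
}

#' Write area statistics in the printed table layout
#'
#' One row of means and one of SDs, columns ordered `O_{i,A1}..O_{i,B6}`.
#'
#' @param stats an `area_stats` data.frame.
#' @param finger finger index (used in the column prefix).
#' @param path CSV output path.
#' @return the written path, invisibly.
#' @export
write_area_table <- function(stats, finger, path) {
  hdr <- paste0("O_", finger, ",", stats$area)
  tab <- rbind(Brightness = stats$mean, STD = stats$sd, SEM = stats$sem,
               N = stats$n)
  colnames(tab) <- hdr
  utils::write.csv(tab, path)
  invisible(path)
}
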