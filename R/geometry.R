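# Hand localization: nearest-neighbour downscale, rotation estimation by
# maximizing the column-concentration criterion over a 1-degree grid,
# Otsu binarization of the band-summed image, the per-column contour curve
# with its local-minima fingertip landmarks, binary opening with a square
# element wider than any finger, and the wrist centroid of the opened mask.

#' Sum a cube over its bands
#'
#' @param cube a [spectral_cube()].
#' @param bands optional integer band subset (default all).
#' @return a numeric matrix, the per-pixel sum over wavelengths.
#' @export
sum_bands <- function(cube, bands = NULL) {
  v <- cube$values
  if (!is.null(bands)) v <- v[, , bands, drop = FALSE]
  rowSums(v, dims = 2L)
}

#' Downscale an image by nearest-neighbour resampling
#'
#' Output dimensions are `round(dim * factor)`; each output pixel copies the
#' source pixel nearest to its centre (`src = ceiling((i - 0.5) * M / Mout)`).
#' 899 x 1312 at factor 0.1 becomes 90 x 131.
#'
#' @param image numeric matrix.
#' @param factor scale factor in `(0, 1]`.
#' @return the resampled matrix.
#' @export
downscale <- function(image, factor) {
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]")
  if (factor == 1) return(image)
  M <- nrow(image); N <- ncol(image)
  Mo <- max(1L, round(M * factor)); No <- max(1L, round(N * factor))
  sr <- pmin(M, pmax(1L, ceiling((seq_len(Mo) - 0.5) * M / Mo)))
  sc <- pmin(N, pmax(1L, ceiling((seq_len(No) - 0.5) * N / No)))
  image[sr, sc, drop = FALSE]
}

#' Estimate the hand inclination angle
#'
#' For each angle `alpha` on a grid over (0, 180) degrees, the band-summed
#' working image is rotated by `-alpha` (the correction sense) and scored by
#' the maximum over columns of the column sums; mass concentrates into few
#' columns exactly when the hand axis is vertical. The returned `alpha_star`
#' is the grid angle with the maximal score (smallest angle on ties), i.e.
#' the rotation that [apply_correction()] must undo.
#'
#' @param ld_sum band-summed downscaled image (numeric matrix).
#' @param step_deg grid step in degrees, default 1.
#' @return `list(alpha_star, score, scores, angles, working)` of class
#'   `rotation_result`.
#' @export
estimate_rotation <- function(ld_sum, step_deg = 1) {
  stopifnot(is.matrix(ld_sum), step_deg > 0)
  if (length(ld_sum) == 0L || all(ld_sum == 0)) {
    stop("empty working image: cannot estimate rotation")
  }
  angles <- seq(step_deg, 180 - step_deg, by = step_deg)
  if (length(angles) == 0L) stop("step_deg leaves no grid angles in (0,180)")
  scores <- vapply(angles, function(a) {
    max(colSums(rotate_image(ld_sum, -a)))
  }, numeric(1))
  best <- which.max(scores)   # first = smallest angle on ties
  structure(list(alpha_star = angles[best], score = scores[best],
                 scores = scores, angles = angles, working = ld_sum),
            class = "rotation_result")
}

#' Otsu threshold
#'
#' The threshold maximizing the between-class variance on a 256-bin
#' histogram of the image rescaled to `[0, 1]`, mapped back to the original
#' value range. Ties take the smallest maximizing cut. The result is
#' invariant to affine rescaling of the input up to the same affine map.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param nbins histogram resolution, default 256.
#' @return the threshold, in the image's own units.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  mn <- min(image); mx <- max(image)
  if (mx <= mn) stop("constant image: Otsu threshold undefined")
  y <- (as.vector(image) - mn) / (mx - mn)
  bin <- pmin(nbins, floor(y * nbins) + 1L)
  counts <- tabulate(bin, nbins)
  p <- counts / sum(counts)
  centres <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * centres)
  mu_tot <- mu[nbins]
  t <- seq_len(nbins - 1L)
  w0t <- w0[t]
  valid <- w0t > 0 & w0t < 1
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_tot * w0t[valid] - mu[t][valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  cut <- which.max(sigma_b)     # smallest maximizing cut
  mn + (mx - mn) * cut / nbins
}

#' Binarize an image at a threshold
#'
#' Strict `>` comparison: a value exactly equal to the threshold maps to 0.
#'
#' @param image numeric matrix.
#' @param threshold scalar cut value.
#' @return a 0/1 integer matrix (a binary mask).
#' @export
binarize <- function(image, threshold) {
  m <- (image > threshold) + 0L
  dim(m) <- dim(image)
  m
}

#' Per-column contour curve of a binary mask
#'
#' For each column, the smallest row index holding a 1 (the first foreground
#' row from the top); columns with no foreground read `NA`.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return integer vector of length `ncol(mask)` with `NA` sentinels.
#' @export
contour_curve <- function(mask) {
  if (all(mask == 0L)) stop("empty mask: no contour")
  apply(mask, 2L, function(col) {
    i <- which(col > 0L)
    if (length(i) == 0L) NA_integer_ else i[1]
  })
}

#' Fingertip landmarks from the contour curve
#'
#' Fingertips protrude towards row 1, so they are the local minima of the
#' contour curve. A plateau of equal values counts once (its centre column
#' represents it). Each candidate's prominence is the climb to the lower of
#' the two enclosing ridges (scanning outward until a strictly lower point
#' or the curve end); candidates below `min_prominence` are dropped, the
#' rest are thinned greedily (deepest first) to a pairwise column separation
#' of at least `min_separation`, and at most five are kept, ordered by
#' column and named V1..V5. When fewer than five fingers are found the
#' remaining names are flagged not visible (e.g. a thumb outside the frame).
#'
#' @param curve contour curve from [contour_curve()] (NA = empty column).
#' @param min_separation minimal column distance between tips, px.
#' @param min_prominence minimal contour depth of a tip, px.
#' @return a data.frame (`point`, `row`, `col`, `visible`), class
#'   `landmark_set`.
#' @export
find_tip_landmarks <- function(curve, min_separation = 4,
                               min_prominence = 5) {
  y <- as.numeric(curve)
  n <- length(y)
  ok <- which(!is.na(y))
  if (length(ok) == 0L) stop("contour curve is empty")

  # plateau-aware local minima over the finite support
  cand <- integer(0)
  i <- 1L
  while (i <= length(ok)) {
    j <- i
    while (j < length(ok) && ok[j + 1L] == ok[j] + 1L &&
           y[ok[j + 1L]] == y[ok[i]]) j <- j + 1L
    left <- if (i == 1L || ok[i - 1L] != ok[i] - 1L) Inf else y[ok[i - 1L]]
    right <- if (j == length(ok) || ok[j + 1L] != ok[j] + 1L) Inf
             else y[ok[j + 1L]]
    if (y[ok[i]] < left && y[ok[i]] < right) {
      cand <- c(cand, ok[(i + j) %/% 2L])
    }
    i <- j + 1L
  }
  if (length(cand) == 0L) stop("no local minima found on the contour")

  prominence <- vapply(cand, function(k) {
    # climb outward to the enclosing ridge; a side where the support ends
    # before any strictly lower point is unbounded (edge fingers keep
    # their full prominence from the inner side)
    climb <- function(idx) {
      best <- y[k]
      for (c2 in idx) {
        if (is.na(y[c2])) return(Inf)
        if (y[c2] < y[k]) return(best - y[k])
        best <- max(best, y[c2])
      }
      Inf
    }
    right_idx <- if (k < n) (k + 1L):n else integer(0)
    min(climb(rev(seq_len(k - 1L))), climb(right_idx))
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) == 0L) stop("no contour minima reach min_prominence = ",
                               min_prominence)
  # greedy thinning, deepest tips first
  ord <- keep[order(y[keep], keep)]
  sel <- integer(0)
  for (k in ord) {
    if (all(abs(k - sel) >= min_separation)) sel <- c(sel, k)
  }
  sel <- sort(utils::head(sel[order(y[sel], sel)], 5L))
  pts <- data.frame(
    point = paste0("V", seq_along(sel)),
    row = y[sel], col = sel, visible = TRUE,
    stringsAsFactors = FALSE
  )
  if (length(sel) < 5L) {
    pts <- rbind(pts, data.frame(
      point = paste0("V", (length(sel) + 1L):5L),
      row = NA_real_, col = NA_real_, visible = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  structure(pts, class = c("landmark_set", "data.frame"))
}

#' Binary opening with a square structuring element
#'
#' Erosion then dilation with a `se_size x se_size` square; pixels outside
#' the frame count as background. With an element wider than any finger the
#' opening deletes the fingers and keeps the palm/wrist blob. At the 10%
#' working resolution the full-resolution 201 px element scales to 21 px
#' (see [pipeline_config()]).
#'
#' @param mask 0/1 matrix.
#' @param se_size odd element size `>= 3` and smaller than both image dims.
#' @return the opened 0/1 matrix.
#' @export
binary_opening <- function(mask, se_size) {
  if (se_size %% 2L == 0L || se_size < 3L) {
    stop("structuring element size must be odd and >= 3")
  }
  if (se_size >= min(dim(mask))) {
    stop("structuring element (", se_size,
         ") must be smaller than the image (", paste(dim(mask),
                                                     collapse = "x"), ")")
  }
  er <- run_window(mask, se_size, pmin, pad = 0L)
  run_window(er, se_size, pmax, pad = 0L)
}

#' Centre of mass of the opened wrist mask
#'
#' Intensity-weighted centroid (binary weights reduce to the plain
#' centroid); the real-valued centre is rounded to the nearest pixel for
#' the wrist landmark V6.
#'
#' @param opened non-empty weight matrix (the opened mask).
#' @return `list(row, col, v6 = c(row, col) integer)`.
#' @export
wrist_centroid <- function(opened) {
  tot <- sum(opened)
  if (tot <= 0) stop("empty opened mask: wrist centroid undefined")
  m <- sum(row(opened) * opened) / tot
  n <- sum(col(opened) * opened) / tot
  list(row = m, col = n, v6 = c(row = as.integer(round(m)),
                                col = as.integer(round(n))))
}
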