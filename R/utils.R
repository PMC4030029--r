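# Internal helpers shared across modules: seeded evaluation, matrix shifting,
# box sums via integral images, a median-of-9 comparator network, separable
# running min/max, and nearest-neighbour rotation with a reusable index map.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# out[i, j] = x[i - dr, j - dc], `fill` where the source falls outside.
shift_mat <- function(x, dr, dc, fill = 0) {
  M <- nrow(x); N <- ncol(x)
  out <- matrix(fill, M, N)
  sr <- max(1L, 1L + dr):min(M, M + dr)
  sc <- max(1L, 1L + dc):min(N, N + dc)
  if (length(sr) > 0L && length(sc) > 0L && sr[1] <= sr[length(sr)] &&
      sc[1] <= sc[length(sc)]) {
    out[sr, sc] <- x[sr - dr, sc - dc]
  }
  out
}

# Window offsets for a length-`size` mask anchored as in the moving-average
# index arithmetic: offsets (1:size) - floor((size + 1) / 2).
# size 30 -> -14..15 ; size 3 -> -1..1.
mask_offsets <- function(size) {
  seq_len(size) - floor((size + 1) / 2)
}

# Replicate-pad a matrix by (lo, hi) rows and (lo2, hi2) cols.
pad_replicate <- function(x, rlo, rhi, clo, chi) {
  M <- nrow(x); N <- ncol(x)
  ri <- c(rep(1L, rlo), seq_len(M), rep(M, rhi))
  ci <- c(rep(1L, clo), seq_len(N), rep(N, chi))
  x[ri, ci, drop = FALSE]
}

# Moving-average over a size x size window (replicate padding), exact via an
# integral image. Returns the full-frame mean image with attribute
# "valid" = list(rows = a:b, cols = a:b) where the padless window fits.
box_mean <- function(x, size) {
  off <- mask_offsets(size)
  plo <- -off[1]; phi <- off[length(off)]
  M <- nrow(x); N <- ncol(x)
  p <- pad_replicate(x, plo, phi, plo, phi)
  # integral image with zero first row/col
  I <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  I[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  r <- seq_len(M); cc <- seq_len(N)
  s <- I[r + size, cc + size, drop = FALSE] - I[r, cc + size, drop = FALSE] -
    I[r + size, cc, drop = FALSE] + I[r, cc, drop = FALSE]
  out <- s / (size * size)
  attr(out, "valid") <- list(
    rows = if (plo + 1L <= M - phi) (plo + 1L):(M - phi) else integer(0),
    cols = if (plo + 1L <= N - phi) (plo + 1L):(N - phi) else integer(0)
  )
  out
}

# Vectorized median of nine equal-length vectors (19-comparator network).
med9 <- function(p) {
  stopifnot(length(p) == 9L)
  xch <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  p[[5]]
}

# Separable running min (op = pmin) or max (op = pmax) over a k x k square,
# with out-of-frame values treated as `pad`.
run_window <- function(x, k, op, pad) {
  h <- (k - 1L) %/% 2L
  acc <- x
  for (d in seq_len(h)) {
    acc <- op(acc, shift_mat(x, d, 0L, pad), shift_mat(x, -d, 0L, pad))
  }
  out <- acc
  for (d in seq_len(h)) {
    out <- op(out, shift_mat(acc, 0L, d, pad), shift_mat(acc, 0L, -d, pad))
  }
  out
}

# Nearest-neighbour rotation index map. Positive angle rotates content by
# `deg` in the (row, col) plane about the image centre (the phantom's
# rotation sense); rotating by -deg undoes it. Returns an integer vector of
# source indices into the original M x N matrix, 0 = background.
rotation_index_map <- function(dims, deg) {
  M <- dims[1]; N <- dims[2]
  cr <- (M + 1) / 2; cc <- (N + 1) / 2
  th <- deg * pi / 180
  dr <- seq_len(M) - cr
  dc <- seq_len(N) - cc
  # src = centre + R(-deg) (p - centre)
  src_r <- round(cr + outer(cos(th) * dr, sin(th) * dc, `+`))
  src_c <- round(cc + outer(-sin(th) * dr, cos(th) * dc, `+`))
  ok <- src_r >= 1 & src_r <= M & src_c >= 1 & src_c <= N
  idx <- integer(M * N)
  idx[ok] <- (as.integer(src_c[ok]) - 1L) * M + as.integer(src_r[ok])
  idx
}

apply_index_map <- function(x, idx, bg = 0) {
  out <- rep(bg, length(idx))
  hit <- idx > 0L
  out[hit] <- x[idx[hit]]
  matrix(out, nrow(x), ncol(x))
}

#' Rotate an image about its centre (nearest neighbour)
#'
#' Positive angles rotate the image content in the same sense as the phantom
#' generator's `rotation_deg`; rotating by the negative angle undoes it.
#' Out-of-frame pixels are filled with `bg`.
#'
#' @param x numeric matrix.
#' @param deg rotation angle in degrees.
#' @param bg fill value for pixels whose source falls outside the frame.
#' @return a matrix with the dimensions of `x`.
#' @export
rotate_image <- function(x, deg, bg = 0) {
  stopifnot(is.matrix(x))
  if (deg %% 360 == 0) return(x)
  apply_index_map(x, rotation_index_map(dim(x), deg), bg)
}

#' Map points through the same rotation as [rotate_image()]
#'
#' @param pts matrix or data.frame with columns `row`, `col` (or a 2-column
#'   matrix), positions in the unrotated frame.
#' @param deg rotation applied to the image content.
#' @param dims image dimensions `c(rows, cols)`.
#' @return a data.frame with columns `row`, `col` (real-valued).
#' @export
rotate_points <- function(pts, deg, dims) {
  p <- as.matrix(as.data.frame(pts)[, c("row", "col")])
  cr <- (dims[1] + 1) / 2; cc <- (dims[2] + 1) / 2
  th <- deg * pi / 180
  dr <- p[, 1] - cr; dc <- p[, 2] - cc
  data.frame(
    row = cr + cos(th) * dr - sin(th) * dc,
    col = cc + sin(th) * dr + cos(th) * dc
  )
}

# Round doubles to the nearest IEEE float32 value (what lands on disk for
# ENVI data type 4), so cubes emitted by the phantom round-trip bit-exactly.
snap_float32 <- function(x) {
  v <- readBin(writeBin(as.double(x), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
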