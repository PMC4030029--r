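# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition (loops, exhaustive scans), sharing no code
# with the package implementation.

# median filter: sort-and-pick-middle over the window, interior pixels only
oracle_median_interior <- function(img, k) {
  h <- (k - 1) %/% 2
  M <- nrow(img); N <- ncol(img)
  out <- matrix(NA_real_, M, N)
  for (r in (h + 1):(M - h)) {
    for (c in (h + 1):(N - h)) {
      v <- sort(as.vector(img[(r - h):(r + h), (c - h):(c + h)]))
      out[r, c] <- v[(k * k + 1) / 2]
    }
  }
  out
}

# illumination removal: the literal padless double sum with the even-mask
# anchoring (offsets (1:s) - floor((s+1)/2)), over the region where the
# window fits
oracle_illum_valid <- function(img, s) {
  off <- seq_len(s) - floor((s + 1) / 2)
  M <- nrow(img); N <- ncol(img)
  out <- matrix(NA_real_, M, N)
  for (r in seq_len(M)) {
    for (c in seq_len(N)) {
      rr <- r + off; cc <- c + off
      if (rr[1] >= 1 && rr[s] <= M && cc[1] >= 1 && cc[s] <= N) {
        acc <- 0
        for (i in rr) for (j in cc) acc <- acc + img[i, j]
        out[r, c] <- img[r, c] - acc / (s * s)
      }
    }
  }
  out
}

# Otsu: exhaustive search over all histogram cut points, class statistics
# recomputed from the binned values each time
oracle_otsu <- function(img, nbins = 256L) {
  mn <- min(img); mx <- max(img)
  y <- (as.vector(img) - mn) / (mx - mn)
  bin <- pmin(nbins, floor(y * nbins) + 1L)
  centres <- (bin - 0.5) / nbins
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(nbins - 1L)) {
    lo <- centres[bin <= t]; hi <- centres[bin > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(centres)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-15) { best <- sb; best_t <- t }
  }
  mn + (mx - mn) * best_t / nbins
}

# morphology: per-pixel window min/max, outside-the-frame = background
oracle_window <- function(mask, k, fun) {
  h <- (k - 1) %/% 2
  M <- nrow(mask); N <- ncol(mask)
  out <- matrix(0L, M, N)
  for (r in seq_len(M)) {
    for (c in seq_len(N)) {
      rr <- max(1, r - h):min(M, r + h)
      cc <- max(1, c - h):min(N, c + h)
      w <- mask[rr, cc]
      full <- length(rr) == k && length(cc) == k
      out[r, c] <- if (identical(fun, "min")) {
        if (full) min(w) else 0L           # window leaves the frame: bg 0
      } else {
        max(w)
      }
    }
  }
  out
}
oracle_opening <- function(mask, k) {
  oracle_window(oracle_window(mask, k, "min"), k, "max")
}

# centroid: the literal double sum
oracle_centroid <- function(w) {
  num_m <- 0; num_n <- 0; den <- 0
  for (r in seq_len(nrow(w))) {
    for (c in seq_len(ncol(w))) {
      num_m <- num_m + w[r, c] * r
      num_n <- num_n + w[r, c] * c
      den <- den + w[r, c]
    }
  }
  c(num_m / den, num_n / den)
}

# criterion J over a displacement grid, independently coded scorer
oracle_J <- function(det, tmp, dm, dn) {
  s <- 0
  for (i in seq_len(nrow(det))) {
    s <- s + (det$row[i] - (tmp$row[i] + dm))^2 +
      (det$col[i] - (tmp$col[i] + dn))^2
  }
  s
}
oracle_grid_min <- function(det, tmp, range_px) {
  best <- Inf; arg <- c(NA, NA)
  for (dm in -range_px:range_px) {
    for (dn in -range_px:range_px) {
      j <- oracle_J(det, tmp, dm, dn)
      better <- j < best - 1e-12
      tie <- abs(j - best) <= 1e-12 &&
        (abs(dm) + abs(dn) < abs(arg[1]) + abs(arg[2]))
      if (better || tie) { best <- j; arg <- c(dm, dn) }
    }
  }
  list(J = best, displacement = arg)
}

# BIL byte-stream decode by explicit index arithmetic
oracle_decode_bil <- function(v, M, N, L) {
  out <- array(NA_real_, c(M, N, L))
  for (m in seq_len(M)) for (k in seq_len(L)) for (n in seq_len(N)) {
    out[m, n, k] <- v[((m - 1) * L + (k - 1)) * N + n]
  }
  out
}

# nearest-neighbour downscale by index arithmetic
oracle_downscale <- function(img, factor) {
  M <- nrow(img); N <- ncol(img)
  Mo <- max(1, round(M * factor)); No <- max(1, round(N * factor))
  out <- matrix(NA_real_, Mo, No)
  for (i in seq_len(Mo)) for (j in seq_len(No)) {
    out[i, j] <- img[min(M, max(1, ceiling((i - 0.5) * M / Mo))),
                     min(N, max(1, ceiling((j - 0.5) * N / No)))]
  }
  out
}

# contour: per-column linear scan
oracle_contour <- function(mask) {
  out <- rep(NA_integer_, ncol(mask))
  for (c in seq_len(ncol(mask))) {
    for (r in seq_len(nrow(mask))) {
      if (mask[r, c] > 0) { out[c] <- r; break }
    }
  }
  out
}

# local minima of a curve with the prominence rule, independently coded:
# candidates are strictly below both neighbours (ends / NA count as +Inf),
# a side with no strictly lower point before the support breaks is an
# unbounded ridge, then greedy deepest-first thinning by separation
oracle_tips <- function(y, min_sep, min_prom) {
  n <- length(y)
  at <- function(i) if (i < 1 || i > n || is.na(y[i])) Inf else y[i]
  cand <- which(!is.na(y) &
                  vapply(seq_len(n), function(k) {
                    !is.na(y[k]) && y[k] < at(k - 1) && y[k] < at(k + 1)
                  }, logical(1)))
  prom <- vapply(cand, function(k) {
    side <- function(step) {
      ridge <- -Inf; i <- k + step
      while (i >= 1 && i <= n && !is.na(y[i])) {
        if (y[i] < y[k]) return(ridge - y[k])
        ridge <- max(ridge, y[i]); i <- i + step
      }
      Inf
    }
    max(min(side(-1L), side(1L)), 0)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  ord <- keep[order(y[keep], keep)]
  sel <- integer(0)
  for (k in ord) if (all(abs(k - sel) >= min_sep)) sel <- c(sel, k)
  sort(head(sel[order(y[sel], sel)], 5))
}
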