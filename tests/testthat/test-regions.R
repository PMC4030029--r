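# 12-area finger partition, per-area statistics, profiles, trends

# axis-aligned rectangular synthetic finger in an otherwise empty frame
rect_finger <- function(rows = 80L, cols = 60L, tip_row = 10, tip_col = 30,
                        len = 48, wid = 12) {
  mask <- matrix(0L, rows, cols)
  half <- wid / 2
  mask[tip_row:(tip_row + len + 4),
       (tip_col - half):(tip_col + half - 1)] <- 1L
  lm <- data.frame(point = paste0("V", 1:5),
                   row = c(tip_row, NA, NA, NA, NA),
                   col = c(tip_col - 0.5, NA, NA, NA, NA),
                   visible = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  tp <- hand_template(
    data.frame(point = c(paste0("V", 1:5), "V6"),
               row = c(tip_row, 1, 1, 1, 1, rows - 5),
               col = c(tip_col, 1, 3, 5, 7, tip_col)),
    finger_lengths = rep(len, 5), finger_widths = rep(wid, 5),
    frame = c(rows, cols))
  list(mask = mask, landmarks = lm, template = tp)
}

test_that("a finger splits into 12 areas, 6 per side, a true partition", {
  rf <- rect_finger()
  p <- partition_finger(rf$mask, rf$landmarks, rf$template, 1)
  expect_s3_class(p, "area_partition")
  expect_equal(p$labels, c(paste0("A", 1:6), paste0("B", 1:6)))
  expect_equal(sum(p$n_pixels > 0), 12L)

  # mirrored A/B areas of a symmetric even-width rectangle are equal
  expect_equal(p$n_pixels[1:6], p$n_pixels[7:12])

  # exhaustive disjoint-cover check against the delimited region
  lm <- p$label_matrix
  region_rows <- p$segment_bounds[1]:(p$segment_bounds[7] - 1)
  n_in_region <- 0L
  for (r in seq_len(nrow(rf$mask))) {
    for (c in seq_len(ncol(rf$mask))) {
      lab <- lm[r, c]
      if (r %in% region_rows && rf$mask[r, c] > 0 &&
          abs(c - 30 + 0.5) <= 12 / 2 + 1) {
        n_in_region <- n_in_region + 1L
        expect_gte(lab, 1L)             # covered
      }
      if (lab > 0L) {
        expect_true(r %in% region_rows && rf$mask[r, c] > 0L)
      }
    }
  }
  expect_equal(sum(p$n_pixels), n_in_region)

  # invisible finger: skipped with a warning
  expect_warning(p2 <- partition_finger(rf$mask, rf$landmarks,
                                        rf$template, 2), "not visible")
  expect_null(p2)
})

test_that("area statistics match a two-pass loop oracle", {
  rf <- rect_finger()
  p <- partition_finger(rf$mask, rf$landmarks, rf$template, 1)

  cmap <- matrix(0.37, nrow(rf$mask), ncol(rf$mask))
  st <- area_stats(cmap, p)
  expect_equal(st$mean, rep(0.37, 12))
  expect_equal(st$sd, rep(0, 12))
  expect_equal(st$area, p$labels)

  set.seed(141)
  rmap <- matrix(runif(nrow(rf$mask) * ncol(rf$mask)), nrow(rf$mask))
  st2 <- area_stats(rmap, p)
  for (l in seq_len(12)) {
    px <- numeric(0)
    for (r in seq_len(nrow(rmap))) {
      for (c in seq_len(ncol(rmap))) {
        if (p$label_matrix[r, c] == l) px <- c(px, rmap[r, c])
      }
    }
    mu <- sum(px) / length(px)
    s2 <- sum((px - mu)^2) / length(px)
    expect_equal(st2$mean[l], mu)
    expect_equal(st2$sd[l], sqrt(s2))
    expect_equal(st2$n[l], length(px))
  }

  # equivariance: mean is affine, SD is scale-only
  st3 <- area_stats(2 * rmap + 1, p)
  expect_equal(st3$mean, 2 * st2$mean + 1)
  expect_equal(st3$sd, 2 * st2$sd)
})

test_that("mirror reflection across the finger axis swaps A and B exactly", {
  rf <- rect_finger()
  p <- partition_finger(rf$mask, rf$landmarks, rf$template, 1)
  set.seed(151)
  rmap <- matrix(runif(nrow(rf$mask) * ncol(rf$mask)), nrow(rf$mask))
  st <- area_stats(rmap, p)

  # reflect mask and map about the axis column interval [24, 35]
  refl_cols <- function(c) 24 + 35 - c
  mask_r <- rf$mask * 0L
  map_r <- rmap
  for (c in 24:35) {
    mask_r[, refl_cols(c)] <- rf$mask[, c]
    map_r[, refl_cols(c)] <- rmap[, c]
  }
  lm_r <- rf$landmarks
  lm_r$col[1] <- refl_cols(rf$landmarks$col[1])
  tp_r <- rf$template
  tp_r$points$col[1] <- refl_cols(tp_r$points$col[1])
  p_r <- partition_finger(mask_r, lm_r, tp_r, 1)
  st_r <- area_stats(map_r, p_r)
  expect_equal(st_r$mean[1:6], st$mean[7:12])
  expect_equal(st_r$mean[7:12], st$mean[1:6])
  expect_equal(st_r$sd[1:6], st$sd[7:12])
})

test_that("spectral profiles are width-means per position and band", {
  rf <- rect_finger(rows = 40L, cols = 30L, tip_row = 5, tip_col = 15,
                    len = 24, wid = 8)
  p <- partition_finger(rf$mask, rf$landmarks, rf$template, 1)
  wl <- seq(450, 600, by = 50)
  # spatially constant cube: flat profile equal to the constant per band
  v <- array(0, c(40, 30, 4))
  for (k in 1:4) v[, , k] <- k / 10
  cube <- spectral_cube(v, wl)
  sp <- spectral_profile(cube, p, 450, 600)
  for (k in 1:4) expect_true(all(sp$profile[, k] == k / 10))

  # random cube vs per-position loop oracle
  set.seed(161)
  v2 <- array(runif(40 * 30 * 4), c(40, 30, 4))
  cube2 <- spectral_cube(v2, wl)
  sp2 <- spectral_profile(cube2, p, 450, 600)
  for (i in seq_along(sp2$positions)) {
    r <- sp2$positions[i]
    cc <- which(p$label_matrix[r, ] > 0)
    for (k in 1:4) {
      expect_equal(sp2$profile[i, k], mean(v2[r, cc, k]))
    }
  }
  expect_equal(sp2$band_mean, rowMeans(sp2$profile))

  # melanin ramp along the finger: monotone band-mean curve
  v3 <- array(0, c(40, 30, 4))
  for (k in 1:4) v3[, , k] <- matrix(rep(seq(0.2, 0.8, length.out = 40),
                                         30), 40, 30)
  sp3 <- spectral_profile(spectral_cube(v3, wl), p, 450, 600)
  expect_true(all(diff(sp3$band_mean) > 0))
})

test_that("along-finger trend reports the wrist/tip ratio", {
  rf <- rect_finger()
  p <- partition_finger(rf$mask, rf$landmarks, rf$template, 1)
  const <- matrix(0.5, nrow(rf$mask), ncol(rf$mask))
  tr <- along_finger_trend(const, list(p))
  expect_equal(unname(tr$ratios), 1)

  # curve agrees with per-segment area means on a uniform-width finger
  set.seed(171)
  rmap <- matrix(runif(nrow(rf$mask) * ncol(rf$mask)), nrow(rf$mask))
  tr2 <- along_finger_trend(rmap, list(p))
  st <- area_stats(rmap, p)
  curve <- tr2$curves$V1
  for (seg in 1:6) {
    rows_seg <- p$segment_bounds[seg]:(p$segment_bounds[seg + 1] - 1)
    seg_mean <- mean(curve$mean[curve$position %in% rows_seg])
    # A and B pooled, equal widths per row: pixel mean == row-mean mean
    pooled <- (st$mean[seg] * st$n[seg] + st$mean[seg + 6] *
                 st$n[seg + 6]) / (st$n[seg] + st$n[seg + 6])
    expect_equal(seg_mean, pooled)
  }
})

test_that("programmed wrist-ward gradient is recovered within 2%", {
  spec <- phantom_spec(rotation_deg = 0, noise_sd = 0, impulse_fraction = 0,
                       illum_gradient = 0, axial_gain = 0.15,
                       background_reflectance = 0)
  pg <- generate_phantom_cube(spec)
  pp <- preprocess_cube(pg$cube)
  tmpl <- hand_template_from_spec(spec)
  mask <- (pg$truth$labels > 0) + 0L
  parts <- lapply(1:5, function(i) {
    partition_finger(mask, pg$truth$landmarks, tmpl, i)
  })
  mel <- aggregate_band(pp$LP, 450, 600)
  tr <- along_finger_trend(mel, parts)
  expect_true(all(abs(tr$ratios / 1.15 - 1) < 0.02))
})
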