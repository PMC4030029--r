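# Criterion J, exhaustive displacement search, per-vertex refinement,
# affine correction, template I/O

toy_template <- function() {
  pts <- data.frame(
    point = c(paste0("V", 1:5), "V6"),
    row = c(20, 12, 10, 13, 18, 60),
    col = c(20, 35, 50, 65, 80, 50),
    stringsAsFactors = FALSE
  )
  hand_template(pts, finger_lengths = c(30, 42, 46, 42, 34),
                finger_widths = c(10, 9, 9, 8, 8), frame = c(100, 100))
}
as_points <- function(df) {
  df$visible <- TRUE
  df
}

test_that("criterion J is the sum of squared coordinate residuals", {
  tp <- toy_template()
  pts <- as_points(tp$points[tp$points$point != "V6", ])
  expect_equal(criterion_J(pts, tp), 0)

  one <- data.frame(point = "V1", row = 0 + 23, col = 0 + 24,
                    visible = TRUE)
  tp1 <- hand_template(data.frame(point = c("V1", "V2"), row = c(20, 1),
                                  col = c(20, 2)),
                       c(1, 1), c(1, 1), c(100, 100))
  expect_equal(criterion_J(one, tp1), 3^2 + 4^2)

  # shift identity: J(p + (a,b)) - J(p) == sum(2a*dm + a^2) + sum(2b*dn + b^2)
  set.seed(91)
  pts2 <- pts
  pts2$row <- pts2$row + rnorm(5); pts2$col <- pts2$col + rnorm(5)
  a <- 3; b <- -2
  shifted <- pts2; shifted$row <- shifted$row + a
  shifted$col <- shifted$col + b
  dm <- pts2$row - tp$points$row[match(pts2$point, tp$points$point)]
  dn <- pts2$col - tp$points$col[match(pts2$point, tp$points$point)]
  expect_equal(criterion_J(shifted, tp) - criterion_J(pts2, tp),
               sum(2 * a * dm + a^2) + sum(2 * b * dn + b^2))
  expect_error(criterion_J(data.frame(point = "V9", row = 1, col = 1,
                                      visible = TRUE), tp),
               "counterpart")
})

test_that("global match is an exact exhaustive minimizer", {
  tp <- toy_template()
  pts <- as_points(tp$points[tp$points$point != "V6", ])
  m0 <- global_match(pts, tp, 20L)
  expect_equal(unname(m0$displacement), c(0L, 0L))
  expect_equal(m0$J_min, 0)

  # the printed example: landmarks constructed as template shifted by
  # (-18, -3) must be recovered exactly
  sh <- pts; sh$row <- sh$row - 18; sh$col <- sh$col - 3
  m <- global_match(sh, tp, 100L)
  expect_equal(unname(m$displacement), c(-18L, -3L))
  expect_equal(m$J_min, 0)
  expect_equal(min(m$J_surface), m$J_min)

  # global minimum over the sampled surface, vs an independent scorer
  set.seed(101)
  for (i in 1:5) {
    noisy <- pts
    noisy$row <- noisy$row + rnorm(5, sample(-8:8, 1), 2)
    noisy$col <- noisy$col + rnorm(5, sample(-8:8, 1), 2)
    gm <- global_match(noisy, tp, 12L)
    det <- noisy[order(noisy$point), ]
    tmp <- tp$points[tp$points$point != "V6", ]
    tmp <- tmp[order(tmp$point), ]
    ref <- oracle_grid_min(det, tmp, 12L)
    expect_equal(gm$J_min, ref$J)
    expect_equal(unname(gm$displacement), ref$displacement)
    # spot-check 1000 random surface entries are never below the minimum
    d <- as.integer(rownames(gm$J_surface))
    for (j in 1:1000) {
      dm <- sample(d, 1); dn <- sample(d, 1)
      expect_gte(gm$J_surface[as.character(dm), as.character(dn)],
                 gm$J_min)
    }
  }
})

test_that("per-vertex refinement recovers single-vertex residuals and never hurts", {
  tp <- toy_template()
  pts <- as_points(tp$points[tp$points$point != "V6", ])
  g <- global_match(pts, tp, 10L)
  r0 <- refine_vertices(pts, tp, g, 10L)
  expect_true(all(r0$refinements$dm == 0L))
  expect_true(all(r0$refinements$dn == 0L))
  expect_equal(r0$J_refined, 0)

  pert <- pts
  i3 <- pert$point == "V3"
  pert$row[i3] <- pert$row[i3] + 4
  pert$col[i3] <- pert$col[i3] - 2
  g2 <- global_match(pert, tp, 10L)
  # global shift absorbs part of the perturbation; vertex residuals must
  # sum back to the constructed offset
  r2 <- refine_vertices(pert, tp, g2, 25L)
  v3 <- r2$refinements[r2$refinements$point == "V3", ]
  expect_equal(v3$dm + g2$displacement[["dm"]], 4)
  expect_equal(v3$dn + g2$displacement[["dn"]], -2)
  others <- r2$refinements[r2$refinements$point != "V3", ]
  expect_true(all(others$dm + g2$displacement[["dm"]] == 0L))
  expect_true(all(others$dn + g2$displacement[["dn"]] == 0L))
  expect_lte(r2$J_refined, g2$J_min)

  set.seed(111)
  for (i in 1:10) {
    noisy <- pts
    noisy$row <- noisy$row + rnorm(5, 0, 4)
    noisy$col <- noisy$col + rnorm(5, 0, 4)
    gg <- global_match(noisy, tp, 15L)
    rr <- refine_vertices(noisy, tp, gg, 15L)
    expect_lte(rr$J_refined, gg$J_min + 1e-9)
  }
})

test_that("affine correction is the identity at zero and composes translations", {
  pg <- clean_phantom()
  lp <- normalize_cube(pg$cube)
  null_match <- structure(list(displacement = c(dm = 0L, dn = 0L)),
                          class = "match_result")
  out <- apply_correction(lp, 0, null_match)
  # identity on the measurable region; the reference rows are blanked
  cr <- lp$calib_rows
  expect_equal(out$values[-(1:cr), , ], lp$values[-(1:cr), , ])
  expect_true(all(out$values[1:cr, , ] == 0))

  x <- matrix(1:20, 4, 5)
  t1 <- translate_image(x, 1, 2)
  t2 <- translate_image(t1, 2, -1)
  t12 <- translate_image(x, 3, 1)
  # pixels in frame at every intermediate step compose additively
  expect_equal(t2[4, 2:4], t12[4, 2:4])
  expect_equal(t2[4, 4], t12[4, 4])
})

test_that("correcting a rotated phantom recovers the upright silhouette", {
  th <- 110
  pg_rot <- generate_phantom_cube(small_spec(rotation_deg = th))
  pg_up <- generate_phantom_cube(small_spec(rotation_deg = 0))
  pp <- preprocess_cube(pg_rot$cube)
  s <- sum_bands(pp$LC); s[1:20, ] <- 0
  alpha <- estimate_rotation(s, 2)$alpha_star
  expect_lte(abs(alpha - th), 2)
  corr <- apply_correction(pp$LP, alpha, NULL)
  sm <- sum_bands(corr)
  mask <- binarize(sm, otsu_threshold(sm))
  truth_mask <- (pg_up$truth$labels > 0L)
  jac <- sum(mask & truth_mask) / sum(mask | truth_mask)
  expect_gte(jac, 0.95)
})

test_that("templates survive a YAML round trip and validate their frame", {
  tp <- default_hand_template(899, 1312)
  expect_equal(nrow(tp$points), 6L)
  expect_true(all(tp$points$row >= 1 & tp$points$row <= 899))
  expect_true(all(tp$points$col >= 1 & tp$points$col <= 1312))
  path <- file.path(tempdir(), "template.yaml")
  write_hand_template(tp, path)
  back <- read_hand_template(path)
  expect_equal(back$points, tp$points)
  expect_equal(back$finger_lengths, tp$finger_lengths)
  expect_equal(back$frame, tp$frame)

  bad <- tp$points; bad$col[2] <- 5000
  expect_error(hand_template(bad, tp$finger_lengths, tp$finger_widths,
                             tp$frame), "inside")
})
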