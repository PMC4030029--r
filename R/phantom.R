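# Synthetic hand phantom: a hand-shaped object (palm ellipse + finger
# capsules) at a known rotation, with per-area melanin/haemoglobin
# concentrations modulating an analytic skin reflectance model, a smooth
# multiplicative illumination field, leading white-reference rows, and
# additive/impulse noise. Every quantity the pipeline estimates is known
# exactly, so the phantom is the ground-truth oracle for the whole chain.

#' Phantom specification
#'
#' Defaults describe a hand-scale object in a 128 x 196 frame with 200
#' VNIR bands, inclined at 80 degrees, moderate illumination non-uniformity
#' (stronger across columns, as for a push-broom line illuminator), mild
#' Gaussian sensor noise and a small impulse-pixel fraction.
#'
#' @param rows,cols frame size in pixels.
#' @param wl_start,wl_step,wl_stop wavelength grid in nm (bands are
#'   `seq(wl_start, wl_stop, by = wl_step)`).
#' @param finger_count number of fingers, 3..5.
#' @param finger_lengths,finger_widths per-finger capsule lengths/widths, px.
#' @param tip_col_offsets fingertip column offsets from the hand axis, px.
#' @param palm_axes ellipse semi-axes `c(rows, cols)`, px.
#' @param forearm_length,forearm_width wrist/forearm stub extending from the
#'   palm towards the image edge, px (real dorsal-hand frames always include
#'   it; it elongates the silhouette along the hand axis, which the
#'   rotation criterion relies on).
#' @param rotation_deg hand inclination in `[0, 180)` degrees.
#' @param melanin_map,haemoglobin_map named concentrations in `[0, 1]` for
#'   areas `V1..V5` and `palm`.
#' @param illum_gradient illumination amplitude across columns in `[0, 0.5)`;
#'   the along-row amplitude is one fifth of it.
#' @param noise_sd additive Gaussian noise SD (reflectance units).
#' @param impulse_fraction fraction of cube elements replaced by 0/1
#'   impulses, in `[0, 0.05]`.
#' @param calib_rows leading 100%-emission reference rows.
#' @param background_reflectance flat background level (default 0.05 keeps
#'   Otsu separation of hand and background trivial).
#' @param axial_gain wrist-ward multiplicative intensity ramp along each
#'   finger: pixel intensity is scaled by `1 + axial_gain * t` with `t = 0`
#'   at the fingertip and `t = 1` at the finger base (palm pixels get the
#'   full gain).
#' @param seed RNG seed for the noise realization.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 128L, cols = 196L,
                         wl_start = 397, wl_step = 3.18, wl_stop = 1030,
                         finger_count = 5L,
                         finger_lengths = c(32, 44, 48, 44, 36),
                         finger_widths = c(11, 10, 10, 9, 9),
                         tip_col_offsets = c(-34, -17, 0, 16, 31),
                         palm_axes = c(20, 24),
                         forearm_length = 20,
                         forearm_width = 34,
                         rotation_deg = 80,
                         melanin_map = c(V1 = 0.25, V2 = 0.30, V3 = 0.35,
                                         V4 = 0.30, V5 = 0.25, palm = 0.28),
                         haemoglobin_map = c(V1 = 0.30, V2 = 0.28, V3 = 0.30,
                                             V4 = 0.32, V5 = 0.30,
                                             palm = 0.35),
                         illum_gradient = 0.15,
                         noise_sd = 0.01,
                         impulse_fraction = 0.002,
                         calib_rows = 4L,
                         background_reflectance = 0.05,
                         axial_gain = 0,
                         seed = 1L) {
  fc <- as.integer(finger_count)
  stopifnot(rows >= 16, cols >= 16, wl_step > 0, wl_stop > wl_start,
            fc >= 3L, fc <= 5L)
  finger_lengths <- finger_lengths[seq_len(fc)]
  finger_widths <- finger_widths[seq_len(fc)]
  tip_col_offsets <- tip_col_offsets[seq_len(fc)]
  if (anyNA(finger_lengths) || anyNA(finger_widths) ||
      anyNA(tip_col_offsets)) {
    stop("finger_lengths, finger_widths and tip_col_offsets must supply ",
         fc, " values")
  }
  if (any(finger_widths <= 0) || any(finger_widths > 200)) {
    stop("finger widths must lie in (0, 200] px")
  }
  if (rotation_deg < 0 || rotation_deg >= 180) {
    stop("rotation_deg must lie in [0, 180)")
  }
  if (illum_gradient < 0 || illum_gradient >= 0.5) {
    stop("illum_gradient must lie in [0, 0.5)")
  }
  if (impulse_fraction < 0 || impulse_fraction > 0.05) {
    stop("impulse_fraction must lie in [0, 0.05]")
  }
  stopifnot(noise_sd >= 0, calib_rows >= 0, axial_gain >= 0)
  areas <- c(paste0("V", seq_len(fc)), "palm")
  for (nm in list(melanin = melanin_map, haemoglobin = haemoglobin_map)) {
    if (!all(areas %in% names(nm))) {
      stop("concentration maps must name every area: ",
           paste(areas, collapse = ", "))
    }
    if (any(nm < 0 | nm > 1)) stop("concentrations must lie in [0, 1]")
  }
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    wl_start = wl_start, wl_step = wl_step, wl_stop = wl_stop,
    finger_count = fc, finger_lengths = finger_lengths,
    finger_widths = finger_widths, tip_col_offsets = tip_col_offsets,
    palm_axes = palm_axes, forearm_length = forearm_length,
    forearm_width = forearm_width, rotation_deg = rotation_deg,
    melanin_map = melanin_map[areas], haemoglobin_map = haemoglobin_map[areas],
    illum_gradient = illum_gradient, noise_sd = noise_sd,
    impulse_fraction = impulse_fraction, calib_rows = as.integer(calib_rows),
    background_reflectance = background_reflectance,
    axial_gain = axial_gain, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Analytic skin reflectance of the phantom
#'
#' Baseline skin reflectance (low in the blue, rising towards the NIR)
#' minus a melanin-weighted broad Gaussian absorption centred at 525 nm
#' (covering 450-600 nm) and haemoglobin-weighted absorption bands centred
#' near 420 (Soret), 542 and 577 nm. Clipped to `[0, 1]`; strictly
#' decreasing in each concentration at its band centre.
#'
#' @param melanin,haemoglobin concentrations in `[0, 1]`.
#' @param lambda_nm wavelength(s) in nm.
#' @return reflectance value(s) in `[0, 1]`.
#' @export
skin_reflectance <- function(melanin, haemoglobin, lambda_nm) {
  if (any(melanin < 0 | melanin > 1) ||
      any(haemoglobin < 0 | haemoglobin > 1)) {
    stop("concentrations must lie in [0, 1]")
  }
  baseline <- 0.30 + 0.45 / (1 + exp(-(lambda_nm - 600) / 60))
  mel_abs <- 0.30 * exp(-(lambda_nm - 525)^2 / (2 * 65^2))
  hb_abs <- 0.22 * exp(-(lambda_nm - 420)^2 / (2 * 20^2)) +
    0.10 * exp(-(lambda_nm - 542)^2 / (2 * 16^2)) +
    0.08 * exp(-(lambda_nm - 577)^2 / (2 * 12^2))
  pmin(pmax(baseline - melanin * mel_abs - haemoglobin * hb_abs, 0), 1)
}

# Upright-frame geometry shared by mask generation and ground truth.
phantom_geometry <- function(spec) {
  M <- spec$rows; N <- spec$cols
  pa <- spec$palm_axes[1]; pb <- spec$palm_axes[2]
  cc0 <- (N + 1) / 2
  len <- spec$finger_lengths; wid <- spec$finger_widths
  # vertical placement: centre the full hand extent in the frame
  top_off <- -(pa - 8) - max(len + wid / 2)   # relative to palm centre row
  bot_off <- pa + spec$forearm_length
  pr <- (M + 1) / 2 - (top_off + bot_off) / 2
  base_row <- pr - pa + 8
  tip_cols <- cc0 + spec$tip_col_offsets
  tip_rows <- base_row - len                 # capsule end centre
  list(palm_centre = c(row = pr, col = cc0), pa = pa, pb = pb,
       base_row = base_row, tip_cols = tip_cols, tip_rows = tip_rows,
       forearm_rows = c(pr, pr + pa + spec$forearm_length),
       forearm_halfwidth = spec$forearm_width / 2,
       tip_points = data.frame(row = tip_rows - wid / 2, col = tip_cols))
}

#' Generate the phantom hand mask and ground truth
#'
#' The upright hand (palm ellipse plus vertical finger capsules sized from
#' the spec's anthropometric lengths/widths) is rotated by `rotation_deg`
#' about the frame centre; each pixel is classified by mapping it back into
#' the upright frame analytically, so the mask is exact, deterministic and
#' independent of the noise seed.
#'
#' @param spec a [phantom_spec()].
#' @return `list(mask = 0/1 matrix, truth = list(...))` where truth carries
#'   the label matrix (1..finger_count fingers, finger_count+1 palm),
#'   fingertip and wrist landmarks in image coordinates, the rotation angle,
#'   per-area concentrations and the per-pixel along-finger coordinate `t`.
#' @export
generate_hand_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  M <- spec$rows; N <- spec$cols
  fc <- spec$finger_count
  th <- spec$rotation_deg * pi / 180
  cr <- (M + 1) / 2; cc <- (N + 1) / 2
  dr <- seq_len(M) - cr
  dc <- seq_len(N) - cc
  # upright-frame coordinates of every pixel: q = centre + R(-theta)(p - c)
  qr <- cr + outer(cos(th) * dr, sin(th) * dc, `+`)
  qc <- cc + outer(-sin(th) * dr, cos(th) * dc, `+`)

  lab <- matrix(0L, M, N)
  tmat <- matrix(NA_real_, M, N)
  pc <- g$palm_centre
  palm <- ((qr - pc["row"]) / g$pa)^2 + ((qc - pc["col"]) / g$pb)^2 <= 1
  palm <- palm | (qr >= g$forearm_rows[1] & qr <= g$forearm_rows[2] &
                    abs(qc - pc["col"]) <= g$forearm_halfwidth)
  lab[palm] <- fc + 1L
  tmat[palm] <- 1
  for (i in seq_len(fc)) {
    w2 <- spec$finger_widths[i] / 2
    ci <- g$tip_cols[i]
    shaft <- qr >= g$tip_rows[i] & qr <= g$base_row & abs(qc - ci) <= w2
    cap <- qr < g$tip_rows[i] &
      (qr - g$tip_rows[i])^2 + (qc - ci)^2 <= w2^2
    fin <- shaft | cap
    lab[fin] <- i
    # ramp coordinate: 0 at the fingertip point, 1 one finger length below
    # (saturating towards the base), i.e. over the span the along-finger
    # trend measures
    tmat[fin] <- pmin(pmax((qr[fin] - (g$tip_rows[i] - w2)) /
                             spec$finger_lengths[i], 0), 1)
  }
  mask <- (lab > 0L) + 0L

  # bounds checks: fingers must stay inside the frame and clear of the
  # reference rows
  tips_img <- rotate_points(g$tip_points, spec$rotation_deg, c(M, N))
  margin <- 1
  bad <- which(tips_img$row < spec$calib_rows + 1 + margin |
                 tips_img$row > M - margin |
                 tips_img$col < 1 + margin | tips_img$col > N - margin)
  if (length(bad) > 0L) {
    stop("phantom finger(s) exceed image bounds: ",
         paste0("V", bad, collapse = ", "))
  }
  if (any(mask[c(1L, M), ] > 0L) || any(mask[, c(1L, N)] > 0L) ||
      (spec$calib_rows > 0L && any(mask[seq_len(spec$calib_rows), ] > 0L))) {
    stop("phantom hand touches the frame border or the reference rows; ",
         "shrink the geometry or the rotation")
  }

  landmarks <- data.frame(
    point = c(paste0("V", seq_len(fc)), "V6"),
    row = c(tips_img$row,
            rotate_points(data.frame(row = pc["row"], col = pc["col"]),
                          spec$rotation_deg, c(M, N))$row),
    col = c(tips_img$col,
            rotate_points(data.frame(row = pc["row"], col = pc["col"]),
                          spec$rotation_deg, c(M, N))$col),
    visible = TRUE,
    stringsAsFactors = FALSE
  )
  areas <- c(paste0("V", seq_len(fc)), "palm")
  truth <- list(
    labels = lab,
    axial_t = tmat,
    landmarks = landmarks,
    rotation_deg = spec$rotation_deg,
    alignment_deg = spec$rotation_deg,
    area_concentrations = data.frame(
      area = areas,
      melanin = as.numeric(spec$melanin_map[areas]),
      haemoglobin = as.numeric(spec$haemoglobin_map[areas]),
      stringsAsFactors = FALSE
    ),
    geometry = g
  )
  list(mask = mask, truth = truth)
}

# Separable smooth illumination field, maximum 1 at the frame centre.
phantom_illumination <- function(spec) {
  xr <- seq(-1, 1, length.out = spec$rows)
  xc <- seq(-1, 1, length.out = spec$cols)
  a_c <- spec$illum_gradient
  a_r <- 0.2 * spec$illum_gradient
  outer(1 - a_r * xr^2, 1 - a_c * xc^2)
}

#' Generate a phantom hyperspectral cube with ground truth
#'
#' Per-pixel spectrum = [skin_reflectance()] of the pixel's area
#' concentrations, times the wrist-ward axial gain, times the smooth
#' illumination field, plus Gaussian noise and impulse pixels; the leading
#' `calib_rows` rows carry the 100%-emission reference (illumination times
#' unit reflectance). Values are snapped to float32 so emitted ENVI files
#' round-trip bit-exactly. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return `list(cube = spectral_cube, truth = list(...))`.
#' @export
generate_phantom_cube <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  hm <- generate_hand_mask(spec)
  truth <- hm$truth
  wl <- seq(spec$wl_start, spec$wl_stop, by = spec$wl_step)
  M <- spec$rows; N <- spec$cols; L <- length(wl)
  fc <- spec$finger_count
  areas <- c(paste0("V", seq_len(fc)), "palm")
  # per-area spectra, rows = areas (+ background first)
  spectra <- rbind(
    rep(spec$background_reflectance, L),
    t(vapply(areas, function(a) {
      skin_reflectance(spec$melanin_map[[a]], spec$haemoglobin_map[[a]], wl)
    }, numeric(L)))
  )
  gain <- matrix(1, M, N)
  inmask <- !is.na(truth$axial_t)
  gain[inmask] <- 1 + spec$axial_gain * truth$axial_t[inmask]
  illum <- phantom_illumination(spec)
  labp1 <- truth$labels + 1L

  values <- array(0, dim = c(M, N, L))
  for (k in seq_len(L)) {
    band <- matrix(spectra[, k][labp1], M, N) * gain
    if (spec$calib_rows > 0L) band[seq_len(spec$calib_rows), ] <- 1
    values[, , k] <- band * illum
  }
  if (spec$noise_sd > 0 || spec$impulse_fraction > 0) {
    values <- with_seed(spec$seed, {
      if (spec$noise_sd > 0) {
        values <- values + array(stats::rnorm(M * N * L, sd = spec$noise_sd),
                                 dim = c(M, N, L))
      }
      n_imp <- round(spec$impulse_fraction * M * N * L)
      if (n_imp > 0) {
        at <- sample.int(M * N * L, n_imp)
        values[at] <- stats::rbinom(n_imp, 1L, 0.5)
      }
      values
    })
  }
  values <- snap_float32(values)
  list(cube = spectral_cube(values, wl, spec$calib_rows), truth = truth)
}

#' Write phantom fixtures: ENVI cube plus truth sidecar
#'
#' Emits `<basename>.dat`, `<basename>.hdr` and `<basename>.truth.json`
#' (landmarks, rotation angle, per-area concentrations) under `out_dir`.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param basename file basename, default `"phantom"`.
#' @param interleave ENVI interleave for the cube payload.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(spec, out_dir, basename = "phantom",
                          interleave = "bil") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pg <- generate_phantom_cube(spec)
  base <- file.path(out_dir, basename)
  write_envi_cube(pg$cube, base, interleave = interleave)
  truth_path <- paste0(base, ".truth.json")
  jsonlite::write_json(list(
    rotation_deg = pg$truth$rotation_deg,
    alignment_deg = pg$truth$alignment_deg,
    landmarks = pg$truth$landmarks,
    area_concentrations = pg$truth$area_concentrations
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(dat = paste0(base, ".dat"), hdr = paste0(base, ".hdr"),
              truth = truth_path))
}
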