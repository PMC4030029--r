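# Anthropometric template matching: the criterion J (sum of squared row and
# column residuals between detected landmarks and pattern points) is
# minimized by exhaustive integer displacement search over +/-100 px, then
# each finger vertex is refined independently; the measurable cube is
# corrected by the recovered rotation and global displacement.

#' Construct a hand template
#'
#' A pattern of fingertip points `V1..V5` (distinct columns, thumb to
#' little finger left to right) plus the wrist point `V6`, with the
#' anthropometric finger lengths/widths used to scale the region partition,
#' all expressed in a `frame` of given dimensions.
#'
#' @param points data.frame with columns `point` ("V1".."V6"), `row`, `col`.
#' @param finger_lengths,finger_widths per-finger sizes in frame px.
#' @param frame `c(rows, cols)` of the pattern frame.
#' @return an object of class `hand_template`.
#' @export
hand_template <- function(points, finger_lengths, finger_widths, frame) {
  stopifnot(is.data.frame(points),
            all(c("point", "row", "col") %in% names(points)))
  tips <- points[points$point %in% paste0("V", 1:5), ]
  if (anyDuplicated(tips$col)) {
    stop("template finger points must have distinct columns")
  }
  if (any(points$row < 1 | points$row > frame[1] |
          points$col < 1 | points$col > frame[2])) {
    stop("template points must lie inside the pattern frame")
  }
  structure(list(points = points[, c("point", "row", "col")],
                 finger_lengths = finger_lengths,
                 finger_widths = finger_widths,
                 frame = as.integer(frame)),
            class = "hand_template")
}

#' Default anthropometric hand template
#'
#' Landmark coordinates computed from standard human hand proportions
#' (middle finger about 0.475 of the hand length; finger length ratios
#' 0.66/0.92/1/0.94/0.76 of the middle finger; fingertips spread across the
#' palm breadth), scaled to the requested frame. Intended as an editable
#' starting point; a measured pattern can be loaded with
#' [read_hand_template()].
#'
#' @param rows,cols pattern frame dimensions.
#' @param hand_length hand length in px (default 75% of `rows`).
#' @param palm_width palm breadth in px (default 42% of `hand_length`).
#' @return a [hand_template()].
#' @export
default_hand_template <- function(rows, cols,
                                  hand_length = 0.75 * rows,
                                  palm_width = 0.42 * hand_length) {
  mid_len <- 0.475 * hand_length
  ratios <- c(0.66, 0.92, 1.00, 0.94, 0.76)
  lens <- ratios * mid_len
  widths <- c(0.26, 0.21, 0.21, 0.20, 0.18) * palm_width
  cc <- (cols + 1) / 2
  wrist_row <- (rows + 1) / 2 + hand_length / 2
  mid_tip_row <- wrist_row - hand_length
  tip_rows <- mid_tip_row + (mid_len - lens)
  tip_cols <- cc + c(-0.62, -0.30, 0, 0.28, 0.55) * palm_width
  pts <- data.frame(
    point = c(paste0("V", 1:5), "V6"),
    row = c(tip_rows, wrist_row - 0.18 * hand_length),
    col = c(tip_cols, cc),
    stringsAsFactors = FALSE
  )
  hand_template(pts, lens, widths, c(rows, cols))
}

#' Hand template matching a phantom specification
#'
#' The upright geometry of a [phantom_spec()] expressed as a template:
#' fingertip extrema, palm centre as V6, and the spec's finger sizes.
#'
#' @param spec a [phantom_spec()].
#' @return a [hand_template()].
#' @export
hand_template_from_spec <- function(spec) {
  g <- phantom_geometry(spec)
  fc <- spec$finger_count
  pts <- data.frame(
    point = c(paste0("V", seq_len(fc)), "V6"),
    row = c(g$tip_points$row, unname(g$palm_centre["row"])),
    col = c(g$tip_points$col, unname(g$palm_centre["col"])),
    stringsAsFactors = FALSE
  )
  hand_template(pts, spec$finger_lengths, spec$finger_widths,
                c(spec$rows, spec$cols))
}

#' Write / read a hand template as a YAML file
#'
#' @param template a [hand_template()].
#' @param path file path.
#' @return `read_hand_template` returns a [hand_template()];
#'   `write_hand_template` returns the path invisibly.
#' @export
write_hand_template <- function(template, path) {
  yaml::write_yaml(list(
    frame = as.integer(template$frame),
    finger_lengths = as.numeric(template$finger_lengths),
    finger_widths = as.numeric(template$finger_widths),
    points = lapply(seq_len(nrow(template$points)), function(i) {
      as.list(template$points[i, ])
    })
  ), path)
  invisible(path)
}

#' @rdname write_hand_template
#' @export
read_hand_template <- function(path) {
  y <- yaml::read_yaml(path)
  pts <- do.call(rbind, lapply(y$points, function(p) {
    data.frame(point = p$point, row = p$row, col = p$col,
               stringsAsFactors = FALSE)
  }))
  hand_template(pts, as.numeric(y$finger_lengths),
                as.numeric(y$finger_widths), as.integer(y$frame))
}

# visible detected points joined with their template counterparts
matched_points <- function(points, template, include = NULL) {
  pts <- as.data.frame(points)
  if (!"visible" %in% names(pts)) pts$visible <- TRUE
  pts <- pts[pts$visible & !is.na(pts$row), ]
  if (!is.null(include)) pts <- pts[pts$point %in% include, ]
  tp <- template$points
  common <- intersect(pts$point, tp$point)
  if (length(common) == 0L) {
    stop("no visible landmarks with a template counterpart")
  }
  merge(pts[, c("point", "row", "col")], tp, by = "point",
        suffixes = c("_v", "_w"))
}

#' Matching criterion J
#'
#' `J = sum_i (m_vi - m_wvi)^2 + sum_i (n_vi - n_wvi)^2` over visible
#' detected points that have a template counterpart (fingertips V1..V5 by
#' default; V6 participates when present in both sets).
#'
#' @param points a landmark set (data.frame `point`, `row`, `col`,
#'   `visible`).
#' @param template a [hand_template()].
#' @return the scalar criterion value.
#' @export
criterion_J <- function(points, template) {
  mp <- matched_points(points, template)
  sum((mp$row_v - mp$row_w)^2) + sum((mp$col_v - mp$col_w)^2)
}

#' Global template match by exhaustive displacement search
#'
#' Evaluates J for every integer template displacement `(dm, dn)` with
#' `|dm|, |dn| <= range_px` and returns the minimizer; ties break towards
#' the smallest `|dm| + |dn|`, then lexicographically. The full criterion
#' surface is retained for diagnostics.
#'
#' @param points detected landmark set.
#' @param template a [hand_template()].
#' @param range_px search half-range in px (default 100).
#' @return `list(displacement, J_min, J_surface, refinements = NULL)` of
#'   class `match_result`; `J_surface` has displacements as dimnames.
#' @export
global_match <- function(points, template, range_px = 100L) {
  stopifnot(range_px >= 0L)
  mp <- matched_points(points, template, include = paste0("V", 1:5))
  d <- seq.int(-range_px, range_px)
  # J is separable in (dm, dn): J(dm, dn) = Jm(dm) + Jn(dn)
  Jm <- vapply(d, function(dm) sum((mp$row_v - mp$row_w - dm)^2), numeric(1))
  Jn <- vapply(d, function(dn) sum((mp$col_v - mp$col_w - dn)^2), numeric(1))
  J <- outer(Jm, Jn, `+`)
  dimnames(J) <- list(dm = d, dn = d)
  jmin <- min(J)
  at <- which(J == jmin, arr.ind = TRUE)
  dm <- d[at[, 1]]; dn <- d[at[, 2]]
  pick <- order(abs(dm) + abs(dn), dm, dn)[1]
  structure(list(
    displacement = c(dm = dm[pick], dn = dn[pick]),
    J_min = jmin, J_surface = J, range_px = as.integer(range_px),
    refinements = NULL
  ), class = "match_result")
}

#' Per-vertex refinement of the global match
#'
#' After the global displacement, each visible finger vertex is adjusted
#' independently by an exhaustive search of its single-vertex criterion
#' within `+/- local_range_px`. Refinement can only decrease the total
#' criterion. Refinements place the per-finger regions; they do not warp
#' the image.
#'
#' @param points detected landmark set.
#' @param template a [hand_template()].
#' @param global a `match_result` from [global_match()].
#' @param local_range_px per-vertex search half-range (default 25).
#' @return the `match_result` with a `refinements` data.frame
#'   (`point`, `dm`, `dn`, `J_vertex`) and `J_refined` added.
#' @export
refine_vertices <- function(points, template, global, local_range_px = 25L) {
  mp <- matched_points(points, template, include = paste0("V", 1:5))
  d <- seq.int(-local_range_px, local_range_px)
  gdm <- global$displacement[["dm"]]; gdn <- global$displacement[["dn"]]
  ref <- do.call(rbind, lapply(seq_len(nrow(mp)), function(i) {
    am <- mp$row_v[i] - (mp$row_w[i] + gdm)
    an <- mp$col_v[i] - (mp$col_w[i] + gdn)
    Jv <- outer((am - d)^2, (an - d)^2, `+`)
    jmin <- min(Jv)
    at <- which(Jv == jmin, arr.ind = TRUE)
    dm <- d[at[, 1]]; dn <- d[at[, 2]]
    pick <- order(abs(dm) + abs(dn), dm, dn)[1]
    data.frame(point = mp$point[i], dm = dm[pick], dn = dn[pick],
               J_vertex = jmin, stringsAsFactors = FALSE)
  }))
  out <- global
  out$refinements <- ref
  out$J_refined <- sum(ref$J_vertex)
  out
}

#' Translate image content by an integer displacement
#'
#' @param x numeric matrix.
#' @param dm,dn content displacement in rows/cols (positive = down/right).
#' @param bg fill value.
#' @return the translated matrix.
#' @export
translate_image <- function(x, dm, dn, bg = 0) {
  shift_mat(x, as.integer(round(dm)), as.integer(round(dn)), fill = bg)
}

#' Correct the measurable cube by the recovered affine transform
#'
#' Every band is rotated by `-alpha_star` (undoing the estimated hand
#' inclination, nearest neighbour, out-of-frame pixels 0) and translated by
#' the negated global displacement, so template coordinates index the
#' corrected cube directly. The white-reference rows, which are not tissue
#' and would otherwise rotate into a diagonal bright band, are blanked
#' first. Per-vertex refinements are carried into the region partition,
#' not warped into the image.
#'
#' @param cube the measurable [spectral_cube()] (L_P).
#' @param alpha_star estimated inclination in degrees.
#' @param match optional `match_result`; `NULL` means no translation.
#' @return the corrected cube (L_P*).
#' @export
apply_correction <- function(cube, alpha_star, match = NULL) {
  v <- cube$values
  d <- dim(v)
  idx <- if (alpha_star %% 360 != 0) {
    rotation_index_map(d[1:2], -alpha_star)
  }
  dm <- if (!is.null(match)) -match$displacement[["dm"]] else 0L
  dn <- if (!is.null(match)) -match$displacement[["dn"]] else 0L
  for (k in seq_len(d[3])) {
    band <- v[, , k]
    if (cube$calib_rows > 0L) band[seq_len(cube$calib_rows), ] <- 0
    if (!is.null(idx)) band <- apply_index_map(band, idx, bg = 0)
    if (dm != 0L || dn != 0L) band <- translate_image(band, dm, dn)
    v[, , k] <- band
  }
  spectral_cube(v, cube$wavelengths_nm, 0L)
}
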