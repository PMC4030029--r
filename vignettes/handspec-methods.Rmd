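---
title: "Methods: automated chromophore mapping of the hand"
author: "handspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated chromophore mapping of the hand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Melanin and haemoglobin are the dominant light-absorbing constituents of
skin in the visible range: melanin absorbs broadly across roughly
450-600 nm, haemoglobin in the blue-green (the Soret band near 420 nm and
the 540/577 nm doublet). A push-broom VNIR hyperspectral camera imaging the
dorsal side of a hand records a cube `L(m, n, lambda)` of brightness for
every pixel and wavelength, from which per-region chromophore content can
be quantified *reproducibly* — provided the hand is located, oriented and
subdivided automatically, without an operator drawing regions.

`handspec` implements that pipeline end to end: ENVI cube ingestion,
calibration and spatial preprocessing, hand localization by a
rotation-search criterion, Otsu binarization and contour-minima fingertip
landmarks, matching against an anthropometric hand template by exhaustive
displacement search, aggregation of wavelength bands into melanin and
haemoglobin maps, and per-finger statistics over a 12-area partition. A
synthetic hand phantom with analytic ground truth makes every stage
verifiable without patient data.

## Pipeline model and conventions

All images are R matrices indexed `(row m, col n)`, 1-based, row 1 at the
top. A cube is an `M x N x Lambda` array with an ascending wavelength
vector in nm. After orientation correction the hand is *vertical*: fingers
point towards row 1, the forearm towards row M. Consequently finger axes
run along rows, and the two sides of a finger split by column; side A is
the smaller-column side. (The contour stage scans first foreground rows
per column and the rotation criterion concentrates mass into columns, so
the vertical pose is the one consistent convention.)

The stages, with the shipped defaults:

1. **Decode** (`read_envi_cube`): BIL/BIP/BSQ raw streams; the
   row-per-wavelength acquisition order of a push-broom camera is plain
   BIL decoding.
2. **Calibrate** (`calibrate`): each band is divided per column by the
   mean of its leading white-reference rows; the dark reference is assumed
   zero. This removes the across-slit illumination profile exactly and
   leaves only the (small) along-track component.
3. **Median filter** (`median_filter`, 3x3): rejects impulse pixels;
   larger masks also delete small real structures, so 3 stays the default.
4. **Normalize** (`normalize`): min-max to `[0, 1]` per band. Because the
   reference area is part of the frame, 1 means 100% emission. A constant
   band raises an error rather than silently becoming zeros — it flags a
   dead band.
5. **Illumination removal** (`remove_illumination`, 30x30 box mean): the
   moving average is subtracted; the even mask is anchored with offsets
   `-14..15`, exactly the index arithmetic of the defining double sum, and
   the returned `"valid"` attribute marks where the padless sum applies.
6. **Downscale** (`downscale`, 10%): nearest-neighbour; 899x1312 becomes
   90x131. Phantom frames are generated at working scale already, so
   phantom runs use factor 1 (or 0.5 to exercise the resampling path).
7. **Rotation search** (`estimate_rotation`): over a grid in (0, 180)
   degrees, the working image is rotated and scored by the maximum over
   columns of the column sums; the score peaks when the hand axis is
   column-aligned. The input is the *illumination-flattened* band sum: the
   high-pass reduces the hand to a thin rim whose long straight edges pin
   the alignment, whereas on the solid normalized image the score is
   angle-insensitive over several degrees (a vertical line keeps
   intersecting a tilted finger of width w and length l fully while the
   tilt is below about atan(w/l)). The estimator's intrinsic resolution
   for hand-proportioned silhouettes is therefore about 2 degrees; the
   default grid step is 1 degree, and recovery is asserted at a 2-degree
   grid ("within one grid step"). Ties take the smallest angle. Because a
   column criterion cannot distinguish up from down, inclinations are
   modelled in [0, 180).
8. **Binarize** (`otsu_threshold` + `binarize`): Otsu's threshold on a
   256-bin histogram of the band-summed *normalized* image (the solid
   object; the rim image would yield a hollow ring that the opening
   annihilates), strict `>` as the definition prints, exact value 0.
   Otsu ties take the smallest maximizing cut.
9. **Landmarks** (`contour_curve` + `find_tip_landmarks`): per column,
   the first foreground row; fingertips are the prominent local minima.
   Prominence is the climb to the lower enclosing ridge; a side where the
   silhouette support simply ends (outside the thumb or little finger)
   counts as unbounded, the classic topographic convention. Defaults:
   prominence 5% of the working-image height, separation half the
   narrowest template finger width at working scale. Up to five tips are
   kept, ordered by column (V1..V5); missing ones are flagged not
   visible.
10. **Wrist** (`binary_opening` + `wrist_centroid`): opening with a square
    element wider than any finger (201 px at full resolution, scaled by
    the downscale factor and forced odd) removes the fingers; the centroid
    of the remaining palm/wrist blob is V6. Out-of-frame pixels count as
    background for both erosion and dilation.
11. **Template match** (`criterion_J`, `global_match`,
    `refine_vertices`): J is the sum of squared row and column residuals
    between detected tips and pattern points — the squared-difference
    reading under which the criterion surface has a single quadratic
    minimum. The search is exhaustive over integer displacements within
    +/-100 px (ties: smallest `|dm|+|dn|`, then lexicographic); each
    vertex is then refined independently within +/-25 px, which can only
    decrease J. The template moves, not the image; the correction negates
    the displacement.
12. **Correct** (`apply_correction`): every band rotated by `-alpha*` and
    translated by the negated displacement, nearest neighbour, background
    0; the reference rows are blanked first (they are not tissue and
    would rotate into a diagonal bright band). Refinements only reposition
    the per-finger regions.
13. **Aggregate** (`aggregate_band`): per-pixel sums over the closed
    intervals [450, 600] nm (melanin; 189 bands on the 0.79 nm camera
    grid) and [397, 500] nm (haemoglobin; the 350 nm figure sometimes
    quoted for the lower bound is below the camera support). Closed
    intervals are declared for determinism; no grid sample lands exactly
    on a bound at 0.79 nm spacing, so the choice is observationally
    neutral there. Maps are kept raw and, for tables and the composite,
    min-max normalized.
14. **Partition** (`partition_finger`): from each matched tip, the
    template's scaled finger length delimits the finger; six equal
    half-open segments along the axis times the two sides of the per-row
    centreline give areas A1..A6 (tip to base) and B1..B6. Boundary
    pixels belong to exactly one area; a pixel exactly on the centreline
    joins side A.
15. **Statistics** (`area_stats`, `spectral_profile`,
    `along_finger_trend`): per-area mean and *population* SD of the
    normalized map (the printed "STD of the mean" magnitudes, 0.01-0.06,
    rule out a standard error, which would be orders smaller at thousands
    of pixels per area; the SEM is emitted alongside for transparency);
    per-finger spectra as width-means per axis position; and the
    wrist/tip intensity ratio, each end averaged over the outermost 5% of
    axis positions.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a hand-shaped object — palm ellipse, five
finger capsules with anthropometric length ratios, and a forearm stub
(real dorsal-hand frames always include the wrist and forearm; without
that elongation the rotation criterion's landscape is nearly flat) — at a
known inclination, rendered through an analytic reflectance model:

* baseline skin reflectance rising from the blue to the NIR
  (`0.30 + 0.45 / (1 + exp(-(lambda - 600)/60))`),
* minus melanin times a broad Gaussian absorption centred at 525 nm
  (SD 65 nm, covering 450-600 nm),
* minus haemoglobin times three Gaussian bands at 420/542/577 nm,
* clipped to [0, 1].

Gaussian band shapes are a modelling choice that keeps the ground truth
analytic; only the integration ranges, not the spectral shapes, matter to
the method under test. On top of the reflectance: a separable low-order
polynomial illumination field (amplitude 0.15 across columns — the
push-broom slit direction — and a fifth of that along rows), leading
100%-emission reference rows, Gaussian sensor noise (SD 0.01), a small
salt-and-pepper fraction (0.002), and flat background at reflectance 0.05
(low enough that Otsu separation is never the interesting failure mode;
configurable, including 0). An optional wrist-ward intensity ramp
(`axial_gain`) multiplies finger pixels by `1 + g t`, where `t` runs from
0 at the fingertip to 1 one template finger length below — the same span
the trend measurement covers. Cube values are snapped to float32 so
emitted ENVI files round-trip bit-exactly.

The phantom is a geometric and radiometric test oracle, **not** a
biophysical skin simulator: no Kubelka-Munk or Monte-Carlo photon
transport, no skin texture, no specular highlights, no wavelength-dependent
illumination, no camera PSF or smile/keystone distortions. Passing the
recovery suites therefore demonstrates that the implementation recovers
what it is defined to recover under controlled conditions; it does not
validate the biology of real-skin measurements.

## Problem sizes and numerical choices

The shipped study conditions are a 128x196 px, 200-band phantom for the
end-to-end run (the full pipeline completes in well under a minute on one
CPU) and 176x176, 8-band phantoms for geometry-only recovery, with the
angle sweep at 10, 30, ..., 170 degrees. Oracle-equivalence suites run 100
random instances per operation at small sizes (images 10-42 px across,
masks 6-30, structuring elements 3-21). Tolerances: oracle comparisons are
exact (or 1e-10 where an integral image meets a literal double sum);
fingertip recovery 2 px noiseless and 4 px at noise SD 0.02 at working
resolution; melanin area contrasts 5%; the programmed 15% wrist-ward
gradient 2%; rotation one (2-degree) grid step.

Degenerate inputs fail loudly and early: constant images cannot be
normalized or thresholded, empty masks have no contour or centroid,
geometry that leaves the frame names the offending finger.

## Known limitations

* The rotation criterion cannot resolve below ~2 degrees for realistic
  hand proportions, and cannot distinguish a hand from its 180-degree
  flip; inclinations are assumed in [0, 180).
* The template match is translation-only (plus per-vertex region
  repositioning); there is no scale or elastic warping, so the template
  must be produced at the acquisition geometry's scale.
* Finger regions are delimited by the template's finger length; the exact
  finger/metacarpus boundary is a template parameter, not an image
  measurement.
* Maps are reflectance band sums, not absorbance or unmixed
  concentrations; no oxy/deoxy-haemoglobin separation is attempted.
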