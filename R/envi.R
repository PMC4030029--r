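# ENVI cube I/O: header parsing, raw-binary decoding for the three standard
# interleaves, writing, and wavelength band selection.
#
# A push-broom VNIR camera writes each spatial row consecutively for every
# wavelength (band-interleaved-by-line); decoding reorganizes that stream
# into the image sequence values[m, n, k] used by the rest of the pipeline.

ENVI_DATA_TYPES <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE, r_mode = "integer"),
  `2`  = list(what = "integer", size = 2L, signed = TRUE,  r_mode = "integer"),
  `4`  = list(what = "double",  size = 4L, signed = TRUE,  r_mode = "double"),
  `12` = list(what = "integer", size = 2L, signed = FALSE, r_mode = "integer")
)

#' Construct a spectral cube
#'
#' A spectral cube is an `M x N x Lambda` array of brightness values plus the
#' ascending wavelength vector (nm) of its bands. `calib_rows` counts leading
#' image rows that hold the in-frame white reference (100% emission) used for
#' calibration; 0 means none.
#'
#' @param values numeric 3-d array, rows x cols x bands.
#' @param wavelengths_nm strictly increasing numeric vector, one per band.
#' @param calib_rows non-negative integer count of leading reference rows.
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths_nm, calib_rows = 0L) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (length(wavelengths_nm) != dim(values)[3]) {
    stop("wavelengths_nm must have one entry per band (",
         dim(values)[3], " bands, ", length(wavelengths_nm), " wavelengths)")
  }
  if (length(wavelengths_nm) > 1L && any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths_nm must be strictly increasing")
  }
  if (!all(is.finite(values))) stop("cube values must be finite")
  if (calib_rows < 0L || calib_rows >= dim(values)[1]) {
    stop("calib_rows must be in [0, rows)")
  }
  structure(
    list(values = values, wavelengths_nm = as.numeric(wavelengths_nm),
         calib_rows = as.integer(calib_rows)),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<spectral_cube> %d x %d px, %d bands (%.1f-%.1f nm), %d calibration row(s)\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$calib_rows))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Parse an ENVI header
#'
#' Accepts the `key = value` ENVI dialect with brace-wrapped (possibly
#' multi-line) list values. Mandatory keys: `samples`, `lines`, `bands`,
#' `data type`, `interleave`. `byte order` defaults to 0 (little-endian)
#' when absent. Unknown keys are preserved in `$extra` and survive a
#' write/parse round trip.
#'
#' @param text header file contents (single string or character vector of
#'   lines) or a path to a `.hdr` file.
#' @return an object of class `envi_header` with fields `samples`, `lines`,
#'   `bands`, `data_type`, `interleave`, `byte_order`, `wavelengths_nm`,
#'   `wavelength_units`, `default_bands`, `sensor_type`, `header_offset`,
#'   `extra`.
#' @export
parse_envi_header <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) > 0L && grepl("^\\s*ENVI\\s*$", lines[1])) {
    lines <- lines[-1]
  }
  # stitch multi-line brace blocks into single logical entries
  entries <- character(0)
  buf <- ""
  open <- 0L
  for (ln in lines) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    open <- open +
      lengths(regmatches(ln, gregexpr("{", ln, fixed = TRUE))) -
      lengths(regmatches(ln, gregexpr("}", ln, fixed = TRUE)))
    if (open <= 0L) {
      entries <- c(entries, buf)
      buf <- ""
      open <- 0L
    }
  }
  if (nzchar(buf)) entries <- c(entries, buf)

  kv <- list()
  for (e in entries) {
    m <- regmatches(e, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)\\s*$", e))[[1]]
    if (length(m) == 3L) kv[[tolower(m[2])]] <- m[3]
  }

  need_int <- function(key) {
    if (is.null(kv[[key]])) {
      stop("missing mandatory ENVI header key: '", key, "'")
    }
    v <- suppressWarnings(as.integer(kv[[key]]))
    if (is.na(v)) stop("ENVI header key '", key, "' is not an integer: ",
                       kv[[key]])
    v
  }
  strip_braces <- function(v) {
    v <- sub("^\\s*\\{\\s*", "", v)
    sub("\\s*\\}\\s*$", "", v)
  }
  parse_num_list <- function(v) {
    as.numeric(strsplit(strip_braces(v), "\\s*,\\s*")[[1]])
  }

  samples <- need_int("samples")
  nlines <- need_int("lines")
  bands <- need_int("bands")
  data_type <- need_int("data type")
  if (is.null(kv[["interleave"]])) {
    stop("missing mandatory ENVI header key: 'interleave'")
  }
  interleave <- tolower(trimws(kv[["interleave"]]))
  if (!interleave %in% c("bil", "bip", "bsq")) {
    stop("unsupported interleave: ", interleave)
  }
  if (!as.character(data_type) %in% names(ENVI_DATA_TYPES)) {
    stop("unsupported ENVI data type code: ", data_type)
  }
  if (min(samples, nlines, bands) < 1L) {
    stop("samples, lines and bands must all be >= 1")
  }

  wl <- NULL
  if (!is.null(kv[["wavelength"]])) {
    wl <- parse_num_list(kv[["wavelength"]])
    if (length(wl) != bands) {
      stop("header declares ", bands, " bands but ", length(wl),
           " wavelengths")
    }
    if (length(wl) > 1L && any(diff(wl) <= 0)) {
      stop("wavelengths in header are not strictly increasing")
    }
  }
  default_bands <- if (!is.null(kv[["default bands"]])) {
    as.integer(parse_num_list(kv[["default bands"]]))
  }

  known <- c("samples", "lines", "bands", "data type", "interleave",
             "byte order", "wavelength", "wavelength units",
             "default bands", "sensor type", "header offset", "description",
             "file type")
  extra <- kv[setdiff(names(kv), known)]

  structure(list(
    samples = samples, lines = nlines, bands = bands,
    data_type = data_type, interleave = interleave,
    byte_order = if (!is.null(kv[["byte order"]]))
      as.integer(kv[["byte order"]]) else 0L,
    wavelengths_nm = wl,
    wavelength_units = if (!is.null(kv[["wavelength units"]]))
      trimws(kv[["wavelength units"]]) else NULL,
    default_bands = default_bands,
    sensor_type = if (!is.null(kv[["sensor type"]]))
      trimws(kv[["sensor type"]]) else NULL,
    header_offset = if (!is.null(kv[["header offset"]]))
      as.integer(kv[["header offset"]]) else 0L,
    extra = extra
  ), class = "envi_header")
}

#' Render an ENVI header back to text
#'
#' @param header an `envi_header`.
#' @return a single string of `.hdr` file contents.
#' @export
format_envi_header <- function(header) {
  num_list <- function(x) paste0("{", paste(format(x, trim = TRUE,
                                                   digits = 15),
                                            collapse = ", "), "}")
  out <- c(
    "ENVI",
    paste0("samples = ", header$samples),
    paste0("lines = ", header$lines),
    paste0("bands = ", header$bands),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", header$data_type),
    paste0("interleave = ", header$interleave),
    paste0("byte order = ", header$byte_order %||% 0L)
  )
  if (!is.null(header$sensor_type)) {
    out <- c(out, paste0("sensor type = ", header$sensor_type))
  }
  if (!is.null(header$wavelength_units)) {
    out <- c(out, paste0("wavelength units = ", header$wavelength_units))
  }
  if (!is.null(header$default_bands)) {
    out <- c(out, paste0("default bands = ", num_list(header$default_bands)))
  }
  if (!is.null(header$wavelengths_nm)) {
    out <- c(out, paste0("wavelength = ", num_list(header$wavelengths_nm)))
  }
  for (k in names(header$extra)) {
    out <- c(out, paste0(k, " = ", header$extra[[k]]))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read an ENVI cube
#'
#' Decodes the raw binary stream into `values[m, n, k]` according to the
#' header's interleave scheme (BIL: row-per-wavelength acquisition order,
#' BIP, BSQ) and copies the wavelength vector. The custom header key
#' `calibration rows` (written by [write_envi_cube()]) is honoured.
#'
#' @param dat path to the `.dat` file or a raw vector.
#' @param header an `envi_header` (or path/text handed to
#'   [parse_envi_header()]).
#' @return a [spectral_cube()].
#' @export
read_envi_cube <- function(dat, header) {
  if (!inherits(header, "envi_header")) header <- parse_envi_header(header)
  tp <- ENVI_DATA_TYPES[[as.character(header$data_type)]]
  n <- header$samples * header$lines * header$bands
  expected <- n * tp$size + header$header_offset
  if (is.character(dat)) {
    actual <- file.info(dat)$size
    if (is.na(actual) || actual != expected) {
      stop("ENVI data size mismatch: expected ", expected, " bytes, got ",
           actual %||% NA)
    }
    con <- file(dat, "rb")
    on.exit(close(con))
    if (header$header_offset > 0L) readBin(con, raw(), header$header_offset)
    raw_src <- con
  } else {
    stopifnot(is.raw(dat))
    if (length(dat) != expected) {
      stop("ENVI data size mismatch: expected ", expected, " bytes, got ",
           length(dat))
    }
    raw_src <- dat[(header$header_offset + 1L):length(dat)]
  }
  endian <- if ((header$byte_order %||% 0L) == 1L) "big" else "little"
  v <- readBin(raw_src, what = tp$what, n = n, size = tp$size,
               signed = tp$signed, endian = endian)
  M <- header$lines; N <- header$samples; L <- header$bands
  values <- switch(header$interleave,
    bsq = aperm(array(v, c(N, M, L)), c(2, 1, 3)),
    bil = aperm(array(v, c(N, L, M)), c(3, 1, 2)),
    bip = aperm(array(v, c(L, N, M)), c(3, 2, 1))
  )
  wl <- header$wavelengths_nm %||% seq_len(L)
  calib_raw <- header$extra[["calibration rows"]]
  calib <- if (is.null(calib_raw)) 0L else
    suppressWarnings(as.integer(calib_raw))
  if (length(calib) != 1L || is.na(calib)) calib <- 0L
  spectral_cube(values, wl, calib)
}

#' Write an ENVI cube
#'
#' Emits the raw `.dat` payload and ASCII `.hdr` text for a cube. Float32
#' (data type 4) payloads round-trip bit-exactly through
#' [read_envi_cube()] provided the cube values are float32-representable
#' (see [snap_float32()]); phantom cubes are emitted that way.
#'
#' @param cube a [spectral_cube()].
#' @param path base path (without extension) to write `<path>.dat` and
#'   `<path>.hdr`; `NULL` returns the bytes/text without touching disk.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code (4 = float32, also 1/2/12).
#' @return invisibly, `list(dat = raw payload, hdr = header text)`.
#' @export
write_envi_cube <- function(cube, path = NULL, interleave = "bil",
                            data_type = 4L) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(tolower(interleave), c("bil", "bip", "bsq"))
  if (!as.character(data_type) %in% names(ENVI_DATA_TYPES)) {
    stop("unsupported ENVI data type code: ", data_type)
  }
  tp <- ENVI_DATA_TYPES[[as.character(data_type)]]
  d <- dim(cube$values)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$values, c(2, 1, 3))),
    bil = as.vector(aperm(cube$values, c(2, 3, 1))),
    bip = as.vector(aperm(cube$values, c(3, 2, 1)))
  )
  if (tp$r_mode == "integer") {
    if (any(v != round(v))) stop("non-integral values cannot be written as ",
                                 "ENVI data type ", data_type)
    payload <- writeBin(as.integer(v), raw(), size = tp$size,
                        endian = "little")
  } else {
    payload <- writeBin(as.double(v), raw(), size = tp$size,
                        endian = "little")
  }
  header <- structure(list(
    samples = d[2], lines = d[1], bands = d[3],
    data_type = as.integer(data_type), interleave = interleave,
    byte_order = 0L, wavelengths_nm = cube$wavelengths_nm,
    wavelength_units = "Nanometers", default_bands = NULL,
    sensor_type = "handspec", header_offset = 0L,
    extra = list(`calibration rows` = as.character(cube$calib_rows))
  ), class = "envi_header")
  hdr <- format_envi_header(header)
  if (!is.null(path)) {
    writeBin(payload, paste0(path, ".dat"))
    writeLines(sub("\n$", "", hdr), paste0(path, ".hdr"))
  }
  invisible(list(dat = payload, hdr = hdr))
}

#' Indices of bands inside a closed wavelength interval
#'
#' Returns all band indices `k` with `lo <= wavelengths_nm[k] <= hi`,
#' ascending. The interval is closed; on the camera's 0.79 nm grid starting
#' at 397 nm the melanin range `[450, 600]` selects exactly 189 bands.
#'
#' @param wavelengths_nm ascending wavelength vector (nm).
#' @param lo,hi interval bounds in nm, `lo <= hi`.
#' @return integer vector of band indices (possibly empty).
#' @export
band_indices <- function(wavelengths_nm, lo, hi) {
  stopifnot(lo <= hi)
  which(wavelengths_nm >= lo & wavelengths_nm <= hi)
}
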