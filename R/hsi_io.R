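# ENVI-style hyperspectral cube container and I/O.

# ENVI numeric data type codes supported here.
.envi_dtypes <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `2`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `4`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `5`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `12` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Hyperspectral cube
#'
#' A 3-D reflectance array (`lines x samples x bands`) with interleave,
#' storage type and wavelength calibration metadata.
#'
#' @param data Numeric 3-D array, dimensions `lines x samples x bands`,
#'   all dimensions at least 1, values non-negative.
#' @param calibration A `wavelength_calibration` covering every band, or
#'   `NULL` for an uncalibrated cube.
#' @param interleave Binary layout used on disk: `"bil"`, `"bip"` or `"bsq"`.
#' @param dtype ENVI data type code (1 = uint8, 2 = int16, 4 = float32,
#'   5 = float64, 12 = uint16). Default 5, which round-trips doubles
#'   bit-exactly.
#' @param extra_header Named character vector of additional header entries
#'   preserved verbatim on round-trip.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, calibration = NULL, interleave = c("bil", "bip", "bsq"),
                      dtype = 5L, extra_header = character()) {
  interleave <- match.arg(interleave)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array (lines x samples x bands)")
  if (any(dim(data) < 1L)) stop("all cube dimensions must be >= 1")
  if (!as.character(dtype) %in% names(.envi_dtypes))
    stop(sprintf("unsupported ENVI data type code %s", dtype))
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "wavelength_calibration"))
    if (calibration$n_bands != dim(data)[3L])
      stop("calibration covers a different number of bands than the cube")
  }
  structure(list(data = data, interleave = interleave, dtype = as.integer(dtype),
                 calibration = calibration, extra_header = extra_header),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube: %d lines x %d samples x %d bands, %s, dtype %d\n",
              d[1], d[2], d[3], x$interleave, x$dtype))
  if (!is.null(x$calibration)) print(x$calibration)
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Number of bands in a cube
#' @param cube A `hypercube`.
#' @return Integer band count.
#' @export
n_bands <- function(cube) dim(cube$data)[3L]

# --- header ----------------------------------------------------------------

.parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header: missing ENVI magic line")
  body <- paste(txt[-1], collapse = "\n")
  # join brace-delimited multi-line values, then split on newlines
  ents <- list()
  pos <- 1L
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{") && !grepl("\\}", val)) {
      while (i < length(lines) && !grepl("\\}", val)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
    }
    ents[[tolower(key)]] <- val
    i <- i + 1L
  }
  ents
}

.header_int <- function(ents, key) {
  if (is.null(ents[[key]])) stop(sprintf("ENVI header missing required key '%s'", key))
  as.integer(ents[[key]])
}

.brace_list <- function(val) {
  inner <- gsub("[{}]", "", val)
  as.numeric(strsplit(inner, ",")[[1]])
}

#' Read an ENVI-style hyperspectral cube
#'
#' Parses a `key = value` text header and reads the binary companion file
#' in BIL, BIP or BSQ interleave. Wavelengths present in the header become
#' an explicit calibration; otherwise `calibration` is used.
#'
#' @param header_path Path to the `.hdr` file. The binary file is located
#'   by dropping the `.hdr` extension, or by the `.bil`/`.bip`/`.bsq`/
#'   `.img` siblings of the header.
#' @param calibration Optional `wavelength_calibration` used when the
#'   header carries no wavelength list.
#' @return A [hypercube()].
#' @export
read_envi_cube <- function(header_path, calibration = NULL) {
  if (!file.exists(header_path)) stop("header file does not exist: ", header_path)
  ents <- .parse_envi_header(header_path)
  samples <- .header_int(ents, "samples")
  lines   <- .header_int(ents, "lines")
  bands   <- .header_int(ents, "bands")
  dtype   <- .header_int(ents, "data type")
  interleave <- tolower(if (is.null(ents[["interleave"]])) stop("ENVI header missing required key 'interleave'") else ents[["interleave"]])
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported interleave: ", interleave)
  spec <- .envi_dtypes[[as.character(dtype)]]
  if (is.null(spec)) stop(sprintf("unsupported ENVI data type code %d", dtype))
  byte_order <- if (!is.null(ents[["byte order"]])) as.integer(ents[["byte order"]]) else 0L
  endian <- if (byte_order == 0L) "little" else "big"

  # locate binary payload
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  cand <- c(base, paste0(base, c(".bil", ".bip", ".bsq", ".img")))
  bin <- cand[file.exists(cand)][1]
  if (is.na(bin)) stop("binary companion file not found for ", header_path)

  n <- as.numeric(samples) * lines * bands
  expected <- n * spec$size
  if (file.info(bin)$size != expected)
    stop(sprintf("corrupt cube: %s has %d bytes, header implies %d",
                 bin, file.info(bin)$size, expected))
  con <- file(bin, "rb"); on.exit(close(con))
  raw <- readBin(con, what = spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = endian)
  a <- switch(interleave,
    bil = aperm(array(raw, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw, c(bands, samples, lines)), c(3, 2, 1)),
    bsq = aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3)))

  if (!is.null(ents[["wavelength"]])) {
    wl <- .brace_list(ents[["wavelength"]])
    if (length(wl) != bands) stop("wavelength list length does not match band count")
    calibration <- wavelength_calibration(wavelengths_nm = wl)
  }
  known <- c("samples", "lines", "bands", "data type", "interleave",
             "byte order", "wavelength", "header offset", "file type")
  extra <- unlist(ents[setdiff(names(ents), known)])
  hypercube(a, calibration = calibration, interleave = interleave,
            dtype = dtype, extra_header = if (length(extra)) extra else character())
}

#' Write a hyperspectral cube as ENVI header + binary
#'
#' Inverse of [read_envi_cube()]: emits a minimal `key = value` header and
#' the raw payload in the cube's declared interleave (little-endian).
#'
#' @param cube A [hypercube()].
#' @param path Output path; `.hdr` is appended for the header and the
#'   interleave name (`.bil`/`.bip`/`.bsq`) for the payload.
#' @return The header path, invisibly.
#' @export
write_envi_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  base <- sub("\\.(hdr|bil|bip|bsq)$", "", path, ignore.case = TRUE)
  hdr <- paste0(base, ".hdr")
  bin <- paste0(base, ".", cube$interleave)
  d <- dim(cube$data)
  spec <- .envi_dtypes[[as.character(cube$dtype)]]

  out <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", cube$dtype),
           sprintf("interleave = %s", cube$interleave),
           "byte order = 0")
  if (!is.null(cube$calibration)) {
    wl <- wavelength_of_band(cube$calibration, seq_len(d[3]))
    out <- c(out, paste0("wavelength = { ",
                         paste(format(wl, trim = TRUE, digits = 15), collapse = ", "),
                         " }"))
  }
  if (length(cube$extra_header))
    out <- c(out, sprintf("%s = %s", names(cube$extra_header), cube$extra_header))
  ok <- tryCatch({ writeLines(out, hdr); TRUE },
                 error = function(e) stop("cannot write header: ", conditionMessage(e)))

  a <- switch(cube$interleave,
    bil = aperm(cube$data, c(2, 3, 1)),
    bip = aperm(cube$data, c(3, 2, 1)),
    bsq = aperm(cube$data, c(2, 1, 3)))
  v <- as.vector(a)
  if (spec$what == "integer") v <- as.integer(round(v))
  con <- file(bin, "wb"); on.exit(close(con))
  writeBin(v, con, size = spec$size, endian = "little")
  invisible(hdr)
}
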