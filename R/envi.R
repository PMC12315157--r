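# ENVI header + flat-binary cube I/O, covering the dialect written by the
# SPECIM IQ camera: a text .hdr with "key = value" pairs ("wavelength" as a
# {...} block) next to a raw file in BSQ, BIL or BIP interleave.

#' Read an ENVI hyperspectral cube
#'
#' Parses an ENVI text header, reads the accompanying raw binary file and
#' returns an [hsi_cube]. The raw file is located by dropping the `.hdr`
#' extension (with or without a `.raw` suffix). Supports BSQ, BIL and BIP
#' interleaves and data types 4 (float32), 5 (float64), 2/12 (int16/uint16).
#'
#' @param header_path path to the `.hdr` file.
#' @param mask_path optional ROI mask: a PNG (non-zero = inside) or a text
#'   matrix of 0/1. When absent the mask is all-TRUE.
#' @return An [hsi_cube] with wavelengths parsed from the header.
#' @export
read_envi_cube <- function(header_path, mask_path = NULL) {
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  if (is.null(hdr$wavelength))
    stop("ENVI header declares no wavelength list")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", hdr$wavelength), ",")[[1L]])
  if (length(wl) != nb)
    stop("ENVI header contradictory: bands = ", nb, " but ",
         length(wl), " wavelengths listed")
  raw_path <- envi_raw_path(header_path)
  dtype <- as.integer(hdr$"data type")
  sz <- switch(as.character(dtype), "4" = 4L, "5" = 8L, "2" = 2L, "12" = 2L,
               stop("unsupported ENVI data type: ", dtype))
  what <- if (dtype %in% c(4L, 5L)) "numeric" else "integer"
  n <- ns * nl * nb
  expect_bytes <- n * sz
  actual <- file.info(raw_path)$size
  if (is.na(actual) || actual != expect_bytes)
    stop("raw file size (", actual, " bytes) inconsistent with header (",
         expect_bytes, " bytes expected)")
  endian <- if (!is.null(hdr$"byte order") && as.integer(hdr$"byte order") == 1L)
    "big" else "little"
  con <- file(raw_path, "rb"); on.exit(close(con))
  v <- readBin(con, what = what, n = n, size = sz, endian = endian,
               signed = dtype != 12L)
  arr <- switch(tolower(hdr$interleave),
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", hdr$interleave))
  mask <- if (!is.null(mask_path)) read_roi_mask(mask_path) else NULL
  meta <- hdr[setdiff(names(hdr), c("wavelength"))]
  hsi_cube(arr, wl, roi_mask = mask, meta = meta)
}

#' Write an ENVI hyperspectral cube
#'
#' Writes `<path_base>.hdr` and `<path_base>.raw` (float32, BSQ,
#' little-endian), the inverse of [read_envi_cube()].
#'
#' @param cube an [hsi_cube].
#' @param path_base output path without extension.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @return `path_base`, invisibly.
#' @export
write_envi_cube <- function(cube, path_base, interleave = "bsq") {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$reflectance)
  hdr_lines <- c(
    "ENVI",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "data type = 4",
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths_nm, trim = TRUE),
                                   collapse = ", "), "}"))
  writeLines(hdr_lines, paste0(path_base, ".hdr"))
  arr <- cube$reflectance
  v <- switch(tolower(interleave),
    bsq = as.numeric(aperm(arr, c(2L, 1L, 3L))),
    bil = as.numeric(aperm(arr, c(2L, 3L, 1L))),
    bip = as.numeric(aperm(arr, c(3L, 2L, 1L))),
    stop("unsupported interleave: ", interleave))
  con <- file(paste0(path_base, ".raw"), "wb"); on.exit(close(con))
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path_base)
}

#' Read a boolean ROI mask from PNG or plain text
#'
#' @param path `.png` (pixels > 0.5 are inside) or whitespace-separated 0/1
#'   text matrix.
#' @return logical matrix.
#' @export
read_roi_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m > 0.5
  } else {
    unname(as.matrix(read.table(path))) > 0.5
  }
}

#' Write a boolean ROI mask
#'
#' @param mask logical matrix.
#' @param path `.png` or text destination (by extension).
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(mask * 1, path)
  } else {
    write.table(mask * 1L, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @noRd
parse_envi_header <- function(path) {
  if (!file.exists(path)) stop("header not found: ", path)
  txt <- readLines(path, warn = FALSE)
  # join {...} blocks that span lines
  joined <- character(); buf <- NULL
  for (ln in txt) {
    if (!is.null(buf)) {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { joined <- c(joined, buf); buf <- NULL }
    } else if (grepl("\\{", ln) && !grepl("\\}", ln)) {
      buf <- ln
    } else joined <- c(joined, ln)
  }
  if (!is.null(buf)) stop("unterminated { block in ENVI header")
  kv <- joined[grepl("=", joined)]
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  out <- as.list(vals)
  names(out) <- tolower(keys)
  out
}

#' @noRd
envi_raw_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (cand in c(paste0(base, ".raw"), base, paste0(base, ".dat"),
                 paste0(base, ".img"))) {
    if (file.exists(cand)) return(cand)
  }
  stop("no raw file found next to ", header_path)
}
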