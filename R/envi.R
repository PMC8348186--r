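# ENVI format I/O: text header (.hdr) + raw interleaved binary.
# Writes BIL float32; reads BIL, BIP and BSQ in float32/float64.

.envi_dtype <- c("4" = "float32", "5" = "float64")
.envi_bytes <- c("4" = 4L, "5" = 8L)

#' Write a hypercube to an ENVI file pair
#'
#' Writes `path` (raw binary, band-interleaved-by-line, little-endian
#' float32 by default) and `path.hdr` (text header carrying dimensions,
#' interleave and the wavelength list).
#'
#' @param cube A [hypercube()].
#' @param path Path of the binary file; the header is `paste0(path, ".hdr")`.
#' @param interleave One of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bip", "bsq"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- as.character(data_type)
  if (!data_type %in% names(.envi_dtype))
    stop("unsupported ENVI data type: ", data_type)
  d <- dim(cube$data)
  perm <- switch(interleave,
                 bil = c(2, 3, 1),   # sample fastest, then band, then line
                 bip = c(3, 2, 1),   # band fastest, then sample, then line
                 bsq = c(2, 1, 3))   # sample, line, band
  vec <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(vec), con, size = .envi_bytes[data_type], endian = "little")
  hdr <- c(
    "ENVI",
    "description = {brulat hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %s", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.17g", cube$wavelengths), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# parse an ENVI header into a named list of strings
.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  # brace-delimited values (may span lines), then simple key = value
  m <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- trimws(sub("=.*", "", piece))
      val <- sub(".*\\{", "", piece); val <- sub("\\}$", "", val)
      out[[tolower(key)]] <- val
    }
    txt <- gsub("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*\\{[^}]*\\}", "", txt)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    out[[key]] <- val
  }
  out
}

#' Read a hypercube from an ENVI file pair
#'
#' @param path Path of the binary file (with header at `paste0(path, ".hdr")`)
#'   or of the header itself.
#' @return A [hypercube()]; header fields are kept in `metadata`.
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin_path <- sub("\\.hdr$", "", path)
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  if (!file.exists(bin_path)) stop("ENVI binary not found: ", bin_path)
  h <- .parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need) if (is.null(h[[k]]))
    stop("ENVI header missing required field '", k, "'")
  if (is.null(h[["wavelength"]]))
    stop("ENVI header missing required field 'wavelength'")
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dtype <- trimws(h[["data type"]])
  if (!dtype %in% names(.envi_dtype))
    stop("unsupported ENVI data type: ", dtype)
  interleave <- tolower(trimws(h[["interleave"]]))
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported ENVI interleave: ", interleave)
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  if (length(wl) != nb)
    stop("ENVI header field 'wavelength' has ", length(wl),
         " entries but field 'bands' is ", nb)
  endian <- if (!is.null(h[["byte order"]]) && trimws(h[["byte order"]]) == "1")
    "big" else "little"
  n_expect <- as.double(nl) * ns * nb
  bytes <- .envi_bytes[dtype]
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L
  if (file.info(bin_path)$size - offset != n_expect * bytes)
    stop("ENVI binary size does not match header fields 'lines'/'samples'/'bands'")
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  if (offset > 0) readBin(con, "raw", n = offset)
  vec <- readBin(con, "numeric", n = n_expect, size = bytes, endian = endian)
  dims <- switch(interleave,
                 bil = c(ns, nb, nl),
                 bip = c(nb, ns, nl),
                 bsq = c(ns, nl, nb))
  unperm <- switch(interleave,
                   bil = c(3, 1, 2),   # back to (lines, samples, bands)
                   bip = c(3, 2, 1),
                   bsq = c(2, 1, 3))
  arr <- aperm(array(vec, dim = dims), unperm)
  hypercube(arr, wl, metadata = h[setdiff(names(h), c("wavelength"))])
}
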