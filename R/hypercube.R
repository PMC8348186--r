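#' Hypercube: a 3-D hyperspectral reflectance image
#'
#' Container for a (lines y x samples x x bands b) reflectance array with
#' its wavelength grid and free-form metadata. Pixel coordinates are
#' (line, sample); band order follows the strictly increasing wavelength
#' grid.
#'
#' @param data Numeric 3-D array, dims (lines, samples, bands).
#' @param wavelengths Strictly increasing numeric vector of band-centre
#'   wavelengths in nm; length must equal `dim(data)[3]`.
#' @param metadata Named list of free-form metadata.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, metadata = list()) {
  if (length(dim(data)) != 3) stop("data must be a 3-D array")
  if (any(dim(data) < 1)) stop("all hypercube dimensions must be >= 1")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop("wavelengths length (", length(wavelengths),
         ") does not match band count (", dim(data)[3], ")")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, metadata = metadata),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands, %.1f-%.1f nm\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Unfold a hypercube into a pixel matrix
#'
#' Rearranges the cube into an (n_pixels x bands) matrix without loss of
#' information. Pixel order is row-major: pixel `p = (y - 1) * n_samples + x`
#' (1-based), i.e. the sample index varies fastest. With a mask, only the
#' masked pixels are kept and their row-major indices are recorded so the
#' selection is invertible.
#'
#' @param cube A [hypercube()].
#' @param mask Optional logical (lines x samples) matrix selecting pixels.
#' @return An object of class `pixel_matrix`: list with `values`
#'   (n_pixels x bands matrix), `shape_origin` (lines, samples) and
#'   `pixel_index` (row-major indices of the rows, NULL when unmasked).
#' @export
unfold <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  X <- matrix(aperm(cube$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  pixel_index <- NULL
  if (!is.null(mask)) {
    if (!all(dim(mask) == d[1:2]))
      stop("mask shape does not match cube spatial dimensions")
    # convert column-major mask positions to row-major pixel indices
    pos <- which(mask)
    y <- (pos - 1L) %% d[1] + 1L
    x <- (pos - 1L) %/% d[1] + 1L
    pixel_index <- sort((y - 1L) * d[2] + x)
    X <- X[pixel_index, , drop = FALSE]
  }
  structure(list(values = X, shape_origin = d[1:2], pixel_index = pixel_index),
            class = "pixel_matrix")
}

#' Fold a pixel matrix back into a hypercube
#'
#' Inverse of [unfold()] for unmasked matrices: restores the 3-D array in
#' the original (lines, samples, bands) layout.
#'
#' @param pm A `pixel_matrix` from [unfold()] (unmasked).
#' @param wavelengths Wavelength grid for the rebuilt cube.
#' @param metadata Metadata for the rebuilt cube.
#' @return A [hypercube()].
#' @export
fold <- function(pm, wavelengths, metadata = list()) {
  stopifnot(inherits(pm, "pixel_matrix"))
  if (!is.null(pm$pixel_index))
    stop("cannot fold a mask-restricted pixel matrix into a full cube")
  d <- pm$shape_origin
  arr <- fold_image_checked(pm$values, d)
  hypercube(arr, wavelengths, metadata)
}

# fold an (n_pixels x k) matrix of per-pixel values into a
# (lines x samples x k) array (k = 1 gives an image), row-major pixel order
fold_image_checked <- function(values, shape) {
  values <- as.matrix(values)
  if (nrow(values) != prod(shape))
    stop("number of pixels (", nrow(values),
         ") inconsistent with shape ", shape[1], " x ", shape[2])
  arr <- array(values, dim = c(shape[2], shape[1], ncol(values)))
  aperm(arr, c(2, 1, 3))
}

#' Fold a per-pixel vector into a spatial image
#'
#' @param values Numeric vector of length `lines * samples`, row-major
#'   pixel order as produced by [unfold()].
#' @param shape Integer pair (lines, samples).
#' @return A (lines x samples) numeric matrix.
#' @export
fold_image <- function(values, shape) {
  fold_image_checked(values, shape)[, , 1]
}

#' Index of the band nearest a target wavelength
#'
#' @param wavelengths Numeric wavelength grid (nm) or a [hypercube()].
#' @param target_nm Target wavelength in nm.
#' @return 1-based band index of the grid value closest to `target_nm`;
#'   ties break toward the lower index.
#' @export
nearest_band <- function(wavelengths, target_nm) {
  if (inherits(wavelengths, "hypercube")) wavelengths <- wavelengths$wavelengths
  if (length(wavelengths) == 0) stop("wavelength grid is empty")
  which.min(abs(wavelengths - target_nm))
}

#' Extract the single-band image at a wavelength
#'
#' @param cube A [hypercube()].
#' @param target_nm Wavelength in nm; the nearest band is used.
#' @return A (lines x samples) reflectance matrix.
#' @export
band_image <- function(cube, target_nm) {
  cube$data[, , nearest_band(cube, target_nm)]
}

#' Automated PCA-based background removal
#'
#' Replaces the interactive score-plot segmentation of hyperspectral
#' workstations with a deterministic rule: PCA on the unfolded cube, Otsu
#' threshold on the first-component scores, keep the side with the higher
#' mean broadband reflectance (PCA sign is arbitrary), retain the largest
#' connected component and fill its holes.
#'
#' @param cube A [hypercube()].
#' @param n_pcs Number of components fitted (only PC1 drives the split).
#' @param min_contrast Minimum ratio of fruit to background mean broadband
#'   reflectance below which the cube is declared non-separable.
#' @return Logical (lines x samples) fruit mask (a single connected
#'   component with holes filled).
#' @export
remove_background <- function(cube, n_pcs = 2, min_contrast = 2) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  pm <- unfold(cube)
  if (stats::sd(pm$values) < .Machine$double.eps^0.5)
    stop("no separable background: cube is constant")
  model <- fit_pca(pm, A = min(n_pcs, d[3], nrow(pm$values)))
  sc1 <- pca_scores(model, pm)[, 1]
  rng <- range(sc1)
  if (diff(rng) < .Machine$double.eps^0.5)
    stop("no separable background: degenerate first component")
  sc01 <- (sc1 - rng[1]) / diff(rng)
  img <- fold_image(sc01, d[1:2])
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  high <- img > thr
  broadband <- fold_image(rowMeans(pm$values), d[1:2])
  m_high <- mean(broadband[high]); m_low <- mean(broadband[!high])
  if (!any(high) || all(high) || !is.finite(m_high) || !is.finite(m_low))
    stop("no separable background: threshold produced an empty class")
  fruit <- if (m_high >= m_low) high else !high
  bright <- max(m_high, m_low); dark <- min(m_high, m_low)
  if (dark <= 0 || bright / max(dark, .Machine$double.eps) < min_contrast)
    stop("no separable background: pixel populations are not distinct")
  lab <- EBImage::bwlabel(EBImage::Image(fruit * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  fruit <- labm == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(fruit * 1))
  matrix(EBImage::imageData(filled) > 0.5, d[1], d[2])
}

#' Pixel agreement between two masks
#'
#' Precision, recall and overall agreement of a predicted mask against a
#' reference mask.
#'
#' @param predicted,reference Logical matrices of equal shape.
#' @return Named numeric vector `precision`, `recall`, `agreement`.
#' @export
mask_agreement <- function(predicted, reference) {
  stopifnot(all(dim(predicted) == dim(reference)))
  tp <- sum(predicted & reference)
  c(precision = tp / max(sum(predicted), 1L),
    recall = tp / max(sum(reference), 1L),
    agreement = mean(predicted == reference))
}
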