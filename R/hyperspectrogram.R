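#' Fit a PCA model to a pixel matrix
#'
#' Mean-centred principal component analysis via thin singular value
#' decomposition. Eigenvalues are singular value^2 / (n - 1). The sign of
#' each component is fixed so its largest-magnitude loading element is
#' positive, making the decomposition deterministic across runs.
#'
#' @param X A `pixel_matrix` from [unfold()] or a plain numeric matrix
#'   (rows = observations/pixels, columns = bands).
#' @param A Number of components to retain, `1 <= A <= min(n, b)`.
#' @return An object of class `pca_model`: list with `mean` (length b),
#'   `loadings` (A x b, orthonormal rows), `eigenvalues` (length A,
#'   non-increasing), `A`, `n_obs`.
#' @export
fit_pca <- function(X, A = 3L) {
  X <- .as_matrix(X)
  n <- nrow(X); b <- ncol(X)
  A <- as.integer(A)
  if (A < 1 || A > min(n, b))
    stop("A must be between 1 and min(n_pixels, bands) = ", min(n, b))
  if (!all(is.finite(X))) stop("pixel matrix contains non-finite values")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = A)
  loadings <- t(sv$v)                       # A x b
  eig <- (sv$d[seq_len(A)]^2) / max(n - 1, 1)
  # deterministic sign: largest-magnitude element of each loading positive
  for (a in seq_len(A)) {
    j <- which.max(abs(loadings[a, ]))
    if (loadings[a, j] < 0) loadings[a, ] <- -loadings[a, ]
  }
  structure(list(mean = mu, loadings = loadings, eigenvalues = eig,
                 A = A, n_obs = n),
            class = "pca_model")
}

.as_matrix <- function(X) {
  if (inherits(X, "pixel_matrix")) X$values else as.matrix(X)
}

.check_bands <- function(model, X) {
  if (ncol(X) != length(model$mean))
    stop("band count of the data (", ncol(X),
         ") does not match the fitted model (", length(model$mean), ")")
}

#' Project data onto a fitted PCA model
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param X A `pixel_matrix` or numeric matrix with matching band count.
#' @return Score matrix (n x A): `(X - mean) %*% t(loadings)`.
#' @export
pca_scores <- function(model, X) {
  X <- .as_matrix(X)
  .check_bands(model, X)
  sweep(X, 2, model$mean) %*% t(model$loadings)
}

#' Q residual (squared reconstruction error) per pixel
#'
#' Distance of each spectrum off the PCA model plane:
#' `Q_p = ||x_p - mean - t_p %*% loadings||^2`.
#'
#' @inheritParams pca_scores
#' @return Non-negative numeric vector of length n.
#' @export
q_residual <- function(model, X) {
  X <- .as_matrix(X)
  .check_bands(model, X)
  Xc <- sweep(X, 2, model$mean)
  res <- Xc - (Xc %*% t(model$loadings)) %*% model$loadings
  rowSums(res^2)
}

#' Hotelling T-squared per pixel
#'
#' Mahalanobis-like distance within the retained score space:
#' `T2_p = sum_a t_{p,a}^2 / lambda_a`.
#'
#' @inheritParams pca_scores
#' @return Non-negative numeric vector of length n.
#' @export
hotelling_t2 <- function(model, X) {
  if (any(model$eigenvalues <= max(model$eigenvalues) * 1e-12))
    stop("Hotelling T2 undefined: a retained component has zero eigenvalue")
  t_sc <- pca_scores(model, X)
  rowSums(sweep(t_sc^2, 2, model$eigenvalues, "/"))
}

#' Build the hyperspectrogram of a pixel matrix
#'
#' Concatenates, in sequence: the A loading vectors (A*b values), the
#' distribution curve of the scores of each component, the distribution
#' curve of the Q residuals, and the distribution curve of the Hotelling
#' T-squared values. With `distribution = "quantile"` (default) each curve
#' is the sorted vector of per-pixel values (length n_pixels), so the
#' total signal length is `A*b + (A + 2) * n_pixels` — `A*b + 5*n_pixels`
#' for the standard A = 3. With `distribution = "histogram"` each curve is
#' a fixed 100-bin frequency histogram instead.
#'
#' @param model A `pca_model` fitted on the same band grid.
#' @param X A `pixel_matrix` or numeric matrix.
#' @param distribution `"quantile"` (sorted per-pixel curves) or
#'   `"histogram"` (100-bin counts).
#' @param bins Number of histogram bins when `distribution = "histogram"`.
#' @return An object of class `hyperspectrogram`: list with `signal`
#'   (numeric vector) and `segments` (named list of index ranges
#'   `c(start, end)` into `signal`, in order).
#' @export
build_hyperspectrogram <- function(model, X, distribution = c("quantile", "histogram"),
                                   bins = 100L) {
  distribution <- match.arg(distribution)
  X <- .as_matrix(X)
  .check_bands(model, X)
  A <- model$A; b <- length(model$mean); n <- nrow(X)
  t_sc <- pca_scores(model, X)
  q <- q_residual(model, X)
  t2 <- hotelling_t2(model, X)
  curve <- function(v) {
    if (distribution == "quantile") return(sort(v))
    rng <- range(v)
    if (diff(rng) == 0) return(c(length(v), numeric(bins - 1)))
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    idx <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), bins)
    as.numeric(tabulate(idx, nbins = bins))
  }
  pieces <- c(
    list(loadings = as.vector(t(model$loadings))),
    stats::setNames(lapply(seq_len(A), function(a) curve(t_sc[, a])),
                    paste0("score_dist_pc", seq_len(A))),
    list(q_dist = curve(q), t2_dist = curve(t2))
  )
  lens <- vapply(pieces, length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  segments <- Map(function(s, e) c(start = s, end = e), starts, ends)
  structure(list(signal = unlist(pieces, use.names = FALSE),
                 segments = segments),
            class = "hyperspectrogram")
}

#' Hyperspectrogram length for given cube dimensions
#'
#' `A*bands + 5*lines*samples` for the quantile-curve construction with
#' three score curves plus Q and T-squared curves.
#'
#' @param lines,samples,bands Cube dimensions.
#' @param A Number of retained components.
#' @return Integer signal length.
#' @export
hyperspectrogram_length <- function(lines, samples, bands, A = 3L) {
  A * bands + (A + 2) * lines * samples
}

#' Hypercube-to-hyperspectrogram compression ratio
#'
#' Ratio of the number of values in the cube to the number in its
#' hyperspectrogram, `(lines*samples*bands) / (A*bands + 5*lines*samples)`
#' for A = 3, reported to one decimal place.
#'
#' @inheritParams hyperspectrogram_length
#' @return Compression ratio rounded to 1 decimal.
#' @export
compression_ratio <- function(lines, samples, bands, A = 3L) {
  stopifnot(lines > 0, samples > 0, bands > 0, A > 0)
  round((lines * samples * bands) /
          hyperspectrogram_length(lines, samples, bands, A), 1)
}

#' Reconstruct the spatial image of one principal component
#'
#' Folds the scores of a chosen component back to the spatial frame and
#' min-max scales them to [0, 1] for display. Latent bruises invisible in
#' broadband images typically appear as contrasted discs in PC2/PC3 score
#' images.
#'
#' @param model A `pca_model`.
#' @param X A `pixel_matrix` unfolded row-major from `shape`, or a matrix.
#' @param component Component index (1..A).
#' @param shape Integer pair (lines, samples).
#' @return A (lines x samples) matrix of scores scaled to [0, 1].
#' @export
score_image <- function(model, X, component, shape) {
  if (component < 1 || component > model$A)
    stop("component must be in 1..", model$A)
  sc <- pca_scores(model, X)[, component]
  if (length(sc) != prod(shape))
    stop("shape inconsistent with number of pixels")
  img <- fold_image(sc, shape)
  rng <- range(img)
  if (diff(rng) == 0) return(img * 0)
  (img - rng[1]) / diff(rng)
}

#' Bruise contrast of a score image
#'
#' Standardised difference between mean score inside and outside a region:
#' `|mean_in - mean_out| / pooled SD`. Used to quantify whether a
#' principal-component image reveals a bruise.
#'
#' @param image Numeric matrix (a score or band image).
#' @param region Logical matrix marking the region (e.g. bruise mask).
#' @param within Optional logical matrix restricting "outside" pixels
#'   (e.g. the fruit mask).
#' @return Non-negative scalar contrast in pooled-SD units.
#' @export
region_contrast <- function(image, region, within = NULL) {
  stopifnot(all(dim(image) == dim(region)))
  outside <- if (is.null(within)) !region else within & !region
  a <- image[region]; b <- image[outside]
  if (length(a) < 2 || length(b) < 2) stop("region or complement too small")
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  abs(mean(a) - mean(b)) / max(sp, .Machine$double.eps)
}
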