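# Separable convolution with reflective (edge-inclusive symmetric) padding.
# ky acts along rows (y), kx along columns (x).
conv_sep <- function(m, ky, kx) {
  nr <- nrow(m); nc <- ncol(m)
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  out <- m
  if (ry > 0L) {
    ridx <- c(ry:1, 1:nr, nr:(nr - ry + 1L))
    p <- out[ridx, , drop = FALSE]
    out <- matrix(0, nr, nc)
    for (t in seq_along(ky))
      out <- out + ky[t] * p[t:(t + nr - 1L), , drop = FALSE]
  } else {
    out <- ky * out
  }
  if (rx > 0L) {
    cidx <- c(rx:1, 1:nc, nc:(nc - rx + 1L))
    p <- out[, cidx, drop = FALSE]
    out2 <- matrix(0, nr, nc)
    for (t in seq_along(kx))
      out2 <- out2 + kx[t] * p[, t:(t + nc - 1L), drop = FALSE]
    out <- out2
  } else {
    out <- kx * out
  }
  out
}

# Sampled Gaussian and its first/second derivatives, normalized so the
# smoothing kernel sums to 1 (derivative kernels share the constant).
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  z <- sum(g)
  g1 <- (-t / sigma^2) * g / z
  g2 <- ((t^2 - sigma^2) / sigma^4) * g / z
  # enforce zero DC response so constants are annihilated exactly despite
  # kernel truncation
  g2 <- g2 - sum(g2) / length(g2)
  list(g = g / z, g1 = g1, g2 = g2)
}

#' Hessian vesselness enhancement
#'
#' Frangi-type tubularity filter: at each scale the image is convolved with
#' Gaussian second-derivative kernels, the Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2|} are formed with scale normalization
#' (\eqn{\sigma^2}), and the vesselness response for bright curvilinear
#' structures (\eqn{\lambda_2 < 0}) is
#' \deqn{V = \exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2)),}
#' with blobness \eqn{R_b = \lambda_1/\lambda_2}, structureness
#' \eqn{S = \sqrt{\lambda_1^2+\lambda_2^2}} and \eqn{c} set to half the
#' maximal \eqn{S} at that scale. The final response is the pixel-wise
#' maximum over scales. A constant image has no second-derivative structure
#' and yields an identically zero response; adding a constant offset to the
#' input leaves the response unchanged.
#'
#' @param img An `en_face_angiogram`.
#' @param scales Gaussian scales in pixels; defaults to `c(1, 2)`, matched
#'   to capillary calibres of roughly 1-4 px at 3/304 mm/px.
#' @param beta Blobness sensitivity (default 0.5).
#' @return An `en_face_angiogram` holding the vesselness response rescaled
#'   to \[0, 1\] (an all-zero image if there is no structure).
#' @export
hessian_vesselness <- function(img, scales = c(1, 2), beta = 0.5) {
  stopifnot(inherits(img, "en_face_angiogram"))
  if (length(scales) == 0L || any(scales <= 0))
    octamv_stop("`scales` must be a non-empty vector of positive pixel scales",
                "octamv_invalid_parameter")
  m <- img$intensity
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    k <- gauss_kernels(s)
    ixx <- s^2 * conv_sep(m, k$g, k$g2)
    iyy <- s^2 * conv_sep(m, k$g2, k$g)
    ixy <- s^2 * conv_sep(m, k$g1, k$g1)
    half_tr <- (ixx + iyy) / 2
    root <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
    mu1 <- half_tr + root
    mu2 <- half_tr - root
    swap <- abs(mu1) > abs(mu2)
    lam1 <- ifelse(swap, mu2, mu1)  # smaller magnitude
    lam2 <- ifelse(swap, mu1, mu2)  # larger magnitude
    s2 <- lam1^2 + lam2^2
    smax <- sqrt(max(s2))
    if (smax <= 1e-12) next  # numerically structureless (constant input)
    cc <- smax / 2
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[lam2 >= 0] <- 0
    best <- pmax(best, v)
  }
  vmax <- max(best)
  if (vmax > 0) best <- best / vmax
  out <- img
  out$intensity <- best
  out
}

#' Local-median adaptive binarization
#'
#' A pixel is on iff its intensity strictly exceeds the exact median of its
#' `window_px` x `window_px` neighbourhood plus `offset`. Borders are handled
#' by reflective padding. On a constant image nothing exceeds its own median,
#' so the result is all-off; raising `offset` can only turn pixels off.
#'
#' @param img An `en_face_angiogram`.
#' @param window_px Odd window size >= 3 (default 31, roughly ten capillary
#'   widths at the default geometry).
#' @param offset Added to the local median before comparison (default 0).
#' @return A `binary_vessel_map` with provenance `"median"`.
#' @export
local_median_binarize <- function(img, window_px = 31L, offset = 0) {
  stopifnot(inherits(img, "en_face_angiogram"))
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 3L || window_px %% 2L == 0L)
    octamv_stop("`window_px` must be an odd integer >= 3", "octamv_invalid_parameter")
  med <- local_median_cpp(img$intensity, window_px)
  binary_vessel_map(img$intensity > med + offset, img$pixel_size, "median")
}

#' Intersect two binary vessel maps
#'
#' Pixel-wise AND of the two binarization branches; only pixels flagged as
#' vessel by both are retained. Commutative and idempotent.
#'
#' @param a,b `binary_vessel_map`s with identical geometry.
#' @return A `binary_vessel_map` with provenance `"combined"`.
#' @export
combine_binaries <- function(a, b) {
  stopifnot(inherits(a, "binary_vessel_map"), inherits(b, "binary_vessel_map"))
  check_same_geometry(a, b, "binary maps")
  binary_vessel_map(a$mask & b$mask, a$pixel_size, "combined")
}

#' Threshold a vesselness response
#'
#' Global threshold on the enhanced image; by default Otsu's method on a
#' 256-bin histogram (via \code{EBImage::otsu}), or a fixed absolute value.
#' An all-zero response yields an all-off map.
#'
#' @param enhanced An `en_face_angiogram` holding a vesselness response in
#'   \[0, 1\].
#' @param threshold `"otsu"` or a number in \[0, 1\].
#' @return A `binary_vessel_map` with provenance `"hessian"`.
#' @export
threshold_vesselness <- function(enhanced, threshold = "otsu") {
  stopifnot(inherits(enhanced, "en_face_angiogram"))
  v <- enhanced$intensity
  if (identical(threshold, "otsu")) {
    if (max(v) == min(v)) {
      return(binary_vessel_map(matrix(FALSE, nrow(v), ncol(v)),
                               enhanced$pixel_size, "hessian"))
    }
    thr <- EBImage::otsu(v, range = c(0, 1))
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      octamv_stop("`threshold` must be \"otsu\" or a single number",
                  "octamv_invalid_parameter")
    thr <- threshold
  }
  binary_vessel_map(v > thr, enhanced$pixel_size, "hessian")
}

#' Dual binarization of an en-face angiogram
#'
#' The production vessel map: the intersection of (i) a thresholded
#' Frangi-type Hessian vesselness response and (ii) a local-median adaptive
#' threshold of the raw image. The Hessian branch enhances curvilinear
#' structure at capillary scales; the median branch suppresses diffuse
#' background and large bright blobs. The combined map is by construction a
#' subset of each branch.
#'
#' @param img An `en_face_angiogram`.
#' @param scales Vesselness scales in px.
#' @param vessel_threshold `"otsu"` or an absolute threshold for the
#'   vesselness branch.
#' @param window_px,offset Local-median parameters.
#' @return A `binary_vessel_map` with provenance `"combined"`.
#' @export
binarize_dual <- function(img, scales = c(1, 2), vessel_threshold = "otsu",
                          window_px = 31L, offset = 0) {
  h <- threshold_vesselness(hessian_vesselness(img, scales), vessel_threshold)
  m <- local_median_binarize(img, window_px, offset)
  combine_binaries(h, m)
}
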