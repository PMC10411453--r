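# Run code with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    octamv_stop("`seed` must be a single integer", "octamv_invalid_parameter")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

seg_lengths <- function(segments) {
  sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2)
}

new_vessel_tree <- function(segments, field_mm, faz_centre, faz_radius,
                            capillary_width, dropout_fraction, seed) {
  structure(
    list(segments = segments,
         total_centerline_length = sum(seg_lengths(segments)),
         field_mm = field_mm,
         faz_centre = faz_centre, faz_radius = faz_radius,
         capillary_width = capillary_width,
         dropout_fraction = dropout_fraction, seed = seed),
    class = "vessel_tree_truth")
}

#' @export
print.vessel_tree_truth <- function(x, ...) {
  cat(sprintf(paste0("<vessel_tree_truth> %d segments, %.2f mm centreline, ",
                     "FAZ radius %.2f mm, dropout %.2f (seed %d)\n"),
              nrow(x$segments), x$total_centerline_length, x$faz_radius,
              x$dropout_fraction, x$seed))
  invisible(x)
}

# First entry of segment A->B into the disc of radius r about the origin,
# as parameter t in (0, 1], or NA if the segment stays outside.
disc_entry_t <- function(ax, ay, bx, by, r) {
  dx <- bx - ax; dy <- by - ay
  a <- dx^2 + dy^2
  if (a == 0) return(NA_real_)
  b <- 2 * (ax * dx + ay * dy)
  cc <- ax^2 + ay^2 - r^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  if (t1 > 0 && t1 <= 1) t1 else NA_real_
}

#' Generate a synthetic macular vessel tree
#'
#' Grows a stochastic branching vascular network over a square field:
#' arteriolar trunks enter from the four field edges and branch toward the
#' centre, segment widths shrinking geometrically with branch depth, all
#' centrelines avoiding a central avascular disc (the FAZ). The output is
#' ground truth for the quantities measured downstream: exact per-segment
#' endpoints and widths, total centreline length, and the FAZ disc.
#'
#' This emulates the geometry of the macular capillary bed well enough to
#' exercise vessel quantification; it makes no claim of anatomical or
#' hemodynamic fidelity.
#'
#' @param seed RNG seed; the tree is bit-reproducible given the seed.
#' @param field_mm Field width in mm (default 3).
#' @param faz_radius Radius of the central avascular disc in mm
#'   (default 0.32, i.e. an area close to a typical healthy FAZ).
#' @param params Branching parameters overriding the defaults:
#'   `n_entries` (trunks per field, default 4), `trunk_width` and
#'   `width_decay` (mm; geometric width decrease per depth), `min_width`
#'   (mm floor), `seg_len` (min/max segment length, mm), `branch_prob`
#'   (bifurcation probability per step), `branch_angle` (min/max split
#'   half-angle, degrees), `jitter_sd` (heading jitter, degrees),
#'   `max_depth`, and `capillary_width` (mm; segments thinner than this are
#'   droppable capillaries).
#' @return A `vessel_tree_truth` object.
#' @export
generate_vessel_tree <- function(seed, field_mm = 3, faz_radius = 0.32,
                                 params = list()) {
  if (field_mm <= 0)
    octamv_stop("`field_mm` must be positive", "octamv_invalid_parameter")
  if (faz_radius < 0 || faz_radius >= field_mm / 2)
    octamv_stop("`faz_radius` must lie in [0, field_mm/2)", "octamv_invalid_parameter")
  p <- modifyList(list(
    n_entries = 4L, trunk_width = 0.045, width_decay = 0.80,
    min_width = 0.010, seg_len = c(0.18, 0.32), branch_prob = 0.75,
    branch_angle = c(20, 40), jitter_sd = 9, max_depth = 7L,
    capillary_width = 0.025), params)
  if (p$trunk_width <= 0 || p$min_width <= 0)
    octamv_stop("widths must be positive", "octamv_invalid_parameter")

  half <- field_mm / 2
  with_seed(seed, {
    # entry points: one mid-edge point per side, jittered along the edge
    sides <- rep_len(1:4, p$n_entries)
    offs <- runif(p$n_entries, -0.5, 0.5) * half
    entry <- lapply(seq_len(p$n_entries), function(k) {
      switch(sides[k],
        list(x = offs[k], y = -half, ang = pi / 2),   # top edge, heading down
        list(x = half, y = offs[k], ang = pi),        # right edge, heading left
        list(x = offs[k], y = half, ang = -pi / 2),   # bottom edge, heading up
        list(x = -half, y = offs[k], ang = 0))        # left edge, heading right
    })
    segs <- vector("list", 4096L)
    nseg <- 0L
    queue <- lapply(entry, function(e)
      list(x = e$x, y = e$y, ang = e$ang + runif(1, -0.3, 0.3), depth = 0L))
    while (length(queue) > 0L) {
      tip <- queue[[1L]]; queue <- queue[-1L]
      if (tip$depth > p$max_depth) next
      width <- max(p$min_width, p$trunk_width * p$width_decay^tip$depth)
      len <- runif(1, p$seg_len[1], p$seg_len[2])
      ang <- tip$ang + rnorm(1, 0, p$jitter_sd * pi / 180)
      bx <- tip$x + len * cos(ang); by <- tip$y + len * sin(ang)
      terminate <- FALSE
      # clip to the field
      tmax <- 1
      if (abs(bx) > half) tmax <- min(tmax, (sign(bx) * half - tip$x) / (bx - tip$x))
      if (abs(by) > half) tmax <- min(tmax, (sign(by) * half - tip$y) / (by - tip$y))
      if (tmax < 1) terminate <- TRUE
      # stop at the FAZ boundary (centrelines never enter the disc)
      tf <- disc_entry_t(tip$x, tip$y, tip$x + tmax * (bx - tip$x),
                         tip$y + tmax * (by - tip$y), faz_radius)
      if (!is.na(tf)) { tmax <- tmax * (tf - 1e-6); terminate <- TRUE }
      if (tmax <= 0.05) next
      bx <- tip$x + tmax * (bx - tip$x); by <- tip$y + tmax * (by - tip$y)
      nseg <- nseg + 1L
      segs[[nseg]] <- c(tip$x, tip$y, bx, by, width, tip$depth)
      if (terminate) next
      if (runif(1) < p$branch_prob) {
        da <- runif(1, p$branch_angle[1], p$branch_angle[2]) * pi / 180
        queue <- c(queue,
                   list(list(x = bx, y = by, ang = ang - da, depth = tip$depth + 1L),
                        list(x = bx, y = by, ang = ang + da, depth = tip$depth + 1L)))
      } else {
        queue <- c(queue,
                   list(list(x = bx, y = by, ang = ang, depth = tip$depth + 1L)))
      }
    }
    segments <- as.data.frame(do.call(rbind, segs[seq_len(nseg)]))
    names(segments) <- c("x0", "y0", "x1", "y1", "width", "depth")
    new_vessel_tree(segments, field_mm, c(0, 0), faz_radius,
                    p$capillary_width, 0, as.integer(seed))
  })
}

#' Apply capillary dropout to a vessel tree
#'
#' Removes a fraction of the droppable (capillary-calibre) segments,
#' emulating the patchy capillary nonperfusion seen with worsening diabetic
#' retinopathy. Only segments thinner than the tree's `capillary_width` are
#' eligible; trunks are protected. For a fixed seed the removal order is a
#' fixed permutation, so masks at increasing fractions are nested and the
#' remaining centreline length is non-increasing in the fraction.
#'
#' @param tree A `vessel_tree_truth`.
#' @param fraction Fraction of droppable segments to remove, in \[0, 1\].
#' @param seed RNG seed for the removal order.
#' @return A `vessel_tree_truth` with `dropout_fraction` recorded.
#' @export
apply_dropout <- function(tree, fraction, seed) {
  stopifnot(inherits(tree, "vessel_tree_truth"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    octamv_stop("`fraction` must lie in [0, 1]", "octamv_invalid_parameter")
  droppable <- which(tree$segments$width < tree$capillary_width)
  n_drop <- round(fraction * length(droppable))
  if (n_drop > 0L) {
    order_drop <- with_seed(seed, sample(droppable))
    keep <- setdiff(seq_len(nrow(tree$segments)), order_drop[seq_len(n_drop)])
    tree$segments <- tree$segments[keep, , drop = FALSE]
    rownames(tree$segments) <- NULL
    tree$total_centerline_length <- sum(seg_lengths(tree$segments))
  }
  tree$dropout_fraction <- fraction
  tree
}

#' Rasterize a vessel tree to a binary mask
#'
#' Ground-truth rasterization: a pixel is on iff its centre lies within half
#' a segment width of any segment centreline.
#'
#' @param tree A `vessel_tree_truth`.
#' @param width_px Raster width in pixels (square grid).
#' @return A `binary_vessel_map` holding the ground-truth vessel mask.
#' @export
rasterize_tree <- function(tree, width_px) {
  px <- tree$field_mm / width_px
  pc <- pixel_centres(width_px, width_px, px)
  mask <- matrix(FALSE, width_px, width_px)
  for (i in seq_len(nrow(tree$segments))) {
    s <- tree$segments[i, ]
    r <- s$width / 2
    xr <- range(s$x0, s$x1); yr <- range(s$y0, s$y1)
    jj <- which(pc$x >= xr[1] - r - px & pc$x <= xr[2] + r + px)
    ii <- which(pc$y >= yr[1] - r - px & pc$y <= yr[2] + r + px)
    if (!length(ii) || !length(jj)) next
    gx <- outer(rep(1, length(ii)), pc$x[jj])
    gy <- outer(pc$y[ii], rep(1, length(jj)))
    dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
    L2 <- dx^2 + dy^2
    tt <- if (L2 == 0) gx * 0 else
      pmin(1, pmax(0, ((gx - s$x0) * dx + (gy - s$y0) * dy) / L2))
    d2 <- (gx - (s$x0 + tt * dx))^2 + (gy - (s$y0 + tt * dy))^2
    mask[ii, jj] <- mask[ii, jj] | (d2 <= r^2)
  }
  binary_vessel_map(mask, px, "combined")
}

#' Render a vessel tree as an en-face angiogram
#'
#' Rasterizes the tree at its segment widths, then applies a simple OCTA-like
#' noise model: multiplicative speckle on the vessel signal plus an additive
#' Gaussian background, clipped to \[0, 1\]. With all noise parameters zero
#' the rendered intensities are exactly the rasterized mask (vessel = 1,
#' background = 0).
#'
#' @param tree A `vessel_tree_truth`.
#' @param width_px Raster width in pixels, >= 64 (default 304 over a 3 mm
#'   field, i.e. the standard 3 x 3 mm scan raster).
#' @param noise List overriding the defaults `background` (mean background
#'   level, 0.10), `background_sd` (additive Gaussian SD, 0.04) and
#'   `speckle_sd` (multiplicative speckle SD on the vessel signal, 0.25).
#' @param seed RNG seed for the noise.
#' @param layer Layer tag attached to the image.
#' @return An `en_face_angiogram`.
#' @export
render_angiogram <- function(tree, width_px = 304L, noise = list(), seed = 1L,
                             layer = "SCP") {
  stopifnot(inherits(tree, "vessel_tree_truth"))
  width_px <- as.integer(width_px)
  if (is.na(width_px) || width_px < 64L)
    octamv_stop("`width_px` must be an integer >= 64", "octamv_invalid_parameter")
  nz <- modifyList(list(background = 0.10, background_sd = 0.04,
                        speckle_sd = 0.25), noise)
  mask <- rasterize_tree(tree, width_px)$mask
  base <- ifelse(mask, 1, 0)
  img <- with_seed(seed, {
    n <- length(base)
    sig <- base * (1 + nz$speckle_sd * rnorm(n))
    sig + nz$background + nz$background_sd * rnorm(n)
  })
  img <- matrix(pmin(1, pmax(0, img)), width_px, width_px)
  en_face_angiogram(img, pixel_size = tree$field_mm / width_px, layer = layer)
}
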