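# Neighbour views of a logical matrix, padded with FALSE outside the grid.
# Returns function nb(dr, dc) -> matrix of neighbour values at that offset.
make_nb <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  function(dr, dc) P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
}

# One Guo-Hall subiteration; returns the updated mask.
guo_hall_sub <- function(m, odd) {
  nb <- make_nb(m)
  p2 <- nb(-1L, 0L); p3 <- nb(-1L, 1L); p4 <- nb(0L, 1L); p5 <- nb(1L, 1L)
  p6 <- nb(1L, 0L); p7 <- nb(1L, -1L); p8 <- nb(0L, -1L); p9 <- nb(-1L, -1L)
  C  <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N  <- pmin(N1, N2)
  O  <- if (odd) (p2 | p3 | !p5) & p4 else (p6 | p7 | !p9) & p8
  m & !(C == 1 & N >= 2 & N <= 3 & !O)
}

# Exact 8-simple test for pixel (i, j) of padded matrix P (foreground
# 8-connected, background 4-connected): deleting the pixel preserves
# topology iff its neighbourhood foreground forms exactly one 8-connected
# component and exactly one 4-connected background component is 4-adjacent
# to the pixel. Endpoints (fewer than 2 neighbours) are never deleted.
is_simple_point <- function(P, i, j) {
  di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  fg <- logical(8L)
  for (k in 1:8) fg[k] <- P[i + di[k], j + dj[k]]
  if (sum(fg) < 2L) return(FALSE)
  comp_labels <- function(idx, conn8) {
    lab <- integer(length(idx)); nxt <- 0L
    for (s in seq_along(idx)) {
      if (lab[s] > 0L) next
      nxt <- nxt + 1L; stack <- s; lab[s] <- nxt
      while (length(stack)) {
        u <- stack[1L]; stack <- stack[-1L]
        for (v in seq_along(idx)) {
          if (lab[v] == 0L) {
            ddi <- abs(di[idx[u]] - di[idx[v]])
            ddj <- abs(dj[idx[u]] - dj[idx[v]])
            adj <- if (conn8) max(ddi, ddj) == 1L else ddi + ddj == 1L
            if (adj) { lab[v] <- nxt; stack <- c(stack, v) }
          }
        }
      }
    }
    lab
  }
  fg_idx <- which(fg)
  if (max(comp_labels(fg_idx, TRUE)) != 1L) return(FALSE)
  bg_idx <- which(!fg)
  orth <- c(2L, 4L, 5L, 7L)             # positions at Manhattan distance 1
  if (!any(bg_idx %in% orth)) return(FALSE)
  bg_lab <- comp_labels(bg_idx, FALSE)
  length(unique(bg_lab[bg_idx %in% orth])) == 1L
}

# Remove redundant pixels so no 2x2 all-on block survives, deleting only
# simple points to preserve topology.
prune_2x2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    blocks <- which(m[-nr, -nc] & m[-1, -nc] & m[-nr, -1] & m[-1, -1],
                    arr.ind = TRUE)
    if (nrow(blocks) == 0L) return(m)
    P <- matrix(FALSE, nr + 2L, nc + 2L)
    P[2:(nr + 1L), 2:(nc + 1L)] <- m
    removed <- FALSE
    for (b in seq_len(nrow(blocks))) {
      for (d in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        i <- blocks[b, 1L] + d[1L]; j <- blocks[b, 2L] + d[2L]
        if (!P[i + 1L, j + 1L]) next
        if (is_simple_point(P, i + 1L, j + 1L)) {
          P[i + 1L, j + 1L] <- FALSE
          m[i, j] <- FALSE
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) return(m)  # nothing deletable without breaking topology
  }
}

#' Skeletonize a binary vessel map
#'
#' Topology-preserving thinning (Guo-Hall two-subiteration scheme): pixels on
#' the outer boundary of the vessel mask are deleted iteratively until the
#' vessels are one pixel wide, preserving connectivity. A conservative
#' post-pass removes any residual pixel that leaves a 2x2 all-on block,
#' deleting only simple points, so the result contains no 2x2 block.
#'
#' @param map A `binary_vessel_map`.
#' @return A `skeleton_map`: the 1-px-wide centreline subset of `map`.
#' @export
skeletonize <- function(map) {
  stopifnot(inherits(map, "binary_vessel_map"))
  m <- map$mask
  repeat {
    before <- m
    m <- guo_hall_sub(m, odd = TRUE)
    m <- guo_hall_sub(m, odd = FALSE)
    if (identical(m, before)) break
  }
  m <- prune_2x2(m)
  structure(list(mask = m, pixel_size = map$pixel_size,
                 source = map$provenance),
            class = c("skeleton_map"))
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %d x %d px, %d centreline pixels (source: %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$source))
  invisible(x)
}

#' Skeleton length
#'
#' Length of the centreline within an optional region. The default `"count"`
#' metric is the on-pixel count (times the pixel size if `units = "mm"`),
#' matching the percent scale of skeleton vessel density. The `"geodesic"`
#' metric instead sums the 8-neighbour chain: each orthogonal link adds 1 px
#' and each diagonal link adds sqrt(2) px (links are shared between the two
#' pixels, so each contributes half a link length to each endpoint).
#'
#' @param skel A `skeleton_map`.
#' @param region Optional `region_mask` restricting the measurement.
#' @param metric `"count"` or `"geodesic"`.
#' @param units `"px"` or `"mm"`.
#' @return Length as a single number.
#' @export
skeleton_length <- function(skel, region = NULL,
                            metric = c("count", "geodesic"),
                            units = c("px", "mm")) {
  stopifnot(inherits(skel, "skeleton_map"))
  metric <- match.arg(metric)
  units <- match.arg(units)
  m <- skel$mask
  if (!is.null(region)) {
    check_same_geometry(skel, region, "skeleton and region")
    m <- m & region$mask
  }
  len <- if (metric == "count") {
    sum(m)
  } else {
    nb <- make_nb(m)
    orth <- sum(m & nb(-1L, 0L)) + sum(m & nb(0L, 1L)) +
            sum(m & nb(1L, 0L)) + sum(m & nb(0L, -1L))
    diag <- sum(m & nb(-1L, 1L)) + sum(m & nb(1L, 1L)) +
            sum(m & nb(1L, -1L)) + sum(m & nb(-1L, -1L))
    # each link counted twice (once from each endpoint)
    orth / 2 + sqrt(2) * diag / 2
  }
  if (units == "mm") len * skel$pixel_size else len
}
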