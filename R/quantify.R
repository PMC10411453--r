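#' Perfusion density (PD, %)
#'
#' Percentage of vessel (white) pixels among all pixels of the region in the
#' binarized angiogram: `PD = 100 * on-pixels-in-region / region-pixels`.
#'
#' @param map A `binary_vessel_map`.
#' @param region A `region_mask` with the same geometry.
#' @param layer Optional layer tag carried into the result.
#' @return A one-row `quant_result` data frame (metric `PD`, %).
#' @export
perfusion_density <- function(map, region, layer = NA_character_) {
  stopifnot(inherits(map, "binary_vessel_map"), inherits(region, "region_mask"))
  check_same_geometry(map, region, "map and region")
  n_region <- sum(region$mask)
  if (n_region == 0L)
    octamv_stop("region is empty", "octamv_degenerate_region")
  quant_result("PD", 100 * sum(map$mask & region$mask) / n_region, "%",
               region = region$label, layer = layer)
}

#' Skeleton vessel density (SVD, %)
#'
#' Skeletonized vessel length divided by the region area excluding the FAZ,
#' as a percentage:
#' \deqn{SVD = 100 \cdot L / (A_{region} - A_{FAZ}).}
#' With the default count-based length metric both numerator and denominator
#' are in pixel units, so SVD with an empty FAZ reduces to PD applied to the
#' skeleton. Because the skeleton is caliber-free, SVD is insensitive to
#' vessel diameter.
#'
#' @param skel A `skeleton_map`.
#' @param faz `region_mask` of the foveal avascular zone (may be empty).
#' @param region `region_mask` over which to measure (default full frame).
#' @param metric Length metric passed to [skeleton_length()].
#' @param layer Optional layer tag.
#' @return A one-row `quant_result` data frame (metric `SVD`, %).
#' @export
skeleton_vessel_density <- function(skel, faz, region = NULL,
                                    metric = c("count", "geodesic"),
                                    layer = NA_character_) {
  stopifnot(inherits(skel, "skeleton_map"), inherits(faz, "region_mask"))
  metric <- match.arg(metric)
  if (is.null(region))
    region <- full_frame_mask(nrow(skel$mask), ncol(skel$mask), skel$pixel_size)
  check_same_geometry(skel, region, "skeleton and region")
  check_same_geometry(skel, faz, "skeleton and FAZ")
  denom <- sum(region$mask) - sum(region$mask & faz$mask)
  if (denom <= 0L)
    octamv_stop("region is entirely covered by the FAZ", "octamv_degenerate_region")
  len <- skeleton_length(skel, region, metric = metric, units = "px")
  quant_result("SVD", 100 * len / denom, "%", region = region$label,
               layer = layer)
}

#' Quantify an en-face angiogram
#'
#' Runs the full quantification chain on one image: dual binarization,
#' skeletonization, then PD, SVD (FAZ-excluded) and FAZ area for the
#' requested regions.
#'
#' @param img An `en_face_angiogram`.
#' @param faz `region_mask` of the FAZ (empty mask if not applicable).
#' @param regions Character vector of regions to quantify: `"full"` and/or
#'   `"parafovea"`.
#' @param scales,vessel_threshold,window_px,offset Dual-binarization
#'   parameters, see [binarize_dual()].
#' @param metric SVD length metric.
#' @return A `quant_result` data frame with one row per metric x region.
#' @export
quantify_image <- function(img, faz = NULL, regions = "full",
                           scales = c(1, 2), vessel_threshold = "otsu",
                           window_px = 31L, offset = 0,
                           metric = c("count", "geodesic")) {
  stopifnot(inherits(img, "en_face_angiogram"))
  metric <- match.arg(metric)
  nr <- nrow(img$intensity); nc <- ncol(img$intensity)
  if (is.null(faz))
    faz <- region_mask(matrix(FALSE, nr, nc), img$pixel_size, "FAZ")
  bad <- setdiff(regions, c("full", "parafovea"))
  if (length(bad))
    octamv_stop(paste("unknown region:", paste(bad, collapse = ", ")),
                "octamv_invalid_parameter")
  vmap <- binarize_dual(img, scales, vessel_threshold, window_px, offset)
  skel <- skeletonize(vmap)
  out <- list()
  for (rg in regions) {
    region <- switch(rg,
      full = full_frame_mask(nr, nc, img$pixel_size),
      parafovea = parafovea_mask(nr, nc, img$pixel_size))
    out[[length(out) + 1L]] <-
      perfusion_density(vmap, region, layer = img$layer)
    out[[length(out) + 1L]] <-
      skeleton_vessel_density(skel, faz, region, metric, layer = img$layer)
  }
  out[[length(out) + 1L]] <- within(faz_area(faz), layer <- img$layer)
  do.call(rbind, out)
}
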