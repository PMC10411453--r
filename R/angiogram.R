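#' Construct an en-face angiogram
#'
#' An en-face angiogram is a calibrated grayscale perfusion image: a matrix of
#' intensities in \[0, 1\] plus the physical pixel size in mm/px, a vascular
#' layer tag and optional scan-quality (SSI) and eye metadata. The default
#' geometry mirrors the common macular scan pattern: a 3 x 3 mm field sampled
#' at 304 x 304 px, i.e. a pixel size of 3/304 (about 0.00987) mm.
#'
#' @param intensity Numeric matrix with all values in \[0, 1\]. Rows run top to
#'   bottom (y), columns left to right (x).
#' @param pixel_size Pixel edge length in mm/px. Give either this or
#'   `field_mm`.
#' @param field_mm Physical field width in mm; used as
#'   `field_mm / ncol(intensity)` when `pixel_size` is missing.
#' @param layer Vascular layer tag: `"SCP"`, `"DCP"` or `"choroid"`.
#' @param ssi Optional signal strength index (device quality score).
#' @param eye_id,group Optional eye identifier and severity group label.
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(intensity, pixel_size = NULL, field_mm = NULL,
                              layer = c("SCP", "DCP", "choroid"),
                              ssi = NULL, eye_id = NULL, group = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(intensity) || !is.numeric(intensity))
    octamv_stop("`intensity` must be a numeric matrix", "octamv_invalid_parameter")
  if (anyNA(intensity) || min(intensity) < 0 || max(intensity) > 1)
    octamv_stop("intensities must lie in [0, 1] and contain no NA",
                "octamv_invalid_parameter")
  if (is.null(pixel_size)) {
    if (is.null(field_mm))
      octamv_stop("give either `pixel_size` or `field_mm`", "octamv_invalid_parameter")
    pixel_size <- field_mm / ncol(intensity)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    octamv_stop("`pixel_size` must be a single positive number", "octamv_invalid_parameter")
  structure(
    list(intensity = intensity, pixel_size = pixel_size,
         layer = layer, ssi = ssi, eye_id = eye_id, group = group),
    class = "en_face_angiogram"
  )
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<en_face_angiogram> %d x %d px, %.4f mm/px (%.2f mm field), layer %s",
              d[1], d[2], x$pixel_size, d[2] * x$pixel_size, x$layer))
  if (!is.null(x$ssi)) cat(sprintf(", SSI %.1f", x$ssi))
  cat("\n")
  invisible(x)
}

#' @export
dim.en_face_angiogram <- function(x) dim(x$intensity)

# Physical pixel-centre coordinates in mm, origin at the field centre.
# Returns list(x = length-nc vector, y = length-nr vector).
pixel_centres <- function(nr, nc, pixel_size) {
  list(x = (seq_len(nc) - 0.5) * pixel_size - nc * pixel_size / 2,
       y = (seq_len(nr) - 0.5) * pixel_size - nr * pixel_size / 2)
}

#' Construct a binary vessel map
#'
#' @param mask Logical matrix (TRUE = vessel).
#' @param pixel_size Pixel size in mm/px.
#' @param provenance Which binarization branch produced the map:
#'   `"hessian"`, `"median"` or `"combined"`.
#' @return An object of class `binary_vessel_map`.
#' @export
binary_vessel_map <- function(mask, pixel_size,
                              provenance = c("hessian", "median", "combined")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask))
    octamv_stop("`mask` must be a logical matrix without NA", "octamv_invalid_parameter")
  structure(list(mask = mask, pixel_size = pixel_size, provenance = provenance),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map:%s> %d x %d px, %d on-pixels (%.1f%%)\n",
              x$provenance, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Construct a region mask
#'
#' A boolean region of interest (FAZ, parafovea annulus, full frame, or
#' custom) sharing the geometry of the image it masks.
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel size in mm/px.
#' @param label Region label.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, pixel_size,
                        label = c("custom", "FAZ", "parafovea", "full")) {
  label <- match.arg(label)
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask))
    octamv_stop("`mask` must be a logical matrix without NA", "octamv_invalid_parameter")
  structure(list(mask = mask, pixel_size = pixel_size, label = label),
            class = "region_mask")
}

#' Full-frame region mask for a given geometry
#' @param nr,nc Grid dimensions in pixels.
#' @param pixel_size Pixel size in mm/px.
#' @return A `region_mask` covering every pixel.
#' @export
full_frame_mask <- function(nr, nc, pixel_size) {
  region_mask(matrix(TRUE, nr, nc), pixel_size, "full")
}

#' Rasterized disc region mask
#'
#' Pixel-centre inclusion: a pixel is on iff its centre lies within `radius`
#' of `centre` (mm from the field centre). Used for synthetic FAZ discs.
#'
#' @param nr,nc Grid dimensions in pixels.
#' @param pixel_size Pixel size in mm/px.
#' @param radius Disc radius in mm.
#' @param centre Disc centre, mm from the field centre (x, y).
#' @param label Region label, default `"FAZ"`.
#' @return A `region_mask`.
#' @export
disc_mask <- function(nr, nc, pixel_size, radius, centre = c(0, 0),
                      label = "FAZ") {
  if (radius < 0)
    octamv_stop("`radius` must be non-negative", "octamv_invalid_parameter")
  pc <- pixel_centres(nr, nc, pixel_size)
  dx <- outer(rep(1, nr), pc$x - centre[1])
  dy <- outer(pc$y - centre[2], rep(1, nc))
  region_mask(dx^2 + dy^2 <= radius^2, pixel_size, label)
}

#' Parafovea annulus mask
#'
#' The parafovea is the annulus between circles of 1 mm and 3 mm diameter
#' (radii 0.5 mm and 1.5 mm) centred on the fovea. Pixels are included by
#' pixel-centre position.
#'
#' @param nr,nc Grid dimensions in pixels.
#' @param pixel_size Pixel size in mm/px.
#' @param centre Fovea position, mm from the field centre.
#' @param inner_radius,outer_radius Annulus radii in mm.
#' @return A `region_mask` labelled `"parafovea"`.
#' @export
parafovea_mask <- function(nr, nc, pixel_size, centre = c(0, 0),
                           inner_radius = 0.5, outer_radius = 1.5) {
  half_x <- nc * pixel_size / 2
  half_y <- nr * pixel_size / 2
  if (abs(centre[1]) > half_x || abs(centre[2]) > half_y)
    octamv_stop("annulus centre lies outside the field", "octamv_invalid_parameter")
  pc <- pixel_centres(nr, nc, pixel_size)
  dx <- outer(rep(1, nr), pc$x - centre[1])
  dy <- outer(pc$y - centre[2], rep(1, nc))
  r2 <- dx^2 + dy^2
  mask <- r2 > inner_radius^2 & r2 <= outer_radius^2
  m <- region_mask(mask, pixel_size, "parafovea")
  m
}

#' FAZ area from a region mask
#'
#' Area of the foveal avascular zone: on-pixel count times the squared pixel
#' size. The FAZ outline itself is an input (traced, or a synthetic disc);
#' only the area computation is performed here.
#'
#' @param faz A `region_mask`.
#' @return A one-row `quant_result` data frame (metric `FAZ_area`, mm^2).
#' @export
faz_area <- function(faz) {
  stopifnot(inherits(faz, "region_mask"))
  quant_result("FAZ_area", sum(faz$mask) * faz$pixel_size^2, "mm^2",
               region = faz$label)
}

# Uniform result row for all quantification outputs.
quant_result <- function(metric, value, units, region = "full", layer = NA_character_) {
  data.frame(metric = metric, value = value, units = units,
             region = region, layer = layer, stringsAsFactors = FALSE)
}

# Shared geometry check for mask/map pairs.
check_same_geometry <- function(a, b, what = "inputs") {
  if (!identical(dim(a$mask), dim(b$mask)))
    octamv_stop(sprintf("%s have mismatched geometry (%s vs %s)", what,
                        paste(dim(a$mask), collapse = "x"),
                        paste(dim(b$mask), collapse = "x")),
                "octamv_shape_error")
  invisible(TRUE)
}
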