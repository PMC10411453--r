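#' Read an en-face angiogram from PNG or TIFF
#'
#' Accepts single-channel 8- or 16-bit grayscale images. Intensities are
#' min-max normalized to \[0, 1\]; a constant image maps to all-zeros rather
#' than erroring, so batch runs survive degenerate frames. The physical
#' pixel size is derived from the configured field width.
#'
#' @param path Image path (`.png`, `.tif` or `.tiff`).
#' @param field_mm Physical field width in mm (default 3).
#' @param layer,ssi,eye_id,group Metadata attached to the image.
#' @return An `en_face_angiogram`.
#' @export
read_angiogram <- function(path, field_mm = 3, layer = "SCP", ssi = NULL,
                           eye_id = NULL, group = NULL) {
  if (!file.exists(path))
    octamv_stop(paste("no such file:", path), "octamv_format_error")
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    octamv_stop(paste("unsupported image format:", path), "octamv_format_error"))
  if (length(dim(m)) != 2L)
    octamv_stop(paste("expected a single-channel grayscale image:", path),
                "octamv_format_error")
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  en_face_angiogram(m, field_mm = field_mm, layer = layer, ssi = ssi,
                    eye_id = eye_id, group = group)
}

#' Write an en-face angiogram to PNG (8-bit) or TIFF (16-bit)
#'
#' @param img An `en_face_angiogram`.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(img, path) {
  stopifnot(inherits(img, "en_face_angiogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img$intensity, path),
    tif = ,
    tiff = tiff::writeTIFF(img$intensity, path, bits.per.sample = 16L),
    octamv_stop(paste("unsupported image format:", path), "octamv_format_error"))
  invisible(path)
}

#' Read a binary mask from PNG (nonzero = on)
#'
#' @param path PNG path.
#' @param pixel_size Pixel size in mm/px.
#' @param label Region label.
#' @return A `region_mask`.
#' @export
read_mask <- function(path, pixel_size, label = "custom") {
  m <- png::readPNG(path)
  if (length(dim(m)) != 2L)
    octamv_stop(paste("expected a single-channel mask:", path),
                "octamv_format_error")
  region_mask(m > 0, pixel_size, label)
}

#' Read and validate a cohort CSV
#'
#' Requires the header `eye_id,group,ssi,<metric columns>`; group labels
#' must come from the ordered severity set.
#'
#' @param path CSV path.
#' @return Cohort data frame with `group` as an ordered factor.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "group", "ssi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    octamv_stop(paste("cohort CSV is missing columns:",
                      paste(missing_cols, collapse = ", ")),
                "octamv_schema_error")
  bad <- setdiff(unique(df$group), severity_levels())
  if (length(bad))
    octamv_stop(paste("unknown group label(s):", paste(bad, collapse = ", ")),
                "octamv_schema_error")
  df$group <- factor(df$group, levels = severity_levels(), ordered = TRUE)
  df
}

#' Write a cohort (or any results table) as CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run report as JSON
#'
#' @param report Named list (typically from [run_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export vessel-tree ground truth as JSON
#'
#' @param tree A `vessel_tree_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_truth <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree_truth"))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# Small order-dependent rolling hash of the deparsed config (hex string),
# embedded in reports so reruns can be matched to their configuration.
config_digest <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "\n")
  codes <- utf8ToInt(txt)
  h <- 5381
  for (c in codes) h <- (h * 33 + c) %% 2^31
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' Severity presets for the synthetic study: per-group eye counts, capillary
#' dropout fractions and FAZ radii chosen so that dropout (and hence PD/SVD
#' loss) and FAZ enlargement increase with severity, mirroring the clinical
#' ordering. FAZ radii correspond to disc areas of about 0.32-0.43 mm^2.
#'
#' @param seed Base RNG seed.
#' @param n_eyes Eyes per group.
#' @param width_px Raster width (default 304 px over a 3 mm field).
#' @return Config list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, n_eyes = 3L, width_px = 304L) {
  list(
    seed = as.integer(seed),
    field_mm = 3,
    width_px = as.integer(width_px),
    groups = list(
      healthy = list(n = n_eyes, dropout = 0.00, faz_radius = 0.32),
      noDR    = list(n = n_eyes, dropout = 0.05, faz_radius = 0.33),
      NPDR    = list(n = n_eyes, dropout = 0.25, faz_radius = 0.34),
      PDR     = list(n = n_eyes, dropout = 0.50, faz_radius = 0.37)),
    faz_radius_sd = 0.015,  # inter-eye FAZ variability (mm)
    noise = list(background = 0.10, background_sd = 0.04, speckle_sd = 0.25),
    quant = list(scales = c(1, 2), vessel_threshold = "otsu",
                 window_px = 31L, offset = 0, metric = "count"),
    ssi = list(mean = 65, sd = 4, threshold = 55),
    coefficients = c(-3, -1, 1, 3),
    roc = list(positive = c("NPDR", "PDR"), negative = "healthy")
  )
}

#' Run the full synthetic pipeline
#'
#' End-to-end orchestration: simulate one vessel tree per eye under its
#' group's severity preset, render, quantify (PD, SVD, FAZ area on the full
#' frame), assemble a cohort table with synthetic SSI, apply the quality
#' filter, then compute per-metric group summaries, the linear trend F and
#' the empirical ROC/AUC for DR vs healthy. Deterministic given the config
#' seed.
#'
#' @param config Config list, see [default_pipeline_config()].
#' @param out_dir Optional directory; when given, the cohort CSV and a JSON
#'   report (embedding the config hash and seed) are written there.
#' @return Report list: config echo/hash, cohort, per-metric summaries,
#'   trend and AUC results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  seed0 <- (config$seed %% 1000000L) * 1000L
  rows <- list(); idx <- 0L
  for (g in names(config$groups)) {
    gp <- config$groups[[g]]
    for (e in seq_len(gp$n)) {
      idx <- idx + 1L
      eye_seed <- seed0 + idx
      sd_faz <- if (is.null(config$faz_radius_sd)) 0.015 else config$faz_radius_sd
      eye_faz <- with_seed(eye_seed + 300L,
                           max(0.1, rnorm(1, gp$faz_radius, sd_faz)))
      tree <- generate_vessel_tree(eye_seed, field_mm = config$field_mm,
                                   faz_radius = eye_faz)
      tree <- apply_dropout(tree, gp$dropout, eye_seed + 500L)
      img <- render_angiogram(tree, config$width_px, config$noise,
                              seed = eye_seed + 900L)
      faz <- disc_mask(config$width_px, config$width_px,
                       config$field_mm / config$width_px, eye_faz)
      q <- quantify_image(img, faz,
                          scales = config$quant$scales,
                          vessel_threshold = config$quant$vessel_threshold,
                          window_px = config$quant$window_px,
                          offset = config$quant$offset,
                          metric = config$quant$metric)
      ssi_val <- with_seed(eye_seed + 700L,
                           min(100, max(0, rnorm(1, config$ssi$mean, config$ssi$sd))))
      rows[[idx]] <- data.frame(
        eye_id = sprintf("%s_%03d", g, e), group = g, ssi = ssi_val,
        PD = q$value[q$metric == "PD"][1],
        SVD = q$value[q$metric == "SVD"][1],
        FAZ_area = q$value[q$metric == "FAZ_area"][1],
        stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, rows)
  cohort$group <- factor(cohort$group, levels = severity_levels(), ordered = TRUE)
  cohort <- suppressMessages(filter_by_ssi(cohort, config$ssi$threshold))

  metrics <- c("PD", "SVD", "FAZ_area")
  stats <- lapply(setNames(metrics, metrics), function(m) {
    sm <- summarize_groups(cohort, m)
    tr <- trend_contrast_F(sm, config$coefficients)
    keep <- cohort$group %in% c(config$roc$positive, config$roc$negative)
    sub <- cohort[keep, , drop = FALSE]
    orientation <- if (m == "FAZ_area") "higher" else "lower"
    curve <- empirical_roc(sub[[m]], sub$group %in% config$roc$positive,
                           orientation)
    list(summaries = sm,
         trend = tr[c("F", "df1", "df2", "p")],
         auc = roc_auc(curve)$auc,
         cutoff = youden_cutoff(curve))
  })

  report <- list(config_hash = config_digest(config), seed = config$seed,
                 n_eyes = nrow(cohort),
                 n_removed = attr(cohort, "n_removed"),
                 metrics = stats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_report(c(report["config_hash"], report["seed"],
                   list(config = config), report[c("n_eyes", "n_removed", "metrics")]),
                 file.path(out_dir, "report.json"))
  }
  report$cohort <- cohort
  report
}
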