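#' Ordered DR severity levels
#'
#' The four severity groups in increasing order: healthy controls, diabetics
#' without retinopathy, non-proliferative DR, proliferative DR.
#'
#' @return Character vector of length 4.
#' @export
severity_levels <- function() c("healthy", "noDR", "NPDR", "PDR")

#' Reference macular OCTA group summaries
#'
#' Per-group (n, mean, SD) summaries of the macular OCTA metrics in a
#' 116-eye clinical severity cohort (41 healthy, 25 diabetic without DR,
#' 27 NPDR, 23 PDR eyes): FAZ area in mm^2 and parafoveal vessel density
#' (VD), perfusion density (PD) and skeleton vessel density (SVD) in percent
#' for the superficial (SCP) and deep (DCP) retinal capillary plexuses, plus
#' choroidal VD. These summaries are the default inputs for the
#' summary-statistic trend analysis and the binormal AUC reconstruction, and
#' the default parameters of [sample_cohort()].
#'
#' @return A data frame with columns `metric`, `group`, `n`, `mean`, `sd`.
#' @export
reference_group_summaries <- function() {
  g <- severity_levels()
  n <- c(41L, 25L, 27L, 23L)
  vals <- list(
    FAZ_area   = list(mean = c(0.33, 0.34, 0.36, 0.43),
                      sd   = c(0.04, 0.04, 0.03, 0.07)),
    SCP_VD     = list(mean = c(56.35, 55.75, 52.28, 46.92),
                      sd   = c(1.52, 2.41, 1.39, 4.42)),
    DCP_VD     = list(mean = c(62.07, 59.75, 56.21, 51.71),
                      sd   = c(1.31, 1.82, 3.47, 1.90)),
    SCP_PD     = list(mean = c(43.34, 40.54, 37.68, 35.81),
                      sd   = c(3.39, 2.48, 1.99, 1.28)),
    DCP_PD     = list(mean = c(47.51, 45.27, 43.14, 40.05),
                      sd   = c(1.92, 1.58, 2.22, 1.27)),
    SCP_SVD    = list(mean = c(14.91, 14.41, 11.82, 10.06),
                      sd   = c(0.87, 0.87, 0.994, 1.14)),
    DCP_SVD    = list(mean = c(17.46, 16.85, 14.30, 11.99),
                      sd   = c(1.46, 1.24, 0.96, 1.20)),
    choroid_VD = list(mean = c(68.75, 68.45, 65.80, 63.03),
                      sd   = c(1.20, 1.10, 1.80, 2.19))
  )
  do.call(rbind, lapply(names(vals), function(m)
    data.frame(metric = m, group = g, n = n,
               mean = vals[[m]]$mean, sd = vals[[m]]$sd,
               stringsAsFactors = FALSE)))
}

#' Build a synthetic cohort specification
#'
#' Validates a long-format summary table (one row per metric x group with
#' n, mean, SD) for cohort sampling: every SD must be positive, every n at
#' least 2, groups must be the ordered severity set and group sizes must be
#' consistent across metrics.
#'
#' @param summaries Data frame with columns `metric`, `group`, `n`, `mean`,
#'   `sd`; defaults to [reference_group_summaries()].
#' @return A `synthetic_cohort_spec` object.
#' @export
cohort_spec <- function(summaries = reference_group_summaries()) {
  need <- c("metric", "group", "n", "mean", "sd")
  if (!all(need %in% names(summaries)))
    octamv_stop(paste("summary table must have columns:",
                      paste(need, collapse = ", ")), "octamv_schema_error")
  if (any(summaries$sd <= 0))
    octamv_stop("every SD must be > 0", "octamv_invalid_parameter")
  if (any(summaries$n < 2))
    octamv_stop("every group size must be >= 2", "octamv_invalid_parameter")
  if (!all(summaries$group %in% severity_levels()))
    octamv_stop("group labels must be drawn from the ordered severity set",
                "octamv_invalid_parameter")
  ns <- unique(summaries[, c("group", "n")])
  if (anyDuplicated(ns$group))
    octamv_stop("group sizes differ between metrics", "octamv_invalid_parameter")
  structure(list(summaries = summaries,
                 groups = intersect(severity_levels(), ns$group),
                 n = setNames(ns$n, ns$group)),
            class = "synthetic_cohort_spec")
}

#' Sample a synthetic per-eye cohort
#'
#' Draws `n_g` eyes per severity group, each metric independently Gaussian
#' with that group's (mean, SD), and attaches synthetic signal-strength
#' (SSI) values. Deterministic for a fixed seed.
#'
#' @param spec A `synthetic_cohort_spec` (or a summary data frame accepted by
#'   [cohort_spec()]).
#' @param seed RNG seed.
#' @param ssi List with `mean` and `sd` of the synthetic SSI distribution
#'   (defaults 65 and 4; values are clamped to \[0, 100\]).
#' @return A cohort data frame: `eye_id`, `group` (ordered factor), `ssi`,
#'   then one column per metric.
#' @export
sample_cohort <- function(spec, seed, ssi = list(mean = 65, sd = 4)) {
  if (!inherits(spec, "synthetic_cohort_spec")) spec <- cohort_spec(spec)
  metrics <- unique(spec$summaries$metric)
  with_seed(seed, {
    rows <- lapply(spec$groups, function(g) {
      ng <- spec$n[[g]]
      df <- data.frame(
        eye_id = sprintf("%s_%03d", g, seq_len(ng)),
        group = g,
        ssi = pmin(100, pmax(0, rnorm(ng, ssi$mean, ssi$sd))),
        stringsAsFactors = FALSE)
      for (m in metrics) {
        s <- spec$summaries[spec$summaries$metric == m &
                              spec$summaries$group == g, ]
        df[[m]] <- rnorm(ng, s$mean, s$sd)
      }
      df
    })
    out <- do.call(rbind, rows)
    out$group <- factor(out$group, levels = severity_levels(), ordered = TRUE)
    rownames(out) <- NULL
    out
  })
}
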