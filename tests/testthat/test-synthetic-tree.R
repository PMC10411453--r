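test_that("vessel tree generation is deterministic and seed-sensitive", {
  t1 <- generate_vessel_tree(11)
  t2 <- generate_vessel_tree(11)
  t3 <- generate_vessel_tree(12)
  expect_identical(t1$segments, t2$segments)
  expect_false(identical(t1$segments, t3$segments))
})

test_that("total centreline length equals the brute-force sum over segments", {
  for (seed in c(1, 7, 42)) {
    tr <- generate_vessel_tree(seed)
    s <- tr$segments
    brute <- sum(sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2))
    expect_equal(tr$total_centerline_length, brute, tolerance = 1e-9)
  }
})

test_that("no centreline point enters the FAZ disc", {
  tr <- generate_vessel_tree(3, faz_radius = 0.3)
  s <- tr$segments
  tgrid <- seq(0, 1, length.out = 25)
  for (i in seq_len(nrow(s))) {
    x <- s$x0[i] + tgrid * (s$x1[i] - s$x0[i])
    y <- s$y0[i] + tgrid * (s$y1[i] - s$y0[i])
    expect_true(all(sqrt(x^2 + y^2) >= 0.3 - 1e-9))
  }
})

test_that("invalid tree parameters are rejected", {
  expect_error(generate_vessel_tree(1, field_mm = 0), class = "octamv_invalid_parameter")
  expect_error(generate_vessel_tree(1, faz_radius = -0.1), class = "octamv_invalid_parameter")
  expect_error(generate_vessel_tree(1, params = list(trunk_width = 0)),
               class = "octamv_invalid_parameter")
})

test_that("dropout removes capillaries monotonically and reproducibly", {
  tr <- generate_vessel_tree(5)
  expect_identical(apply_dropout(tr, 0, 9)$segments, tr$segments)
  expect_equal(apply_dropout(tr, 0, 9)$dropout_fraction, 0)

  full <- apply_dropout(tr, 1, 9)
  protected <- tr$segments[tr$segments$width >= tr$capillary_width, ]
  expect_equal(full$total_centerline_length,
               sum(sqrt((protected$x1 - protected$x0)^2 +
                          (protected$y1 - protected$y0)^2)),
               tolerance = 1e-12)

  fractions <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  lens <- vapply(fractions, function(f)
    apply_dropout(tr, f, 9)$total_centerline_length, numeric(1))
  expect_true(all(diff(lens) <= 0))

  # same seed: nested removals (segments at higher fraction are a subset)
  a <- apply_dropout(tr, 0.2, 9)$segments
  b <- apply_dropout(tr, 0.5, 9)$segments
  key <- function(d) paste(d$x0, d$y0, d$x1, d$y1)
  expect_true(all(key(b) %in% key(a)))

  expect_error(apply_dropout(tr, 1.2, 9), class = "octamv_invalid_parameter")
  expect_error(apply_dropout(tr, -0.1, 9), class = "octamv_invalid_parameter")
})

test_that("noiseless rendering reproduces the rasterized bar exactly", {
  # horizontal 3-px-wide bar through pixel-row centres on a 32 px / 32 mm grid
  seg <- data.frame(x0 = -10, y0 = -0.5, x1 = 10, y1 = -0.5,
                    width = 3, depth = 0L)
  tr <- toy_tree(seg, field_mm = 32)
  img <- render_angiogram(tr, 64, noise = noiseless, seed = 1)
  expect_equal(dim(img$intensity), c(64L, 64L))
  px <- 32 / 64
  expect_equal(img$pixel_size, px)
  truth <- rasterize_tree(tr, 64)$mask
  expect_identical(img$intensity == 1, truth)
  expect_true(sum(truth) > 0)
  # all on-pixels lie in the 3-mm band around y = -0.5
  on <- which(truth, arr.ind = TRUE)
  yc <- (on[, 1] - 0.5) * px - 16
  expect_true(all(abs(yc + 0.5) <= 1.5 + 1e-12))
})

test_that("default raster geometry gives the standard pixel size", {
  tr <- generate_vessel_tree(2)
  img <- render_angiogram(tr, 304, seed = 1)
  expect_equal(img$pixel_size, 3 / 304)
  expect_equal(ncol(img$intensity) * img$pixel_size, 3)
})

test_that("vessels are brighter than background at default noise", {
  tr <- generate_vessel_tree(8)
  img <- render_angiogram(tr, 304, seed = 4)
  truth <- rasterize_tree(tr, 304)$mask
  expect_gt(mean(img$intensity[truth]), mean(img$intensity[!truth]))
  # determinism
  img2 <- render_angiogram(tr, 304, seed = 4)
  expect_identical(img$intensity, img2$intensity)
  expect_error(render_angiogram(tr, 32), class = "octamv_invalid_parameter")
})

test_that("cohort sampling is deterministic and matches the spec shape", {
  spec <- cohort_spec()
  c1 <- sample_cohort(spec, 31)
  c2 <- sample_cohort(spec, 31)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 116L)  # 41 + 25 + 27 + 23 eyes
  expect_true(all(c("eye_id", "group", "ssi") %in% names(c1)))
  expect_true(all(table(c1$group) == c(41, 25, 27, 23)))
})

test_that("large-sample cohort means converge to the spec means", {
  rs <- reference_group_summaries()
  sub <- rs[rs$metric == "DCP_SVD", ]
  sub$n <- rep(1e5L, 4)
  big <- sample_cohort(cohort_spec(sub), 99)
  for (i in seq_len(4)) {
    x <- big$DCP_SVD[big$group == sub$group[i]]
    se <- sub$sd[i] / sqrt(length(x))
    expect_lt(abs(mean(x) - sub$mean[i]), 3 * se)
  }
})

test_that("invalid cohort specs are rejected", {
  rs <- reference_group_summaries()
  bad_sd <- rs; bad_sd$sd[1] <- 0
  expect_error(cohort_spec(bad_sd), class = "octamv_invalid_parameter")
  bad_n <- rs; bad_n$n[2] <- 1
  expect_error(cohort_spec(bad_n), class = "octamv_invalid_parameter")
  bad_g <- rs; bad_g$group[3] <- "severe"
  expect_error(cohort_spec(bad_g), class = "octamv_invalid_parameter")
})
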