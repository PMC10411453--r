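test_that("vesselness kills constants and is offset-invariant", {
  flat <- en_face_angiogram(matrix(0.4, 24, 24), pixel_size = 1)
  expect_equal(max(hessian_vesselness(flat)$intensity), 0)

  bar <- matrix(0, 40, 40); bar[20:21, 5:35] <- 0.5
  img <- en_face_angiogram(bar, pixel_size = 1)
  shifted <- en_face_angiogram(bar + 0.3, pixel_size = 1)
  v <- hessian_vesselness(img)$intensity
  vs <- hessian_vesselness(shifted)$intensity
  expect_equal(v, vs, tolerance = 1e-12)

  # response ridge follows the bar centreline
  argmax <- apply(v[, 10:30], 2, which.max)
  expect_true(all(argmax %in% 20:21))

  expect_error(hessian_vesselness(img, scales = numeric(0)),
               class = "octamv_invalid_parameter")
  expect_error(hessian_vesselness(img, scales = c(1, -2)),
               class = "octamv_invalid_parameter")
})

test_that("local median binarization matches a brute-force oracle", {
  set.seed(42)
  m <- matrix(runif(81), 9, 9)
  img <- en_face_angiogram(m, pixel_size = 1)
  got <- local_median_binarize(img, 5, offset = 0.01)$mask
  # brute-force reflective-padding median
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  expected <- matrix(FALSE, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    w <- numeric(0)
    for (a in -2:2) for (b in -2:2)
      w <- c(w, m[refl(i + a, 9), refl(j + b, 9)])
    expected[i, j] <- m[i, j] > median(w) + 0.01
  }
  expect_identical(got, expected)
})

test_that("local median binarization: constants, bars and monotone offset", {
  flat <- en_face_angiogram(matrix(0.7, 12, 12), pixel_size = 1)
  expect_false(any(local_median_binarize(flat, 5)$mask))

  bar <- matrix(0, 15, 15); bar[7:9, ] <- 1
  img <- en_face_angiogram(bar, pixel_size = 1)
  got <- local_median_binarize(img, 9)$mask
  expect_true(all(got[7:9, ]))
  expect_false(any(got[-(7:9), ]))

  set.seed(1)
  noisy <- en_face_angiogram(matrix(runif(400), 20, 20), pixel_size = 1)
  lo <- local_median_binarize(noisy, 7, offset = 0)$mask
  hi <- local_median_binarize(noisy, 7, offset = 0.1)$mask
  expect_true(all(lo | !hi))  # raising the offset never turns a pixel on

  expect_error(local_median_binarize(noisy, 4), class = "octamv_invalid_parameter")
  expect_error(local_median_binarize(noisy, 1), class = "octamv_invalid_parameter")
})

test_that("combining binary maps is an intersection", {
  set.seed(3)
  mk <- function() binary_vessel_map(matrix(runif(100) < 0.5, 10, 10), 1, "median")
  for (i in 1:5) {
    a <- mk(); b <- mk()
    ab <- combine_binaries(a, b)
    expect_identical(ab$mask, a$mask & b$mask)
    expect_identical(ab$provenance, "combined")
    expect_identical(combine_binaries(a, a)$mask, a$mask)
    expect_identical(combine_binaries(b, a)$mask, ab$mask)
    expect_lte(sum(ab$mask), min(sum(a$mask), sum(b$mask)))
  }
  small <- binary_vessel_map(matrix(TRUE, 5, 5), 1, "median")
  expect_error(combine_binaries(mk(), small), class = "octamv_shape_error")
})

test_that("dual binarization is a subset of both branches and of dilated truth", {
  tree <- generate_vessel_tree(5)
  img <- render_angiogram(tree, 304, noise = noiseless, seed = 1)
  h <- threshold_vesselness(hessian_vesselness(img))
  m <- local_median_binarize(img)
  dual <- binarize_dual(img)
  expect_true(all(h$mask | !dual$mask))
  expect_true(all(m$mask | !dual$mask))
  truth <- rasterize_tree(tree, 304)$mask
  expect_true(all(dilate4(truth, 3) | !dual$mask))
  expect_gt(sum(dual$mask), 0)

  dark <- en_face_angiogram(matrix(0, 64, 64), pixel_size = 1)
  expect_false(any(binarize_dual(dark)$mask))
})

test_that("skeletonization thins to 1-px centrelines preserving topology", {
  # 1-px line is already thin
  l <- matrix(FALSE, 10, 10); l[5, 2:9] <- TRUE
  expect_identical(skeletonize(binary_vessel_map(l, 1, "combined"))$mask, l)

  # 3-px-wide bar of length 20 reduces to a single-row centreline
  b <- matrix(FALSE, 30, 30); b[14:16, 6:25] <- TRUE
  sk <- skeletonize(binary_vessel_map(b, 1, "combined"))$mask
  expect_true(all(sk[!b] == FALSE))
  expect_equal(length(unique(which(sk, arr.ind = TRUE)[, 1])), 1L)
  expect_true(abs(sum(sk) - 20) <= 2)
  expect_equal(nrow(blocks_2x2(sk)), 0L)

  # empty map stays empty
  e <- matrix(FALSE, 8, 8)
  expect_identical(skeletonize(binary_vessel_map(e, 1, "combined"))$mask, e)

  # random blobs: subset, component count preserved, no reducible 2x2 block
  set.seed(7)
  for (i in 1:8) {
    r <- matrix(runif(900) < 0.4, 30, 30)
    s <- skeletonize(binary_vessel_map(r, 1, "combined"))$mask
    expect_true(all(r | !s))
    expect_equal(count_components8(s), count_components8(r))
    blk <- blocks_2x2(s)
    if (nrow(blk) > 0) {
      # any surviving block must be an irreducible junction core:
      # removing any of its pixels would change the topology
      P <- matrix(FALSE, 32, 32); P[2:31, 2:31] <- s
      for (k in seq_len(nrow(blk)))
        for (d in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
          expect_false(octamv:::is_simple_point(P, blk[k, 1] + d[1] + 1L,
                                                blk[k, 2] + d[2] + 1L))
    }
  }
})

test_that("skeleton length metrics behave on known shapes", {
  l <- matrix(FALSE, 10, 10); l[5, 2:9] <- TRUE
  sk <- skeletonize(binary_vessel_map(l, 0.5, "combined"))
  expect_equal(skeleton_length(sk, metric = "count"), 8)
  expect_equal(skeleton_length(sk, metric = "geodesic"), 7)  # 7 links
  expect_equal(skeleton_length(sk, metric = "count", units = "mm"), 4)
  d <- matrix(FALSE, 10, 10); diag(d) <- TRUE
  skd <- skeletonize(binary_vessel_map(d, 1, "combined"))
  expect_equal(skeleton_length(skd, metric = "geodesic"), 9 * sqrt(2))
})

test_that("perfusion density follows its counting definition", {
  px <- 1
  region <- full_frame_mask(4, 4, px)
  all_on <- binary_vessel_map(matrix(TRUE, 4, 4), px, "combined")
  all_off <- binary_vessel_map(matrix(FALSE, 4, 4), px, "combined")
  half <- binary_vessel_map(matrix(c(TRUE, FALSE), 4, 4), px, "combined")
  expect_equal(perfusion_density(all_on, region)$value, 100)
  expect_equal(perfusion_density(all_off, region)$value, 0)
  expect_equal(perfusion_density(half, region)$value, 50)

  # invariance to relabeling off-region pixels
  sub <- region_mask(matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4), px, "custom")
  m2 <- half; m2$mask[!sub$mask] <- !m2$mask[!sub$mask]
  expect_equal(perfusion_density(half, sub)$value,
               perfusion_density(m2, sub)$value)

  empty <- region_mask(matrix(FALSE, 4, 4), px, "custom")
  expect_error(perfusion_density(all_on, empty), class = "octamv_degenerate_region")
})

test_that("skeleton vessel density excludes the FAZ from the denominator", {
  px <- 1
  sk_mask <- matrix(FALSE, 10, 10); sk_mask[5, 1:10] <- TRUE
  sk <- structure(list(mask = sk_mask, pixel_size = px, source = "combined"),
                  class = "skeleton_map")
  region <- full_frame_mask(10, 10, px)
  empty_faz <- region_mask(matrix(FALSE, 10, 10), px, "FAZ")
  expect_equal(skeleton_vessel_density(sk, empty_faz, region)$value, 10)

  # FAZ covering half the region (but not the skeleton row)
  faz_half <- region_mask(matrix(rep(c(TRUE, FALSE), each = 50), 10, 10), px, "FAZ")
  faz_half$mask[5, ] <- FALSE
  denom <- 100 - sum(faz_half$mask)
  expect_equal(skeleton_vessel_density(sk, faz_half, region)$value,
               100 * 10 / denom)

  empty_sk <- structure(list(mask = matrix(FALSE, 10, 10), pixel_size = px,
                             source = "combined"), class = "skeleton_map")
  expect_equal(skeleton_vessel_density(empty_sk, empty_faz, region)$value, 0)

  full_faz <- region_mask(matrix(TRUE, 10, 10), px, "FAZ")
  expect_error(skeleton_vessel_density(sk, full_faz, region),
               class = "octamv_degenerate_region")

  # with an empty FAZ and count metric, SVD is PD applied to the skeleton
  pd_of_skel <- perfusion_density(
    binary_vessel_map(sk_mask, px, "combined"), region)$value
  expect_equal(skeleton_vessel_density(sk, empty_faz, region)$value, pd_of_skel)
})

test_that("FAZ area and parafovea geometry match closed forms", {
  px <- 3 / 304
  empty <- region_mask(matrix(FALSE, 304, 304), px, "FAZ")
  expect_equal(faz_area(empty)$value, 0)
  full <- full_frame_mask(304, 304, px)
  expect_equal(faz_area(region_mask(full$mask, px, "FAZ"))$value, 9)

  disc <- disc_mask(304, 304, px, 0.3)
  expect_equal(faz_area(disc)$value, pi * 0.09, tolerance = 0.02)

  ann <- parafovea_mask(304, 304, px)
  area <- sum(ann$mask) * px^2
  expect_equal(area, 2 * pi, tolerance = 0.02)
  # the exact-centre pixels are inside the inner disc, hence off
  expect_false(ann$mask[152, 152])
  # 90-degree rotational symmetry of the grid
  expect_identical(ann$mask, t(ann$mask[304:1, ]))
  expect_error(parafovea_mask(304, 304, px, centre = c(5, 0)),
               class = "octamv_invalid_parameter")
})

test_that("quantify_image orders PD > SVD > 0 and is deterministic", {
  tree <- generate_vessel_tree(9)
  img <- render_angiogram(tree, 304, noise = noiseless, seed = 2)
  q1 <- quantify_image(img)
  q2 <- quantify_image(img)
  expect_identical(q1, q2)
  pd <- q1$value[q1$metric == "PD"]
  svd <- q1$value[q1$metric == "SVD"]
  expect_gt(pd, svd)
  expect_gt(svd, 0)
  expect_error(quantify_image(img, regions = "macula"),
               class = "octamv_invalid_parameter")
})

test_that("truth-mask perfusion density is stable when resolution doubles", {
  tree <- generate_vessel_tree(5)
  pd <- vapply(c(152, 304), function(w) {
    perfusion_density(rasterize_tree(tree, w), full_frame_mask(w, w, 3 / w))$value
  }, numeric(1))
  expect_lt(abs(pd[2] - pd[1]) / pd[1], 0.02)
})
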