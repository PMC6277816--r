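# thresholds, median filter, wall construction, orifice tagging, smoothing

test_that("threshold formulas: zero-variance case and pooled-sample oracle", {
  img <- voxel_image(array(0, c(6, 6, 6)))
  myo <- array(FALSE, c(6, 6, 6)); blood <- myo
  myo[1:2, , ] <- TRUE; blood[5:6, , ] <- TRUE
  img$data[myo] <- 200; img$data[blood] <- 400
  thr <- compute_thresholds(img, myo, blood)$thresholds
  expect_equal(unlist(thr), c(LT = 200, MT = 300, UT = 400))

  # noisy phantom: brute-force mean/SD over the drawn sample voxels
  ph <- make_voxel_phantom(phantom_spec(seed = 11))
  res <- compute_thresholds(ph$image, ph$myo_samples, ph$blood_samples)
  xm <- ph$image$data[ph$myo_samples]; xb <- ph$image$data[ph$blood_samples]
  sd_or <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))
  expect_equal(res$thresholds$LT, mean(xm) - 3 * sd_or(xm), tolerance = 1e-12)
  expect_equal(res$thresholds$UT, mean(xb) + 3 * sd_or(xb), tolerance = 1e-12)
  expect_equal(res$thresholds$MT, (mean(xm) + mean(xb)) / 2, tolerance = 1e-12)
  # near the generator design values
  expect_lt(abs(res$thresholds$MT - 350), 15)

  # MT is the mean of the two sample means regardless of the SDs
  img2 <- img; img2$data[myo] <- img2$data[myo] + rep(c(-30, 30), length.out = sum(myo))
  thr2 <- compute_thresholds(img2, myo, blood)$thresholds
  expect_equal(thr2$MT, 300)

  # inverted/overlapping populations -> degenerate-statistics error
  img3 <- img; img3$data[myo] <- 500; img3$data[blood] <- 400
  expect_error(compute_thresholds(img3, myo, blood), "degenerate")
})

test_that("median prefilter: constant, impulse, and brute-force oracle", {
  cst <- voxel_image(array(7, c(5, 5, 5)))
  expect_equal(median_prefilter(cst)$data, cst$data)

  imp <- voxel_image(array(10, c(7, 7, 7)))
  imp$data[4, 4, 4] <- 1000
  expect_equal(median_prefilter(imp)$data[4, 4, 4], 10)

  # checkerboard block vs nested-loop oracle over the same kernel
  set.seed(3)
  a <- array(sample(0:1, 5 * 5 * 5, TRUE) * 100 + rnorm(125), c(5, 5, 5))
  out <- median_prefilter(voxel_image(a))$data
  oracle <- array(0, dim(a))
  cl <- function(i, n) min(max(i, 1L), n)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    vals <- c(a[i, j, k],
              a[cl(i - 1, 5), j, k], a[cl(i + 1, 5), j, k],
              a[i, cl(j - 1, 5), k], a[i, cl(j + 1, 5), k],
              a[i, j, cl(k - 1, 5)], a[i, j, cl(k + 1, 5)])
    oracle[i, j, k] <- median(vals)
  }
  expect_equal(out, oracle)
})

test_that("build_wall recovers a thin wall and honors the 3 mm cap", {
  ph <- make_voxel_phantom(phantom_spec())   # 1.5 mm wall < 3 mm cap
  thr <- compute_thresholds(ph$image, ph$myo_samples, ph$blood_samples)
  seg <- build_wall(ph$image, thr$thresholds, ph$seed_point)
  expect_gt(dice(seg_mask(seg, "mc"), ph$truth$wall), 0.9)

  # intensity band deliberately 5 mm thick: every wall voxel within 3 mm of
  # the blood pool (Euclidean, brute-force nearest-point oracle)
  ph5 <- make_voxel_phantom(phantom_spec(wall_thickness = 5))
  thr5 <- compute_thresholds(ph5$image, ph5$myo_samples, ph5$blood_samples)
  seg5 <- build_wall(ph5$image, thr5$thresholds, ph5$seed_point, max_thickness = 3)
  widx <- which(seg_mask(seg5, "mc"), arr.ind = TRUE)
  bidx <- which(seg_mask(seg5, "blood_pool"), arr.ind = TRUE)
  wp <- sweep(widx - 1, 2, seg5$spacing, `*`)
  bp <- sweep(bidx - 1, 2, seg5$spacing, `*`)
  expect_lte(max(atriofiber:::.nn_min_dist(wp, bp)), 3)

  # monotone in max_thickness
  seg2 <- build_wall(ph5$image, thr5$thresholds, ph5$seed_point, max_thickness = 2)
  expect_true(all(seg_mask(seg5, "mc")[seg_mask(seg2, "mc")]))

  # blood pool touching the image edge: 1-voxel minimum ring survives
  img <- voxel_image(array(100, c(8, 8, 8)))
  img$data[1:4, , ] <- 400       # blood occupies half, touches the x edge
  thr_e <- list(LT = 150, MT = 300, UT = 450)
  seg_e <- build_wall(img, thr_e, c(0, 3, 3))
  wall <- seg_mask(seg_e, "mc")
  expect_true(all(wall[5, , ]))  # ring adjacent to blood across the face
  expect_identical(dim(wall), c(8L, 8L, 8L))

  expect_error(build_wall(img, list(LT = 999, MT = 1000, UT = 1001), c(0, 3, 3)),
               "empty blood")
})

test_that("orifice tagging: cylinder geometry, tag algebra, collinear error", {
  # 3 points on a circle of radius 10 in the z = 0 plane
  cc <- atriofiber:::circumcircle3(rbind(c(10, 0, 0), c(0, 10, 0), c(-10, 0, 0)))
  expect_equal(cc$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(cc$radius, 10, tolerance = 1e-9)
  expect_equal(abs(cc$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_error(atriofiber:::circumcircle3(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")

  ph <- make_voxel_phantom(phantom_spec())
  thr <- compute_thresholds(ph$image, ph$myo_samples, ph$blood_samples)
  seg <- build_wall(ph$image, thr$thresholds, ph$seed_point)
  rc <- 8.75 * sin(35 * pi / 180); zc <- -8.75 * cos(35 * pi / 180)
  seg2 <- tag_orifices(seg,
                       mv_points = rbind(c(rc, 0, zc), c(-rc, 0, zc), c(0, rc, zc)),
                       pv_points = list(rbind(c(2, 8.4, 0), c(-2, 8.4, 0),
                                              c(0, 8.4, 2))),
                       shell_thickness = 1.5, cyl_height = 4)
  mc <- seg_mask(seg2, "mc"); aw <- seg_mask(seg2, "aw")
  mv <- seg_mask(seg2, "mv"); pv <- seg_mask(seg2, "pv")
  expect_gt(sum(mv), 0)
  expect_gt(sum(pv), 0)
  # {aw, mv, pv} partitions mc, pairwise disjoint
  expect_true(all(mc == (aw | mv | pv)))
  expect_false(any(aw & mv) || any(aw & pv) || any(mv & pv))
})

test_that("constrained smoothing honors the displacement cap and smooths", {
  seg <- make_sphere_seg(2, 10)       # staircase sphere, 2 mm voxels
  sm <- smooth_and_resample(seg, target_spacing = NULL,
                            max_displacement_fraction = 0.5)
  expect_lte(sm$max_displacement_fraction, 0.5 + 1e-9)
  expect_gt(sm$max_displacement_fraction, 0.05)  # it actually moved

  # staircase radius scatter shrinks
  d0 <- atriofiber:::signed_distance(seg_mask(seg, "mc"), seg$spacing)
  sp0 <- atriofiber:::surface_crossings(d0, seg$spacing, seg$origin)
  expect_lt(sd(sqrt(rowSums(sm$surface_points^2))),
            0.5 * sd(sqrt(rowSums(sp0^2))))
})

test_that("resampling is exactly isotropic and upsampling-only", {
  seg <- make_sphere_seg(1, 4, margin = 2)
  sm <- smooth_and_resample(seg, target_spacing = 0.5)
  expect_identical(sm$seg$spacing, c(0.5, 0.5, 0.5))
  expect_error(smooth_and_resample(seg, target_spacing = 2), "upsampling")

  # smooth analytic sphere: voxel-count volume within 1% of analytic
  seg2 <- make_sphere_seg(1, 10)
  sm2 <- smooth_and_resample(seg2, target_spacing = 0.5)
  v <- sum(seg_mask(sm2$seg, "mc")) * 0.5^3
  expect_lt(abs(v - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.01)

  # topology preserved: complement of the shell wall keeps its two
  # components (cavity + background) through smoothing and resampling
  ph <- make_voxel_phantom(phantom_spec(spacing = 0.5, cavity_radius = 5))
  thr <- compute_thresholds(ph$image, ph$myo_samples, ph$blood_samples)
  segw <- build_wall(ph$image, thr$thresholds, ph$seed_point)
  smw <- smooth_and_resample(segw, target_spacing = 0.4)
  # components with at least 100 voxels (noise speckles ignored)
  n_comp <- function(mask) {
    seen <- array(FALSE, dim(mask)); n <- 0L
    while (any(todo <- mask & !seen)) {
      idx <- which(todo, arr.ind = TRUE)[1, ]
      comp <- atriofiber:::connected_component6(mask, idx)
      seen <- seen | comp
      if (sum(comp) >= 100) n <- n + 1L
    }
    n
  }
  expect_identical(n_comp(!seg_mask(segw, "mc")), 2L)
  expect_identical(n_comp(!seg_mask(smw$seg, "mc")), 2L)
})
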