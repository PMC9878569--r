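test_that("stacking validates shapes and computes voxel volumes", {
  s1 <- matrix(0L, 8, 9)
  expect_error(stack_labels(list(s1, matrix(0L, 9, 8))), "slice 2")
  one <- stack_labels(list(label_slice(square_ring_slice())), voxel_mm = 0.1)
  expect_equal(dim(one), c(60, 60, 1))
  # 10x10x10 solid cube at 0.1 mm -> exactly 1 mm^3
  cube <- array(0L, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1L
  vol <- label_volume(cube, 0.1)
  expect_equal(class_volume(vol, 1L), 1)
  expect_equal(class_volume(vol, c(1L, 2L)),
               class_volume(vol, 1L) + class_volume(vol, 2L))
  # sphere radius 3 mm within 2% of 4/3 pi 27
  expect_lt(abs(class_volume(sphere_volume_01(), c(1L, 2L)) -
                  4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.02)
})

test_that("component cleanup removes specks but keeps lobed cores", {
  sp2 <- phantom_spec(c(5, 4.5, 4), 0.8, gap_mm = 0.3, lobes = 2L, seed = 5)
  vol <- voxelize(sp2, 0.1)
  expect_identical(clean_components(vol)$classes, vol$classes)  # identity
  noisy <- vol
  set.seed(8)
  # specks scattered outside the fruit bounding box, so they cannot touch it
  d <- dim(noisy$classes)
  idx <- which(noisy$classes > 0L, arr.ind = TRUE)
  lo <- apply(idx, 2, min) - 2L; hi <- apply(idx, 2, max) + 2L
  bg <- which(noisy$classes == 0L, arr.ind = TRUE)
  far <- bg[bg[, 1] < lo[1] | bg[, 1] > hi[1] | bg[, 2] < lo[2] |
              bg[, 2] > hi[2] | bg[, 3] < lo[3] | bg[, 3] > hi[3], , drop = FALSE]
  specks <- far[sample(nrow(far), 50), , drop = FALSE]
  noisy$classes[specks] <- 1L
  cleaned <- suppressWarnings(clean_components(noisy))
  expect_equal(class_volume(cleaned, c(1L, 2L)), class_volume(vol, c(1L, 2L)))
  # two disjoint fruits: larger kept, warning emitted
  two <- array(0L, c(40, 40, 12))
  two[5:20, 5:20, 3:10] <- 1L
  two[30:36, 30:36, 3:8] <- 1L
  expect_warning(c2 <- clean_components(label_volume(two, 0.1)), "largest")
  expect_equal(sum(c2$classes > 0), 16 * 16 * 8)
  expect_error(clean_components(label_volume(array(0L, c(4, 4, 4)), 0.1)),
               "no sample")
})

test_that("surface estimators agree with analytic shapes", {
  sph <- fruitct:::fill_fruit_mask(sphere_volume_01()$classes)
  a_true <- 4 * pi * 9
  a_mesh <- surface_area(sph, voxel_mm = 0.1, method = "mesh")
  a_grad <- surface_area(sph, voxel_mm = 0.1, method = "gradient")
  expect_lt(abs(a_mesh - a_true) / a_true, 0.03)
  expect_lt(abs(a_grad - a_true) / a_true, 0.03)
  expect_lt(abs(a_mesh - a_grad) / a_true, 0.03)
  # face counting overestimates a sphere by ~1.5x; the estimator beats it
  a_face <- surface_area(sph, voxel_mm = 0.1, method = "faces")
  expect_gt(a_face / a_true, 1.4)
  expect_lt(abs(a_mesh - a_true), abs(a_face - a_true))
  # 1 mm cube (10^3 voxels at 0.1 mm): smoothing rounds corners and edges,
  # a measured bias of about -18% on a cube this small relative to the
  # smoothing kernel; the estimate stays within 20% of the analytic 6 mm^2
  # and well below the face count (which is exact only for boxes)
  cube <- array(0L, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- 1L
  a_cube <- surface_area(cube, voxel_mm = 0.1, method = "mesh")
  expect_lt(abs(a_cube - 6) / 6, 0.20)
  expect_equal(surface_area(array(0L, c(5, 5, 5)), voxel_mm = 0.1), 0)
})

test_that("mid-slice selection matches a brute-force scan", {
  cc <- desk_classical()
  vol <- cc$truth
  counts <- vapply(seq_len(dim(vol)[3]), function(i) {
    m <- vol$classes[, , i] > 0L
    if (!any(m)) 0 else sum(EBImage::fillHull(matrix(as.integer(m), nrow(m))))
  }, numeric(1))
  idx1 <- mid_slices(vol, 1)
  expect_equal(attr(idx1, "center"), which.max(counts))
  expect_length(idx1, 1)
  idx5 <- mid_slices(vol, 5)
  expect_length(idx5, 5)
  expect_true(attr(idx5, "center") %in% idx5)
  expect_error(mid_slices(vol, dim(vol)[3] + 2), "depth")
})

test_that("rectangle fitting recovers ellipse axes rotation-invariantly", {
  mk_ellipse <- function(a, b, th) {
    n <- 101
    x <- matrix(seq_len(n) - 51, n, n); y <- t(x)
    xr <- cos(th) * x + sin(th) * y; yr <- -sin(th) * x + cos(th) * y
    matrix(as.integer((xr / a)^2 + (yr / b)^2 <= 1), n, n)
  }
  f0 <- rectangle_fit(mk_ellipse(30, 25, 0), 0.1)
  expect_lte(abs(f0[[1]] - 6.0), 0.1 + 1e-9)   # within one pixel
  expect_lte(abs(f0[[2]] - 5.0), 0.1 + 1e-9)
  f37 <- rectangle_fit(mk_ellipse(30, 25, 37 * pi / 180), 0.1)
  expect_lt(max(abs(f37 - f0)), 0.15)
  fc <- rectangle_fit(mk_ellipse(28, 28, 0.4), 0.1)
  expect_lt(abs(fc[1] - fc[2]), 0.12)
  expect_error(rectangle_fit(matrix(0L, 5, 5)), "empty")
})

test_that("length/width and cross-section traits match phantom geometry", {
  sp <- phantom_spec(c(3.5, 3.0, 3.0), 0.6, gap_mm = 0.2, lobes = 1L, seed = 2)
  vol <- voxelize(sp, 0.1)
  lw <- fruit_length_width(vol, 5)
  expect_equal(unname(lw[["FL"]]), 7.0, tolerance = 0.2 / 7)
  expect_equal(unname(lw[["FW"]]), 6.0, tolerance = 0.2 / 6)
  # circle of radius 30 mm: FMCA within 1%, FLP within 2%
  disk <- matrix(0L, 620, 620)
  x <- matrix(seq_len(620) - 310.5, 620, 620)
  disk[x^2 + t(x)^2 <= 300^2] <- 1L
  dv <- label_volume(array(disk, c(620, 620, 1)), 0.1)
  mc <- max_cross_section(dv, 1)
  expect_lt(abs(mc[["FMCA"]] - pi * 900) / (pi * 900), 0.01)
  expect_lt(abs(mc[["FLP"]] - 2 * pi * 30) / (2 * pi * 30), 0.02)
  # single-pixel fruit
  one <- label_volume(array(c(rep(0L, 12), 1L, rep(0L, 12)), c(5, 5, 1)), 0.1)
  expect_equal(unname(max_cross_section(one, 1)[["FMCA"]]), 0.01)
})

test_that("pericarp thickness is recovered on annuli", {
  ring_slice <- function(shift = 0) {
    n <- 101
    x <- matrix(seq_len(n) - 51, n, n); y <- t(x)
    outer <- x^2 + y^2 <= 40^2
    inner <- (x - shift)^2 + y^2 <= 30^2
    matrix(as.integer(outer & !inner), n, n)
  }
  vol <- label_volume(array(ring_slice(0), c(101, 101, 1)), 0.1)
  pat <- pericarp_thickness(vol, 1, n_points = 200, seed = 4)
  expect_equal(pat, 1.0, tolerance = 0.05)
  # eccentric annulus vs dense analytic thickness oracle
  vol5 <- label_volume(array(ring_slice(5), c(101, 101, 1)), 0.1)
  pat5 <- pericarp_thickness(vol5, 1, n_points = 400, seed = 4)
  th <- seq(0, 2 * pi, length.out = 4000)
  ox <- 40 * cos(th); oy <- 40 * sin(th)
  ix <- 30 * cos(th) + 5; iy <- 30 * sin(th)
  oracle <- mean(vapply(seq_along(th)[1:2000 * 2], function(i)
    sqrt(min((ox - ix[i])^2 + (oy - iy[i])^2)), numeric(1))) / 10
  expect_lt(abs(pat5 - oracle) / oracle, 0.05)
  # sampling convergence: doubling n changes the estimate by < 1%
  p1 <- pericarp_thickness(vol5, 1, n_points = 2000, seed = 11)
  p2 <- pericarp_thickness(vol5, 1, n_points = 4000, seed = 12)
  expect_lt(abs(p2 - p1) / p1, 0.01)
  solid <- label_volume(array(as.integer(disk_mask(60, 30, 30, 20)),
                              c(60, 60, 1)), 0.1)
  expect_error(pericarp_thickness(solid, 1), "inner boundary")
})

test_that("trait ratios follow their definitions on a constructed volume", {
  cls <- array(0L, c(60, 60, 10))
  for (k in 1:10) cls[, , k] <- square_ring_slice()
  vol <- label_volume(cls, 0.1)
  rec <- compute_traits(vol, k = 5, seed = 1)
  n_per <- sum(cls == 1L); n_sar <- sum(cls == 2L); n_env <- 40 * 40 * 10
  expect_equal(rec$FV, n_env * 1e-3)
  expect_equal(rec$PV, n_per * 1e-3)
  expect_equal(rec$SV, n_sar * 1e-3)
  expect_equal(rec$SC, 100 * n_sar / n_env)
  expect_equal(rec$PC, 100 * n_per / n_env)
  expect_equal(rec$SFR, 100 * n_sar / (n_env - n_per))
  expect_gte(rec$SFR, rec$SC)
  expect_lte(rec$SC + rec$PC, 100)
})

test_that("a spherical fruit has shape index 1 and unit aspect", {
  rec <- compute_traits(sphere_volume_01(), seed = 6)
  expect_equal(rec$FSI, 1, tolerance = 0.03)
  expect_equal(rec$FLWR, 1, tolerance = 0.02)
})

test_that("traits are invariant under in-plane translation", {
  cc <- desk_classical()
  vol <- cc$truth
  shifted <- array(0L, dim(vol$classes))
  shifted[6:nrow(shifted), 4:ncol(shifted), ] <-
    vol$classes[1:(nrow(shifted) - 5), 1:(ncol(shifted) - 3), ]
  r1 <- compute_traits(vol, seed = 2)
  r2 <- compute_traits(label_volume(shifted, 0.1), seed = 2)
  for (tn in c("FW", "FL", "FV", "FSA", "FMCA", "SV", "PV"))
    expect_equal(r1[[tn]], r2[[tn]], tolerance = 1e-6, label = tn)
})

test_that("depth order reversal leaves a symmetric phantom unchanged", {
  vol <- sphere_volume_01()
  rev_vol <- label_volume(vol$classes[, , rev(seq_len(dim(vol)[3]))], 0.1)
  r1 <- compute_traits(vol, seed = 3)
  r2 <- compute_traits(rev_vol, seed = 3)
  expect_equal(r1$FV, r2$FV)
  expect_equal(r1$FW, r2$FW)
})
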