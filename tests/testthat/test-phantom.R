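test_that("phantom specs are deterministic and respect their invariants", {
  expect_identical(make_phantom_spec(1), make_phantom_spec(1))
  expect_error(phantom_spec(c(30, 30, 30), pericarp_thickness_mm = 40),
               "smaller than the smallest semi-axis")
  bad <- phantom_ranges("fruit")
  bad$thickness_mm <- c(40, 45)
  expect_error(make_phantom_spec(1, bad), "infeasible|room")
  specs <- lapply(1:50, make_phantom_spec, ranges = phantom_ranges("fruit"))
  expect_true(all(vapply(specs, function(s) s$lobes %in% 1:3, logical(1))))
  fw <- vapply(specs, function(s) 2 * min(s$outer_semiaxes[1:2]), numeric(1))
  fl <- vapply(specs, function(s) 2 * max(s$outer_semiaxes[1:2]), numeric(1))
  expect_true(all(fw >= 50.9 & fw <= 68.3))
  expect_true(all(fl <= 73.2 & fl / fw >= 1 & fl / fw <= 1.31))
})

test_that("voxelization matches analytic geometry", {
  vol <- sphere_volume_01()
  v_sphere <- 4 / 3 * pi * 27
  expect_lt(abs(fruit_volume(vol) - v_sphere) / v_sphere, 0.02)
  expect_lt(abs(sum(vol$classes > 0) * 0.001 - v_sphere) / v_sphere, 0.02)
  # boundary faces are background (containment margin)
  cls <- vol$classes
  expect_true(all(cls[1, , ] == 0) && all(cls[, 1, ] == 0) &&
                all(cls[, , 1] == 0) && all(cls[dim(cls)[1], , ] == 0))
  # two lobes -> exactly two 26-connected sarcocarp components
  sp2 <- phantom_spec(c(5, 4.5, 4), 0.8, gap_mm = 0.3, lobes = 2L, seed = 5)
  v2 <- voxelize(sp2, 0.1)
  lab <- fruitct:::label3d_cpp(as.integer(v2$classes == 2L), dim(v2$classes))
  expect_identical(attr(lab, "ncomp"), 2L)
  expect_error(voxelize(sphere_spec(), 0.1, c(30, 80, 80)), "axis 1")
})

test_that("rendered stacks reproduce the three grayscale strata", {
  vol <- sphere_volume_01()
  noiseless <- noise_model(background_zero_fraction_target = 1,
                           lowgray_density = 0, seed = 2)
  ct0 <- render_ct(vol, noiseless)
  vals <- unique(as.vector(ct0$voxels))
  expect_true(all(vals == 0 | vals > 60))
  expect_true(all(ct0$voxels[vol$classes == 0] == 0))

  nm <- noise_model(seed = 2)
  ct <- render_ct(vol, nm)
  bg <- ct$voxels[vol$classes == 0]
  expect_lt(abs(mean(bg == 0) - nm$background_zero_fraction_target), 0.02)
  expect_true(all(bg <= 60))
  expect_true(all(bg[bg != 0] >= 1))
  tis <- ct$voxels[vol$classes > 0]
  expect_true(all(tis > 60 & tis <= 255))
  # same labels + same seed -> bit-identical stacks
  expect_identical(ct$voxels, render_ct(vol, nm)$voxels)
})

test_that("pericarp and sarcocarp draw from one intensity distribution", {
  vol <- sphere_volume_01()
  ct <- render_ct(vol, noise_model(seed = 9))
  p <- ct$voxels[vol$classes == 1]
  s <- ct$voxels[vol$classes == 2]
  expect_lt(abs(mean(p) - mean(s)), 2)
  expect_lt(abs(sd(p) - sd(s)), 2)
})

test_that("ground-truth oracle matches closed forms and converges", {
  gt <- ground_truth_traits(sphere_spec())
  expect_equal(gt$FV, 4 / 3 * pi * 27, tolerance = 1e-6)
  expect_equal(gt$FSA, 4 * pi * 9, tolerance = 1e-4)
  expect_equal(gt$FSI, 1, tolerance = 0.001)
  expect_equal(gt$FLWR, 1, tolerance = 1e-12)
  # voxel-counting oracle at pitch r/60 reproduces the sphere volume
  gv <- ground_truth_traits(sphere_spec(), oracle_pitch = 0.05,
                            method = "voxel")
  expect_lt(abs(gv$FV - gt$FV) / gt$FV, 0.005)
  expect_lt(abs(gv$FSI - 1), 0.02)
  # grid refinement: halving the pitch does not grow the volume error
  sp <- make_phantom_spec(4, phantom_ranges("desk"))
  ga <- ground_truth_traits(sp)
  e1 <- abs(ground_truth_traits(sp, 0.2, "voxel")$FV - ga$FV)
  e2 <- abs(ground_truth_traits(sp, 0.1, "voxel")$FV - ga$FV)
  expect_lt(e2, e1 + 0.02 * ga$FV / 100)
  expect_lt(e2 / ga$FV, 0.02)
})

test_that("ground-truth trait relations hold over random draws", {
  for (s in 1:20) {
    gt <- ground_truth_traits(make_phantom_spec(s, phantom_ranges("fruit")))
    expect_lt(gt$SC + gt$PC, 100)
    expect_gte(gt$SFR, gt$SC)
    expect_gte(gt$FL, gt$FW)
    expect_lte(gt$SV + gt$PV, gt$FV)
  }
})

test_that("slice sets mix tissue-bearing and pericarp-only depths", {
  ss <- phantom_slice_set(40, seed = 11, slices_per_phantom = 20)
  expect_length(ss$images, 40)
  has_sarc <- vapply(ss$truth, function(t) any(t$classes == 2L), logical(1))
  expect_true(any(has_sarc) && !all(has_sarc))
  expect_true(all(vapply(ss$images, function(i) all(dim(i) == c(128, 128)),
                         logical(1))))
})
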