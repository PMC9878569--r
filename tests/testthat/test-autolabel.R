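test_that("Otsu on non-zero pixels separates bimodal tissue exactly", {
  img <- matrix(0L, 40, 40)
  img[1:10, ] <- 30L
  img[31:40, ] <- 200L
  ot <- otsu_nonzero(img)
  expect_gte(ot$threshold, 30); expect_lt(ot$threshold, 200)
  expect_identical(ot$mask, img == 200L)
  # adding zeros never moves the threshold
  img2 <- rbind(img, matrix(0L, 60, 40))
  expect_identical(otsu_nonzero(img2)$threshold, ot$threshold)
  expect_error(otsu_nonzero(matrix(c(0L, 7L), 10, 10)), "degenerate")
})

test_that("Otsu equals the exhaustive between-class-variance argmax", {
  with_seed <- function(s, e) { set.seed(s); e }
  brute_otsu <- function(img) {
    v <- img[img > 0]
    bv <- vapply(1:254, function(t) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (length(lo) == 0 || length(hi) == 0) return(-Inf)
      w0 <- length(lo) / length(v)
      w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }, numeric(1))
    which.max(bv)
  }
  set.seed(17)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 900, replace = TRUE,
                         prob = c(3, runif(255))), 30, 30)
    expect_identical(otsu_nonzero(img)$threshold, brute_otsu(img))
  }
})

test_that("contour hierarchy is extracted with filled areas, largest first", {
  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  cs <- extract_contours(sq)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$area, 100^2)

  ann <- disk_mask(100, 50, 50, 40) & !disk_mask(100, 50, 50, 30)
  ca <- extract_contours(ann)
  expect_length(ca, 2)
  expect_gt(ca[[1]]$area, ca[[2]]$area)
  # enclosed areas agree with analytic disk areas to within the perimeter
  expect_lt(abs(ca[[1]]$area - pi * 40^2), 2 * pi * 40 + 10)
  expect_lt(abs(ca[[2]]$area - pi * 30^2), 2 * pi * 30 + 10)
  expect_length(extract_contours(matrix(FALSE, 10, 10)), 0)
  # at most five contours retained
  m <- matrix(FALSE, 40, 90)
  for (j in 0:6) m[5:10, (j * 12 + 2):(j * 12 + 8)] <- TRUE
  expect_length(extract_contours(m), 5)
})

test_that("the 25% merge rule is a strict-inequality gate", {
  build <- function(a4_side) {
    m <- matrix(FALSE, 140, 140)
    m[11:110, 11:110] <- TRUE          # fruit, fill area 10000
    m[21:100, 21:100] <- FALSE         # shell hole, fill area 6400
    m[31:50, 31:50] <- TRUE            # lobe 1: 20x20 = 400
    if (a4_side > 0) m[61:(60 + a4_side), 61:(60 + a4_side)] <- TRUE
    m
  }
  # fourth area 100 = exactly 0.25 * 400: NOT merged
  lab_eq <- assign_regions(extract_contours(build(10)), build(10))
  expect_equal(sum(lab_eq$classes == 2L), 400)
  # fourth area 121 > 100: merged
  lab_gt <- assign_regions(extract_contours(build(11)), build(11))
  expect_equal(sum(lab_gt$classes == 2L), 400 + 121)
  # pericarp is the region between contours 1 and 2 in both cases
  expect_equal(sum(lab_eq$classes == 1L), 10000 - 6400)
  # classes partition the slice
  expect_true(all(lab_eq$classes %in% 0:2))
})

test_that("region assignment is invariant to zero padding", {
  m <- disk_mask(80, 40, 40, 30) & !disk_mask(80, 40, 40, 22)
  m <- m | disk_mask(80, 40, 40, 12)
  lab <- assign_regions(extract_contours(m), m)
  mp <- rbind(matrix(FALSE, 15, ncol(m) + 30),
              cbind(matrix(FALSE, 80, 15), m, matrix(FALSE, 80, 15)),
              matrix(FALSE, 15, ncol(m) + 30))
  labp <- assign_regions(extract_contours(mp), mp)
  expect_identical(labp$classes[16:95, 16:95], lab$classes)
})

test_that("classical labels match voxelized truth on a noiseless slice", {
  sp <- make_phantom_spec(5, phantom_ranges("desk"))
  gs <- fruitct:::default_grid_shape(sp, 0.1); gs[1:2] <- 128L
  vol <- voxelize(sp, 0.1, gs)
  mid <- mid_slices(vol, 1)
  cls <- vol$classes[, , mid]
  ct <- render_ct(vol, noise_model(background_zero_fraction_target = 1,
                                   lowgray_density = 0, seed = 5))
  lab <- autolabel_slice(ct$voxels[, , mid])
  s <- score(lab$classes, cls)
  expect_gte(min(s$dice_per_class), 0.98)
  expect_length(lab$quality_flags, 0)
})

test_that("quality filter flags constructed violations", {
  # valid equatorial phantom slice: no flags (covered above); border touch:
  cls <- square_ring_slice()
  cls2 <- cls
  cls2[, 1:32] <- cls2[, 29:60]   # shift sarcocarp block onto the border
  lab <- label_quality_filter(label_slice(cls2))
  expect_true("touches_border" %in% lab$quality_flags)
  # broken ring
  cls3 <- cls
  cls3[1:30 + 10, 30] <- 0L
  cls3[cls3 == 2L] <- 0L
  lab3 <- label_quality_filter(label_slice(cls3))
  expect_true("ring_broken" %in% lab3$quality_flags)
  # more than three sarcocarp components
  cls4 <- matrix(0L, 80, 80)
  cls4[11:70, 11:70] <- 1L
  cls4[16:65, 16:65] <- 0L
  for (o in seq(20, 56, by = 12)) cls4[o:(o + 3), 30:33] <- 2L
  lab4 <- label_quality_filter(label_slice(cls4))
  expect_true("sarcocarp_components" %in% lab4$quality_flags)
  # empty slice
  expect_true("empty" %in%
                label_quality_filter(label_slice(matrix(0L, 8, 8)))$quality_flags)
})

test_that("unflagged noisy phantom slices carry trustworthy labels", {
  ss <- phantom_slice_set(200, seed = 101)
  labs <- lapply(ss$images, autolabel_slice)
  flagged <- vapply(labs, function(l) length(l$quality_flags) > 0, logical(1))
  expect_gt(mean(flagged), 0)      # poles and partial sections are caught
  expect_lt(mean(flagged), 0.95)   # equatorial sections survive
  ok <- which(!flagged)
  dice <- vapply(ok, function(i)
    score(labs[[i]]$classes, ss$truth[[i]]$classes)$mDice_All, numeric(1))
  expect_gte(min(dice), 0.95)
})
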