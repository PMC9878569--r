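#' @useDynLib fruitct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor prcomp pt qnorm rnorm runif sd
#' @importFrom utils head read.csv write.csv
NULL

# Run an expression with a private RNG stream and restore global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a synthetic fruit phantom specification
#'
#' A phantom is an ellipsoidal fruit: an outer ellipsoid (the fruit
#' surface), a pericarp shell of constant per-axis thickness, an air gap
#' between the pericarp inner wall and the sarcocarp, and 1-3 ellipsoidal
#' sarcocarp lobes strictly inside the gap-shrunken inner wall. The long
#' axis lies in the slice plane, matching a scan in which the fruit's
#' longitudinal axis is parallel to the rotation platform.
#'
#' Lobes are parameterised in the normalised coordinates of the container
#' ellipsoid (inner wall shrunk by the gap), where each lobe is a ball of
#' radius `q` at offset `delta` from the centre; this makes containment and
#' pairwise disjointness checks exact.
#'
#' @param outer_semiaxes numeric length 3, semi-axes in mm: in-plane x,
#'   in-plane y, and along the stack (depth) axis.
#' @param pericarp_thickness_mm positive shell thickness (mm).
#' @param gap_mm nonnegative air gap between pericarp inner wall and
#'   sarcocarp (mm).
#' @param lobes integer, number of sarcocarp lobes (1, 2 or 3).
#' @param lobe_params list with numeric vectors `q` (per-lobe normalised
#'   radius) and `delta`, `phi` (normalised centre offset and its polar
#'   angle in the slice plane). Defaults to a single centred lobe.
#' @param orientation rotation about the stack axis, degrees.
#' @param seed integer stored with the spec (used by downstream rendering).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semiaxes, pericarp_thickness_mm, gap_mm = 1,
                         lobes = 1L, lobe_params = NULL, orientation = 0,
                         seed = 1L) {
  outer_semiaxes <- as.numeric(outer_semiaxes)
  if (length(outer_semiaxes) != 3 || any(outer_semiaxes <= 0))
    stop("outer_semiaxes must be 3 positive lengths (mm)")
  if (pericarp_thickness_mm <= 0)
    stop("pericarp_thickness_mm must be positive")
  if (pericarp_thickness_mm >= min(outer_semiaxes))
    stop(sprintf(
      "pericarp thickness %.2f mm must be smaller than the smallest semi-axis %.2f mm",
      pericarp_thickness_mm, min(outer_semiaxes)))
  if (gap_mm < 0) stop("gap_mm must be nonnegative")
  lobes <- as.integer(lobes)
  if (!lobes %in% 1:3) stop("lobes must be 1, 2 or 3")
  container <- outer_semiaxes - pericarp_thickness_mm - gap_mm
  if (any(container <= 0))
    stop("pericarp thickness plus gap leaves no room for the sarcocarp")
  if (is.null(lobe_params)) {
    lobe_params <- list(q = rep(if (lobes == 1) 0.9 else 0.42, lobes),
                        delta = if (lobes == 1) 0 else rep(0.5, lobes),
                        phi = 2 * pi * (seq_len(lobes) - 1) / lobes)
  }
  lp <- lobe_params
  if (length(lp$q) != lobes || length(lp$delta) != lobes || length(lp$phi) != lobes)
    stop("lobe_params q/delta/phi must each have one entry per lobe")
  if (any(lp$q <= 0)) stop("lobe radii must be positive")
  if (any(lp$delta + lp$q >= 1))
    stop("each lobe must lie strictly inside the pericarp inner wall minus gap")
  if (lobes > 1) {
    cx <- lp$delta * cos(lp$phi); cy <- lp$delta * sin(lp$phi)
    for (i in seq_len(lobes - 1)) for (j in (i + 1):lobes) {
      d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
      if (d < lp$q[i] + lp$q[j]) stop("sarcocarp lobes overlap")
    }
  }
  structure(list(outer_semiaxes = outer_semiaxes,
                 pericarp_thickness_mm = pericarp_thickness_mm,
                 gap_mm = gap_mm, lobes = lobes, lobe_params = lp,
                 orientation = orientation, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Parameter ranges for random phantom generation
#'
#' `scale = "fruit"` emulates the sizes reported for real passion fruit
#' cohorts (width about 51-68 mm, length-width ratio 1.00-1.31, pericarp
#' thickness 1.5-5.5 mm). `scale = "desk"` is a miniature profile whose
#' fruit fit a 128 x 128 pixel slice at 0.1 mm pitch, used for fast
#' segmentation experiments.
#'
#' @param scale `"fruit"` or `"desk"`.
#' @return named list of ranges consumed by [make_phantom_spec()].
#' @export
phantom_ranges <- function(scale = c("fruit", "desk")) {
  scale <- match.arg(scale)
  if (scale == "fruit") {
    list(width_mm = c(51, 68), flwr = c(1.0, 1.31), flwr_cap_mm = 73.2,
         depth_frac = c(0.92, 1.02), thickness_mm = c(1.5, 5.5),
         gap_mm = c(0.5, 2.5))
  } else {
    list(width_mm = c(8.0, 10.4), flwr = c(1.0, 1.25), flwr_cap_mm = 12.2,
         depth_frac = c(0.92, 1.02), thickness_mm = c(0.7, 1.6),
         gap_mm = c(0.2, 0.6))
  }
}

#' Draw a random phantom specification
#'
#' Deterministic for a fixed seed. Lobe count is uniform on \{1, 2, 3\};
#' lobe radii and offsets are drawn within the exact feasibility bounds of
#' the normalised-container parameterisation, so every draw satisfies the
#' `phantom_spec` invariants.
#'
#' @param seed integer seed.
#' @param ranges list as returned by [phantom_ranges()].
#' @return `phantom_spec`.
#' @export
make_phantom_spec <- function(seed, ranges = phantom_ranges("fruit")) {
  r <- ranges
  with_seed(seed, {
    fw <- runif(1, r$width_mm[1], r$width_mm[2])
    flwr_hi <- min(r$flwr[2], r$flwr_cap_mm / fw)
    if (flwr_hi < r$flwr[1])
      stop("infeasible ranges: length cap below minimum length-width ratio")
    flwr <- runif(1, r$flwr[1], flwr_hi)
    fl <- fw * flwr
    a <- fl / 2; b <- fw / 2
    cc <- b * runif(1, r$depth_frac[1], r$depth_frac[2])
    thick <- runif(1, r$thickness_mm[1], r$thickness_mm[2])
    gap <- runif(1, r$gap_mm[1], r$gap_mm[2])
    if (thick + gap >= min(a, b, cc))
      stop("infeasible ranges: thickness plus gap exceeds smallest semi-axis")
    k <- sample.int(3L, 1L)
    if (k == 1L) {
      q <- runif(1, 0.82, 0.95)
      lp <- list(q = q, delta = 0, phi = 0)
    } else if (k == 2L) {
      q <- runif(1, 0.38, 0.47)
      delta <- runif(1, q + 0.02, 1 - q - 0.02)
      phi0 <- runif(1, 0, pi)
      lp <- list(q = rep(q, 2), delta = rep(delta, 2), phi = phi0 + c(0, pi))
    } else {
      q <- runif(1, 0.33, 0.42)
      lo <- 2 * q / sqrt(3) + 0.02
      delta <- runif(1, lo, 1 - q - 0.02)
      phi0 <- runif(1, 0, 2 * pi / 3)
      lp <- list(q = rep(q, 3), delta = rep(delta, 3),
                 phi = phi0 + 2 * pi * (0:2) / 3)
    }
    phantom_spec(outer_semiaxes = c(a, b, cc), pericarp_thickness_mm = thick,
                 gap_mm = gap, lobes = k, lobe_params = lp,
                 orientation = runif(1, 0, 180), seed = seed)
  })
}

# Classify one slice of voxel centres. x, y are coordinate matrices (mm,
# phantom-centred, already in the grid frame); z is the slice coordinate.
# Returns an integer matrix with 0 background, 1 pericarp, 2 sarcocarp.
classify_slice <- function(spec, x, y, z) {
  th <- spec$orientation * pi / 180
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  s <- spec$outer_semiaxes
  t <- spec$pericarp_thickness_mm
  g <- spec$gap_mm
  out <- (xr / s[1])^2 + (yr / s[2])^2 + (z / s[3])^2 <= 1
  si <- s - t
  inn <- (xr / si[1])^2 + (yr / si[2])^2 + (z / si[3])^2 <= 1
  cls <- matrix(0L, nrow(x), ncol(x))
  cls[out & !inn] <- 1L
  sc <- s - t - g
  u <- xr / sc[1]; v <- yr / sc[2]; w <- z / sc[3]
  lp <- spec$lobe_params
  for (j in seq_len(spec$lobes)) {
    cxj <- lp$delta[j] * cos(lp$phi[j]); cyj <- lp$delta[j] * sin(lp$phi[j])
    inlobe <- (u - cxj)^2 + (v - cyj)^2 + w^2 <= lp$q[j]^2
    cls[inlobe] <- 2L
  }
  cls
}

# Grid geometry helper: voxel-centre coordinates for a phantom-centred grid.
grid_coords <- function(n, voxel_mm) (seq_len(n) - (n + 1) / 2) * voxel_mm

# Default grid: bounding box of the rotated outer ellipsoid plus margin.
default_grid_shape <- function(spec, voxel_mm, margin = 3L) {
  s <- spec$outer_semiaxes
  th <- spec$orientation * pi / 180
  # extent of the rotated ellipse in grid x and y
  ex <- sqrt((s[1] * cos(th))^2 + (s[2] * sin(th))^2)
  ey <- sqrt((s[1] * sin(th))^2 + (s[2] * cos(th))^2)
  2L * (ceiling(c(ex, ey, s[3]) / voxel_mm) + margin) + 1L
}

#' Voxelize a phantom into a tri-class label volume
#'
#' Each voxel takes the class of the analytic region containing its
#' centre: 0 background (exterior, gap, cavities), 1 pericarp, 2
#' sarcocarp. The phantom is centred in the grid.
#'
#' @param spec `phantom_spec`.
#' @param voxel_mm isotropic voxel pitch (mm), default 0.1.
#' @param grid_shape integer length 3 (nx, ny, nz); `NULL` fits the grid
#'   to the phantom with a 3-voxel margin.
#' @return `label_volume` (see [label_volume()]).
#' @export
voxelize <- function(spec, voxel_mm = 0.1, grid_shape = NULL) {
  if (is.null(grid_shape)) grid_shape <- default_grid_shape(spec, voxel_mm)
  grid_shape <- as.integer(grid_shape)
  s <- spec$outer_semiaxes
  th <- spec$orientation * pi / 180
  ext <- c(sqrt((s[1] * cos(th))^2 + (s[2] * sin(th))^2),
           sqrt((s[1] * sin(th))^2 + (s[2] * cos(th))^2), s[3])
  half <- grid_shape * voxel_mm / 2
  for (ax in 1:3) if (ext[ax] >= half[ax])
    stop(sprintf("phantom exceeds grid along axis %d (%s): extent %.1f mm, grid %.1f mm",
                 ax, c("x", "y", "z")[ax], 2 * ext[ax], 2 * half[ax]))
  xs <- grid_coords(grid_shape[1], voxel_mm)
  ys <- grid_coords(grid_shape[2], voxel_mm)
  zs <- grid_coords(grid_shape[3], voxel_mm)
  X <- matrix(xs, grid_shape[1], grid_shape[2])
  Y <- matrix(ys, grid_shape[1], grid_shape[2], byrow = TRUE)
  arr <- array(0L, dim = grid_shape)
  for (k in seq_len(grid_shape[3]))
    arr[, , k] <- classify_slice(spec, X, Y, zs[k])
  label_volume(arr, voxel_mm = voxel_mm,
               sample_id = sprintf("phantom_seed%d", spec$seed))
}

#' CT noise model
#'
#' Describes the three grayscale strata of a tomogram: a pure-zero
#' background stratum, a low-gray system-noise stratum in (0, lowgray_upper],
#' and a tissue stratum above `lowgray_upper`. The defaults reproduce a
#' frame in which roughly 29% of all pixels are zero, 47% are low-gray
#' noise and 24% are tissue when the field of view is about three-quarters
#' background. Pericarp and sarcocarp share one intensity distribution:
#' the two tissues are not separable by gray value.
#'
#' @param background_zero_fraction_target fraction of background voxels
#'   rendered as exactly zero.
#' @param lowgray_upper upper gray level of the noise stratum (default 60).
#' @param tissue_mean,tissue_sd gray-level moments of the tissue stratum
#'   (normal, truncated to `(lowgray_upper, 255]`).
#' @param lowgray_density per-voxel probability that a background voxel
#'   carries nonzero low-gray noise; must equal
#'   `1 - background_zero_fraction_target`.
#' @param seed integer RNG seed for rendering.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(background_zero_fraction_target = 0.379,
                        lowgray_upper = 60, tissue_mean = 150,
                        tissue_sd = 30,
                        lowgray_density = 1 - background_zero_fraction_target,
                        seed = 1L) {
  if (lowgray_upper <= 0 || lowgray_upper >= tissue_mean || tissue_mean > 255)
    stop("need 0 < lowgray_upper < tissue_mean <= 255")
  fr <- c(background_zero_fraction_target, lowgray_density)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(background_zero_fraction_target + lowgray_density - 1) > 1e-8)
    stop("lowgray_density must equal 1 - background_zero_fraction_target")
  structure(list(background_zero_fraction_target = background_zero_fraction_target,
                 lowgray_upper = lowgray_upper, tissue_mean = tissue_mean,
                 tissue_sd = tissue_sd, lowgray_density = lowgray_density,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Render one label slice to gray values under a noise model, consuming the
# current RNG stream (callers seed it).
render_slice_rng <- function(cls, noise) {
  n <- length(cls)
  g <- integer(n)
  bg <- cls == 0L
  nbg <- sum(bg)
  if (nbg > 0 && noise$lowgray_density > 0) {
    hit <- runif(nbg) < noise$lowgray_density
    vals <- integer(nbg)
    vals[hit] <- as.integer(ceiling(runif(sum(hit), 0, noise$lowgray_upper)))
    g[bg] <- vals
  }
  tis <- !bg
  nt <- sum(tis)
  if (nt > 0) {
    lo <- pnorm(noise$lowgray_upper, noise$tissue_mean, noise$tissue_sd)
    hi <- pnorm(255, noise$tissue_mean, noise$tissue_sd)
    u <- runif(nt, lo, hi)
    v <- qnorm(u, noise$tissue_mean, noise$tissue_sd)
    g[tis] <- pmin(255L, pmax(as.integer(noise$lowgray_upper) + 1L,
                              as.integer(round(v))))
  }
  matrix(g, nrow(cls), ncol(cls))
}

#' Render a label volume as a CT-like tomogram stack
#'
#' Tissue voxels (pericarp and sarcocarp alike) draw from a truncated
#' normal on `(lowgray_upper, 255]`; background voxels are zero with the
#' configured probability and otherwise uniform low-gray noise in
#' `(0, lowgray_upper]`. Bit-identical for a fixed seed.
#'
#' @param labels `label_volume`.
#' @param noise `noise_model`.
#' @return `tomogram_stack`.
#' @export
#' @importFrom stats pnorm
render_ct <- function(labels, noise = noise_model()) {
  stopifnot(inherits(labels, "label_volume"))
  arr <- labels$classes
  out <- array(0L, dim = dim(arr))
  with_seed(noise$seed, {
    for (k in seq_len(dim(arr)[3]))
      out[, , k] <- render_slice_rng(arr[, , k], noise)
  })
  tomogram_stack(out, voxel_mm = labels$voxel_mm, sample_id = labels$sample_id)
}

# --- analytic geometry helpers for the ground-truth oracle ----------------

ellipsoid_area <- function(a, b, c, n = 400) {
  th <- (seq_len(n) - 0.5) * pi / n        # polar angle
  ph <- (seq_len(n) - 0.5) * 2 * pi / n    # azimuth
  st <- sin(th); ct <- cos(th)
  # |r_theta x r_phi| for x = a sin t cos p, y = b sin t sin p, z = c cos t
  A <- 0
  for (i in seq_len(n)) {
    sp <- sin(ph); cp <- cos(ph)
    f <- st[i] * sqrt((b * c * st[i] * cp)^2 + (a * c * st[i] * sp)^2 +
                        (a * b * ct[i])^2)
    A <- A + sum(f)
  }
  A * (pi / n) * (2 * pi / n)
}

ellipse_perimeter <- function(a, b, n = 20000) {
  t <- (seq_len(n) - 0.5) * 2 * pi / n
  sum(sqrt((a * sin(t))^2 + (b * cos(t))^2)) * 2 * pi / n
}

# Mean thickness of the shell between inner ellipse (a-t, b-t) and outer
# ellipse (a, b): average over inner-boundary points (uniform in arc
# length) of the distance to the nearest outer-boundary point.
ellipse_shell_thickness <- function(a, b, t, n_in = 2000, n_out = 20000) {
  ti <- (seq_len(n_in) - 0.5) * 2 * pi / n_in
  ai <- a - t; bi <- b - t
  # uniform-in-arc-length weights on the inner ellipse
  w <- sqrt((ai * sin(ti))^2 + (bi * cos(ti))^2)
  px <- ai * cos(ti); py <- bi * sin(ti)
  to <- (seq_len(n_out) - 0.5) * 2 * pi / n_out
  qx <- a * cos(to); qy <- b * sin(to)
  d <- vapply(seq_len(n_in), function(i)
    sqrt(min((qx - px[i])^2 + (qy - py[i])^2)), numeric(1))
  sum(d * w) / sum(w)
}

#' Ground-truth traits of a phantom
#'
#' The analytic oracle (default) derives every trait from the closed-form
#' geometry of the spec: ellipsoid volumes and surface area (numerically
#' integrated to high precision), mid-plane ellipse cross-section and
#' perimeter, and mean shell thickness from dense point-to-ellipse
#' distances. `method = "voxel"` instead voxelizes at `oracle_pitch` and
#' runs the measurement pipeline, which is useful for grid-convergence
#' checks at small scales.
#'
#' @param spec `phantom_spec`.
#' @param oracle_pitch voxel pitch for `method = "voxel"` (mm).
#' @param method `"analytic"` or `"voxel"`.
#' @return `trait_record`.
#' @export
ground_truth_traits <- function(spec, oracle_pitch = 0.025,
                                method = c("analytic", "voxel")) {
  method <- match.arg(method)
  if (method == "voxel") {
    vol <- voxelize(spec, voxel_mm = oracle_pitch)
    return(compute_traits(vol, seed = spec$seed))
  }
  s <- spec$outer_semiaxes
  a <- s[1]; b <- s[2]; cc <- s[3]
  t <- spec$pericarp_thickness_mm
  FL <- 2 * max(a, b); FW <- 2 * min(a, b)
  FV <- 4 / 3 * pi * a * b * cc
  FSA <- ellipsoid_area(a, b, cc)
  FMCA <- pi * a * b
  FLP <- ellipse_perimeter(max(a, b), min(a, b))
  FLWR <- FL / FW
  FSI <- pi^(1 / 3) * (6 * FV)^(2 / 3) / (FSA * FLWR)
  inner <- 4 / 3 * pi * prod(s - t)
  PV <- FV - inner
  sc <- s - t - spec$gap_mm
  SV <- sum(4 / 3 * pi * spec$lobe_params$q^3 * prod(sc))
  SC <- 100 * SV / FV
  PC <- 100 * PV / FV
  SFR <- 100 * SV / (FV - PV)
  PAT <- ellipse_shell_thickness(a, b, t)
  trait_record(FW = FW, FL = FL, FSA = FSA, FV = FV, FMCA = FMCA, FLP = FLP,
               FLWR = FLWR, FSI = FSI, SV = SV, SC = SC, SFR = SFR,
               PV = PV, PC = PC, PAT = PAT,
               sample_id = sprintf("phantom_seed%d", spec$seed))
}

#' Generate a set of rendered phantom tomogram slices with truth labels
#'
#' Draws desk-scale phantoms and samples `slices_per_phantom` tomograms
#' at evenly spaced depths across each fruit, rendering every slice with
#' the CT noise model. The set mixes equatorial three-tissue sections
#' with near-polar pericarp-only sections, the depth variety a
#' segmentation network meets in a real stack.
#'
#' @param n_slices total number of slices to return.
#' @param seed base seed (phantom i uses `seed + i - 1`).
#' @param ranges phantom parameter ranges (default desk scale).
#' @param voxel_mm voxel pitch.
#' @param grid_px in-plane grid size (slices are `grid_px` square).
#' @param slices_per_phantom depths sampled per phantom (default 20).
#' @return list with `images` (gray matrices), `truth` (`label_slice`
#'   list, provenance `"truth"`) and `specs`.
#' @export
phantom_slice_set <- function(n_slices, seed = 42L,
                              ranges = phantom_ranges("desk"),
                              voxel_mm = 0.1, grid_px = 128L,
                              slices_per_phantom = 20L) {
  n_ph <- ceiling(n_slices / slices_per_phantom)
  images <- vector("list", n_slices)
  truth <- vector("list", n_slices)
  specs <- vector("list", n_ph)
  xs <- grid_coords(grid_px, voxel_mm)
  X <- matrix(xs, grid_px, grid_px)
  Y <- matrix(xs, grid_px, grid_px, byrow = TRUE)
  i <- 0L
  for (p in seq_len(n_ph)) {
    sp <- make_phantom_spec(seed + p - 1L, ranges)
    specs[[p]] <- sp
    noise <- noise_model(seed = sp$seed)
    zmax <- 0.92 * sp$outer_semiaxes[3]
    zs <- seq(-zmax, zmax, length.out = slices_per_phantom)
    for (z in zs) {
      if (i >= n_slices) break
      i <- i + 1L
      cls <- classify_slice(sp, X, Y, z)
      images[[i]] <- with_seed(noise$seed * 1000L + i,
                               render_slice_rng(cls, noise))
      truth[[i]] <- label_slice(cls, provenance = "truth")
    }
  }
  list(images = images, truth = truth, specs = specs)
}

#' Generate a phantom cohort with stacks, labels and ground truth
#'
#' Writes (optionally) per-sample tomogram TIFF stacks and label stacks,
#' and returns the specs together with a ground-truth trait table.
#'
#' @param n number of phantoms.
#' @param seed base seed; sample `i` uses `seed + i - 1`.
#' @param ranges see [phantom_ranges()].
#' @param voxel_mm voxel pitch for the optional stacks.
#' @param out_dir if non-`NULL`, directory receiving `sample_XX/ct/`,
#'   `sample_XX/labels/` TIFF sequences and `ground_truth.csv`.
#' @return list with `specs` and `truth` (data frame, one row per sample).
#' @export
phantom_generate <- function(n, seed = 42L, ranges = phantom_ranges("fruit"),
                             voxel_mm = 0.1, out_dir = NULL) {
  specs <- lapply(seq_len(n), function(i) make_phantom_spec(seed + i - 1L, ranges))
  truth <- do.call(rbind, lapply(specs, function(sp)
    as.data.frame(ground_truth_traits(sp))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      lab <- voxelize(specs[[i]], voxel_mm = voxel_mm)
      ct <- render_ct(lab, noise_model(seed = specs[[i]]$seed))
      write_stack(ct, file.path(out_dir, sprintf("sample_%02d", i), "ct"))
      lab_stack <- tomogram_stack(lab$classes, voxel_mm = voxel_mm,
                                  sample_id = lab$sample_id)
      write_stack(lab_stack, file.path(out_dir, sprintf("sample_%02d", i), "labels"))
    }
    write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  }
  list(specs = specs, truth = truth)
}
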