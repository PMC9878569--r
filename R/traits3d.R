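#' Tri-class label volume container
#'
#' @param classes 3D integer array (rows x cols x depth), values 0
#'   (background), 1 (pericarp), 2 (sarcocarp).
#' @param voxel_mm isotropic voxel pitch (mm).
#' @param sample_id identifier.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(classes, voxel_mm = 0.1, sample_id = "sample") {
  if (length(dim(classes)) == 2) dim(classes) <- c(dim(classes), 1L)
  if (length(dim(classes)) != 3) stop("classes must be a 3D array")
  if (voxel_mm <= 0) stop("voxel pitch must be positive")
  structure(list(classes = classes, voxel_mm = voxel_mm, sample_id = sample_id),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$classes)

#' Stack ordered label slices into a label volume
#'
#' Slices whose quality flags mark them as untrustworthy (by default a
#' broken contour nesting or foreground touching the image border, the
#' signatures of a degenerate threshold on a nearly empty tomogram)
#' contribute background rather than their garbage labels, so that
#' downstream mid-slice selection and volume counting stay robust.
#'
#' @param slices list of `label_slice` (or integer matrices) in ascending
#'   depth order.
#' @param voxel_mm isotropic pitch; one voxel has volume `voxel_mm^3`.
#' @param sample_id identifier.
#' @param reject_flags quality flags that blank a slice to background.
#' @return `label_volume`.
#' @export
stack_labels <- function(slices, voxel_mm = 0.1, sample_id = "sample",
                         reject_flags = c("nesting_violation", "touches_border")) {
  mats <- lapply(slices, function(s) {
    if (!inherits(s, "label_slice")) return(s)
    if (any(s$quality_flags %in% reject_flags))
      array(0L, dim(s$classes)) else s$classes
  })
  d1 <- dim(mats[[1]])
  for (i in seq_along(mats))
    if (!identical(dim(mats[[i]]), d1))
      stop(sprintf("slice %d has shape %s, expected %s", i,
                   paste(dim(mats[[i]]), collapse = "x"),
                   paste(d1, collapse = "x")))
  arr <- array(0L, dim = c(d1, length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  label_volume(arr, voxel_mm = voxel_mm, sample_id = sample_id)
}

#' Remove stray components from a label volume
#'
#' Keeps the largest 26-connected component of the fruit foreground
#' (pericarp plus sarcocarp); within it, the sarcocarp keeps at most its
#' `max_lobes` largest components. Everything else becomes background.
#'
#' @param vol `label_volume`.
#' @param max_lobes maximum sarcocarp components retained (default 3).
#' @return cleaned `label_volume`.
#' @export
clean_components <- function(vol, max_lobes = 3L) {
  cls <- vol$classes
  fg <- cls > 0L
  if (!any(fg)) stop("no sample found: label volume has empty foreground")
  # component analysis on the filled envelope, so the gap-separated
  # sarcocarp stays attached to its fruit
  filled <- fill_fruit_mask(cls)
  lab <- label3d_cpp(as.integer(filled), dim(cls))
  nc <- attr(lab, "ncomp")
  if (nc > 1) {
    sizes <- tabulate(lab, nbins = nc)
    keep <- which.max(sizes)
    if (sort(sizes, decreasing = TRUE)[2] > 0.01 * sizes[keep])
      warning("multiple foreground objects found; keeping the largest")
    cls[lab != keep & fg] <- 0L
  }
  sarc <- cls == 2L
  if (any(sarc)) {
    sl <- label3d_cpp(as.integer(sarc), dim(cls))
    ns <- attr(sl, "ncomp")
    if (ns > max_lobes) {
      sizes <- tabulate(sl, nbins = ns)
      drop <- setdiff(seq_len(ns), order(sizes, decreasing = TRUE)[seq_len(max_lobes)])
      cls[array(sl %in% drop, dim(cls))] <- 0L
    }
  }
  label_volume(cls, voxel_mm = vol$voxel_mm, sample_id = vol$sample_id)
}

#' Volume of a class set
#'
#' @param vol `label_volume`.
#' @param classes integer vector of class values to count.
#' @return volume in mm^3 (voxel count times `voxel_mm^3`).
#' @export
class_volume <- function(vol, classes) {
  sum(vol$classes %in% classes) * vol$voxel_mm^3
}

# Fill the fruit envelope slice-wise: fruit region including internal
# cavities and the pericarp-sarcocarp gap.
fill_fruit_mask <- function(cls) {
  d <- dim(cls)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    m <- cls[, , k] > 0L
    if (any(m)) out[, , k] <- fill_holes(m)
  }
  out
}

#' Whole-fruit (envelope) volume
#'
#' Volume enclosed by the outer fruit surface, i.e. tissue plus internal
#' cavities and the low-density gap, obtained by hole-filling each slice.
#' This is the fruit volume that enters content percentages and the shape
#' index.
#'
#' @param vol `label_volume`.
#' @return volume in mm^3.
#' @export
fruit_volume <- function(vol) {
  sum(fill_fruit_mask(vol$classes)) * vol$voxel_mm^3
}

pad_mask <- function(mask, pad) {
  d <- dim(mask)
  out <- array(0, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  out
}

#' Surface area of a voxel mask
#'
#' The default estimator Gaussian-smooths the binary indicator and meshes
#' the 0.5 isosurface by marching tetrahedra, summing triangle areas; the
#' alternative integrates the gradient magnitude of the same smoothed
#' indicator (coarea formula). Both remove the stair-step bias of the
#' voxel surface; naive exposed-face counting, provided as
#' `method = "faces"` for reference, overestimates a sphere by about 50%.
#'
#' @param x `label_volume` or logical/integer 3D array (the mask).
#' @param classes when `x` is a `label_volume`, the class set defining the
#'   mask.
#' @param method `"mesh"`, `"gradient"` or `"faces"`.
#' @param voxel_mm pitch when `x` is a bare array.
#' @param smooth_sigma Gaussian sigma in voxels (default 1).
#' @return surface area in mm^2.
#' @export
surface_area <- function(x, classes = NULL, method = c("mesh", "gradient", "faces"),
                         voxel_mm = NULL, smooth_sigma = 1) {
  method <- match.arg(method)
  if (inherits(x, "label_volume")) {
    if (is.null(classes)) stop("classes must be given for a label volume")
    mask <- array(x$classes %in% classes, dim(x$classes))
    voxel_mm <- x$voxel_mm
  } else {
    mask <- array(as.logical(x), dim(x))
    if (is.null(voxel_mm)) stop("voxel_mm must be given for a bare mask")
  }
  if (!any(mask)) return(0)
  if (method == "faces")
    return(exposed_faces_cpp(as.integer(mask), dim(mask)) * voxel_mm^2)
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1L)
  m <- pad_mask(mask, pad)
  sm <- gauss3d_cpp(as.numeric(m), dim(m), smooth_sigma)
  if (method == "mesh") {
    a <- march_tet_area_cpp(sm, dim(m), 0.5)
  } else {
    arr <- array(sm, dim(m))
    d <- dim(m)
    gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    gx[i, , ] <- (arr[i + 1, , ] - arr[i - 1, , ]) / 2
    gy[, j, ] <- (arr[, j + 1, ] - arr[, j - 1, ]) / 2
    gz[, , k] <- (arr[, , k + 1] - arr[, , k - 1]) / 2
    a <- sum(sqrt(gx^2 + gy^2 + gz^2))
  }
  a * voxel_mm^2
}

#' Mid-depth slice indices
#'
#' The slice maximising the fruit cross-sectional area (the filled
#' envelope, so internal cavities count toward the fruit), with
#' `(k - 1) / 2` neighbours on each side, shifted to stay in range.
#'
#' @param vol `label_volume`.
#' @param k odd number of slices.
#' @return integer slice indices, centre first attribute `center`.
#' @export
mid_slices <- function(vol, k = 5L) {
  k <- as.integer(k)
  d <- dim(vol$classes)
  if (k > d[3]) stop("k exceeds stack depth")
  counts <- vapply(seq_len(d[3]), function(i) {
    m <- vol$classes[, , i] > 0L
    if (any(m)) sum(fill_holes(m)) else 0
  }, numeric(1))
  ctr <- which.max(counts)
  half <- (k - 1L) %/% 2L
  lo <- max(1L, min(ctr - half, d[3] - k + 1L))
  idx <- lo:(lo + k - 1L)
  attr(idx, "center") <- ctr
  idx
}

# Rotated-rectangle sides by rotating calipers over the convex hull:
# the long side is the maximum caliper (Feret) diameter, the short side
# the minimum caliper width. This orientation choice is stable where the
# minimum-area criterion is nearly flat (near-circular sections). pts:
# n x 2 pixel coordinates; sides in px, counting a side of n pixel
# centres as extent + 1.
min_area_rect <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 1) return(c(1, 1))
  if (nh == 2) {
    len <- sqrt(sum((hp[2, ] - hp[1, ])^2))
    return(c(len + 1, 1))
  }
  dmax <- 0
  for (i in seq_len(nh - 1)) {
    d2 <- (hp[(i + 1):nh, 1] - hp[i, 1])^2 + (hp[(i + 1):nh, 2] - hp[i, 2])^2
    dmax <- max(dmax, d2)
  }
  wmin <- Inf
  for (e in seq_len(nh)) {
    p1 <- hp[e, ]; p2 <- hp[if (e == nh) 1 else e + 1, ]
    u <- p2 - p1
    nu <- sqrt(sum(u^2))
    if (nu == 0) next
    v <- c(-u[2], u[1]) / nu
    wmin <- min(wmin, diff(range(hp %*% v)))
  }
  c(sqrt(dmax) + 1, wmin + 1)
}

#' Fit a rotated bounding rectangle to a fruit slice
#'
#' The rectangle is oriented along the maximum caliper (Feret) diameter
#' of the convex outline; its short side is the minimum caliper width.
#'
#' @param slice `label_slice` or integer class matrix.
#' @param voxel_mm pixel pitch (mm).
#' @return named numeric `c(long_mm, short_mm)`, long side first.
#' @export
rectangle_fit <- function(slice, voxel_mm = 0.1) {
  cls <- if (inherits(slice, "label_slice")) slice$classes else slice
  m <- cls > 0L
  if (!any(m)) stop("empty slice: no fruit pixels")
  filled <- fill_holes(m)
  pts <- which(filled, arr.ind = TRUE)
  sides <- min_area_rect(pts)
  c(long_mm = sides[1] * voxel_mm, short_mm = sides[2] * voxel_mm)
}

#' Fruit length and width from mid-depth rectangle fits
#'
#' Rectangle fitting on the `k` mid-depth slices; the fruit length is the
#' largest long side, the width the largest short side. `FL >= FW` by
#' construction.
#'
#' @param vol `label_volume`.
#' @param k number of mid slices (default 5).
#' @return named numeric `c(FL, FW)` in mm.
#' @export
fruit_length_width <- function(vol, k = 5L) {
  idx <- mid_slices(vol, k)
  fits <- vapply(idx, function(i)
    rectangle_fit(vol$classes[, , i], vol$voxel_mm), numeric(2))
  res <- sort(c(max(fits[1, ]), max(fits[2, ])), decreasing = TRUE)
  c(FL = res[1], FW = res[2])
}

#' Maximum cross-sectional area and longitudinal perimeter
#'
#' Measured on the slice with the largest fruit area: the cross-sectional
#' area is the filled fruit pixel count and the perimeter is the length of
#' the convex outline of the filled region (polygonal, limiting pixel-edge
#' quantisation bias).
#'
#' @param vol `label_volume`.
#' @param k mid-slice window (the argmax slice is used).
#' @return named numeric `c(FMCA, FLP)` in mm^2 and mm.
#' @export
max_cross_section <- function(vol, k = 5L) {
  idx <- mid_slices(vol, k)
  ctr <- attr(idx, "center")
  m <- vol$classes[, , ctr] > 0L
  filled <- fill_holes(m)
  fmca <- sum(filled) * vol$voxel_mm^2
  pts <- which(filled, arr.ind = TRUE)
  h <- grDevices::chull(pts)
  hp <- pts[c(h, h[1]), , drop = FALSE]
  per <- sum(sqrt(rowSums(diff(hp)^2))) * vol$voxel_mm
  c(FMCA = fmca, FLP = per)
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  r <- seq_len(nrow(m)); c <- seq_len(ncol(m))
  rs <- r + dr; cs <- c + dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[r[ok_r], c[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Pericarp average thickness by random boundary sampling
#'
#' On each mid-depth slice, uniform random points on the pericarp inner
#' boundary are paired with their nearest outer-boundary point; the trait
#' is the grand mean distance. Deterministic for a fixed seed.
#'
#' @param vol `label_volume`.
#' @param k number of mid slices.
#' @param n_points sample size per slice (default 200).
#' @param seed RNG seed.
#' @return PAT in mm.
#' @export
pericarp_thickness <- function(vol, k = 5L, n_points = 200L, seed = 1L) {
  idx <- mid_slices(vol, k)
  with_seed(seed, {
    dists <- lapply(idx, function(i) {
      cls <- vol$classes[, , i]
      P <- cls == 1L
      if (!any(P)) return(numeric(0))
      Ff <- fill_holes(cls > 0L)
      inner_region <- Ff & !P
      nb_out <- !(shift_mask(Ff, 1, 0) & shift_mask(Ff, -1, 0) &
                    shift_mask(Ff, 0, 1) & shift_mask(Ff, 0, -1))
      outer_b <- P & nb_out
      nb_in <- shift_mask(inner_region, 1, 0) | shift_mask(inner_region, -1, 0) |
        shift_mask(inner_region, 0, 1) | shift_mask(inner_region, 0, -1)
      inner_b <- P & nb_in
      if (!any(inner_b))
        stop("missing inner boundary: pericarp has no interior cavity")
      ip <- which(inner_b, arr.ind = TRUE)
      op <- which(outer_b, arr.ind = TRUE)
      take <- if (nrow(ip) <= n_points) seq_len(nrow(ip)) else
        sample.int(nrow(ip), n_points)
      # +1 px: boundary pixel centres sit half a pixel inside each wall
      vapply(take, function(j)
        sqrt(min((op[, 1] - ip[j, 1])^2 + (op[, 2] - ip[j, 2])^2)) + 1,
        numeric(1))
    })
    mean(unlist(dists)) * vol$voxel_mm
  })
}

#' The fourteen-trait record of one sample
#'
#' Whole-fruit traits (FW, FL, FSA, FV, FMCA, FLP, FLWR, FSI), sarcocarp
#' traits (SV, SC, SFR) and pericarp traits (PV, PC, PAT), in canonical
#' order. Units: mm, mm^2, mm^3, percent, or dimensionless.
#'
#' @param FW,FL,FSA,FV,FMCA,FLP,FLWR,FSI,SV,SC,SFR,PV,PC,PAT trait values.
#' @param sample_id identifier.
#' @return object of class `trait_record`.
#' @export
trait_record <- function(FW, FL, FSA, FV, FMCA, FLP, FLWR, FSI,
                         SV, SC, SFR, PV, PC, PAT, sample_id = "sample") {
  structure(list(sample_id = sample_id, FW = FW, FL = FL, FSA = FSA, FV = FV,
                 FMCA = FMCA, FLP = FLP, FLWR = FLWR, FSI = FSI, SV = SV,
                 SC = SC, SFR = SFR, PV = PV, PC = PC, PAT = PAT),
            class = "trait_record")
}

#' Canonical trait column order
#' @return character vector of the fourteen trait abbreviations.
#' @export
trait_names <- function() c("FW", "FL", "FSA", "FV", "FMCA", "FLP", "FLWR",
                            "FSI", "SV", "SC", "SFR", "PV", "PC", "PAT")

#' @export
as.data.frame.trait_record <- function(x, ...) {
  data.frame(sample_id = x$sample_id,
             as.data.frame(x[trait_names()], check.names = FALSE),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Compute the fourteen morphological traits of a label volume
#'
#' Volumes count voxels (sarcocarp and pericarp classes; the whole-fruit
#' volume is the filled envelope, so cavities and the shell gap count
#' toward the fruit but not toward tissue); the surface area comes from
#' isosurface meshing of the envelope; length and width come from
#' mid-depth rectangle fits; the shape index combines sphericity with the
#' length-width ratio:
#' \deqn{FSI = \pi^{1/3} (6 FV)^{2/3} / (FSA \cdot FLWR).}
#' Content percentages are `SC = 100 SV / FV`, `PC = 100 PV / FV`, and the
#' sarcocarp filling rate `SFR = 100 SV / (FV - PV)` (share of the pulp in
#' everything inside the fruit except the pericarp).
#'
#' @param vol `label_volume` (cleaned internally).
#' @param k mid-depth window (default 5 slices).
#' @param n_points PAT boundary samples per slice.
#' @param seed RNG seed for PAT sampling.
#' @param surface_method estimator passed to [surface_area()].
#' @return `trait_record`.
#' @export
compute_traits <- function(vol, k = 5L, n_points = 200L, seed = 1L,
                           surface_method = "mesh") {
  vol <- clean_components(vol)
  v3 <- vol$voxel_mm^3
  filled <- fill_fruit_mask(vol$classes)
  FV <- sum(filled) * v3
  SV <- class_volume(vol, 2L)
  PV <- class_volume(vol, 1L)
  if (FV <= 0) stop("fruit volume is zero")
  FSA <- surface_area(filled, voxel_mm = vol$voxel_mm, method = surface_method)
  lw <- fruit_length_width(vol, k)
  mc <- max_cross_section(vol, k)
  FLWR <- lw[["FL"]] / lw[["FW"]]
  FSI <- pi^(1 / 3) * (6 * FV)^(2 / 3) / (FSA * FLWR)
  if (FV == PV) stop("fruit volume equals pericarp volume; SFR undefined")
  PAT <- pericarp_thickness(vol, k, n_points, seed)
  trait_record(FW = lw[["FW"]], FL = lw[["FL"]], FSA = FSA, FV = FV,
               FMCA = mc[["FMCA"]], FLP = mc[["FLP"]], FLWR = FLWR, FSI = FSI,
               SV = SV, SC = 100 * SV / FV, SFR = 100 * SV / (FV - PV),
               PV = PV, PC = 100 * PV / FV, PAT = PAT,
               sample_id = vol$sample_id)
}

#' Streaming classical-path measurement of mid-depth traits
#'
#' Runs the classical-only pipeline on a phantom without materialising the
#' full volume: slices are voxelized one at a time to locate the
#' mid-depth window by fruit pixel area, then only the window slices are
#' rendered as CT, weak-labeled with [autolabel_slice()], and measured.
#' Suited to full-size fruit at 0.1 mm pitch, where a whole stack would
#' occupy hundreds of millions of voxels.
#'
#' @param spec `phantom_spec`.
#' @param voxel_mm voxel pitch (default 0.1 mm).
#' @param k mid-depth window size.
#' @param noise `noise_model`; defaults to the standard model seeded from
#'   the spec.
#' @param low_cut autolabel noise ceiling.
#' @param n_points PAT samples per slice.
#' @return list with `FW`, `FL`, `FMCA`, `FLP`, `PAT` (mm-based units),
#'   the mid-slice indices and per-slice quality flags.
#' @export
measure_sample_classical <- function(spec, voxel_mm = 0.1, k = 5L,
                                     noise = NULL, low_cut = 60,
                                     n_points = 200L) {
  if (is.null(noise)) noise <- noise_model(seed = spec$seed)
  shape <- default_grid_shape(spec, voxel_mm)
  xs <- grid_coords(shape[1], voxel_mm)
  ys <- grid_coords(shape[2], voxel_mm)
  zs <- grid_coords(shape[3], voxel_mm)
  X <- matrix(xs, shape[1], shape[2])
  Y <- matrix(ys, shape[1], shape[2], byrow = TRUE)
  # envelope cross-section area profile: the filled fruit area of a slice
  # is the in-ellipse pixel count, computable from one precomputed
  # quadratic form per slice
  th <- spec$orientation * pi / 180
  s <- spec$outer_semiaxes
  Q <- ((cos(th) * X + sin(th) * Y) / s[1])^2 +
    ((-sin(th) * X + cos(th) * Y) / s[2])^2
  counts <- vapply(seq_len(shape[3]), function(kk)
    sum(Q <= 1 - (zs[kk] / s[3])^2), numeric(1))
  ctr <- which.max(counts)
  half <- (k - 1L) %/% 2L
  lo <- max(1L, min(ctr - half, shape[3] - k + 1L))
  idx <- lo:(lo + k - 1L)
  labs <- vector("list", length(idx))
  flags <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    cls <- classify_slice(spec, X, Y, zs[idx[j]])
    ct <- with_seed(noise$seed + idx[j], render_slice_rng(cls, noise))
    lab <- autolabel_slice(ct, low_cut = low_cut)
    labs[[j]] <- lab
    flags[[j]] <- lab$quality_flags
  }
  vol <- stack_labels(labs, voxel_mm = voxel_mm,
                      sample_id = sprintf("phantom_seed%d", spec$seed))
  lw <- fruit_length_width(vol, k = length(idx))
  mc <- max_cross_section(vol, k = length(idx))
  pat <- pericarp_thickness(vol, k = length(idx), n_points = n_points,
                            seed = spec$seed)
  list(FW = lw[["FW"]], FL = lw[["FL"]], FMCA = mc[["FMCA"]],
       FLP = mc[["FLP"]], PAT = pat, mid_indices = idx, quality_flags = flags)
}
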