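#' Tomogram stack container
#'
#' A 3D grayscale volume of reconstructed CT slices with an isotropic
#' voxel pitch. The array is stored `rows x cols x depth`, so `voxels[, , k]`
#' is the k-th tomogram in acquisition (depth) order. Gray levels are
#' integers in 0-255; 16-bit sources are rescaled at read time.
#'
#' @param voxels 3D integer array (rows x cols x depth), values 0-255.
#' @param voxel_mm isotropic voxel pitch in mm (default 0.1).
#' @param sample_id identifier string.
#' @param bits source bit depth (8 or 16), kept for pass-through writing.
#' @return object of class `tomogram_stack`.
#' @export
tomogram_stack <- function(voxels, voxel_mm = 0.1, sample_id = "sample",
                           bits = 8L) {
  if (length(dim(voxels)) == 2) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (voxel_mm <= 0) stop("voxel pitch must be positive")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 255) stop("gray values must lie in 0-255")
  structure(list(voxels = voxels, voxel_mm = voxel_mm,
                 sample_id = sample_id, bits = as.integer(bits)),
            class = "tomogram_stack")
}

#' @export
dim.tomogram_stack <- function(x) dim(x$voxels)

stack_files <- function(path) {
  f <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                  full.names = TRUE)
  if (length(f) == 0) stop("no TIFF files found in ", path)
  idx <- suppressWarnings(as.numeric(gsub("\\D", "", basename(f))))
  if (anyNA(idx)) f[order(basename(f))] else f[order(idx)]
}

#' Read a tomogram stack from a directory of TIFF slices
#'
#' Slices are ordered by the numeric part of their filenames. Single
#' channel images are required; 16-bit inputs are linearly rescaled to the
#' canonical 0-255 range.
#'
#' @param path directory containing one single-channel TIFF per slice.
#' @param voxel_mm isotropic voxel pitch (mm).
#' @param sample_id identifier; defaults to the directory name.
#' @return `tomogram_stack`.
#' @export
read_stack <- function(path, voxel_mm = 0.1, sample_id = basename(normalizePath(path))) {
  files <- stack_files(path)
  imgs <- lapply(files, function(f) {
    x <- tiff::readTIFF(f, info = TRUE)
    if (length(dim(x)) == 3) {
      if (dim(x)[3] != 1) stop("multi-channel TIFF not supported: ", f)
      x <- x[, , 1]
    }
    x
  })
  shp <- vapply(imgs, function(x) paste(dim(x), collapse = "x"), character(1))
  if (length(unique(shp)) > 1) {
    bad <- basename(files)[shp != shp[1]]
    stop("mixed slice shapes; offending files: ", paste(bad, collapse = ", "))
  }
  bits <- attr(imgs[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  # readTIFF normalises to [0,1] whatever the depth; 0-255 is canonical
  arr <- array(0L, dim = c(dim(imgs[[1]]), length(imgs)))
  for (k in seq_along(imgs)) arr[, , k] <- as.integer(round(imgs[[k]] * 255))
  tomogram_stack(arr, voxel_mm = voxel_mm, sample_id = sample_id, bits = bits)
}

#' Write a tomogram stack as a TIFF slice sequence
#'
#' One lossless single-channel TIFF per slice with zero-padded numeric
#' names. Refuses to overwrite an existing non-empty directory unless
#' `force = TRUE`. With `bits = 16` the 0-255 gray values are written into
#' the 16-bit container (pass-through mode).
#'
#' @param stack `tomogram_stack`.
#' @param path output directory (created on demand).
#' @param force overwrite existing slices.
#' @param bits 8 or 16.
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, path, force = FALSE, bits = stack$bits) {
  stopifnot(inherits(stack, "tomogram_stack"))
  if (dir.exists(path) && length(list.files(path)) > 0 && !force)
    stop("directory ", path, " is not empty; use force = TRUE to overwrite")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$voxels)
  files <- file.path(path, sprintf("slice_%04d.tif", seq_len(d[3])))
  for (k in seq_len(d[3])) {
    ok <- tryCatch({
      tiff::writeTIFF(stack$voxels[, , k] / 255, files[k],
                      bits.per.sample = as.integer(bits), compression = "none")
      TRUE
    }, error = function(e) stop("failed writing ", files[k], ": ",
                                conditionMessage(e)))
    if (!isTRUE(ok)) stop("failed writing ", files[k])
  }
  invisible(files)
}

#' Crop a stack to a fixed region of interest
#'
#' One global crop window is applied to every slice so that the geometry
#' stays consistent across depth. The window is centred on the 3D centroid
#' of above-noise voxels (gray > `noise_ceiling`); an all-background stack
#' falls back to the image centre. If the above-noise extent of the sample
#' exceeds the window, an error reports the measured extent rather than
#' truncating the sample.
#'
#' @param stack `tomogram_stack`.
#' @param out_size integer length 2 (rows, cols) of the crop window.
#' @param noise_ceiling gray level separating system noise from tissue.
#' @return cropped `tomogram_stack`.
#' @export
extract_roi <- function(stack, out_size, noise_ceiling = 60) {
  stopifnot(inherits(stack, "tomogram_stack"))
  out_size <- rep(as.integer(out_size), length.out = 2)
  d <- dim(stack$voxels)
  if (any(out_size > d[1:2])) stop("out_size exceeds slice size")
  fg <- stack$voxels > noise_ceiling
  if (!any(fg)) {
    ctr <- (d[1:2] + 1) / 2
  } else {
    idx <- which(fg, arr.ind = TRUE)
    ext <- c(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1L
    if (any(ext > out_size))
      stop(sprintf("sample extent %d x %d px exceeds window %d x %d px",
                   ext[1], ext[2], out_size[1], out_size[2]))
    ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  start <- round(ctr - (out_size - 1) / 2)
  start <- pmax(1L, pmin(as.integer(start), d[1:2] - out_size + 1L))
  rows <- start[1]:(start[1] + out_size[1] - 1L)
  cols <- start[2]:(start[2] + out_size[2] - 1L)
  tomogram_stack(stack$voxels[rows, cols, , drop = FALSE],
                 voxel_mm = stack$voxel_mm, sample_id = stack$sample_id,
                 bits = stack$bits)
}

#' Contrast-enhancing grayscale transform
#'
#' Suppresses the low-gray system-noise stratum and stretches the
#' remaining range: values at or below `low_cut` map to 0 and values in
#' `(low_cut, 255]` map linearly onto `(0, 255]`. Monotone non-decreasing.
#'
#' @param img 2D integer gray image (0-255).
#' @param low_cut gray level in (0, 255); default 60, the noise ceiling.
#' @return transformed image, same dimensions, integer 0-255.
#' @export
grayscale_transform <- function(img, low_cut = 60) {
  if (low_cut <= 0 || low_cut >= 255) stop("low_cut must lie in (0, 255)")
  out <- (img - low_cut) * 255 / (255 - low_cut)
  out[img <= low_cut] <- 0
  matrix(as.integer(round(pmax(0, out))), nrow(img), ncol(img))
}
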