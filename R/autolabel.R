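# 8-connected 2D labeling via the 3D kernel with a depth-1 volume, so one
# connectivity rule (26-connectivity, 8 in-plane) is used everywhere.
label2d <- function(mask) {
  m <- label3d_cpp(as.integer(mask), c(dim(mask), 1L))
  matrix(m, nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  f <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  matrix(as.logical(f), nrow(mask), ncol(mask))
}

#' Otsu threshold restricted to non-zero pixels
#'
#' The threshold maximises the between-class variance of the histogram of
#' strictly positive gray values, so the abundant zero background cannot
#' bias the split between noise and tissue. Ties take the lowest level.
#'
#' @param img 2D integer gray image (0-255).
#' @return list with `threshold` (gray level) and `mask`
#'   (`img > threshold`, logical matrix).
#' @export
otsu_nonzero <- function(img) {
  v <- img[img > 0]
  if (length(unique(v)) < 2)
    stop("degenerate histogram: fewer than 2 distinct nonzero gray levels")
  h <- tabulate(v, nbins = 255)          # counts of levels 1..255
  n <- sum(h)
  lv <- seq_len(255)
  w0 <- cumsum(h) / n                    # P(value <= t), t = 1..255
  mu <- cumsum(h * lv) / n
  mu_t <- mu[255]
  t_cand <- 1:254
  w0c <- w0[t_cand]
  between <- (mu_t * w0c - mu[t_cand])^2 / (w0c * (1 - w0c))
  between[!is.finite(between)] <- -Inf
  thr <- t_cand[which.max(between)]
  list(threshold = thr, mask = img > thr)
}

#' Extract the area-ranked contour hierarchy of a binary mask
#'
#' Returns the boundaries of connected regions and of their holes,
#' recursively (full hierarchy), each as a closed polygon with the filled
#' area it encloses. Contours are sorted by enclosed area, descending,
#' with ties broken by hierarchy level and then by topmost boundary point;
#' at most `max_contours` are retained. An empty mask yields an empty set.
#'
#' @param mask logical matrix.
#' @param max_contours maximum retained contours (default 5).
#' @return object of class `contour_set`: list of contours, each with
#'   `poly` (n x 2, row/col), `area` (filled px^2), `fill` (logical
#'   matrix) and `level` (hierarchy depth, 1 = outermost).
#' @export
extract_contours <- function(mask, max_contours = 5L) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  out <- list()
  recurse <- function(m, level) {
    if (!any(m)) return(invisible())
    lab <- label2d(m)
    for (id in seq_len(max(lab))) {
      comp <- lab == id
      filled <- fill_holes(comp)
      oc <- EBImage::ocontour(matrix(as.integer(filled), nrow(m), ncol(m)))
      poly <- if (length(oc) > 0) oc[[1]] + 1L else
        matrix(which(filled, arr.ind = TRUE)[1, ], 1, 2)
      out[[length(out) + 1]] <<- list(poly = poly, area = sum(filled),
                                      fill = filled, level = level)
      interior <- filled & !comp
      if (any(interior)) recurse(interior, level + 1L)
    }
  }
  recurse(mask, 1L)
  if (length(out) > 0) {
    areas <- vapply(out, `[[`, numeric(1), "area")
    levels <- vapply(out, `[[`, numeric(1), "level")
    tops <- vapply(out, function(ct) {
      p <- ct$poly
      min(p[, 1] * (ncol(ct$fill) + 1) + p[, 2])
    }, numeric(1))
    ord <- order(-areas, levels, tops)
    out <- out[head(ord, max_contours)]
  }
  structure(out, class = "contour_set")
}

#' Tri-class label slice container
#'
#' @param classes 2D integer map: 0 background, 1 pericarp, 2 sarcocarp.
#' @param provenance one of `"auto"`, `"manual"`, `"predicted"`, `"truth"`.
#' @param quality_flags character vector of failed sanity checks (empty =
#'   accepted).
#' @return object of class `label_slice`.
#' @export
label_slice <- function(classes, provenance = "auto",
                        quality_flags = character(0)) {
  if (!all(classes %in% 0:2)) stop("classes must take values 0, 1, 2")
  structure(list(classes = matrix(as.integer(classes), nrow(classes), ncol(classes)),
                 provenance = provenance, quality_flags = quality_flags),
            class = "label_slice")
}

#' Assign tissue classes from the contour hierarchy
#'
#' Area-ranked rule: contour 1 is the fruit outer edge, contour 2 the
#' pericarp inner edge, contour 3 the sarcocarp outer edge. The pericarp
#' is the region between contours 1 and 2; the sarcocarp is the interior
#' of contour 3, merged with contour 4 when `area4 > merge_ratio * area3`
#' (strict inequality) and, after merging 4, with contour 5 when
#' `area5 > merge_ratio * area3` — the extension of the same rule to a
#' triple-lobed core. Everything else is background.
#'
#' @param contours `contour_set`.
#' @param image the source gray image (used only for dimensions when the
#'   contour set is empty; the stored artifact is the class map).
#' @param merge_ratio merge threshold on the area ratio (default 0.25).
#' @return `label_slice` with provenance `"auto"`; slices with fewer than
#'   3 contours or broken nesting carry quality flags.
#' @export
assign_regions <- function(contours, image, merge_ratio = 0.25) {
  dims <- dim(image)
  cls <- matrix(0L, dims[1], dims[2])
  flags <- character(0)
  n <- length(contours)
  if (n < 3) flags <- c(flags, "partial_contours")
  if (n >= 2) {
    f1 <- contours[[1]]$fill
    f2 <- contours[[2]]$fill
    if (any(f2 & !f1)) flags <- c(flags, "nesting_violation")
    cls[f1 & !f2] <- 1L
    if (n >= 3) {
      a3 <- contours[[3]]$area
      sarc <- contours[[3]]$fill
      if (n >= 4 && contours[[4]]$area > merge_ratio * a3) {
        sarc <- sarc | contours[[4]]$fill
        if (n >= 5 && contours[[5]]$area > merge_ratio * a3)
          sarc <- sarc | contours[[5]]$fill
      }
      cls[sarc] <- 2L
    }
  } else if (n == 1) {
    cls[contours[[1]]$fill] <- 1L
  }
  label_slice(cls, provenance = "auto", quality_flags = flags)
}

#' Automated quality filter for generated label slices
#'
#' Replaces manual selection of trustworthy slices with explicit checks:
#' broken contour nesting, foreground touching the image border, more
#' than `max_lobes` sarcocarp components, a pericarp ring that is not a
#' single connected annulus, and (on tri-class sections) a pericarp area
#' fraction outside `pericarp_frac_range` of the filled fruit area.
#' Sarcocarp-free sections are valid pericarp-only labels when their
#' structure matches real polar anatomy: either an intact ring (one
#' connected pericarp component with exactly one hole) or a compact
#' solid cap (one component, no hole, convex-outline circularity at
#' least 0.8 — the section just beyond the inner wall's polar extent).
#' For these the `partial_contours` mark is cleared, and the fraction
#' band — whose purpose is to catch mis-ranked contours on tri-class
#' sections — does not apply. Unflagged slices are eligible training
#' labels.
#'
#' @param label `label_slice` produced by [assign_regions()].
#' @param pericarp_frac_range allowed pericarp fraction of fruit area on
#'   sections that contain sarcocarp.
#' @param max_lobes maximum sarcocarp connected components (default 3).
#' @return the `label_slice` with `quality_flags` updated.
#' @export
label_quality_filter <- function(label, pericarp_frac_range = c(0.02, 0.60),
                                 max_lobes = 3L) {
  cls <- label$classes
  flags <- label$quality_flags
  fg <- cls > 0L
  if (!any(fg)) {
    label$quality_flags <- unique(c(flags, "empty"))
    return(label)
  }
  if (any(fg[1, ]) || any(fg[nrow(fg), ]) || any(fg[, 1]) || any(fg[, ncol(fg)]))
    flags <- c(flags, "touches_border")
  per <- cls == 1L
  sarc <- cls == 2L
  per_ok <- FALSE
  if (any(per)) {
    if (max(label2d(per)) != 1) {
      flags <- c(flags, "ring_broken")
    } else {
      hole <- fill_holes(per) & !per
      if (any(hole)) {
        if (max(label2d(hole)) != 1) flags <- c(flags, "ring_broken")
        else per_ok <- TRUE
      } else if (!any(sarc)) {
        # solid cap: a compact disk of pericarp with no cavity, the
        # expected anatomy just beyond the inner wall's polar extent
        pts <- which(per, arr.ind = TRUE)
        hp <- pts[grDevices::chull(pts), , drop = FALSE]
        hp <- rbind(hp, hp[1, ])
        perim <- sum(sqrt(rowSums(diff(hp)^2)))
        circ <- if (perim > 0) 4 * pi * sum(per) / perim^2 else 0
        if (circ >= 0.8) per_ok <- TRUE else flags <- c(flags, "ring_broken")
      } else {
        flags <- c(flags, "ring_broken")
      }
    }
  }
  if (any(sarc)) {
    filled <- fill_holes(fg)
    pfrac <- sum(per) / sum(filled)
    if (pfrac < pericarp_frac_range[1] || pfrac > pericarp_frac_range[2])
      flags <- c(flags, "pericarp_fraction")
    ns <- max(label2d(sarc))
    if (ns > max_lobes) flags <- c(flags, "sarcocarp_components")
  } else if (per_ok && !"touches_border" %in% flags &&
             !"nesting_violation" %in% flags) {
    flags <- setdiff(flags, "partial_contours")
  }
  label$quality_flags <- unique(flags)
  label
}

#' Classical label generation for one tomogram
#'
#' Convenience wrapper for the full weak-labeling path: grayscale
#' transform (contrast), Otsu on non-zero pixels, contour hierarchy,
#' area-ranked class assignment and quality filtering.
#'
#' The Otsu threshold is computed on the strictly positive raw histogram
#' and bounded above by `low_cut`, the configured system-noise ceiling:
#' when preprocessing (or a noiseless acquisition) has already removed the
#' whole noise stratum, the positive histogram is unimodal tissue and an
#' unbounded Otsu split would land inside it.
#'
#' @param img 2D integer gray image (0-255).
#' @param low_cut noise ceiling; used by [grayscale_transform()] and as
#'   the upper bound of the tissue threshold.
#' @param merge_ratio see [assign_regions()].
#' @param max_contours see [extract_contours()].
#' @return `label_slice` with quality flags.
#' @export
autolabel_slice <- function(img, low_cut = 60, merge_ratio = 0.25,
                            max_contours = 5L) {
  tr <- grayscale_transform(img, low_cut = low_cut)
  thr <- tryCatch(otsu_nonzero(img)$threshold, error = function(e) 0L)
  mask <- img > min(thr, low_cut)
  ct <- extract_contours(mask, max_contours = max_contours)
  lab <- assign_regions(ct, tr, merge_ratio = merge_ratio)
  label_quality_filter(lab)
}
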