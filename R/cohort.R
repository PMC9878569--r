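#' Assemble a cohort trait matrix
#'
#' @param records list of `trait_record` (or a data frame with
#'   `sample_id` plus the fourteen trait columns).
#' @return numeric matrix, samples in rows (named by sample id), the
#'   fourteen traits in canonical order as columns.
#' @export
trait_matrix <- function(records) {
  df <- if (is.data.frame(records)) records else
    do.call(rbind, lapply(records, as.data.frame))
  miss <- setdiff(trait_names(), colnames(df))
  if (length(miss) > 0) stop("missing trait columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, trait_names()])
  rownames(m) <- as.character(df$sample_id)
  if (anyNA(m)) stop("trait matrix contains missing values")
  m
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson r over samples; p-values from the two-sided t test
#' with n - 2 degrees of freedom. No multiple-testing correction is
#' applied. Zero-variance columns yield NA rows/columns with a warning.
#'
#' @param m trait matrix (samples x traits), at least 3 rows.
#' @return list with `r`, `p` and logical flags `sig05`, `sig01`.
#' @export
pearson_matrix <- function(m) {
  if (nrow(m) < 3) stop("need at least 3 samples for correlation")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(cor(m))
  n <- nrow(m)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, sig05 = !is.na(p) & p < 0.05, sig01 = !is.na(p) & p < 0.01)
}

#' Principal component analysis of standardized traits
#'
#' Traits mix mm, mm^2, mm^3 and percentages, so columns are standardized
#' to zero mean and unit variance before decomposition (correlation-matrix
#' PCA). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results reproducible.
#'
#' @param m trait matrix (samples x traits), at least 4 rows.
#' @param n_components number of components to keep (default: all).
#' @return list of class `trait_pca` with `loadings` (traits x comp),
#'   `explained_variance_ratio`, `scores` (samples x comp) and `sdev`.
#' @export
trait_pca <- function(m, n_components = NULL) {
  if (nrow(m) < 4) stop("need at least 4 samples for PCA")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  n_avail <- ncol(pc$rotation)   # min(n - 1, n_traits)
  if (is.null(n_components)) n_components <- n_avail
  if (n_components > n_avail)
    stop("n_components exceeds the available components (", n_avail, ")")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  keep <- seq_len(n_components)
  structure(list(loadings = pc$rotation[, keep, drop = FALSE],
                 explained_variance_ratio = evr[keep],
                 evr_all = evr,
                 scores = pc$x[, keep, drop = FALSE],
                 sdev = pc$sdev[keep]),
            class = "trait_pca")
}

#' Composite quality score from retained principal components
#'
#' Each sample's score is the weighted sum of its component scores over
#' the first `n_dims` dimensions, the weight of dimension d being its
#' explained-variance ratio normalised within the retained dimensions.
#' Samples are ranked by descending score; ties break by sample id.
#'
#' @param pca `trait_pca`.
#' @param n_dims retained dimensions (default 3).
#' @return data frame `sample_id`, `score`, `rank`, ordered best first.
#' @export
composite_score <- function(pca, n_dims = 3L) {
  if (n_dims > ncol(pca$scores)) stop("n_dims exceeds available components")
  evr <- pca$explained_variance_ratio[seq_len(n_dims)]
  w <- evr / sum(evr)
  sc <- as.numeric(pca$scores[, seq_len(n_dims), drop = FALSE] %*% w)
  ids <- rownames(pca$scores)
  if (is.null(ids)) ids <- as.character(seq_along(sc))
  ord <- order(-sc, ids)
  data.frame(sample_id = ids[ord], score = sc[ord],
             rank = seq_along(sc), stringsAsFactors = FALSE)
}

#' Min-max normalization within a sample subset
#'
#' Per column `(x - min) / (max - min)` computed over the given subset of
#' samples (used to display trait contributions of top-ranked samples on
#' a common 0-1 scale). Constant columns become all zero with a warning.
#'
#' @param m trait matrix.
#' @param subset sample ids (rownames) to normalise within; default all.
#' @return normalized matrix over the subset rows.
#' @export
minmax_normalize <- function(m, subset = rownames(m)) {
  if (length(subset) < 2) stop("subset must contain at least 2 samples")
  x <- m[subset, , drop = FALSE]
  out <- apply(x, 2, function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) rep(0, length(col)) else (col - rng[1]) / diff(rng)
  })
  if (any(apply(x, 2, function(col) diff(range(col)) == 0)))
    warning("constant column(s) normalised to zero")
  rownames(out) <- subset
  out
}
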