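#' Segmentation benchmark on synthetic phantom slices
#'
#' Generates rendered phantom tomograms, weak-labels them with the
#' classical path, trains the reduced network on the unflagged labels of
#' the training split, and scores the trained model against voxelized
#' ground truth on held-out slices. This is the package's end-to-end
#' validation of the label-generation + learning strategy.
#'
#' @param n_slices total slices generated.
#' @param n_train slices forming the training pool (the rest are held
#'   out).
#' @param seed seed for phantom generation and rendering.
#' @param config `unet_config` for the network and optimisation.
#' @param verbose print training progress.
#' @return list with `mdice` (mean held-out mDice over the three
#'   classes), `per_slice` dice values, `n_labeled` (unflagged training
#'   slices) and the trained `model`.
#' @export
segmentation_benchmark <- function(n_slices = 240L, n_train = 200L,
                                   seed = 42L, config = unet_config(seed = seed),
                                   verbose = FALSE) {
  ss <- phantom_slice_set(n_slices, seed = seed)
  labs <- lapply(ss$images, autolabel_slice)
  tr <- seq_len(n_train)
  te <- setdiff(seq_len(n_slices), tr)
  ok <- tr[vapply(labs[tr], function(l) length(l$quality_flags) == 0,
                  logical(1))]
  model <- train(build_model(config), ss$images[ok], labs[ok],
                 verbose = verbose)
  per_slice <- vapply(te, function(i) {
    pred <- predict_stack(model, tomogram_stack(ss$images[[i]]))
    score(pred$classes[, , 1], ss$truth[[i]]$classes)$mDice_All
  }, numeric(1))
  list(mdice = mean(per_slice), per_slice = per_slice,
       n_labeled = length(ok), model = model)
}

#' Width/length accuracy benchmark on a fruit-scale phantom cohort
#'
#' Generates full-size ellipsoid phantoms at 0.1 mm pitch, measures fruit
#' width and length through the classical-only pipeline (CT rendering,
#' weak labeling, mid-depth rectangle fitting), and compares them with
#' the analytic ground truth: mean absolute percentage errors and squared
#' Pearson correlations across the cohort.
#'
#' @param n cohort size.
#' @param seed base seed (sample i uses `seed + i - 1`).
#' @param voxel_mm voxel pitch.
#' @param k mid-depth window size.
#' @return list with `mape_fw`, `mape_fl` (percent), `r2_fw`, `r2_fl`,
#'   and the per-sample `table` of measured and true values.
#' @export
width_length_benchmark <- function(n = 20L, seed = 7L, voxel_mm = 0.1,
                                   k = 5L) {
  rows <- lapply(seq_len(n), function(i) {
    sp <- make_phantom_spec(seed + i - 1L, phantom_ranges("fruit"))
    gt <- ground_truth_traits(sp)
    m <- measure_sample_classical(sp, voxel_mm = voxel_mm, k = k)
    data.frame(sample = i, fw = m$FW, fl = m$FL,
               fw_true = gt$FW, fl_true = gt$FL)
  })
  tab <- do.call(rbind, rows)
  list(mape_fw = 100 * mean(abs(tab$fw - tab$fw_true) / tab$fw_true),
       mape_fl = 100 * mean(abs(tab$fl - tab$fl_true) / tab$fl_true),
       r2_fw = cor(tab$fw, tab$fw_true)^2,
       r2_fl = cor(tab$fl, tab$fl_true)^2,
       table = tab)
}

#' Full trait-recovery benchmark on a desk-scale phantom cohort
#'
#' Runs the complete classical chain (voxelize, render, weak-label,
#' stack, measure) on a cohort of miniature phantoms and reports the mean
#' absolute percentage error of every trait against the analytic ground
#' truth.
#'
#' @param n cohort size.
#' @param seed base seed.
#' @return list with `mape` (named per-trait MAPE, percent) and the
#'   per-sample error `table`.
#' @export
trait_recovery_benchmark <- function(n = 20L, seed = 300L) {
  errs <- lapply(seq_len(n), function(i) {
    sp <- make_phantom_spec(seed + i - 1L, phantom_ranges("desk"))
    gt <- ground_truth_traits(sp)
    gs <- default_grid_shape(sp, 0.1)
    gs[1:2] <- 128L
    vol <- voxelize(sp, 0.1, gs)
    ct <- render_ct(vol, noise_model(seed = sp$seed))
    labs <- lapply(seq_len(dim(ct)[3]), function(kk)
      autolabel_slice(ct$voxels[, , kk]))
    rec <- compute_traits(stack_labels(labs, 0.1), seed = sp$seed)
    vapply(trait_names(), function(tn)
      100 * abs(rec[[tn]] / gt[[tn]] - 1), numeric(1))
  })
  tab <- do.call(rbind, errs)
  list(mape = colMeans(tab), table = tab)
}
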