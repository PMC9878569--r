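default_pipeline_config <- function() {
  list(
    n_samples = 20L,
    scale = "desk",            # phantom size profile: "desk" or "fruit"
    grid_px = 128L,            # in-plane grid for desk-scale stacks
    voxel_mm = 0.1,
    seed = 42L,
    use_unet = FALSE,          # classical-only mode is the default path
    autolabel = list(low_cut = 60, merge_ratio = 0.25, max_contours = 5L),
    train = list(batch_size = 4L, learning_rate = 1e-3, input_scale = 0.5,
                 epochs = 20L, base_filters = 16L, depth = 2L),
    traits = list(k = 5L, n_points = 200L),
    stats = list(n_dims = 3L),
    out_dir = NULL
  )
}

merge_config <- function(defaults, user, path = "", warnings = NULL) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      warning("unknown config key ignored: ", paste0(path, nm))
      next
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), fills defaults for every
#' missing key, and checks all invariants at once, reporting every
#' violation in a single error. Unknown keys warn but do not fail.
#'
#' @param x path to a YAML file, a list, or `NULL` for all defaults.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
  else if (is.character(x)) {
    y <- tryCatch(yaml::read_yaml(x), error = function(e)
      stop("unparseable config file ", x, ": ", conditionMessage(e)))
    if (is.null(y)) list() else y
  } else if (is.list(x)) x
  else stop("config must be a file path or a list")
  cfg <- merge_config(default_pipeline_config(), user)
  v <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(cfg$n_samples >= 1, "n_samples must be >= 1")
  chk(cfg$scale %in% c("desk", "fruit"), "scale must be 'desk' or 'fruit'")
  chk(cfg$voxel_mm > 0, "voxel_mm must be positive")
  chk(cfg$autolabel$merge_ratio >= 0 && cfg$autolabel$merge_ratio <= 1,
      "autolabel.merge_ratio must lie in [0, 1]")
  chk(cfg$autolabel$low_cut > 0 && cfg$autolabel$low_cut < 255,
      "autolabel.low_cut must lie in (0, 255)")
  chk(cfg$autolabel$max_contours >= 3, "autolabel.max_contours must be >= 3")
  chk(cfg$traits$k >= 1 && cfg$traits$k %% 2 == 1, "traits.k must be odd and >= 1")
  chk(cfg$traits$n_points >= 1, "traits.n_points must be >= 1")
  chk(cfg$stats$n_dims >= 1 && cfg$stats$n_dims <= 14,
      "stats.n_dims must lie in 1..14")
  chk(cfg$train$input_scale > 0 && cfg$train$input_scale <= 1,
      "train.input_scale must lie in (0, 1]")
  chk(cfg$train$epochs >= 1, "train.epochs must be >= 1")
  if (length(v) > 0)
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end phenotyping pipeline on synthetic phantoms
#'
#' Phantom generation, CT rendering, weak labeling (and optionally U-Net
#' training plus prediction), 3D trait extraction, and cohort statistics,
#' all driven by one config and one seed. Identical config and seed give
#' an identical traits table.
#'
#' @param config `pipeline_config` (see [validate_config()]).
#' @param verbose print per-stage progress.
#' @return list with `traits` (data frame), `correlation`, `pca`,
#'   `scores`, and per-sample `quality` (fraction of flagged slices);
#'   artifacts are written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = validate_config(), verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  ranges <- phantom_ranges(cfg$scale)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  specs <- lapply(seq_len(cfg$n_samples), function(i)
    make_phantom_spec(cfg$seed + i - 1L, ranges))

  labeled <- vector("list", cfg$n_samples)
  stacks <- vector("list", cfg$n_samples)
  quality <- numeric(cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    sp <- specs[[i]]
    gs <- default_grid_shape(sp, cfg$voxel_mm)
    if (cfg$scale == "desk") gs[1:2] <- cfg$grid_px
    truthvol <- tryCatch(voxelize(sp, cfg$voxel_mm, gs), error = function(e)
      stop("stage voxelize failed for sample ", i, ": ", conditionMessage(e)))
    ct <- render_ct(truthvol, noise_model(seed = sp$seed))
    labs <- lapply(seq_len(dim(ct)[3]), function(k)
      autolabel_slice(ct$voxels[, , k], low_cut = cfg$autolabel$low_cut,
                      merge_ratio = cfg$autolabel$merge_ratio,
                      max_contours = cfg$autolabel$max_contours))
    quality[i] <- mean(vapply(labs, function(l)
      length(l$quality_flags) > 0, logical(1)))
    labeled[[i]] <- labs
    stacks[[i]] <- ct
    say("sample %d/%d labeled (%.0f%% slices flagged), %.1fs elapsed",
        i, cfg$n_samples, 100 * quality[i], proc.time()[3] - t0)
  }

  model <- NULL
  if (cfg$use_unet) {
    imgs <- list(); labs <- list()
    for (i in seq_len(cfg$n_samples)) {
      ok <- which(vapply(labeled[[i]], function(l)
        length(l$quality_flags) == 0, logical(1)))
      for (k in ok) {
        imgs[[length(imgs) + 1]] <- stacks[[i]]$voxels[, , k]
        labs[[length(labs) + 1]] <- labeled[[i]][[k]]
      }
    }
    tc <- do.call(unet_config, c(cfg$train, list(seed = cfg$seed)))
    model <- train(build_model(tc), imgs, labs, verbose = verbose)
    say("network trained on %d slices", length(imgs))
  }

  traits <- vector("list", cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    vol <- if (cfg$use_unet) predict_stack(model, stacks[[i]])
    else stack_labels(labeled[[i]], voxel_mm = cfg$voxel_mm,
                      sample_id = stacks[[i]]$sample_id)
    vol$sample_id <- sprintf("sample_%02d", i)
    rec <- tryCatch(
      compute_traits(vol, k = cfg$traits$k, n_points = cfg$traits$n_points,
                     seed = cfg$seed + i),
      error = function(e)
        stop("stage traits failed for sample ", i, ": ", conditionMessage(e)))
    traits[[i]] <- as.data.frame(rec)
    say("sample %d/%d traits done, %.1fs elapsed", i, cfg$n_samples,
        proc.time()[3] - t0)
  }
  traits <- do.call(rbind, traits)

  m <- trait_matrix(traits)
  corr <- pearson_matrix(m)
  pca <- trait_pca(m)
  scores <- composite_score(pca, n_dims = cfg$stats$n_dims)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(traits, file.path(cfg$out_dir, "traits.csv"), row.names = FALSE)
    write.csv(as.data.frame(corr$r), file.path(cfg$out_dir, "correlation_r.csv"))
    write.csv(as.data.frame(corr$p), file.path(cfg$out_dir, "correlation_p.csv"))
    write.csv(as.data.frame(pca$loadings), file.path(cfg$out_dir, "pca_loadings.csv"))
    write.csv(data.frame(component = seq_along(pca$explained_variance_ratio),
                         evr = pca$explained_variance_ratio),
              file.path(cfg$out_dir, "pca_variance.csv"), row.names = FALSE)
    write.csv(scores, file.path(cfg$out_dir, "scores.csv"), row.names = FALSE)
  }
  list(traits = traits, correlation = corr, pca = pca, scores = scores,
       quality = quality, model = model, config = cfg)
}
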