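# Compact U-Net for tri-class tomogram segmentation, in plain R on
# BLAS-backed im2col matrix products. Arrays are (H, W, C, N).

#' Training configuration for the segmentation network
#'
#' Defaults: batch size 4, RMSprop with initial learning rate 0.001 and
#' inputs scaled by 0.5, at the desk-scale profile (depth-2 encoder, 16
#' base filters, 20 epochs on 128 x 128 slices). The full-scale profile
#' differs only in `epochs = 200` and native 1000 x 1000 slices.
#'
#' @param batch_size mini-batch size (default 4).
#' @param optimizer only `"rmsprop"` is implemented.
#' @param learning_rate initial learning rate (default 0.001).
#' @param input_scale spatial scale factor applied to inputs in (0, 1].
#' @param epochs training epochs (desk default 20; full scale 200).
#' @param base_filters encoder filters at the first level (default 16).
#' @param depth number of encoder levels (default 2).
#' @param seed RNG seed for initialisation and shuffling.
#' @param val_frac fraction of pairs held out for validation (train:val
#'   5:1 by default).
#' @return list of class `unet_config`.
#' @export
unet_config <- function(batch_size = 4L, optimizer = "rmsprop",
                        learning_rate = 1e-3, input_scale = 0.5,
                        epochs = 20L, base_filters = 16L, depth = 2L,
                        seed = 1L, val_frac = 1 / 6) {
  if (optimizer != "rmsprop") stop("only the rmsprop optimizer is implemented")
  if (input_scale <= 0 || input_scale > 1) stop("input_scale must lie in (0, 1]")
  stopifnot(batch_size >= 1, epochs >= 1, base_filters >= 1, depth >= 1,
            learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, input_scale = input_scale,
                 epochs = as.integer(epochs), base_filters = as.integer(base_filters),
                 depth = as.integer(depth), seed = as.integer(seed),
                 val_frac = val_frac),
            class = "unet_config")
}

he_init <- function(k, cin, cout) {
  matrix(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), k * cin, cout)
}

#' Build an untrained U-Net model
#'
#' Symmetric encoder/decoder with skip concatenations: each encoder level
#' is conv3x3 + ReLU + 2x2 max-pool, the bottleneck doubles the filters,
#' and each decoder level nearest-upsamples, concatenates the encoder
#' feature map and convolves back down; a 1x1 convolution emits the three
#' class logits at the (scaled) input resolution.
#'
#' @param config `unet_config`.
#' @return list of class `unet_model` with `params`, `config` and
#'   RMSprop state.
#' @export
build_model <- function(config = unet_config()) {
  D <- config$depth; B <- config$base_filters
  params <- list()
  with_seed(config$seed, {
    cin <- 1L
    for (d in seq_len(D)) {
      cout <- B * 2^(d - 1)
      params[[paste0("enc", d)]] <- list(W = he_init(9, cin, cout),
                                         b = numeric(cout))
      cin <- cout
    }
    params$bott <- list(W = he_init(9, cin, B * 2^D), b = numeric(B * 2^D))
    for (d in rev(seq_len(D))) {
      cin_d <- B * 2^d + B * 2^(d - 1)
      cout <- B * 2^(d - 1)
      params[[paste0("dec", d)]] <- list(W = he_init(9, cin_d, cout),
                                         b = numeric(cout))
    }
    params$out <- list(W = he_init(1, B, 3L), b = numeric(3))
  })
  structure(list(params = params, config = config,
                 rms = lapply(params, function(p)
                   list(W = 0 * p$W, b = 0 * p$b))),
            class = "unet_model")
}

#' Number of trainable parameters
#' @param model `unet_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

# gather-index cache for im2col/col2im: for a given (H, W, C, N) the
# (H*W*N) x (9*C) matrix of flat indices into the zero-padded input
.conv_cache <- new.env(parent = emptyenv())

conv_idx <- function(H, W, C, N) {
  key <- paste(H, W, C, N, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H + 2L; W2 <- W + 2L
  i <- rep.int(seq_len(H), W * N)
  j <- rep.int(rep(seq_len(W), each = H), N)
  n <- rep(seq_len(N), each = H * W)
  rowbase <- i + (j - 1L) * H2 + (n - 1L) * (H2 * W2 * C)
  coloff <- integer(9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    coloff[(k - 1L) * C + seq_len(C)] <-
      di + dj * H2 + (seq_len(C) - 1L) * (H2 * W2)
  }
  idx <- outer(rowbase, coloff, "+")
  storage.mode(idx) <- "integer"
  .conv_cache[[key]] <- idx
  idx
}

conv_fwd <- function(x, layer, relu = TRUE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- nrow(layer$W) / C
  if (k == 9) {
    xp <- array(0, c(H + 2, W + 2, C, N))
    xp[2:(H + 1), 2:(W + 1), , ] <- x
    Xm <- gather_cpp(xp, conv_idx(H, W, C, N))
  } else {
    Xm <- matrix(aperm(x, c(1, 2, 4, 3)), H * W * N, C)
  }
  Y <- Xm %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  if (relu) Y[Y < 0] <- 0
  out <- aperm(array(Y, c(H, W, N, ncol(Y))), c(1, 2, 4, 3))
  list(out = out, Xm = Xm, act = Y, dims = d)
}

conv_bwd <- function(dout, cache, layer, relu = TRUE) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), H * W * N, dim(dout)[3])
  if (relu) dm[cache$act <= 0] <- 0
  dW <- crossprod(cache$Xm, dm)
  db <- colSums(dm)
  dXm <- tcrossprod(dm, layer$W)
  k <- nrow(layer$W) / C
  if (k == 1) {
    dx <- aperm(array(dXm, c(H, W, N, C)), c(1, 2, 4, 3))
  } else {
    dxp <- scatter_add_cpp(dXm, conv_idx(H, W, C, N),
                           (H + 2L) * (W + 2L) * C * N)
    dx <- array(dxp, c(H + 2, W + 2, C, N))[2:(H + 1), 2:(W + 1), , ,
                                            drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

pool_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  parts <- list(x[ro, co, , , drop = FALSE], x[ro + 1, co, , , drop = FALSE],
                x[ro, co + 1, , , drop = FALSE], x[ro + 1, co + 1, , , drop = FALSE])
  cur <- parts[[1]]
  pick <- array(1L, dim(cur))
  for (j in 2:4) {
    better <- parts[[j]] > cur
    pick[better] <- j
    cur[better] <- parts[[j]][better]
  }
  list(out = cur, pick = pick, dims = d)
}

pool_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  sel <- function(j) {
    m <- array(0, dim(dout))
    w <- cache$pick == j
    m[w] <- dout[w]
    m
  }
  dx[ro, co, , ] <- sel(1); dx[ro + 1, co, , ] <- sel(2)
  dx[ro, co + 1, , ] <- sel(3); dx[ro + 1, co + 1, , ] <- sel(4)
  dx
}

up_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  ro <- seq(1, 2 * d[1], 2); co <- seq(1, 2 * d[2], 2)
  y[ro, co, , ] <- x; y[ro + 1, co, , ] <- x
  y[ro, co + 1, , ] <- x; y[ro + 1, co + 1, , ] <- x
  y
}

up_bwd <- function(dout) {
  d <- dim(dout)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  dout[ro, co, , , drop = FALSE] + dout[ro + 1, co, , , drop = FALSE] +
    dout[ro, co + 1, , , drop = FALSE] + dout[ro + 1, co + 1, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(model, x, train = FALSE) {
  D <- model$config$depth
  H <- dim(x)[1]
  if (H %% 2^D != 0 || dim(x)[2] %% 2^D != 0)
    stop(sprintf("scaled input size %dx%d not divisible by 2^depth = %d; pad the input",
                 dim(x)[1], dim(x)[2], 2^D))
  caches <- list()
  skips <- list()
  cur <- x
  for (d in seq_len(D)) {
    cv <- conv_fwd(cur, model$params[[paste0("enc", d)]])
    skips[[d]] <- cv$out
    pl <- pool_fwd(cv$out)
    caches[[paste0("enc", d)]] <- cv
    caches[[paste0("pool", d)]] <- pl
    cur <- pl$out
  }
  bt <- conv_fwd(cur, model$params$bott)
  caches$bott <- bt
  cur <- bt$out
  for (d in rev(seq_len(D))) {
    up <- up_fwd(cur)
    cat_in <- concat_c(up, skips[[d]])
    cv <- conv_fwd(cat_in, model$params[[paste0("dec", d)]])
    caches[[paste0("dec", d)]] <- cv
    caches[[paste0("decnch", d)]] <- dim(up)[3]
    cur <- cv$out
  }
  ot <- conv_fwd(cur, model$params$out, relu = FALSE)
  caches$out <- ot
  if (train) list(logits = ot$out, caches = caches) else ot$out
}

softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  n <- d[1] * d[2] * d[4]
  M <- matrix(aperm(logits, c(1, 2, 4, 3)), n, d[3])
  M <- M - apply(M, 1, max)
  P <- exp(M)
  P <- P / rowSums(P)
  ti <- as.integer(labels) + 1L
  loss <- -mean(log(pmax(P[cbind(seq_len(n), ti)], 1e-12)))
  G <- P
  G[cbind(seq_len(n), ti)] <- G[cbind(seq_len(n), ti)] - 1
  G <- G / n
  dlogits <- aperm(array(G, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(loss = loss, dlogits = dlogits)
}

unet_backward <- function(model, caches, dlogits) {
  D <- model$config$depth
  grads <- list()
  bk <- conv_bwd(dlogits, caches$out, model$params$out, relu = FALSE)
  grads$out <- bk[c("dW", "db")]
  dcur <- bk$dx
  dskips <- vector("list", D)
  for (d in seq_len(D)) {  # dec1 was applied last, so it comes first here
    bk <- conv_bwd(dcur, caches[[paste0("dec", d)]],
                   model$params[[paste0("dec", d)]])
    grads[[paste0("dec", d)]] <- bk[c("dW", "db")]
    ncu <- caches[[paste0("decnch", d)]]
    dskips[[d]] <- bk$dx[, , ncu + seq_len(dim(bk$dx)[3] - ncu), , drop = FALSE]
    dcur <- up_bwd(bk$dx[, , seq_len(ncu), , drop = FALSE])
  }
  bk <- conv_bwd(dcur, caches$bott, model$params$bott)
  grads$bott <- bk[c("dW", "db")]
  dcur <- bk$dx
  for (e in rev(seq_len(D))) {
    dtot <- pool_bwd(dcur, caches[[paste0("pool", e)]]) + dskips[[e]]
    bk <- conv_bwd(dtot, caches[[paste0("enc", e)]],
                   model$params[[paste0("enc", e)]])
    grads[[paste0("enc", e)]] <- bk[c("dW", "db")]
    dcur <- bk$dx
  }
  grads
}

rmsprop_step <- function(model, grads, lr, alpha = 0.99, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    model$rms[[nm]]$W <- alpha * model$rms[[nm]]$W + (1 - alpha) * g$dW^2
    model$rms[[nm]]$b <- alpha * model$rms[[nm]]$b + (1 - alpha) * g$db^2
    model$params[[nm]]$W <- model$params[[nm]]$W -
      lr * g$dW / (sqrt(model$rms[[nm]]$W) + eps)
    model$params[[nm]]$b <- model$params[[nm]]$b -
      lr * g$db / (sqrt(model$rms[[nm]]$b) + eps)
  }
  model
}

downscale_img <- function(m, scale) {
  if (scale == 1) return(m / 255)
  f <- as.integer(round(1 / scale))
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  out <- matrix(0, nr, nc)
  for (i in seq_len(f)) for (j in seq_len(f))
    out <- out + m[seq(i, by = f, length.out = nr),
                   seq(j, by = f, length.out = nc)]
  out / (f * f * 255)
}

downscale_lab <- function(m, scale) {
  if (scale == 1) return(m)
  f <- as.integer(round(1 / scale))
  m[seq(1, by = f, length.out = nrow(m) %/% f),
    seq(1, by = f, length.out = ncol(m) %/% f)]
}

upscale_lab <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
}

batch_array <- function(lst) {
  d <- dim(lst[[1]])
  arr <- array(0, c(d[1], d[2], 1, length(lst)))
  for (i in seq_along(lst)) arr[, , 1, i] <- lst[[i]]
  arr
}

#' Train the segmentation network
#'
#' Multiclass cross-entropy loss optimised with RMSprop. Images are
#' scaled by `config$input_scale` (2x2 mean pooling) and labels follow by
#' nearest neighbour. A fixed fraction of the pairs is held out for
#' validation; the checkpoint with the best validation mean Dice over the
#' three classes is returned. Reproducible for a fixed seed.
#'
#' @param model `unet_model` from [build_model()].
#' @param images list of 2D gray matrices (0-255).
#' @param labels list of `label_slice` or integer matrices (same order).
#' @param config `unet_config` (defaults to the model's).
#' @param verbose print per-epoch progress.
#' @return `unet_model` with a `history` data frame (epoch, train_loss,
#'   val_mdice).
#' @export
train <- function(model, images, labels, config = model$config,
                  verbose = FALSE) {
  labels <- lapply(labels, function(l)
    if (inherits(l, "label_slice")) l$classes else l)
  stopifnot(length(images) == length(labels))
  n <- length(images)
  if (n < config$batch_size) stop("need at least batch_size training pairs")
  present <- sort(unique(unlist(lapply(labels, unique))))
  if (!all(0:2 %in% present))
    warning("class(es) ", paste(setdiff(0:2, present), collapse = ", "),
            " absent from the training labels")
  xs <- lapply(images, downscale_img, scale = config$input_scale)
  ys <- lapply(labels, downscale_lab, scale = config$input_scale)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_mdice = numeric(0))
  best <- list(mdice = -Inf, params = model$params)
  with_seed(config$seed + 1L, {
    n_val <- max(1L, round(n * config$val_frac))
    perm <- sample.int(n)
    val_id <- perm[seq_len(n_val)]
    tr_id <- perm[-seq_len(n_val)]
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_id)
      losses <- numeric(0)
      for (s in seq(1, length(ord), by = config$batch_size)) {
        ids <- ord[s:min(s + config$batch_size - 1, length(ord))]
        xb <- batch_array(xs[ids])
        yb <- array(unlist(ys[ids]), c(dim(ys[[1]]), length(ids)))
        fw <- unet_forward(model, xb, train = TRUE)
        sc <- softmax_ce(fw$logits, yb)
        grads <- unet_backward(model, fw$caches, sc$dlogits)
        model <- rmsprop_step(model, grads, config$learning_rate)
        losses <- c(losses, sc$loss)
      }
      # validation mean Dice at the scaled resolution
      dices <- vapply(val_id, function(i) {
        lg <- unet_forward(model, batch_array(xs[i]))
        pred <- apply(lg[, , , 1], c(1, 2), which.max) - 1L
        score(label_volume(pred, 1), label_volume(ys[[i]], 1))$mDice_All
      }, numeric(1))
      hist[nrow(hist) + 1, ] <- list(ep, mean(losses), mean(dices))
      if (mean(dices) >= best$mdice)
        best <- list(mdice = mean(dices), params = model$params)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val mDice %.4f",
                        ep, mean(losses), mean(dices)))
    }
  })
  model$params <- best$params
  model$history <- hist
  model
}

#' Predict a label volume for a tomogram stack
#'
#' Per-slice argmax over the class logits, computed at the configured
#' input scale and upsampled back to native resolution by nearest
#' neighbour.
#'
#' @param model trained `unet_model`.
#' @param stack `tomogram_stack` (or a single 2D matrix).
#' @return `label_volume` with provenance `"predicted"`.
#' @export
predict_stack <- function(model, stack) {
  if (is.matrix(stack)) stack <- tomogram_stack(stack)
  d <- dim(stack$voxels)
  f <- as.integer(round(1 / model$config$input_scale))
  out <- array(0L, d)
  for (k in seq_len(d[3])) {
    x <- downscale_img(stack$voxels[, , k], model$config$input_scale)
    lg <- unet_forward(model, array(x, c(dim(x), 1, 1)))
    pred <- apply(lg[, , , 1], c(1, 2), which.max) - 1L
    out[, , k] <- if (f == 1) pred else upscale_lab(pred, f)[seq_len(d[1]),
                                                            seq_len(d[2])]
  }
  label_volume(out, voxel_mm = stack$voxel_mm, sample_id = stack$sample_id)
}

#' Dice and IoU of a predicted label volume
#'
#' Per class c: `Dice = 2|P∩T| / (|P|+|T|)` and `IoU = |P∩T| / |P∪T|`;
#' when a class is empty in both volumes its Dice and IoU are 1, so
#' all-background slices do not zero out the aggregates. `mDice_All` and
#' `mIoU_All` average the three classes; the `_Passion` aggregates drop
#' the background class.
#'
#' @param pred,truth `label_volume` (or integer arrays) of equal shape.
#' @return list of class `seg_metrics`.
#' @export
score <- function(pred, truth) {
  p <- if (inherits(pred, "label_volume")) pred$classes else pred
  t <- if (inherits(truth, "label_volume")) truth$classes else truth
  if (!identical(dim(p), dim(t)))
    stop("shape mismatch between prediction and reference")
  dice <- iou <- numeric(3)
  for (c in 0:2) {
    P <- p == c; T <- t == c
    np <- sum(P); nt <- sum(T); ni <- sum(P & T)
    if (np + nt == 0) { dice[c + 1] <- 1; iou[c + 1] <- 1 }
    else {
      dice[c + 1] <- 2 * ni / (np + nt)
      iou[c + 1] <- ni / (np + nt - ni)
    }
  }
  names(dice) <- names(iou) <- c("background", "pericarp", "sarcocarp")
  structure(list(dice_per_class = dice, iou_per_class = iou,
                 mDice_All = mean(dice), mIoU_All = mean(iou),
                 mDice_Passion = mean(dice[2:3]), mIoU_Passion = mean(iou[2:3])),
            class = "seg_metrics")
}
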