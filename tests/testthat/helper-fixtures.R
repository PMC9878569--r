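# Shared fixtures, built in code and memoised per test run.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) assign(key, expr, envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# a thin-shell sphere phantom: radius 3 mm, nearly solid core
sphere_spec <- function(seed = 1L) {
  phantom_spec(c(3, 3, 3), pericarp_thickness_mm = 0.6, gap_mm = 0,
               lobes = 1L,
               lobe_params = list(q = 0.995, delta = 0, phi = 0),
               seed = seed)
}

sphere_volume_01 <- function() memo("sphere_vol_01", voxelize(sphere_spec(), 0.1))

# one desk phantom taken through the full classical chain
desk_classical <- function(seed = 3L) {
  memo(paste0("desk_classical_", seed), {
    sp <- make_phantom_spec(seed, phantom_ranges("desk"))
    gs <- fruitct:::default_grid_shape(sp, 0.1)
    gs[1:2] <- 128L
    vol <- voxelize(sp, 0.1, gs)
    ct <- render_ct(vol, noise_model(seed = seed))
    labs <- lapply(seq_len(dim(ct)[3]), function(k)
      autolabel_slice(ct$voxels[, , k]))
    list(spec = sp, truth = vol, ct = ct, labs = labs,
         pred = stack_labels(labs, 0.1))
  })
}

# binary disk mask
disk_mask <- function(n, cx, cy, r) {
  x <- matrix(seq_len(n), n, n)
  y <- matrix(seq_len(n), n, n, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# ring label slice: square outer shell (class 1), square core (class 2)
square_ring_slice <- function(n = 60, outer = 40, shell = 4, core = 10) {
  cls <- matrix(0L, n, n)
  o0 <- (n - outer) / 2
  cls[o0 + seq_len(outer), o0 + seq_len(outer)] <- 1L
  i0 <- o0 + shell
  cls[i0 + seq_len(outer - 2 * shell), i0 + seq_len(outer - 2 * shell)] <- 0L
  c0 <- (n - core) / 2
  cls[c0 + seq_len(core), c0 + seq_len(core)] <- 2L
  cls
}
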