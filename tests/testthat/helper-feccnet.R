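# Shared fixtures: everything is generated in code, seeded.

# tiny network configuration used where only the wiring matters
tiny_cfg <- function(input_size = 16L) {
  fecc_config(input_size = input_size,
              channel_schedule = c(8L, 16L, 24L, 32L),
              aspp_rates = c(1L, 2L),
              aspp_channels = 16L,
              enhanced_channels = c(8L, 16L, 24L, 32L),
              enhanced_stack = 1L)
}

random_mask <- function(S, p = 0.3) {
  matrix(rbinom(S * S, 1L, p), S, S)
}

# brute-force per-pixel confusion loop, the independent oracle for all
# pixel metrics
oracle_counts <- function(gt, pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(gt)) {
    if (gt[i] == 1 && pred[i] == 1) tp <- tp + 1L
    else if (gt[i] == 0 && pred[i] == 1) fp <- fp + 1L
    else if (gt[i] == 1 && pred[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_dsc <- function(gt, pred) {
  o <- oracle_counts(gt, pred)
  if (2 * o$tp + o$fp + o$fn == 0) 1 else 2 * o$tp / (2 * o$tp + o$fp + o$fn)
}

oracle_iou <- function(gt, pred) {
  o <- oracle_counts(gt, pred)
  if (o$tp + o$fp + o$fn == 0) 1 else o$tp / (o$tp + o$fp + o$fn)
}

# central finite-difference gradient of f at x
fd_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small split slice dataset for harness tests
tiny_dataset <- function(n = 12L, S = 32L, seed = 5L) {
  cfg <- synth_config(image_size = S, n_slices = n,
                      stratum_mix = c(lesion_free = 0.25, small = 0.25,
                                      medium = 0.25, large = 0.25),
                      slices_per_case = 2L, seed = seed)
  if (S < 64L) {
    # the large stratum needs room; shift its share to medium on tiny grids
    cfg$stratum_mix <- c(lesion_free = 0.25, small = 0.25, medium = 0.5,
                         large = 0)
  }
  ds <- generate_dataset(cfg)
  split_dataset(ds, seed = seed)
}
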