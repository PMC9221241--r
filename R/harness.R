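# Training, noise-robustness and prediction harness.

#' Train FECC-Net on a slice dataset
#'
#' Minimises the chosen loss with Adam (learning rate 1e-4, batch size 16 by
#' default, mirroring the network's training protocol), early-stopping when
#' validation DSC has not improved for `patience` epochs. The returned fit
#' carries the weights of the best validation epoch. Fully seeded: the same
#' seed, config and data reproduce the run bit for bit.
#'
#' @param records Slice tibble carrying a `split` column (see
#'   [split_dataset()]) with non-empty `train` and `val` partitions.
#' @param cfg A [fecc_config()] matching the slice size.
#' @param loss One of `"hybrid"` (default), `"bce"`, `"dice"`, `"focal"`.
#' @param lr,batch_size,max_epochs,patience Optimiser protocol.
#' @param delta Dice smoothing constant.
#' @param gamma,alpha Focal-loss hyperparameters.
#' @param augment Apply random augmentation to each training slice, fresh
#'   every epoch.
#' @param seed Master seed (weights, shuffling, augmentation).
#' @param verbose Print per-epoch progress.
#' @return A `fecc_fit`: the trained network plus per-epoch history.
#'   [tidy()] returns the epoch curves, [glance()] a one-row summary,
#'   [ggplot2::autoplot()] the training curves.
#' @export
train_fecc <- function(records, cfg, loss = c("hybrid", "bce", "dice",
                                              "focal"),
                       lr = 1e-4, batch_size = 16L, max_epochs = 300L,
                       patience = 20L, delta = 1e-15, gamma = 2,
                       alpha = 0.25, augment = FALSE, seed = 1L,
                       verbose = FALSE) {
  loss <- match.arg(loss)
  if (!"split" %in% names(records)) {
    stop("records need a 'split' column; run split_dataset() first",
         call. = FALSE)
  }
  tr <- dplyr::filter(records, .data$split == "train")
  va <- dplyr::filter(records, .data$split == "val")
  if (nrow(tr) == 0L || nrow(va) == 0L) {
    stop("train and val partitions must both be non-empty", call. = FALSE)
  }
  S <- nrow(tr$image[[1L]])
  if (S != cfg$input_size) {
    stop("cfg$input_size (", cfg$input_size, ") != slice size (", S, ")",
         call. = FALSE)
  }
  lf <- loss_fns(loss, delta = delta, gamma = gamma, alpha = alpha)
  net <- build_fecc_net(cfg, seed = seed)
  opt <- adam_init(net$graph$params)
  n_tr <- nrow(tr)
  history <- vector("list", max_epochs)
  best <- list(dsc = -Inf, params = NULL, state = NULL, epoch = 0L)
  wait <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- with_seed(seed + 7919L * epoch, sample.int(n_tr))
    ep_losses <- c()
    for (bstart in seq(1L, n_tr, by = batch_size)) {
      idx <- ord[bstart:min(bstart + batch_size - 1L, n_tr)]
      nb <- length(idx)
      x <- array(0, c(S, S, 1L, nb))
      y <- array(0, c(S, S, 1L, nb))
      for (j in seq_len(nb)) {
        rec <- tr[idx[j], ]
        if (augment) {
          rec <- augment_record(rec,
                                seed = (seed + 104729L * epoch +
                                          idx[j]) %% .Machine$integer.max)
        }
        x[, , 1L, j] <- rec$image[[1L]]
        y[, , 1L, j] <- rec$mask[[1L]]
      }
      fw <- g_forward(net$graph, x / 255, train = TRUE, keep = TRUE)
      net$graph$state <- fw$state
      p <- fw$out
      ep_losses <- c(ep_losses, lf$value(y, p))
      dout <- lf$grad(y, p)
      bw <- g_backward(net$graph, fw, dout)
      upd <- adam_step(net$graph$params, bw$grads, opt, lr = lr)
      net$graph$params <- upd$params
      opt <- upd$opt
    }
    val_dsc <- mean(slice_metrics(net, va, batch_size = batch_size)$dsc)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(ep_losses),
                                       val_dsc = val_dsc)
    epochs_run <- epoch
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", epoch,
                      mean(ep_losses), val_dsc))
    }
    if (val_dsc > best$dsc) {
      best <- list(dsc = val_dsc, params = net$graph$params,
                   state = net$graph$state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net$graph$params <- best$params
  net$graph$state <- best$state
  structure(list(net = net,
                 history = dplyr::bind_rows(history[seq_len(epochs_run)]),
                 loss = loss, seed = as.integer(seed),
                 best_epoch = best$epoch, best_val_dsc = best$dsc,
                 args = list(lr = lr, batch_size = batch_size,
                             max_epochs = max_epochs, patience = patience,
                             delta = delta, gamma = gamma, alpha = alpha,
                             augment = augment)),
            class = "fecc_fit")
}

#' @export
print.fecc_fit <- function(x, ...) {
  cat(sprintf("fecc_fit: %s loss, %d epoch(s), best val DSC %.4f (epoch %d)\n",
              x$loss, nrow(x$history), x$best_val_dsc, x$best_epoch))
  print(x$net)
  invisible(x)
}

#' Noise-robustness experiment
#'
#' Evaluates the same slices clean and corrupted with additive Gaussian
#' noise (default sigma = 40 on the [0, 255] scale) and reports per-stratum
#' DSC for both conditions plus the drop.
#'
#' @param net A `fecc_net` or `fecc_fit`.
#' @param records Test slice tibble.
#' @param sigma Noise standard deviation.
#' @param seed Seed for the noise draws (one derived stream per slice).
#' @param batch_size Slices per forward pass.
#' @return Tibble: `stratum`, `n_slices`, `dsc_clean`, `dsc_noisy`,
#'   `dsc_drop`.
#' @export
run_noise_experiment <- function(net, records, sigma = 40, seed = 1L,
                                 batch_size = 16L) {
  noisy <- records
  slice_seeds <- with_seed(seed,
                           sample.int(.Machine$integer.max - 1L,
                                      nrow(records)))
  noisy$image <- purrr::map2(records$image, slice_seeds,
                             function(im, sd) add_gaussian_noise(im, sigma,
                                                                 seed = sd))
  clean_rep <- evaluate_segmentation(net, records, batch_size = batch_size)
  noisy_rep <- evaluate_segmentation(net, noisy, batch_size = batch_size)
  out <- dplyr::inner_join(
    dplyr::select(clean_rep, "stratum", "n_slices", dsc_clean = "dsc"),
    dplyr::select(noisy_rep, "stratum", dsc_noisy = "dsc"),
    by = "stratum")
  dplyr::mutate(out, dsc_drop = .data$dsc_clean - .data$dsc_noisy)
}

#' Re-train under each loss for comparison
#'
#' Runs [train_fecc()] once per loss on identical data and seed and
#' evaluates each fit on the `test` partition (falling back to `val` if no
#' test slices exist), giving a loss-ablation table.
#'
#' @inheritParams train_fecc
#' @param losses Losses to compare.
#' @return Tibble: `loss`, `dsc`, `miou`, `recall`, `precision`,
#'   `best_epoch`.
#' @export
compare_losses <- function(records, cfg,
                           losses = c("bce", "dice", "focal", "hybrid"),
                           ..., seed = 1L) {
  eval_part <- if (any(records$split == "test")) "test" else "val"
  held <- dplyr::filter(records, .data$split == eval_part)
  purrr::map(losses, function(ls) {
    fit <- train_fecc(records, cfg, loss = ls, ..., seed = seed)
    rep <- evaluate_segmentation(fit, held)
    ov <- dplyr::filter(rep, .data$stratum == "overall")
    tibble::tibble(loss = ls, dsc = ov$dsc, miou = ov$miou,
                   recall = ov$recall, precision = ov$precision,
                   best_epoch = fit$best_epoch)
  }) |> dplyr::bind_rows()
}

#' Predict masks and overlays to files
#'
#' Writes, for every input image, a binary mask PNG and an overlay PNG in
#' which predicted lesion pixels are tinted red over the grayscale slice.
#'
#' @param net A `fecc_net` or `fecc_fit` (or a checkpoint path).
#' @param images A list of [0, 255] matrices, or paths to grayscale PNGs.
#' @param out_dir Output directory.
#' @param threshold Optional binarization override.
#' @return Tibble with `input`, `mask_path`, `overlay_path`,
#'   `lesion_pixels`.
#' @export
predict_to_files <- function(net, images, out_dir, threshold = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  read_gray <- function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a * 255
  }
  nms <- names(images)
  if (is.character(images)) {
    paths <- images
    images <- purrr::map(paths, read_gray)
    nms <- tools::file_path_sans_ext(basename(paths))
  }
  if (is.null(nms)) nms <- sprintf("slice%03d", seq_along(images))
  rows <- purrr::map2(images, nms, function(im, nm) {
    m <- predict_mask(net, im, threshold = threshold)
    mask_path <- file.path(out_dir, paste0(nm, "_mask.png"))
    over_path <- file.path(out_dir, paste0(nm, "_overlay.png"))
    png::writePNG(m, mask_path)
    gray <- im / 255
    rgb <- array(rep(gray, 3L), c(dim(gray), 3L))
    les <- m == 1
    r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
    r[les] <- 1; g[les] <- 0.3 * g[les]; b[les] <- 0.3 * b[les]
    rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
    png::writePNG(rgb, over_path)
    tibble::tibble(input = nm, mask_path = mask_path,
                   overlay_path = over_path, lesion_pixels = sum(m))
  })
  dplyr::bind_rows(rows)
}
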