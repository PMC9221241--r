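# Assembly of the FECC-Net segmentation architecture.

#' Network configuration
#'
#' Describes a FECC-Net instance: a `depth`-level main encoder (each level two
#' 3x3 conv blocks followed by squeeze-and-excitation, then 2x2 max pooling),
#' atrous spatial pyramid pooling (ASPP) at the bottleneck, a decoder that at
#' each level bilinearly upsamples 2x, concatenates the main-encoder skip and
#' (for the full variant) the enhanced-encoder skip, and applies conv blocks,
#' ending in a 1x1 convolution with logistic output.
#'
#' The default channel widths are the calibrated configuration whose trainable
#' parameter count rounds to 7.0 million for the full network and 3.8 million
#' for the lite variant (enhanced encoder disabled); see the methods vignette
#' for the calibration procedure.
#'
#' @param input_size Side length of the (square) input slice; must be
#'   divisible by `2^depth`. Default 512.
#' @param input_channels Number of input channels (1 for grayscale T1 MRI).
#' @param depth Number of down/upsampling levels.
#' @param channel_schedule Integer vector, one width per encoder level,
#'   strictly increasing, each divisible by `se_reduction`.
#' @param aspp_rates Distinct dilation rates of the parallel ASPP branches.
#' @param aspp_channels Width of each ASPP branch and of its 1x1 fusion.
#' @param enhanced_encoder If `TRUE` build the full network with the
#'   depthwise-separable enhanced encoder; `FALSE` gives FECC-Net-lite.
#' @param enhanced_channels Widths of the enhanced encoder, one per level.
#' @param enhanced_stack Number of stacked depthwise-separable blocks per
#'   enhanced-encoder level below the stem.
#' @param se_reduction Squeeze-and-excitation bottleneck reduction ratio.
#' @param threshold Probability cut for binarizing predictions.
#' @return A `fecc_config` list.
#' @export
#' @examples
#' cfg <- fecc_config(input_size = 64, channel_schedule = c(8, 16, 24, 32),
#'                    aspp_channels = 32, enhanced_channels = c(8, 16, 24, 32))
fecc_config <- function(input_size = 512L,
                        input_channels = 1L,
                        depth = 4L,
                        channel_schedule = c(24L, 48L, 96L, 192L),
                        aspp_rates = c(1L, 6L, 12L, 18L),
                        aspp_channels = 168L,
                        enhanced_encoder = TRUE,
                        enhanced_channels = c(64L, 128L, 256L, 760L),
                        enhanced_stack = 3L,
                        se_reduction = 8L,
                        threshold = 0.5) {
  cfg <- list(input_size = as.integer(input_size),
              input_channels = as.integer(input_channels),
              depth = as.integer(depth),
              channel_schedule = as.integer(channel_schedule),
              aspp_rates = as.integer(aspp_rates),
              aspp_channels = as.integer(aspp_channels),
              enhanced_encoder = isTRUE(enhanced_encoder),
              enhanced_channels = as.integer(enhanced_channels),
              enhanced_stack = as.integer(enhanced_stack),
              se_reduction = as.integer(se_reduction),
              threshold = threshold)
  validate_fecc_config(cfg)
  structure(cfg, class = "fecc_config")
}

#' Reduced-width configuration for CPU-scale runs
#'
#' A named profile of [fecc_config()] sized for desk-scale experiments and
#' the test suite: 64 x 64 slices, a narrow channel schedule and a shallow
#' ASPP rate set matched to the 4 x 4 bottleneck. The architecture is
#' identical to the full-scale profile; only widths differ.
#'
#' @param input_size Slice side (default 64).
#' @param enhanced_encoder Build the full (TRUE) or lite (FALSE) variant.
#' @return A `fecc_config`.
#' @export
fecc_test_config <- function(input_size = 64L, enhanced_encoder = TRUE) {
  fecc_config(input_size = input_size,
              channel_schedule = c(8L, 16L, 24L, 32L),
              aspp_rates = c(1L, 2L, 4L),
              aspp_channels = 32L,
              enhanced_encoder = enhanced_encoder,
              enhanced_channels = c(8L, 16L, 24L, 32L),
              enhanced_stack = 1L)
}

#' @noRd
validate_fecc_config <- function(cfg) {
  if (length(cfg$channel_schedule) != cfg$depth) {
    stop("channel_schedule must have one entry per level (depth = ",
         cfg$depth, ")", call. = FALSE)
  }
  if (any(diff(cfg$channel_schedule) <= 0)) {
    stop("channel_schedule must be strictly increasing", call. = FALSE)
  }
  if (cfg$input_size %% (2L^cfg$depth) != 0L) {
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  }
  if (any(cfg$channel_schedule %% cfg$se_reduction != 0L)) {
    stop("channel widths must be divisible by se_reduction", call. = FALSE)
  }
  if (length(cfg$aspp_rates) == 0L || anyDuplicated(cfg$aspp_rates)) {
    stop("aspp_rates must be non-empty and distinct", call. = FALSE)
  }
  if (any(cfg$aspp_rates < 1L) || cfg$aspp_channels < 1L) {
    stop("aspp rates and channels must be positive", call. = FALSE)
  }
  if (cfg$enhanced_encoder &&
      length(cfg$enhanced_channels) != cfg$depth) {
    stop("enhanced_channels must have one entry per level", call. = FALSE)
  }
  if (!(cfg$threshold > 0 && cfg$threshold < 1)) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add the enhanced encoder to a graph; returns list(g, skip_ids).
#'
#' Stem: two conv blocks at full resolution, then pooling; deeper levels are
#' stacks of depthwise-separable blocks, each followed by pooling, so level l
#' emits its feature map at resolution input_size / 2^l.
#' @noRd
g_enhanced_encoder <- function(g, input_id, cfg) {
  ech <- cfg$enhanced_channels
  skips <- integer(cfg$depth)
  g <- g_conv_block(g, input_id, cfg$input_channels, ech[1L])
  g <- g_conv_block(g, g$last_id, ech[1L], ech[1L])
  g <- g_add(g, "maxpool", g$last_id)
  skips[1L] <- g$last_id
  for (l in seq(2L, cfg$depth)) {
    in_ch <- ech[l - 1L]
    for (s in seq_len(cfg$enhanced_stack)) {
      g <- g_dwsep_block(g, g$last_id, in_ch, ech[l])
      in_ch <- ech[l]
    }
    g <- g_add(g, "maxpool", g$last_id)
    skips[l] <- g$last_id
  }
  list(g = g, skips = skips)
}

#' Build the FECC-Net segmentation network
#'
#' Assembles the computation graph and initializes all weights (He-uniform,
#' seeded). `build_fecc_net_lite()` is a convenience wrapper that disables the
#' enhanced encoder.
#'
#' @param cfg A [fecc_config()].
#' @param seed Integer seed for weight initialization; the same config and
#'   seed always give the same network.
#' @return A `fecc_net` object.
#' @export
build_fecc_net <- function(cfg = fecc_config(), seed = 42L) {
  validate_fecc_config(cfg)
  ch <- cfg$channel_schedule
  g <- new_graph()
  g <- g_add(g, "input")
  input_id <- g$last_id

  # main encoder: skips kept before pooling, at resolution S / 2^(l-1)
  skips <- integer(cfg$depth)
  in_ch <- cfg$input_channels
  for (l in seq_len(cfg$depth)) {
    g <- g_conv_block(g, g$last_id, in_ch, ch[l])
    g <- g_conv_block(g, g$last_id, ch[l], ch[l])
    g <- g_add(g, "se", g$last_id, ch = ch[l], reduction = cfg$se_reduction)
    skips[l] <- g$last_id
    g <- g_add(g, "maxpool", g$last_id)
    in_ch <- ch[l]
  }

  # ASPP bottleneck at resolution S / 2^depth
  g <- g_aspp(g, g$last_id, ch[cfg$depth], cfg$aspp_rates,
              cfg$aspp_channels, cfg$aspp_channels)
  aspp_id <- g$last_id

  # enhanced encoder (full variant): level-l map at resolution S / 2^l,
  # upsampled 2x (parameter-free) to join the decoder concat at S / 2^(l-1)
  enh <- NULL
  if (cfg$enhanced_encoder) {
    r <- g_enhanced_encoder(g, input_id, cfg)
    g <- r$g
    enh <- r$skips
  }

  # decoder
  prev_ch <- cfg$aspp_channels
  prev_id <- aspp_id
  for (l in rev(seq_len(cfg$depth))) {
    g <- g_add(g, "upsample", prev_id)
    g <- g_conv_block(g, g$last_id, prev_ch, ch[l])
    up_id <- g$last_id
    ins <- c(up_id, skips[l])
    cat_ch <- 2L * ch[l]
    if (cfg$enhanced_encoder) {
      g <- g_add(g, "upsample", enh[l])
      ins <- c(ins, g$last_id)
      cat_ch <- cat_ch + cfg$enhanced_channels[l]
    }
    g <- g_add(g, "concat", ins)
    g <- g_conv_block(g, g$last_id, cat_ch, ch[l])
    g <- g_conv_block(g, g$last_id, ch[l], ch[l])
    prev_ch <- ch[l]
    prev_id <- g$last_id
  }

  # 1x1 head with bias + logistic squashing
  g <- g_add(g, "conv", g$last_id, in_ch = ch[1L], out_ch = 1L, k = 1L,
             bias = TRUE)
  g <- g_add(g, "sigmoid", g$last_id)
  g$out_ids <- g$last_id

  g <- with_seed(seed, g_init_params(g))
  structure(list(graph = g, cfg = cfg, seed = as.integer(seed),
                 variant = if (cfg$enhanced_encoder) "full" else "lite"),
            class = "fecc_net")
}

#' @rdname build_fecc_net
#' @export
build_fecc_net_lite <- function(cfg = fecc_config(), seed = 42L) {
  cfg$enhanced_encoder <- FALSE
  build_fecc_net(cfg, seed = seed)
}

#' Build the enhanced encoder on its own
#'
#' Returns the secondary (boundary-enhancement) encoder as a standalone
#' network emitting one feature map per level, at resolutions
#' `input_size / 2^l` for `l = 1..depth`. Used by the full network as
#' secondary skip connections; exposed separately for inspection.
#'
#' @inheritParams build_fecc_net
#' @return A `fecc_net` object whose forward pass yields a list of `depth`
#'   feature maps.
#' @export
build_enhanced_encoder <- function(cfg = fecc_config(), seed = 42L) {
  validate_fecc_config(cfg)
  if (!cfg$enhanced_encoder) {
    stop("cfg$enhanced_encoder must be TRUE", call. = FALSE)
  }
  g <- new_graph()
  g <- g_add(g, "input")
  r <- g_enhanced_encoder(g, g$last_id, cfg)
  g <- r$g
  g$out_ids <- r$skips
  g <- with_seed(seed, g_init_params(g))
  structure(list(graph = g, cfg = cfg, seed = as.integer(seed),
                 variant = "enhanced_encoder"),
            class = "fecc_net")
}

#' Count trainable parameters
#'
#' Exact sum of all trainable scalars (convolution kernels, biases,
#' batch-norm scale/shift, squeeze-and-excitation dense layers). Batch-norm
#' running statistics are not trainable and are excluded.
#'
#' @param net A `fecc_net` (or a fitted `fecc_fit`).
#' @return Integer parameter count.
#' @export
#' @examples
#' cfg <- fecc_config(input_size = 64, channel_schedule = c(8, 16, 24, 32),
#'                    aspp_channels = 24, enhanced_channels = c(8, 16, 24, 32),
#'                    enhanced_stack = 1)
#' count_parameters(build_fecc_net(cfg))
count_parameters <- function(net) {
  net <- as_fecc_net(net)
  sum(vapply(net$graph$params, length, numeric(1)))
}

#' @noRd
as_fecc_net <- function(x) {
  if (inherits(x, "fecc_fit")) return(x$net)
  if (inherits(x, "fecc_net") || inherits(x, "fecc_block")) return(x)
  stop("expected a 'fecc_net', 'fecc_block' or 'fecc_fit' object",
       call. = FALSE)
}

#' Prepare a (H, W) image matrix or (H, W, C, N) array for the network.
#' Intensities on [0, 255] are rescaled to [0, 1].
#' @noRd
as_input_tensor <- function(net, image) {
  cfg <- net$cfg
  if (is.matrix(image)) {
    image <- array(image, c(dim(image), 1L, 1L))
  }
  d <- dim(image)
  if (length(d) != 4L || d[1L] != d[2L] || d[3L] != cfg$input_channels) {
    stop("input must be a square (H, W) matrix or (H, W, ",
         cfg$input_channels, ", N) array", call. = FALSE)
  }
  if (d[1L] %% (2L^cfg$depth) != 0L) {
    stop("input side must be divisible by 2^depth = ", 2L^cfg$depth,
         call. = FALSE)
  }
  image / 255
}

#' Predict lesion probabilities / masks for one slice
#'
#' `predict_prob()` returns the per-pixel lesion probability map in (0, 1);
#' `predict_mask()` thresholds it at `net$cfg$threshold` (default 0.5) into a
#' binary \{0, 1\} mask, lesion = 1.
#'
#' @param net A `fecc_net` or `fecc_fit`.
#' @param image Square grayscale matrix on the [0, 255] intensity scale with
#'   side divisible by `2^depth`.
#' @param threshold Optional override of the config threshold.
#' @return A matrix the same size as `image`.
#' @export
predict_prob <- function(net, image) {
  net <- as_fecc_net(net)
  x <- as_input_tensor(net, image)
  out <- g_forward(net$graph, x, train = FALSE, keep = FALSE)$out
  matrix(out[, , 1L, 1L], dim(x)[1L], dim(x)[2L])
}

#' @rdname predict_prob
#' @export
predict_mask <- function(net, image, threshold = NULL) {
  net <- as_fecc_net(net)
  threshold <- threshold %||% net$cfg$threshold
  p <- predict_prob(net, image)
  (p > threshold) + 0
}

#' Batched forward pass over an (H, W, C, N) tensor of [0,255] images.
#' @noRd
predict_prob_batch <- function(net, images) {
  net <- as_fecc_net(net)
  x <- as_input_tensor(net, images)
  g_forward(net$graph, x, train = FALSE, keep = FALSE)$out
}

#' Forward pass of a multi-output network (e.g. the standalone enhanced
#' encoder); returns the list of per-level feature maps.
#' @noRd
forward_maps <- function(net, image) {
  x <- as_input_tensor(net, image)
  out <- g_forward(net$graph, x, train = FALSE, keep = FALSE)$out
  if (!is.list(out)) out <- list(out)
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file holding the network (or fit) object; a JSON
#' sidecar `<path>.json` records the exact configuration, variant and seed for
#' inspection without loading the weights.
#'
#' @param net A `fecc_net` or `fecc_fit`.
#' @param path Destination file path.
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` the
#'   restored object.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  obj <- as_fecc_net(net)
  jsonlite::write_json(
    list(config = unclass(obj$cfg), variant = obj$variant, seed = obj$seed,
         total_parameters = count_parameters(obj)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  readRDS(path)
}

#' @export
print.fecc_net <- function(x, ...) {
  cat(sprintf("FECC-Net (%s variant)\n", x$variant))
  cat(sprintf("  input: %d x %d x %d\n", x$cfg$input_size, x$cfg$input_size,
              x$cfg$input_channels))
  cat(sprintf("  channel schedule: %s | ASPP: rates {%s} x %d\n",
              paste(x$cfg$channel_schedule, collapse = ", "),
              paste(x$cfg$aspp_rates, collapse = ","), x$cfg$aspp_channels))
  cat(sprintf("  trainable parameters: %s (%.1f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}
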