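# User-facing network building blocks.
#
# These operate on a single FeatureMap: a rank-3 numeric array
# (height, width, channels). Each convenience function builds a freshly
# initialized block (seeded) and applies it in evaluation mode; for weight
# surgery or parameter counting build the block once with `new_block()` and
# apply it with `apply_block()`.

#' @noRd
as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("a FeatureMap is a (height, width, channels) array", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("FeatureMap values must be finite", call. = FALSE)
  x
}

#' Construct a reusable network block
#'
#' @param type One of `"conv"` (3x3 conv + batch norm + ReLU), `"se"`
#'   (squeeze-and-excitation channel attention), `"dwsep"` (depthwise 3x3 +
#'   pointwise 1x1, each with batch norm + ReLU) or `"aspp"` (parallel
#'   dilated conv blocks + 1x1 fusion).
#' @param in_channels Channels of the input feature map.
#' @param out_channels Output channels (`conv`, `dwsep`, `aspp`).
#' @param kernel_size Odd kernel size, default 3.
#' @param dilation Dilation rate of a conv block.
#' @param reduction SE bottleneck reduction; `in_channels` must be divisible
#'   by it.
#' @param dilation_rates Distinct positive dilation rates for `aspp`.
#' @param seed RNG seed for weight initialization.
#' @return A `fecc_block` object (its parameters live in
#'   `block$graph$params`).
#' @export
new_block <- function(type = c("conv", "se", "dwsep", "aspp"),
                      in_channels,
                      out_channels = NULL,
                      kernel_size = 3L,
                      dilation = 1L,
                      reduction = 8L,
                      dilation_rates = c(1L, 6L, 12L, 18L),
                      seed = 1L) {
  type <- match.arg(type)
  in_channels <- as.integer(in_channels)
  if (in_channels < 1L) stop("in_channels must be positive", call. = FALSE)
  if (kernel_size %% 2L != 1L || kernel_size < 1L) {
    stop("kernel_size must be a positive odd integer", call. = FALSE)
  }
  if (type != "se") {
    out_channels <- as.integer(out_channels)
    if (is.na(out_channels) || out_channels < 1L) {
      stop("out_channels must be a positive integer", call. = FALSE)
    }
  }
  g <- new_graph()
  g <- g_add(g, "input")
  g <- switch(type,
    conv = g_conv_block(g, g$last_id, in_channels, out_channels,
                        k = as.integer(kernel_size),
                        dilation = as.integer(dilation)),
    se = {
      if (in_channels %% reduction != 0L) {
        stop("in_channels must be divisible by reduction", call. = FALSE)
      }
      g_add(g, "se", g$last_id, ch = in_channels,
            reduction = as.integer(reduction))
    },
    dwsep = g_dwsep_block(g, g$last_id, in_channels, out_channels,
                          k = as.integer(kernel_size)),
    aspp = {
      rates <- as.integer(dilation_rates)
      if (length(rates) == 0L) {
        stop("dilation_rates must be non-empty", call. = FALSE)
      }
      if (anyDuplicated(rates) || any(rates < 1L)) {
        stop("dilation_rates must be distinct positive integers",
             call. = FALSE)
      }
      g_aspp(g, g$last_id, in_channels, rates, out_channels, out_channels)
    })
  g$out_ids <- g$last_id
  g <- with_seed(seed, g_init_params(g))
  structure(list(graph = g, type = type, in_channels = in_channels,
                 out_channels = if (type == "se") in_channels else out_channels),
            class = "fecc_block")
}

#' Apply a block to a FeatureMap
#'
#' @param block A [new_block()] object.
#' @param x FeatureMap: (height, width, channels) array (a matrix is treated
#'   as single-channel).
#' @param train Use batch statistics (`TRUE`) or running statistics (`FALSE`)
#'   in batch norm.
#' @param force_se_identity Test hook: clamp all SE gates to 1, making the SE
#'   block the identity.
#' @return FeatureMap with `block$out_channels` channels and the spatial size
#'   of `x`.
#' @export
apply_block <- function(block, x, train = FALSE, force_se_identity = FALSE) {
  stopifnot(inherits(block, "fecc_block"))
  x <- as_feature_map(x)
  if (dim(x)[3L] != block$in_channels) {
    stop("input has ", dim(x)[3L], " channels; block expects ",
         block$in_channels, call. = FALSE)
  }
  x4 <- array(x, c(dim(x), 1L))
  out <- g_forward(block$graph, x4, train = train, keep = FALSE,
                   force_se_identity = force_se_identity)$out
  array(out, dim(out)[1:3])
}

#' Standard network blocks applied to a FeatureMap
#'
#' One-shot convenience wrappers: each builds a seeded, freshly initialized
#' block and applies it. All blocks are stride-1 with size-preserving
#' padding, so spatial dimensions never change.
#'
#' * `conv_block()`: 3x3 convolution (optionally dilated) + batch
#'   normalization + ReLU; output is non-negative.
#' * `se_block()`: squeeze-and-excitation — global average pooling to one
#'   scalar per channel, a bottleneck of two dense layers, and per-channel
#'   rescaling by sigmoid gates in (0,1).
#' * `depthwise_separable_block()`: depthwise 3x3 then pointwise 1x1
#'   convolution, each followed by batch norm + ReLU; parameter count is far
#'   below the equivalent full convolution.
#' * `aspp()`: atrous spatial pyramid pooling — parallel 3x3 conv blocks at
#'   the given dilation rates, concatenated and fused by a 1x1 conv block.
#'
#' @inheritParams new_block
#' @param x FeatureMap: (height, width, channels) array; a matrix is treated
#'   as a single-channel map.
#' @param ... Passed on to [apply_block()].
#' @return A FeatureMap with the requested number of output channels.
#' @export
#' @examples
#' x <- array(runif(16 * 16 * 4), c(16, 16, 4))
#' dim(conv_block(x, out_channels = 8))            # 16 16 8
#' dim(aspp(x, out_channels = 8, dilation_rates = c(1, 2, 4)))
conv_block <- function(x, out_channels, kernel_size = 3L, dilation = 1L,
                       seed = 1L, ...) {
  x <- as_feature_map(x)
  b <- new_block("conv", dim(x)[3L], out_channels, kernel_size = kernel_size,
                 dilation = dilation, seed = seed)
  apply_block(b, x, ...)
}

#' @rdname conv_block
#' @export
se_block <- function(x, reduction = 8L, seed = 1L, ...) {
  x <- as_feature_map(x)
  b <- new_block("se", dim(x)[3L], reduction = reduction, seed = seed)
  apply_block(b, x, ...)
}

#' @rdname conv_block
#' @export
depthwise_separable_block <- function(x, out_channels, kernel_size = 3L,
                                      seed = 1L, ...) {
  x <- as_feature_map(x)
  b <- new_block("dwsep", dim(x)[3L], out_channels,
                 kernel_size = kernel_size, seed = seed)
  apply_block(b, x, ...)
}

#' @rdname conv_block
#' @export
aspp <- function(x, out_channels, dilation_rates = c(1L, 6L, 12L, 18L),
                 seed = 1L, ...) {
  x <- as_feature_map(x)
  b <- new_block("aspp", dim(x)[3L], out_channels,
                 dilation_rates = dilation_rates, seed = seed)
  apply_block(b, x, ...)
}

#' @export
print.fecc_block <- function(x, ...) {
  cat(sprintf("fecc_block <%s>: %d -> %d channels, %d parameters\n",
              x$type, x$in_channels, x$out_channels, count_parameters(x)))
  invisible(x)
}
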