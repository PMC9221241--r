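get_param <- function(block, suffix) {
  nm <- grep(paste0(suffix, "$"), names(block$graph$params), value = TRUE)
  block$graph$params[[nm[1]]]
}

test_that("conv block preserves spatial size, is non-negative, and counts parameters in closed form", {
  x <- array(runif(64 * 64), c(64, 64, 1))
  y <- conv_block(x, out_channels = 32)
  expect_equal(dim(y), c(64, 64, 32))
  expect_gte(min(y), 0)
  expect_true(all(is.finite(y)))

  # 3x3 kernel from 32 to 32 channels, bias-free: 3*3*32*32 scalars
  b <- new_block("conv", 32, 32)
  expect_equal(length(get_param(b, "_W")), 9216)
  # plus batch-norm scale and shift
  expect_equal(count_parameters(b), 9216 + 2 * 32)

  # all-zero input stays finite (the block's normalization/shift response)
  z <- conv_block(array(0, c(16, 16, 4)), out_channels = 8)
  expect_true(all(is.finite(z)))
  expect_error(conv_block(x, out_channels = 0), "positive")
  expect_error(new_block("conv", 4, 8, kernel_size = 4), "odd")
})

test_that("SE block rescales channels by gates in (0,1) and is identity when gates are forced", {
  set.seed(21)
  x <- array(runif(32 * 32 * 64, 0.1, 1), c(32, 32, 64))
  b <- new_block("se", 64, reduction = 8)
  y <- apply_block(b, x)
  expect_equal(dim(y), dim(x))
  # each output channel is the input channel times one scalar in (0,1)
  for (ch in sample(64, 8)) {
    ratio <- y[, , ch] / x[, , ch]
    expect_lt(diff(range(ratio)), 1e-10)
    expect_gt(ratio[1], 0)
    expect_lt(ratio[1], 1)
  }
  # forced gates: exact identity
  expect_identical(apply_block(b, x, force_se_identity = TRUE), x)
  expect_error(new_block("se", 66, reduction = 8), "divisible")
})

test_that("SE squeeze is the per-channel spatial mean (brute-force oracle)", {
  set.seed(22)
  x <- array(runif(4 * 4 * 2), c(4, 4, 2, 1))
  z <- feccnet:::se_squeeze(x)
  manual <- c(mean(x[, , 1, 1]), mean(x[, , 2, 1]))
  expect_equal(as.vector(z), manual, tolerance = 1e-12)
})

test_that("depthwise-separable block meets its parameter formulas and contracts", {
  x <- array(runif(16 * 16 * 8), c(16, 16, 8))
  y <- depthwise_separable_block(x, out_channels = 16)
  expect_equal(dim(y), c(16, 16, 16))

  # depthwise 3x3 on 64 channels + pointwise to 64: 3*3*64 + 64*64 kernels
  b <- new_block("dwsep", 64, 64)
  w <- vapply(b$graph$params, length, numeric(1))
  kernels <- sum(w[grep("_W$", names(w))])
  expect_equal(kernels, 3 * 3 * 64 + 64 * 64)  # 4672
  expect_lt(kernels, 3 * 3 * 64 * 64)          # full conv: 36864
  # and for the degenerate single-channel case: 9 + 1
  b1 <- new_block("dwsep", 1, 1)
  w1 <- vapply(b1$graph$params, length, numeric(1))
  expect_equal(sum(w1[grep("_W$", names(w1))]), 10)
})

test_that("depthwise separable factorization always undercuts the full convolution", {
  for (cin in c(2, 8, 32)) {
    for (cout in c(2, 16, 64)) {
      sep <- 3 * 3 * cin + cin * cout
      full <- 3 * 3 * cin * cout
      expect_lt(sep, full)
    }
  }
})

test_that("ASPP fuses parallel dilated branches and keeps the spatial contract", {
  x <- array(runif(32 * 32 * 16), c(32, 32, 16))
  y <- aspp(x, out_channels = 16, dilation_rates = c(1, 6, 12, 18))
  expect_equal(dim(y), c(32, 32, 16))
  expect_error(aspp(x, out_channels = 16, dilation_rates = integer(0)),
               "non-empty")
  expect_error(aspp(x, out_channels = 16, dilation_rates = c(2, 2)),
               "distinct")
})

test_that("a dilated 3x3 kernel touches offsets -d, 0, +d (impulse response)", {
  S <- 25L
  x <- array(0, c(S, S, 1, 1))
  x[13, 13, 1, 1] <- 1
  W <- array(1, c(3, 3, 1, 1))
  y <- feccnet:::conv2d_fwd(x, W, dilation = 6L)
  hit <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
  expect_setequal(unique(hit[, 1]) - 13, c(-6, 0, 6))
  expect_setequal(unique(hit[, 2]) - 13, c(-6, 0, 6))
  # dilation 1 gives the ordinary 3x3 footprint
  y1 <- feccnet:::conv2d_fwd(x, W, dilation = 1L)
  hit1 <- which(y1[, , 1, 1] != 0, arr.ind = TRUE)
  expect_setequal(unique(hit1[, 1]) - 13, c(-1, 0, 1))
})

test_that("single-rate ASPP collapses to a conv block on identical weights", {
  set.seed(30)
  x <- array(runif(12 * 12 * 4), c(12, 12, 4))
  a <- new_block("aspp", 4, 8, dilation_rates = 1L, seed = 3)
  cb <- new_block("conv", 4, 8, seed = 4)
  # copy the ASPP branch weights into the conv block
  pa <- names(a$graph$params)
  pc <- names(cb$graph$params)
  cb$graph$params[[grep("_W$", pc, value = TRUE)[1]]] <-
    a$graph$params[[grep("_W$", pa, value = TRUE)[1]]]
  # neutralize the 1x1 fusion: identity kernel, neutral batch norm
  fusion_W <- grep("_W$", pa, value = TRUE)[2]
  a$graph$params[[fusion_W]] <- array(diag(8), c(1, 1, 8, 8))
  ya <- apply_block(a, x)
  yc <- apply_block(cb, x)
  # both paths share the branch conv; the neutralized fusion only applies
  # one extra fresh-stats normalization (a 1/sqrt(1+eps) scale)
  expect_equal(dim(ya), dim(yc))
  expect_equal(ya, yc / sqrt(1 + 1e-3), tolerance = 1e-10)
})

test_that("every block preserves spatial dimensions", {
  x <- array(runif(20 * 20 * 8), c(20, 20, 8))
  dims <- list(
    conv_block(x, out_channels = 4),
    se_block(x, reduction = 4),
    depthwise_separable_block(x, out_channels = 4),
    aspp(x, out_channels = 8, dilation_rates = c(1, 2)))
  for (y in dims) expect_equal(dim(y)[1:2], c(20, 20))
})
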