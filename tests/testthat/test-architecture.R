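test_that("forward pass is shape preserving with outputs strictly in (0,1)", {
  for (S in c(16L, 32L)) {
    net <- build_fecc_net(tiny_cfg(S), seed = 1)
    img <- matrix(runif(S * S, 0, 255), S, S)
    p <- predict_prob(net, img)
    expect_equal(dim(p), c(S, S))
    expect_gt(min(p), 0)
    expect_lt(max(p), 1)
    m <- predict_mask(net, img)
    expect_true(all(m %in% c(0, 1)))
    expect_equal(dim(m), dim(img))
  }
})

test_that("prediction thresholds exactly at the configured cut", {
  net <- build_fecc_net(tiny_cfg(16), seed = 1)
  # force the head to constant logits via zero weights and a chosen bias
  head_id <- length(net$graph$nodes) - 1L
  pn <- net$graph$nodes[[head_id]]$pname
  net$graph$params[[paste0(pn, "_W")]][] <- 0
  img <- matrix(runif(256, 0, 255), 16, 16)
  for (target in c(0.49, 0.51)) {
    net$graph$params[[paste0(pn, "_b")]] <- log(target / (1 - target))
    p <- predict_prob(net, img)
    expect_equal(max(abs(p - target)), 0, tolerance = 1e-12)
    m <- predict_mask(net, img)
    expect_true(all(m == as.integer(target > 0.5)))
  }
  # strongly negative logits: all-background mask
  net$graph$params[[paste0(pn, "_b")]] <- -20
  expect_equal(sum(predict_mask(net, img)), 0)
})

test_that("parameter counter is exact for hand-countable layers", {
  g <- feccnet:::new_graph()
  g <- feccnet:::g_add(g, "input")
  g <- feccnet:::g_add(g, "conv", g$last_id, in_ch = 1L, out_ch = 32L,
                       k = 3L, bias = TRUE)
  g <- feccnet:::with_seed(1, feccnet:::g_init_params(g))
  expect_equal(sum(vapply(g$params, length, numeric(1))), 3 * 3 * 32 + 32)
  # a batch-norm layer adds 2C trainable scalars
  b <- new_block("conv", 4, 8)
  expect_equal(count_parameters(b), 3 * 3 * 4 * 8 + 2 * 8)
})

test_that("network builds are deterministic and monotone in width", {
  cfg <- tiny_cfg(16)
  n1 <- build_fecc_net(cfg, seed = 9)
  n2 <- build_fecc_net(cfg, seed = 9)
  expect_identical(n1$graph$params, n2$graph$params)
  img <- matrix(runif(256, 0, 255), 16, 16)
  expect_identical(predict_prob(n1, img), predict_prob(n2, img))
  n3 <- build_fecc_net(cfg, seed = 10)
  expect_false(identical(n1$graph$params, n3$graph$params))
  # doubling the channel schedule strictly increases the parameter count
  cfg2 <- cfg
  cfg2$channel_schedule <- cfg$channel_schedule * 2L
  cfg2$enhanced_channels <- cfg$enhanced_channels * 2L
  expect_gt(count_parameters(build_fecc_net(cfg2, seed = 1)),
            count_parameters(n1))
})

test_that("lite variant is a strict parameter subset of the full network", {
  cfg <- tiny_cfg(16)
  full <- build_fecc_net(cfg, seed = 1)
  lite <- build_fecc_net_lite(cfg, seed = 1)
  expect_lt(count_parameters(lite), count_parameters(full))
  expect_equal(lite$variant, "lite")
  img <- matrix(runif(256, 0, 255), 16, 16)
  p <- predict_prob(lite, img)
  expect_equal(dim(p), c(16, 16))
  expect_true(all(p > 0 & p < 1))
})

test_that("the enhanced encoder emits one map per level at halved resolutions", {
  cfg <- tiny_cfg(32)
  enc <- build_enhanced_encoder(cfg, seed = 1)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  maps <- feccnet:::forward_maps(enc, img)
  expect_length(maps, cfg$depth)
  for (l in seq_len(cfg$depth)) {
    expect_equal(dim(maps[[l]])[1:2], rep(32 / 2^l, 2))
    expect_equal(dim(maps[[l]])[3], cfg$enhanced_channels[l])
  }
  # its depthwise-separable stacks undercut the same topology in full convs
  dw_kernels <- sum(vapply(
    enc$graph$params[grep("_W$", names(enc$graph$params))], length,
    numeric(1)))
  full_equiv <- sum({
    ch <- c(cfg$input_channels, cfg$enhanced_channels)
    9 * ch[1] * ch[2] + 9 * ch[2] * ch[2] +  # stem convs
      sum(9 * ch[2:4] * ch[3:5])             # one 3x3 conv per dwsep block
  })
  expect_lt(dw_kernels, full_equiv)
})

test_that("invalid configurations are rejected", {
  expect_error(fecc_config(input_size = 100), "divisible")
  expect_error(fecc_config(channel_schedule = c(32, 16, 64, 128)),
               "increasing")
  expect_error(fecc_config(channel_schedule = c(8, 16, 32)), "one entry")
  expect_error(fecc_config(aspp_rates = c(2, 2)), "distinct")
  expect_error(fecc_config(threshold = 1.2), "threshold")
  expect_error(fecc_config(channel_schedule = c(12, 24, 36, 48)),
               "divisible by se_reduction")
  net <- build_fecc_net(tiny_cfg(16), seed = 1)
  expect_error(predict_prob(net, matrix(0, 15, 15)), "divisible|square")
})

test_that("checkpoints round-trip through disk with identical predictions", {
  net <- build_fecc_net(tiny_cfg(16), seed = 4)
  img <- matrix(runif(256, 0, 255), 16, 16)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$total_parameters, count_parameters(net))
  back <- load_checkpoint(path)
  expect_identical(predict_prob(back, img), predict_prob(net, img))
  expect_error(load_checkpoint(tempfile()), "not found")
})
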