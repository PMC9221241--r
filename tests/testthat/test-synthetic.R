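test_that("generated slices honour their stratum pixel budgets", {
  cfg <- synth_config(image_size = 64, seed = 2)
  counts <- list(lesion_free = c(0, 0), small = c(1, 99),
                 medium = c(100, 999), large = c(1000, Inf))
  for (st in names(counts)) {
    for (seed in c(3, 14, 159)) {
      rec <- generate_slice(cfg, st, seed = seed)
      n <- sum(rec$mask[[1]])
      expect_gte(n, counts[[st]][1])
      expect_lte(n, counts[[st]][2])
      expect_equal(stratify_by_lesion_size(rec$mask[[1]]), st)
    }
  }
})

test_that("slice records satisfy their invariants", {
  cfg <- synth_config(image_size = 64, seed = 5)
  for (st in c("lesion_free", "medium", "large")) {
    rec <- generate_slice(cfg, st, seed = 11)
    img <- rec$image[[1]]; msk <- rec$mask[[1]]
    expect_equal(dim(img), dim(msk))
    expect_true(all(msk %in% c(0, 1)))
    expect_true(all(img >= 0 & img <= 255))
    expect_true(all(is.finite(img)))
  }
})

test_that("lesions are darker than their local tissue background", {
  cfg <- synth_config(image_size = 64, seed = 6)
  for (seed in c(21, 22, 23)) {
    rec <- generate_slice(cfg, "large", seed = seed)
    img <- rec$image[[1]]; msk <- rec$mask[[1]]
    # local background: three dilation rings of tissue around the lesion
    region <- msk == 1
    ring <- matrix(FALSE, 64, 64)
    for (i in 1:3) {
      px <- feccnet:::ring_pixels(region | ring, msk == 0 & !ring, 64L)
      ring[px] <- TRUE
    }
    expect_gte(mean(img[ring]) - mean(img[region]),
               cfg$lesion_intensity_drop / 2)
  }
})

test_that("slice generation is bit-reproducible for a fixed seed", {
  cfg <- synth_config(image_size = 64, seed = 1)
  a <- generate_slice(cfg, "medium", seed = 33)
  b <- generate_slice(cfg, "medium", seed = 33)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_slice(cfg, "medium", seed = 34)
  expect_false(identical(a$mask, c$mask))
})

test_that("datasets allocate strata exactly and round-trip the labels", {
  cfg <- synth_config(image_size = 64, n_slices = 20,
                      stratum_mix = c(lesion_free = 0.4, small = 0.2,
                                      medium = 0.2, large = 0.2), seed = 4)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds), 20)
  tab <- table(ds$stratum)
  expect_equal(unname(tab[c("lesion_free", "small", "medium", "large")]),
               c(8L, 4L, 4L, 4L), ignore_attr = TRUE)
  for (i in seq_len(nrow(ds))) {
    expect_equal(stratify_by_lesion_size(ds$mask[[i]]), ds$stratum[i])
  }
  expect_equal(length(unique(ds$case_id)), 2L)  # 20 slices / 10 per case
})

test_that("written datasets have identical manifests under one seed", {
  cfg <- synth_config(image_size = 32, n_slices = 6,
                      stratum_mix = c(lesion_free = 0.5, small = 0.25,
                                      medium = 0.25, large = 0), seed = 12)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  sum1 <- unname(tools::md5sum(file.path(d1, "manifest.csv")))
  sum2 <- unname(tools::md5sum(file.path(d2, "manifest.csv")))
  expect_equal(sum1, sum2)
  cfg$seed <- 13L
  generate_dataset(cfg, dir = d3)
  expect_false(identical(sum1,
                         unname(tools::md5sum(file.path(d3,
                                                        "manifest.csv")))))
})

test_that("the NIfTI stack written alongside a dataset is loadable", {
  cfg <- synth_config(image_size = 32, n_slices = 4,
                      stratum_mix = c(lesion_free = 0.5, small = 0.5,
                                      medium = 0, large = 0), seed = 3)
  d <- tempfile()
  ds <- generate_dataset(cfg, dir = d, nifti = TRUE)
  vol <- load_volume(file.path(d, "stack.nii.gz"))
  expect_equal(dim(vol$data), c(32, 32, 4))
  expect_equal(vol$data[, , 2], ds$image[[2]], tolerance = 1e-4)
})

test_that("infeasible budgets raise configuration errors", {
  cfg <- synth_config(image_size = 16, seed = 1)
  expect_error(generate_slice(cfg, "large", seed = 1), "infeasible")
  expect_error(synth_config(stratum_mix = c(lesion_free = 0.5, small = 0.5,
                                            medium = 0.5, large = 0)),
               "sum to 1")
  expect_error(synth_config(image_size = 8), ">= 16")
})
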