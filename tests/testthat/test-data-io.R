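make_nifti_pair <- function(dims = c(8, 8, 4), seed = 1) {
  set.seed(seed)
  # whole numbers survive the single-precision on-disk representation
  vol <- array(round(runif(prod(dims), 0, 1000)), dims)
  msk <- array(rbinom(prod(dims), 1, 0.2), dims)
  dir <- tempfile()
  dir.create(dir)
  vp <- file.path(dir, "t1.nii.gz")
  mp <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), vp)
  RNifti::writeNifti(RNifti::asNifti(msk), mp)
  list(vol = vol, msk = msk, vp = vp, mp = mp, dir = dir)
}

test_that("NIfTI volumes round-trip bit-exact, gz or plain", {
  fx <- make_nifti_pair()
  v <- load_volume(fx$vp)
  expect_s3_class(v, "fecc_volume")
  expect_equal(v$data, fx$vol, tolerance = 1e-12)
  plain <- file.path(fx$dir, "t1.nii")
  RNifti::writeNifti(RNifti::asNifti(fx$vol), plain)
  expect_equal(load_volume(plain)$data, v$data)
  # malformed input fails loudly
  bad <- file.path(fx$dir, "bad.nii")
  writeBin(as.raw(1:64), bad)
  expect_error(load_volume(bad), "NIfTI")
  expect_error(load_volume(file.path(fx$dir, "missing.nii")), "no such")
})

test_that("axial slicing yields one conserving slice per axial index", {
  fx <- make_nifti_pair(c(8, 8, 4))
  recs <- extract_axial_slices(load_volume(fx$vp), load_volume(fx$mp))
  expect_equal(nrow(recs), 4)
  rng <- range(fx$vol)
  for (k in 1:4) {
    # voxel values conserved up to the volume-level [0,255] rescale
    expect_equal(recs$image[[k]],
                 (fx$vol[, , k] - rng[1]) / diff(rng) * 255,
                 tolerance = 1e-10)
    expect_true(all(recs$mask[[k]] %in% c(0, 1)))
    expect_equal(recs$mask[[k]], fx$msk[, , k])
  }
  # an ATLAS-sized case yields one slice per axial index
  big <- array(0, c(233, 197, 189))
  recs_big <- extract_axial_slices(big, big, case_id = "case01")
  expect_equal(nrow(recs_big), 189)
  expect_error(extract_axial_slices(fx$vol, array(0, c(8, 8, 5))),
               "identical dimensions")
})

test_that("resizing keeps masks binary and scales pixel counts as expected", {
  sq <- matrix(0, 32, 32)
  sq[12:21, 12:21] <- 1   # centered 10x10 square, 100 px
  rec <- tibble::tibble(case_id = "c", slice_index = 1L,
                        stratum = stratify_by_lesion_size(sq),
                        image = list(sq * 255), mask = list(sq))
  same <- resize_record(rec, 32)
  expect_equal(same$mask[[1]], sq)
  up <- resize_record(rec, 64)
  expect_true(all(up$mask[[1]] %in% c(0, 1)))
  expect_equal(sum(up$mask[[1]]), 400)   # exact under nearest-neighbour 2x
  expect_equal(up$stratum, "medium")
  down <- resize_record(rec, 16)
  expect_true(all(down$mask[[1]] %in% c(0, 1)))
})

test_that("case-level splitting is a deterministic 8:1:1 partition", {
  recs <- tibble::tibble(
    case_id = rep(sprintf("case%02d", 1:10), each = 3),
    slice_index = rep(1:3, 10),
    image = replicate(30, matrix(0, 4, 4), simplify = FALSE),
    mask = replicate(30, matrix(0, 4, 4), simplify = FALSE))
  sp <- split_dataset(recs, seed = 7)
  cases <- table(unique(sp[, c("case_id", "split")])$split)
  expect_equal(unname(cases), c(8L, 1L, 1L), ignore_attr = TRUE)
  # all slices of one case share a partition
  per_case <- tapply(as.character(sp$split), sp$case_id,
                     function(x) length(unique(x)))
  expect_true(all(per_case == 1))
  # exhaustive and reproducible
  expect_false(any(is.na(sp$split)))
  sp2 <- split_dataset(recs, seed = 7)
  expect_identical(sp$split, sp2$split)
  sp3 <- split_dataset(recs, seed = 8)
  expect_false(identical(sp$split, sp3$split))
  # slice-level splitting allocates by slice count
  sl <- split_dataset(recs, seed = 7, unit = "slice")
  expect_equal(unname(table(sl$split)), c(24L, 3L, 3L), ignore_attr = TRUE)
  expect_error(split_dataset(recs, ratios = c(0.5, 0.2, 0.2)), "summing")
})

test_that("augmentation keeps image and mask geometrically aligned", {
  cfg <- synth_config(image_size = 64, seed = 2)
  rec <- generate_slice(cfg, "large", seed = 5)
  # encode the mask as the image so both channels see the same transform
  probe <- rec
  probe$image[[1]] <- rec$mask[[1]] * 255
  aug <- augment_record(probe, seed = 99, noise_sd = 0)
  img_mask <- (aug$image[[1]] > 127) + 0
  expect_gte(dsc(aug$mask[[1]], img_mask), 0.95)
  expect_true(all(aug$mask[[1]] %in% c(0, 1)))
})

test_that("zero-angle rotation and zero-amplitude elastic transform are identity", {
  cfg <- synth_config(image_size = 32, seed = 3)
  rec <- generate_slice(cfg, "medium", seed = 8)
  aug <- augment_record(rec, seed = 4, rotation_range = 0,
                        elastic_alpha = 0, noise_sd = 0, p = 1)
  expect_equal(aug$image[[1]], rec$image[[1]], tolerance = 1e-10)
  expect_equal(aug$mask[[1]], rec$mask[[1]])
})

test_that("default elastic deformation moves a large blob's area by < 20%", {
  cfg <- synth_config(image_size = 64, seed = 4)
  for (seed in c(1, 2, 3)) {
    rec <- generate_slice(cfg, "large", seed = seed)
    n0 <- sum(rec$mask[[1]])
    aug <- augment_record(rec, seed = seed + 50, rotation_range = 0,
                          noise_sd = 0, p = 1)
    expect_lt(abs(sum(aug$mask[[1]]) - n0) / n0, 0.2)
  }
})

test_that("Gaussian corruption has the requested scale and bounds", {
  img <- matrix(128, 512, 512)
  expect_identical(add_gaussian_noise(img, 0), img)
  noisy <- add_gaussian_noise(img, 40, seed = 6)
  expect_true(all(noisy >= 0 & noisy <= 255))
  expect_lt(abs(sd(noisy - img) - 40) / 40, 0.05)
  expect_identical(add_gaussian_noise(img, 40, seed = 6), noisy)
  expect_error(add_gaussian_noise(img, -1), "non-negative")
})

test_that("the PNG + CSV dataset layout round-trips", {
  cfg <- synth_config(image_size = 32, n_slices = 4,
                      stratum_mix = c(lesion_free = 0.25, small = 0.5,
                                      medium = 0.25, large = 0), seed = 9)
  ds <- generate_dataset(cfg)
  dir <- tempfile()
  write_slice_dataset(ds, dir)
  back <- read_slice_dataset(dir)
  expect_equal(nrow(back), 4)
  expect_equal(back$stratum, ds$stratum)
  for (i in 1:4) {
    expect_identical(back$mask[[i]], ds$mask[[i]])
    # 8-bit PNG quantization bounds the intensity error
    expect_lt(max(abs(back$image[[i]] - ds$image[[i]])), 0.51)
  }
  expect_error(read_slice_dataset(tempfile()), "manifest")
})
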