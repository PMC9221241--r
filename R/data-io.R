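# Reading ATLAS-style NIfTI volumes, slicing, resizing, splitting and
# augmenting 2D slice datasets.

#' Load a NIfTI volume
#'
#' @param path A `.nii` or `.nii.gz` file.
#' @return A `fecc_volume`: list with `data` (rank-3 array), `spacing`
#'   (voxel sizes, mm), `affine` (4x4 orientation matrix) and `path`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (length(dim(img)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  }
  data <- array(as.numeric(img), dim(img))  # plain array, no NIfTI attrs
  structure(list(data = data,
                 spacing = RNifti::pixdim(img),
                 affine = structure(RNifti::xform(img), class = NULL),
                 path = path),
            class = "fecc_volume")
}

#' Extract axial 2D slices from an image/mask volume pair
#'
#' The axial axis is the third array axis, so a volume of extent
#' `X x Y x Z` yields `Z` slices. Image intensities are min-max rescaled to
#' [0, 255] per volume before slicing; the mask is binarized at 0.5. No
#' interpolation happens along the way: voxel values are conserved.
#'
#' @param vol,mask_vol `fecc_volume` objects (or plain 3D arrays) of
#'   identical dimensions.
#' @param case_id Identifier stored with every slice; defaults to the image
#'   file name.
#' @return Slice tibble: `case_id`, `slice_index`, `stratum`, `image`,
#'   `mask`.
#' @export
extract_axial_slices <- function(vol, mask_vol, case_id = NULL) {
  vd <- if (inherits(vol, "fecc_volume")) vol$data else vol
  md <- if (inherits(mask_vol, "fecc_volume")) mask_vol$data else mask_vol
  if (!identical(dim(vd), dim(md))) {
    stop("image and mask volumes must have identical dimensions",
         call. = FALSE)
  }
  case_id <- case_id %||%
    (if (inherits(vol, "fecc_volume")) basename(vol$path) else "volume")
  rng <- range(vd)
  vd <- if (diff(rng) > 0) (vd - rng[1L]) / diff(rng) * 255 else vd * 0
  nz <- dim(vd)[3L]
  images <- purrr::map(seq_len(nz), function(k) vd[, , k])
  masks <- purrr::map(seq_len(nz), function(k) (md[, , k] > 0.5) + 0)
  tibble::tibble(
    case_id = case_id,
    slice_index = seq_len(nz),
    stratum = vapply(masks, function(m) stratum_of_count(sum(m)),
                     character(1)),
    image = images,
    mask = masks)
}

#' Resize a slice record
#'
#' The image is resampled bilinearly; the mask with nearest neighbour and
#' re-binarized, and the stratum label is recomputed on the resized mask
#' (a lesion can change stratum when its pixel count scales).
#'
#' @param record One-row slice tibble.
#' @param size Target side length.
#' @return The resized one-row tibble.
#' @export
resize_record <- function(record, size) {
  stopifnot(nrow(record) == 1L, size >= 1)
  img <- EBImage::imageData(EBImage::resize(record$image[[1L]], w = size,
                                            h = size))
  msk <- EBImage::imageData(EBImage::resize(record$mask[[1L]], w = size,
                                            h = size, filter = "none"))
  msk <- (msk > 0.5) + 0
  record$image[[1L]] <- img
  record$mask[[1L]] <- msk
  record$stratum <- stratum_of_count(sum(msk))
  record
}

#' @rdname resize_record
#' @param records Slice tibble (any number of rows).
#' @export
resize_slices <- function(records, size) {
  rows <- purrr::map(seq_len(nrow(records)),
                     function(i) resize_record(records[i, ], size))
  dplyr::bind_rows(rows)
}

#' Train/validation/test split
#'
#' Deterministic seeded partition with largest-remainder allocation of the
#' ratios. With `unit = "case"` (default) all slices of a case land in the
#' same partition — the leakage-safe choice for multi-slice patients; with
#' `unit = "slice"` slices are shuffled individually.
#'
#' @param records Slice tibble with a `case_id` column.
#' @param ratios Train/val/test proportions, summing to 1 (default 8:1:1).
#' @param seed Shuffle seed.
#' @param unit `"case"` or `"slice"`.
#' @return `records` with a `split` column
#'   (factor: `train`/`val`/`test`).
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          unit = c("case", "slice")) {
  unit <- match.arg(unit)
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no records to split", call. = FALSE)
  keys <- if (unit == "case") unique(records$case_id) else
    seq_len(nrow(records))
  n <- length(keys)
  counts <- largest_remainder(stats::setNames(ratios,
                                              c("train", "val", "test")), n)
  # tiny datasets: every partition with a positive ratio gets at least one
  # unit, taken from the largest partition, while that leaves it non-empty
  for (nm in names(counts)) {
    big <- which.max(counts)
    if (ratios[match(nm, names(counts))] > 0 && counts[nm] == 0 &&
        counts[big] >= 2) {
      counts[big] <- counts[big] - 1L
      counts[nm] <- 1L
    }
  }
  keys <- with_seed(seed, sample(keys))
  lab <- rep(names(counts), counts)
  map <- stats::setNames(lab, keys)
  assign_key <- if (unit == "case") records$case_id else
    as.character(seq_len(nrow(records)))
  records$split <- factor(unname(map[as.character(assign_key)]),
                          levels = c("train", "val", "test"))
  records
}

# ---- geometric warping ------------------------------------------------------

#' Sample `img` at source coordinates (sr, sc) with bilinear interpolation,
#' clamping to the border.
#' @noRd
warp_bilinear <- function(img, sr, sc) {
  H <- nrow(img); W <- ncol(img)
  sr <- pmin(pmax(sr, 1), H)
  sc <- pmin(pmax(sc, 1), W)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  wr <- sr - r0; wc <- sc - c0
  g <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
  v <- (1 - wr) * (1 - wc) * g(r0, c0) + wr * (1 - wc) * g(r1, c0) +
    (1 - wr) * wc * g(r0, c1) + wr * wc * g(r1, c1)
  matrix(v, H, W)
}

#' @noRd
warp_nearest <- function(img, sr, sc) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(round(sr), 1), H)
  c <- pmin(pmax(round(sc), 1), W)
  matrix(img[cbind(as.vector(r), as.vector(c))], H, W)
}

#' Random augmentation of one slice record
#'
#' Randomly applies a subset of \{rotation within `rotation_range` degrees,
#' elastic deformation, additive Gaussian intensity noise\}. Image and mask
#' share the same geometric transform (the image is sampled bilinearly, the
#' mask with nearest neighbour and re-binarized); intensity noise touches
#' the image only.
#'
#' @param record One-row slice tibble.
#' @param seed Seed for this augmentation draw.
#' @param rotation_range Max absolute rotation (degrees).
#' @param elastic_alpha Peak elastic displacement (pixels).
#' @param elastic_sigma Smoothness of the elastic displacement field
#'   (pixels).
#' @param noise_sd Intensity noise standard deviation ([0, 255] scale).
#' @param p Probability of applying each of the three transforms.
#' @return The augmented one-row tibble (stratum recomputed).
#' @export
augment_record <- function(record, seed = 1L, rotation_range = 15,
                           elastic_alpha = 2.5, elastic_sigma = 8,
                           noise_sd = 10, p = 0.5) {
  stopifnot(nrow(record) == 1L)
  img <- record$image[[1L]]
  msk <- record$mask[[1L]]
  S <- nrow(img)
  with_seed(seed, {
    do_rot <- stats::runif(1) < p
    do_ela <- stats::runif(1) < p
    do_noi <- stats::runif(1) < p
    rg <- matrix(rep(seq_len(S), S), S, S)        # row coordinate
    cg <- matrix(rep(seq_len(S), each = S), S, S) # column coordinate
    sr <- rg; sc <- cg
    if (do_rot) {
      ang <- stats::runif(1, -rotation_range, rotation_range) * pi / 180
      ctr <- (S + 1) / 2
      sr <- ctr + cos(ang) * (rg - ctr) - sin(ang) * (cg - ctr)
      sc <- ctr + sin(ang) * (rg - ctr) + cos(ang) * (cg - ctr)
    }
    if (do_ela) {
      dr <- elastic_alpha * smooth_field(S, elastic_sigma)
      dc <- elastic_alpha * smooth_field(S, elastic_sigma)
      sr <- sr + dr
      sc <- sc + dc
    }
    if (do_rot || do_ela) {
      img <- warp_bilinear(img, sr, sc)
      msk <- (warp_nearest(msk, sr, sc) > 0.5) + 0
    }
    if (do_noi) {
      img <- add_gaussian_noise(img, noise_sd)
    }
    record$image[[1L]] <- img
    record$mask[[1L]] <- msk
    record$stratum <- stratum_of_count(sum(msk))
    record
  })
}

#' Corrupt an image with additive Gaussian noise
#'
#' Adds i.i.d. `N(0, sigma^2)` per pixel on the [0, 255] intensity scale and
#' clips back to [0, 255]. `sigma = 0` is the identity. The robustness
#' experiments use `sigma = 40`.
#'
#' @param image Intensity matrix on [0, 255].
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Optional seed for a reproducible draw.
#' @return The corrupted matrix.
#' @export
add_gaussian_noise <- function(image, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(image)
  noise_expr <- function() {
    pmin(pmax(image + stats::rnorm(length(image), 0, sigma), 0), 255)
  }
  out <- if (is.null(seed)) noise_expr() else with_seed(seed, noise_expr())
  matrix(out, nrow(image), ncol(image))
}

# ---- on-disk slice layout ---------------------------------------------------

#' Write / read a slice dataset as PNG pairs plus a CSV manifest
#'
#' Layout: `images/NNNN.png`, `masks/NNNN.png` and `manifest.csv` with
#' columns `case_id`, `slice_index`, `stratum`, `image_path`, `mask_path`
#' (plus `split` when present).
#'
#' @param records Slice tibble.
#' @param dir Dataset directory.
#' @return `write_slice_dataset()`: the records with path columns added;
#'   `read_slice_dataset()`: the slice tibble reassembled from disk.
#' @export
write_slice_dataset <- function(records, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- nrow(records)
  img_paths <- file.path(dir, "images", sprintf("%04d.png", seq_len(n)))
  msk_paths <- file.path(dir, "masks", sprintf("%04d.png", seq_len(n)))
  for (i in seq_len(n)) {
    png::writePNG(records$image[[i]] / 255, img_paths[i])
    png::writePNG(records$mask[[i]], msk_paths[i])
  }
  records$image_path <- img_paths
  records$mask_path <- msk_paths
  manifest <- dplyr::select(records, -dplyr::any_of(c("image", "mask")))
  # manifest paths are dataset-relative, so a dataset directory can move
  # (and two seeded writes are byte-identical wherever they land)
  manifest$image_path <- file.path("images", basename(img_paths))
  manifest$mask_path <- file.path("masks", basename(msk_paths))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  records
}

#' @rdname write_slice_dataset
#' @export
read_slice_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    stop("no manifest.csv under ", dir, call. = FALSE)
  }
  man <- tibble::as_tibble(utils::read.csv(man_path,
                                           stringsAsFactors = FALSE))
  man$image <- purrr::map(file.path(dir, man$image_path),
                          function(p) png::readPNG(p) * 255)
  man$mask <- purrr::map(file.path(dir, man$mask_path),
                         function(p) (png::readPNG(p) > 0.5) + 0)
  man
}
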