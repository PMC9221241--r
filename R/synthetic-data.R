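# Seeded generator of pseudo-brain slices with ground-truth lesions.
#
# A slice is an elliptical bright "brain" on a dark background with a smooth
# low-frequency intensity texture plus pixel noise, emulating the appearance
# of an axial T1 slice. Lesions are hypo-intense (darker than surrounding
# tissue, as chronic-stroke infarcts appear on T1): irregular blobs grown
# from random-walk seeds, placed inside the brain, with the total foreground
# pixel count sampled exactly within the requested stratum's interval.

#' Synthetic dataset configuration
#'
#' @param image_size Side of the square slice (>= 16). 512 matches the
#'   network's native resolution; tests use 64.
#' @param n_slices Number of slices in a generated dataset.
#' @param stratum_mix Named proportions over
#'   `lesion_free`/`small`/`medium`/`large`, summing to 1.
#' @param lesion_intensity_drop Contrast between a lesion pixel and the local
#'   (smoothed) brain intensity, on the [0, 255] scale. Every lesion pixel is
#'   at least `lesion_intensity_drop / 2` darker than its local background.
#' @param texture_noise_sd Per-pixel Gaussian texture noise (intensity units).
#' @param n_lesions_range Integer pair: min/max number of lesion blobs per
#'   lesion-bearing slice (the pixel budget is split among them).
#' @param slices_per_case Slices grouped under one pseudo-case id, so
#'   case-level splitting is exercised.
#' @param seed Master seed; every slice derives its own stream from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(image_size = 512L,
                         n_slices = 100L,
                         stratum_mix = c(lesion_free = 0.4, small = 0.2,
                                         medium = 0.2, large = 0.2),
                         lesion_intensity_drop = 60,
                         texture_noise_sd = 6,
                         n_lesions_range = c(1L, 3L),
                         slices_per_case = 10L,
                         seed = 1L) {
  if (image_size < 16L) stop("image_size must be >= 16", call. = FALSE)
  if (abs(sum(stratum_mix) - 1) > 1e-8) {
    stop("stratum_mix must sum to 1", call. = FALSE)
  }
  if (!all(stratum_levels %in% names(stratum_mix))) {
    stop("stratum_mix must name all of: ",
         paste(stratum_levels, collapse = ", "), call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 stratum_mix = stratum_mix[stratum_levels],
                 lesion_intensity_drop = lesion_intensity_drop,
                 texture_noise_sd = texture_noise_sd,
                 n_lesions_range = as.integer(n_lesions_range),
                 slices_per_case = as.integer(slices_per_case),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Smooth low-frequency random field on an S x S grid (zero mean, unit-ish
#' amplitude), built by blurring white noise.
#' @noRd
smooth_field <- function(S, sigma) {
  f <- matrix(stats::rnorm(S * S), S, S)
  # brush must be odd-sized and fit inside the image
  radius <- min(2L * ceiling(3 * sigma) + 1L, S - (1L - S %% 2L))
  f <- EBImage::imageData(EBImage::gblur(f, sigma = sigma, radius = radius))
  f / max(stats::sd(f), 1e-8)
}

#' sample() misreads a length-one vector; draw uniformly from lo:hi safely.
#' @noRd
sample_int_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Grow an irregular blob of exactly `target` pixels inside `allowed`.
#'
#' Seeded with a short random walk, then dilated ring by ring
#' (4-neighbourhood); the final ring is subsampled to land exactly on the
#' pixel budget.
#' @noRd
grow_blob <- function(allowed, target, S) {
  inside <- which(allowed)
  if (length(inside) < target) {
    stop("lesion pixel budget infeasible at this image size", call. = FALSE)
  }
  region <- matrix(FALSE, S, S)
  seed_px <- inside[sample.int(length(inside), 1L)]
  region[seed_px] <- TRUE
  count <- 1L
  # random-walk skeleton for irregular shape
  rr <- (seed_px - 1L) %% S + 1L
  cc <- (seed_px - 1L) %/% S + 1L
  walk_len <- min(target - 1L, max(0L, as.integer(target / 3)))
  for (i in seq_len(walk_len)) {
    st <- sample(c(-1L, 1L), 2L, replace = TRUE) *
      sample(c(0L, 1L), 2L, replace = TRUE)
    r2 <- min(max(rr + st[1L], 1L), S)
    c2 <- min(max(cc + st[2L], 1L), S)
    if (allowed[r2, c2]) {
      rr <- r2; cc <- c2
      if (!region[rr, cc]) {
        region[rr, cc] <- TRUE
        count <- count + 1L
      }
    }
  }
  grown <- grow_region(region, allowed, target - count, S)
  if (is.null(grown)) return(NULL)  # boxed in; caller retries elsewhere
  grown
}

#' Add exactly `need` ring pixels to `region` (NULL if it gets boxed in).
#' @noRd
grow_region <- function(region, allowed, need, S) {
  while (need > 0L) {
    ring <- ring_pixels(region, allowed, S)
    if (length(ring) == 0L) return(NULL)
    if (length(ring) > need) {
      ring <- ring[sample.int(length(ring), need)]
    }
    region[ring] <- TRUE
    need <- need - length(ring)
  }
  region
}

#' Linear indices of allowed pixels 4-adjacent to the region.
#' @noRd
ring_pixels <- function(region, allowed, S) {
  nb <- matrix(FALSE, S, S)
  nb[-1, ] <- nb[-1, ] | region[-S, ]
  nb[-S, ] <- nb[-S, ] | region[-1, ]
  nb[, -1] <- nb[, -1] | region[, -S]
  nb[, -S] <- nb[, -S] | region[, -1]
  which(nb & allowed & !region)
}

#' Generate one synthetic slice
#'
#' @param cfg A [synth_config()].
#' @param stratum Requested lesion-size stratum (see
#'   [stratify_by_lesion_size()]).
#' @param seed Seed for this slice; the same seed gives a bit-identical
#'   slice.
#' @return One-row tibble: `case_id`, `slice_index`, `stratum`, `image`
#'   (list-column, [0,255] matrix), `mask` (list-column, \{0,1\} matrix).
#' @export
#' @examples
#' cfg <- synth_config(image_size = 64)
#' rec <- generate_slice(cfg, "medium", seed = 7)
#' sum(rec$mask[[1]])  # within [100, 1000)
generate_slice <- function(cfg, stratum = c("lesion_free", "small", "medium",
                                            "large"),
                           seed = 1L) {
  stratum <- match.arg(stratum)
  S <- cfg$image_size
  with_seed(seed, {
    # brain ellipse
    cx <- S / 2 + stats::runif(1, -0.03, 0.03) * S
    cy <- S / 2 + stats::runif(1, -0.03, 0.03) * S
    rx <- min(stats::runif(1, 0.40, 0.46) * S, S / 2 - 2)
    ry <- min(stats::runif(1, 0.40, 0.46) * S, S / 2 - 2)
    theta <- stats::runif(1, 0, pi)
    xg <- matrix(rep(seq_len(S), each = S), S, S)   # column coordinate
    yg <- matrix(rep(seq_len(S), S), S, S)          # row coordinate
    xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
    yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
    brain <- (xr / rx)^2 + (yr / ry)^2 <= 1

    base <- matrix(8, S, S)
    tissue <- 150 + 20 * smooth_field(S, sigma = S / 8)
    base[brain] <- tissue[brain]

    mask <- matrix(0, S, S)
    if (stratum != "lesion_free") {
      # lesions stay off the brain rim; budgets are capped by that interior
      interior <- brain & ((xr / (rx - 2))^2 + (yr / (ry - 2))^2 <= 1)
      budget_cap <- floor(0.6 * sum(interior))
      target <- switch(stratum,
        small = sample_int_range(1L, min(99L, budget_cap)),
        medium = {
          if (budget_cap < 100L) {
            stop("medium-lesion budget infeasible at image_size = ", S,
                 call. = FALSE)
          }
          sample_int_range(100L, min(999L, budget_cap))
        },
        large = {
          if (budget_cap < 1000L) {
            stop("large-lesion budget infeasible at image_size = ", S,
                 call. = FALSE)
          }
          sample_int_range(1000L, min(2500L, budget_cap))
        })
      n_les <- sample_int_range(cfg$n_lesions_range[1L],
                                cfg$n_lesions_range[2L])
      n_les <- min(n_les, target)
      # random composition of the pixel budget over blobs
      shares <- if (n_les == 1L) target else
        diff(c(0L, sort(sample.int(target - 1L, n_les - 1L)), target))
      for (s in shares) {
        allowed <- interior & mask == 0
        blob <- NULL
        for (attempt in 1:10) {
          blob <- grow_blob(allowed, s, S)
          if (!is.null(blob)) break
        }
        if (is.null(blob)) {
          # pocket too small anywhere: dilate the existing lesion set instead
          grown <- grow_region(mask == 1, allowed, s, S)
          if (is.null(grown)) {
            stop("lesion pixel budget infeasible at this image size",
                 call. = FALSE)
          }
          blob <- grown & mask == 0
        }
        mask[blob] <- 1
      }
    }

    img <- base
    img <- img + cfg$texture_noise_sd * matrix(stats::rnorm(S * S), S, S)
    les <- mask == 1
    if (any(les)) {
      img[les] <- tissue[les] - cfg$lesion_intensity_drop +
        stats::runif(sum(les), -cfg$lesion_intensity_drop / 4,
                     cfg$lesion_intensity_drop / 4)
    }
    img <- pmin(pmax(img, 0), 255)

    tibble::tibble(case_id = NA_character_, slice_index = NA_integer_,
                   stratum = stratum, image = list(img), mask = list(mask))
  })
}

#' Generate a synthetic slice dataset
#'
#' Allocates slices to strata by largest remainder of `cfg$stratum_mix`
#' (exact to within one slice), generates each slice from a per-slice seed
#' derived from `cfg$seed`, and groups slices into pseudo-cases of
#' `cfg$slices_per_case`. Optionally writes the PNG + CSV layout shared with
#' the NIfTI slicing path, plus a NIfTI stack of the images for exercising
#' volume IO.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory: writes `images/NNN.png`,
#'   `masks/NNN.png` and `manifest.csv`; with `nifti = TRUE` also
#'   `stack.nii.gz`.
#' @param nifti Also write the image stack as a NIfTI volume.
#' @return Slice tibble (`case_id`, `slice_index`, `stratum`, `image`,
#'   `mask`, and file paths when written).
#' @export
generate_dataset <- function(cfg, dir = NULL, nifti = FALSE) {
  n <- cfg$n_slices
  counts <- largest_remainder(cfg$stratum_mix, n)
  strata <- rep(names(counts), counts)
  with_seed(cfg$seed, {
    strata <- sample(strata)
    slice_seeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  recs <- purrr::map2(strata, slice_seeds,
                      function(st, sd) generate_slice(cfg, st, seed = sd))
  recs <- dplyr::bind_rows(recs)
  recs$slice_index <- seq_len(n)
  recs$case_id <- sprintf("synth-%03d",
                          (seq_len(n) - 1L) %/% cfg$slices_per_case + 1L)
  recs <- recs[, c("case_id", "slice_index", "stratum", "image", "mask")]
  if (!is.null(dir)) {
    recs <- write_slice_dataset(recs, dir)
    if (nifti) {
      S <- cfg$image_size
      stack <- array(0, c(S, S, n))
      for (i in seq_len(n)) stack[, , i] <- recs$image[[i]]
      RNifti::writeNifti(RNifti::asNifti(stack),
                         file.path(dir, "stack.nii.gz"))
    }
  }
  recs
}

#' Largest-remainder integer allocation of n among proportions p.
#' @noRd
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}
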