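# Pixel-level evaluation and lesion-size stratification.

#' @noRd
check_mask_pair <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)) || length(gt) != length(pred)) {
    stop("gt and pred must have identical shape", call. = FALSE)
  }
  if (any(gt != 0 & gt != 1) || any(pred != 0 & pred != 1)) {
    stop("masks must be binary \\{0,1\\}", call. = FALSE)
  }
  invisible(NULL)
}

#' Pixel confusion counts between two binary masks
#'
#' @param gt,pred Binary \{0,1\} masks of identical shape (lesion = 1).
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`; the four
#'   counts sum to the number of pixels.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
confusion_counts <- function(gt, pred) {
  check_mask_pair(gt, pred)
  tp <- sum(gt == 1 & pred == 1)
  fp <- sum(gt == 0 & pred == 1)
  fn <- sum(gt == 1 & pred == 0)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = length(gt) - tp - fp - fn)
}

#' Segmentation metrics for a single slice
#'
#' `dsc()` is the Dice similarity coefficient `2 tp / (2 tp + fp + fn)`;
#' `iou()` the foreground intersection-over-union `tp / (tp + fp + fn)`;
#' `recall()` is `tp / (tp + fn)` and `precision()` `tp / (tp + fp)`;
#' `miou()` averages the foreground and background IoU of the slice.
#' Degenerate denominators (e.g. comparing two empty masks) return 1 by
#' convention: an empty prediction of an empty truth is a perfect match.
#' Lesion-free slices are excluded from stratified reports anyway.
#'
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' dsc(c(1, 1, 0, 0), c(1, 0, 1, 0))   # 0.5
#' miou(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
dsc <- function(gt, pred) {
  check_mask_pair(gt, pred)
  tp <- sum(gt * pred)
  den <- 2 * tp + sum(pred) - tp + sum(gt) - tp
  if (den == 0) 1 else 2 * tp / den
}

#' @rdname dsc
#' @export
iou <- function(gt, pred) {
  check_mask_pair(gt, pred)
  tp <- sum(gt * pred)
  den <- sum(gt) + sum(pred) - tp
  if (den == 0) 1 else tp / den
}

#' @rdname dsc
#' @export
recall <- function(gt, pred) {
  check_mask_pair(gt, pred)
  tp <- sum(gt * pred)
  if (sum(gt) == 0) 1 else tp / sum(gt)
}

#' @rdname dsc
#' @export
precision <- function(gt, pred) {
  check_mask_pair(gt, pred)
  tp <- sum(gt * pred)
  if (sum(pred) == 0) 1 else tp / sum(pred)
}

#' @rdname dsc
#' @export
miou <- function(gt, pred) {
  fg <- iou(gt, pred)
  bg <- iou(1 - gt, 1 - pred)
  (fg + bg) / 2
}

#' Lesion-size strata
#'
#' Slices are grouped by ground-truth foreground pixel count `c`: `c = 0`
#' lesion-free, `1 <= c < 100` small, `100 <= c < 1000` medium, `c >= 1000`
#' large (half-open intervals, so a 100-pixel lesion is "medium" and a
#' 1000-pixel lesion "large").
#'
#' @param gt Binary ground-truth mask.
#' @return One of `"lesion_free"`, `"small"`, `"medium"`, `"large"`.
#' @export
#' @examples
#' stratify_by_lesion_size(matrix(0, 8, 8))    # lesion_free
stratify_by_lesion_size <- function(gt) {
  if (any(gt != 0 & gt != 1)) stop("mask must be binary", call. = FALSE)
  stratum_of_count(sum(gt))
}

#' Vectorized stratum lookup from foreground pixel counts.
#' @noRd
stratum_of_count <- function(n) {
  cut(n, breaks = c(-Inf, 0.5, 99.5, 999.5, Inf),
      labels = c("lesion_free", "small", "medium", "large")) |>
    as.character()
}

#' @noRd
stratum_levels <- c("lesion_free", "small", "medium", "large")

#' Per-slice metrics for a dataset
#'
#' Runs the network on every slice of `records` and returns one row per
#' slice with its stratum and pixel-level metrics.
#'
#' @param net A `fecc_net` or `fecc_fit`.
#' @param records Slice tibble with list-columns `image` and `mask`
#'   (as produced by [generate_dataset()] or [extract_axial_slices()]).
#' @param threshold Optional override of the binarization threshold.
#' @param batch_size Slices per forward pass.
#' @return Tibble: `case_id`, `slice_index`, `stratum`, `dsc`, `miou`,
#'   `recall`, `precision`.
#' @export
slice_metrics <- function(net, records, threshold = NULL, batch_size = 16L) {
  net <- as_fecc_net(net)
  threshold <- threshold %||% net$cfg$threshold
  n <- nrow(records)
  stopifnot(n > 0)
  S <- nrow(records$image[[1L]])
  res <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- array(0, c(S, S, 1L, length(idx)))
    for (j in seq_along(idx)) x[, , 1L, j] <- records$image[[idx[j]]]
    probs <- predict_prob_batch(net, x)
    for (j in seq_along(idx)) {
      gt <- records$mask[[idx[j]]]
      pm <- (matrix(probs[, , 1L, j], S, S) > threshold) + 0
      res[[idx[j]]] <- tibble::tibble(
        dsc = dsc(gt, pm), miou = miou(gt, pm),
        recall = recall(gt, pm), precision = precision(gt, pm))
    }
  }
  dplyr::bind_cols(
    tibble::tibble(
      case_id = records$case_id %||% NA_character_,
      slice_index = records$slice_index %||% seq_len(n),
      stratum = vapply(records$mask, function(m) stratum_of_count(sum(m)),
                       character(1))),
    dplyr::bind_rows(res))
}

#' Stratified evaluation report
#'
#' Evaluates a network over a slice dataset and reports macro-averaged (mean
#' over slices) DSC, mean IoU, recall and precision per lesion-size stratum,
#' plus an `overall` row over all lesion-bearing slices. Lesion-free slices
#' are counted but excluded from the metric rows; empty strata are absent.
#'
#' @inheritParams slice_metrics
#' @return Tibble: `stratum`, `n_slices`, `dsc`, `miou`, `recall`,
#'   `precision`.
#' @export
evaluate_segmentation <- function(net, records, threshold = NULL,
                                  batch_size = 16L) {
  sm <- slice_metrics(net, records, threshold, batch_size)
  lesioned <- dplyr::filter(sm, .data$stratum != "lesion_free")
  by_stratum <- lesioned |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_slices = dplyr::n(),
                     dsc = mean(.data$dsc), miou = mean(.data$miou),
                     recall = mean(.data$recall),
                     precision = mean(.data$precision),
                     .groups = "drop") |>
    dplyr::arrange(factor(.data$stratum, levels = stratum_levels))
  rows <- by_stratum
  if (nrow(lesioned) > 0) {
    overall <- dplyr::summarise(
      lesioned, stratum = "overall", n_slices = dplyr::n(),
      dsc = mean(.data$dsc), miou = mean(.data$miou),
      recall = mean(.data$recall), precision = mean(.data$precision))
    rows <- dplyr::bind_rows(rows, overall)
  }
  n_free <- sum(sm$stratum == "lesion_free")
  if (n_free > 0) {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(stratum = "lesion_free", n_slices = n_free,
                     dsc = NA_real_, miou = NA_real_, recall = NA_real_,
                     precision = NA_real_))
  }
  rows
}

#' Write an evaluation report to CSV
#'
#' @param report Tibble from [evaluate_segmentation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
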