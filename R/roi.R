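#' Threshold and binarize a probability map
#'
#' Voxels at or above `threshold` become 1, the rest 0. Idempotent on
#' binary input for any threshold in (0, 1\].
#'
#' @param prob_map 3D numeric array with values in \[0, 1\].
#' @param threshold Cutoff in (0, 1).
#' @return 3D integer array of 0/1 (a binary mask).
#' @export
threshold_binarize <- function(prob_map, threshold = 0.9) {
  stopifnot(length(dim(prob_map)) == 3, threshold > 0, threshold < 1)
  array((prob_map >= threshold) * 1L, dim(prob_map))
}

#' Morphological erosion of a binary mask
#'
#' Erodes with a 6-connected (face-adjacent) structuring element: a voxel
#' survives one pass only if it and all six face neighbors are in the
#' mask; voxels on the array boundary are always removed (the outside
#' counts as background). The result is always a subset of the input.
#'
#' @param mask 3D binary array.
#' @param iterations Number of erosion passes (>= 0; 0 is the identity).
#' @return Eroded 3D integer mask.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3, iterations >= 0)
  m <- (mask != 0) * 1L
  d <- dim(m)
  shift1 <- function(a, axis, by) {
    # shift with zero fill along one axis
    out <- array(0L, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (abs(by) >= n) return(out)
    if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
    else if (by < 0) { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
    do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
  }
  for (it in seq_len(iterations)) {
    keep <- m
    for (axis in 1:3) for (by in c(-1L, 1L))
      keep <- keep & shift1(m, axis, by)
    m <- keep * 1L
  }
  array(m, d)
}

#' Mean MWF over a region of interest
#'
#' Arithmetic mean and SD of the map over in-mask voxels, excluding
#' undefined (`NA`) voxels; the excluded count is reported.
#'
#' @param map 3D numeric array (e.g. an MWF map; `NA` = undefined).
#' @param mask 3D binary array of the same shape.
#' @param roi Optional ROI name carried into the result.
#' @return List: `roi`, `mean`, `sd`, `n_voxels` (defined, in-mask),
#'   `n_undefined`.
#' @export
roi_mean <- function(map, mask, roi = "roi") {
  if (!identical(dim(map), dim(mask)))
    stop("map and mask dimensions differ", call. = FALSE)
  vals <- map[mask != 0]
  n_undef <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("mask contains no defined voxels", call. = FALSE)
  list(roi = roi, mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n_voxels = length(vals), n_undefined = n_undef)
}

#' Percentile of in-mask map values
#'
#' Linear-interpolation percentile (type 7 order-statistic interpolation)
#' of the defined in-mask values.
#'
#' @inheritParams roi_mean
#' @param q Percentile in \[0, 100\].
#' @return The percentile value.
#' @export
mask_percentile <- function(map, mask, q) {
  stopifnot(q >= 0, q <= 100)
  if (!identical(dim(map), dim(mask)))
    stop("map and mask dimensions differ", call. = FALSE)
  vals <- map[mask != 0]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("mask contains no defined voxels", call. = FALSE)
  unname(stats::quantile(vals, q / 100, type = 7))
}
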