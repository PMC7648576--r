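# Nuclear / bud-neck segmentation and per-object intensity measurement.
#
# Nuclei are found in the histone-marker channel by a global automatic
# threshold followed by 4-connected component labeling; local background
# is taken from a morphological ring around each nucleus (the pixels
# between an outer and an inner box-dilation of the object), and the
# corrected intensity of a channel is object mean minus ring mean.

#' Segmentation configuration
#'
#' @param method global threshold choice: `"otsu"` (default for nuclear
#'   channels), `"mad"` (median + `k_mad` * MAD; robust when foreground
#'   covers a tiny pixel fraction, as bud-neck spots do), or `"fixed"`.
#' @param threshold fixed threshold value (method `"fixed"`).
#' @param k_mad multiplier for the `"mad"` method.
#' @param min_area,max_area inclusive object-area band in pixels; objects
#'   outside the band are dropped.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(method = c("otsu", "mad", "fixed"), threshold = NULL,
                       k_mad = 6, min_area = 6L, max_area = 400L) {
  method <- match.arg(method)
  if (method == "fixed" && (is.null(threshold) || !is.finite(threshold)))
    stopf("method 'fixed' needs a finite `threshold`")
  if (min_area < 1 || max_area < min_area)
    stopf("need 1 <= min_area <= max_area")
  structure(list(method = method, threshold = threshold, k_mad = k_mad,
                 min_area = as.integer(min_area),
                 max_area = as.integer(max_area)),
            class = "seg_config")
}

# Dilate a binary matrix by `steps` applications of a 3x3 square
# structuring element (equivalently one dilation with a (2*steps+1)^2 box).
dilate_steps <- function(mask, steps) {
  if (steps == 0L) return(mask * 1)
  EBImage::dilate(mask * 1, EBImage::makeBrush(2L * steps + 1L, "box"))
}

auto_threshold <- function(image, config) {
  switch(config$method,
    otsu = {
      rng <- range(image)
      norm <- (image - rng[1]) / diff(rng)
      rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
    },
    mad = {
      scale <- stats::mad(image)
      # a mostly-constant (noise-free) background has MAD 0; fall back to
      # the standard deviation so sparse bright spots still stand out
      if (scale == 0) scale <- stats::sd(image)
      stats::median(image) + config$k_mad * scale
    },
    fixed = config$threshold)
}

segment_channel <- function(image, config, channel_role, note = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a 2-D numeric matrix")
  if (any(!is.finite(image))) stopf("image contains non-finite values")
  stopifnot(inherits(config, "seg_config"))
  empty <- function(thr) structure(
    list(labels = matrix(0L, nrow(image), ncol(image)),
         channel_role = channel_role, threshold = thr,
         border_ids = integer(), note = note),
    class = "label_mask")
  if (diff(range(image)) == 0) return(empty(NA_real_))
  thr <- auto_threshold(image, config)
  mask <- image > thr
  if (!any(mask)) return(empty(thr))
  lab <- EBImage::bwlabel(mask * 1)          # 4-connected components
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= config$min_area & areas <= config$max_area)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  structure(list(labels = lab, channel_role = channel_role, threshold = thr,
                 border_ids = sort(border[border > 0]), note = note),
            class = "label_mask")
}

#' Segment nuclei from the nuclear-marker channel
#'
#' Connected components (4-connectivity) above an automatically chosen
#' global threshold, filtered by the configured area band. Objects that
#' touch the image border are kept but flagged in `border_ids`; downstream
#' pair statistics exclude them by default.
#'
#' A constant image yields zero objects (not an error).
#'
#' @param image 2-D numeric matrix (marker channel).
#' @param config a [seg_config()].
#' @return `label_mask`: list with `labels` (integer matrix, 0 =
#'   background, consecutive positive ids), `channel_role`, `threshold`,
#'   `border_ids`.
#' @export
segment_nuclei <- function(image, config = seg_config()) {
  segment_channel(image, config, "marker")
}

#' Segment nuclei from the reporter channel
#'
#' Same algorithm as [segment_nuclei()] applied to the reporter channel.
#' Only reporter-positive nuclei are visible in this mode: cells with no
#' reporter in either nucleus are invisible and silently excluded from any
#' downstream analysis, which the returned mask records in its `note`.
#'
#' @inheritParams segment_nuclei
#' @return `label_mask` with `channel_role = "reporter"`.
#' @export
segment_reporter_nuclei <- function(image, config = seg_config()) {
  segment_channel(image, config, "reporter",
                  note = paste("reporter-based segmentation: nuclei without",
                               "reporter signal are not detected and are",
                               "excluded from the analysis"))
}

#' Segment bud-neck (Myo1) spots
#'
#' Compact objects above threshold within a small area band. Bud-neck
#' spots occupy a tiny fraction of the image, so the default threshold is
#' the robust median + 6*MAD rule rather than Otsu.
#'
#' @inheritParams segment_nuclei
#' @return `label_mask` with `channel_role = "budneck"`.
#' @export
segment_budneck <- function(image,
                            config = seg_config(method = "mad",
                                                min_area = 2L,
                                                max_area = 40L)) {
  segment_channel(image, config, "budneck")
}

#' Per-object background rings
#'
#' For object k the ring is `dilate^outer(k)` minus `dilate^inner(k)`,
#' additionally minus the inner dilation of every other object (so a
#' neighbouring nucleus never contaminates a background estimate), clipped
#' to the image. One dilation step applies a 3x3 square structuring
#' element. Ring pixel sets of nearby objects may overlap; background is
#' diffuse, so both objects may count the shared pixels.
#'
#' An isolated single-pixel object with the default 2 inner / 4 outer
#' steps has a ring of exactly 9^2 - 5^2 = 56 pixels.
#'
#' @param mask a `label_mask`.
#' @param inner_steps,outer_steps dilation iteration counts,
#'   `0 <= inner_steps < outer_steps`.
#' @return `ring_set`: list with `rings` (per-object integer pixel
#'   indices into the image matrix), `ring_area`, and the step counts.
#' @export
background_ring <- function(mask, inner_steps = 2L, outer_steps = 4L) {
  stopifnot(inherits(mask, "label_mask"))
  inner_steps <- as.integer(inner_steps); outer_steps <- as.integer(outer_steps)
  if (inner_steps < 0L || inner_steps >= outer_steps)
    stopf("need 0 <= inner_steps < outer_steps (got %d, %d)",
          inner_steps, outer_steps)
  lab <- mask$labels
  n_obj <- max(lab, 0L)
  union_inner <- if (n_obj > 0) dilate_steps(lab > 0, inner_steps) > 0
    else matrix(FALSE, nrow(lab), ncol(lab))
  rings <- vector("list", n_obj)
  for (k in seq_len(n_obj)) {
    douter <- dilate_steps(lab == k, outer_steps) > 0
    rings[[k]] <- which(douter & !union_inner)
  }
  structure(list(rings = rings,
                 ring_area = vapply(rings, length, integer(1)),
                 inner_steps = inner_steps, outer_steps = outer_steps),
            class = "ring_set")
}

#' Measure objects across channels
#'
#' For every labeled object and every supplied channel: the mean over the
#' object pixels, the mean over its background ring, and the corrected
#' intensity (object mean minus ring mean). Objects whose ring was fully
#' clipped away (`ring_area = 0`) get `NA` ring and corrected values and
#' are flagged.
#'
#' @param mask a `label_mask`.
#' @param rings the matching [background_ring()] result.
#' @param channels named list of numeric matrices sharing the mask's
#'   shape, e.g. `list(marker = ..., reporter = ...)`.
#' @return data.frame with one row per object: `object_id`, `row`, `col`
#'   (0-based centroid), `area`, `ring_area`, `border` flag, and per
#'   channel `mean_<ch>`, `ring_mean_<ch>`, `corrected_<ch>`.
#' @export
measure_objects <- function(mask, rings, channels) {
  stopifnot(inherits(mask, "label_mask"), inherits(rings, "ring_set"))
  if (!length(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stopf("channels must be a non-empty named list of matrices")
  lab <- mask$labels
  for (ch in names(channels))
    if (!identical(dim(channels[[ch]]), dim(lab)))
      stopf("channel '%s' shape %s does not match mask shape %s", ch,
            paste(dim(channels[[ch]]), collapse = "x"),
            paste(dim(lab), collapse = "x"))
  n_obj <- max(lab, 0L)
  if (length(rings$rings) != n_obj)
    stopf("ring set has %d objects, mask has %d", length(rings$rings), n_obj)
  idx <- which(lab > 0)
  obj <- lab[idx]
  rr <- (idx - 1L) %% nrow(lab)        # 0-based row
  cc <- (idx - 1L) %/% nrow(lab)       # 0-based col
  area <- tabulate(obj, nbins = n_obj)
  out <- data.frame(
    object_id = seq_len(n_obj),
    row = as.numeric(rowsum(rr, obj)) / area,
    col = as.numeric(rowsum(cc, obj)) / area,
    area = area,
    ring_area = rings$ring_area,
    border = seq_len(n_obj) %in% mask$border_ids
  )
  for (ch in names(channels)) {
    img <- channels[[ch]]
    m <- as.numeric(rowsum(img[idx], obj)) / area
    rm <- vapply(rings$rings, function(px)
      if (length(px)) mean(img[px]) else NA_real_, numeric(1))
    out[[paste0("mean_", ch)]] <- m
    out[[paste0("ring_mean_", ch)]] <- rm
    out[[paste0("corrected_", ch)]] <- m - rm
  }
  out
}

#' Match measured objects to ground-truth nuclei
#'
#' Mutual-nearest-centroid matching between a measurement table and a
#' [truth_table()]: a truth nucleus and an object are matched when each is
#' the other's nearest neighbour and they lie within `max_distance`.
#'
#' @param measures output of [measure_objects()].
#' @param truth a [truth_table()] data.frame.
#' @param max_distance maximum centroid distance in pixels.
#' @return `truth` with an extra `object_id` column (`NA` = unmatched).
#' @export
match_objects <- function(measures, truth, max_distance = 3) {
  truth$object_id <- NA_integer_
  if (nrow(measures) == 0 || nrow(truth) == 0) return(truth)
  d <- sqrt(outer(truth$row, measures$row, "-")^2 +
            outer(truth$col, measures$col, "-")^2)
  nn_obj <- apply(d, 1, which.min)           # nearest object per truth
  nn_tru <- apply(d, 2, which.min)           # nearest truth per object
  for (i in seq_len(nrow(truth))) {
    j <- nn_obj[i]
    if (nn_tru[j] == i && d[i, j] <= max_distance)
      truth$object_id[i] <- measures$object_id[j]
  }
  truth
}
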