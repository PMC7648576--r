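# Telophase-pair analysis: reporter-presence threshold calibrated from an
# S-phase reference population, pair formation, category assignment,
# asymmetry index, cumulative pair intensity, and cytokinesis staging.

#' Calibrate the reporter-presence threshold from S-phase nuclei
#'
#' S-phase cells exclude the reporter from their (single) nucleus, so
#' their background-corrected reporter intensities sample the
#' reporter-absent null; a nucleus is called reporter-positive only when
#' its corrected intensity exceeds every plausible null value. The default
#' statistic is the maximum of the reference values, giving a
#' false-presence rate of roughly 1/(n+1) per negative nucleus; a
#' percentile (linearly interpolated) or a user-fixed value are available
#' alternatives.
#'
#' @param reference_values corrected reporter intensities of annotated
#'   S-phase nuclei (ignored for `statistic = "fixed"`).
#' @param statistic `"max"` (default), `"percentile"` or `"fixed"`.
#' @param probability percentile level for `statistic = "percentile"`.
#' @param value threshold for `statistic = "fixed"`.
#' @return `threshold_model`: list with `threshold`, `statistic`,
#'   `probability`, `n_reference` and a `reference_summary`
#'   (median/quartiles of the reference population).
#' @export
calibrate_threshold <- function(reference_values = numeric(),
                                statistic = c("max", "percentile", "fixed"),
                                probability = 0.95, value = NULL) {
  statistic <- match.arg(statistic)
  reference_values <- reference_values[is.finite(reference_values)]
  if (statistic != "fixed" && length(reference_values) < 1L)
    stopf(paste("no S-phase reference values: annotate S-phase cells or",
                "supply a fixed threshold (statistic = 'fixed')"))
  thr <- switch(statistic,
    max = max(reference_values),
    percentile = {
      if (probability < 0 || probability > 1)
        stopf("probability must be in [0, 1]")
      unname(stats::quantile(reference_values, probability, type = 7))
    },
    fixed = {
      if (is.null(value) || !is.finite(value))
        stopf("statistic 'fixed' needs a finite `value`")
      value
    })
  structure(list(
    threshold = thr, statistic = statistic,
    probability = if (statistic == "percentile") probability else NA_real_,
    n_reference = length(reference_values),
    reference_summary = if (length(reference_values))
      summarize_values(reference_values) else NULL
  ), class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("threshold_model: %.4g (%s%s, n_reference = %d)\n",
              x$threshold, x$statistic,
              if (x$statistic == "percentile")
                sprintf(" p = %.3g", x$probability) else "",
              x$n_reference))
  invisible(x)
}

#' Form telophase mother/daughter pairs
#'
#' In annotation mode (`annotation` supplied) pairs are taken verbatim
#' from a table with columns `pair_id`, `mother_object_id`,
#' `daughter_object_id` — the in-silico analog of manually selected
#' telophase cells — and roles are trusted. In heuristic mode, nuclei are
#' paired by mutual nearest centroid within `max_distance`; roles cannot
#' be inferred from geometry (`role_known = FALSE`: the lower object id is
#' stored as "mother" arbitrarily), and unpaired nuclei are dropped with
#' their count recorded in the `n_unpaired` attribute.
#'
#' @param measures [measure_objects()] output.
#' @param annotation optional pair annotation data.frame.
#' @param max_distance heuristic pairing radius, pixels.
#' @param exclude_border drop pairs touching the image border
#'   (heuristic mode).
#' @return data.frame with `pair_id`, `mother_object_id`,
#'   `daughter_object_id`, `role_known`.
#' @export
pair_telophase <- function(measures, annotation = NULL, max_distance = 20,
                           exclude_border = TRUE) {
  if (!is.null(annotation)) {
    need <- c("pair_id", "mother_object_id", "daughter_object_id")
    if (!all(need %in% names(annotation)))
      stopf("annotation needs columns: %s", paste(need, collapse = ", "))
    ids <- c(annotation$mother_object_id, annotation$daughter_object_id)
    missing <- setdiff(ids, measures$object_id)
    if (length(missing))
      stopf("annotation references missing object ids: %s",
            paste(sort(missing), collapse = ", "))
    out <- data.frame(pair_id = annotation$pair_id,
                      mother_object_id = annotation$mother_object_id,
                      daughter_object_id = annotation$daughter_object_id,
                      role_known = TRUE)
    attr(out, "n_unpaired") <- 0L
    return(out)
  }
  cand <- measures
  if (exclude_border) cand <- cand[!cand$border, , drop = FALSE]
  n <- nrow(cand)
  if (n < 2) {
    out <- data.frame(pair_id = integer(), mother_object_id = integer(),
                      daughter_object_id = integer(), role_known = logical())
    attr(out, "n_unpaired") <- n
    return(out)
  }
  d <- sqrt(outer(cand$row, cand$row, "-")^2 +
            outer(cand$col, cand$col, "-")^2)
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  first <- seq_len(n)
  mutual <- nn[nn[first]] == first & first < nn &
    d[cbind(first, nn)] <= max_distance
  i <- which(mutual)
  out <- data.frame(
    pair_id = seq_along(i),
    mother_object_id = pmin(cand$object_id[i], cand$object_id[nn[i]]),
    daughter_object_id = pmax(cand$object_id[i], cand$object_id[nn[i]]),
    role_known = FALSE)
  attr(out, "n_unpaired") <- n - 2L * length(i)
  out
}

#' Asymmetry index of a mother/daughter pair
#'
#' `AI = |daughter - mother| / (daughter + mother)`, computed on
#' background-corrected reporter intensities with negative values clamped
#' to zero. 1 means total asymmetry (all reporter in one nucleus), 0 total
#' symmetry; `NA` when both values are zero (no reporter anywhere, so the
#' index is undefined). Vectorized; symmetric in its arguments and
#' invariant under intensity rescaling.
#'
#' @param mother_value,daughter_value corrected reporter intensities, a.u.
#' @return numeric vector in `[0, 1]` (or `NA`).
#' @export
asymmetry_index <- function(mother_value, daughter_value) {
  m <- pmax(mother_value, 0)
  d <- pmax(daughter_value, 0)
  s <- m + d
  ifelse(s > 0, abs(d - m) / s, NA_real_)
}

#' Cumulative reporter intensity of a pair
#'
#' Sum of the corrected reporter intensities of the two nascent nuclei
#' (negatives clamped to zero): the pair-level total reporter signal.
#'
#' @inheritParams asymmetry_index
#' @return numeric vector, a.u.
#' @export
cumulative_intensity <- function(mother_value, daughter_value) {
  pmax(mother_value, 0) + pmax(daughter_value, 0)
}

#' Classify a pair from its presence calls
#'
#' Presence of the reporter in a nucleus means corrected intensity
#' strictly above the calibrated threshold (the threshold defines nuclei
#' *without* reporter, so equality stays negative). Both present ->
#' `symmetric`; daughter only -> `asymmetric_daughter`; mother only ->
#' `asymmetric_mother`; neither -> `none`. Undefined corrected values give
#' `unknown`. Vectorized.
#'
#' @inheritParams asymmetry_index
#' @param model a [calibrate_threshold()] model.
#' @return character vector of categories.
#' @export
classify_pair <- function(mother_value, daughter_value, model) {
  stopifnot(inherits(model, "threshold_model"))
  pm <- mother_value > model$threshold
  pd <- daughter_value > model$threshold
  out <- ifelse(is.na(pm) | is.na(pd), "unknown",
         ifelse(pm & pd, "symmetric",
         ifelse(pd, "asymmetric_daughter",
         ifelse(pm, "asymmetric_mother", "none"))))
  out
}

#' Classify all pairs and compute their asymmetry statistics
#'
#' Joins corrected reporter intensities onto the pair table, assigns the
#' category under the threshold model, and adds the asymmetry index and
#' cumulative intensity (negative corrected values clamped to zero; the
#' clamped count is recorded in the `n_clamped` attribute).
#'
#' @param pairs [pair_telophase()] output.
#' @param measures [measure_objects()] output.
#' @param model a [calibrate_threshold()] model.
#' @return `pairs` with added columns `mother_corrected`,
#'   `daughter_corrected`, `category`, `ai`, `cumulative`.
#' @export
classify_pairs <- function(pairs, measures, model) {
  look <- function(ids, col)
    measures[[col]][match(ids, measures$object_id)]
  m <- look(pairs$mother_object_id, "corrected_reporter")
  d <- look(pairs$daughter_object_id, "corrected_reporter")
  pairs$mother_corrected <- m
  pairs$daughter_corrected <- d
  pairs$category <- classify_pair(m, d, model)
  pairs$ai <- asymmetry_index(m, d)
  pairs$cumulative <- cumulative_intensity(m, d)
  attr(pairs, "n_clamped") <- sum(c(m, d) < 0, na.rm = TRUE)
  pairs
}

#' Stage pairs relative to cytokinesis from bud-neck signal
#'
#' A pair still showing a bud-neck (Myo1) spot near the midpoint between
#' its two nuclei is `before` cytokinesis; otherwise `after`. With no
#' bud-neck channel analyzed every pair is `unknown`.
#'
#' @param pairs [pair_telophase()] (or [classify_pairs()]) output.
#' @param measures nucleus measurement table (for pair centroids).
#' @param budneck_objects measurement/centroid table of bud-neck objects
#'   with columns `row`, `col`, or `NULL` if the channel was not analyzed.
#' @param max_distance maximum spot-to-midpoint distance, pixels.
#' @return character vector, one stage per pair.
#' @export
stage_cytokinesis <- function(pairs, measures, budneck_objects,
                              max_distance = 15) {
  if (nrow(pairs) == 0) return(character())
  if (is.null(budneck_objects)) return(rep("unknown", nrow(pairs)))
  look <- function(ids, col) measures[[col]][match(ids, measures$object_id)]
  mid_r <- (look(pairs$mother_object_id, "row") +
            look(pairs$daughter_object_id, "row")) / 2
  mid_c <- (look(pairs$mother_object_id, "col") +
            look(pairs$daughter_object_id, "col")) / 2
  if (nrow(budneck_objects) == 0) return(rep("after", nrow(pairs)))
  d <- sqrt(outer(mid_r, budneck_objects$row, "-")^2 +
            outer(mid_c, budneck_objects$col, "-")^2)
  ifelse(apply(d, 1, min) <= max_distance, "before", "after")
}

#' Tally pair categories
#'
#' Counts and fractions per category. `merge_asymmetric` pools
#' `asymmetric_mother` and `asymmetric_daughter` into `asymmetric`, the
#' convention of screen-style reporting; `unknown` pairs are excluded
#' from the denominator.
#'
#' @param categories character vector of pair categories.
#' @param merge_asymmetric pool the two asymmetric orientations.
#' @return data.frame with `category`, `n`, `fraction`.
#' @export
tally_categories <- function(categories, merge_asymmetric = TRUE) {
  categories <- categories[categories != "unknown"]
  if (merge_asymmetric) {
    categories[categories %in%
                 c("asymmetric_mother", "asymmetric_daughter")] <- "asymmetric"
    levels <- c("asymmetric", "symmetric", "none")
  } else {
    levels <- c("asymmetric_daughter", "asymmetric_mother", "symmetric",
                "none")
  }
  n <- vapply(levels, function(l) sum(categories == l), integer(1))
  data.frame(category = levels, n = n,
             fraction = if (length(categories)) n / length(categories)
                        else rep(NA_real_, length(levels)),
             row.names = NULL)
}
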