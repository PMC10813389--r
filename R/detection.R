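#' Detection configuration
#'
#' Converts a probability map into discrete predicted cell centers: threshold
#' the cell-center class probability, label connected components of the
#' resulting binary mask, drop specks below `min_component_px`, and report
#' each surviving component's probability-weighted centroid (sub-pixel).
#'
#' @param prob_threshold Foreground probability threshold in (0, 1).
#' @param min_component_px Minimum component area in pixels (>= 1).
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return `cec_detection_config`.
#' @export
detection_config <- function(prob_threshold = 0.5, min_component_px = 2L,
                             connectivity = 8L) {
  stopifnot(prob_threshold > 0, prob_threshold < 1, min_component_px >= 1,
            connectivity %in% c(4L, 8L))
  structure(list(prob_threshold = prob_threshold,
                 min_component_px = as.integer(min_component_px),
                 connectivity = as.integer(connectivity)),
            class = "cec_detection_config")
}

#' Extract predicted cell centers from a probability map
#'
#' @param pmap A `cec_probability_map` (from [predict_probs()]) or a plain
#'   H x W matrix of foreground probabilities.
#' @param cfg A [detection_config()].
#' @return `cec_detection_result`: list with `image_id` and `centers` (data
#'   frame `x`, `y`, 0-based pixel coordinates at working resolution).
#' @export
extract_centers <- function(pmap, cfg = detection_config()) {
  if (inherits(pmap, "cec_probability_map")) {
    fg <- pmap$probs[, , 2]
    id <- pmap$image_id
  } else {
    stopifnot(is.matrix(pmap))
    fg <- pmap
    id <- ""
  }
  mask <- matrix(as.integer(fg > cfg$prob_threshold), nrow(fg), ncol(fg))
  if (!any(mask == 1L)) {
    return(structure(list(image_id = id,
                          centers = data.frame(x = numeric(0), y = numeric(0))),
                     class = "cec_detection_result"))
  }
  lab <- cpp_label_components(mask, cfg$connectivity)
  labv <- as.vector(lab)
  keepv <- labv > 0
  sizes <- tabulate(labv[keepv])
  keep_ids <- which(sizes >= cfg$min_component_px)
  if (length(keep_ids) == 0) {
    return(structure(list(image_id = id,
                          centers = data.frame(x = numeric(0), y = numeric(0))),
                     class = "cec_detection_result"))
  }
  # probability-weighted centroids per surviving component
  h <- nrow(fg)
  idx <- which(keepv)
  l <- labv[idx]
  w <- as.vector(fg)[idx]
  xs <- (idx - 1) %/% h      # 0-based column
  ys <- (idx - 1) %% h       # 0-based row
  wsum <- rowsum(w, l)[, 1]
  cx <- rowsum(w * xs, l)[, 1] / wsum
  cy <- rowsum(w * ys, l)[, 1] / wsum
  ord <- sort(keep_ids)
  # guard against centroids drifting past the last pixel by rounding error
  structure(list(image_id = id,
                 centers = data.frame(
                   x = clamp(unname(cx[as.character(ord)]), 0, ncol(fg) - 1),
                   y = clamp(unname(cy[as.character(ord)]), 0, nrow(fg) - 1))),
            class = "cec_detection_result")
}
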