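#' Tracker configuration
#'
#' Weights and thresholds of the mapping cost
#' \deqn{d = w_o O + w_c \delta_c + w_s \delta_s,}
#' where \eqn{O} is the overlap metric, \eqn{\delta_c} the centroid-offset
#' metric and \eqn{\delta_s} the size metric, each normalized to `[0, 1]`.
#' Lower cost means a more plausible identity link. A source/target pair
#' with no pixels in common whose raw centroid distance exceeds
#' `max_centroid_distance` is declared pathological and assigned the
#' sentinel `max_cost`; such mappings are invalid by definition and are
#' never chosen by the assignment stage.
#'
#' @param weight_overlap weight \eqn{w_o} of the overlap term (default 2).
#' @param weight_centroid weight \eqn{w_c} of the centroid-offset term
#'   (default 1).
#' @param weight_size weight \eqn{w_s} of the size term (default 0.5).
#' @param max_centroid_distance pathological-filter threshold in raw pixels
#'   (default 50): cells with zero overlap further apart than this can never
#'   be the same cell.
#' @param max_cost sentinel cost marking an invalid mapping; must exceed
#'   `weight_overlap + weight_centroid + weight_size`, the largest cost any
#'   valid mapping can attain.
#' @param frame_interval_min minutes between consecutive frames, used when
#'   converting trajectory path lengths to travel rates (default 15).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(weight_overlap = 2,
                           weight_centroid = 1,
                           weight_size = 0.5,
                           max_centroid_distance = 50,
                           max_cost = 1e9,
                           frame_interval_min = 15) {
  w <- c(weight_overlap, weight_centroid, weight_size)
  if (anyNA(w) || any(w < 0)) {
    mt_validation_error("tracking weights must be non-negative numbers")
  }
  if (!is.numeric(max_centroid_distance) || max_centroid_distance <= 0) {
    mt_validation_error("max_centroid_distance must be > 0 pixels")
  }
  if (!is.numeric(max_cost) || max_cost <= sum(w)) {
    mt_validation_error(sprintf(
      "max_cost (%g) must exceed the maximum attainable valid cost (sum of weights = %g)",
      max_cost, sum(w)))
  }
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    mt_validation_error("frame_interval_min must be > 0")
  }
  structure(list(weight_overlap = weight_overlap,
                 weight_centroid = weight_centroid,
                 weight_size = weight_size,
                 max_centroid_distance = max_centroid_distance,
                 max_cost = max_cost,
                 frame_interval_min = frame_interval_min),
            class = "tracker_config")
}

#' Read a tracker configuration from a JSON file
#'
#' Recognized keys are the arguments of [tracker_config()]; any other key is
#' an error (misspelled keys must not be silently ignored).
#'
#' @param path path to a JSON file of key/value pairs.
#' @return A [tracker_config()].
#' @export
read_tracker_config <- function(path) {
  if (!file.exists(path)) mt_io_error(sprintf("config file '%s' does not exist", path))
  vals <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) mt_format_error(sprintf(
                     "config file '%s' is not valid JSON: %s", path, conditionMessage(e))))
  known <- names(formals(tracker_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    mt_validation_error(sprintf("unknown config key '%s' in '%s' (known keys: %s)",
                                bad[1], path, paste(known, collapse = ", ")))
  }
  do.call(tracker_config, vals)
}

#' @export
print.tracker_config <- function(x, ...) {
  cat(sprintf(paste0("<tracker_config> w_o=%g w_c=%g w_s=%g, ",
                     "max centroid distance %g px, MAX_COST %g, frame interval %g min\n"),
              x$weight_overlap, x$weight_centroid, x$weight_size,
              x$max_centroid_distance, x$max_cost, x$frame_interval_min))
  invisible(x)
}

#' Overlap metric
#'
#' \deqn{O = 1 - \frac{n_o}{2}\left(\frac{1}{s_i} + \frac{1}{s_j}\right)}
#' where \eqn{s_i, s_j} are the source and target pixel counts and
#' \eqn{n_o} the number of pixels the two cells have in common. Equals 0
#' only for a perfect overlap of equal-sized cells, and 1 when the cells
#' share no pixels. Symmetric in source and target; all arguments are
#' vectorized.
#'
#' @param source_size,target_size cell sizes in pixels (>= 1).
#' @param n_overlap shared pixel count, in `[0, min(source_size, target_size)]`.
#' @return Metric value(s) in `[0, 1]`.
#' @export
overlap_metric <- function(source_size, target_size, n_overlap) {
  if (any(source_size < 1) || any(target_size < 1)) {
    mt_validation_error("cell sizes must be >= 1 pixel")
  }
  if (any(n_overlap < 0) || any(n_overlap > pmin(source_size, target_size))) {
    mt_validation_error("n_overlap must lie in [0, min(source_size, target_size)]")
  }
  1 - (n_overlap / 2) * (1 / source_size + 1 / target_size)
}

#' Centroid-offset metric
#'
#' Euclidean distance between the source and target centroids, normalized by
#' the image diagonal \eqn{\sqrt{I_{height}^2 + I_{width}^2}} so that the
#' metric is 1 exactly for a full-diagonal displacement.
#'
#' @param source_centroid,target_centroid numeric `(row, col)` pairs in
#'   pixels, or n-by-2 matrices of such pairs.
#' @param height,width image dimensions in pixels.
#' @return Metric value(s) in `[0, 1]`.
#' @export
centroid_metric <- function(source_centroid, target_centroid, height, width) {
  if (height < 1 || width < 1) mt_validation_error("image dimensions must be >= 1")
  a <- rbind(source_centroid)
  b <- rbind(target_centroid)
  d <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  unname(d / sqrt(height^2 + width^2))
}

#' Size metric
#'
#' Relative size difference \eqn{\delta_s = |s_i - s_j| / \max(s_i, s_j)}:
#' 0 for equal sizes, approaching (never reaching) 1 as sizes diverge.
#'
#' @param source_size,target_size cell sizes in pixels (>= 1); vectorized.
#' @return Metric value(s) in `[0, 1)`.
#' @export
size_metric <- function(source_size, target_size) {
  if (any(source_size < 1) || any(target_size < 1)) {
    mt_validation_error("cell sizes must be >= 1 pixel")
  }
  abs(source_size - target_size) / pmax(source_size, target_size)
}

#' Cost of mapping one source cell to one target cell
#'
#' Applies the pathological filter first: if the pair shares no pixels and
#' the raw (unnormalized) centroid distance exceeds
#' `config$max_centroid_distance`, the mapping gets `config$max_cost` and is
#' invalid. Otherwise the cost is the weighted sum of the three normalized
#' metrics.
#'
#' @param source,target single-row region records as returned by
#'   [extract_regions()] (fields `size`, `row`, `col`), or lists with those
#'   fields.
#' @param n_overlap shared pixel count for this pair.
#' @param config a [tracker_config()].
#' @param height,width image dimensions in pixels.
#' @return A single non-negative cost.
#' @export
pair_cost <- function(source, target, n_overlap, config = tracker_config(),
                      height, width) {
  raw_dist <- sqrt((source$row - target$row)^2 + (source$col - target$col)^2)
  if (n_overlap == 0 && raw_dist > config$max_centroid_distance) {
    return(config$max_cost)
  }
  config$weight_overlap * overlap_metric(source$size, target$size, n_overlap) +
    config$weight_centroid * centroid_metric(c(source$row, source$col),
                                             c(target$row, target$col),
                                             height, width) +
    config$weight_size * size_metric(source$size, target$size)
}

#' Build the full source-by-target cost matrix for a frame pair
#'
#' Entry `(i, j)` is [pair_cost()] for source cell `i` and target cell `j`;
#' pairs absent from the overlap table use `n_overlap = 0`.
#'
#' @param source_regions,target_regions region tables from
#'   [extract_regions()] for frames `k` and `k + 1`.
#' @param overlaps overlap table from [count_overlaps()] for the same pair.
#' @param config a [tracker_config()].
#' @param height,width image dimensions in pixels.
#' @return A numeric matrix of class `cost_matrix` with source labels as row
#'   names, target labels as column names and a `max_cost` attribute.
#' @export
build_cost_matrix <- function(source_regions, target_regions, overlaps,
                              config = tracker_config(), height, width) {
  ns <- nrow(source_regions)
  nt <- nrow(target_regions)
  V <- matrix(numeric(0), ns, nt,
              dimnames = list(source_regions$label, target_regions$label))
  if (ns > 0L && nt > 0L) {
    no <- matrix(0, ns, nt)
    if (nrow(overlaps)) {
      i <- match(overlaps$source_label, source_regions$label)
      j <- match(overlaps$target_label, target_regions$label)
      if (anyNA(i) || anyNA(j)) {
        mt_validation_error("overlap table references labels absent from the region tables")
      }
      no[cbind(i, j)] <- overlaps$overlap
    }
    s1 <- source_regions$size
    s2 <- target_regions$size
    O <- 1 - (no / 2) * outer(1 / s1, 1 / s2, `+`)
    raw_d <- sqrt(outer(source_regions$row, target_regions$row, `-`)^2 +
                  outer(source_regions$col, target_regions$col, `-`)^2)
    dc <- raw_d / sqrt(height^2 + width^2)
    ds <- abs(outer(s1, s2, `-`)) / outer(s1, s2, pmax)
    V <- config$weight_overlap * O + config$weight_centroid * dc +
      config$weight_size * ds
    V[no == 0 & raw_d > config$max_centroid_distance] <- config$max_cost
    dimnames(V) <- list(source_regions$label, target_regions$label)
  }
  structure(V, max_cost = config$max_cost, class = c("cost_matrix", "matrix", "array"))
}
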