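#' Chain frame-to-frame mappings into global track numbers
#'
#' Every cell of frame 1 seeds a track; each link extends the source cell's
#' track onto its target; each unmatched target starts a new track; an
#' unmatched source's track terminates (and never resumes — a cell that
#' disappears and reappears gets a fresh number). Track ids are assigned in
#' order of first appearance, scanning frames in time and labels ascending,
#' so they are 1..T with no gaps.
#'
#' @param sequence a [mask_sequence()].
#' @param mappings list of `N - 1` [frame_mapping()]s, one per consecutive
#'   frame pair, consistent with the labels present in `sequence`.
#' @return A data frame of class `track_table` with one row per cell
#'   appearance: columns `frame`, `track_id`, `label`, `size`, `row`,
#'   `col`; the number of tracks `T` is in attribute `n_tracks`.
#' @export
chain_mappings <- function(sequence, mappings) {
  N <- length(sequence)
  if (length(mappings) != N - 1L) {
    mt_validation_error(sprintf("expected %d frame mappings for %d frames, got %d",
                                N - 1L, N, length(mappings)))
  }
  regions <- lapply(sequence, extract_regions)
  rows <- vector("list", N)

  labels1 <- regions[[1]]$label
  active <- integer(0) # active[as.character(label)] = track id in current frame
  next_track <- 1L
  if (length(labels1)) {
    active <- stats::setNames(seq_along(labels1), labels1)
    next_track <- length(labels1) + 1L
  }
  rows[[1]] <- data.frame(frame = rep(1L, length(labels1)),
                          track_id = unname(active[as.character(labels1)]),
                          regions[[1]][c("label", "size", "row", "col")])

  for (k in seq_len(N - 1L)) {
    m <- mappings[[k]]
    lab_k <- regions[[k]]$label
    lab_k1 <- regions[[k + 1L]]$label
    referenced_src <- c(m$links$source_label, m$unmatched_sources)
    referenced_tgt <- c(m$links$target_label, m$unmatched_targets)
    if (!all(referenced_src %in% lab_k) || !all(referenced_tgt %in% lab_k1)) {
      mt_validation_error(sprintf(
        "mapping for frames %d->%d references labels absent from those frames", k, k + 1L))
    }
    new_active <- integer(0)
    if (nrow(m$links)) {
      inherited <- active[as.character(m$links$source_label)]
      if (anyNA(inherited)) {
        mt_validation_error(sprintf(
          "mapping for frames %d->%d links a source label with no active track", k, k + 1L))
      }
      new_active <- stats::setNames(unname(inherited), m$links$target_label)
    }
    births <- sort(m$unmatched_targets)
    if (length(births)) {
      ids <- seq.int(next_track, length.out = length(births))
      next_track <- next_track + length(births)
      new_active <- c(new_active, stats::setNames(ids, births))
    }
    active <- new_active
    rows[[k + 1L]] <- data.frame(frame = rep(k + 1L, length(lab_k1)),
                                 track_id = unname(active[as.character(lab_k1)]),
                                 regions[[k + 1L]][c("label", "size", "row", "col")])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tracks = next_track - 1L,
            class = c("track_table", "data.frame"))
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d track(s) over %d frame(s), %d cell appearance(s)\n",
              attr(x, "n_tracks") %||% length(unique(x$track_id)),
              length(unique(x$frame)), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Relabel masks with global track numbers
#'
#' Rewrites every frame so that each tracked cell's pixels carry its track
#' id instead of the per-frame cell number: the same cell has the same
#' number through time. Background stays 0 and region geometry is
#' untouched — only pixel values change.
#'
#' @param sequence the original [mask_sequence()].
#' @param table a `track_table` from [chain_mappings()] consistent with
#'   `sequence`.
#' @return A [mask_sequence()] of relabeled masks.
#' @export
relabel_masks <- function(sequence, table) {
  frames <- lapply(seq_along(sequence), function(k) {
    mask <- sequence[[k]]
    m <- as_bare_matrix(mask)
    rows_k <- table[table$frame == k, , drop = FALSE]
    present <- mask_labels(mask)
    if (!all(present %in% rows_k$label)) {
      mt_validation_error(sprintf("track table has no entry for some labels of frame %d", k))
    }
    if (length(present)) {
      lut <- integer(max(present))
      lut[rows_k$label] <- rows_k$track_id
      fg <- m > 0L
      m[fg] <- lut[m[fg]]
    }
    labeled_mask(m, k)
  })
  mask_sequence(frames)
}

#' Track all cells of a mask sequence
#'
#' Runs the full linking pipeline: per-frame region extraction, pairwise
#' overlap counting, cost-matrix construction with pathological filtering,
#' minimum-cost assignment per frame pair, and chaining into global track
#' numbers.
#'
#' @param sequence a [mask_sequence()] (frames are canonicalized if needed).
#' @param config a [tracker_config()].
#' @return A list of class `cell_tracks` with elements `table` (the
#'   [chain_mappings()] track table), `mappings` (per-pair
#'   [frame_mapping()]s), `config`, `height`, `width`.
#' @examples
#' sim <- simulate_sequence(simulation_config(n_frames = 4, n_cells = 3,
#'                                            height = 120, width = 160, seed = 7))
#' tr <- track_cells(sim$sequence)
#' tr$table
#' @export
track_cells <- function(sequence, config = tracker_config()) {
  if (!inherits(sequence, "mask_sequence")) sequence <- mask_sequence(sequence)
  H <- attr(sequence, "height")
  W <- attr(sequence, "width")
  regions <- lapply(sequence, extract_regions)
  mappings <- vector("list", length(sequence) - 1L)
  for (k in seq_len(length(sequence) - 1L)) {
    ov <- count_overlaps(sequence[[k]], sequence[[k + 1L]])
    cm <- build_cost_matrix(regions[[k]], regions[[k + 1L]], ov, config, H, W)
    mappings[[k]] <- solve_mapping(cm, config, frame_pair = c(k, k + 1L))
  }
  table <- chain_mappings(sequence, mappings)
  structure(list(table = table, mappings = mappings, config = config,
                 height = H, width = W),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("<cell_tracks> %d track(s) across %d frame(s) (%d x %d px)\n",
              attr(x$table, "n_tracks"), length(x$mappings) + 1L, x$height, x$width))
  invisible(x)
}

#' Export a track table as CSV
#'
#' Columns: `frame`, `track_id`, `label` (the original per-frame cell
#' number), `centroid_x`, `centroid_y`, `size_px`, with `x` = 0-based
#' column and `y` = 0-based row of the centroid.
#'
#' @param table a `track_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(table, path) {
  df <- data.frame(frame = table$frame, track_id = table$track_id,
                   label = table$label,
                   centroid_x = table$col, centroid_y = table$row,
                   size_px = table$size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_track_table()]
#'
#' @param path CSV path.
#' @return A `track_table` data frame.
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) mt_io_error(sprintf("track table '%s' does not exist", path))
  df <- utils::read.csv(path)
  needed <- c("frame", "track_id", "label", "centroid_x", "centroid_y", "size_px")
  if (!all(needed %in% names(df))) {
    mt_format_error(sprintf("'%s' must have columns %s", path, paste(needed, collapse = ", ")))
  }
  out <- data.frame(frame = as.integer(df$frame), track_id = as.integer(df$track_id),
                    label = as.integer(df$label), size = as.integer(df$size_px),
                    row = df$centroid_y, col = df$centroid_x)
  structure(out, n_tracks = length(unique(out$track_id)),
            class = c("track_table", "data.frame"))
}
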