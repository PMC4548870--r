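#' Configuration of the synthetic mask-sequence generator
#'
#' Describes a scene of non-touching elliptical cells whose centers follow a
#' bounded random walk, emulating segmented time-lapse masks of cultured
#' fibroblast-like cells imaged at a high enough rate that consecutive
#' instances of a cell share pixels — the operating premise of
#' overlap-based linking.
#'
#' Defaults describe a moderate scene on a full-size frame: a 520 x 696
#' image with 10 cells of semi-axes 8–14 px taking per-axis steps of at
#' most 4 px per frame (half the smallest semi-axis, so every cell overlaps
#' its own previous footprint), no size fluctuation and no
#' appearance/disappearance events over 25 frames.
#'
#' @param n_frames number of frames (>= 2).
#' @param height,width frame dimensions in pixels.
#' @param n_cells number of cells placed in frame 1.
#' @param cell_radius_range `c(min, max)` of ellipse semi-axes in pixels;
#'   each cell draws its two semi-axes independently from this range.
#' @param max_step per-axis per-frame displacement bound in pixels (the
#'   walk step is uniform on `[-max_step, max_step]`, reflected at borders).
#' @param size_jitter per-frame fractional area change bound: each frame a
#'   cell's area is scaled by a factor uniform in
#'   `[1 - size_jitter, 1 + size_jitter]` of its base area.
#' @param appear_prob probability per frame (from frame 2 on) that one new
#'   cell enters the scene.
#' @param disappear_prob per-cell per-frame probability of permanently
#'   leaving the scene.
#' @param seed integer RNG seed; the same seed reproduces the sequence
#'   bit for bit.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_frames = 25L, height = 520L, width = 696L,
                              n_cells = 10L, cell_radius_range = c(8, 14),
                              max_step = 4, size_jitter = 0,
                              appear_prob = 0, disappear_prob = 0,
                              seed = 1L) {
  if (n_frames < 2L) mt_validation_error("a simulated sequence needs n_frames >= 2")
  if (height < 1L || width < 1L) mt_validation_error("frame dimensions must be >= 1")
  if (n_cells < 0L) mt_validation_error("n_cells must be >= 0")
  if (length(cell_radius_range) != 2L || any(cell_radius_range < 1) ||
      cell_radius_range[1] > cell_radius_range[2]) {
    mt_validation_error("cell_radius_range must be c(min, max) with 1 <= min <= max")
  }
  if (max_step < 0) mt_validation_error("max_step must be >= 0")
  if (size_jitter < 0 || size_jitter >= 1) mt_validation_error("size_jitter must be in [0, 1)")
  for (p in c(appear_prob, disappear_prob)) {
    if (p < 0 || p > 1) mt_validation_error("event probabilities must lie in [0, 1]")
  }
  structure(list(n_frames = as.integer(n_frames), height = as.integer(height),
                 width = as.integer(width), n_cells = as.integer(n_cells),
                 cell_radius_range = as.numeric(cell_radius_range),
                 max_step = as.numeric(max_step), size_jitter = as.numeric(size_jitter),
                 appear_prob = as.numeric(appear_prob),
                 disappear_prob = as.numeric(disappear_prob),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from a JSON file
#'
#' @param path JSON file whose keys are arguments of [simulation_config()];
#'   unknown keys are an error.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) mt_io_error(sprintf("config file '%s' does not exist", path))
  vals <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) mt_format_error(sprintf(
                     "config file '%s' is not valid JSON: %s", path, conditionMessage(e))))
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    mt_validation_error(sprintf("unknown config key '%s' in '%s' (known keys: %s)",
                                bad[1], path, paste(known, collapse = ", ")))
  }
  do.call(simulation_config, vals)
}

## Reflect a scalar position into [lo, hi].
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  span <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- lo + (lo - x)
    if (x > hi) x <- hi - (x - hi)
  }
  x
}

## Center-distance safety margin between two cells: footprints stay at
## least ~2 px apart even at maximal size jitter.
cell_gap_ok <- function(cy, cx, rmax, ys, xs, rmaxs) {
  if (length(ys) == 0L) return(TRUE)
  all(sqrt((ys - cy)^2 + (xs - cx)^2) >= rmax + rmaxs + 3)
}

#' Simulate a mask sequence with ground-truth identities
#'
#' Places non-touching discretized ellipses and advances them frame by
#' frame with a bounded uniform random walk (reflecting at borders), mild
#' area jitter and optional appearance/disappearance events. Per-frame
#' labels are randomly permuted so that numbering carries no identity
#' information — exactly as independent per-frame segmentation would number
#' cells. Deterministic for a given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list with `sequence` (a [mask_sequence()]) and `truth` (data
#'   frame `frame`, `label`, `cell_id` giving each label's true identity).
#' @examples
#' sim <- simulate_sequence(simulation_config(n_frames = 3, n_cells = 2,
#'                                            height = 80, width = 100, seed = 2))
#' head(sim$truth)
#' @export
simulate_sequence <- function(config = simulation_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  H <- config$height
  W <- config$width
  jit <- config$size_jitter
  rmax_scale <- sqrt(1 + jit) # area factor bound -> linear scale bound

  # live-cell state (parallel vectors)
  id <- integer(0); cy <- numeric(0); cx <- numeric(0)
  ry <- numeric(0); rx <- numeric(0); scale <- numeric(0)
  next_id <- 1L

  draw_radii <- function() stats::runif(2, config$cell_radius_range[1], config$cell_radius_range[2])

  place_cell <- function(tries) {
    r <- draw_radii()
    rmax <- max(r) * rmax_scale
    lo_y <- rmax + 1; hi_y <- H - 2 - rmax
    lo_x <- rmax + 1; hi_x <- W - 2 - rmax
    if (hi_y <= lo_y || hi_x <= lo_x) return(NULL)
    rmaxs <- pmax(ry, rx) * rmax_scale
    for (t in seq_len(tries)) {
      y <- stats::runif(1, lo_y, hi_y)
      x <- stats::runif(1, lo_x, hi_x)
      if (cell_gap_ok(y, x, rmax, cy, cx, rmaxs)) {
        return(list(y = y, x = x, ry = r[1], rx = r[2]))
      }
    }
    NULL
  }

  for (n in seq_len(config$n_cells)) {
    pc <- place_cell(200L)
    if (is.null(pc)) {
      mt_validation_error(sprintf(
        "could not place %d non-touching cells of radius %g-%g in a %dx%d frame; use fewer or smaller cells",
        config$n_cells, config$cell_radius_range[1], config$cell_radius_range[2], H, W))
    }
    id <- c(id, next_id); next_id <- next_id + 1L
    cy <- c(cy, pc$y); cx <- c(cx, pc$x)
    ry <- c(ry, pc$ry); rx <- c(rx, pc$rx)
    scale <- c(scale, 1)
  }

  rasterize <- function() {
    m <- matrix(0L, H, W)
    n_live <- length(id)
    labels <- if (n_live) sample.int(n_live) else integer(0)
    for (c in seq_len(n_live)) {
      a <- ry[c] * scale[c]
      b <- rx[c] * scale[c]
      r0 <- max(0L, floor(cy[c] - a)); r1 <- min(H - 1L, ceiling(cy[c] + a))
      c0 <- max(0L, floor(cx[c] - b)); c1 <- min(W - 1L, ceiling(cx[c] + b))
      rr <- r0:r1; cc <- c0:c1
      inside <- outer((rr - cy[c])^2 / a^2, (cc - cx[c])^2 / b^2, `+`) <= 1
      # guarantee at least the center pixel
      inside[which.min(abs(rr - cy[c])), which.min(abs(cc - cx[c]))] <- TRUE
      sub <- m[rr + 1L, cc + 1L, drop = FALSE]
      sub[inside] <- labels[c]
      m[rr + 1L, cc + 1L] <- sub
    }
    list(mask = m, labels = labels)
  }

  frames <- vector("list", config$n_frames)
  truth_rows <- vector("list", config$n_frames)

  for (k in seq_len(config$n_frames)) {
    if (k > 1L) {
      # permanent disappearance
      if (length(id) && config$disappear_prob > 0) {
        gone <- stats::runif(length(id)) < config$disappear_prob
        keep <- !gone
        id <- id[keep]; cy <- cy[keep]; cx <- cx[keep]
        ry <- ry[keep]; rx <- rx[keep]; scale <- scale[keep]
      }
      # bounded random walk with reflection and contact rejection
      for (c in seq_along(id)) {
        rmax_c <- max(ry[c], rx[c]) * rmax_scale
        lo_y <- rmax_c + 1; hi_y <- H - 2 - rmax_c
        lo_x <- rmax_c + 1; hi_x <- W - 2 - rmax_c
        others <- setdiff(seq_along(id), c)
        rmaxs <- pmax(ry[others], rx[others]) * rmax_scale
        for (try in seq_len(20L)) {
          step <- stats::runif(2, -config$max_step, config$max_step)
          ny <- reflect_into(cy[c] + step[1], lo_y, hi_y)
          nx <- reflect_into(cx[c] + step[2], lo_x, hi_x)
          if (cell_gap_ok(ny, nx, rmax_c, cy[others], cx[others], rmaxs)) {
            cy[c] <- ny; cx[c] <- nx
            break
          }
        }
      }
      # per-frame area jitter relative to the base area
      if (jit > 0 && length(id)) {
        scale <- sqrt(stats::runif(length(id), 1 - jit, 1 + jit))
      }
      # one possible entry per frame
      if (config$appear_prob > 0 && stats::runif(1) < config$appear_prob) {
        pc <- place_cell(50L)
        if (!is.null(pc)) {
          id <- c(id, next_id); next_id <- next_id + 1L
          cy <- c(cy, pc$y); cx <- c(cx, pc$x)
          ry <- c(ry, pc$ry); rx <- c(rx, pc$rx)
          scale <- c(scale, 1)
        }
      }
    }
    ras <- rasterize()
    frames[[k]] <- labeled_mask(ras$mask, k)
    truth_rows[[k]] <- data.frame(frame = rep(k, length(id)),
                                  label = ras$labels,
                                  cell_id = id)
  }
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$frame, truth$label), , drop = FALSE]
  rownames(truth) <- NULL
  list(sequence = mask_sequence(frames), truth = truth)
}

#' Fraction of correct frame-to-frame links against ground truth
#'
#' A consecutive-frame link is correct when the two mask labels that the
#' truth assigns to one persisting cell received the same track id. The
#' score is correct links divided by the number of true persisting pairs;
#' an empty denominator (no cell persists anywhere) scores 1 vacuously.
#'
#' @param table a `track_table` from [track_cells()] / [chain_mappings()].
#' @param truth ground-truth data frame (`frame`, `label`, `cell_id`) from
#'   [simulate_sequence()].
#' @return Fraction in `[0, 1]`.
#' @export
score_tracking <- function(table, truth) {
  frames_truth <- sort(unique(truth$frame))
  frames_table <- sort(unique(table$frame))
  if (length(frames_table) && length(frames_truth) &&
      !all(frames_truth %in% frames_table)) {
    mt_validation_error("tracking result and ground truth cover different frames")
  }
  track_of <- stats::setNames(table$track_id, paste(table$frame, table$label))
  total <- 0L
  correct <- 0L
  for (k in frames_truth[-length(frames_truth)]) {
    t1 <- truth[truth$frame == k, , drop = FALSE]
    t2 <- truth[truth$frame == k + 1L, , drop = FALSE]
    common <- intersect(t1$cell_id, t2$cell_id)
    for (cid in common) {
      lab1 <- t1$label[t1$cell_id == cid]
      lab2 <- t2$label[t2$cell_id == cid]
      tr1 <- track_of[paste(k, lab1)]
      tr2 <- track_of[paste(k + 1L, lab2)]
      total <- total + 1L
      if (!is.na(tr1) && !is.na(tr2) && tr1 == tr2) correct <- correct + 1L
    }
  }
  if (total == 0L) return(1)
  correct / total
}
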