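#' Construct a labeled mask
#'
#' A labeled mask is one frame of a segmented image series: an integer matrix
#' in which 0 marks background and each positive value marks the pixels of
#' one cell. Cell numbers are per-frame and carry no identity across frames
#' until tracking assigns global track numbers.
#'
#' @param pixels integer matrix (rows = image height, columns = width) of
#'   non-negative labels. Numeric input is accepted if all values are whole.
#' @param frame_index 1-based position of this frame in its sequence.
#' @return An object of class `labeled_mask`: the integer matrix with a
#'   `frame_index` attribute.
#' @examples
#' m <- labeled_mask(matrix(c(0, 1, 1, 0, 0, 2), 2, 3))
#' mask_labels(m)
#' @export
labeled_mask <- function(pixels, frame_index = 1L) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels)) {
    mt_format_error("a labeled mask must be a 2-D matrix of non-negative integers")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    mt_format_error("a labeled mask must have height >= 1 and width >= 1")
  }
  if (anyNA(pixels)) mt_format_error("labeled mask contains missing pixel values")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels))) {
      mt_format_error("labeled mask contains non-integer (floating-point) pixel values")
    }
    storage.mode(pixels) <- "integer"
  }
  if (!is.integer(pixels)) {
    mt_format_error("labeled mask pixels must be integer-valued")
  }
  if (any(pixels < 0L)) {
    mt_format_error("labeled mask contains negative pixel values; 0 is background, labels are positive")
  }
  structure(pixels,
            frame_index = as.integer(frame_index),
            class = c("labeled_mask", "matrix", "array"))
}

#' @rdname labeled_mask
#' @param mask a `labeled_mask`.
#' @export
frame_index <- function(mask) attr(mask, "frame_index") %||% 1L

#' @rdname labeled_mask
#' @return `mask_labels()`: sorted positive labels present in the mask.
#' @export
mask_labels <- function(mask) {
  v <- as.integer(mask)
  sort(unique(v[v > 0L]))
}

as_bare_matrix <- function(mask) {
  m <- unclass(mask)
  attr(m, "frame_index") <- NULL
  m
}

#' @export
print.labeled_mask <- function(x, ...) {
  lab <- mask_labels(x)
  cat(sprintf("<labeled_mask> frame %d, %d x %d px, %d cell(s)\n",
              frame_index(x), nrow(x), ncol(x), length(lab)))
  invisible(x)
}

#' Read a label mask from a TIFF or PNG file
#'
#' Reads a single-channel 8- or 16-bit grayscale image and returns its pixel
#' values exactly as stored (no rescaling or remapping). Multi-channel and
#' floating-point images are rejected: a segmentation mask is by definition
#' an integer label image.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param frame_index frame index to attach to the returned mask.
#' @return A [labeled_mask()].
#' @export
read_mask <- function(path, frame_index = 1L) {
  if (!file.exists(path)) {
    mt_io_error(sprintf("cannot read mask: no such file '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = read_tiff_integer(path),
    png = read_png_integer(path),
    mt_format_error(sprintf("unsupported mask format '.%s' for '%s' (expected TIFF or PNG)",
                            ext, path))
  )
  if (length(dim(img)) != 2L) {
    mt_format_error(sprintf("'%s' is not a single-channel image; masks must be grayscale", path))
  }
  labeled_mask(img, frame_index)
}

read_tiff_integer <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) mt_io_error(sprintf("failed to decode TIFF '%s': %s",
                                                          path, conditionMessage(e))))
  bits <- attr(img, "bits.per.sample") %||% NA_integer_
  if (!is.na(bits) && !bits %in% c(1L, 8L, 16L)) {
    mt_format_error(sprintf("'%s' has %d bits per sample; masks must be 8- or 16-bit integer images",
                            path, bits))
  }
  attributes(img) <- list(dim = dim(img))
  img
}

read_png_integer <- function(path) {
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) mt_io_error(sprintf("failed to decode PNG '%s': %s",
                                                          path, conditionMessage(e))))
  info <- attr(img, "info")
  depth <- info$bit.depth %||% 8L
  attributes(img) <- list(dim = dim(img))
  # readPNG scales samples to [0, 1]; undo the scaling to recover raw labels
  vals <- img * (2^depth - 1)
  if (max(abs(vals - round(vals))) > 1e-6) {
    mt_format_error(sprintf("'%s' does not decode to integer labels", path))
  }
  round(vals)
}

#' Renumber mask labels to a canonical 1..M sequence
#'
#' A mask is canonical when its positive label set is exactly `{1, ..., M}`.
#' A canonical mask is returned unchanged — per-frame numbering is
#' arbitrary and carries no identity, so an already-consecutive numbering
#' is preserved as stored. Otherwise positive labels are renumbered to
#' consecutive integers starting at 1 in the order each label is first
#' encountered during a row-major (raster) scan: left to right along the
#' top row, then the next row, and so on. Background pixels and the
#' partition of foreground pixels into regions are never changed, and the
#' operation is idempotent.
#'
#' @param mask a [labeled_mask()].
#' @return A `labeled_mask` whose positive labels are exactly `1..M`.
#' @export
canonicalize_labels <- function(mask) {
  m <- as_bare_matrix(mask)
  present <- sort(unique(m[m > 0L]))
  if (length(present) == 0L || identical(present, seq_along(present))) {
    return(labeled_mask(m, frame_index(mask)))
  }
  raster <- as.integer(t(m)) # row-major scan order
  old <- unique(raster[raster > 0L])
  lut <- integer(max(old))
  lut[old] <- seq_along(old)
  fg <- m > 0L
  m[fg] <- lut[m[fg]]
  labeled_mask(m, frame_index(mask))
}

#' Construct a validated mask sequence
#'
#' @param frames list of [labeled_mask()] objects in time order.
#' @return An object of class `mask_sequence`: a list of masks with
#'   consecutive `frame_index` values 1..N and identical dimensions.
#' @export
mask_sequence <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L) {
    mt_validation_error(sprintf("a mask sequence needs >= 2 frames (got %d)", length(frames)))
  }
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    mt_format_error(sprintf(
      "all frames must share dimensions: frame 1 is %dx%d but frame %d is %dx%d",
      dims[1, 1], dims[2, 1], bad, dims[1, bad], dims[2, bad]))
  }
  frames <- lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    if (!inherits(f, "labeled_mask")) f <- labeled_mask(f)
    attr(f, "frame_index") <- as.integer(k)
    f
  })
  structure(frames,
            height = dims[1, 1], width = dims[2, 1],
            class = "mask_sequence")
}

#' @export
print.mask_sequence <- function(x, ...) {
  cat(sprintf("<mask_sequence> %d frames, %d x %d px\n",
              length(x), attr(x, "height"), attr(x, "width")))
  invisible(x)
}

#' Natural (numeric-aware) ordering of file names
#'
#' Orders `t2.tif` before `t10.tif` by comparing embedded digit runs as
#' numbers, which plain lexicographic sorting does not.
#' @param x character vector of names.
#' @return An integer permutation, as [order()].
#' @export
natural_order <- function(x) {
  key <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    isnum <- grepl("^[0-9]", parts)
    parts[isnum] <- sprintf("%020.0f", as.numeric(parts[isnum]))
    paste(parts, collapse = "")
  }, character(1))
  order(key, x)
}

#' Read a directory of mask files as a sequence
#'
#' Files matching `pattern` are ordered by natural filename order (numeric
#' chunks compared as numbers), read, canonicalized with
#' [canonicalize_labels()] and validated to share dimensions.
#'
#' @param directory directory containing per-frame mask images.
#' @param pattern filename glob, e.g. `"*.tif"`.
#' @return A [mask_sequence()].
#' @export
read_sequence <- function(directory, pattern = "*.tif*") {
  if (!dir.exists(directory)) {
    mt_io_error(sprintf("mask directory '%s' does not exist", directory))
  }
  files <- Sys.glob(file.path(directory, pattern))
  if (length(files) < 2L) {
    mt_validation_error(sprintf(
      "need >= 2 frames: found %d file(s) matching '%s' in '%s'",
      length(files), pattern, directory))
  }
  files <- files[natural_order(basename(files))]
  frames <- lapply(seq_along(files), function(k) {
    canonicalize_labels(read_mask(files[k], frame_index = k))
  })
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad)) {
    mt_format_error(sprintf("frame dimension mismatch: '%s' is %dx%d but '%s' is %dx%d",
                            basename(files[1]), dims[1, 1], dims[2, 1],
                            basename(files[bad[1]]), dims[1, bad[1]], dims[2, bad[1]]))
  }
  seq <- mask_sequence(frames)
  attr(seq, "files") <- files
  seq
}

#' Write a label mask to disk
#'
#' Writes a 16-bit (default) grayscale TIFF whose stored sample values are
#' the labels themselves, so `read_mask(write_mask(m))` is pixel-exact.
#' PNG output is supported at 8 bits only (labels must fit in 0..255).
#'
#' @param mask a [labeled_mask()].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @param bits bits per sample for TIFF output: 8 or 16.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, bits = 16L) {
  if (!inherits(mask, "labeled_mask")) mask <- labeled_mask(mask)
  ext <- tolower(tools::file_ext(path))
  m <- as_bare_matrix(mask)
  maxlab <- max(m, 0L)
  if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8L, 16L)) mt_validation_error("TIFF output supports 8 or 16 bits per sample")
    if (maxlab > 2^bits - 1) {
      mt_validation_error(sprintf("label %d exceeds the %d-bit output range (max %d)",
                                  maxlab, bits, 2^bits - 1))
    }
    ok <- tryCatch({
      tiff::writeTIFF(m / (2^bits - 1), path, bits.per.sample = as.integer(bits))
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) mt_io_error(sprintf("failed to write TIFF '%s'", path))
  } else if (ext == "png") {
    if (maxlab > 255L) {
      mt_validation_error(sprintf("label %d exceeds the 8-bit PNG output range; write TIFF instead",
                                  maxlab))
    }
    ok <- tryCatch({
      png::writePNG(m / 255, path)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) mt_io_error(sprintf("failed to write PNG '%s'", path))
  } else {
    mt_format_error(sprintf("unsupported output format '.%s' for '%s'", ext, path))
  }
  invisible(path)
}

#' Write every frame of a sequence to a directory
#'
#' @param sequence a [mask_sequence()].
#' @param directory output directory (created if missing).
#' @param prefix filename prefix; frames become `<prefix>001.tif`, ...
#' @param bits bits per sample.
#' @return Character vector of written paths, invisibly.
#' @export
write_sequence <- function(sequence, directory, prefix = "mask_", bits = 16L) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(sequence), function(k) {
    p <- file.path(directory, sprintf("%s%03d.tif", prefix, k))
    write_mask(sequence[[k]], p, bits = bits)
    p
  }, character(1))
  invisible(paths)
}
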