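# Small in-code fixtures shared across test files.

# Build a labeled mask from a row-wise vector spec.
mk_mask <- function(v, nrow, frame_index = 1L) {
  labeled_mask(matrix(as.integer(v), nrow = nrow, byrow = TRUE), frame_index)
}

# Mask with rectangular blocks: blocks is a list of list(rows, cols, label),
# rows/cols given 1-based for convenience.
block_mask <- function(h, w, blocks, frame_index = 1L) {
  m <- matrix(0L, h, w)
  for (b in blocks) m[b$rows, b$cols] <- as.integer(b$label)
  labeled_mask(m, frame_index)
}

# Random rectangle mask (later rectangles overwrite earlier ones), used to
# exercise overlap counting against the brute-force oracle.
random_rect_mask <- function(h, w, n_labels) {
  m <- matrix(0L, h, w)
  for (lab in seq_len(n_labels)) {
    r0 <- sample.int(h, 1); r1 <- min(h, r0 + sample.int(6, 1))
    c0 <- sample.int(w, 1); c1 <- min(w, c0 + sample.int(6, 1))
    m[r0:r1, c0:c1] <- lab
  }
  labeled_mask(m)
}

# Brute-force overlap oracle: explicit double loop over all pixels.
brute_overlap <- function(source, target) {
  s <- unclass(source); t <- unclass(target)
  counts <- list()
  for (r in seq_len(nrow(s))) {
    for (c in seq_len(ncol(s))) {
      if (s[r, c] > 0L && t[r, c] > 0L) {
        key <- paste(s[r, c], t[r, c])
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(counts) == 0L) {
    return(data.frame(source_label = integer(), target_label = integer(),
                      overlap = integer()))
  }
  parts <- do.call(rbind, lapply(names(counts), function(k) {
    as.integer(strsplit(k, " ")[[1]])
  }))
  out <- data.frame(source_label = parts[, 1], target_label = parts[, 2],
                    overlap = unlist(counts, use.names = FALSE))
  out <- out[order(out$source_label, out$target_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multiset of region sizes per frame.
size_multiset <- function(mask) sort(extract_regions(mask)$size)
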