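#' Extract per-cell features from a labeled mask
#'
#' Computes, for every positive label, the pixel count and the centroid
#' (unweighted mean of member pixel coordinates). Coordinates are 0-based
#' `(row, col)`; a centroid may be fractional.
#'
#' @param mask a [labeled_mask()].
#' @param pixels if `TRUE`, attach a list-column `pixel_set` of 0-based
#'   `(row, col)` matrices (one per region).
#' @return A data frame ordered by label with columns `label`, `frame`,
#'   `size`, `row`, `col` (and optionally `pixel_set`). An empty mask gives
#'   zero rows.
#' @examples
#' m <- labeled_mask(matrix(c(1, 1, 0, 1, 1, 0), 2, 3))
#' extract_regions(m) # one region, size 4, centroid (0.5, 0.5)
#' @export
extract_regions <- function(mask, pixels = FALSE) {
  m <- as_bare_matrix(mask)
  idx <- which(m > 0L)
  if (length(idx) == 0L) {
    out <- data.frame(label = integer(), frame = integer(), size = integer(),
                      row = numeric(), col = numeric())
    if (pixels) out$pixel_set <- list()
    return(out)
  }
  lab <- m[idx]
  rc <- arrayInd(idx, dim(m)) - 1L # 0-based (row, col)
  sums <- rowsum(cbind(rc[, 1], rc[, 2]), lab)
  labs <- as.integer(rownames(sums))
  size <- tabulate(lab)[labs]
  out <- data.frame(label = labs,
                    frame = frame_index(mask),
                    size = as.integer(size),
                    row = sums[, 1] / size,
                    col = sums[, 2] / size)
  rownames(out) <- NULL
  if (pixels) {
    ord <- order(lab)
    out$pixel_set <- unname(lapply(split.data.frame(rc[ord, , drop = FALSE], lab[ord]),
                                   function(x) unname(as.matrix(x))))
  }
  out
}

#' Count pixel overlaps between cells of two frames
#'
#' For every pair of a source-frame label and a target-frame label, counts
#' the pixel positions where both masks carry that pair of labels (evaluated
#' at identical coordinates, with no registration). Pairs with zero overlap
#' are omitted.
#'
#' @param source,target [labeled_mask()]s of identical dimensions
#'   (consecutive frames).
#' @return A data frame with columns `source_label`, `target_label`,
#'   `overlap`, ordered by source then target label; zero rows when no
#'   cells overlap.
#' @export
count_overlaps <- function(source, target) {
  s <- as_bare_matrix(source)
  t <- as_bare_matrix(target)
  if (!identical(dim(s), dim(t))) {
    mt_format_error(sprintf("cannot count overlaps: source is %dx%d but target is %dx%d",
                            nrow(s), ncol(s), nrow(t), ncol(t)))
  }
  both <- s > 0L & t > 0L
  if (!any(both)) {
    return(data.frame(source_label = integer(), target_label = integer(),
                      overlap = integer()))
  }
  sl <- s[both]
  tl <- t[both]
  tab <- table(sl, tl)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, , drop = FALSE]
  out <- data.frame(source_label = as.integer(df$sl),
                    target_label = as.integer(df$tl),
                    overlap = as.integer(df$Freq))
  out <- out[order(out$source_label, out$target_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
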