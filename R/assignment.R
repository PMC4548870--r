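#' Construct a frame mapping
#'
#' The chosen one-to-one partial matching between the cells of frame `k`
#' (sources) and frame `k + 1` (targets). Every source label appears in
#' exactly one of `links$source_label` / `unmatched_sources` and every
#' target label in exactly one of `links$target_label` /
#' `unmatched_targets`; an unmatched source terminates its track, an
#' unmatched target starts a new one.
#'
#' @param links data frame with columns `source_label`, `target_label`,
#'   `cost`.
#' @param unmatched_sources,unmatched_targets integer label vectors.
#' @param frame_pair optional `c(k, k + 1)`.
#' @return An object of class `frame_mapping`.
#' @export
frame_mapping <- function(links, unmatched_sources = integer(),
                          unmatched_targets = integer(), frame_pair = NULL) {
  if (anyDuplicated(links$source_label) || anyDuplicated(links$target_label)) {
    mt_validation_error("frame mapping links must be one-to-one")
  }
  structure(list(links = links,
                 unmatched_sources = as.integer(unmatched_sources),
                 unmatched_targets = as.integer(unmatched_targets),
                 frame_pair = frame_pair),
            class = "frame_mapping")
}

#' @export
print.frame_mapping <- function(x, ...) {
  fp <- if (is.null(x$frame_pair)) "" else sprintf(" frames %d->%d,", x$frame_pair[1], x$frame_pair[2])
  cat(sprintf("<frame_mapping>%s %d link(s), %d track end(s), %d new track(s)\n",
              fp, nrow(x$links), length(x$unmatched_sources), length(x$unmatched_targets)))
  invisible(x)
}

empty_links <- function() {
  data.frame(source_label = integer(), target_label = integer(), cost = numeric())
}

## Jonker-Volgenant shortest augmenting path solver for a square cost
## matrix with finite entries. Returns, for each row, the assigned column.
## O(n^3) with the Dijkstra scan over columns vectorized.
lap_square <- function(C) {
  n <- nrow(C)
  u <- numeric(n)              # row potentials
  v <- numeric(n + 1)          # column potentials, index 1 = virtual column
  p <- integer(n + 1)          # p[j + 1] = row assigned to column j (0 = free)
  way <- integer(n + 1)        # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      jfree <- which(!used[-1])
      cur <- C[i0, jfree] - u[i0] - v[jfree + 1]
      upd <- cur < minv[jfree + 1]
      minv[(jfree + 1)[upd]] <- cur[upd]
      way[(jfree + 1)[upd]] <- j0
      jm <- jfree[which.min(minv[jfree + 1])]
      delta <- minv[jm + 1]
      usedIdx <- which(used)
      u[p[usedIdx]] <- u[p[usedIdx]] + delta
      v[usedIdx] <- v[usedIdx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- jm
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  col_of <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) col_of[p[j + 1]] <- j
  col_of
}

## Deterministic canonicalization among cost-ties: repeatedly apply
## cost-neutral rewrites that move links toward lower source labels first,
## then lower target labels. Operates on row/col indices.
canonicalize_ties <- function(assign_col, V, valid, tol = 1e-9) {
  nr <- nrow(V)
  nc <- ncol(V)
  repeat {
    changed <- FALSE
    linked <- which(assign_col > 0L)
    free_cols <- setdiff(seq_len(nc), assign_col[linked])
    # move a link to an equal-cost free column with a smaller index
    for (i in linked) {
      j <- assign_col[i]
      cand <- free_cols[free_cols < j & valid[i, free_cols]]
      cand <- cand[abs(V[i, cand] - V[i, j]) <= tol]
      if (length(cand)) {
        free_cols <- sort(c(setdiff(free_cols, cand[1]), j))
        assign_col[i] <- cand[1]
        changed <- TRUE
      }
    }
    # swap targets between two links when cost-neutral and lexicographically smaller
    linked <- which(assign_col > 0L)
    if (length(linked) >= 2L) {
      for (ai in seq_len(length(linked) - 1L)) {
        for (bi in seq(ai + 1L, length(linked))) {
          i1 <- linked[ai]; i2 <- linked[bi]
          j1 <- assign_col[i1]; j2 <- assign_col[i2]
          if (j2 < j1 && valid[i1, j2] && valid[i2, j1] &&
              abs(V[i1, j2] + V[i2, j1] - V[i1, j1] - V[i2, j2]) <= tol) {
            assign_col[i1] <- j2
            assign_col[i2] <- j1
            changed <- TRUE
          }
        }
      }
    }
    # hand a link to an equal-cost unmatched source with a smaller index
    linked <- which(assign_col > 0L)
    free_rows <- setdiff(seq_len(nr), linked)
    for (i in linked) {
      j <- assign_col[i]
      cand <- free_rows[free_rows < i & valid[free_rows, j]]
      cand <- cand[abs(V[cand, j] - V[i, j]) <= tol]
      if (length(cand)) {
        assign_col[cand[1]] <- j
        assign_col[i] <- 0L
        free_rows <- sort(c(setdiff(free_rows, cand[1]), i))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assign_col
}

#' Solve the optimal one-to-one mapping for a frame pair
#'
#' Finds the globally optimal partial matching between source and target
#' cells: among matchings that exclude invalid (`max_cost`) pairs it first
#' maximizes the number of links, then minimizes the total cost of the
#' matched pairs — equal to exhaustive enumeration
#' ([brute_force_mapping()]) on every instance. Cost ties are broken
#' deterministically toward the lowest source label, then the lowest target
#' label.
#'
#' The solver pads the matrix to square form (one slack column per source
#' and one slack row per target, so any cell may stay unmatched) and runs a
#' Jonker–Volgenant shortest-augmenting-path assignment.
#'
#' @param costs a `cost_matrix` from [build_cost_matrix()], or any numeric
#'   matrix (row/column names are taken as labels when present).
#' @param config a [tracker_config()]; `config$max_cost` marks invalid
#'   entries unless the matrix carries its own `max_cost` attribute.
#' @param frame_pair optional `c(k, k + 1)` recorded in the result.
#' @return A [frame_mapping()].
#' @examples
#' solve_mapping(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2))
#' @export
solve_mapping <- function(costs, config = tracker_config(), frame_pair = NULL) {
  max_cost <- attr(costs, "max_cost") %||% config$max_cost
  V <- costs
  attributes(V) <- attributes(V)["dim"]
  nr <- nrow(V)
  nc <- ncol(V)
  slab <- as.integer(rownames(costs) %||% seq_len(nr))
  tlab <- as.integer(colnames(costs) %||% seq_len(nc))
  valid <- V < max_cost
  if (nr == 0L || nc == 0L || !any(valid)) {
    return(frame_mapping(empty_links(), slab, tlab, frame_pair))
  }
  # square augmentation: matching a real pair costs its entry; leaving a
  # source or target unmatched costs K through its private slack; K exceeds
  # the total finite cost so cardinality dominates, then total cost.
  K <- sum(V[valid]) + 1
  n <- nr + nc
  BIG <- n * K + 1
  M <- matrix(BIG, n, n)
  M[seq_len(nr), seq_len(nc)] <- ifelse(valid, V, BIG)
  M[cbind(seq_len(nr), nc + seq_len(nr))] <- K
  M[cbind(nr + seq_len(nc), seq_len(nc))] <- K
  M[nr + seq_len(nc), nc + seq_len(nr)] <- 0
  col_of <- lap_square(M)
  assign_col <- integer(nr)
  for (i in seq_len(nr)) {
    j <- col_of[i]
    if (j <= nc && valid[i, j]) assign_col[i] <- j
  }
  assign_col <- canonicalize_ties(assign_col, V, valid)
  linked <- which(assign_col > 0L)
  links <- data.frame(source_label = slab[linked],
                      target_label = tlab[assign_col[linked]],
                      cost = V[cbind(linked, assign_col[linked])])
  links <- links[order(links$source_label), , drop = FALSE]
  rownames(links) <- NULL
  frame_mapping(links,
                unmatched_sources = slab[setdiff(seq_len(nr), linked)],
                unmatched_targets = tlab[setdiff(seq_len(nc), assign_col[linked])],
                frame_pair = frame_pair)
}

#' Exhaustive-search mapping (test oracle)
#'
#' Enumerates every injective partial mapping that excludes invalid
#' (`max_cost`) pairs and returns the optimum under the same objective and
#' tie-break as [solve_mapping()]: maximal number of links, then minimal
#' total cost, then lexicographically smallest by source label and target
#' label. Intended as an independent oracle on small instances.
#'
#' @param costs numeric cost matrix.
#' @param max_cost sentinel marking invalid entries.
#' @param max_dim refuse matrices whose smaller dimension exceeds this.
#' @return A [frame_mapping()].
#' @export
brute_force_mapping <- function(costs, max_cost = attr(costs, "max_cost") %||% 1e9,
                                max_dim = 8L) {
  V <- costs
  attributes(V) <- attributes(V)["dim"]
  nr <- nrow(V)
  nc <- ncol(V)
  if (min(nr, nc) > max_dim) {
    mt_validation_error(sprintf(
      "brute-force enumeration refused: min dimension %d exceeds %d", min(nr, nc), max_dim))
  }
  slab <- as.integer(rownames(costs) %||% seq_len(nr))
  tlab <- as.integer(colnames(costs) %||% seq_len(nc))
  valid <- if (nr && nc) V < max_cost else matrix(FALSE, nr, nc)

  best_assign <- integer(nr)
  best_nlink <- -1L
  best_cost <- Inf
  assign_col <- integer(nr)
  used_col <- logical(nc)

  recurse <- function(i, nlink, cost) {
    # upper bound on achievable links from here on
    bound <- nlink + min(nr - i + 1L, sum(!used_col))
    if (bound < best_nlink) return()
    if (bound == best_nlink && cost >= best_cost - 1e-12) return()
    if (i > nr) {
      if (nlink > best_nlink ||
          (nlink == best_nlink && cost < best_cost - 1e-12)) {
        best_assign <<- assign_col
        best_nlink <<- nlink
        best_cost <<- cost
      }
      return()
    }
    for (j in seq_len(nc)) {
      if (!used_col[j] && valid[i, j]) {
        used_col[j] <<- TRUE
        assign_col[i] <<- j
        recurse(i + 1L, nlink + 1L, cost + V[i, j])
        used_col[j] <<- FALSE
        assign_col[i] <<- 0L
      }
    }
    recurse(i + 1L, nlink, cost) # leave source i unmatched
  }
  if (nr == 0L || nc == 0L) {
    best_assign <- integer(nr)
  } else {
    recurse(1L, 0L, 0)
  }
  linked <- which(best_assign > 0L)
  links <- data.frame(source_label = slab[linked],
                      target_label = tlab[best_assign[linked]],
                      cost = if (length(linked)) V[cbind(linked, best_assign[linked])] else numeric())
  rownames(links) <- NULL
  frame_mapping(links,
                unmatched_sources = slab[setdiff(seq_len(nr), linked)],
                unmatched_targets = tlab[setdiff(seq_len(nc), best_assign[linked])])
}
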