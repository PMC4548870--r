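# Two 3-frame fixtures used throughout: cells drift by one column per frame
# so consecutive instances overlap heavily.

persistent_pair_seq <- function() {
  f <- function(shift, frame) {
    block_mask(20, 30, list(list(rows = 3:7, cols = (3:7) + shift, label = 1),
                            list(rows = 12:16, cols = (18:22) + shift, label = 2)),
               frame_index = frame)
  }
  mask_sequence(list(f(0, 1), f(1, 2), f(2, 3)))
}

test_that("a single linked cell forms one track spanning both frames", {
  s <- mask_sequence(list(
    block_mask(10, 10, list(list(rows = 2:5, cols = 2:5, label = 1))),
    block_mask(10, 10, list(list(rows = 3:6, cols = 2:5, label = 1)))))
  tab <- track_cells(s)$table
  expect_identical(attr(tab, "n_tracks"), 1L)
  expect_identical(tab$frame, c(1L, 2L))
  expect_identical(tab$track_id, c(1L, 1L))
})

test_that("an unmatched source ends its track and a new target starts one", {
  # cell 1 disappears after frame 1; a distant cell appears in frame 2
  s <- mask_sequence(list(
    block_mask(200, 200, list(list(rows = 2:5, cols = 2:5, label = 1))),
    block_mask(200, 200, list(list(rows = 150:153, cols = 150:153, label = 1)))))
  res <- track_cells(s)
  tab <- res$table
  expect_identical(attr(tab, "n_tracks"), 2L)
  expect_identical(nrow(res$mappings[[1]]$links), 0L)
  expect_identical(tab$track_id[tab$frame == 1L], 1L)
  expect_identical(tab$track_id[tab$frame == 2L], 2L)
})

test_that("a cell appearing mid-sequence gets the next track number", {
  # two persistent cells plus one appearing in frame 2, all well separated
  f1 <- block_mask(60, 80, list(list(rows = 3:7, cols = 3:7, label = 1),
                                list(rows = 40:44, cols = 60:64, label = 2)))
  f2 <- block_mask(60, 80, list(list(rows = 4:8, cols = 3:7, label = 1),
                                list(rows = 41:45, cols = 60:64, label = 2),
                                list(rows = 40:44, cols = 5:9, label = 3)))
  f3 <- block_mask(60, 80, list(list(rows = 5:9, cols = 3:7, label = 1),
                                list(rows = 42:46, cols = 60:64, label = 2),
                                list(rows = 41:45, cols = 5:9, label = 3)))
  tab <- track_cells(mask_sequence(list(f1, f2, f3)))$table
  expect_identical(attr(tab, "n_tracks"), 3L)
  t3 <- tab[tab$track_id == 3L, ]
  expect_identical(t3$frame, c(2L, 3L))
  # every track covers consecutive frames only
  for (id in unique(tab$track_id)) {
    fr <- sort(tab$frame[tab$track_id == id])
    expect_identical(fr, seq(min(fr), max(fr)))
  }
})

test_that("chain_mappings validates its inputs", {
  s <- persistent_pair_seq()
  res <- track_cells(s)
  expect_error(chain_mappings(s, res$mappings[1]), class = "masktrack_validation_error")

  bad <- res$mappings
  bad[[1]]$links$source_label[1] <- 99L
  expect_error(chain_mappings(s, bad), class = "masktrack_validation_error")
})

test_that("relabel_masks rewrites values but preserves geometry", {
  s <- persistent_pair_seq()
  res <- track_cells(s)
  out <- relabel_masks(s, res$table)
  for (k in seq_along(s)) {
    # conservation: identical multiset of region sizes
    expect_identical(size_multiset(out[[k]]), size_multiset(s[[k]]))
    # background untouched
    expect_identical(unclass(out[[k]]) == 0L, unclass(s[[k]]) == 0L)
  }
  # each tracked cell carries its track id in every frame
  for (i in seq_len(nrow(res$table))) {
    r <- res$table[i, ]
    px <- unclass(out[[r$frame]])[unclass(s[[r$frame]]) == r$label]
    expect_true(all(px == r$track_id))
  }
})

test_that("relabeling is the identity when labels already equal track ids", {
  s <- mask_sequence(list(
    block_mask(10, 10, list(list(rows = 2:5, cols = 2:5, label = 1))),
    block_mask(10, 10, list(list(rows = 2:5, cols = 3:6, label = 1)))))
  res <- track_cells(s)
  out <- relabel_masks(s, res$table)
  for (k in 1:2) expect_identical(unclass(out[[k]])[, ], unclass(s[[k]])[, ])
})

test_that("a mid-sequence label change maps onto the continuing track", {
  # same cell, but frame 2 numbers it 3: its pixels must become track 1
  f1 <- block_mask(10, 10, list(list(rows = 2:5, cols = 2:5, label = 1)))
  m2 <- matrix(0L, 10, 10); m2[3:6, 2:5] <- 3L
  f2 <- labeled_mask(m2) # non-canonical on purpose
  s <- mask_sequence(list(f1, canonicalize_labels(f2)))
  res <- track_cells(s)
  out <- relabel_masks(s, res$table)
  expect_identical(attr(res$table, "n_tracks"), 1L)
  expect_true(all(unclass(out[[2]])[3:6, 2:5] == 1L))
})

test_that("appearance counts balance between tracks and frames", {
  sim <- simulate_sequence(simulation_config(n_frames = 8, n_cells = 6,
                                             height = 200, width = 260,
                                             appear_prob = 0.5, disappear_prob = 0.1,
                                             seed = 11))
  tab <- track_cells(sim$sequence)$table
  m_k <- vapply(sim$sequence, function(f) length(mask_labels(f)), integer(1))
  expect_identical(nrow(tab), sum(m_k))
  # track ids are 1..T with no gaps; no two tracks share a label in a frame
  expect_identical(sort(unique(tab$track_id)), seq_len(attr(tab, "n_tracks")))
  expect_false(any(duplicated(tab[c("frame", "track_id")])))
  expect_false(any(duplicated(tab[c("frame", "label")])))
})

test_that("track tables round-trip through CSV", {
  s <- persistent_pair_seq()
  tab <- track_cells(s)$table
  dir <- withr::local_tempdir()
  p <- write_track_table(tab, file.path(dir, "tt.csv"))
  back <- read_track_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tab)[names(back)],
               ignore_attr = TRUE)
})
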