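test_that("tracker_config validates weights and thresholds", {
  cfg <- tracker_config()
  expect_equal(cfg$weight_overlap, 2)
  expect_equal(cfg$weight_centroid, 1)
  expect_equal(cfg$weight_size, 0.5)
  expect_equal(cfg$max_centroid_distance, 50)
  expect_gt(cfg$max_cost, cfg$weight_overlap + cfg$weight_centroid + cfg$weight_size)

  expect_error(tracker_config(weight_overlap = -1), class = "masktrack_validation_error")
  expect_error(tracker_config(max_centroid_distance = 0), class = "masktrack_validation_error")
  expect_error(tracker_config(max_cost = 3), class = "masktrack_validation_error")
})

test_that("JSON config round-trips and rejects unknown keys", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(weight_overlap = 3, max_centroid_distance = 80),
                       good, auto_unbox = TRUE)
  cfg <- read_tracker_config(good)
  expect_equal(cfg$weight_overlap, 3)
  expect_equal(cfg$max_centroid_distance, 80)
  expect_equal(cfg$weight_size, 0.5) # untouched default

  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(weight_overlp = 3), bad, auto_unbox = TRUE)
  err <- tryCatch(read_tracker_config(bad), error = function(e) e)
  expect_s3_class(err, "masktrack_validation_error")
  expect_match(conditionMessage(err), "weight_overlp")
})

test_that("the three metrics reproduce hand-computed values", {
  # overlap: perfect match, no overlap, and a half-sized target
  expect_equal(overlap_metric(100, 100, 100), 0)
  expect_equal(overlap_metric(100, 100, 0), 1)
  expect_equal(overlap_metric(100, 50, 50), 1 - 25 * (1 / 100 + 1 / 50),
               tolerance = 1e-12)
  expect_equal(overlap_metric(100, 50, 50), 0.25)

  # centroid offset, normalized by the image diagonal
  expect_equal(centroid_metric(c(10, 20), c(10, 20), 520, 696), 0)
  expect_equal(centroid_metric(c(0, 0), c(520, 696), 520, 696), 1)
  expect_equal(centroid_metric(c(0, 0), c(3, 4), 520, 696),
               5 / sqrt(520^2 + 696^2), tolerance = 1e-12)

  # relative size difference
  expect_equal(size_metric(100, 100), 0)
  expect_equal(size_metric(100, 50), 0.5)
  expect_equal(size_metric(80, 100), 0.2)
})

test_that("metric contracts are enforced", {
  expect_error(overlap_metric(100, 50, 60), class = "masktrack_validation_error")
  expect_error(overlap_metric(100, 50, -1), class = "masktrack_validation_error")
  expect_error(overlap_metric(0, 50, 0), class = "masktrack_validation_error")
  expect_error(size_metric(0, 10), class = "masktrack_validation_error")
})

test_that("metrics stay in [0, 1] over randomized valid inputs", {
  set.seed(202)
  n <- 2000
  s1 <- sample(1:10000, n, replace = TRUE)
  s2 <- sample(1:10000, n, replace = TRUE)
  no <- floor(runif(n) * (pmin(s1, s2) + 1))
  o <- overlap_metric(s1, s2, no)
  ds <- size_metric(s1, s2)
  a <- cbind(runif(n, 0, 519), runif(n, 0, 695))
  b <- cbind(runif(n, 0, 519), runif(n, 0, 695))
  dc <- centroid_metric(a, b, 520, 696)
  for (v in list(o, ds, dc)) {
    expect_true(all(v >= 0))
    expect_true(all(v <= 1))
  }
})

test_that("overlap metric is symmetric and strictly decreasing in overlap", {
  expect_equal(overlap_metric(120, 40, 30), overlap_metric(40, 120, 30))
  vals <- overlap_metric(100, 80, 0:80)
  expect_true(all(diff(vals) < 0))
})

test_that("pair_cost combines metrics and applies the pathological filter", {
  cfg <- tracker_config()
  r1 <- list(size = 100L, row = 10, col = 10)

  # identical cell in both frames: all metrics zero, cost zero
  expect_equal(pair_cost(r1, r1, n_overlap = 100, cfg, height = 520, width = 696), 0)

  # no shared pixels and a 400 px jump: invalid by definition
  far <- list(size = 100L, row = 10, col = 410)
  expect_identical(pair_cost(r1, far, n_overlap = 0, cfg, 520, 696), cfg$max_cost)

  # the filter is conjunctive: any shared pixel keeps the mapping valid
  expect_lt(pair_cost(r1, far, n_overlap = 1, cfg, 520, 696), cfg$max_cost)

  # zero overlap but a short hop stays finite
  near <- list(size = 100L, row = 10, col = 30)
  expect_lt(pair_cost(r1, near, n_overlap = 0, cfg, 520, 696), cfg$max_cost)

  # weighted sum of hand-computed components
  src <- list(size = 100L, row = 0, col = 0)
  tgt <- list(size = 50L, row = 3, col = 4)
  expected <- 2 * 0.25 + 1 * (5 / sqrt(520^2 + 696^2)) + 0.5 * 0.5
  expect_equal(pair_cost(src, tgt, n_overlap = 50, cfg, 520, 696),
               expected, tolerance = 1e-12)

  # with sizes fixed, cost strictly decreases as overlap grows
  costs <- vapply(0:50, function(n) pair_cost(src, tgt, n, cfg, 520, 696), numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("build_cost_matrix fills every source-target pair", {
  cfg <- tracker_config()
  one <- block_mask(30, 30, list(list(rows = 5:10, cols = 5:10, label = 1)))
  reg <- extract_regions(one)
  ov <- count_overlaps(one, one)
  cm <- build_cost_matrix(reg, reg, ov, cfg, 30, 30)
  expect_identical(dim(cm), c(1L, 1L))
  expect_equal(cm[1, 1], 0)

  # empty target frame: zero columns, all sources terminate
  empty <- extract_regions(mk_mask(rep(0, 900), 30))
  cm0 <- build_cost_matrix(reg, empty, count_overlaps(one, mk_mask(rep(0, 900), 30)),
                           cfg, 30, 30)
  expect_identical(dim(cm0), c(1L, 0L))

  # two distant stationary cells: finite diagonal, MAX_COST off-diagonal
  two <- block_mask(300, 500, list(list(rows = 10:14, cols = 10:14, label = 1),
                                   list(rows = 280:284, cols = 480:484, label = 2)))
  r2 <- extract_regions(two)
  cm2 <- build_cost_matrix(r2, r2, count_overlaps(two, two), cfg, 300, 500)
  expect_equal(unname(diag(cm2)), c(0, 0))
  expect_identical(cm2[1, 2], cfg$max_cost)
  expect_identical(cm2[2, 1], cfg$max_cost)

  # entries match pair_cost computed pair by pair (brute-force oracle)
  ovr <- count_overlaps(two, two)
  for (i in 1:2) for (j in 1:2) {
    n_o <- ovr$overlap[ovr$source_label == i & ovr$target_label == j]
    if (length(n_o) == 0L) n_o <- 0L
    expect_equal(cm2[i, j],
                 pair_cost(as.list(r2[i, ]), as.list(r2[j, ]), n_o, cfg, 300, 500))
  }

  # finite entries are bounded by the weight sum
  finite <- cm2[cm2 < cfg$max_cost]
  expect_true(all(finite <= cfg$weight_overlap + cfg$weight_centroid + cfg$weight_size))
})
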