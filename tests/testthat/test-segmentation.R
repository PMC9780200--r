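test_that("mean + k*SD threshold on a constant control equals the constant", {
  ctl <- const_field(10, is_control = TRUE)
  thr <- derive_background_threshold(list(ctl),
                                     threshold_rule("mean_plus_ksd", 3))
  expect_identical(thr$cutoff, 10)
  expect_equal(thr$n_control_pixels, 32 * 32)
})

test_that("percentile cutoff matches an independent sort-based oracle", {
  # reporter holds each of 0..999 exactly once; oracle reimplements the
  # type-7 quantile from sorted values
  vals <- matrix(sample(0:999), 25, 40)
  ctl <- field_from_channels(matrix(0, 25, 40) + 1, matrix(0, 25, 40) + 1,
                             vals, is_control = TRUE)
  ctl$meta$is_control <- TRUE
  thr <- derive_background_threshold(list(ctl),
                                     threshold_rule("percentile", 99.5))
  x <- sort(as.numeric(vals))
  h <- (length(x) - 1) * 0.995
  oracle <- x[floor(h) + 1] + (h - floor(h)) * (x[floor(h) + 2] - x[floor(h) + 1])
  expect_equal(thr$cutoff, oracle)
})

test_that("mean + 3SD on pooled Gaussian controls matches pooled moments", {
  withr::with_seed(11, {
    mk <- function() {
      px <- matrix(rnorm(256 * 256, 100, 10), 256, 256)
      px[px < 0] <- 0
      field_from_channels(matrix(1, 256, 256), matrix(1, 256, 256), px,
                          is_control = TRUE)
    }
    ctls <- list(mk(), mk())
  })
  for (f in seq_along(ctls)) ctls[[f]]$meta$is_control <- TRUE
  thr <- derive_background_threshold(list(ctls[[1]], ctls[[2]]),
                                     threshold_rule("mean_plus_ksd", 3))
  pooled <- c(field_channel(ctls[[1]], "reporter"),
              field_channel(ctls[[2]], "reporter"))
  expect_equal(thr$cutoff, mean(pooled) + 3 * sd(pooled))
  expect_gte(thr$cutoff, 128); expect_lte(thr$cutoff, 132)
})

test_that("threshold derivation rejects invalid control sets", {
  expect_error(derive_background_threshold(list()), "non-empty")
  not_ctl <- const_field(5, is_control = FALSE)
  expect_error(derive_background_threshold(list(not_ctl)), "is_control")
  a <- const_field(5, condition_id = "a", is_control = TRUE)
  b <- const_field(5, condition_id = "b", is_control = TRUE)
  expect_error(derive_background_threshold(list(a, b)), "multiple")
})

test_that("an all-background field yields zero objects", {
  f <- const_field(3)
  thr <- make_threshold(5)
  cells <- segment_cells(f, thr)
  expect_equal(n_cells(cells), 0L)
  # and golgi segmentation of an empty map returns an empty mask
  expect_false(any(segment_golgi(f, cells)))
})

test_that("a solid square above cutoff becomes one object of exact area", {
  rep_ch <- matrix(0, 64, 64)
  rep_ch[10:49, 12:51] <- 105    # 40 x 40 square at cutoff + 100
  f <- field_from_channels(matrix(0, 64, 64), matrix(0, 64, 64), rep_ch)
  thr <- make_threshold(5)
  cells <- segment_cells(f, thr, segmentation_params(min_area_px = 500,
                                                     closing_radius_px = 0))
  expect_equal(n_cells(cells), 1L)
  expect_equal(sum(cells$labels == 1L), 1600)
})

test_that("condition mismatch between field and threshold is an error", {
  f <- const_field(10, condition_id = "a")
  thr <- make_threshold(5, condition_id = "b")
  expect_error(segment_cells(f, thr), "does not match")
})

test_that("planted cells are recovered with high overlap", {
  sc <- generate_scene(scene_params(seed = 5))
  ctl <- generate_control_scene(scene_params(seed = 5))
  seg <- segment_scene(sc, ctl)
  expect_equal(n_cells(seg$cells), max(sc$truth$cell_labels))
  for (k in seq_len(max(sc$truth$cell_labels))) {
    truth_mask <- sc$truth$cell_labels == k
    jac <- vapply(seq_len(n_cells(seg$cells)), function(l)
      jaccard(truth_mask, seg$cells$labels == l), numeric(1))
    expect_equal(sum(jac >= 0.8), 1L)   # exactly one matching label
  }
})

test_that("golgi mask on a bimodal two-level marker is the bright square", {
  rep_ch <- matrix(0, 64, 64); rep_ch[5:54, 5:54] <- 50
  marker <- matrix(0, 64, 64); marker[20:29, 20:29] <- 200
  f <- field_from_channels(matrix(0, 64, 64), marker, rep_ch)
  cells <- segment_cells(f, make_threshold(5),
                         segmentation_params(closing_radius_px = 0))
  golgi <- segment_golgi(f, cells)
  expect_identical(golgi, marker == 200)
  # all-zero marker: empty mask
  f0 <- field_from_channels(matrix(0, 64, 64), matrix(0, 64, 64), rep_ch)
  expect_false(any(segment_golgi(f0, cells)))
})

test_that("planted Golgi is recovered against ground truth", {
  sc <- generate_scene(scene_params(seed = 5))
  ctl <- generate_control_scene(scene_params(seed = 5))
  seg <- segment_scene(sc, ctl)
  for (k in seq_len(max(sc$truth$cell_labels))) {
    truth_g <- sc$truth$golgi_labels == k
    cell_rec <- which(vapply(seq_len(n_cells(seg$cells)), function(l)
      jaccard(sc$truth$cell_labels == k, seg$cells$labels == l) >= 0.8,
      logical(1)))
    rec_g <- seg$golgi & (seg$cells$labels == cell_rec)
    expect_gte(jaccard(truth_g, rec_g), 0.6)
  }
})

test_that("partitions are exact complements within the cell", {
  rep_ch <- matrix(0, 64, 64); rep_ch[5:54, 5:54] <- 50
  f <- field_from_channels(matrix(0, 64, 64), matrix(0, 64, 64), rep_ch)
  cells <- segment_cells(f, make_threshold(5),
                         segmentation_params(closing_radius_px = 0))
  cell_mask <- cells$labels == 1L

  empty_golgi <- matrix(FALSE, 64, 64)
  p <- partition_cell(cells, empty_golgi, 1L)
  expect_false(any(p$in_golgi))
  expect_identical(p$out_golgi, cell_mask)

  all_golgi <- matrix(TRUE, 64, 64)
  p2 <- partition_cell(cells, all_golgi, 1L)
  expect_false(any(p2$out_golgi))
  expect_identical(p2$in_golgi, cell_mask)

  # random golgi masks: disjointness and exact union, pixelwise
  withr::with_seed(9, {
    for (i in 1:5) {
      g <- matrix(runif(64 * 64) < 0.3, 64, 64)
      pr <- partition_cell(cells, g, 1L)
      expect_false(any(pr$in_golgi & pr$out_golgi))
      expect_identical(pr$in_golgi | pr$out_golgi, cell_mask)
      expect_equal(sum(pr$in_golgi) + sum(pr$out_golgi), sum(cell_mask))
    }
  })
  expect_error(partition_cell(cells, empty_golgi, 99L), "unknown cell_id")
})

test_that("raising the cutoff never increases the foreground", {
  sc <- generate_scene(small_scene(seed = 3))
  cuts <- c(2, 10, 40, 200)
  fg <- vapply(cuts, function(cutoff) {
    cells <- segment_cells(sc$field, make_threshold(cutoff, "synthetic"))
    cells$foreground_fraction
  }, numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("segmentation is deterministic", {
  sc <- generate_scene(small_scene(seed = 4))
  ctl <- generate_control_scene(small_scene(seed = 4))
  a <- segment_scene(sc, ctl)
  b <- segment_scene(sc, ctl)
  expect_identical(a$cells$labels, b$cells$labels)
  expect_identical(a$golgi, b$golgi)
})

test_that("nucleus-seeded propagation splits touching cells", {
  # two bright squares sharing an edge, one nucleus each
  rep_ch <- matrix(0, 80, 80); rep_ch[20:59, 10:69] <- 50
  nuc <- matrix(0, 80, 80)
  nuc[35:44, 20:29] <- 200; nuc[35:44, 50:59] <- 200
  f <- field_from_channels(nuc, matrix(0, 80, 80), rep_ch)
  merged <- segment_cells(f, make_threshold(5),
                          segmentation_params(closing_radius_px = 0))
  expect_equal(n_cells(merged), 1L)
  split <- segment_cells(f, make_threshold(5),
                         segmentation_params(closing_radius_px = 0,
                                             use_nuclei_seeds = TRUE))
  expect_equal(n_cells(split), 2L)
})
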