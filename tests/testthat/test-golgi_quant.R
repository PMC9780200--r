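test_that("measure_mask summarizes uniform and single-pixel regions", {
  ch <- matrix(7, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:7, 3:12] <- TRUE
  s <- measure_mask(ch, mask)
  expect_equal(s$min, 7); expect_equal(s$max, 7); expect_equal(s$mean, 7)
  expect_equal(s$intden, 7 * 50); expect_equal(s$area_px, 50L)

  one <- matrix(FALSE, 20, 20); one[5, 5] <- TRUE
  s0 <- measure_mask(matrix(0, 20, 20), one)
  expect_equal(unlist(s0[c("min", "max", "mean", "intden")]),
               c(min = 0, max = 0, mean = 0, intden = 0))
  expect_equal(s0$area_px, 1L)
})

test_that("measure_mask matches a brute-force per-pixel loop", {
  withr::with_seed(2, {
    for (i in 1:200) {
      ch <- matrix(sample(0:255, 64, TRUE), 8, 8)
      mask <- matrix(runif(64) < 0.4, 8, 8)
      if (!any(mask)) mask[1, 1] <- TRUE
      s <- measure_mask(ch, mask)
      acc <- c(); tot <- 0
      for (r in 1:8) for (cc in 1:8) if (mask[r, cc]) {
        acc <- c(acc, ch[r, cc]); tot <- tot + ch[r, cc]
      }
      expect_identical(s$intden, tot)
      expect_equal(s$min, min(acc)); expect_equal(s$max, max(acc))
      expect_equal(s$mean, tot / length(acc))
      expect_equal(s$area_px, length(acc))
    }
  })
})

test_that("measure_mask rejects empty masks and shape mismatches", {
  ch <- matrix(1, 8, 8)
  expect_error(measure_mask(ch, matrix(FALSE, 8, 8)), "empty mask")
  expect_error(measure_mask(ch, matrix(TRUE, 4, 4)), "shape")
})

test_that("quantify_field handles the no-Golgi and all-Golgi limits", {
  rep_ch <- matrix(0, 64, 64); rep_ch[5:54, 5:54] <- 50
  f <- field_from_channels(matrix(0, 64, 64), matrix(0, 64, 64), rep_ch)
  cells <- segment_cells(f, make_threshold(5),
                         segmentation_params(closing_radius_px = 0))

  no_golgi <- quantify_field(f, partition_all_cells(cells,
                                                    matrix(FALSE, 64, 64)))
  whole <- no_golgi[no_golgi$region == "whole_cell", ]
  outg <- no_golgi[no_golgi$region == "out_golgi", ]
  ing <- no_golgi[no_golgi$region == "in_golgi", ]
  expect_equal(outg[c("min", "max", "mean", "intden", "area_px")],
               whole[c("min", "max", "mean", "intden", "area_px")],
               ignore_attr = TRUE)
  expect_equal(ing$area_px, 0)
  expect_equal(ing$intden, 0)
  expect_true(is.na(ing$mean))
  expect_length(attr(no_golgi, "empty_regions"), 1L)

  all_golgi <- quantify_field(f, partition_all_cells(cells,
                                                     matrix(TRUE, 64, 64)))
  expect_equal(all_golgi[all_golgi$region == "in_golgi",
                         c("min", "max", "mean", "intden", "area_px")],
               all_golgi[all_golgi$region == "whole_cell",
                         c("min", "max", "mean", "intden", "area_px")],
               ignore_attr = TRUE)
})

test_that("in + out integrated density is conserved exactly on scenes", {
  sc <- generate_scene(scene_params(seed = 5))
  ctl <- generate_control_scene(scene_params(seed = 5))
  seg <- segment_scene(sc, ctl)
  tab <- quantify_field(sc$field, seg$partitions)
  for (cid in unique(tab$cell_id)) {
    r <- tab[tab$cell_id == cid, ]
    expect_identical(r$intden[r$region == "in_golgi"] +
                       r$intden[r$region == "out_golgi"],
                     r$intden[r$region == "whole_cell"])
    expect_identical(r$area_px[r$region == "in_golgi"] +
                       r$area_px[r$region == "out_golgi"],
                     r$area_px[r$region == "whole_cell"])
  }
})

test_that("scaling the reporter channel scales every summary linearly", {
  sc <- generate_scene(small_scene(seed = 6))
  ctl <- generate_control_scene(small_scene(seed = 6))
  seg <- segment_scene(sc, ctl)
  tab1 <- quantify_field(sc$field, seg$partitions)
  scaled <- sc$field
  scaled$pixels[, , scaled$channel_roles[["reporter"]]] <-
    scaled$pixels[, , scaled$channel_roles[["reporter"]]] * 3
  tab3 <- quantify_field(scaled, seg$partitions)
  nonempty <- tab1$area_px > 0
  for (col in c("min", "max", "mean", "intden"))
    expect_equal(tab3[[col]][nonempty], 3 * tab1[[col]][nonempty])
})

test_that("condition aggregation treats the image as the replication unit", {
  mk_tab <- function(fid, intdens) as_measurement_table(do.call(rbind,
    lapply(seq_along(intdens), function(i) data.frame(
      field_id = fid, cell_id = i,
      region = c("whole_cell", "in_golgi", "out_golgi"),
      min = 0, max = 1, mean = 0.5,
      intden = c(intdens[i], intdens[i], 0),
      area_px = c(10, 5, 5)))))
  meta <- function(cond) list(condition_id = cond, is_control = FALSE)

  # two images with one cell each at IntDen 100: mean 100, sd 0
  s <- summarize_condition(list(
    list(meta = meta("c1"), table = mk_tab("i1", 100)),
    list(meta = meta("c1"), table = mk_tab("i2", 100))))
  row <- s[s$region == "in_golgi", ]
  expect_equal(row$mean_intden, 100); expect_equal(row$sd_intden, 0)
  expect_equal(row$n_images, 2); expect_equal(row$n_cells, 2)

  # image-level values {10, 30}: mean 20, sample SD sqrt(200)
  s2 <- summarize_condition(list(
    list(meta = meta("c1"), table = mk_tab("i1", c(5, 15))),
    list(meta = meta("c1"), table = mk_tab("i2", 30))))
  row2 <- s2[s2$region == "in_golgi", ]
  expect_equal(row2$mean_intden, 20)
  expect_equal(row2$sd_intden, sqrt(200))  # 14.142...
})

test_that("aggregation matches an independent oracle on ground truth", {
  # feed summarize_condition tables built from planted per-cell expected
  # IntDen, and recompute mean-over-cells / mean-and-SD-over-images by hand
  entries <- list(); truth_vals <- list()
  for (s in 1:4) {
    sc <- generate_scene(small_scene(seed = s))
    pc <- sc$truth$per_cell
    rows <- do.call(rbind, lapply(seq_len(nrow(pc)), function(i) data.frame(
      field_id = paste0("img", s), cell_id = i,
      region = c("whole_cell", "in_golgi", "out_golgi"),
      min = 0, max = 1, mean = 0.5,
      intden = c(pc$exp_intden_whole[i], pc$exp_intden_in[i],
                 pc$exp_intden_out[i]),
      area_px = c(pc$area_cell[i], pc$area_golgi[i],
                  pc$area_cell[i] - pc$area_golgi[i]))))
    entries[[s]] <- list(meta = list(condition_id = "truth"),
                         table = as_measurement_table(rows))
    truth_vals[[s]] <- pc$exp_intden_in
  }
  s <- summarize_condition(entries)
  img_means <- vapply(truth_vals, mean, numeric(1))
  row <- s[s$region == "in_golgi", ]
  expect_equal(row$mean_intden, mean(img_means))
  expect_equal(row$sd_intden, sd(img_means))
  expect_equal(row$n_images, 4)
  expect_equal(row$n_cells, sum(lengths(truth_vals)))
})

test_that("a condition with zero measured cells is flagged, not zeroed", {
  empty_tab <- as_measurement_table(data.frame(
    field_id = character(0), cell_id = integer(0), region = character(0),
    min = numeric(0), max = numeric(0), mean = numeric(0),
    intden = numeric(0), area_px = numeric(0)))
  s <- summarize_condition(list(list(meta = list(condition_id = "c"),
                                     table = empty_tab)))
  expect_true(all(is.na(s$mean_intden)))
  expect_true(all(s$n_cells == 0))
  expect_true(length(attr(s, "flags")) > 0)
})

test_that("golgi fraction estimator obeys symmetry and boundaries", {
  mk_sum <- function(cond, reg, intden, area) data.frame(
    condition_id = cond, region = reg, mean_intden = intden,
    sd_intden = 0, n_images = 2, n_cells = 4, mean_area_px = area)
  s_in <- mk_sum("c", "in_golgi", 500, 100)
  s_out <- mk_sum("c", "out_golgi", 500, 100)
  expect_equal(estimate_golgi_fraction(s_in, s_out, 0), 0.5)
  # equal background-corrected signals after unequal areas
  s_out2 <- mk_sum("c", "out_golgi", 900, 500)
  expect_equal(estimate_golgi_fraction(s_in, s_out2, 1),
               400 / (400 + 400))
  # out region zero after correction -> 1
  s_out3 <- mk_sum("c", "out_golgi", 100, 100)
  expect_equal(estimate_golgi_fraction(s_in, s_out3, 1), 1)
  expect_error(estimate_golgi_fraction(mk_sum("c", "in_golgi", 10, 10),
                                       mk_sum("c", "out_golgi", 10, 10), 1),
               "undefined")
  expect_error(estimate_golgi_fraction(s_in,
                                       mk_sum("d", "out_golgi", 1, 1), 0),
               "different conditions")
  # scale equivariance: scaling signal and background together is neutral
  f1 <- estimate_golgi_fraction(s_in, s_out2, 1)
  s_in_c <- s_in; s_in_c$mean_intden <- s_in$mean_intden * 5
  s_out_c <- s_out2; s_out_c$mean_intden <- s_out2$mean_intden * 5
  expect_equal(estimate_golgi_fraction(s_in_c, s_out_c, 5), f1)
})
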