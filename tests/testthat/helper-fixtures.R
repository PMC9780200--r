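# Fixtures are built in code; scenes used by unit tests are smaller than the
# package defaults purely to keep single-module checks quick.

small_scene <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(shape = c(256, 256), n_cells = 3, cell_radius_px = c(20, 28),
         seed = seed),
    list(...))
  do.call(scene_params, args)
}

# a constant-valued 3-channel field
const_field <- function(value, shape = c(32, 32), condition_id = "cond",
                        is_control = FALSE, replicate = 1) {
  px <- array(value, dim = c(shape[1], shape[2], 3))
  fluorescence_field(px, c(nuclei = 1, golgi_marker = 2, reporter = 3),
                     list(condition_id = condition_id,
                          is_control = is_control, replicate = replicate))
}

# field with explicit channel matrices
field_from_channels <- function(nuclei, marker, reporter,
                                condition_id = "cond", is_control = FALSE) {
  px <- array(0, dim = c(nrow(reporter), ncol(reporter), 3))
  px[, , 1] <- nuclei; px[, , 2] <- marker; px[, , 3] <- reporter
  fluorescence_field(px, c(nuclei = 1, golgi_marker = 2, reporter = 3),
                     list(condition_id = condition_id,
                          is_control = is_control))
}

# threshold model with an exact cutoff, built through the public API
# (constant control field, mean + 0*SD rule)
make_threshold <- function(cutoff, condition_id = "cond") {
  ctl <- const_field(cutoff, condition_id = condition_id, is_control = TRUE)
  derive_background_threshold(list(ctl),
                              threshold_rule("mean_plus_ksd", parameter = 0))
}

# Jaccard overlap of two masks
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# segment a scene end-to-end against its matched control, return the pieces
segment_scene <- function(scene, control, seg = segmentation_params(),
                          rule = threshold_rule()) {
  thr <- derive_background_threshold(list(control$field), rule)
  cells <- segment_cells(scene$field, thr, seg)
  golgi <- segment_golgi(scene$field, cells)
  list(threshold = thr, cells = cells, golgi = golgi,
       partitions = partition_all_cells(cells, golgi))
}
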