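#' Derive the background threshold from negative-control fields
#'
#' The reporter channel of negative-control acquisitions (cells fed the
#' natural sugar, so any streptavidin signal is nonspecific binding) defines
#' the per-condition background cutoff. Pixels of all control fields are
#' pooled and the cutoff is either a high percentile of the pooled values
#' (default: 99.5th, quantile type 7) or mean + k * SD (sample SD).
#'
#' @param control_fields list of [fluorescence_field()]s, all with
#'   `meta$is_control = TRUE` and a common `condition_id`.
#' @param rule list with `method` (`"percentile"` or `"mean_plus_ksd"`) and
#'   `parameter` (the percentile p, default 99.5, or the multiplier k,
#'   default 3).
#' @return an object of class `threshold_model`: `condition_id`, `cutoff`,
#'   `rule`, `n_control_pixels`.
#' @export
derive_background_threshold <- function(control_fields,
                                        rule = threshold_rule()) {
  if (!is.list(control_fields) || length(control_fields) == 0 ||
      !all(vapply(control_fields, inherits, logical(1), "fluorescence_field")))
    stop("`control_fields` must be a non-empty list of fluorescence fields",
         call. = FALSE)
  if (!all(vapply(control_fields, function(f) f$meta$is_control, logical(1))))
    stop("all control fields must have meta$is_control = TRUE", call. = FALSE)
  cond <- unique(vapply(control_fields, function(f) f$meta$condition_id,
                        character(1)))
  if (length(cond) != 1L)
    stop("control fields span multiple condition_ids: ",
         paste(cond, collapse = ", "), call. = FALSE)
  rule <- validate_threshold_rule(rule)
  px <- unlist(lapply(control_fields, function(f)
    as.numeric(field_channel(f, "reporter"))), use.names = FALSE)
  cutoff <- switch(rule$method,
    percentile = stats::quantile(px, rule$parameter / 100, type = 7,
                                 names = FALSE),
    mean_plus_ksd = mean(px) + rule$parameter * stats::sd(px))
  if (length(px) == 1L && rule$method == "mean_plus_ksd") cutoff <- px  # SD undefined
  structure(list(condition_id = cond, cutoff = as.numeric(cutoff),
                 rule = rule, n_control_pixels = length(px)),
            class = "threshold_model")
}

#' @rdname derive_background_threshold
#' @param method threshold rule name.
#' @param parameter rule parameter; defaults to 99.5 for `percentile` and 3
#'   for `mean_plus_ksd`.
#' @export
threshold_rule <- function(method = c("percentile", "mean_plus_ksd"),
                           parameter = NULL) {
  method <- match.arg(method)
  if (is.null(parameter))
    parameter <- if (method == "percentile") 99.5 else 3
  validate_threshold_rule(list(method = method, parameter = parameter))
}

validate_threshold_rule <- function(rule) {
  if (!is.list(rule) || is.null(rule$method) || is.null(rule$parameter))
    stop("threshold rule needs `method` and `parameter`", call. = FALSE)
  rule$method <- match.arg(rule$method, c("percentile", "mean_plus_ksd"))
  rule$parameter <- as.numeric(rule$parameter)
  if (rule$method == "percentile" &&
      (rule$parameter <= 0 || rule$parameter >= 100))
    stop("percentile parameter must be in (0, 100)", call. = FALSE)
  if (rule$method == "mean_plus_ksd" && rule$parameter < 0)
    stop("k must be >= 0", call. = FALSE)
  rule
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> condition %s: cutoff %.4g (%s %.4g, %d control px)\n",
              x$condition_id, x$cutoff, x$rule$method, x$rule$parameter,
              x$n_control_pixels))
  invisible(x)
}

#' Default whole-cell segmentation parameters
#'
#' Defaults are sized for 512 x 512 fields with cell radii of 25-40 px.
#'
#' @param min_area_px smallest object kept, in pixels.
#' @param closing_radius_px disc radius of the morphological closing.
#' @param use_nuclei_seeds split touching cells with nucleus-seeded
#'   propagation.
#' @param exclude_border drop cells touching the image border.
#' @return list of segmentation parameters.
#' @export
segmentation_params <- function(min_area_px = 500, closing_radius_px = 2,
                                use_nuclei_seeds = FALSE,
                                exclude_border = FALSE) {
  list(min_area_px = min_area_px, closing_radius_px = closing_radius_px,
       use_nuclei_seeds = isTRUE(use_nuclei_seeds),
       exclude_border = isTRUE(exclude_border))
}

#' Segment whole-cell ROIs from the thresholded reporter channel
#'
#' Mirrors the ImageJ-style measurement workflow: the binary foreground is
#' `reporter > cutoff`, cleaned by a morphological closing (disc), hole
#' filling, and removal of objects below `min_area_px`; connected components
#' are labeled with 4-connectivity. Optionally, touching cells are split by
#' propagation from nucleus-channel seeds (Otsu on the nuclei channel).
#'
#' @param field a [fluorescence_field()].
#' @param threshold a `threshold_model` for the same condition.
#' @param params see [segmentation_params()].
#' @return an object of class `cell_label_map`: integer `labels` matrix
#'   (0 = background, k >= 1 = cell k, consecutively numbered) and
#'   `min_area_px`.
#' @export
segment_cells <- function(field, threshold, params = segmentation_params()) {
  stopifnot(inherits(field, "fluorescence_field"),
            inherits(threshold, "threshold_model"))
  if (!identical(field$meta$condition_id, threshold$condition_id))
    stop("field condition (", field$meta$condition_id,
         ") does not match threshold condition (", threshold$condition_id,
         ")", call. = FALSE)
  reporter <- field_channel(field, "reporter")
  fg <- reporter > threshold$cutoff
  mask <- fg * 1
  if (params$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$closing_radius_px) + 1L,
                                shape = "disc")
    mask <- EBImage::closing(mask, brush)
  }
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(mask)          # 4-connected components
  labels <- matrix(as.integer(round(as.numeric(labels))), nrow = nrow(reporter))

  if (params$use_nuclei_seeds && max(labels) > 0) {
    labels <- split_by_nuclei(field, labels)
  }
  if (params$exclude_border && max(labels) > 0) {
    border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)]))
    labels[labels %in% setdiff(border_ids, 0L)] <- 0L
  }
  labels <- filter_relabel(labels, params$min_area_px)
  structure(list(labels = labels, min_area_px = params$min_area_px,
                 cutoff = threshold$cutoff,
                 foreground_fraction = mean(fg)),
            class = "cell_label_map")
}

# nucleus-seeded split of touching foreground objects (Voronoi-style
# propagation on the reporter intensity landscape)
split_by_nuclei <- function(field, labels) {
  nuc <- field_channel(field, "nuclei")
  rng <- range(nuc)
  if (rng[2] <= rng[1]) return(labels)
  nuc01 <- (nuc - rng[1]) / (rng[2] - rng[1])
  cut <- EBImage::otsu(EBImage::Image(nuc01))
  seeds <- EBImage::bwlabel((nuc01 > cut) & (labels > 0))
  seeds <- matrix(as.integer(round(as.numeric(seeds))), nrow = nrow(nuc))
  if (max(seeds) == 0L) return(labels)
  rep01 <- field_channel(field, "reporter")
  rep01 <- rep01 / max(rep01, 1)
  prop <- EBImage::propagate(EBImage::Image(rep01), seeds = seeds,
                             mask = labels > 0)
  prop <- matrix(as.integer(round(as.numeric(prop))), nrow = nrow(nuc))
  # components that received no seed keep their original identity
  orphan <- labels > 0 & prop == 0L
  prop[orphan] <- labels[orphan] + max(seeds)
  prop
}

filter_relabel <- function(labels, min_area_px) {
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0L], nbins = max(labels))
    keep <- which(areas >= min_area_px)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  labels
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d cell(s), min area %d px\n",
              max(x$labels), as.integer(x$min_area_px)))
  invisible(x)
}

#' Number of labeled cells
#' @param cells a `cell_label_map`.
#' @return integer count of labeled objects.
#' @export
n_cells <- function(cells) {
  stopifnot(inherits(cells, "cell_label_map"))
  max(cells$labels)
}

#' Segment Golgi ROIs from the Golgi-marker channel
#'
#' Thresholds the TGN46 marker channel restricted to pixels inside cell
#' ROIs. The default method is Otsu computed on the in-cell marker
#' histogram; `"percentile"` keeps marker pixels above the given in-cell
#' percentile. Components smaller than `min_golgi_area_px` are discarded.
#' The result is always a subset of the union of cell ROIs; an empty cell
#' map yields an empty mask.
#'
#' @param field a [fluorescence_field()].
#' @param cells a `cell_label_map` derived from the same field.
#' @param method `"otsu"` or `"percentile"`.
#' @param percentile in-cell marker percentile for `method = "percentile"`.
#' @param min_golgi_area_px smallest Golgi component kept.
#' @return logical H x W mask.
#' @export
segment_golgi <- function(field, cells, method = c("otsu", "percentile"),
                          percentile = 90, min_golgi_area_px = 20) {
  stopifnot(inherits(field, "fluorescence_field"),
            inherits(cells, "cell_label_map"))
  marker <- field_channel(field, "golgi_marker")
  if (!identical(dim(marker), dim(cells$labels)))
    stop("cell map shape does not match the field", call. = FALSE)
  method <- match.arg(method)
  incell <- cells$labels > 0L
  empty <- matrix(FALSE, nrow(marker), ncol(marker))
  if (!any(incell)) return(empty)
  vals <- marker[incell]
  if (max(vals) <= min(vals)) return(empty)
  cutoff <- if (method == "otsu") {
    v01 <- (vals - min(vals)) / (max(vals) - min(vals))
    c01 <- EBImage::otsu(EBImage::Image(matrix(v01, nrow = 1)))
    min(vals) + c01 * (max(vals) - min(vals))
  } else {
    stats::quantile(vals, percentile / 100, type = 7, names = FALSE)
  }
  golgi <- incell & (marker > cutoff)
  if (min_golgi_area_px > 1 && any(golgi)) {
    comp <- EBImage::bwlabel(golgi * 1)
    comp <- matrix(as.integer(round(as.numeric(comp))), nrow = nrow(marker))
    areas <- tabulate(comp[comp > 0L], nbins = max(comp))
    golgi <- golgi & matrix(areas[pmax(comp, 1L)] >= min_golgi_area_px &
                              comp > 0L, nrow = nrow(marker))
  }
  golgi
}

#' Partition one cell into in-Golgi and out-of-Golgi regions
#'
#' `in_golgi` is the intersection of the cell ROI with the Golgi mask;
#' `out_golgi` is the remainder of the cell ROI. By construction the two
#' masks are disjoint and their union is exactly the cell ROI.
#'
#' @param cells a `cell_label_map`.
#' @param golgi logical Golgi mask of the same shape.
#' @param cell_id integer label present in `cells`.
#' @return an object of class `roi_partition`: `cell_id`, `in_golgi`,
#'   `out_golgi` logical masks.
#' @export
partition_cell <- function(cells, golgi, cell_id) {
  stopifnot(inherits(cells, "cell_label_map"))
  if (!identical(dim(golgi), dim(cells$labels)))
    stop("golgi mask shape does not match the cell map", call. = FALSE)
  cell_id <- as.integer(cell_id)
  cell_mask <- cells$labels == cell_id
  if (!any(cell_mask))
    stop("unknown cell_id: ", cell_id, call. = FALSE)
  structure(list(cell_id = cell_id,
                 in_golgi = cell_mask & golgi,
                 out_golgi = cell_mask & !golgi),
            class = "roi_partition")
}

#' Partition every cell of a label map
#'
#' @inheritParams partition_cell
#' @return list of [partition_cell()] results, one per labeled cell.
#' @export
partition_all_cells <- function(cells, golgi) {
  lapply(seq_len(n_cells(cells)), function(k) partition_cell(cells, golgi, k))
}
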