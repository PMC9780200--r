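#' Summarize the raw signal inside a region mask
#'
#' Computes min, max and mean grey value and the integrated density
#' (IntDen = plain pixel-value sum; with pixel calibration fixed at 1 this
#' equals mean x area) over the masked pixels of the *raw* channel. The
#' threshold used to build the geometry never touches the measured values.
#'
#' @param channel numeric H x W matrix of raw grey values.
#' @param mask logical H x W mask; must be non-empty.
#' @return an object of class `signal_summary`:
#'   `min`, `max`, `mean`, `intden`, `area_px`.
#' @export
measure_mask <- function(channel, mask) {
  if (!is.matrix(channel) || !is.logical(mask))
    stop("`channel` must be a matrix and `mask` a logical mask", call. = FALSE)
  if (!identical(dim(channel), dim(mask)))
    stop("mask shape does not match the channel", call. = FALSE)
  if (!any(mask))
    stop("empty mask: no pixels to measure", call. = FALSE)
  v <- as.numeric(channel[mask])
  structure(list(min = min(v), max = max(v), mean = mean(v),
                 intden = sum(v), area_px = length(v)),
            class = "signal_summary")
}

empty_summary <- function() {
  structure(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                 intden = 0, area_px = 0L),
            class = "signal_summary")
}

#' Measure the reporter channel over every cell partition of a field
#'
#' For each cell, emits whole_cell, in_golgi and out_golgi rows of
#' reporter-channel summaries. An empty region (e.g. a cell with no detected
#' Golgi) is recorded with `area_px = 0`, `intden = 0` and NA min/max/mean,
#' and the affected cells are flagged in the `empty_regions` attribute, so
#' that per-cell conservation intden(in) + intden(out) = intden(whole cell)
#' holds exactly for every row group.
#'
#' @param field a [fluorescence_field()].
#' @param partitions list of `roi_partition`s from [partition_all_cells()].
#' @param field_id identifier written into the table; defaults to the
#'   condition id with the replicate appended.
#' @return a measurement table (see [as_measurement_table()]).
#' @export
quantify_field <- function(field, partitions, field_id = NULL) {
  stopifnot(inherits(field, "fluorescence_field"))
  if (is.null(field_id))
    field_id <- paste0(field$meta$condition_id, "_r", field$meta$replicate)
  reporter <- field_channel(field, "reporter")
  rows <- list()
  empty_flags <- character(0)
  for (p in partitions) {
    if (!inherits(p, "roi_partition"))
      stop("`partitions` must contain roi_partition objects", call. = FALSE)
    if (!identical(dim(p$in_golgi), dim(reporter)))
      stop("partition shape does not match the field", call. = FALSE)
    whole <- p$in_golgi | p$out_golgi
    summaries <- list(
      whole_cell = measure_mask(reporter, whole),
      in_golgi  = if (any(p$in_golgi)) measure_mask(reporter, p$in_golgi)
                  else empty_summary(),
      out_golgi = if (any(p$out_golgi)) measure_mask(reporter, p$out_golgi)
                  else empty_summary())
    for (reg in names(summaries)) {
      s <- summaries[[reg]]
      if (s$area_px == 0)
        empty_flags <- c(empty_flags, paste0(field_id, "/cell", p$cell_id,
                                             "/", reg))
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = field_id, cell_id = p$cell_id, region = reg,
        min = s$min, max = s$max, mean = s$mean,
        intden = s$intden, area_px = s$area_px,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(0), cell_id = integer(0),
               region = character(0), min = numeric(0), max = numeric(0),
               mean = numeric(0), intden = numeric(0), area_px = numeric(0))
  tab <- as_measurement_table(tab)
  attr(tab, "empty_regions") <- empty_flags
  tab
}

#' Aggregate integrated densities per condition and region
#'
#' The image is the replication unit: for each image the per-cell IntDen
#' values of a region are averaged, then `mean_intden` and `sd_intden`
#' (sample SD, n - 1) are computed over the image-level values. SD is
#' reported only when at least two images are available; a condition with
#' zero measured cells is returned with `n_cells = 0` and NA means (flagged
#' in the `flags` attribute), never silently zero.
#'
#' @param tables list of entries `list(meta = <field meta>, table =
#'   <measurement table>)`, one per image.
#' @param regions regions to summarize (default in_golgi and out_golgi).
#' @return data.frame of class `condition_summary` with columns
#'   `condition_id, region, mean_intden, sd_intden, n_images, n_cells,
#'   mean_area_px`.
#' @export
summarize_condition <- function(tables, regions = c("in_golgi", "out_golgi")) {
  if (!length(tables))
    stop("need at least one (meta, table) entry", call. = FALSE)
  conds <- vapply(tables, function(x) x$meta$condition_id, character(1))
  out <- list(); flags <- character(0)
  for (cond in unique(conds)) {
    sel <- tables[conds == cond]
    for (reg in regions) {
      img_means <- vapply(sel, function(x) {
        rows <- x$table[x$table$region == reg, , drop = FALSE]
        if (nrow(rows) == 0) NA_real_ else mean(rows$intden)
      }, numeric(1))
      cellcounts <- vapply(sel, function(x)
        sum(x$table$region == reg & x$table$area_px > 0), numeric(1))
      areas <- unlist(lapply(sel, function(x)
        x$table$area_px[x$table$region == reg]))
      n_img <- sum(!is.na(img_means))
      n_cell <- sum(cellcounts)
      if (n_cell == 0) {
        flags <- c(flags, paste0(cond, "/", reg, ": no measured cells"))
        mean_id <- NA_real_; sd_id <- NA_real_
        n_img <- length(sel)
      } else {
        vals <- img_means[!is.na(img_means)]
        mean_id <- mean(vals)
        sd_id <- if (n_img >= 2) stats::sd(vals) else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        condition_id = cond, region = reg,
        mean_intden = mean_id, sd_intden = sd_id,
        n_images = n_img, n_cells = n_cell,
        mean_area_px = if (length(areas)) mean(areas) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("condition_summary", "data.frame")
  attr(res, "flags") <- flags
  res
}

#' Estimate the in-Golgi fraction of the reporter signal
#'
#' Background-corrects the mean in-Golgi and out-of-Golgi integrated
#' densities of a condition and returns the in-Golgi share
#' `B_in / (B_in + B_out)` with
#' `B_region = max(0, mean_intden - background_per_px * mean_area_px)`.
#' Used to validate the pipeline against planted ground truth.
#'
#' @param summary_in,summary_out single rows of a
#'   [summarize_condition()] result for the in_golgi and out_golgi regions
#'   of the same condition.
#' @param background_per_px expected background grey value per pixel
#'   (>= 0).
#' @param areas optional list with `in_` and `out` mean areas overriding
#'   the `mean_area_px` columns.
#' @return the estimated fraction in `[0, 1]`.
#' @export
estimate_golgi_fraction <- function(summary_in, summary_out,
                                    background_per_px, areas = NULL) {
  if (background_per_px < 0)
    stop("background_per_px must be >= 0", call. = FALSE)
  if (!identical(summary_in$condition_id, summary_out$condition_id))
    stop("summaries belong to different conditions", call. = FALSE)
  area_in <- if (is.null(areas)) summary_in$mean_area_px else areas$in_
  area_out <- if (is.null(areas)) summary_out$mean_area_px else areas$out
  b_in <- max(0, summary_in$mean_intden - background_per_px * area_in)
  b_out <- max(0, summary_out$mean_intden - background_per_px * area_out)
  if (b_in + b_out == 0)
    stop("undefined fraction: both regions are zero after background ",
         "correction", call. = FALSE)
  b_in / (b_in + b_out)
}
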