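CHANNEL_ROLES <- c("nuclei", "golgi_marker", "reporter")
MEASUREMENT_COLS <- c("field_id", "cell_id", "region",
                      "min", "max", "mean", "intden", "area_px")
REGIONS <- c("in_golgi", "out_golgi", "whole_cell")

#' Construct a multi-channel fluorescence field
#'
#' A `fluorescence_field` holds one single-z-plane acquisition as an
#' H x W x C array of raw grey values together with a mapping from the three
#' biological roles (`nuclei` = DAPI, `golgi_marker` = TGN46 immunostain,
#' `reporter` = streptavidin detecting the click-labeled glycoconjugates) to
#' channel indices, plus acquisition metadata. Grey values are kept exactly
#' as acquired; no rescaling or gamma is ever applied.
#'
#' @param pixels numeric array, `dim = c(H, W, C)` with `C >= 3`,
#'   all values >= 0, both spatial dimensions >= 16. A plain H x W matrix is
#'   accepted for single-channel arrays only in internal use; user-facing
#'   fields always carry three roles.
#' @param channel_roles named integer vector mapping each of
#'   `"nuclei"`, `"golgi_marker"`, `"reporter"` to a distinct 1-based
#'   channel index.
#' @param meta list with elements `condition_id`, `cell_line`, `analog`,
#'   `timepoint_h`, `replicate` (integer >= 1) and `is_control` (logical).
#'   Missing entries are filled with neutral defaults; `condition_id`
#'   defaults to `"<cell_line>_<analog>_<timepoint_h>h"`.
#' @return an object of class `fluorescence_field`.
#' @export
fluorescence_field <- function(pixels, channel_roles, meta = list()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be a 3-dimensional array (H x W x C)", call. = FALSE)
  storage.mode(pixels) <- "double"
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L)
    stop("both spatial dimensions must be >= 16", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("all pixel values must be finite and >= 0", call. = FALSE)
  channel_roles <- validate_channel_roles(channel_roles, n_channels = d[3])
  meta <- normalize_field_meta(meta)
  structure(list(pixels = pixels, channel_roles = channel_roles, meta = meta),
            class = "fluorescence_field")
}

validate_channel_roles <- function(channel_roles, n_channels) {
  if (is.null(names(channel_roles)) ||
      !setequal(names(channel_roles), CHANNEL_ROLES))
    stop("`channel_roles` must be named with exactly: ",
         paste(CHANNEL_ROLES, collapse = ", "), call. = FALSE)
  channel_roles <- as.integer(channel_roles[CHANNEL_ROLES])
  names(channel_roles) <- CHANNEL_ROLES
  if (anyNA(channel_roles) || any(channel_roles < 1L))
    stop("channel indices must be positive integers", call. = FALSE)
  if (anyDuplicated(channel_roles))
    stop("duplicate channel index: each role must map to a distinct channel",
         call. = FALSE)
  if (any(channel_roles > n_channels))
    stop("channel index exceeds the number of channels (", n_channels, ")",
         call. = FALSE)
  channel_roles
}

normalize_field_meta <- function(meta) {
  defaults <- list(cell_line = "unknown", analog = "unknown",
                   timepoint_h = NA_real_, replicate = 1L,
                   is_control = FALSE)
  meta <- utils::modifyList(defaults, meta)
  meta$replicate <- as.integer(meta$replicate)
  if (is.na(meta$replicate) || meta$replicate < 1L)
    stop("`replicate` must be an integer >= 1", call. = FALSE)
  meta$is_control <- isTRUE(meta$is_control)
  if (is.null(meta$condition_id))
    meta$condition_id <- paste0(meta$cell_line, "_", meta$analog, "_",
                                meta$timepoint_h, "h")
  meta
}

#' Extract one channel of a field by role
#'
#' @param field a [fluorescence_field()].
#' @param role one of `"nuclei"`, `"golgi_marker"`, `"reporter"`.
#' @return the H x W numeric matrix of raw grey values for that role.
#' @export
field_channel <- function(field, role) {
  stopifnot(inherits(field, "fluorescence_field"))
  role <- match.arg(role, CHANNEL_ROLES)
  field$pixels[, , field$channel_roles[[role]]]
}

#' @export
print.fluorescence_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fluorescence_field> %dx%d px, %d channel(s)\n", d[1], d[2], d[3]))
  cat("  roles: ", paste(names(x$channel_roles), x$channel_roles,
                         sep = "=", collapse = " "), "\n")
  cat(sprintf("  condition: %s%s\n", x$meta$condition_id,
              if (x$meta$is_control) " (negative control)" else ""))
  invisible(x)
}

#' Read a multi-channel fluorescence field from a TIFF file
#'
#' Channels are stored one per TIFF page (grayscale), which preserves raw
#' integer grey values exactly. Multi-sample (e.g. RGB-interleaved) pages and
#' z-stacks disguised as extra pages beyond the mapped channels are rejected
#' rather than projected: quantification is strictly per single z-plane.
#'
#' @param path path to a TIFF/OME-TIFF file written by [save_field()] or any
#'   writer producing one grayscale page per channel.
#' @param channel_roles role map as in [fluorescence_field()].
#' @param meta metadata list as in [fluorescence_field()].
#' @return a [fluorescence_field()] with grey values unmodified.
#' @export
load_field <- function(path, channel_roles, meta = list()) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("format error: expected one grayscale page per channel ",
         "(multi-sample pages are not supported)", call. = FALSE)
  roles <- validate_channel_roles(channel_roles, n_channels = length(pages))
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
    stop("format error: channel pages differ in shape", call. = FALSE)
  pixels <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) pixels[, , k] <- as.numeric(pages[[k]])
  fluorescence_field(pixels, roles, meta)
}

#' Write a fluorescence field as a multi-page TIFF
#'
#' Grey values must be integers in `[0, 65535]` (8- or 16-bit unsigned
#' acquisition model); they are stored losslessly as 16-bit pages so that
#' [load_field()] returns a pixel-identical array.
#'
#' @param field a [fluorescence_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_field <- function(field, path) {
  stopifnot(inherits(field, "fluorescence_field"))
  px <- field$pixels
  if (any(px != round(px)) || any(px > 65535))
    stop("save_field() stores 16-bit unsigned data: grey values must be ",
         "integers in [0, 65535]", call. = FALSE)
  pages <- lapply(seq_len(dim(px)[3]), function(k) px[, , k] / 65535)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to ", path, call. = FALSE)
  invisible(path)
}

#' Validate a measurement table
#'
#' A measurement table has one row per (field, cell, region) with the raw
#' reporter-channel summaries min/max/mean grey value, integrated density
#' (IntDen, the plain pixel-value sum at unit pixel calibration) and region
#' area in pixels. For every (field_id, cell_id) the in_golgi and out_golgi
#' rows exist exactly when the whole_cell row exists; empty regions carry
#' area_px = 0, intden = 0 and NA min/max/mean.
#'
#' @param table data.frame with columns
#'   `field_id, cell_id, region, min, max, mean, intden, area_px`.
#' @return the validated data.frame (invisibly classed
#'   `measurement_table`).
#' @export
as_measurement_table <- function(table) {
  if (!is.data.frame(table))
    stop("measurement table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  table <- table[MEASUREMENT_COLS]
  if (nrow(table)) {
    if (!all(table$region %in% REGIONS))
      stop("region must be one of: ", paste(REGIONS, collapse = ", "),
           call. = FALSE)
    if (any(table$area_px < 0))
      stop("area_px must be >= 0", call. = FALSE)
    key <- paste(table$field_id, table$cell_id)
    for (k in unique(key)) {
      regs <- table$region[key == k]
      if (("whole_cell" %in% regs) !=
          all(c("in_golgi", "out_golgi") %in% regs))
        stop("in_golgi/out_golgi rows must exist iff the whole_cell row ",
             "exists (cell ", k, ")", call. = FALSE)
    }
  }
  class(table) <- c("measurement_table", "data.frame")
  table
}

#' Write a measurement table to CSV
#'
#' The CSV has the fixed header
#' `field_id,cell_id,region,min,max,mean,intden,area_px`; reloading with
#' [read_measurement_table()] reproduces every numeric cell exactly for
#' integers and to better than 1e-9 relative for reals (values are written
#' with 15 significant digits).
#'
#' @param table a measurement table (see [as_measurement_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_table <- function(table, path) {
  table <- as_measurement_table(table)
  ok <- try(utils::write.csv(as.data.frame(table), path, row.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write CSV to ", path, call. = FALSE)
  invisible(path)
}

#' Read a measurement table written by [save_table()]
#'
#' @param path CSV path.
#' @return a validated measurement table.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, colClasses = c(
    field_id = "character", cell_id = "integer", region = "character",
    min = "numeric", max = "numeric", mean = "numeric",
    intden = "numeric", area_px = "numeric"))
  as_measurement_table(tab)
}
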