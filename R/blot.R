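#' Construct lane densitometry records for one blot
#'
#' Each lane carries its biotin-signal density and its Ponceau-red
#' (total-protein loading stain) density; exactly one lane per blot group is
#' the reference against which relative intensities are expressed.
#'
#' @param lane_id character labels, unique.
#' @param biotin_density numeric >= 0.
#' @param ponceau_density numeric > 0.
#' @param is_reference logical; exactly one `TRUE`.
#' @param blot_id blot group label.
#' @return data.frame of class `lane_records`.
#' @export
lane_records <- function(lane_id, biotin_density, ponceau_density,
                         is_reference, blot_id = "blot1") {
  n <- length(lane_id)
  if (length(biotin_density) != n || length(ponceau_density) != n ||
      length(is_reference) != n)
    stop("all lane vectors must have equal length", call. = FALSE)
  if (anyDuplicated(lane_id))
    stop("lane_id values must be unique", call. = FALSE)
  if (any(!is.finite(biotin_density)) || any(biotin_density < 0))
    stop("biotin_density must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(ponceau_density)) || any(ponceau_density <= 0))
    stop("ponceau_density must be finite and > 0", call. = FALSE)
  if (sum(is_reference) != 1L)
    stop("exactly one lane must be the reference", call. = FALSE)
  structure(data.frame(blot_id = blot_id, lane_id = as.character(lane_id),
                       biotin_density = as.numeric(biotin_density),
                       ponceau_density = as.numeric(ponceau_density),
                       is_reference = as.logical(is_reference),
                       stringsAsFactors = FALSE),
            class = c("lane_records", "data.frame"))
}

#' Relative lane intensity (Rel. Int.)
#'
#' Each lane's biotin density is first normalized to its Ponceau density
#' (loading control), then expressed relative to the reference lane:
#' `rel_int = (biotin/ponceau)_lane / (biotin/ponceau)_reference`. The
#' reference lane is 1 exactly, always, and the result is invariant to
#' rescaling all biotin densities by one constant and all Ponceau densities
#' by another.
#'
#' @param lanes a [lane_records()] data.frame (or one coercible to it).
#' @return named numeric vector of relative intensities, names = lane ids.
#' @export
relative_lane_intensity <- function(lanes) {
  if (!inherits(lanes, "lane_records"))
    lanes <- lane_records(lanes$lane_id, lanes$biotin_density,
                          lanes$ponceau_density, lanes$is_reference,
                          blot_id = if (!is.null(lanes$blot_id))
                            lanes$blot_id[1] else "blot1")
  ref <- which(lanes$is_reference)
  if (lanes$biotin_density[ref] <= 0)
    stop("reference lane biotin density must be > 0", call. = FALSE)
  ratio <- lanes$biotin_density / lanes$ponceau_density
  rel <- ratio / ratio[ref]
  names(rel) <- lanes$lane_id
  rel
}

#' Read lane densitometry records from CSV
#'
#' Expected columns: `blot_id, lane_id, biotin_density, ponceau_density,
#' is_reference` (is_reference as TRUE/FALSE or 0/1).
#'
#' @param path CSV path.
#' @return a [lane_records()] data.frame (one blot group per file).
#' @export
read_lane_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  for (col in c("lane_id", "biotin_density", "ponceau_density",
                "is_reference"))
    if (!col %in% names(tab))
      stop("format error: missing column '", col, "' in ", path,
           call. = FALSE)
  lane_records(tab$lane_id, tab$biotin_density, tab$ponceau_density,
               as.logical(tab$is_reference),
               blot_id = if ("blot_id" %in% names(tab)) tab$blot_id[1]
                         else "blot1")
}
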