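#' Parameters of a synthetic fluorescence scene
#'
#' Describes a ground-truthed three-channel field emulating the confocal
#' acquisitions the pipeline quantifies: cells with a nucleus (DAPI-like
#' channel), a perinuclear Golgi blob (TGN46-like marker channel) and a
#' reporter channel whose expected total signal per cell
#' (`reporter_budget`, in detector counts) is split
#' `f_golgi : membrane_frac : remainder` over the Golgi mask, a 2-px
#' plasma-membrane annulus and the diffuse cytoplasm (uniform within each
#' compartment; the nucleus carries no reporter signal). Observed pixels are
#' Poisson shot-noise draws plus additive Gaussian read noise, quantized to
#' integer counts and clipped to `[0, 65535]` (16-bit detector model).
#'
#' @param shape image shape `c(H, W)`.
#' @param n_cells number of non-overlapping cells to place.
#' @param cell_radius_px range `c(min, max)` of cell semi-major axes.
#' @param nucleus_radius_frac nucleus radius as a fraction of the cell
#'   radius.
#' @param golgi_area_frac Golgi area as a fraction of the cytoplasmic
#'   (non-nuclear) cell area.
#' @param reporter_budget expected total reporter counts per cell.
#' @param f_golgi planted in-Golgi fraction of the reporter budget.
#' @param membrane_frac fraction of the budget on the membrane annulus;
#'   `f_golgi + membrane_frac` must be <= 1.
#' @param background_level expected per-pixel background counts.
#' @param read_noise_sd SD of the additive Gaussian read noise (counts).
#' @param nonspecific_level expected per-pixel counts inside cells of a
#'   negative-control field (nonspecific streptavidin binding).
#' @param nuclei_level,golgi_marker_level expected per-pixel counts of the
#'   stained structures in their own channels.
#' @param condition_id,analog,cell_line,timepoint_h,replicate metadata
#'   passed to the generated field.
#' @param seed integer seed; generation is a pure function of
#'   (params, seed).
#' @return list of validated scene parameters.
#' @export
scene_params <- function(shape = c(512, 512), n_cells = 6,
                         cell_radius_px = c(25, 40),
                         nucleus_radius_frac = 0.4,
                         golgi_area_frac = 0.05,
                         reporter_budget = 5e5,
                         f_golgi = 0.6, membrane_frac = 0.2,
                         background_level = 2, read_noise_sd = 2,
                         nonspecific_level = 4,
                         nuclei_level = 150, golgi_marker_level = 150,
                         condition_id = "synthetic", analog = "analog",
                         cell_line = "synthetic", timepoint_h = 24,
                         replicate = 1, seed = 1) {
  p <- list(shape = as.integer(shape), n_cells = as.integer(n_cells),
            cell_radius_px = as.numeric(cell_radius_px),
            nucleus_radius_frac = nucleus_radius_frac,
            golgi_area_frac = golgi_area_frac,
            reporter_budget = reporter_budget,
            f_golgi = f_golgi, membrane_frac = membrane_frac,
            background_level = background_level,
            read_noise_sd = read_noise_sd,
            nonspecific_level = nonspecific_level,
            nuclei_level = nuclei_level,
            golgi_marker_level = golgi_marker_level,
            condition_id = condition_id, analog = analog,
            cell_line = cell_line, timepoint_h = timepoint_h,
            replicate = as.integer(replicate), seed = as.integer(seed))
  if (length(p$shape) != 2L || any(p$shape < 64L))
    stop("shape must be c(H, W) with both >= 64", call. = FALSE)
  if (p$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  if (length(p$cell_radius_px) != 2L || p$cell_radius_px[1] < 5 ||
      diff(p$cell_radius_px) < 0)
    stop("cell_radius_px must be an increasing range with min >= 5",
         call. = FALSE)
  if (p$f_golgi < 0 || p$f_golgi > 1 || p$membrane_frac < 0 ||
      p$f_golgi + p$membrane_frac > 1 + 1e-12)
    stop("need f_golgi, membrane_frac >= 0 and f_golgi + membrane_frac <= 1",
         call. = FALSE)
  rates <- c(p$reporter_budget, p$background_level, p$read_noise_sd,
             p$nonspecific_level, p$nuclei_level, p$golgi_marker_level,
             p$golgi_area_frac, p$nucleus_radius_frac)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  p
}

# Sample the cell/nucleus/golgi/membrane geometry. Consumes RNG; callers
# wrap in withr::with_seed so labeled and control scenes with the same seed
# share identical geometry (geometry is drawn before any pixel noise).
generate_geometry <- function(params) {
  H <- params$shape[1]; W <- params$shape[2]
  rmin <- params$cell_radius_px[1]; rmax <- params$cell_radius_px[2]
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  ecc <- numeric(0); phis <- numeric(0)
  failures <- 0L
  while (nrow(centers) < params$n_cells) {
    r <- stats::runif(1, rmin, rmax)
    cy <- stats::runif(1, r + 3, H - r - 3)
    cx <- stats::runif(1, r + 3, W - r - 3)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      ok <- all(d > radii + r + 3)
    }
    if (ok) {
      centers <- rbind(centers, c(cy, cx)); radii <- c(radii, r)
      ecc <- c(ecc, stats::runif(1, 0.85, 1)); phis <- c(phis, stats::runif(1, 0, pi))
      failures <- 0L
    } else {
      failures <- failures + 1L
      if (failures >= 1000L)
        stop("placement error: could not place ", params$n_cells,
             " non-overlapping cells in 1000 attempts; reduce n_cells or ",
             "cell_radius_px", call. = FALSE)
    }
  }
  cell_labels <- matrix(0L, H, W)
  nucleus_labels <- matrix(0L, H, W)
  golgi_labels <- matrix(0L, H, W)
  membrane_labels <- matrix(0L, H, W)
  row_idx <- matrix(rep(seq_len(H), W), H, W)
  col_idx <- matrix(rep(seq_len(W), each = H), H, W)
  brush <- EBImage::makeBrush(5L, shape = "disc")   # radius-2 annulus
  for (k in seq_len(params$n_cells)) {
    a <- radii[k]; b <- ecc[k] * a; phi <- phis[k]
    dy <- row_idx - centers[k, 1]; dx <- col_idx - centers[k, 2]
    xr <- cos(phi) * dx + sin(phi) * dy
    yr <- -sin(phi) * dx + cos(phi) * dy
    cell <- (xr / a)^2 + (yr / b)^2 <= 1
    eroded <- EBImage::erode(cell * 1, brush) > 0.5
    membrane <- cell & !eroded
    rn <- params$nucleus_radius_frac * a
    shift_max <- max(0, b - rn - 3)
    th <- stats::runif(1, 0, 2 * pi)
    sh <- stats::runif(1, 0, min(shift_max, 0.25 * a))
    ny <- centers[k, 1] + sh * sin(th); nx <- centers[k, 2] + sh * cos(th)
    dn <- sqrt((row_idx - ny)^2 + (col_idx - nx)^2)
    nucleus <- (dn <= rn) & eroded
    # perinuclear crescent: closest cytoplasmic pixels to a random bearing
    # around the nucleus edge, sized to golgi_area_frac of the non-nuclear
    # cell area
    cand <- which(cell & !nucleus & !membrane)
    n_cyt_ref <- sum(cell & !nucleus)
    k_golgi <- max(1L, min(length(cand),
                           as.integer(round(params$golgi_area_frac * n_cyt_ref))))
    th0 <- stats::runif(1, 0, 2 * pi)
    d_cand <- sqrt((row_idx[cand] - ny)^2 + (col_idx[cand] - nx)^2)
    ang <- atan2(row_idx[cand] - ny, col_idx[cand] - nx)
    angdist <- abs(((ang - th0 + pi) %% (2 * pi)) - pi)
    score <- pmax(0, d_cand - rn) / 2 + angdist * rn
    golgi_px <- cand[order(score)[seq_len(k_golgi)]]
    cell_labels[cell] <- k
    nucleus_labels[nucleus] <- k
    membrane_labels[membrane] <- k
    golgi_labels[golgi_px] <- k
  }
  list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
       golgi_labels = golgi_labels, membrane_labels = membrane_labels,
       centers = centers, radii = radii)
}

observe_counts <- function(lambda, read_noise_sd) {
  n <- length(lambda)
  obs <- stats::rpois(n, lambda)
  if (read_noise_sd > 0)
    obs <- obs + round(stats::rnorm(n, 0, read_noise_sd))
  matrix(pmin(pmax(obs, 0), 65535), nrow = nrow(lambda))
}

scene_field_meta <- function(params, is_control) {
  list(condition_id = params$condition_id, cell_line = params$cell_line,
       analog = if (is_control) "ManNAc-control" else params$analog,
       timepoint_h = params$timepoint_h, replicate = params$replicate,
       is_control = is_control)
}

#' Generate a labeled synthetic scene with ground truth
#'
#' See [scene_params()] for the forward model. The same (params, seed)
#' always produces a bit-identical field and truth.
#'
#' @param params from [scene_params()].
#' @return list with `field` (a [fluorescence_field()]) and `truth`, an
#'   object of class `scene_truth` carrying the per-cell label matrices
#'   (`cell_labels`, `nucleus_labels`, `golgi_labels`,
#'   `membrane_labels`), the planted `f_golgi` and `membrane_frac`, and a
#'   `per_cell` data.frame of region areas and expected integrated
#'   densities (signal + background) for the in_golgi / out_golgi /
#'   whole_cell regions.
#' @export
generate_scene <- function(params = scene_params()) {
  withr::with_seed(params$seed, {
    geom <- generate_geometry(params)
    H <- params$shape[1]; W <- params$shape[2]
    bg <- params$background_level
    lam_nuc <- matrix(bg, H, W)
    lam_nuc[geom$nucleus_labels > 0L] <- bg + params$nuclei_level
    lam_mark <- matrix(bg, H, W)
    lam_mark[geom$golgi_labels > 0L] <- bg + params$golgi_marker_level
    lam_rep <- matrix(bg, H, W)
    f <- params$f_golgi; m <- params$membrane_frac
    cyt_share <- 1 - f - m
    per_cell <- vector("list", params$n_cells)
    for (k in seq_len(params$n_cells)) {
      golgi <- geom$golgi_labels == k
      memb <- geom$membrane_labels == k
      cellm <- geom$cell_labels == k
      nuc <- geom$nucleus_labels == k
      cyto <- cellm & !nuc & !golgi & !memb
      comps <- list(golgi = golgi, membrane = memb, cytoplasm = cyto)
      shares <- c(golgi = f, membrane = m, cytoplasm = cyt_share)
      for (nm in names(comps)) {
        npx <- sum(comps[[nm]])
        if (shares[[nm]] > 0) {
          if (npx == 0)
            stop("compartment '", nm, "' of cell ", k, " is empty but has ",
                 "a positive budget share", call. = FALSE)
          lam_rep[comps[[nm]]] <- lam_rep[comps[[nm]]] +
            shares[[nm]] * params$reporter_budget / npx
        }
      }
      a_cell <- sum(cellm); a_golgi <- sum(golgi)
      per_cell[[k]] <- data.frame(
        cell_id = k, area_cell = a_cell, area_nucleus = sum(nuc),
        area_golgi = a_golgi, area_membrane = sum(memb),
        area_cytoplasm = sum(cyto),
        exp_intden_in = f * params$reporter_budget + bg * a_golgi,
        exp_intden_out = (1 - f) * params$reporter_budget +
          bg * (a_cell - a_golgi),
        exp_intden_whole = params$reporter_budget + bg * a_cell)
    }
    pixels <- array(0, dim = c(H, W, 3))
    pixels[, , 1] <- observe_counts(lam_nuc, params$read_noise_sd)
    pixels[, , 2] <- observe_counts(lam_mark, params$read_noise_sd)
    pixels[, , 3] <- observe_counts(lam_rep, params$read_noise_sd)
    field <- fluorescence_field(
      pixels, c(nuclei = 1, golgi_marker = 2, reporter = 3),
      scene_field_meta(params, is_control = FALSE))
    truth <- structure(
      list(cell_labels = geom$cell_labels,
           nucleus_labels = geom$nucleus_labels,
           golgi_labels = geom$golgi_labels,
           membrane_labels = geom$membrane_labels,
           f_golgi = f, membrane_frac = m,
           per_cell = do.call(rbind, per_cell), params = params),
      class = "scene_truth")
    list(field = field, truth = truth)
  })
}

#' Generate a matched negative-control scene
#'
#' Same geometry pipeline as [generate_scene()] (identical seed gives
#' identical cell placement), but the reporter channel carries only
#' `nonspecific_level` expected counts uniformly inside cells and
#' `background_level` outside: the nonspecific streptavidin binding a
#' natural-sugar control measures.
#'
#' @inheritParams generate_scene
#' @return as [generate_scene()], with `field$meta$is_control = TRUE`.
#' @export
generate_control_scene <- function(params = scene_params()) {
  withr::with_seed(params$seed, {
    geom <- generate_geometry(params)
    H <- params$shape[1]; W <- params$shape[2]
    bg <- params$background_level
    lam_nuc <- matrix(bg, H, W)
    lam_nuc[geom$nucleus_labels > 0L] <- bg + params$nuclei_level
    lam_mark <- matrix(bg, H, W)
    lam_mark[geom$golgi_labels > 0L] <- bg + params$golgi_marker_level
    lam_rep <- matrix(bg, H, W)
    lam_rep[geom$cell_labels > 0L] <- params$nonspecific_level
    pixels <- array(0, dim = c(H, W, 3))
    pixels[, , 1] <- observe_counts(lam_nuc, params$read_noise_sd)
    pixels[, , 2] <- observe_counts(lam_mark, params$read_noise_sd)
    pixels[, , 3] <- observe_counts(lam_rep, params$read_noise_sd)
    field <- fluorescence_field(
      pixels, c(nuclei = 1, golgi_marker = 2, reporter = 3),
      scene_field_meta(params, is_control = TRUE))
    truth <- structure(
      list(cell_labels = geom$cell_labels,
           nucleus_labels = geom$nucleus_labels,
           golgi_labels = geom$golgi_labels,
           membrane_labels = geom$membrane_labels,
           f_golgi = 0, membrane_frac = 0,
           per_cell = NULL, params = params),
      class = "scene_truth")
    list(field = field, truth = truth)
  })
}

#' Generate a synthetic cytometry event table
#'
#' Emulates the gated populations of a surface-labeling experiment: a main
#' population with normal FSC/SSC clusters and lognormal fluorescence whose
#' mean is `fold_over_control` times the control mean; optional debris
#' (near-zero FSC) and doublets (about twice the main FSC/SSC).
#'
#' @param n_main main-population events (>= 100).
#' @param n_debris,n_doublets contaminating events.
#' @param main_fl_lognormal `c(meanlog, sdlog)` of the control-level
#'   fluorescence; `sdlog` must be > 0.
#' @param fold_over_control planted fold-change of the mean fluorescence
#'   over the control level.
#' @param condition_id,channel,is_control metadata for [event_table()].
#' @param seed integer seed.
#' @return an [event_table()]; the attribute `population` labels each event
#'   `"main"`, `"debris"` or `"doublet"` (ground truth for gate checks).
#' @export
generate_event_table <- function(n_main = 10000, n_debris = 0,
                                 n_doublets = 0,
                                 main_fl_lognormal = c(meanlog = log(500),
                                                       sdlog = 0.5),
                                 fold_over_control = 1,
                                 condition_id = "synthetic",
                                 channel = "FL1A", is_control = FALSE,
                                 seed = 1) {
  if (n_main < 100) stop("n_main must be >= 100", call. = FALSE)
  mu <- main_fl_lognormal[[1]]; sg <- main_fl_lognormal[[2]]
  if (!is.finite(sg) || sg <= 0)
    stop("lognormal sdlog must be > 0", call. = FALSE)
  if (fold_over_control <= 0)
    stop("fold_over_control must be > 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    fsc <- stats::rnorm(n_main, 5e5, 5e4)
    ssc <- stats::rnorm(n_main, 2e5, 3e4)
    fl <- stats::rlnorm(n_main, mu + log(fold_over_control), sg)
    pop <- rep("main", n_main)
    if (n_debris > 0) {
      fsc <- c(fsc, abs(stats::rnorm(n_debris, 2e4, 1e4)))
      ssc <- c(ssc, abs(stats::rnorm(n_debris, 1.5e4, 8e3)))
      fl <- c(fl, stats::rlnorm(n_debris, mu - 1, sg))
      pop <- c(pop, rep("debris", n_debris))
    }
    if (n_doublets > 0) {
      fsc <- c(fsc, stats::rnorm(n_doublets, 1e6, 7e4))
      ssc <- c(ssc, stats::rnorm(n_doublets, 4e5, 5e4))
      fl <- c(fl, stats::rlnorm(n_doublets,
                                mu + log(fold_over_control) + log(2), sg))
      pop <- c(pop, rep("doublet", n_doublets))
    }
    ev <- event_table(fsc, ssc, fl, condition_id = condition_id,
                      channel = channel, is_control = is_control)
    attr(ev, "population") <- pop
    ev
  })
}

#' Generate a synthetic lane densitometry table
#'
#' Lane 1 is the reference; each lane's planted biotin/Ponceau ratio is
#' `ratios[i]`, perturbed (non-reference lanes only) by mean-one
#' multiplicative lognormal noise with coefficient of variation `noise_cv`.
#' Ponceau loadings vary between lanes so the normalization is exercised.
#'
#' @param ratios planted biotin/Ponceau ratios, one per lane (length >= 2,
#'   all > 0); `ratios[1]` belongs to the reference lane.
#' @param noise_cv coefficient of variation of the ratio noise (>= 0).
#' @param blot_id blot group label.
#' @param seed integer seed.
#' @return a [lane_records()] data.frame with lanes `lane1..laneN`.
#' @export
generate_lane_table <- function(ratios, noise_cv = 0, blot_id = "blot1",
                                seed = 1) {
  if (length(ratios) < 2L)
    stop("need at least 2 lanes", call. = FALSE)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("all planted ratios must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    n <- length(ratios)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- c(1, stats::rlnorm(n - 1, -sdlog^2 / 2, sdlog))
    ponceau <- 1000 * stats::runif(n, 0.8, 1.2)
    biotin <- ratios * noise * ponceau
    lane_records(paste0("lane", seq_len(n)), biotin, ponceau,
                 is_reference = seq_len(n) == 1L, blot_id = blot_id)
  })
}
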