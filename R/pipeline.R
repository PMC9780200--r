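#' Read and validate a run configuration
#'
#' The configuration is one YAML mapping; relative paths are resolved
#' against the directory containing the file. Sections: `seed`,
#' `output_dir`, `imaging` (channel_roles, threshold_rule, segmentation,
#' golgi, background_per_px, conditions with `images` and `controls`
#' paths), `cytometry` (gate, conditions with `events` and `control`
#' paths), `densitometry` (`lanes` CSV path) and `stats` (`variant`).
#' Every imaging/cytometry condition must name at least one control; all
#' referenced paths must exist at validation time.
#'
#' @param path YAML config path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) cfg$output_dir <- file.path(base, "results")
  else cfg$output_dir <- resolve(cfg$output_dir)
  if (!is.null(cfg$imaging)) {
    im <- cfg$imaging
    im$channel_roles <- unlist(if (is.null(im$channel_roles))
      c(nuclei = 1, golgi_marker = 2, reporter = 3) else im$channel_roles)
    im$threshold_rule <- validate_threshold_rule(
      if (is.null(im$threshold_rule)) threshold_rule() else im$threshold_rule)
    seg_defaults <- segmentation_params()
    im$segmentation <- utils::modifyList(seg_defaults,
      if (is.null(im$segmentation)) list() else im$segmentation)
    golgi_defaults <- list(method = "otsu", percentile = 90,
                           min_golgi_area_px = 20)
    im$golgi <- utils::modifyList(golgi_defaults,
      if (is.null(im$golgi)) list() else im$golgi)
    if (is.null(im$background_per_px)) im$background_per_px <- 0
    if (!length(im$conditions))
      stop("imaging section has no conditions", call. = FALSE)
    for (i in seq_along(im$conditions)) {
      cond <- im$conditions[[i]]
      if (is.null(cond$condition_id))
        stop("imaging condition ", i, " lacks condition_id", call. = FALSE)
      if (!length(cond$controls))
        stop("config error: imaging condition '", cond$condition_id,
             "' has no control images", call. = FALSE)
      cond$images <- resolve(unlist(cond$images))
      cond$controls <- resolve(unlist(cond$controls))
      missing <- c(cond$images, cond$controls)
      missing <- missing[!file.exists(missing)]
      if (length(missing))
        stop("config error: missing file(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      im$conditions[[i]] <- cond
    }
    cfg$imaging <- im
  }
  if (!is.null(cfg$cytometry)) {
    cy <- cfg$cytometry
    gate_defaults <- list(fsc_floor_quantile = 0.02, robust_z_max = 2.5)
    cy$gate <- utils::modifyList(gate_defaults,
      if (is.null(cy$gate)) list() else cy$gate)
    if (!length(cy$conditions))
      stop("cytometry section has no conditions", call. = FALSE)
    for (i in seq_along(cy$conditions)) {
      cond <- cy$conditions[[i]]
      if (is.null(cond$control))
        stop("config error: cytometry condition '", cond$condition_id,
             "' has no control event table", call. = FALSE)
      cond$events <- resolve(cond$events)
      cond$control <- resolve(cond$control)
      if (is.null(cond$channel)) cond$channel <- "FL1A"
      missing <- c(cond$events, cond$control)
      missing <- missing[!file.exists(missing)]
      if (length(missing))
        stop("config error: missing file(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      cy$conditions[[i]] <- cond
    }
    cfg$cytometry <- cy
  }
  if (!is.null(cfg$densitometry)) {
    cfg$densitometry$lanes <- resolve(cfg$densitometry$lanes)
    if (!file.exists(cfg$densitometry$lanes))
      stop("config error: missing lane table ", cfg$densitometry$lanes,
           call. = FALSE)
  }
  if (is.null(cfg$stats)) cfg$stats <- list(variant = "student")
  if (is.null(cfg$stats$variant)) cfg$stats$variant <- "student"
  class(cfg) <- "run_config"
  cfg
}

quantify_one_condition <- function(cond, im, is_control_set) {
  paths <- if (is_control_set) cond$controls else cond$images
  cid <- if (is_control_set) paste0(cond$condition_id, "_control")
         else cond$condition_id
  fields <- lapply(seq_along(paths), function(i)
    load_field(paths[i], im$channel_roles,
               meta = list(condition_id = cid, replicate = i,
                           is_control = is_control_set)))
  fields
}

#' Run the imaging quantification pipeline
#'
#' Per condition: derive the background threshold from the control images,
#' segment cells and Golgi on every labeled image, partition, measure and
#' aggregate; the control images themselves are quantified with the same
#' threshold (as condition `<id>_control`) and analog-vs-control t-tests on
#' image-level IntDen are reported per region with star labels. For
#' significance testing, an image in which no cell passes the size filter
#' contributes an image-level IntDen of 0 (no detected signal); condition
#' summaries still flag such conditions with NA means. A degenerate
#' comparison (zero variance in both groups, e.g. a null experiment where
#' the labeled images are controls) is reported as `ns` with p = NA and a
#' note. All outputs plus a manifest echoing every parameter are written
#' under `output_dir/imaging`.
#'
#' @param config a [read_run_config()] result.
#' @return invisibly, list with `measurements`, `summaries`, `stats`
#'   data.frames and the output paths.
#' @export
run_imaging <- function(config) {
  stopifnot(inherits(config, "run_config"))
  im <- config$imaging
  if (is.null(im)) stop("config has no imaging section", call. = FALSE)
  out_dir <- file.path(config$output_dir, "imaging")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_tables <- list(); entries <- list(); stat_rows <- list()
  for (cond in im$conditions) {
    ctrl_fields <- quantify_one_condition(cond, im, is_control_set = TRUE)
    thr <- derive_background_threshold(ctrl_fields,
                                       rule = im$threshold_rule)
    groups <- list(labeled = quantify_one_condition(cond, im,
                                                    is_control_set = FALSE),
                   control = ctrl_fields)
    img_levels <- list(labeled = list(), control = list())
    for (g in names(groups)) {
      for (f in groups[[g]]) {
        thr_g <- thr; thr_g$condition_id <- f$meta$condition_id
        cells <- segment_cells(f, thr_g, im$segmentation)
        golgi <- segment_golgi(f, cells, method = im$golgi$method,
                               percentile = im$golgi$percentile,
                               min_golgi_area_px = im$golgi$min_golgi_area_px)
        parts <- partition_all_cells(cells, golgi)
        tab <- quantify_field(f, parts)
        all_tables[[length(all_tables) + 1L]] <- tab
        entries[[length(entries) + 1L]] <- list(meta = f$meta, table = tab)
        lv <- lapply(c(in_golgi = "in_golgi", out_golgi = "out_golgi"),
                     function(reg) {
          rows <- tab[tab$region == reg, , drop = FALSE]
          if (nrow(rows) == 0) 0 else mean(rows$intden)
        })
        img_levels[[g]][[length(img_levels[[g]]) + 1L]] <- lv
      }
    }
    for (reg in c("in_golgi", "out_golgi")) {
      va <- vapply(img_levels$labeled, function(x) x[[reg]], numeric(1))
      vb <- vapply(img_levels$control, function(x) x[[reg]], numeric(1))
      row <- data.frame(comparison_id = paste0(cond$condition_id, "_", reg),
                        group_a = cond$condition_id,
                        group_b = paste0(cond$condition_id, "_control"),
                        region = reg, n_a = length(va), n_b = length(vb),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        label = "ns", variant = config$stats$variant,
                        note = "", stringsAsFactors = FALSE)
      if (length(va) >= 2 && length(vb) >= 2) {
        res <- try(t_test_two_sample(va, vb, config$stats$variant),
                   silent = TRUE)
        if (inherits(res, "try-error")) {
          row$note <- "degenerate variance"
        } else {
          row$t <- res$t_stat; row$df <- res$df; row$p <- res$p_value
          row$label <- res$label
        }
      } else row$note <- "insufficient images"
      stat_rows[[length(stat_rows) + 1L]] <- row
    }
  }
  measurements <- do.call(rbind, lapply(all_tables, as.data.frame))
  summaries <- summarize_condition(entries)
  stats_tab <- do.call(rbind, stat_rows)
  paths <- c(measurements = file.path(out_dir, "measurements.csv"),
             summaries = file.path(out_dir, "condition_summary.csv"),
             stats = file.path(out_dir, "stats.csv"))
  utils::write.csv(measurements, paths[["measurements"]], row.names = FALSE)
  utils::write.csv(as.data.frame(summaries), paths[["summaries"]],
                   row.names = FALSE)
  utils::write.csv(stats_tab, paths[["stats"]], row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.yaml"), config,
                 stage = "imaging")
  invisible(list(measurements = measurements, summaries = summaries,
                 stats = stats_tab, paths = paths))
}

#' Run the flow-cytometry quantification pipeline
#'
#' Per condition: gate the analog and control event tables on FSC/SSC,
#' compute MFIs and the relative MFI (fold over the negative control).
#' Writes `cytometry/relative_mfi.csv` plus a manifest recording the gate
#' parameters.
#'
#' @param config a [read_run_config()] result.
#' @return invisibly, list with the `relative_mfi` data.frame and paths.
#' @export
run_cytometry <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cy <- config$cytometry
  if (is.null(cy)) stop("config has no cytometry section", call. = FALSE)
  out_dir <- file.path(config$output_dir, "cytometry")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cy$conditions, function(cond) {
    ev <- read_event_csv(cond$events, channel = cond$channel,
                         condition_id = cond$condition_id)
    ctl <- read_event_csv(cond$control, channel = cond$channel,
                          condition_id = paste0(cond$condition_id, "_control"),
                          is_control = TRUE)
    g_ev <- gate_events(ev, cy$gate$fsc_floor_quantile, cy$gate$robust_z_max)
    g_ctl <- gate_events(ctl, cy$gate$fsc_floor_quantile, cy$gate$robust_z_max)
    mfi <- mean_fluorescence(ev, g_ev)
    mfi_ctl <- mean_fluorescence(ctl, g_ctl)
    data.frame(condition_id = cond$condition_id, channel = cond$channel,
               n_total = g_ev$n_total, n_in = g_ev$n_in,
               mfi = mfi, mfi_control = mfi_ctl,
               relative_mfi = relative_mfi(mfi, mfi_ctl),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  path <- file.path(out_dir, "relative_mfi.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.yaml"), config,
                 stage = "cytometry")
  invisible(list(relative_mfi = tab, paths = c(relative_mfi = path)))
}

#' Run the blot densitometry normalization
#'
#' @param config a [read_run_config()] result with a `densitometry`
#'   section.
#' @return invisibly, the lane table with a `rel_int` column and the
#'   output path.
#' @export
run_densitometry <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$densitometry))
    stop("config has no densitometry section", call. = FALSE)
  out_dir <- file.path(config$output_dir, "densitometry")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lanes <- read_lane_csv(config$densitometry$lanes)
  rel <- relative_lane_intensity(lanes)
  out <- as.data.frame(lanes)
  out$rel_int <- unname(rel[out$lane_id])
  path <- file.path(out_dir, "relative_intensity.csv")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(list(lanes = out, paths = c(relative_intensity = path)))
}

#' Run every configured stage
#'
#' Executes imaging, cytometry and densitometry stages as present in the
#' config. Outputs are a pure function of the config and its seed: two
#' runs with identical inputs produce byte-identical CSVs.
#'
#' @param config a [read_run_config()] result, or a path to a YAML config.
#' @return invisibly, list of per-stage results.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  res <- list()
  if (!is.null(config$imaging)) res$imaging <- run_imaging(config)
  if (!is.null(config$cytometry)) res$cytometry <- run_cytometry(config)
  if (!is.null(config$densitometry))
    res$densitometry <- run_densitometry(config)
  invisible(res)
}

write_manifest <- function(path, config, stage) {
  cfg <- unclass(config)
  manifest <- list(stage = stage,
                   package = "glycoquant",
                   version = as.character(utils::packageVersion("glycoquant")),
                   seed = cfg$seed,
                   config = cfg)
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Group comparisons from a long-format CSV
#'
#' Input columns: `comparison_id, group, value`; each comparison must
#' contain exactly two groups. One unpaired two-tailed t-test per
#' comparison, star-labeled.
#'
#' @param path input CSV.
#' @param variant `"student"` or `"welch"`.
#' @param out optional output CSV path.
#' @return data.frame: comparison_id, group_a, group_b, n_a, n_b, t, df,
#'   p, label, variant.
#' @export
stats_from_csv <- function(path, variant = c("student", "welch"),
                           out = NULL) {
  variant <- match.arg(variant)
  tab <- utils::read.csv(path)
  for (col in c("comparison_id", "group", "value"))
    if (!col %in% names(tab))
      stop("format error: missing column '", col, "'", call. = FALSE)
  rows <- lapply(split(tab, tab$comparison_id), function(d) {
    gs <- unique(d$group)
    if (length(gs) != 2L)
      stop("comparison '", d$comparison_id[1], "' must have exactly two ",
           "groups", call. = FALSE)
    a <- d$value[d$group == gs[1]]; b <- d$value[d$group == gs[2]]
    res <- t_test_two_sample(a, b, variant)
    data.frame(comparison_id = d$comparison_id[1], group_a = gs[1],
               group_b = gs[2], n_a = res$n_a, n_b = res$n_b,
               t = res$t_stat, df = res$df, p = res$p_value,
               label = res$label, variant = variant,
               stringsAsFactors = FALSE)
  })
  result <- do.call(rbind, rows)
  rownames(result) <- NULL
  if (!is.null(out)) utils::write.csv(result, out, row.names = FALSE)
  result
}

#' Simulate a complete demo experiment on disk
#'
#' Writes labeled and control synthetic fields (multi-page TIFF), analog
#' and control cytometry event tables (CSV), a lane densitometry table and
#' a ready-to-run YAML config referencing them. Useful for demos and
#' end-to-end determinism checks.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-image seeds are derived from it.
#' @param n_images,n_controls labeled/control fields per condition.
#' @param scene base [scene_params()] for the imaging conditions.
#' @param fold planted cytometry fold-change over control.
#' @param n_events events per cytometry table.
#' @param lane_ratios planted lane ratios (reference first).
#' @return path to the written config file.
#' @export
simulate_experiment <- function(out_dir, seed = 1, n_images = 4,
                                n_controls = 2,
                                scene = scene_params(),
                                fold = 10, n_events = 10000,
                                lane_ratios = c(1, 0.5, 1.6, 0.8)) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- as.integer(seed)
  cond <- scene$condition_id
  img_paths <- character(n_images); ctl_paths <- character(n_controls)
  for (i in seq_len(n_images)) {
    p <- scene; p$seed <- seed * 1000L + i; p$replicate <- i
    sc <- generate_scene(p)
    img_paths[i] <- file.path(out_dir, "images",
                              sprintf("%s_img%02d.tif", cond, i))
    save_field(sc$field, img_paths[i])
  }
  for (i in seq_len(n_controls)) {
    p <- scene; p$seed <- seed * 1000L + 500L + i; p$replicate <- i
    sc <- generate_control_scene(p)
    ctl_paths[i] <- file.path(out_dir, "images",
                              sprintf("%s_ctrl%02d.tif", cond, i))
    save_field(sc$field, ctl_paths[i])
  }
  ev <- generate_event_table(n_main = n_events, n_debris = n_events %/% 20,
                             n_doublets = n_events %/% 20,
                             fold_over_control = fold,
                             condition_id = cond, seed = seed * 1000L + 7L)
  ctl_ev <- generate_event_table(n_main = n_events,
                                 n_debris = n_events %/% 20,
                                 n_doublets = n_events %/% 20,
                                 fold_over_control = 1,
                                 condition_id = paste0(cond, "_control"),
                                 is_control = TRUE, seed = seed * 1000L + 8L)
  ev_path <- file.path(out_dir, "events.csv")
  ctl_ev_path <- file.path(out_dir, "events_control.csv")
  write_event_csv(ev, ev_path)
  write_event_csv(ctl_ev, ctl_ev_path)
  lanes <- generate_lane_table(lane_ratios, noise_cv = 0.05,
                               seed = seed * 1000L + 9L)
  lanes_path <- file.path(out_dir, "lanes.csv")
  utils::write.csv(as.data.frame(lanes), lanes_path, row.names = FALSE)
  cfg <- list(
    seed = seed,
    output_dir = "results",
    imaging = list(
      channel_roles = list(nuclei = 1, golgi_marker = 2, reporter = 3),
      threshold_rule = list(method = "percentile", parameter = 99.5),
      background_per_px = scene$background_level,
      conditions = list(list(condition_id = cond,
                             images = file.path("images", basename(img_paths)),
                             controls = file.path("images",
                                                  basename(ctl_paths))))),
    cytometry = list(
      conditions = list(list(condition_id = cond,
                             channel = "FL1A",
                             events = basename(ev_path),
                             control = basename(ctl_ev_path)))),
    densitometry = list(lanes = basename(lanes_path)),
    stats = list(variant = "student"))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
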