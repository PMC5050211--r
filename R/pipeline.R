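## End-to-end pipeline driver: (optional) synthetic scene -> render ->
## upsample -> smooth -> per-channel segmentation -> merge -> dissect ->
## local density -> profiles -> tables, plus event gating, under one seed
## split deterministically into per-stage substreams. Every run writes a
## manifest sufficient to reproduce it.

stage_wrap <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

scene_from_config <- function(cfg, seed) {
  sp <- do.call(scene_params, cfg$synthetic$scene[names(cfg$synthetic$scene) %in%
                                                    names(formals(scene_params))])
  generate_scene(sp, unlist(cfg$synthetic$domain_size_um), seed = seed)
}

optics_from_config <- function(cfg, seed) {
  o <- cfg$synthetic$optics
  o <- o[names(o) %in% names(formals(optics_params))]
  o$seed <- seed
  do.call(optics_params, o)
}

mixture_from_config <- function(cfg, seed) {
  m <- cfg$synthetic$mixture
  m <- m[names(m) %in% names(formals(mixture_params))]
  m$seed <- seed
  do.call(mixture_params, m)
}

#' Run the full quantification pipeline
#'
#' Executes synthesis (when enabled) or stack reading, the segmentation
#' chain, cube dissection with local density, surface roughness, profiles
#' and event gating; writes all tabular artifacts plus a JSON manifest
#' (config echo, seed, per-stage seeds, Otsu thresholds, package and R
#' versions) into the output directory. Two runs with identical config and
#' seed produce byte-identical tables.
#'
#' @param config a \code{run_config} from \code{\link{validate_config}},
#'   or a path to a YAML config file.
#' @param outdir output directory (default from the config).
#' @return Invisibly, a list with the main in-memory artifacts (scene,
#'   cube table, surface map, gate result, manifest).
#' @export
run_pipeline <- function(config = validate_config(), outdir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  seeds <- list(scene = derive_seed(seed, 1), optics = derive_seed(seed, 2),
                events = derive_seed(seed, 3))
  manifest <- list(config = unclass(config), seed = seed, stage_seeds = seeds,
                   package_version = as.character(utils::packageVersion("biofilmcubes")),
                   r_version = R.version.string)

  scene <- NULL
  if (isTRUE(config$synthetic$enabled)) {
    scene <- stage_wrap("synth", scene_from_config(config, seeds$scene))
    write_scene_truth(scene, file.path(outdir, "scene_truth.csv"))
    optics <- optics_from_config(config, seeds$optics)
    channels <- unlist(config$synthetic$channels)
    stack <- stage_wrap("render", render_scene(scene, optics, channels))
    write_stack(stack, file.path(outdir, "stack.tif"), dtype = "float32")
  } else {
    paths <- unlist(config$input$stacks)
    if (!length(paths)) stop("stage 'input' failed: no input stacks configured")
    stack <- stage_wrap("input", read_stack(
      paths, spacing_um = config$input$spacing_um,
      channel_names = unlist(config$input$channel_names)))
  }

  iso <- stage_wrap("upsample", upsample_to_isotropic(stack))
  smoothed <- stage_wrap("smooth",
                         smooth_stack(iso, config$segmentation$smooth_radius))
  seg_channels <- unlist(config$segmentation$segment_channels)
  seg_channels <- seg_channels[seg_channels %in% stack$channel_names]
  if (!length(seg_channels))
    stop("stage 'segment' failed: no configured segment channel is present in the stack")
  masks <- list(); thresholds <- list()
  for (ch in seg_channels) {
    m <- stage_wrap(paste0("segment:", ch),
                    segment(smoothed, ch, config$segmentation$bins))
    ot <- attr(m, "thresholds")
    thresholds[[ch]] <- list(t1 = ot$t1, t2 = ot$t2,
                             foreground_fraction = attr(m, "foreground_fraction"))
    masks[[ch]] <- m
    write_stack(m, file.path(outdir, paste0("mask_", ch, ".tif")))
  }
  manifest$otsu_thresholds <- thresholds
  merged <- stage_wrap("merge", merge_masks(masks))

  cubes <- stage_wrap("dissect",
                      dissect(merged, iso, config$quantification$cube_side_vox,
                              config$quantification$min_occupancy))
  cubes <- stage_wrap("density",
                      annotate_density(cubes, merged,
                                       config$quantification$density_radius_um))
  if (length(masks) > 1L)
    cubes <- stage_wrap("classify", classify_cubes(cubes, masks))
  write_cube_table(cubes, file.path(outdir, "cubes.csv"))

  prof <- stage_wrap("profiles",
                     density_z_profile(cubes, config$quantification$z_bin_um))
  utils::write.csv(data.frame(z_lo_um = utils::head(prof$bin_edges, -1),
                              z_hi_um = utils::tail(prof$bin_edges, -1),
                              mean_local_density = prof$values,
                              n_cubes = prof$n_per_bin),
                   file.path(outdir, "density_z_profile.csv"), row.names = FALSE)

  surf <- stage_wrap("roughness",
                     roughness_map(height_map(merged),
                                   config$quantification$roughness_window_px))
  utils::write.csv(surf$roughness_um, file.path(outdir, "roughness.csv"),
                   row.names = FALSE)

  gate <- NULL
  if (isTRUE(config$synthetic$enabled)) {
    ev <- stage_wrap("events", generate_events(mixture_from_config(config, seeds$events)))
    write_event_table(ev, file.path(outdir, "events.csv"))
    gate <- stage_wrap("gate", gate_on_off(ev, config$cytometry$channel,
                                           config$cytometry$threshold,
                                           config$cytometry$cofactor))
    utils::write.csv(data.frame(threshold = gate$threshold,
                                fraction_on_pct = gate$fraction_on,
                                fraction_off_pct = gate$fraction_off,
                                n_events = gate$n_events),
                     file.path(outdir, "gates.csv"), row.names = FALSE)
  } else if (!is.null(config$input$events)) {
    ev <- stage_wrap("events", read_event_table(config$input$events))
    if (!is.null(config$input$control)) {
      ctrl <- read_event_table(config$input$control)
      ev <- stage_wrap("background",
                       subtract_background(ev, ctrl, config$cytometry$channel))
    }
    gate <- stage_wrap("gate", gate_on_off(ev, config$cytometry$channel,
                                           config$cytometry$threshold,
                                           config$cytometry$cofactor))
    utils::write.csv(data.frame(threshold = gate$threshold,
                                fraction_on_pct = gate$fraction_on,
                                fraction_off_pct = gate$fraction_off,
                                n_events = gate$n_events),
                     file.path(outdir, "gates.csv"), row.names = FALSE)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(scene = scene, stack = stack, masks = masks, merged = merged,
                 cubes = cubes, profile = prof, surface = surf, gate = gate,
                 manifest = manifest))
}
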