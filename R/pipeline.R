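# Pipeline orchestration: a JSON-validated configuration drives the two
# phases (mesh generation: phantom -> segment -> smooth -> mesh; fiber
# generation: regions -> surface fibers -> volume fibers -> CV fit ->
# monodomain simulation), writing every artifact plus a reproducibility
# manifest (inputs, hashes, seeds) to the output directory.

#' Default pipeline configuration
#'
#' Stage-parameter blocks mirroring the module defaults.  Units are fixed
#' package-wide: mm, ms, mV, S/cm, uF/cm^2; `seed` feeds every random
#' stage.  Override any subset via `...` (unknown keys are rejected).
#'
#' @param ... nested overrides, e.g. `segmentation = list(max_thickness = 3)`
#' @return validated config list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    units = list(length = "mm", time = "ms", voltage = "mV",
                 conductivity = "S/cm"),
    phantom = list(wall_thickness = 1.5, cavity_radius = 8, spacing = 0.4,
                   mean_wall = 250, sd_wall = 30, mean_cavity = 450,
                   sd_cavity = 40),
    segmentation = list(max_thickness = 3, target_spacing = 0.2,
                        max_displacement_fraction = 0.5, iterations = 50),
    shell = list(n = 8L, nr = 2L),
    fibers = list(scheme = "linear", band_width = 2, passes = 3),
    ep = list(target_cv_l = 1.2, target_cv_t = 0.4, resolution = 0.2,
              dt = 0.01, n_beats = 50, stim_rate = 50, stim_dur = 2,
              t_end = 40, simulate = TRUE))
  override_config(cfg, list(...), "config")
}

override_config <- function(cfg, over, path) {
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stopf("pipeline_config: unknown key '%s.%s'", path, nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- override_config(cfg[[nm]], over[[nm]], paste(path, nm, sep = "."))
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read and validate a pipeline configuration from JSON
#' @param path JSON file with any subset of the [pipeline_config()] keys
#' @return validated config list
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes, in order: voxel-phantom generation, statistics-based
#' segmentation, constrained smoothing/resampling, shell-atrium mesh
#' generation, region partition, surface fiber generation (endo + epi),
#' transmural fiber interpolation, conduction-velocity fitting and (when
#' enabled) a monodomain simulation with LAT output on a tissue sheet.
#' Writes all artifacts under `out_dir` and a `manifest.json` with
#' parameters and MD5 hashes of every output.
#'
#' @param config from [pipeline_config()]
#' @param out_dir output directory (created)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  stages <- list()
  outputs <- character()
  note <- function(stage, ...) {
    message(sprintf("[atriofiber] %s: %s", stage, sprintf(...)))
  }

  # -- stage 1: phantom
  ph <- make_voxel_phantom(do.call(phantom_spec, c(config$phantom,
                                                   list(seed = config$seed))))
  p_img <- file.path(out_dir, "phantom.mha")
  write_metaimage(ph$image, p_img)
  outputs <- c(outputs, p_img)
  stages$phantom <- list(spec = ph$spec[setdiff(names(ph$spec), "geometry")],
                         voxels = dim(ph$image$data))
  note("phantom", "%s voxels", paste(dim(ph$image$data), collapse = "x"))

  # -- stage 2: segment
  thr <- compute_thresholds(median_prefilter(ph$image), ph$myo_samples,
                            ph$blood_samples)
  seg <- build_wall(ph$image, thr$thresholds, ph$seed_point,
                    max_thickness = config$segmentation$max_thickness)
  p_seg <- file.path(out_dir, "segmentation.mha")
  write_metaimage(voxel_image(array(as.numeric(seg$labels), dim(seg$labels)),
                              seg$spacing, seg$origin), p_seg,
                  element_type = "MET_SHORT")
  outputs <- c(outputs, p_seg)
  stages$segment <- list(thresholds = thr$thresholds,
                         dice_wall = dice(seg_mask(seg, "mc"), ph$truth$wall))
  note("segment", "LT/MT/UT = %.1f/%.1f/%.1f, Dice %.3f",
       thr$thresholds$LT, thr$thresholds$MT, thr$thresholds$UT,
       stages$segment$dice_wall)

  # -- stage 3: smooth + resample
  sm <- smooth_and_resample(seg, config$segmentation$target_spacing,
                            config$segmentation$max_displacement_fraction,
                            config$segmentation$iterations)
  p_sm <- file.path(out_dir, "segmentation_smoothed.mha")
  write_metaimage(voxel_image(array(as.numeric(sm$seg$labels),
                                    dim(sm$seg$labels)),
                              sm$seg$spacing, sm$seg$origin), p_sm,
                  element_type = "MET_SHORT")
  outputs <- c(outputs, p_sm)
  stages$smooth <- list(max_displacement_fraction = sm$max_displacement_fraction,
                        out_spacing = sm$seg$spacing)
  note("smooth", "max displacement %.1f%% of voxel",
       100 * sm$max_displacement_fraction)

  # -- stage 4: mesh (idealized shell atrium stands in for the meshed
  # patient segmentation; the proprietary mesher is out of scope)
  shell <- make_shell_atrium(do.call(shell_atrium_spec, config$shell))
  p_mesh <- file.path(out_dir, "shell_mesh")
  write_mesh(shell$mesh, p_mesh, "carp")
  outputs <- c(outputs, paste0(p_mesh, c(".pts", ".elem")))
  stages$mesh <- list(vertices = nrow(shell$mesh$vertices),
                      tets = nrow(shell$mesh$tets))
  note("mesh", "%d vertices, %d tets", nrow(shell$mesh$vertices),
       nrow(shell$mesh$tets))

  # -- stage 5: regions
  lab <- partition_regions(shell$endo, shell$atlas_endo$lines, shell$seeds_endo)
  if (!identical(as.integer(lab), as.integer(shell$atlas_endo$labels)))
    stopf("run_pipeline: region partition does not reproduce the atlas labels")
  p_atlas <- file.path(out_dir, "atlas_endo.json")
  write_atlas(shell$atlas_endo, p_atlas, landmarks = shell$landmarks,
              seeds = shell$seeds_endo)
  outputs <- c(outputs, p_atlas)
  stages$regions <- list(n_regions = length(shell$atlas_endo$region_names))
  note("regions", "%d regions partitioned", stages$regions$n_regions)

  # -- stage 6: surface fibers
  sf_endo <- surface_fibers(shell$endo, shell$atlas_endo,
                            config$fibers$band_width, config$fibers$passes)
  sf_epi <- surface_fibers(shell$epi, shell$atlas_epi,
                           config$fibers$band_width, config$fibers$passes)
  p_fe <- file.path(out_dir, "fibers_endo")
  write_mesh(sf_endo$surface, p_fe, "carp")
  p_fp <- file.path(out_dir, "fibers_epi")
  write_mesh(sf_epi$surface, p_fp, "carp")
  outputs <- c(outputs, paste0(p_fe, c(".pts", ".elem", ".lon")),
               paste0(p_fp, c(".pts", ".elem", ".lon")))
  stages$fibers_surface <- list(endo_filled = sum(sf_endo$field$provenance == "filled"),
                                epi_filled = sum(sf_epi$field$provenance == "filled"))
  note("fibers-surface", "endo/epi fields complete")

  # -- stage 7: volume fibers
  endo_v <- sort(unique(as.vector(shell$endo$triangles)))
  epi_v <- sort(unique(as.vector(shell$epi$triangles)))
  u <- transmural_laplace(shell$mesh, endo_v, epi_v)
  corr <- build_correspondence(shell$mesh, u, shell$endo, shell$epi)
  vol <- assign_volume_fibers(shell$mesh, corr, sf_endo$surface, sf_epi$surface,
                              config$fibers$scheme)
  p_vol <- file.path(out_dir, "fibers_volume")
  write_mesh(vol, p_vol, "carp")
  p_prov <- file.path(out_dir, "fibers_volume_provenance.csv")
  utils::write.csv(attr(vol, "provenance"), p_prov, row.names = FALSE)
  outputs <- c(outputs, paste0(p_vol, c(".pts", ".elem", ".lon")), p_prov)
  stages$fibers_volume <- list(scheme = config$fibers$scheme,
                               traced = sum(corr$provenance == "traced"),
                               fallback = sum(corr$provenance != "traced"))
  note("fibers-volume", "%d traced, %d rim fallbacks",
       stages$fibers_volume$traced, stages$fibers_volume$fallback)

  # -- stage 8: conduction-velocity fit
  paced <- pace_to_steady_state(config$ep$n_beats, 1000, config$ep$dt)
  fit <- fit_conductivity(config$ep$target_cv_l, config$ep$target_cv_t,
                          paced$state, config$ep$resolution, config$ep$dt)
  stages$fit_cv <- list(sigma_l = fit$sigma_l, sigma_t = fit$sigma_t,
                        cv_l = fit$cv_l, cv_t = fit$cv_t,
                        iterations = nrow(fit$trace))
  note("fit-cv", "sigma_l %.4g S/cm (CV %.3f), sigma_t %.4g S/cm (CV %.3f)",
       fit$sigma_l, fit$cv_l, fit$sigma_t, fit$cv_t)

  # -- stage 9: monodomain simulation (sheet domain, corner stimulus)
  if (isTRUE(config$ep$simulate)) {
    sheet <- make_sheet_mesh(c(8, 8), 0.4)
    sheet$fibers <- matrix(rep(c(1, 0, 0), each = n_elements(sheet)),
                           n_elements(sheet), 3)
    model <- monodomain_model(fit$sigma_l, fit$sigma_t, dt = config$ep$dt)
    stim_v <- which(rowSums(sheet$vertices[, 1:2]^2) < 1.0^2)
    sim <- simulate_monodomain(sheet, model, config$ep$t_end, paced$state,
                               stim_vertices = stim_v,
                               stim_rate = config$ep$stim_rate,
                               stim_dur = config$ep$stim_dur)
    p_lat <- file.path(out_dir, "lat.csv")
    utils::write.csv(data.frame(vertex = seq_along(sim$lat),
                                x = sheet$vertices[, 1],
                                y = sheet$vertices[, 2],
                                lat_ms = sim$lat), p_lat, row.names = FALSE)
    outputs <- c(outputs, p_lat)
    stages$simulate <- list(max_lat = max(sim$lat, na.rm = TRUE),
                            activated = mean(!is.na(sim$lat)))
    note("simulate", "max LAT %.2f ms", stages$simulate$max_lat)
  }

  manifest <- list(
    package = "atriofiber",
    version = as.character(utils::packageVersion("atriofiber")),
    seed = config$seed,
    config = config,
    stages = stages,
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(f) list(md5 = unname(tools::md5sum(f)),
                                    bytes = file.size(f))),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run --config cfg.json --out dir`, `phantom --out dir`
#' (writes the voxel phantom), `fit-cv --cvl 1.2 --cvt 0.4 --beats 50 --out
#' file.json`.  Installed as `inst/cli/atriofiber`.
#'
#' @param args character vector (default: command-line arguments)
#' @return exit status, invisibly
#' @export
atriofiber_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: atriofiber {run|phantom|fit-cv} [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stopf("atriofiber_cli: unexpected '%s'", args[i])
    opts[[substring(args[i], 3)]] <- if (i + 1L <= length(args)) args[i + 1L] else ""
    i <- i + 2L
  }
  if (cmd == "run") {
    cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
           else pipeline_config()
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    run_pipeline(cfg, opts$out %||% "atriofiber_out")
  } else if (cmd == "phantom") {
    ph <- make_voxel_phantom(phantom_spec(seed = as.integer(opts$seed %||% "1")))
    out <- opts$out %||% "phantom_out"
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_metaimage(ph$image, file.path(out, "phantom.mha"))
    cat(sprintf("phantom written to %s\n", out))
  } else if (cmd == "fit-cv") {
    paced <- pace_to_steady_state(as.integer(opts$beats %||% "50"), 1000)
    fit <- fit_conductivity(as.numeric(opts$cvl %||% "1.2"),
                            as.numeric(opts$cvt %||% "0.4"), paced$state,
                            resolution = as.numeric(opts$res %||% "0.2"),
                            dt = as.numeric(opts$dt %||% "0.01"))
    out <- list(sigma_l = fit$sigma_l, sigma_t = fit$sigma_t,
                cv_l = fit$cv_l, cv_t = fit$cv_t)
    if (!is.null(opts$out))
      jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA)
    cat(jsonlite::toJSON(out, auto_unbox = TRUE), "\n")
  } else stopf("atriofiber_cli: unknown command '%s'", cmd)
  invisible(0L)
}
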