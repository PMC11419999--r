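#' Experiment configuration
#'
#' A fully serializable description of one end-to-end run: phantom
#' arrangement, light model, acoustic grid, reconstruction and filter
#' settings, and the seed. Round-trips losslessly through YAML.
#'
#' @param arrangement_id phantom arrangement label.
#' @param light_mode `"uniform"` or `"gaussian"`.
#' @param waist_radius Gaussian waist, mm (`light_mode = "gaussian"`).
#' @param photons photon packets for the Monte Carlo stage.
#' @param seed integer seed.
#' @param tube_radius,spacing phantom geometry, mm.
#' @param grid_shape,grid_pitch,dt,n_samples,pml_width acoustic grid.
#' @param recon_shape,recon_pitch,speed_mode,lowpass_cutoff reconstruction.
#' @param adf_k,adf_dt,adf_n_iter,adf_coefficient ADF hyperparameters
#'   (`adf_k = NULL` uses 0.1 x dynamic range).
#' @param nlm_h,nlm_patch,nlm_search NLM hyperparameters.
#' @param output_dir where [run_pipeline()] writes its artifacts.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(arrangement_id = "s4", light_mode = "uniform",
                              waist_radius = 10, photons = 1e5, seed = 1L,
                              tube_radius = 0.5, spacing = 10,
                              grid_shape = c(121, 121), grid_pitch = 1,
                              dt = 12.5e-9, n_samples = 4096, pml_width = 10,
                              recon_shape = c(300, 300), recon_pitch = 0.4,
                              speed_mode = "uniform", lowpass_cutoff = 750e3,
                              adf_k = NULL, adf_dt = 0.2, adf_n_iter = 20,
                              adf_coefficient = "exponential",
                              nlm_h = NULL, nlm_patch = 2, nlm_search = 7,
                              output_dir = tempfile("pacavity_run_")) {
  light_mode <- match.arg(light_mode, c("uniform", "gaussian"))
  cfg <- list(arrangement_id = arrangement_id, light_mode = light_mode,
              waist_radius = waist_radius, photons = photons,
              seed = as.integer(seed), tube_radius = tube_radius,
              spacing = spacing, grid_shape = as.integer(grid_shape),
              grid_pitch = grid_pitch, dt = dt,
              n_samples = as.integer(n_samples),
              pml_width = as.integer(pml_width),
              recon_shape = as.integer(recon_shape),
              recon_pitch = recon_pitch, speed_mode = speed_mode,
              lowpass_cutoff = lowpass_cutoff,
              adf_k = adf_k, adf_dt = adf_dt,
              adf_n_iter = as.integer(adf_n_iter),
              adf_coefficient = adf_coefficient,
              nlm_h = nlm_h, nlm_patch = as.integer(nlm_patch),
              nlm_search = as.integer(nlm_search),
              output_dir = output_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg[setdiff(names(cfg), "output_dir")]), path)
  invisible(path)
}

#' @rdname experiment_config
#' @param cfg an `experiment_config`.
#' @export
read_config_yaml <- function(path, output_dir = tempfile("pacavity_run_")) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, c(vals, list(output_dir = output_dir)))
}

#' Run the full simulation pipeline
#'
#' Composes phantom -> optics -> acoustics -> reconstruction -> filters ->
#' evaluation for one configuration, writing every intermediate artifact to
#' `cfg$output_dir`: the label map, initial pressure (float TIFF + JSON
#' sidecars), sensor data (RDS), the reconstruction and both filtered images
#' (TIFF), and the metric report (JSON). Returns a manifest of files with MD5
#' hashes; identical configurations produce identical manifests.
#'
#' @param cfg an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return list with `manifest` (data.frame file/md5), `report` (the
#'   `metric_report`), and `config`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- "phantom"
  res <- tryCatch({
    say("stage: phantom")
    model <- build_arrangement(cfg$arrangement_id, cfg$tube_radius, cfg$spacing)
    grid <- acoustic_grid_spec(cfg$grid_shape, cfg$grid_pitch, cfg$dt,
                               cfg$n_samples, cfg$pml_width)
    labels <- rasterize(model, grid$shape, grid$pitch)
    rspec <- recon_spec(cfg$recon_shape, cfg$recon_pitch,
                        speed_mode = cfg$speed_mode,
                        lowpass_cutoff = cfg$lowpass_cutoff)
    f_lab <- file.path(cfg$output_dir, "labels.tiff")
    lab_out <- labels; lab_out$values <- labels$values / max(labels$values)
    lab_out$quantity <- "image"
    write_field_tiff(lab_out, f_lab, meta = list(config_seed = cfg$seed))

    stage <- "optics"
    say("stage: optics (", cfg$light_mode, ")")
    if (cfg$light_mode == "uniform") {
      p0 <- uniform_initial_pressure(labels)
    } else {
      beam <- beam_spec(cfg$waist_radius, photon_count = cfg$photons,
                        seed = cfg$seed)
      flu <- mc_fluence(labels, media_mc(), beam)
      A <- absorption_map(flu, labels, media_mc())
      p0 <- field_map(A$values, pitch = A$pitch,
                      quantity = "initial_pressure")
    }
    f_p0 <- file.path(cfg$output_dir, "p0.tiff")
    write_field_tiff(p0, f_p0, meta = list(light_mode = cfg$light_mode,
                                           seed = cfg$seed))

    stage <- "acoustics"
    say("stage: acoustics")
    sd <- forward_simulate(p0, labels, grid = grid)
    f_sd <- file.path(cfg$output_dir, "sensor_data.rds")
    saveRDS(sd, f_sd, version = 2)

    stage <- "recon"
    say("stage: reconstruction")
    sdf <- lowpass(sd, rspec$lowpass_cutoff)
    go <- das_reconstruct(sdf, rspec, labels = labels)
    f_go <- file.path(cfg$output_dir, "recon.tiff")
    write_field_tiff(go, f_go, meta = list(speed_mode = cfg$speed_mode))

    stage <- "filters"
    say("stage: filters")
    apar <- adf_params(k = cfg$adf_k, dt = cfg$adf_dt, n_iter = cfg$adf_n_iter,
                       coefficient = cfg$adf_coefficient)
    npar <- nlm_params(h = cfg$nlm_h, patch_radius = cfg$nlm_patch,
                       search_radius = cfg$nlm_search)
    gf_adf <- adf(go, apar)
    gf_nlm <- nlm(go, npar)
    f_adf <- file.path(cfg$output_dir, "filtered_adf.tiff")
    f_nlm <- file.path(cfg$output_dir, "filtered_nlm.tiff")
    write_field_tiff(gf_adf, f_adf, meta = apar)
    write_field_tiff(gf_nlm, f_nlm, meta = npar)

    stage <- "evaluate"
    say("stage: evaluation")
    ga <- ideal_image(model, rspec)
    rep_adf <- metric_report(ga, go, gf_adf, ids = list(gf = "adf"))
    rep_nlm <- metric_report(ga, go, gf_nlm, ids = list(gf = "nlm"))
    f_rep <- file.path(cfg$output_dir, "metrics.json")
    jsonlite::write_json(
      list(adf = rep_adf[c("baseline", "filtered", "lift_ratios")],
           nlm = rep_nlm[c("baseline", "filtered", "lift_ratios")],
           params = list(adf = unclass(apar), nlm = unclass(npar)),
           seed = cfg$seed),
      f_rep, auto_unbox = TRUE, digits = NA, null = "null")

    files <- c(f_lab, f_p0, f_sd, f_go, f_adf, f_nlm, f_rep)
    manifest <- data.frame(file = basename(files),
                           md5 = as.character(tools::md5sum(files)),
                           row.names = NULL)
    write_config_yaml(cfg, file.path(cfg$output_dir, "config.yaml"))
    list(manifest = manifest,
         report = list(adf = rep_adf, nlm = rep_nlm),
         config = cfg)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}
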