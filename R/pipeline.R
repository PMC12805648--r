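#' Pipeline run configuration
#'
#' Collects every physical parameter of the quantification pipeline in one
#' serializable object: channel-name mapping, smoothing sigma, per-channel
#' background-subtraction scales, spot diameters, proximity thresholds and
#' statistical settings. Defaults follow the published midgut workflow
#' (Gaussian 0.6 um; background 10/5/20/20 um for nuclei/Pros/Esg/RFP; spots
#' 3.75 um xy and 5 um z; close-to-surface 0.5 um; colocalization 5 um).
#'
#' @param mode one of `"populations"`, `"reddm"`, `"puncta"`, `"intensity"`.
#' @param channels named channel mapping (roles: dapi, pros, esg, rfp,
#'   puncta, reporter).
#' @param smooth_sigma_um pre-detection Gaussian sigma.
#' @param background_um named background-subtraction scales per role.
#' @param spot_diameter_xy_um,spot_diameter_z_um nucleus-scale spot diameters.
#' @param puncta_diameter_um puncta spot diameter.
#' @param quality_threshold spot quality threshold or `"otsu"`.
#' @param min_surface_volume_um3 minimum surface component volume.
#' @param close_threshold_um spot-to-surface threshold (0.5 or 1).
#' @param coloc_threshold_um spot colocalization threshold.
#' @param alpha significance level for the stats layer.
#' @param control_group control group label for normalization/post-hocs.
#' @param seed integer seed recorded in provenance.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = "populations",
                       channels = c(dapi = "dapi", pros = "pros",
                                    esg = "esg", rfp = "rfp",
                                    puncta = "ref2p", reporter = "stat_gfp"),
                       smooth_sigma_um = 0.6,
                       background_um = c(dapi = 10, pros = 5, esg = 20,
                                         rfp = 20),
                       spot_diameter_xy_um = 3.75,
                       spot_diameter_z_um = 5,
                       puncta_diameter_um = 0.7,
                       quality_threshold = "otsu",
                       min_surface_volume_um3 = 10,
                       close_threshold_um = 0.5,
                       coloc_threshold_um = 5,
                       alpha = 0.05,
                       control_group = "control",
                       seed = 1L) {
  mode <- match.arg(mode, c("populations", "reddm", "puncta", "intensity"))
  for (p in c(smooth_sigma_um, background_um, spot_diameter_xy_um,
              spot_diameter_z_um, puncta_diameter_um,
              min_surface_volume_um3, coloc_threshold_um)) {
    if (any(!is.finite(p)) || any(p < 0)) {
      stop("physical parameters must be finite and >= 0", call. = FALSE)
    }
  }
  stopifnot(close_threshold_um >= 0, alpha > 0, alpha < 1)
  structure(
    list(mode = mode, channels = as.list(channels),
         smooth_sigma_um = smooth_sigma_um,
         background_um = as.list(background_um),
         spot_diameter_xy_um = spot_diameter_xy_um,
         spot_diameter_z_um = spot_diameter_z_um,
         puncta_diameter_um = puncta_diameter_um,
         quality_threshold = quality_threshold,
         min_surface_volume_um3 = min_surface_volume_um3,
         close_threshold_um = close_threshold_um,
         coloc_threshold_um = coloc_threshold_um,
         alpha = alpha, control_group = control_group,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read/write a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return the config (read) or `path` invisibly (write).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(
    raw[setdiff(names(raw), c("channels", "background_um"))],
    list(channels = unlist(raw$channels),
         background_um = unlist(raw$background_um))
  ))
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

require_channel <- function(stack, role, config) {
  ch <- config$channels[[role]]
  if (is.null(ch) || !ch %in% channel_names(stack)) {
    stop("missing required channel: role '", role, "' maps to '",
         if (is.null(ch)) "<unset>" else ch,
         "' which is not in the stack (available: ",
         paste(channel_names(stack), collapse = ", "), ")", call. = FALSE)
  }
  ch
}

condition_channel <- function(stack, ch, role, config) {
  stack <- gaussian_smooth(stack, ch, config$smooth_sigma_um)
  bg <- config$background_um[[role]]
  if (!is.null(bg) && bg > 0) {
    stack <- subtract_background(stack, ch, bg)
  }
  stack
}

#' Run the quantification pipeline on one stack
#'
#' Executes preprocess, detect and classify/measure for the configured mode:
#'
#' * `populations`: nuclei + Prospero spots, Esg surfaces,
#'   [classify_populations()].
#' * `reddm`: adds RFP spots and runs [classify_reddm()].
#' * `puncta`: puncta spots + cell surfaces, [count_puncta_per_cell()].
#' * `intensity`: maximal projection of the reporter, 2D primary objects on
#'   the processed projection, integrated intensity on the raw projection.
#'
#' @param config a [run_config()].
#' @param stack an [image_stack()] or a path readable by [read_stack()].
#' @return a `pipeline_result`: mode-specific tables plus `provenance`
#'   (config echo, hash, package version).
#' @export
run_pipeline <- function(config, stack) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"))
  params <- classification_params(config$close_threshold_um,
                                  config$coloc_threshold_um)
  detect_role_spots <- function(st, role, diameter_xy, diameter_z) {
    ch <- require_channel(st, role, config)
    st <- condition_channel(st, ch, role, config)
    detect_spots(st, ch, diameter_xy, diameter_z, config$quality_threshold)
  }
  res <- switch(
    config$mode,
    populations = {
      dapi <- detect_role_spots(stack, "dapi", config$spot_diameter_xy_um,
                                config$spot_diameter_z_um)
      pros <- detect_role_spots(stack, "pros", config$spot_diameter_xy_um,
                                config$spot_diameter_z_um)
      esg_ch <- require_channel(stack, "esg", config)
      st <- condition_channel(stack, esg_ch, "esg", config)
      surfaces <- segment_surfaces(st, esg_ch,
                                   min_volume_um3 = config$min_surface_volume_um3)
      cl <- classify_populations(dapi, pros, surfaces, params)
      list(spots = list(dapi = dapi, pros = pros), surfaces = surfaces,
           cells = cl$cells, counts = cl$counts)
    },
    reddm = {
      dapi <- detect_role_spots(stack, "dapi", config$spot_diameter_xy_um,
                                config$spot_diameter_z_um)
      pros <- detect_role_spots(stack, "pros", config$spot_diameter_xy_um,
                                config$spot_diameter_z_um)
      rfp <- detect_role_spots(stack, "rfp", config$spot_diameter_xy_um,
                               config$spot_diameter_z_um)
      esg_ch <- require_channel(stack, "esg", config)
      st <- condition_channel(stack, esg_ch, "esg", config)
      surfaces <- segment_surfaces(st, esg_ch,
                                   min_volume_um3 = config$min_surface_volume_um3)
      cl <- classify_reddm(dapi, pros, rfp, surfaces, params)
      list(spots = list(dapi = dapi, pros = pros, rfp = rfp),
           surfaces = surfaces, cells = cl$cells, counts = cl$counts)
    },
    puncta = {
      pn_ch <- require_channel(stack, "puncta", config)
      st <- gaussian_smooth(stack, pn_ch, config$puncta_diameter_um / 3)
      puncta <- detect_spots(st, pn_ch, config$puncta_diameter_um,
                             config$puncta_diameter_um,
                             config$quality_threshold)
      esg_ch <- require_channel(stack, "esg", config)
      st2 <- condition_channel(stack, esg_ch, "esg", config)
      surfaces <- segment_surfaces(st2, esg_ch,
                                   min_volume_um3 = config$min_surface_volume_um3)
      nuclei <- NULL
      dapi_ch <- config$channels[["dapi"]]
      if (!is.null(dapi_ch) && dapi_ch %in% channel_names(stack)) {
        # nucleus-seeded split so touching cell surfaces stay per-cell objects
        nuclei <- detect_role_spots(stack, "dapi", config$spot_diameter_xy_um,
                                    config$spot_diameter_z_um)
        if (nrow(nuclei) > 0) surfaces <- split_surfaces(surfaces, nuclei)
      }
      counts <- count_puncta_per_cell(puncta, surfaces,
                                      config$close_threshold_um)
      list(spots = list(puncta = puncta, nuclei = nuclei),
           surfaces = surfaces, puncta_per_cell = counts)
    },
    intensity = {
      rep_ch <- require_channel(stack, "reporter", config)
      raw_proj <- max_project(stack, rep_ch)
      proc <- rescale_and_denoise(raw_proj)
      objects <- identify_primary_objects_2d(
        proc, diameter_range_um = c(config$spot_diameter_xy_um * 0.4,
                                    config$spot_diameter_xy_um * 4))
      meas <- measure_object_intensity(raw_proj, objects)
      list(objects = objects, intensities = meas,
           mean_per_cell = gut_mean_intensity(meas))
    }
  )
  res$provenance <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("midgutcyto")),
    mode = config$mode
  )
  class(res) <- "pipeline_result"
  res
}

#' Write a pipeline result bundle to a directory
#'
#' Writes the mode-specific CSVs plus a provenance JSON (config echo, config
#' hash, package version). Every CSV carries the config hash as a column.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param gut_id identifier recorded in the CSVs.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, gut_id = "gut1") {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- result$provenance$config_hash
  put <- function(df, name) {
    df <- as.data.frame(df)
    if (nrow(df) > 0) {
      df$gut_id <- gut_id
      df$config_hash <- h
    }
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  if (!is.null(result$counts)) put(result$counts, "population_counts.csv")
  if (!is.null(result$cells)) put(result$cells, "cell_table.csv")
  if (!is.null(result$puncta_per_cell)) {
    put(result$puncta_per_cell, "puncta_per_cell.csv")
  }
  if (!is.null(result$intensities)) put(result$intensities, "intensities.csv")
  if (!is.null(result$spots)) {
    for (nm in names(result$spots)) {
      put(result$spots[[nm]], paste0("spots_", nm, ".csv"))
    }
  }
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
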