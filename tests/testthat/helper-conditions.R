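# Study-condition parameter builders used by the acceptance suite.

puncta_scene_params <- function(seed, n_cells, noisy) {
  synthesis_params(
    image_shape_voxels = c(20, 176, 176), voxel_size_um = c(0.25, 0.2, 0.2),
    n_cells = n_cells, class_proportions = c(ISC = 1),
    nucleus_diameter_um = c(xy = 4, z = 3.5),
    surface_marker_thickness_um = 0.8,
    puncta_per_cell_rate = c(ISC = 3),
    intensity_levels = c(dapi = 300, esg = 500, pros = 220, rfp = 200,
                         ref2p = 250, stat_gfp = 150),
    noise_model = if (noisy) list(gaussian_sd = 50, poisson_scale = 1)
                  else list(gaussian_sd = 0, poisson_scale = 0),
    psf_sigma_um = c(xy = 0, z = 0),
    seed = seed)
}

rfi_gut_params <- function(seed, factor) {
  synthesis_params(
    image_shape_voxels = c(10, 160, 160), n_cells = 50,
    class_proportions = c(ISC = 0.12, EEP = 0.06, EE_mature = 0.12,
                          other = 0.70),
    reporter_classes = c("ISC", "EEP"), reporter_factor = factor,
    reporter_sd_log = 0.15, seed = seed)
}

# map ground-truth cells to surface labels via the voxel containing each
# nucleus centre (split surfaces are labeled by detected-nucleus index)
truth_cell_labels <- function(truth, surfaces) {
  midgutcyto:::containing_label(
    spot_set(tibble::tibble(
      z_um = truth$z_um, y_um = truth$y_um, x_um = truth$x_um,
      radius_xy_um = 1, radius_z_um = 1, channel = "dapi", quality = 1),
      frame = surfaces$frame),
    surfaces)
}

# naive greedy colocalization oracle: explicit pair list sorted by
# (distance, a_id, b_id), consumed one at a time
oracle_colocalize <- function(a, b, threshold_um) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$z_um[i] - b$z_um[j])^2 + (a$y_um[i] - b$y_um[j])^2 +
                  (a$x_um[i] - b$x_um[j])^2)
      if (d <= threshold_um) {
        pairs[[length(pairs) + 1L]] <- c(a$spot_id[i], b$spot_id[j], d)
      }
    }
  }
  if (length(pairs) == 0L) {
    return(tibble::tibble(a_id = integer(), b_id = integer(),
                          distance_um = numeric()))
  }
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 3], m[, 1], m[, 2]), , drop = FALSE]
  used_a <- used_b <- integer()
  keep <- logical(nrow(m))
  for (k in seq_len(nrow(m))) {
    if (!(m[k, 1] %in% used_a) && !(m[k, 2] %in% used_b)) {
      keep[k] <- TRUE
      used_a <- c(used_a, m[k, 1]); used_b <- c(used_b, m[k, 2])
    }
  }
  tibble::tibble(a_id = as.integer(m[keep, 1]), b_id = as.integer(m[keep, 2]),
                 distance_um = m[keep, 3])
}
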