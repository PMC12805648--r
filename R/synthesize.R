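#' Parameters for synthetic midgut scenes
#'
#' Describes a simulated confocal field of the posterior midgut: nuclei as
#' anisotropic Gaussian blobs, a cytoplasmic Esg/YFP reporter as a shell
#' around progenitor nuclei, nuclear Prospero in enteroendocrine cells and
#' their progenitors, optional lineage (RFP) and STAT-reporter channels,
#' sparse sub-micron puncta, Gaussian point-spread blur and mixed
#' Poisson-Gaussian noise. All physical quantities are micrometres.
#'
#' @param image_shape_voxels `(z, y, x)` voxel counts.
#' @param voxel_size_um `(dz, dy, dx)` in um.
#' @param n_cells number of nuclei to place.
#' @param class_proportions named non-negative fractions summing to 1 over a
#'   subset of `{ISC, EEP, EE_mature, EB, EC, new_EE, new_EC, other}`.
#' @param marker_model named list: channels expressed by each class. Channels
#'   `dapi` (all nuclei) is implicit; `esg` renders as a cytoplasmic shell,
#'   all others as nuclear blobs.
#' @param nucleus_diameter_um `(xy, z)` nucleus diameter in um.
#' @param surface_marker_thickness_um thickness of the cytoplasmic shell.
#' @param puncta_per_cell_rate named Poisson means per class (for puncta
#'   scenes), or `NULL`.
#' @param puncta_diameter_um puncta diameter in um.
#' @param intensity_levels named per-channel peak intensities (arbitrary
#'   units).
#' @param noise_model list with `gaussian_sd` (additive read noise) and
#'   `poisson_scale` (photons per intensity unit for shot noise; 0 disables).
#' @param psf_sigma_um `(xy, z)` Gaussian PSF sigma applied after rendering;
#'   0 disables.
#' @param reporter_classes classes carrying the STAT reporter channel
#'   (`stat_gfp`), or `NULL` for none.
#' @param reporter_factor group-level multiplier on the reporter intensity
#'   (the planted effect size).
#' @param reporter_sd_log lognormal sd of per-cell reporter variation.
#' @param seed integer seed; every generated artifact uses its own stream.
#' @return a validated `synthesis_params` list.
#' @export
synthesis_params <- function(
    image_shape_voxels = c(z = 16L, y = 256L, x = 256L),
    voxel_size_um = c(1.0, 0.4, 0.4),
    n_cells = 300L,
    class_proportions = c(ISC = 0.08, EEP = 0.04, EE_mature = 0.12,
                          other = 0.76),
    marker_model = list(ISC = "esg", EEP = c("esg", "pros"),
                        EE_mature = "pros", EB = "esg",
                        EC = character(), other = character()),
    nucleus_diameter_um = c(xy = 3.75, z = 5),
    surface_marker_thickness_um = 1.0,
    puncta_per_cell_rate = NULL,
    puncta_diameter_um = 0.7,
    intensity_levels = c(dapi = 200, esg = 180, pros = 220, rfp = 200,
                         ref2p = 250, stat_gfp = 150),
    noise_model = list(gaussian_sd = 5, poisson_scale = 1),
    psf_sigma_um = c(xy = 0.2, z = 0.4),
    reporter_classes = NULL,
    reporter_factor = 1,
    reporter_sd_log = 0.15,
    seed = 1L) {
  image_shape_voxels <- as.integer(image_shape_voxels)
  voxel_size_um <- as.numeric(voxel_size_um)
  stopifnot(length(image_shape_voxels) == 3L, all(image_shape_voxels >= 1L),
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            n_cells >= 0, nucleus_diameter_um[1] > 0,
            nucleus_diameter_um[2] > 0, surface_marker_thickness_um > 0,
            puncta_diameter_um > 0, all(intensity_levels > 0),
            noise_model$gaussian_sd >= 0, noise_model$poisson_scale >= 0,
            all(psf_sigma_um >= 0), reporter_factor > 0)
  p <- as.numeric(class_proportions)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class_proportions must be >= 0 and sum to 1", call. = FALSE)
  }
  if (is.null(names(class_proportions)) || any(names(class_proportions) == "")) {
    stop("class_proportions must be named", call. = FALSE)
  }
  # feasibility: combined nucleus volume must fit in the image
  rz <- nucleus_diameter_um[["z"]] / 2
  rxy <- nucleus_diameter_um[["xy"]] / 2
  cell_vol <- 4 / 3 * pi * rz * rxy^2
  img_vol <- prod(image_shape_voxels * voxel_size_um)
  if (n_cells * cell_vol > img_vol) {
    stop("impossible packing: ", n_cells, " nuclei of ",
         signif(cell_vol, 3), " um^3 exceed the image volume ",
         signif(img_vol, 3), " um^3", call. = FALSE)
  }
  structure(
    list(image_shape_voxels = stats::setNames(image_shape_voxels, c("z", "y", "x")),
         voxel_size_um = stats::setNames(voxel_size_um, c("z", "y", "x")),
         n_cells = as.integer(n_cells),
         class_proportions = class_proportions,
         marker_model = marker_model,
         nucleus_diameter_um = nucleus_diameter_um,
         surface_marker_thickness_um = surface_marker_thickness_um,
         puncta_per_cell_rate = puncta_per_cell_rate,
         puncta_diameter_um = puncta_diameter_um,
         intensity_levels = intensity_levels,
         noise_model = noise_model,
         psf_sigma_um = psf_sigma_um,
         reporter_classes = reporter_classes,
         reporter_factor = reporter_factor,
         reporter_sd_log = reporter_sd_log,
         seed = as.integer(seed)),
    class = "synthesis_params"
  )
}

# run code with an isolated, explicitly seeded RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic midgut stack with ground truth
#'
#' Draws the per-class cell counts from a multinomial at the planted
#' proportions, places nuclei by rejection sampling with a minimum
#' centre-to-centre distance of one (anisotropy-normalized) nucleus diameter,
#' renders each marker channel, applies the Gaussian PSF and then
#' Poisson-Gaussian noise, and records every planted object in a ground-truth
#' table. Identical parameters and seed give bit-identical output.
#'
#' Classes expressing the `esg` surface marker are assigned to mutually
#' well-separated nuclei (farthest-candidate heuristic) so cytoplasmic shells
#' resolve as distinct surfaces; the realized class counts still equal the
#' recorded multinomial draw.
#'
#' @param params a [synthesis_params()].
#' @return list with `stack` (an [image_stack()]) and `truth` (tibble:
#'   cell_id, class, centroid in um, markers, puncta_count, intensity_factor;
#'   attributes `class_counts` and `planted_proportions`).
#' @export
generate_midgut_stack <- function(params) {
  stopifnot(inherits(params, "synthesis_params"))
  with_seed(params$seed, generate_midgut_stack_impl(params))
}

generate_midgut_stack_impl <- function(params, extra_channels = list()) {
  shp <- params$image_shape_voxels
  vox <- params$voxel_size_um
  classes <- names(params$class_proportions)
  counts <- as.vector(stats::rmultinom(1, params$n_cells,
                                       params$class_proportions))
  names(counts) <- classes

  rz <- params$nucleus_diameter_um[["z"]] / 2
  rxy <- params$nucleus_diameter_um[["xy"]] / 2
  radii <- c(z = rz, y = rxy, x = rxy)
  shell_t <- params$surface_marker_thickness_um

  centers <- place_nuclei(params$n_cells, shp, vox, radii,
                          margin_um = radii + shell_t + 0.5)
  cls <- assign_classes(centers, counts, params$marker_model, radii)

  markers <- lapply(cls, function(cl) {
    mm <- params$marker_model[[cl]]
    if (is.null(mm)) character() else mm
  })
  channel_names <- unique(c("dapi", unlist(markers)))
  use_reporter <- !is.null(params$reporter_classes)
  if (use_reporter) channel_names <- unique(c(channel_names, "stat_gfp"))

  n <- nrow(centers)
  factors <- rep(1, n)
  if (use_reporter) {
    rep_cells <- cls %in% params$reporter_classes
    factors[rep_cells] <- params$reporter_factor *
      exp(stats::rnorm(sum(rep_cells), 0, params$reporter_sd_log))
  }

  channels <- list()
  sigma_blob <- radii / sqrt(3)  # blob sigma: diameter / (2*sqrt(3))
  for (ch in channel_names) {
    arr <- array(0, shp)
    level <- intensity_for(params$intensity_levels, ch)
    for (i in seq_len(n)) {
      p <- if (ch == "dapi") {
        blob_patch(centers[i, ], sigma_blob, level, vox, shp)
      } else if (ch == "esg" && "esg" %in% markers[[i]]) {
        shell_patch(centers[i, ], radii, shell_t, level, vox, shp)
      } else if (ch == "stat_gfp" && use_reporter &&
                 cls[i] %in% params$reporter_classes) {
        blob_patch(centers[i, ], sigma_blob * 1.2, level * factors[i],
                   vox, shp)
      } else if (!ch %in% c("dapi", "esg", "stat_gfp") &&
                 ch %in% markers[[i]]) {
        blob_patch(centers[i, ], sigma_blob, level, vox, shp)
      } else NULL
      if (!is.null(p)) {
        arr[p$zi, p$yi, p$xi] <- arr[p$zi, p$yi, p$xi] + p$values
      }
    }
    channels[[ch]] <- arr
  }
  for (ch in names(extra_channels)) channels[[ch]] <- extra_channels[[ch]]

  channels <- lapply(channels, function(arr) {
    apply_psf_and_noise(arr, params, vox)
  })

  stack <- image_stack(channels, vox,
                       metadata = list(generator = "generate_midgut_stack",
                                       seed = params$seed))
  truth <- tibble::tibble(
    cell_id = seq_len(n),
    class = cls,
    z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
    markers = vapply(markers, paste, "", collapse = ";"),
    puncta_count = 0L,
    intensity_factor = factors
  )
  attr(truth, "class_counts") <- counts
  attr(truth, "planted_proportions") <- params$class_proportions
  list(stack = stack, truth = truth)
}

intensity_for <- function(levels, ch) {
  if (ch %in% names(levels)) unname(levels[[ch]]) else unname(levels[[1]])
}

# rejection-sampled nucleus centres, snapped to voxel centres; minimum
# anisotropy-normalized centre distance of one diameter
place_nuclei <- function(n, shp, vox, radii, margin_um,
                         max_attempts = 10000L, min_sep = 2) {
  ext <- shp * vox
  lo <- pmin(margin_um, ext / 2)
  hi <- pmax(ext - margin_um, ext / 2)
  centers <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- stats::runif(3, lo, hi)
      cand <- snap_to_voxel_center(cand, vox, shp)
      if (i > 1L) {
        d <- sweep(centers[seq_len(i - 1L), , drop = FALSE], 2, cand, `-`)
        nd <- sqrt((d[, 1] / radii[1])^2 + (d[, 2] / radii[2])^2 +
                     (d[, 3] / radii[3])^2)
        if (min(nd) < min_sep) next
      }
      centers[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("packing failed: could not place nucleus ", i, " of ", n,
           " after ", max_attempts, " attempts", call. = FALSE)
    }
  }
  centers
}

snap_to_voxel_center <- function(pos_um, vox, shp) {
  idx <- pmin(pmax(round(pos_um / vox + 0.5), 1), shp)
  (idx - 0.5) * vox
}

# assign classes to placed nuclei; surface-marker classes go to mutually
# well-separated nuclei so their shells stay resolvable
assign_classes <- function(centers, counts, marker_model, radii) {
  n <- nrow(centers)
  classes <- names(counts)
  esg_classes <- classes[vapply(classes, function(cl) {
    "esg" %in% (marker_model[[cl]] %||% character())
  }, TRUE)]
  n_esg <- sum(counts[esg_classes])
  cls <- character(n)
  if (n == 0L) return(cls)
  nd <- normalized_dist_matrix(centers, radii)
  diag(nd) <- Inf
  esg_idx <- integer(0)
  if (n_esg > 0L) {
    nn <- apply(nd, 1, min)
    order_cand <- order(-nn)
    for (sep in c(3.0, 2.5, 2.0, 0)) {
      esg_idx <- integer(0)
      for (i in order_cand) {
        if (length(esg_idx) == n_esg) break
        if (length(esg_idx) == 0L ||
            min(nd[i, esg_idx]) >= sep) {
          esg_idx <- c(esg_idx, i)
        }
      }
      if (length(esg_idx) == n_esg) break
    }
    esg_pool <- sample(rep(esg_classes, counts[esg_classes]))
    cls[esg_idx] <- esg_pool
  }
  rest_classes <- setdiff(classes, esg_classes)
  rest_pool <- sample(rep(rest_classes, counts[rest_classes]))
  cls[setdiff(seq_len(n), esg_idx)] <- rest_pool
  cls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalized_dist_matrix <- function(centers, radii) {
  s <- sweep(centers, 2, radii, `/`)
  as.matrix(stats::dist(s))
}

# separable anisotropic Gaussian blob patch, peak `intensity` at the centre
# voxel; returned as (index ranges, values) so callers can add it in place
blob_patch <- function(center_um, sigma_um, intensity, vox, shp) {
  cvox <- center_um / vox + 0.5  # continuous voxel coordinate of the centre
  half <- ceiling(4 * sigma_um / vox)
  lo <- pmax(floor(cvox - half), 1)
  hi <- pmin(ceiling(cvox + half), shp)
  axes <- lapply(1:3, function(ax) {
    i <- lo[ax]:hi[ax]
    pos <- (i - 0.5) * vox[ax]
    exp(-(pos - center_um[ax])^2 / (2 * sigma_um[ax]^2))
  })
  list(zi = lo[1]:hi[1], yi = lo[2]:hi[2], xi = lo[3]:hi[3],
       values = intensity * (axes[[1]] %o% axes[[2]] %o% axes[[3]]))
}

# cytoplasmic shell patch: Gaussian radial profile peaking at the nucleus
# boundary plus half the shell thickness (anisotropy-normalized radius units)
shell_patch <- function(center_um, radii, thickness_um, intensity, vox, shp) {
  u0 <- 1 + (thickness_um / 2) / radii[2]
  su <- (thickness_um / 2) / (2 * radii[2])
  u_max <- u0 + 4 * su
  half_um <- radii * u_max
  lo <- pmax(floor((center_um - half_um) / vox + 0.5), 1)
  hi <- pmin(ceiling((center_um + half_um) / vox + 0.5), shp)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz <- ((zi - 0.5) * vox[1] - center_um[1]) / radii[1]
  dy <- ((yi - 0.5) * vox[2] - center_um[2]) / radii[2]
  dx <- ((xi - 0.5) * vox[3] - center_um[3]) / radii[3]
  u <- sqrt(outer(outer(dz^2, dy^2, `+`), dx^2, `+`))
  shell <- intensity * exp(-(u - u0)^2 / (2 * su^2))
  shell[u > u_max] <- 0
  list(zi = zi, yi = yi, xi = xi, values = shell)
}

apply_psf_and_noise <- function(arr, params, vox) {
  psf <- params$psf_sigma_um
  if (any(psf > 0)) {
    sig_um <- c(psf[["z"]], psf[["xy"]], psf[["xy"]])
    arr <- gaussian_blur_3d(arr, sig_um / vox)
  }
  nm <- params$noise_model
  if (nm$poisson_scale > 0) {
    lam <- pmax(arr * nm$poisson_scale, 0)
    arr <- array(stats::rpois(length(lam), lam) / nm$poisson_scale, dim(arr))
  }
  if (nm$gaussian_sd > 0) {
    arr <- arr + stats::rnorm(length(arr), 0, nm$gaussian_sd)
  }
  arr[arr < 0] <- 0
  arr
}

#' Generate a puncta scene with exact per-cell ground truth
#'
#' Builds a midgut scene (typically at finer voxel pitch) and adds a punctate
#' channel (`ref2p`): each cell of a class with a positive
#' `puncta_per_cell_rate` receives a Poisson number of ~0.7 um puncta placed
#' strictly inside its cytoplasmic surface region (within 85% of the nucleus
#' ellipsoid, which the filled surface encloses), with a minimum separation
#' of 1.2 puncta diameters. Exact per-cell counts and coordinates are stored
#' in the ground truth.
#'
#' @param params a [synthesis_params()] with `puncta_per_cell_rate` set for
#'   at least one class.
#' @param puncta_counts optional integer vector (length `n_cells`) overriding
#'   the Poisson draw with exact planted counts.
#' @return list with `stack`, `truth` (per-cell `puncta_count`) and `puncta`
#'   (tibble of planted puncta: cell_id, z_um, y_um, x_um).
#' @export
generate_puncta_scene <- function(params, puncta_counts = NULL) {
  stopifnot(inherits(params, "synthesis_params"))
  if (is.null(puncta_counts) &&
      (is.null(params$puncta_per_cell_rate) ||
       length(params$puncta_per_cell_rate) == 0L)) {
    stop("puncta_per_cell_rate must be set for at least one class ",
         "(or pass explicit puncta_counts)", call. = FALSE)
  }
  with_seed(params$seed, generate_puncta_scene_impl(params, puncta_counts))
}

generate_puncta_scene_impl <- function(params, puncta_counts) {
  base <- generate_midgut_stack_impl_noiseless(params)
  truth <- base$truth
  n <- nrow(truth)
  rates <- params$puncta_per_cell_rate
  if (is.null(puncta_counts)) {
    lam <- vapply(truth$class, function(cl) {
      if (!is.null(rates) && cl %in% names(rates)) rates[[cl]] else 0
    }, 0)
    puncta_counts <- stats::rpois(n, lam)
  } else {
    stopifnot(length(puncta_counts) == n, all(puncta_counts >= 0))
    puncta_counts <- as.integer(puncta_counts)
  }
  vox <- params$voxel_size_um
  shp <- params$image_shape_voxels
  rz <- params$nucleus_diameter_um[["z"]] / 2
  rxy <- params$nucleus_diameter_um[["xy"]] / 2
  radii <- c(rz, rxy, rxy)
  min_sep_um <- 1.2 * params$puncta_diameter_um
  pl <- list()
  for (i in seq_len(n)) {
    k <- puncta_counts[i]
    if (k == 0L) next
    center <- c(truth$z_um[i], truth$y_um[i], truth$x_um[i])
    pts <- place_puncta(k, center, radii, vox, shp, min_sep_um)
    pl[[length(pl) + 1L]] <- tibble::tibble(
      cell_id = truth$cell_id[i],
      z_um = pts[, 1], y_um = pts[, 2], x_um = pts[, 3]
    )
  }
  puncta <- if (length(pl) > 0) dplyr::bind_rows(pl) else
    tibble::tibble(cell_id = integer(), z_um = numeric(), y_um = numeric(),
                   x_um = numeric())
  # render puncta channel and apply PSF/noise to the whole scene
  sigma_p <- rep(params$puncta_diameter_um / (2 * sqrt(3)), 3)
  level <- intensity_for(params$intensity_levels, "ref2p")
  arr <- array(0, shp)
  for (j in seq_len(nrow(puncta))) {
    p <- blob_patch(c(puncta$z_um[j], puncta$y_um[j], puncta$x_um[j]),
                    sigma_p, level, vox, shp)
    arr[p$zi, p$yi, p$xi] <- arr[p$zi, p$yi, p$xi] + p$values
  }
  channels <- c(base$channels, list(ref2p = arr))
  channels <- lapply(channels, function(a) apply_psf_and_noise(a, params, vox))
  stack <- image_stack(channels, vox,
                       metadata = list(generator = "generate_puncta_scene",
                                       seed = params$seed))
  truth$puncta_count <- as.integer(puncta_counts)
  list(stack = stack, truth = truth, puncta = puncta)
}

# noiseless render reused by the puncta generator (noise applied once, after
# the puncta channel is added)
generate_midgut_stack_impl_noiseless <- function(params) {
  saved_noise <- params$noise_model
  saved_psf <- params$psf_sigma_um
  params$noise_model <- list(gaussian_sd = 0, poisson_scale = 0)
  params$psf_sigma_um <- c(xy = 0, z = 0)
  out <- generate_midgut_stack_impl(params)
  list(channels = out$stack$channels, truth = out$truth)
}

place_puncta <- function(k, center_um, radii, vox, shp, min_sep_um,
                         max_attempts = 5000L) {
  pts <- matrix(0, 0, 3)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      t <- stats::runif(1)^(1 / 3) * 0.85
      cand <- center_um + t * radii * dir
      cand <- snap_to_voxel_center(cand, vox, shp)
      if (nrow(pts) > 0) {
        d <- sweep(pts, 2, cand, `-`)
        if (min(sqrt(rowSums(d^2))) < min_sep_um) next
      }
      pts <- rbind(pts, cand)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("packing failed: could not place punctum ", j, " of ", k,
           " inside one cell", call. = FALSE)
    }
  }
  pts
}

#' Generate a synthetic survival cohort
#'
#' Exponential death times per group, discretized to the 2-day monitoring
#' grid, with independent uniform censoring.
#'
#' @param group_hazards named per-day hazards (> 0), one per group.
#' @param n_per_group flies per group.
#' @param censor_prob probability a fly is censored (escaped/handling death)
#'   before its death is observed; `0 <= censor_prob < 1`.
#' @param max_day end of the study; flies alive then are censored at
#'   `max_day`.
#' @param seed integer seed.
#' @return tibble `(id, group, time_days, event, time_raw)`: `event` 1 =
#'   death, 0 = censored; `time_days` on the even 2-day grid; `time_raw` is
#'   the continuous pre-discretization time.
#' @export
generate_survival_cohort <- function(group_hazards, n_per_group,
                                     censor_prob = 0, max_day = 60,
                                     seed = 1L) {
  stopifnot(length(group_hazards) >= 1, all(group_hazards > 0),
            !is.null(names(group_hazards)),
            censor_prob >= 0, censor_prob < 1, n_per_group >= 1, max_day >= 2)
  with_seed(seed, {
    rows <- purrr::imap_dfr(as.list(group_hazards), function(h, gname) {
      t_death <- stats::rexp(n_per_group, rate = h)
      censored <- stats::runif(n_per_group) < censor_prob
      t_cens <- stats::runif(n_per_group, 0, pmin(t_death, max_day))
      t_obs <- ifelse(censored, t_cens, t_death)
      event <- ifelse(censored, 0L, 1L)
      # discretize to the 2-day monitoring grid; truncate at max_day
      t_grid <- pmax(2, 2 * ceiling(t_obs / 2))
      over <- t_grid > max_day
      t_grid[over] <- max_day
      event[over] <- 0L
      tibble::tibble(group = gname, time_days = t_grid,
                     event = as.integer(event), time_raw = t_death)
    })
    rows$id <- seq_len(nrow(rows))
    dplyr::relocate(rows, "id")
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Ct values consistent with the 2^-ddCt model: the treatment group's target
#' Ct is shifted by `-log2(fold)` relative to control, reference Ct is
#' common, and Gaussian noise of sd `noise_sd` is added to every Ct.
#'
#' @param true_fold_changes named per-target fold changes (> 0) of treatment
#'   over control.
#' @param reference_gene reference gene name.
#' @param replicates replicates per group.
#' @param noise_sd Gaussian Ct noise sd.
#' @param seed integer seed.
#' @param base_ct_target,base_ct_reference baseline Ct values.
#' @return tibble `(group, replicate, gene, ct)` with groups `control` and
#'   `treatment`.
#' @export
generate_ct_table <- function(true_fold_changes, reference_gene = "rp49",
                              replicates = 3L, noise_sd = 0, seed = 1L,
                              base_ct_target = 24, base_ct_reference = 18) {
  stopifnot(all(true_fold_changes > 0), !is.null(names(true_fold_changes)),
            replicates >= 1, noise_sd >= 0)
  with_seed(seed, {
    groups <- c("control", "treatment")
    rows <- list()
    for (g in groups) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = g, replicate = r, gene = reference_gene,
          ct = base_ct_reference + stats::rnorm(1, 0, noise_sd)
        )
        for (tg in names(true_fold_changes)) {
          shift <- if (g == "treatment") -log2(true_fold_changes[[tg]]) else 0
          rows[[length(rows) + 1L]] <- tibble::tibble(
            group = g, replicate = r, gene = tg,
            ct = base_ct_target + shift + stats::rnorm(1, 0, noise_sd)
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a ground-truth table and parameter echo
#' @param truth ground-truth tibble from a generator.
#' @param params the [synthesis_params()] used.
#' @param csv_path,json_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truth, params, csv_path, json_path) {
  utils::write.csv(as.data.frame(truth), csv_path, row.names = FALSE)
  echo <- params
  echo$marker_model <- lapply(echo$marker_model, as.list)
  class(echo) <- NULL
  jsonlite::write_json(echo, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}
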