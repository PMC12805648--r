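# Shared fixture builders. Everything is generated in code at test time.

# minimal single-channel stack from an array
tiny_stack <- function(arr, vox = c(1, 0.4, 0.4), name = "ch") {
  ch <- list(arr)
  names(ch) <- name
  image_stack(ch, vox)
}

# small noise-free gut parameters used across detection/classification tests
noisefree_params <- function(n_cells = 60, seed = 1,
                             proportions = c(ISC = 0.15, EEP = 0.1,
                                             EE_mature = 0.15, other = 0.6)) {
  synthesis_params(
    image_shape_voxels = c(12, 160, 160),
    voxel_size_um = c(1, 0.4, 0.4),
    n_cells = n_cells,
    class_proportions = proportions,
    noise_model = list(gaussian_sd = 0, poisson_scale = 0),
    psf_sigma_um = c(xy = 0, z = 0),
    seed = seed
  )
}

# surface set built directly from a label array (bypasses segmentation)
surfaces_from_labels <- function(labels, vox = c(1, 0.4, 0.4)) {
  ss <- midgutcyto:::new_surface_set(labels, vox)
  ss$frame <- list(dim = dim(labels), voxel_size_um = as.numeric(vox))
  ss
}

# spot table in a given frame from a coordinate matrix (z, y, x in um)
spots_at <- function(coords, frame = NULL, channel = "test") {
  coords <- matrix(coords, ncol = 3)
  spot_set(tibble::tibble(
    z_um = coords[, 1], y_um = coords[, 2], x_um = coords[, 3],
    radius_xy_um = 1.875, radius_z_um = 2.5,
    channel = channel, quality = 1
  ), frame = frame)
}

# independent exhaustive oracle for spot-to-surface proximity: per spot,
# distance 0 if its containing voxel is foreground, else the minimum over all
# foreground voxel centres; nearest label with exact ties to the smallest.
oracle_close_to_surface <- function(spots, surfaces, threshold_um) {
  labels <- surfaces$labels
  vox <- surfaces$voxel_size_um
  d <- dim(labels)
  fg_lin <- which(labels > 0L)
  fg_idx <- arrayInd(fg_lin, d)
  fg_um <- sweep(fg_idx - 0.5, 2, vox, `*`)
  fg_lab <- labels[fg_lin]
  n <- nrow(spots)
  dist <- numeric(n); lab <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- c(spots$z_um[i], spots$y_um[i], spots$x_um[i])
    ivox <- pmin(pmax(ceiling(p / vox), 1L), d)
    if (labels[ivox[1], ivox[2], ivox[3]] > 0L) {
      dist[i] <- 0
      lab[i] <- labels[ivox[1], ivox[2], ivox[3]]
    } else if (length(fg_lin) > 0L) {
      dd <- sqrt((fg_um[, 1] - p[1])^2 + (fg_um[, 2] - p[2])^2 +
                   (fg_um[, 3] - p[3])^2)
      dist[i] <- min(dd)
      lab[i] <- min(fg_lab[dd == min(dd)])
    } else {
      dist[i] <- Inf
    }
  }
  close <- dist <= threshold_um
  list(close = close, dist = dist,
       label = ifelse(close, lab, NA_integer_))
}

# random proximity scene: a few ellipsoidal surfaces plus uniform spots
random_proximity_scene <- function(seed, max_spots = 200, max_surfaces = 5,
                                   shape = c(10, 24, 24),
                                   vox = c(1, 0.5, 0.5)) {
  set.seed(seed)
  labels <- array(0L, shape)
  n_surf <- sample.int(max_surfaces, 1)
  ext <- shape * vox
  idx <- arrayInd(seq_along(labels), shape)
  pos <- sweep(idx - 0.5, 2, vox, `*`)
  for (l in seq_len(n_surf)) {
    c0 <- runif(3, 0.2, 0.8) * ext
    r0 <- runif(3, c(1.5, 1.5, 1.5), c(3, 3, 3))
    inside <- ((pos[, 1] - c0[1]) / r0[1])^2 + ((pos[, 2] - c0[2]) / r0[2])^2 +
      ((pos[, 3] - c0[3]) / r0[3])^2 <= 1
    labels[inside & labels == 0L] <- l
  }
  # renumber to consecutive labels (an ellipsoid may be fully occluded)
  present <- sort(unique(labels[labels > 0L]))
  relab <- integer(max(c(labels, 1)))
  relab[present] <- seq_along(present)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  surfaces <- surfaces_from_labels(labels, vox)
  n_spots <- sample.int(max_spots, 1)
  coords <- cbind(runif(n_spots, 0, ext[1]), runif(n_spots, 0, ext[2]),
                  runif(n_spots, 0, ext[3]))
  spots <- spots_at(coords, frame = surfaces$frame)
  list(spots = spots, surfaces = surfaces)
}

# greedy 1:1 matching of detected spots to planted centres within tol_um
match_to_truth <- function(spots, truth, tol_um) {
  if (nrow(spots) == 0L || nrow(truth) == 0L) return(integer())
  ds <- spot_matrix_truth_dist(spots, truth)
  matched <- rep(NA_integer_, nrow(truth))
  used <- logical(nrow(spots))
  ord <- order(ds)
  for (k in ord) {
    i <- (k - 1L) %% nrow(spots) + 1L
    j <- (k - 1L) %/% nrow(spots) + 1L
    if (ds[i, j] > tol_um) break
    if (!used[i] && is.na(matched[j])) {
      matched[j] <- i
      used[i] <- TRUE
    }
  }
  matched
}

spot_matrix_truth_dist <- function(spots, truth) {
  sqrt(outer(spots$z_um, truth$z_um, `-`)^2 +
         outer(spots$y_um, truth$y_um, `-`)^2 +
         outer(spots$x_um, truth$x_um, `-`)^2)
}
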