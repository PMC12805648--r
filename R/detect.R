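#' Spot tables (SpotSet)
#'
#' Detected point objects are plain tibbles with one row per spot and columns
#' `spot_id`, `z_um`, `y_um`, `x_um` (physical centroid), `radius_xy_um`,
#' `radius_z_um`, `channel` and `quality` (the scale-normalized
#' Laplacian-of-Gaussian response at the detection maximum; arbitrary units).
#' The physical frame of the source stack travels along as the `frame`
#' attribute so proximity operations can verify that inputs share a
#' coordinate system.
#'
#' @param df data frame with the columns above (missing `spot_id` is filled).
#' @param frame frame descriptor of the source stack (internal; pass a stack's
#'   frame when building spot tables by hand for the same geometry).
#' @return a `spot_set` tibble.
#' @export
spot_set <- function(df, frame = NULL) {
  df <- tibble::as_tibble(df)
  needed <- c("z_um", "y_um", "x_um", "radius_xy_um", "radius_z_um",
              "channel", "quality")
  for (col in setdiff(needed, names(df))) {
    df[[col]] <- switch(col,
                        radius_xy_um = 1, radius_z_um = 1,
                        channel = NA_character_, quality = NA_real_)
  }
  if (!"spot_id" %in% names(df)) {
    df$spot_id <- seq_len(nrow(df))
  }
  df <- dplyr::relocate(df, "spot_id")
  if (nrow(df) > 0) {
    stopifnot(all(is.finite(df$z_um)), all(is.finite(df$y_um)),
              all(is.finite(df$x_um)),
              all(df$radius_xy_um > 0), all(df$radius_z_um > 0))
    if (!is.null(frame)) {
      ext <- frame$dim * frame$voxel_size_um
      inside <- df$z_um >= 0 & df$z_um <= ext[1] &
        df$y_um >= 0 & df$y_um <= ext[2] &
        df$x_um >= 0 & df$x_um <= ext[3]
      if (!all(inside)) stop("spot centroids outside the image extent", call. = FALSE)
    }
  }
  attr(df, "frame") <- frame
  class(df) <- c("spot_set", class(df))
  df
}

spot_frame <- function(spots) attr(spots, "frame")

spot_matrix_um <- function(spots) {
  cbind(z = spots$z_um, y = spots$y_um, x = spots$x_um)
}

#' Detect blob-like objects with an anisotropic Laplacian of Gaussian
#'
#' Nuclei and nuclear markers appear as roughly Gaussian blobs whose xy and z
#' extents differ (confocal anisotropy), so detection runs a scale-normalized
#' LoG filter at per-axis sigmas derived from the requested physical
#' diameters: `sigma = diameter / (2 * sqrt(3))` per axis, the scale at which
#' the 3D LoG response of a blob of that diameter peaks. Local maxima of the
#' response (26-neighbourhood) above `quality_threshold` become spots; their
#' centroids are refined to sub-voxel precision by an intensity-weighted
#' centre of mass within one radius, and near-duplicates closer than one
#' (anisotropy-normalized) radius are suppressed keeping the higher quality.
#'
#' @param stack an [image_stack()] (already conditioned, e.g. via
#'   [gaussian_smooth()] and [subtract_background()]).
#' @param channel channel to detect in.
#' @param diameter_xy_um,diameter_z_um expected object diameter in um. For
#'   midgut nuclei 3.5-4 um xy (default midpoint 3.75) and 5 um z; autophagy
#'   puncta use 0.7 um.
#' @param quality_threshold numeric threshold on the LoG response, or
#'   `"otsu"` (default) to separate object maxima from noise maxima with
#'   Otsu's method on the response distribution of all local maxima. The
#'   threshold actually used is recorded in the `quality_threshold` attribute.
#' @return a [spot_set()] tibble, one row per detected spot.
#' @export
detect_spots <- function(stack, channel, diameter_xy_um, diameter_z_um,
                         quality_threshold = "otsu") {
  check_channel(stack, channel)
  stopifnot(diameter_xy_um > 0, diameter_z_um > 0)
  vox <- stack$voxel_size_um
  sigma_um <- c(z = diameter_z_um, y = diameter_xy_um, x = diameter_xy_um) /
    (2 * sqrt(3))
  sigma_vox <- sigma_um / vox
  ch <- get_channel(stack, channel)
  sm <- gaussian_blur_3d(ch, sigma_vox)
  # scale-normalized anisotropic LoG: -sum_axis sigma_ax^2 d2/d(ax)^2
  resp <- -(sigma_vox[1]^2 * second_derivative_axis(sm, 1) +
              sigma_vox[2]^2 * second_derivative_axis(sm, 2) +
              sigma_vox[3]^2 * second_derivative_axis(sm, 3))
  mx <- local_maxima_3d(resp)
  if (length(mx) == 0L) {
    return(spot_set(empty_spot_df(channel), stack_frame(stack)))
  }
  q <- resp[mx]
  thr <- if (identical(quality_threshold, "otsu")) {
    otsu_threshold(q)
  } else {
    as.numeric(quality_threshold)
  }
  keep <- q >= thr & q > 0
  mx <- mx[keep]; q <- q[keep]
  if (length(mx) == 0L) {
    out <- spot_set(empty_spot_df(channel), stack_frame(stack))
    attr(out, "quality_threshold") <- thr
    return(out)
  }
  d <- dim(resp)
  coord <- arrayInd(mx, d)  # (z, y, x) voxel indices
  # sub-voxel centre-of-mass refinement in a +/- one-radius window
  rad_vox <- pmax(1L, as.integer(round(
    c(diameter_z_um / 2, diameter_xy_um / 2, diameter_xy_um / 2) / vox)))
  cen <- matrix(0, nrow(coord), 3)
  for (i in seq_len(nrow(coord))) {
    cen[i, ] <- refine_centroid(sm, coord[i, ], rad_vox)
  }
  pos_um <- sweep(cen - 0.5, 2, vox, `*`)
  df <- tibble::tibble(
    z_um = pos_um[, 1], y_um = pos_um[, 2], x_um = pos_um[, 3],
    radius_xy_um = diameter_xy_um / 2,
    radius_z_um = diameter_z_um / 2,
    channel = channel,
    quality = q
  )
  df <- suppress_duplicates(df)
  out <- spot_set(df, stack_frame(stack))
  attr(out, "quality_threshold") <- thr
  out
}

empty_spot_df <- function(channel) {
  tibble::tibble(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                 radius_xy_um = numeric(), radius_z_um = numeric(),
                 channel = character(), quality = numeric())
}

# linear indices of strict 26-neighbourhood local maxima (borders excluded
# by -Inf padding)
local_maxima_3d <- function(arr) {
  d <- dim(arr)
  if (any(d < 3L)) return(integer())
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L) - 1L] <- arr
  core <- function(dz, dy, dx) {
    pad[(2:(d[1] + 1L)) + dz, (2:(d[2] + 1L)) + dy, (2:(d[3] + 1L)) + dx]
  }
  is_max <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    is_max <- is_max & (arr > core(dz, dy, dx))
    if (!any(is_max)) return(integer())
  }
  which(is_max)
}

refine_centroid <- function(img, idx, rad_vox) {
  d <- dim(img)
  lo <- pmax(idx - rad_vox, 1L)
  hi <- pmin(idx + rad_vox, d)
  win <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  w <- pmax(win - min(win), 0)
  tw <- sum(w)
  if (tw <= 0) return(as.numeric(idx))
  dz <- dim(w)
  zi <- slice.index(w, 1); yi <- slice.index(w, 2); xi <- slice.index(w, 3)
  c(sum(w * zi), sum(w * yi), sum(w * xi)) / tw + (lo - 1L)
}

# greedy duplicate suppression: keep highest-quality spot among any pair
# closer than one anisotropy-normalized radius
suppress_duplicates <- function(df) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(-df$quality, df$z_um, df$y_um, df$x_um)
  df <- df[ord, ]
  keep <- logical(nrow(df))
  kz <- ky <- kx <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (length(kz) > 0) {
      nd <- sqrt(((df$z_um[i] - kz) / df$radius_z_um[i])^2 +
                   ((df$y_um[i] - ky) / df$radius_xy_um[i])^2 +
                   ((df$x_um[i] - kx) / df$radius_xy_um[i])^2)
      if (any(nd < 1)) next
    }
    keep[i] <- TRUE
    kz <- c(kz, df$z_um[i]); ky <- c(ky, df$y_um[i]); kx <- c(kx, df$x_um[i])
  }
  df[keep, ]
}

#' Labeled surface segmentation (SurfaceSet)
#'
#' Segments a (conditioned) marker channel into labeled 3D regions: the
#' channel is lightly smoothed, thresholded (Otsu by default), connected
#' components are labeled with 26-connectivity, interior holes are filled
#' (cytoplasmic markers form shells around the nucleus; the enclosed volume
#' belongs to the cell), and components smaller than `min_volume_um3` are
#' discarded. Labels are renumbered to consecutive positive integers; 0 is
#' background.
#'
#' @param stack an [image_stack()].
#' @param channel marker channel (e.g. the Esg/YFP reporter).
#' @param min_volume_um3 minimum component volume in cubic micrometres.
#' @param threshold intensity threshold or `"otsu"` (default).
#' @param smooth_sigma_um pre-threshold smoothing sigma in um (default 0.5).
#' @param fill_holes fill enclosed background cavities per component
#'   (default `TRUE`).
#' @return a `surface_set`: list with `labels` (integer array), `table`
#'   (tibble: label, n_voxels, volume_um3), `voxel_size_um`, `dimensionality`.
#' @export
segment_surfaces <- function(stack, channel, min_volume_um3 = 0,
                             threshold = "otsu", smooth_sigma_um = 0.5,
                             fill_holes = TRUE) {
  check_channel(stack, channel)
  ch <- get_channel(stack, channel)
  if (smooth_sigma_um > 0) {
    ch <- gaussian_blur_3d(ch, smooth_sigma_um / stack$voxel_size_um)
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(as.vector(ch)) else
    as.numeric(threshold)
  mask <- is.finite(thr) & ch > thr
  if (!any(mask)) {
    return(new_surface_set(array(0L, dim(ch)), stack$voxel_size_um,
                           frame = stack_frame(stack)))
  }
  labels <- label_components_3d(mask)
  if (fill_holes) labels <- fill_holes_3d(labels)
  vox_vol <- prod(stack$voxel_size_um)
  counts <- tabulate(labels[labels > 0L])
  keep <- which(counts * vox_vol >= min_volume_um3)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  pos <- labels > 0L
  out[pos] <- relab[labels[pos]]
  new_surface_set(out, stack$voxel_size_um, frame = stack_frame(stack))
}

new_surface_set <- function(labels, voxel_size_um, frame = NULL,
                            dimensionality = length(dim(labels))) {
  counts <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer()
  vox_vol <- prod(voxel_size_um)
  tab <- tibble::tibble(
    label = seq_along(counts),
    n_voxels = as.integer(counts),
    volume_um3 = counts * vox_vol
  )
  structure(
    list(labels = labels, table = tab,
         voxel_size_um = as.numeric(voxel_size_um),
         dimensionality = dimensionality, frame = frame),
    class = "surface_set"
  )
}

#' @export
print.surface_set <- function(x, ...) {
  cat("<surface_set> ", nrow(x$table), " labeled region(s), ",
      x$dimensionality, "D\n", sep = "")
  print(x$table, n = 5)
  invisible(x)
}

n_surfaces <- function(surfaces) nrow(surfaces$table)

# 26-connectivity (8 in 2D) connected-component labeling by vectorized
# frontier flood fill on linear indices of a FALSE-padded mask.
label_components_3d <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  if (nd == 3L) {
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    lin_off <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  } else {
    pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
    offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    lin_off <- offs[, 1] + offs[, 2] * dp[1]
  }
  lab <- integer(length(pad))
  fg <- which(pad)
  next_label <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    next_label <- next_label + 1L
    lab[seed] <- next_label
    frontier <- seed
    while (length(frontier) > 0L) {
      cand <- unique(as.vector(outer(frontier, lin_off, `+`)))
      cand <- cand[pad[cand] & lab[cand] == 0L]
      lab[cand] <- next_label
      frontier <- cand
    }
  }
  lab_arr <- array(lab, dp)
  if (nd == 3L) {
    out <- lab_arr[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  } else {
    out <- lab_arr[2:(d[1] + 1L), 2:(d[2] + 1L), drop = FALSE]
  }
  array(out, d)
}

# Fill background cavities: background components (6/4-connectivity) not
# reachable from the image border are holes; each hole is assigned the label
# of its (unique, else smallest) enclosing component.
fill_holes_3d <- function(labels) {
  d <- dim(labels)
  bg_labels <- label_components_3d(labels == 0L)
  if (max(bg_labels) == 0L) return(labels)
  border_ids <- border_values(bg_labels)
  hole_ids <- setdiff(seq_len(max(bg_labels)), border_ids[border_ids > 0L])
  if (length(hole_ids) == 0L) return(labels)
  out <- labels
  for (h in hole_ids) {
    hv <- which(bg_labels == h)
    neigh <- neighbor_labels(labels, hv, d)
    if (length(neigh) > 0L) out[hv] <- min(neigh)
  }
  out
}

border_values <- function(arr) {
  d <- dim(arr)
  if (length(d) == 3L) {
    unique(c(arr[c(1, d[1]), , ], arr[, c(1, d[2]), ], arr[, , c(1, d[3])]))
  } else {
    unique(c(arr[c(1, d[1]), ], arr[, c(1, d[2])]))
  }
}

neighbor_labels <- function(labels, lin_idx, d) {
  nd <- length(d)
  idx <- arrayInd(lin_idx, d)
  vals <- integer(0)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      shifted <- idx
      shifted[, ax] <- pmin(pmax(shifted[, ax] + s, 1L), d[ax])
      lin <- shifted[, 1]
      mult <- 1L
      for (a in seq_len(nd - 1L)) {
        mult <- mult * d[a]
        lin <- lin + (shifted[, a + 1L] - 1L) * mult
      }
      vals <- c(vals, labels[lin])
    }
  }
  unique(vals[vals > 0L])
}

#' Split touching surfaces by seed points
#'
#' Cytoplasmic reporters of neighbouring cells can blur into a single
#' connected component; connected-component labels then no longer correspond
#' to cells. Given seed points (typically detected nuclei), every foreground
#' voxel is reassigned to its nearest seed (Euclidean distance in um), i.e. a
#' Voronoi partition of the segmented foreground. The returned label `k`
#' corresponds to the `k`-th seed row.
#'
#' @param surfaces a `surface_set`.
#' @param seeds a [spot_set()] of seed points in the same frame.
#' @return a `surface_set` with one label per seed (possibly empty labels for
#'   seeds whose Voronoi cell contains no foreground).
#' @export
split_surfaces <- function(surfaces, seeds) {
  stopifnot(inherits(surfaces, "surface_set"))
  check_same_frame(spot_frame(seeds), surfaces$frame, "seeds and surfaces")
  if (nrow(seeds) == 0L) {
    warning("no seeds: surfaces returned unchanged", call. = FALSE)
    return(surfaces)
  }
  lin <- which(surfaces$labels > 0L)
  out <- array(0L, dim(surfaces$labels))
  if (length(lin) > 0L) {
    idx <- arrayInd(lin, dim(surfaces$labels))
    vox <- surfaces$voxel_size_um
    coords <- sweep(idx - 0.5, 2, vox, `*`)
    sm <- spot_matrix_um(seeds)
    chunk <- max(1L, floor(5e6 / nrow(sm)))
    nearest <- integer(length(lin))
    for (start in seq(1L, length(lin), by = chunk)) {
      ii <- start:min(start + chunk - 1L, length(lin))
      d2 <- outer(coords[ii, 1], sm[, 1], `-`)^2 +
        outer(coords[ii, 2], sm[, 2], `-`)^2 +
        outer(coords[ii, 3], sm[, 3], `-`)^2
      nearest[ii] <- max.col(-d2, ties.method = "first")
    }
    out[lin] <- nearest
  }
  res <- new_surface_set(out, surfaces$voxel_size_um, frame = surfaces$frame)
  # keep one (possibly empty) row per seed
  full <- tibble::tibble(label = seq_len(nrow(seeds)))
  tab <- dplyr::left_join(full, res$table, by = "label")
  tab$n_voxels[is.na(tab$n_voxels)] <- 0L
  tab$volume_um3[is.na(tab$volume_um3)] <- 0
  res$table <- tab
  res
}

#' Identify 2D primary objects in a processed projection
#'
#' CellProfiler-style primary-object identification on a rescaled/denoised
#' projection: Otsu threshold, distance-transform watershed to split touching
#' objects, then a size gate on the equivalent circular diameter.
#'
#' @param image2d processed 2D image (from [rescale_and_denoise()]), with a
#'   `pixel_size_um` attribute or via `pixel_size_um`.
#' @param diameter_range_um length-2 vector; objects whose equivalent diameter
#'   falls outside are discarded.
#' @param pixel_size_um `(dy, dx)` pixel size override in um.
#' @return a 2D `surface_set` (labels matrix + per-object table with
#'   `area_px` and `area_um2`).
#' @export
identify_primary_objects_2d <- function(image2d, diameter_range_um,
                                        pixel_size_um = NULL) {
  stopifnot(is.matrix(image2d), length(diameter_range_um) == 2L,
            diameter_range_um[1] >= 0, diff(diameter_range_um) >= 0)
  if (is.null(pixel_size_um)) pixel_size_um <- attr(image2d, "pixel_size_um")
  if (is.null(pixel_size_um)) {
    stop("pixel size unknown: supply `pixel_size_um`", call. = FALSE)
  }
  pixel_size_um <- rep(as.numeric(pixel_size_um), length.out = 2L)
  thr <- otsu_threshold(as.vector(image2d))
  mask <- is.finite(thr) & image2d > thr
  if (!any(mask)) {
    return(surface_set_2d(array(0L, dim(image2d)), pixel_size_um))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(image2d),
                   ncol(image2d))
  px_area <- prod(pixel_size_um)
  counts <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer()
  eq_diam <- 2 * sqrt(counts * px_area / pi)
  keep <- which(eq_diam >= diameter_range_um[1] &
                  eq_diam <= diameter_range_um[2] & counts > 0L)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0L
  out[pos] <- relab[labels[pos]]
  surface_set_2d(out, pixel_size_um)
}

surface_set_2d <- function(labels, pixel_size_um) {
  counts <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer()
  px_area <- prod(pixel_size_um)
  tab <- tibble::tibble(
    label = seq_along(counts),
    n_voxels = as.integer(counts),
    area_px = as.integer(counts),
    area_um2 = counts * px_area
  )
  structure(
    list(labels = labels, table = tab,
         voxel_size_um = as.numeric(pixel_size_um),
         dimensionality = 2L,
         frame = list(dim = dim(labels), voxel_size_um = pixel_size_um)),
    class = "surface_set"
  )
}

#' Write a spot table to CSV
#' @param spots a [spot_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(spots, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE)
  invisible(path)
}
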