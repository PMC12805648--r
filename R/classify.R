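#' Classification parameters
#'
#' Proximity thresholds for the marker-combinatoric cell typing. A spot is
#' "close" to a surface iff its centroid-to-surface distance is less than or
#' equal to `close_threshold_um` (ties count as close); the published pipeline
#' used 0.5 or 1 um, default 0.5. Spot-to-spot colocalization uses
#' `coloc_threshold_um`, default 5 um.
#'
#' @param close_threshold_um spot-to-surface threshold in um (>= 0).
#' @param coloc_threshold_um spot-to-spot colocalization threshold in um.
#' @return a `classification_params` list.
#' @export
classification_params <- function(close_threshold_um = 0.5,
                                  coloc_threshold_um = 5) {
  stopifnot(close_threshold_um >= 0, coloc_threshold_um >= 0)
  structure(list(close_threshold_um = close_threshold_um,
                 coloc_threshold_um = coloc_threshold_um,
                 tie_rule = "<="),
            class = "classification_params")
}

# physical coordinates (um, voxel centres) and labels of all foreground voxels
surface_foreground_um <- function(surfaces) {
  lin <- which(surfaces$labels > 0L)
  if (length(lin) == 0L) {
    return(list(coords = matrix(0, 0, 3), labels = integer()))
  }
  idx <- arrayInd(lin, dim(surfaces$labels))
  vox <- surfaces$voxel_size_um
  coords <- sweep(idx - 0.5, 2, vox, `*`)
  if (ncol(coords) == 2L) coords <- cbind(0, coords)
  list(coords = coords, labels = as.integer(surfaces$labels[lin]))
}

# label of the voxel containing each spot centroid (0 outside all surfaces)
containing_label <- function(spots, surfaces) {
  if (nrow(spots) == 0L) return(integer())
  vox <- surfaces$voxel_size_um
  d <- dim(surfaces$labels)
  pos <- spot_matrix_um(spots)
  if (length(d) == 2L) { pos <- pos[, 2:3, drop = FALSE] }
  idx <- sweep(pos, 2, vox, `/`)
  idx <- pmin(pmax(ceiling(idx), 1L), matrix(rep(d, each = nrow(idx)),
                                             nrow = nrow(idx)))
  lin <- idx[, 1]
  mult <- 1L
  for (a in seq_len(length(d) - 1L)) {
    mult <- mult * d[a]
    lin <- lin + (idx[, a + 1L] - 1L) * mult
  }
  as.integer(surfaces$labels[lin])
}

#' Partition spots by distance to the nearest labeled surface
#'
#' For each spot the distance is the Euclidean distance in micrometres from
#' its centroid to the nearest foreground voxel centre of any surface, and 0
#' if the centroid lies inside a surface. A spot is close iff
#' `distance <= threshold_um`. Each close spot is assigned to its nearest
#' surface label; exact distance ties go to the smallest label.
#'
#' @param spots a [spot_set()].
#' @param surfaces a `surface_set` from [segment_surfaces()] in the same
#'   physical frame.
#' @param threshold_um proximity threshold in um.
#' @return list with `close` and `far` (disjoint [spot_set()]s whose union is
#'   the input) and `assignment` (tibble: spot_id, surface_label,
#'   distance_um for every input spot; label `NA` for far spots).
#' @export
spots_close_to_surface <- function(spots, surfaces, threshold_um) {
  stopifnot(inherits(surfaces, "surface_set"), threshold_um >= 0)
  check_same_frame(spot_frame(spots), surfaces$frame, "spots and surfaces")
  n <- nrow(spots)
  if (n == 0L) {
    asg <- tibble::tibble(spot_id = integer(), surface_label = integer(),
                          distance_um = numeric())
    return(list(close = spots, far = spots, assignment = asg))
  }
  fg <- surface_foreground_um(surfaces)
  inside <- containing_label(spots, surfaces)
  dist <- rep(Inf, n)
  lab <- rep(NA_integer_, n)
  dist[inside > 0L] <- 0
  lab[inside > 0L] <- inside[inside > 0L]
  todo <- which(inside == 0L)
  if (length(todo) > 0L && nrow(fg$coords) > 0L) {
    nn <- nearest_foreground(spot_matrix_um(spots)[todo, , drop = FALSE], fg)
    dist[todo] <- nn$dist
    lab[todo] <- nn$label
  }
  is_close <- dist <= threshold_um
  asg <- tibble::tibble(
    spot_id = spots$spot_id,
    surface_label = ifelse(is_close, lab, NA_integer_),
    distance_um = dist
  )
  list(close = spots[is_close, ], far = spots[!is_close, ], assignment = asg)
}

# chunked exact nearest-foreground-voxel search (vectorized all-pairs within
# memory-bounded chunks; ties resolved to the smallest label)
nearest_foreground <- function(pos, fg, chunk_target = 5e6) {
  n_fg <- nrow(fg$coords)
  n <- nrow(pos)
  chunk <- max(1L, floor(chunk_target / n_fg))
  dist <- numeric(n); lab <- integer(n)
  fz <- fg$coords[, 1]; fy <- fg$coords[, 2]; fx <- fg$coords[, 3]
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    d2 <- outer(pos[ii, 1], fz, `-`)^2 +
      outer(pos[ii, 2], fy, `-`)^2 +
      outer(pos[ii, 3], fx, `-`)^2
    mins <- apply(d2, 1, min)
    for (k in seq_along(ii)) {
      at_min <- which(d2[k, ] == mins[k])
      lab[ii[k]] <- min(fg$labels[at_min])
    }
    dist[ii] <- sqrt(mins)
  }
  list(dist = dist, label = lab)
}

#' Greedy nearest-pair spot colocalization
#'
#' Candidate pairs closer than `threshold_um` are sorted by distance (ties by
#' spot ids) and accepted greedily so each spot is used at most once —
#' mirroring object-colocalization in commercial spot tools.
#'
#' @param a,b [spot_set()]s in the same frame.
#' @param threshold_um maximum pairing distance in um.
#' @return tibble with `a_id`, `b_id`, `distance_um`, one row per matched
#'   pair.
#' @export
colocalize_spots <- function(a, b, threshold_um) {
  stopifnot(threshold_um >= 0)
  check_same_frame(spot_frame(a), spot_frame(b), "spot sets")
  empty <- tibble::tibble(a_id = integer(), b_id = integer(),
                          distance_um = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  pa <- spot_matrix_um(a); pb <- spot_matrix_um(b)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2 +
    outer(pa[, 3], pb[, 3], `-`)^2
  cand <- which(d2 <= threshold_um^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  dd <- sqrt(d2[cand])
  ord <- order(dd, a$spot_id[cand[, 1]], b$spot_id[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]; dd <- dd[ord]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  tibble::tibble(a_id = a$spot_id[cand[keep, 1]],
                 b_id = b$spot_id[cand[keep, 2]],
                 distance_um = dd[keep])
}

#' Classify midgut populations from nuclei, Prospero spots and marker surfaces
#'
#' Implements the marker-combinatoric typing used for midgut population
#' counts: Prospero spots close to an Esg/YFP surface are enteroendocrine
#' progenitors (EEP, Pros+ Esg+); Prospero spots far from any surface are
#' mature enteroendocrine cells (Pros+ Esg-); nuclei (DAPI spots) close to a
#' surface count all Esg/YFP+ cells; the ISC count is that total minus the
#' EEP count (floored at zero with a warning when detection noise drives it
#' negative). Percentages are over the total nucleus count.
#'
#' @param dapi nuclei [spot_set()].
#' @param pros Prospero [spot_set()].
#' @param marker_surfaces Esg/YFP `surface_set`.
#' @param params a [classification_params()].
#' @return list with `cells` (tibble: one row per nucleus, marker profile and
#'   class) and `counts` (a `population_counts` tibble: class, count,
#'   total_nuclei, percent).
#' @export
classify_populations <- function(dapi, pros, marker_surfaces,
                                 params = classification_params()) {
  stopifnot(inherits(params, "classification_params"))
  thr <- params$close_threshold_um
  pr <- spots_close_to_surface(pros, marker_surfaces, thr)
  da <- spots_close_to_surface(dapi, marker_surfaces, thr)
  n_eep <- nrow(pr$close)
  n_ee <- nrow(pr$far)
  n_marker <- nrow(da$close)
  n_isc <- n_marker - n_eep
  if (n_isc < 0) {
    warning("ISC count ", n_isc, " floored at 0 ",
            "(more Pros+ than DAPI+ spots near surfaces)", call. = FALSE)
    n_isc <- 0L
  }
  total <- nrow(dapi)
  # per-nucleus table: pair nuclei with Pros spots to attach the Pros marker
  coloc <- colocalize_spots(dapi, pros, params$coloc_threshold_um)
  dapi_close <- da$assignment$distance_um <= thr
  has_pros <- dapi$spot_id %in% coloc$a_id
  cells <- tibble::tibble(
    cell_id = dapi$spot_id,
    esg = dapi_close,
    pros = has_pros,
    class = dplyr::case_when(
      dapi_close & has_pros ~ "EEP",
      dapi_close & !has_pros ~ "ISC",
      !dapi_close & has_pros ~ "EE_mature",
      TRUE ~ "unclassified"
    )
  )
  counts <- population_counts(
    tibble::tibble(class = c("ISC", "EEP", "EE_mature"),
                   count = c(n_isc, n_eep, n_ee)),
    total_nuclei = total
  )
  list(cells = cells, counts = counts)
}

population_counts <- function(df, total_nuclei) {
  stopifnot(all(df$count >= 0), length(total_nuclei) == 1L)
  pct <- if (total_nuclei > 0) 100 * df$count / total_nuclei else
    rep(0, nrow(df))
  out <- tibble::tibble(
    class = df$class,
    count = as.integer(df$count),
    total_nuclei = as.integer(total_nuclei),
    percent = pct
  )
  stopifnot(all(out$percent >= 0), all(out$percent <= 100 + 1e-9))
  class(out) <- c("population_counts", class(out))
  out
}

#' Classify lineage-traced (ReDDM) populations
#'
#' In dual-stability lineage tracing, progenitors carry an unstable Esg-driven
#' marker plus a stable nuclear RFP that persists in their differentiated
#' progeny. RFP spots are partitioned by the Esg surface: far-RFP spots
#' (RFP+ Esg-) are newly differentiated cells, split into new enteroendocrine
#' cells (colocalized with a Prospero spot) and new enterocytes (colocalized
#' with a nucleus but not Prospero); Esg-close RFP spots colocalized with
#' Prospero are EEPs. Percentages are over the total nucleus count.
#'
#' @param dapi,pros,rfp [spot_set()]s for nuclei, Prospero, lineage label.
#' @param esg_surfaces Esg `surface_set`.
#' @param params a [classification_params()].
#' @return list with `cells` (one row per RFP spot: marker profile, class) and
#'   `counts` (`population_counts` for new_EE, new_EC, EEP).
#' @export
classify_reddm <- function(dapi, pros, rfp, esg_surfaces,
                           params = classification_params()) {
  stopifnot(inherits(params, "classification_params"))
  rp <- spots_close_to_surface(rfp, esg_surfaces, params$close_threshold_um)
  far <- rp$far; close <- rp$close
  m_pros_far <- colocalize_spots(far, pros, params$coloc_threshold_um)
  new_ee_ids <- m_pros_far$a_id
  far_rest <- far[!far$spot_id %in% new_ee_ids, ]
  m_dapi <- colocalize_spots(far_rest, dapi, params$coloc_threshold_um)
  new_ec_ids <- m_dapi$a_id
  m_pros_close <- colocalize_spots(close, pros, params$coloc_threshold_um)
  eep_ids <- m_pros_close$a_id
  ids <- rfp$spot_id
  cls <- dplyr::case_when(
    ids %in% new_ee_ids ~ "new_EE",
    ids %in% new_ec_ids ~ "new_EC",
    ids %in% eep_ids ~ "EEP",
    TRUE ~ "unclassified"
  )
  cells <- tibble::tibble(
    cell_id = ids,
    esg = ids %in% close$spot_id,
    pros = ids %in% c(new_ee_ids, eep_ids),
    rfp = rep(TRUE, length(ids)),
    class = cls
  )
  counts <- population_counts(
    tibble::tibble(class = c("new_EE", "new_EC", "EEP"),
                   count = c(length(new_ee_ids), length(new_ec_ids),
                             length(eep_ids))),
    total_nuclei = nrow(dapi)
  )
  list(cells = cells, counts = counts)
}

#' Count puncta per cell surface
#'
#' Assigns each punctum (e.g. a Ref(2)P autophagy dot) to the surface label
#' whose region contains its centroid; a punctum outside all surfaces is
#' assigned to the nearest surface if within `close_threshold_um`, otherwise
#' it lands in the remainder bin and increments no cell.
#'
#' @param puncta puncta [spot_set()].
#' @param cell_surfaces cell `surface_set` (e.g. Esg+ ISC surfaces).
#' @param close_threshold_um rescue distance for puncta just outside a
#'   surface (default 0: strict containment).
#' @return tibble with one row per surface label (`label`, `n_puncta`) plus
#'   attributes `n_unassigned` (remainder bin) and `assignment` (per-punctum
#'   label, `NA` for remainder).
#' @export
count_puncta_per_cell <- function(puncta, cell_surfaces,
                                  close_threshold_um = 0) {
  stopifnot(inherits(cell_surfaces, "surface_set"), close_threshold_um >= 0)
  check_same_frame(spot_frame(puncta), cell_surfaces$frame,
                   "puncta and surfaces")
  labs <- cell_surfaces$table$label
  if (nrow(puncta) == 0L) {
    out <- tibble::tibble(label = labs, n_puncta = rep(0L, length(labs)))
    attr(out, "n_unassigned") <- 0L
    attr(out, "assignment") <- integer()
    return(out)
  }
  assigned <- containing_label(puncta, cell_surfaces)
  if (close_threshold_um > 0 && any(assigned == 0L)) {
    todo <- which(assigned == 0L)
    fg <- surface_foreground_um(cell_surfaces)
    if (nrow(fg$coords) > 0L) {
      nn <- nearest_foreground(spot_matrix_um(puncta)[todo, , drop = FALSE], fg)
      rescue <- nn$dist <= close_threshold_um
      assigned[todo[rescue]] <- nn$label[rescue]
    }
  }
  counts <- vapply(labs, function(l) sum(assigned == l), 0L)
  out <- tibble::tibble(label = labs, n_puncta = counts)
  attr(out, "n_unassigned") <- sum(assigned == 0L)
  attr(out, "assignment") <- ifelse(assigned == 0L, NA_integer_, assigned)
  out
}

#' Enteroblast proportion
#'
#' Ratio of Su(H)-reporter-positive enteroblasts to CFP+ Esg+ progenitor
#' cells, both given as detected spot tables.
#'
#' @param suh_spots Su(H)-GFP+ [spot_set()].
#' @param cfp_spots CFP+ Esg+ [spot_set()].
#' @return single numeric ratio.
#' @export
enteroblast_ratio <- function(suh_spots, cfp_spots) {
  if (nrow(cfp_spots) == 0L) {
    stop("undefined enteroblast ratio: no CFP+ Esg+ cells detected",
         call. = FALSE)
  }
  nrow(suh_spots) / nrow(cfp_spots)
}

#' Count mitotic cells
#'
#' Validates phospho-histone-3 spots by colocalization with a nucleus within
#' `coloc_threshold_um` and reports the mitotic percentage over total nuclei.
#'
#' @param ph3_spots pH3 [spot_set()].
#' @param dapi nuclei [spot_set()].
#' @param coloc_threshold_um colocalization threshold in um (default 5).
#' @return tibble with `n_mitotic`, `total_nuclei`, `percent`.
#' @export
count_mitotic <- function(ph3_spots, dapi, coloc_threshold_um = 5) {
  m <- colocalize_spots(ph3_spots, dapi, coloc_threshold_um)
  n <- nrow(m)
  total <- nrow(dapi)
  tibble::tibble(
    n_mitotic = n,
    total_nuclei = total,
    percent = if (total > 0) 100 * n / total else 0
  )
}

#' Write population counts to CSV
#' @param counts a `population_counts` tibble.
#' @param path output path.
#' @param gut_id optional gut identifier column.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path, gut_id = NA) {
  df <- as.data.frame(counts)
  df$gut_id <- gut_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
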