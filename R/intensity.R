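#' Integrated intensity per 2D object
#'
#' Sums raw pixel values over each labeled object's pixel set. Intensities
#' must come from the unprocessed projection: segmentation runs on processed
#' images, measurement on the original, and this function enforces only the
#' grid match, recording the separation in its output attributes.
#'
#' @param raw_projection unmodified 2D projection (matrix) on the same pixel
#'   grid as `objects`.
#' @param objects 2D `surface_set` from [identify_primary_objects_2d()].
#' @return tibble with `label`, `area_px`, `integrated_intensity`.
#' @export
measure_object_intensity <- function(raw_projection, objects) {
  stopifnot(inherits(objects, "surface_set"), objects$dimensionality == 2L)
  if (!identical(unname(dim(raw_projection)), unname(dim(objects$labels)))) {
    stop("grid mismatch: projection is ", paste(dim(raw_projection), collapse = "x"),
         " but objects are ", paste(dim(objects$labels), collapse = "x"),
         call. = FALSE)
  }
  labs <- objects$table$label
  if (length(labs) == 0L) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          integrated_intensity = numeric()))
  }
  lv <- objects$labels
  pos <- lv > 0L
  sums <- rowsum(as.numeric(raw_projection[pos]), group = lv[pos])
  got <- as.integer(rownames(sums))
  intensity <- stats::setNames(rep(0, length(labs)), labs)
  intensity[as.character(got)] <- sums[, 1]
  out <- tibble::tibble(
    label = labs,
    area_px = objects$table$area_px,
    integrated_intensity = as.numeric(intensity[as.character(labs)])
  )
  attr(out, "measured_on") <- "raw_projection"
  out
}

#' Per-gut mean reporter intensity per cell
#'
#' @param object_intensities tibble from [measure_object_intensity()].
#' @return single numeric: mean integrated intensity per object (one value
#'   per cell, unweighted by area).
#' @export
gut_mean_intensity <- function(object_intensities) {
  if (nrow(object_intensities) == 0L) return(NA_real_)
  mean(object_intensities$integrated_intensity)
}

#' Normalize per-gut reporter intensities to the control group
#'
#' Relative fluorescence intensity (RFI): each gut's mean per-cell intensity
#' divided by the mean of the control group, so the control mean is exactly
#' 1. When a `batch` column is present the normalization is per batch
#' (per independent experiment); otherwise pooled.
#'
#' @param per_gut_means data frame with columns `group` and `mean_per_cell`
#'   (one row per intestine), optionally `batch`.
#' @param control_group name of the control group.
#' @return input tibble with an added `normalized_rfi` column.
#' @export
normalize_rfi <- function(per_gut_means, control_group) {
  df <- tibble::as_tibble(per_gut_means)
  stopifnot(all(c("group", "mean_per_cell") %in% names(df)))
  if (!control_group %in% df$group) {
    stop("control group '", control_group, "' not present", call. = FALSE)
  }
  if (!"batch" %in% names(df)) df$batch <- 1L
  out <- df |>
    dplyr::group_by(.data$batch) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$mean_per_cell[d$group == control_group]
      if (length(ctrl) == 0L) {
        stop("control group missing in batch ", key$batch, call. = FALSE)
      }
      cm <- mean(ctrl)
      if (!is.finite(cm) || cm <= 0) {
        stop("control group mean must be positive", call. = FALSE)
      }
      d$normalized_rfi <- d$mean_per_cell / cm
      d
    }) |>
    dplyr::ungroup()
  out
}
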