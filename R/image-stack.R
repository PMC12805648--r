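#' Multichannel 3D image stack with physical voxel sizes
#'
#' An `image_stack` bundles one 3D intensity array per named channel with the
#' voxel size along each axis in micrometres. All downstream operations
#' (smoothing scales, spot diameters, proximity thresholds) are expressed in
#' micrometres and converted to voxels internally using these sizes.
#'
#' Axis order is `(z, y, x)` throughout. Voxel `i` (1-based) along an axis of
#' spacing `d` has its centre at physical coordinate `(i - 0.5) * d`, so the
#' physical extent of an axis with `n` voxels is `n * d`.
#'
#' @param channels named list of numeric 3D arrays, all with identical
#'   dimensions, finite and non-negative.
#' @param voxel_size_um numeric length-3 vector `(dz, dy, dx)` in micrometres,
#'   all strictly positive.
#' @param metadata optional named list of provenance fields carried along.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um, metadata = list()) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of 3D arrays", call. = FALSE)
  }
  if (anyDuplicated(names(channels))) {
    stop("channel names must be unique", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("every channel must be a 3D array (z, y, x)", call. = FALSE)
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!all(is.finite(v))) stop("channel '", nm, "' has non-finite values", call. = FALSE)
    if (min(v) < 0) stop("channel '", nm, "' has negative intensities", call. = FALSE)
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop("`voxel_size_um` must be three strictly positive values (dz, dy, dx)",
         call. = FALSE)
  }
  names(voxel_size_um) <- c("z", "y", "x")
  structure(
    list(channels = channels, voxel_size_um = voxel_size_um,
         metadata = metadata),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<image_stack> ", paste(d, collapse = " x "), " voxels (z y x)\n", sep = "")
  cat("  voxel size (um): ", paste(format(x$voxel_size_um), collapse = " x "), "\n", sep = "")
  cat("  channels: ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Channel names of an image stack
#' @param stack an [image_stack()].
#' @return character vector.
#' @export
channel_names <- function(stack) names(stack$channels)

#' Extract one channel as a 3D array
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return numeric 3D array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  check_channel(stack, channel)
  stack$channels[[channel]]
}

check_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.character(channel) || length(channel) != 1L ||
      !channel %in% names(stack$channels)) {
    stop("unknown channel '", paste(channel, collapse = ","), "'; available: ",
         paste(names(stack$channels), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

set_channel <- function(stack, channel, value) {
  stopifnot(identical(dim(value), dim(stack$channels[[1]])))
  stack$channels[[channel]] <- value
  stack
}

#' Physical extent of a stack in micrometres
#' @param stack an [image_stack()].
#' @return numeric `(z, y, x)` extents in um.
#' @export
stack_extent_um <- function(stack) {
  dim(stack) * stack$voxel_size_um
}

# Physical frame descriptor used to check that spots/surfaces/stacks live in
# the same coordinate system before any proximity computation.
stack_frame <- function(stack) {
  list(dim = dim(stack), voxel_size_um = unname(stack$voxel_size_um))
}

frames_match <- function(a, b, tol = 1e-9) {
  identical(as.integer(a$dim), as.integer(b$dim)) &&
    max(abs(a$voxel_size_um - b$voxel_size_um)) <= tol
}

check_same_frame <- function(a, b, what = "inputs") {
  if (is.null(a) || is.null(b)) return(invisible(TRUE))
  if (!frames_match(a, b)) {
    stop("frame mismatch: ", what,
         " have different voxel sizes or extents", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an image stack to multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z planes of channel 1, then channel 2,
#' ...), stored as 32-bit float scaled to `[0, 1]`. The sidecar
#' (`<path>.json`) records axis order, channel names, voxel sizes in um and
#' the intensity scale so [read_stack()] can restore the stack losslessly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(vapply(stack$channels, max, 0), 1e-12)
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]] / mx
    for (z in seq_len(dim(arr)[1])) {
      pages[[length(pages) + 1L]] <- arr[z, , ]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(
    format = "midgutcyto-stack-v1",
    axes = "czyx",
    shape_zyx = as.integer(dim(stack)),
    channel_names = names(stack$channels),
    voxel_size_um = as.numeric(stack$voxel_size_um),
    intensity_scale = mx,
    metadata = stack$metadata
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Voxel sizes and channel names are taken from the JSON sidecar; both can be
#' overridden. A plain TIFF without sidecar and without explicit
#' `voxel_size_um` + `channel_names` overrides is an error, because physical
#' units are required by every downstream step.
#'
#' @param path TIFF path.
#' @param voxel_size_um optional `(dz, dy, dx)` override in um.
#' @param channel_names optional channel-name override.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size_um = NULL, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  scale <- 1
  if (!is.null(meta)) {
    if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
    if (is.null(channel_names)) channel_names <- meta$channel_names
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(voxel_size_um) || is.null(channel_names)) {
    stop("no metadata sidecar found for '", path,
         "'; supply `voxel_size_um` and `channel_names` explicitly",
         call. = FALSE)
  }
  n_ch <- length(channel_names)
  if (length(pages) %% n_ch != 0L) {
    stop("page count ", length(pages), " is not a multiple of ", n_ch,
         " channels", call. = FALSE)
  }
  nz <- length(pages) %/% n_ch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  channels <- list()
  for (ci in seq_len(n_ch)) {
    arr <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) {
      pg <- pages[[(ci - 1L) * nz + z]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # grayscale stored with alpha
      arr[z, , ] <- pg
    }
    channels[[channel_names[ci]]] <- arr * scale
  }
  image_stack(channels, voxel_size_um,
              metadata = if (is.null(meta$metadata)) list() else meta$metadata)
}
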