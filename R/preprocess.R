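#' Anisotropic Gaussian smoothing of one channel
#'
#' Smooths a channel with a Gaussian whose standard deviation is given in
#' micrometres; the per-axis sigma in voxels is `sigma_um / voxel_size` for
#' that axis, so the physical footprint of the filter is isotropic even on
#' anisotropic stacks (e.g. confocal z-steps coarser than the xy pixel size).
#' Borders are handled by symmetric reflection, which conserves total
#' intensity. `sigma_um = 0` is the identity.
#'
#' @param stack an [image_stack()].
#' @param channel channel to smooth; other channels are untouched.
#' @param sigma_um Gaussian sigma in micrometres (>= 0). The population
#'   pipeline uses 0.6 um.
#' @return the stack with the channel replaced by its smoothed version.
#' @export
gaussian_smooth <- function(stack, channel, sigma_um) {
  check_channel(stack, channel)
  stopifnot(is.numeric(sigma_um), length(sigma_um) == 1L, sigma_um >= 0)
  if (sigma_um == 0) return(stack)
  sig_vox <- sigma_um / stack$voxel_size_um
  set_channel(stack, channel,
              gaussian_blur_3d(get_channel(stack, channel), sig_vox))
}

#' Gaussian high-pass background subtraction
#'
#' Estimates the background as a wide Gaussian blur of the channel at
#' `scale_um` and subtracts it, clipping at zero. Structures much smaller than
#' `scale_um` (nuclei, puncta) survive nearly intact while slowly varying
#' background (tissue autofluorescence, uneven illumination) is removed. The
#' population pipeline uses 10 um for nuclei, 5 um for Prospero and 20 um for
#' the Esg/YFP and RFP channels.
#'
#' @param stack an [image_stack()].
#' @param channel channel to filter.
#' @param scale_um background scale in micrometres (> 0), used as the Gaussian
#'   sigma. Set `scale_is_diameter = TRUE` to interpret it as a diameter
#'   (sigma = scale/2) instead.
#' @param scale_is_diameter interpret `scale_um` as a diameter rather than a
#'   sigma.
#' @return the stack with the channel background-subtracted (everywhere >= 0).
#' @export
subtract_background <- function(stack, channel, scale_um,
                                scale_is_diameter = FALSE) {
  check_channel(stack, channel)
  stopifnot(is.numeric(scale_um), length(scale_um) == 1L, scale_um > 0)
  sigma_um <- if (scale_is_diameter) scale_um / 2 else scale_um
  ch <- get_channel(stack, channel)
  bg <- gaussian_blur_3d(ch, sigma_um / stack$voxel_size_um)
  set_channel(stack, channel, pmax(ch - bg, 0))
}

#' Maximal z-projection of one channel
#'
#' @param stack an [image_stack()].
#' @param channel channel to project.
#' @param z_range integer range of z planes to include (default all).
#' @return a 2D matrix `(y, x)` with attributes `pixel_size_um` (dy, dx) and
#'   `channel`.
#' @export
max_project <- function(stack, channel, z_range = NULL) {
  check_channel(stack, channel)
  ch <- get_channel(stack, channel)
  nz <- dim(ch)[1]
  if (is.null(z_range)) z_range <- seq_len(nz)
  z_range <- as.integer(z_range)
  if (length(z_range) == 0L) stop("empty z_range", call. = FALSE)
  if (any(z_range < 1L | z_range > nz)) {
    stop("z_range out of bounds [1, ", nz, "]", call. = FALSE)
  }
  out <- Reduce(pmax, lapply(z_range, function(z) ch[z, , ]))
  dim(out) <- unname(dim(out))
  attr(out, "pixel_size_um") <- unname(stack$voxel_size_um[c("y", "x")])
  attr(out, "channel") <- channel
  out
}

#' Robust intensity rescaling and median denoising of a 2D projection
#'
#' Mirrors a CellProfiler-style "rescale intensity" + "reduce noise" pair:
#' intensities are affinely mapped to `[0, 1]` between robust percentile
#' limits (clipping beyond them), then passed through a 3x3 median filter to
#' knock out shot/salt noise while preserving edges. Intended to precede 2D
#' object identification; intensity measurement must use the unprocessed
#' projection.
#'
#' @param image2d numeric matrix (a projection from [max_project()]).
#' @param probs lower/upper percentile limits for the rescale (defaults 0.5%
#'   and 99.5%).
#' @return matrix in `[0, 1]` with the input's attributes preserved. A
#'   constant input returns all zeros with a warning.
#' @export
rescale_and_denoise <- function(image2d, probs = c(0.005, 0.995)) {
  stopifnot(is.matrix(image2d), all(is.finite(image2d)))
  lim <- stats::quantile(image2d, probs = probs, names = FALSE)
  if (diff(lim) <= 0) {
    warning("constant image: rescale is degenerate, returning zeros",
            call. = FALSE)
    out <- matrix(0, nrow(image2d), ncol(image2d))
  } else {
    out <- (image2d - lim[1]) / (lim[2] - lim[1])
    out[out < 0] <- 0
    out[out > 1] <- 1
    out <- median_filter_3x3(out)
  }
  attributes(out) <- c(attributes(out)[c("dim")],
                       attributes(image2d)[setdiff(names(attributes(image2d)), "dim")])
  out
}

# 3x3 median filter with edge-replicated borders (EBImage's constant-time
# median filter; input must be in [0, 1], which rescaling guarantees).
median_filter_3x3 <- function(img) {
  m <- EBImage::medianFilter(EBImage::Image(img), size = 1)
  matrix(EBImage::imageData(m), nrow(img), ncol(img))
}
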