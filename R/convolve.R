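# Internal separable filtering primitives.
#
# All 3D filters in the package are separable and use symmetric (reflect with
# edge repeat) border handling. With a normalized kernel this border rule
# redistributes out-of-bound taps back inside the image, so the total image
# intensity is conserved exactly.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# indices implementing symmetric padding of length n by r on both sides
reflect_index <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  # half-sample symmetric extension, periodic with period 2n so that any
  # radius (even r >= n) keeps the redistribution exact:
  # ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
  i <- (1L - r):(n + r)
  j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# convolve a 3D array along one axis (1 = z, 2 = y, 3 = x) with kernel k;
# small kernels use direct shifted adds, large ones an exact FFT path
# (identical result up to floating-point rounding)
convolve_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr * k)
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- prod(dim(a)[-1])
  mat <- matrix(a, nrow = n, ncol = m)
  r <- (length(k) - 1L) %/% 2L
  pad <- mat[reflect_index(n, r), , drop = FALSE]
  out <- if (length(k) <= 48L) {
    conv_direct(pad, k, n)
  } else {
    conv_fft(pad, k, n)
  }
  res <- array(out, dim(a))
  aperm(res, order(perm))
}

conv_direct <- function(pad, k, n) {
  out <- matrix(0, nrow = n, ncol = ncol(pad))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

conv_fft <- function(pad, k, n, chunk_target = 4e6) {
  m <- nrow(pad)
  L <- length(k)
  kf <- stats::fft(c(k, rep(0, m - L)))
  out <- matrix(0, nrow = n, ncol = ncol(pad))
  chunk <- max(1L, floor(chunk_target / m))
  for (start in seq(1L, ncol(pad), by = chunk)) {
    jj <- start:min(start + chunk - 1L, ncol(pad))
    y <- stats::mvfft(stats::mvfft(pad[, jj, drop = FALSE]) * kf,
                      inverse = TRUE) / m
    out[, jj] <- Re(y[L:(L + n - 1L), , drop = FALSE])
  }
  out
}

# anisotropic separable Gaussian blur, sigmas given per axis in voxels
gaussian_blur_3d <- function(arr, sigma_vox) {
  out <- arr
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      out <- convolve_axis(out, gaussian_kernel_1d(sigma_vox[ax]), ax)
    }
  }
  out
}

# second finite difference along an axis (unit voxel spacing)
second_derivative_axis <- function(arr, axis) {
  convolve_axis(arr, c(1, -2, 1), axis)
}

# Otsu threshold on a numeric vector (maximises between-class variance over a
# fixed-bin histogram). Returns a value separating the two modes.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins = n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_mu <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (tot_mu * w0[valid] - tot_w * mu[-n_bins][valid])^2 /
    (w0[valid] * w1[valid])
  br[-c(1L, n_bins + 1L)][which.max(between)]
}
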