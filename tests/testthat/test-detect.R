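test_that("detect_spots on an empty image returns an empty spot table", {
  st <- tiny_stack(array(0, c(8, 40, 40)), c(1, 0.4, 0.4))
  sp <- detect_spots(st, "ch", 3.75, 5, quality_threshold = 0.1)
  expect_s3_class(sp, "spot_set")
  expect_equal(nrow(sp), 0L)
  expect_error(detect_spots(st, "nope", 3.75, 5), "unknown channel")
  expect_error(detect_spots(st, "ch", -1, 5))
})

test_that("a single noise-free nucleus is found within half a voxel", {
  p <- noisefree_params(n_cells = 1, seed = 13)
  g <- generate_midgut_stack(p)
  sp <- detect_spots(g$stack, "dapi", 3.75, 5, quality_threshold = 1)
  expect_equal(nrow(sp), 1L)
  vox <- g$stack$voxel_size_um
  expect_lt(abs(sp$z_um - g$truth$z_um) / vox[1], 0.5)
  expect_lt(abs(sp$y_um - g$truth$y_um) / vox[2], 0.5)
  expect_lt(abs(sp$x_um - g$truth$x_um) / vox[3], 0.5)
})

test_that("20 planted nuclei at SNR 10 are matched 1:1 within one voxel", {
  p <- synthesis_params(
    image_shape_voxels = c(12, 160, 160), n_cells = 20,
    class_proportions = c(other = 1),
    noise_model = list(gaussian_sd = 20, poisson_scale = 0),
    psf_sigma_um = c(xy = 0, z = 0), seed = 17)
  g <- generate_midgut_stack(p)
  st <- gaussian_smooth(g$stack, "dapi", 0.6)
  st <- subtract_background(st, "dapi", 10)
  sp <- detect_spots(st, "dapi", 3.75, 5)
  expect_equal(nrow(sp), 20L)
  matched <- match_to_truth(sp, g$truth, tol_um = 1.0)
  expect_true(all(!is.na(matched)))
  expect_equal(length(unique(matched)), 20L)
})

test_that("raising the quality threshold never adds spots", {
  p <- noisefree_params(n_cells = 25, seed = 19)
  p$noise_model <- list(gaussian_sd = 10, poisson_scale = 1)
  g <- generate_midgut_stack(p)
  st <- gaussian_smooth(g$stack, "dapi", 0.6)
  prev <- Inf
  for (thr in c(0.5, 2, 10, 50, 200)) {
    n <- nrow(detect_spots(st, "dapi", 3.75, 5, quality_threshold = thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("noise-free detection has perfect recall and precision for well-separated nuclei", {
  p <- noisefree_params(n_cells = 15, seed = 23)
  g <- generate_midgut_stack(p)
  sp <- detect_spots(g$stack, "dapi", 3.75, 5, quality_threshold = 1)
  expect_equal(nrow(sp), nrow(g$truth))
  matched <- match_to_truth(sp, g$truth, tol_um = 0.5)
  expect_true(all(!is.na(matched)))
})

test_that("segment_surfaces labels disjoint shells with near-analytic volumes", {
  # two far-apart Esg+ cells, no blur/noise; threshold at half peak so the
  # segmented shell has a closed-form volume
  p <- synthesis_params(
    image_shape_voxels = c(14, 120, 120), n_cells = 2,
    class_proportions = c(ISC = 1),
    noise_model = list(gaussian_sd = 0, poisson_scale = 0),
    psf_sigma_um = c(xy = 0, z = 0), seed = 3)
  g <- generate_midgut_stack(p)
  level <- p$intensity_levels[["esg"]]
  surf <- segment_surfaces(g$stack, "esg", threshold = level / 2,
                           smooth_sigma_um = 0, fill_holes = FALSE)
  expect_equal(nrow(surf$table), 2L)
  rz <- 2.5; rxy <- 1.875; th <- 1
  u0 <- 1 + (th / 2) / rxy
  su <- (th / 2) / (2 * rxy)
  delta <- su * sqrt(2 * log(2))
  v_analytic <- 4 / 3 * pi * rz * rxy^2 * ((u0 + delta)^3 - (u0 - delta)^3)
  for (v in surf$table$volume_um3) {
    expect_lt(abs(v - v_analytic) / v_analytic, 0.10)
  }
  # per-label volume = voxel count x voxel volume
  expect_equal(surf$table$volume_um3,
               surf$table$n_voxels * prod(g$stack$voxel_size_um))

  # all-zero image: no labels, not an error
  st0 <- tiny_stack(array(0, c(6, 20, 20)), c(1, 0.4, 0.4))
  expect_equal(nrow(segment_surfaces(st0, "ch")$table), 0L)
})

test_that("hole filling assigns enclosed cavities to the surrounding label", {
  # closed box shell with a hollow interior: the cavity must be absorbed
  arr <- array(0, c(12, 30, 30))
  arr[3:9, 8:20, 8:20] <- 100   # solid box
  arr[4:8, 10:18, 10:18] <- 0   # carve the cavity
  st <- tiny_stack(arr, c(1, 0.4, 0.4))
  open_shell <- segment_surfaces(st, "ch", threshold = 50,
                                 smooth_sigma_um = 0, fill_holes = FALSE)
  filled <- segment_surfaces(st, "ch", threshold = 50,
                             smooth_sigma_um = 0, fill_holes = TRUE)
  expect_equal(nrow(filled$table), 1L)
  cavity_voxels <- 5 * 9 * 9
  expect_equal(filled$table$n_voxels,
               open_shell$table$n_voxels + cavity_voxels)
  # a point in the cavity is inside the filled surface but not the open shell
  centre <- spots_at(c(5.5, 14 * 0.4, 14 * 0.4), frame = filled$frame)
  expect_equal(midgutcyto:::containing_label(centre, filled), 1L)
  expect_equal(midgutcyto:::containing_label(centre, open_shell), 0L)
})

test_that("surface labels are equivariant under voxel translation", {
  set.seed(31)
  arr <- array(0, c(8, 40, 40))
  arr[3:5, 8:12, 8:12] <- 50
  arr[5:6, 25:30, 20:26] <- 80
  shift <- c(1, 4, 6)
  arr2 <- array(0, c(8, 40, 40))
  arr2[3:5 + shift[1], 8:12 + shift[2], 8:12 + shift[3]] <- 50
  arr2[5:6 + shift[1], 25:30 + shift[2], 20:26 + shift[3]] <- 80
  s1 <- segment_surfaces(tiny_stack(arr, c(1, 0.4, 0.4)), "ch",
                         threshold = 10, smooth_sigma_um = 0)
  s2 <- segment_surfaces(tiny_stack(arr2, c(1, 0.4, 0.4)), "ch",
                         threshold = 10, smooth_sigma_um = 0)
  expect_equal(nrow(s1$table), 2L)
  expect_equal(sort(s1$table$n_voxels), sort(s2$table$n_voxels))
})

test_that("2D primary objects: disk area, watershed split, blank image", {
  px <- c(0.5, 0.5)
  mk_disks <- function(centres, r, n = 80) {
    img <- matrix(0, n, n)
    for (k in seq_len(nrow(centres))) {
      for (y in 1:n) for (x in 1:n) {
        if ((y - centres[k, 1])^2 + (x - centres[k, 2])^2 <= r^2) {
          img[y, x] <- 1
        }
      }
    }
    img
  }
  one <- mk_disks(matrix(c(40, 40), 1), r = 10)
  obj1 <- identify_primary_objects_2d(one, c(2, 30), pixel_size_um = px)
  expect_equal(nrow(obj1$table), 1L)
  disk_area_um2 <- pi * 10^2 * prod(px)
  expect_lt(abs(obj1$table$area_um2 - disk_area_um2) / disk_area_um2, 0.10)

  two <- mk_disks(matrix(c(40, 31, 40, 47), 2, byrow = TRUE), r = 9)
  obj2 <- identify_primary_objects_2d(two, c(2, 30), pixel_size_um = px)
  expect_equal(nrow(obj2$table), 2L)

  blank <- matrix(0, 50, 50)
  obj0 <- identify_primary_objects_2d(blank, c(2, 30), pixel_size_um = px)
  expect_equal(nrow(obj0$table), 0L)
})
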