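test_that("spot inside a surface is close with distance 0; empty surfaces put all far", {
  labels <- array(0L, c(6, 20, 20))
  labels[3:4, 8:12, 8:12] <- 1L
  surf <- surfaces_from_labels(labels, c(1, 0.4, 0.4))
  inside <- spots_at(c(3.2, 4.0, 4.0), frame = surf$frame)
  res <- spots_close_to_surface(inside, surf, 0.5)
  expect_equal(nrow(res$close), 1L)
  expect_equal(res$assignment$distance_um, 0)
  expect_equal(res$assignment$surface_label, 1L)

  empty <- surfaces_from_labels(array(0L, c(6, 20, 20)), c(1, 0.4, 0.4))
  far <- spots_close_to_surface(inside, empty, 5)
  expect_equal(nrow(far$close), 0L)
  expect_equal(nrow(far$far), 1L)
})

test_that("proximity partition matches the exhaustive oracle on random scenes", {
  for (seed in 1:8) {
    sc <- random_proximity_scene(seed)
    for (thr in c(0.5, 1)) {
      res <- spots_close_to_surface(sc$spots, sc$surfaces, thr)
      orc <- oracle_close_to_surface(sc$spots, sc$surfaces, thr)
      expect_identical(res$assignment$distance_um <= thr, orc$close)
      expect_equal(res$assignment$distance_um, orc$dist)
      expect_identical(res$assignment$surface_label, orc$label)
      # partition property
      expect_equal(sort(c(res$close$spot_id, res$far$spot_id)),
                   sort(sc$spots$spot_id))
      expect_length(intersect(res$close$spot_id, res$far$spot_id), 0)
    }
  }
})

test_that("close/far is monotone in the threshold", {
  sc <- random_proximity_scene(99)
  n_close <- vapply(c(0, 0.25, 0.5, 1, 2, 5),
                    function(thr) nrow(spots_close_to_surface(
                      sc$spots, sc$surfaces, thr)$close), 0L)
  expect_true(all(diff(n_close) >= 0))
})

test_that("colocalize_spots: identical sets pair at distance 0; planted pairs beat decoys", {
  fr <- list(dim = c(10, 70, 70), voxel_size_um = c(1, 0.4, 0.4))
  set.seed(7)
  a <- spots_at(cbind(runif(10, 2, 8), runif(10, 2, 18), runif(10, 2, 18)),
                frame = fr)
  m <- colocalize_spots(a, a, 1)
  expect_equal(nrow(m), 10L)
  expect_equal(m$distance_um, rep(0, 10))
  expect_equal(m$a_id, m$b_id)

  expect_equal(nrow(colocalize_spots(a, spots_at(matrix(numeric(0), 0, 3),
                                                 frame = fr), 5)), 0L)

  # planted pairs at 3 um, decoys at 8 um, threshold 5 -> only planted pairs
  base <- cbind(c(3, 5, 7), c(4, 10, 16), c(4, 10, 16))
  partner <- base + matrix(rep(c(0, 3, 0), each = 3), 3)      # 3 um away
  decoy <- base + matrix(rep(c(0, 0, 8), each = 3), 3)        # 8 um away
  aa <- spots_at(base, frame = fr)
  bb <- spots_at(rbind(partner, decoy), frame = fr)
  mm <- colocalize_spots(aa, bb, 5)
  expect_equal(nrow(mm), 3L)
  expect_equal(sort(mm$b_id), 1:3)
  expect_equal(mm$distance_um, rep(3, 3))
})

test_that("population classification follows the marker-combinatoric rules", {
  labels <- array(0L, c(8, 40, 40))
  labels[3:5, 5:10, 5:10] <- 1L     # one Esg surface
  surf <- surfaces_from_labels(labels, c(1, 0.4, 0.4))
  fr <- surf$frame
  # nuclei: one inside the surface with Pros (EEP), one inside without
  # (ISC), one far with Pros (mature EE), one far plain (other)
  dapi <- spots_at(rbind(c(4, 3, 3), c(4, 2, 2), c(4, 12, 12), c(4, 14, 8)),
                   frame = fr)
  pros <- spots_at(rbind(c(4, 3, 3), c(4, 12, 12)), frame = fr)
  out <- classify_populations(dapi, pros, surf, classification_params())
  counts <- out$counts
  expect_equal(counts$count[counts$class == "EEP"], 1L)
  expect_equal(counts$count[counts$class == "EE_mature"], 1L)
  expect_equal(counts$count[counts$class == "ISC"], 1L)
  expect_equal(unique(counts$total_nuclei), 4L)
  expect_equal(counts$percent, c(25, 25, 25))
  # conservation: EEP + EE_mature equals the Pros spot count
  expect_equal(sum(counts$count[counts$class %in% c("EEP", "EE_mature")]),
               nrow(pros))
  # per-cell table classes
  expect_setequal(out$cells$class[1:2], c("EEP", "ISC"))
  expect_equal(out$cells$class[3], "EE_mature")

  # empty Pros set: EEP = EE_mature = 0, ISC = all marker cells
  out2 <- classify_populations(dapi, spots_at(matrix(numeric(0), 0, 3),
                                              frame = fr),
                               surf, classification_params())
  expect_equal(out2$counts$count, c(2L, 0L, 0L))
})

test_that("EEP conservation and ISC flooring hold under arbitrary inputs", {
  for (seed in 21:24) {
    sc <- random_proximity_scene(seed)
    n <- nrow(sc$spots)
    pros <- sc$spots[sample(n, min(n, 30)), ]
    out <- classify_populations(sc$spots, pros, sc$surfaces,
                                classification_params())
    cnt <- out$counts
    expect_equal(sum(cnt$count[cnt$class %in% c("EEP", "EE_mature")]),
                 nrow(pros))
    expect_true(all(cnt$percent >= 0 & cnt$percent <= 100))
    expect_true(all(cnt$count >= 0))
  }
  # flooring: more Pros-close spots than DAPI-close spots warns, floors at 0
  labels <- array(0L, c(4, 10, 10)); labels[2, 4:6, 4:6] <- 1L
  surf <- surfaces_from_labels(labels, c(1, 0.4, 0.4))
  pros <- spots_at(rbind(c(1.5, 2, 2), c(1.5, 2.2, 2.2)), frame = surf$frame)
  dapi <- spots_at(rbind(c(3.5, 3.6, 3.6), c(3.5, 0.4, 0.4),
                         c(3.5, 0.4, 3.6), c(3.5, 3.6, 0.4),
                         c(3.5, 2, 2)), frame = surf$frame)
  expect_warning(out <- classify_populations(dapi, pros, surf,
                                             classification_params(2, 5)),
                 "floored")
  expect_gte(out$counts$count[out$counts$class == "ISC"], 0)
})

test_that("increasing the close threshold never shrinks EEP nor grows mature EE", {
  sc <- random_proximity_scene(55)
  pros <- sc$spots[seq_len(min(nrow(sc$spots), 40)), ]
  dapi <- sc$spots
  prev_eep <- -1; prev_ee <- Inf
  for (thr in c(0.25, 0.5, 1, 2)) {
    out <- classify_populations(dapi, pros, sc$surfaces,
                                classification_params(thr, 5))
    eep <- out$counts$count[out$counts$class == "EEP"]
    ee <- out$counts$count[out$counts$class == "EE_mature"]
    expect_gte(eep, prev_eep)
    expect_lte(ee, prev_ee)
    prev_eep <- eep; prev_ee <- ee
  }
})

test_that("ReDDM classification separates new EEs, new ECs and EEPs", {
  labels <- array(0L, c(8, 40, 40))
  labels[3:5, 5:10, 5:10] <- 1L
  surf <- surfaces_from_labels(labels, c(1, 0.4, 0.4))
  fr <- surf$frame
  # RFP spots: one in the surface with Pros (EEP), one far with Pros
  # (new EE), one far with a nucleus only (new EC)
  rfp <- spots_at(rbind(c(4, 3, 3), c(4, 12, 12), c(4, 14, 6)), frame = fr)
  pros <- spots_at(rbind(c(4, 3, 3), c(4, 12, 12)), frame = fr)
  dapi <- spots_at(rbind(c(4, 3, 3), c(4, 12, 12), c(4, 14, 6), c(4, 2, 14)),
                   frame = fr)
  out <- classify_reddm(dapi, pros, rfp, surf, classification_params())
  expect_equal(out$cells$class, c("EEP", "new_EE", "new_EC"))
  cnt <- out$counts
  expect_equal(cnt$count[cnt$class == "new_EE"], 1L)
  expect_equal(cnt$count[cnt$class == "new_EC"], 1L)
  expect_equal(cnt$count[cnt$class == "EEP"], 1L)
  expect_equal(unique(cnt$total_nuclei), 4L)

  # no RFP spots -> all lineage counts 0
  out0 <- classify_reddm(dapi, pros,
                         spots_at(matrix(numeric(0), 0, 3), frame = fr),
                         surf, classification_params())
  expect_equal(out0$counts$count, c(0L, 0L, 0L))
})

test_that("puncta are counted per containing surface with a remainder bin", {
  labels <- array(0L, c(8, 30, 30))
  labels[2:6, 4:10, 4:10] <- 1L
  labels[2:6, 18:24, 18:24] <- 2L
  surf <- surfaces_from_labels(labels, c(1, 0.4, 0.4))
  fr <- surf$frame
  # no puncta -> all zero
  res0 <- count_puncta_per_cell(spots_at(matrix(numeric(0), 0, 3), frame = fr),
                                surf)
  expect_equal(res0$n_puncta, c(0L, 0L))

  # 5 puncta in cell 1, none elsewhere
  pts <- cbind(runif(5, 1.6, 5.4), runif(5, 1.7, 3.9), runif(5, 1.7, 3.9))
  res5 <- count_puncta_per_cell(spots_at(pts, frame = fr), surf)
  expect_equal(res5$n_puncta[res5$label == 1], 5L)
  expect_equal(res5$n_puncta[res5$label == 2], 0L)
  expect_equal(attr(res5, "n_unassigned"), 0L)

  # a punctum far outside all surfaces goes to the remainder bin
  outp <- spots_at(c(1, 11, 1), frame = fr)
  reso <- count_puncta_per_cell(outp, surf, close_threshold_um = 0.5)
  expect_equal(sum(reso$n_puncta), 0L)
  expect_equal(attr(reso, "n_unassigned"), 1L)
})

test_that("enteroblast ratio and mitotic counting follow their defining formulas", {
  fr <- list(dim = c(10, 40, 40), voxel_size_um = c(1, 0.4, 0.4))
  suh <- spots_at(cbind(runif(12, 1, 9), runif(12, 1, 15), runif(12, 1, 15)),
                  frame = fr)
  cfp <- spots_at(cbind(runif(48, 1, 9), runif(48, 1, 15), runif(48, 1, 15)),
                  frame = fr)
  expect_equal(enteroblast_ratio(suh, cfp), 0.25)
  expect_equal(enteroblast_ratio(cfp, cfp), 1.0)
  expect_error(enteroblast_ratio(suh, spots_at(matrix(numeric(0), 0, 3),
                                               frame = fr)),
               "undefined")

  # 2 pH3 spots near nuclei out of 400 nuclei -> 0.5%
  set.seed(2)
  dapi <- spots_at(cbind(runif(400, 1, 9), runif(400, 0.5, 15.5),
                         runif(400, 0.5, 15.5)), frame = fr)
  ph3 <- spots_at(rbind(as.matrix(dapi[5, c("z_um", "y_um", "x_um")]),
                        as.matrix(dapi[50, c("z_um", "y_um", "x_um")])),
                  frame = fr)
  mit <- count_mitotic(ph3, dapi, coloc_threshold_um = 5)
  expect_equal(mit$n_mitotic, 2L)
  expect_equal(mit$percent, 0.5)

  # a pH3 spot with no nucleus within threshold is excluded (oracle check)
  lonely <- spots_at(rbind(c(5, 8, 8), c(5, 8.2, 8.2)), frame = fr)
  nuclei <- spots_at(c(5, 1, 1), frame = fr)
  d_oracle <- sqrt(sum((c(5, 8, 8) - c(5, 1, 1))^2))
  expect_gt(d_oracle, 5)
  mit2 <- count_mitotic(lonely, nuclei, coloc_threshold_um = 5)
  expect_equal(mit2$n_mitotic, 0L)
})

test_that("a planted noise-free gut is classified exactly", {
  p <- noisefree_params(n_cells = 60, seed = 41)
  g <- generate_midgut_stack(p)
  dapi <- detect_spots(g$stack, "dapi", 3.75, 5, quality_threshold = 1)
  pros <- detect_spots(g$stack, "pros", 3.75, 5, quality_threshold = 1)
  surf <- segment_surfaces(g$stack, "esg", min_volume_um3 = 10)
  out <- classify_populations(dapi, pros, surf, classification_params())
  truth_counts <- table(factor(g$truth$class,
                               levels = c("ISC", "EEP", "EE_mature", "other")))
  cnt <- out$counts
  expect_equal(cnt$count[cnt$class == "ISC"],
               as.integer(truth_counts["ISC"]))
  expect_equal(cnt$count[cnt$class == "EEP"],
               as.integer(truth_counts["EEP"]))
  expect_equal(cnt$count[cnt$class == "EE_mature"],
               as.integer(truth_counts["EE_mature"]))
  expect_equal(unique(cnt$total_nuclei), 60L)
})
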