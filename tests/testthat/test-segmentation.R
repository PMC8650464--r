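test_that("artery segmentation recovers the rasterized arteries exactly", {
  gt <- small_ground_truth()
  thr <- segmentation_thresholds()
  art <- segment_arteries(gt$t1_map, gt$brain_mask, thr,
                          gt$artery_class_map)
  codes <- label_codes()
  expect_equal(art$artery, gt$labels$data == codes[["Artery"]])
  expect_equal(art$surface, gt$artery_class_map == 1L)
  expect_equal(art$branching, gt$artery_class_map == 2L)
})

test_that("degenerate artery thresholds warn instead of failing", {
  gt <- small_ground_truth()
  cmap <- gt$artery_class_map
  low <- segmentation_thresholds(artery_t1_max = 600)
  expect_warning(art <- segment_arteries(gt$t1_map, gt$brain_mask, low,
                                         cmap),
                 "no voxels")
  expect_false(any(art$artery))
  cmap_all <- array(1L, dim(cmap))
  high <- segmentation_thresholds(artery_t1_max = 2900)
  expect_warning(art2 <- segment_arteries(array(1000, dim(gt$t1_map)),
                                          gt$brain_mask, high, cmap_all),
                 "entire brain")
})

test_that("PAS segmentation combines threshold and distance (brute force)", {
  d <- c(21, 21, 5)
  # straight artery along y at x = 11, z = 3
  art_mask <- array(FALSE, d); art_mask[11, , 3] <- TRUE
  arteries <- list(artery = art_mask, surface = art_mask,
                   branching = array(FALSE, d))
  conc <- array(0.01, c(d, 1))
  hot <- abs(slice.index(array(0, d), 1) - 11) %in% 2:9  # ring in x
  conc[, , , 1][hot] <- 0.2
  cs <- conc_series(conc, 20, 0.1)
  thr <- segmentation_thresholds()
  pas <- segment_pas(cs, arteries, thr)
  # brute-force reference: threshold AND Chebyshev distance in [1, 7]
  art_idx <- which(art_mask, arr.ind = TRUE)
  for (v in sample(which(hot), 40)) {
    vi <- arrayInd(v, d)
    cheb <- min(apply(abs(sweep(art_idx, 2, vi)), 1, max))
    expect_equal(pas$pas_surf[v], cheb <= 7)
  }
  # cold voxels never become PAS
  expect_false(any(pas$pas_surf[!hot]))
  expect_equal(pas$time_used, 20)
})

test_that("all-cold concentration yields empty PAS masks", {
  d <- c(8, 8, 4)
  art <- array(FALSE, d); art[4, , 2] <- TRUE
  arteries <- list(artery = art, surface = art,
                   branching = array(FALSE, d))
  cs <- conc_series(array(0.05, c(d, 1)), 20, 0.1)
  pas <- segment_pas(cs, arteries, segmentation_thresholds())
  expect_false(any(pas$pas_surf) || any(pas$pas_branch))
})

test_that("voxels near both artery classes go to PAS_Branch", {
  d <- c(9, 9, 3)
  surf <- array(FALSE, d); surf[3, , 2] <- TRUE
  branch <- array(FALSE, d); branch[7, , 2] <- TRUE
  arteries <- list(artery = surf | branch, surface = surf,
                   branching = branch)
  cs <- conc_series(array(0.2, c(d, 1)), 20, 0.1)
  pas <- segment_pas(cs, arteries, segmentation_thresholds())
  expect_true(pas$pas_branch[5, 5, 2])   # distance 2 from both classes
  expect_false(pas$pas_surf[5, 5, 2])
})

test_that("raising pas_conc_min shrinks, raising distance grows PAS", {
  gt <- small_truth()
  thr0 <- segmentation_thresholds()
  art <- segment_arteries(gt$t1_map, gt$brain_mask, thr0,
                          gt$artery_class_map)
  n_pas <- function(thr) {
    p <- segment_pas(gt$concentration, art, thr)
    c(sum(p$pas_surf), sum(p$pas_branch))
  }
  base <- n_pas(thr0)
  stricter <- n_pas(segmentation_thresholds(pas_conc_min = 5))
  expect_true(all(stricter <= base))
  # each distance bound is monotone for its own class; the tie-break can
  # move voxels from PAS_Surf to PAS_Branch, so the union is what grows
  wider_s <- n_pas(segmentation_thresholds(surf_max_dist = 9))
  expect_gte(wider_s[1], base[1])
  wider_b <- n_pas(segmentation_thresholds(branch_max_dist = 5))
  expect_gte(wider_b[2], base[2])
  expect_gte(sum(wider_b), sum(base))
})

test_that("compose_labels applies precedence and covers the brain", {
  d <- c(4, 4, 2)
  brain <- array(TRUE, d)
  art <- array(FALSE, d); art[1, 1, 1] <- TRUE
  pas <- array(FALSE, d); pas[1, 1, 1] <- TRUE; pas[2, 1, 1] <- TRUE
  vent <- array(FALSE, d); vent[3, 1, 1] <- TRUE
  lab <- compose_labels(brain, art, vent, pas, array(FALSE, d), 0.1)
  codes <- label_codes()
  expect_equal(lab$data[1, 1, 1], codes[["Artery"]])     # artery > pas
  expect_equal(lab$data[2, 1, 1], codes[["PAS_Surf"]])
  expect_equal(lab$data[3, 1, 1], codes[["Ventricle"]])
  expect_equal(sum(lab$data == codes[["BT"]]), prod(d) - 3)
})

test_that("noiseless phantom end-to-end relabels >= 99% away from borders", {
  gt <- small_truth()
  acq <- acquisition_params()
  art <- artifact_spec(noise_sigma = 0, surface_dropout_voxels = 0L,
                       injection_dropout = Inf)
  sig <- synthesize_signal(gt$concentration, gt$t1_map, gt$brain_mask, acq,
                           art)
  t1fit <- fit_t1_vfa(sig$baseline_low, sig$baseline_high, acq)
  conc <- signal_to_concentration(sig, t1fit, acq)
  est <- segment_transport_regions(t1fit, conc, gt$brain_mask,
                                   segmentation_thresholds(),
                                   gt$artery_class_map)
  # interior = in-brain voxels more than 1 voxel from any true label change
  truth <- gt$labels$data
  interior <- gt$brain_mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- braintransport:::shift3(truth, dx, dy, dz,
                                       fill = label_codes()[["Background"]])
    interior <- interior & (shifted == truth)
  }
  agree <- mean(est$data[interior] == truth[interior])
  expect_gte(agree, 0.99)
  # determinism: identical inputs give identical labels
  est2 <- segment_transport_regions(t1fit, conc, gt$brain_mask,
                                    segmentation_thresholds(),
                                    gt$artery_class_map)
  expect_identical(est$data, est2$data)
})
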