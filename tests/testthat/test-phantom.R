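test_that("degenerate geometry: no arteries, no ventricles -> all BT", {
  spec <- phantom_spec(grid_shape = c(16, 16, 12),
                       brain_semi_axes = c(0.7, 0.7, 0.5),
                       artery_paths = list(),
                       ventricle_centers_radii = list())
  gt <- build_phantom(spec)
  counts <- label_counts(gt$labels)
  expect_equal(sum(counts), prod(dim(gt$labels$data)))
  expect_equal(unname(counts[["BT"]]), sum(gt$brain_mask))
  expect_true(all(counts[c("PAS_Surf", "PAS_Branch", "Artery",
                           "Ventricle")] == 0))
})

test_that("default phantom has five nonempty labels partitioning the grid", {
  gt <- small_ground_truth()
  counts <- label_counts(gt$labels)
  expect_true(all(counts[c("BT", "PAS_Surf", "PAS_Branch", "Artery",
                           "Ventricle")] > 0))
  expect_equal(sum(counts), prod(gt$spec$grid_shape))
  # Background is exactly the ellipsoid complement
  expect_equal(unname(counts[["Background"]]), sum(!gt$brain_mask))
})

test_that("PAS_Surf lies within Chebyshev distance 7 of surface arteries", {
  gt <- small_ground_truth()
  codes <- label_codes()
  surf_art <- gt$artery_class_map == 1L
  art_idx <- which(surf_art, arr.ind = TRUE)
  pas_idx <- which(gt$labels$data == codes[["PAS_Surf"]], arr.ind = TRUE)
  # brute-force Chebyshev distance from every PAS_Surf voxel to the artery
  for (r in sample(nrow(pas_idx), 50)) {
    dmin <- min(apply(abs(sweep(art_idx, 2, pas_idx[r, ])), 1, max))
    expect_lte(dmin, 7)
    expect_gte(dmin, 1)
  }
})

test_that("t1 map is exactly three-valued without jitter (simple tissues)", {
  spec <- phantom_spec(grid_shape = c(24, 24, 20),
                       brain_semi_axes = c(1.1, 1.1, 0.9),
                       pas_shell_voxels = c(surface = 0L, branching = 0L),
                       t1_by_tissue = c(BT = 1800, PAS_Surf = 1800,
                                        PAS_Branch = 1800, Artery = 800,
                                        Ventricle = 4000),
                       t1_jitter = 0)
  gt <- build_phantom(spec)
  vals <- sort(unique(gt$t1_map[gt$brain_mask]))
  expect_equal(vals, c(800, 1800, 4000))
})

test_that("artery path leaving the brain is rejected", {
  path <- list(list(points = rbind(c(0.1, 0.1, 0.1), c(3, 3, 2)),
                    radius = 0.1, class = "surface"))
  spec <- phantom_spec(grid_shape = c(24, 24, 20),
                       brain_semi_axes = c(1.0, 1.0, 0.8),
                       artery_paths = path)
  expect_error(build_phantom(spec), "exits the brain")
})

test_that("spec validation rejects non-physiological T1 and bad radii", {
  expect_error(phantom_spec(t1_by_tissue = c(BT = 100, PAS_Surf = 1900,
                                             PAS_Branch = 1900, Artery = 800,
                                             Ventricle = 4000)),
               "500-4500")
  expect_error(phantom_spec(t1_by_tissue = c(BT = 1800, PAS_Surf = 1900,
                                             PAS_Branch = 1900,
                                             Artery = 1300,
                                             Ventricle = 4000)),
               "artery T1")
  expect_error(phantom_spec(brain_semi_axes = c(-1, 2, 2)), "positive")
})

test_that("simulate_truth: zero source gives an all-zero series", {
  gt <- small_ground_truth()
  src <- source_spec(gt$spec$injection_site, rate = 0)
  out <- simulate_truth(gt, transport_params(), src,
                        frame_times = c(0, 10, 20))
  expect_equal(max(abs(out$concentration$data)), 0)
  expect_error(simulate_truth(gt, frame_times = c(-5, 0, 10)), ">= 0")
})

test_that("simulate_truth: PAS_Surf outpaces BT at t = 20 min", {
  gt <- small_truth()
  codes <- label_codes()
  fr <- nearest_frame(gt$concentration, 20)
  m_pas <- mean(fr$volume[gt$labels$data == codes[["PAS_Surf"]]])
  m_bt <- mean(fr$volume[gt$labels$data == codes[["BT"]]])
  expect_gt(m_pas, m_bt)
  # PAS voxels clear the segmentation threshold at the segmentation frame
  expect_gt(min(fr$volume[gt$labels$data == codes[["PAS_Surf"]]]), 0.15)
})

test_that("uniform-phantom truth matches the continuous point-source form", {
  # degenerate phantom (no arteries/ventricles) = one uniform subdomain;
  # the voxel-sampled concentration must follow the heat-kernel solution
  # away from the source (>= 3 cell diameters) before the boundary is felt
  spec <- phantom_spec(grid_shape = c(24, 24, 24),
                       brain_semi_axes = c(1.1, 1.1, 1.1),
                       artery_paths = list(),
                       ventricle_centers_radii = list(),
                       injection_site = c(1.25, 1.25, 1.25))
  gt <- build_phantom(spec)
  D <- 0.1; q <- 0.01; tprobe <- 1
  src <- source_spec(spec$injection_site, rate = q, start = 0, stop = 100)
  gt <- simulate_truth(gt, transport_params(c(BT = D, PAS_Surf = 1,
                                              PAS_Branch = 1)),
                       src, frame_times = c(0, tprobe),
                       cfg = solver_config(dt = 0.05))
  vol <- gt$concentration$data[, , , 2]
  idx <- which(gt$brain_mask, arr.ind = TRUE)
  rr <- sqrt(colSums((t(idx - 0.5) * 0.1 - spec$injection_site)^2))
  sel <- rr >= 3 * sqrt(3) * 0.1 & rr <= 0.7
  ana <- analytic_point_source(D, rr[sel], tprobe, "continuous", q = q)
  num <- vol[gt$brain_mask][sel]
  expect_lt(max(abs(num - ana) / ana), 0.05)
})

test_that("synthesize/invert round trip is the identity on concentration", {
  gt <- small_truth()
  acq <- acquisition_params()
  art <- artifact_spec(noise_sigma = 0, surface_dropout_voxels = 0L,
                       injection_dropout = Inf)
  sig <- synthesize_signal(gt$concentration, gt$t1_map, gt$brain_mask, acq,
                           art)
  t1fit <- fit_t1_vfa(sig$baseline_low, sig$baseline_high, acq)
  conc <- signal_to_concentration(sig, t1fit, acq)
  ib <- gt$brain_mask
  err <- max(abs(conc$data[, , , 3][ib] - gt$concentration$data[, , , 3][ib]))
  expect_lt(err, 1e-8)
})

test_that("zero concentration reproduces the high-angle baseline exactly", {
  gt <- small_ground_truth()
  cz <- conc_series(array(0, c(dim(gt$t1_map), 2)), c(0, 10),
                    gt$spec$voxel_size)
  sig <- synthesize_signal(cz, gt$t1_map, gt$brain_mask,
                           acquisition_params(),
                           artifact_spec(noise_sigma = 0,
                                         surface_dropout_voxels = 0L))
  expect_equal(sig$frames[, , , 1], sig$baseline_high)
  expect_equal(sig$frames[, , , 2], sig$baseline_high)
})

test_that("noise is seed-deterministic and seed-sensitive", {
  gt <- small_truth()
  acq <- acquisition_params()
  mk <- function(seed) synthesize_signal(gt$concentration, gt$t1_map,
                                         gt$brain_mask, acq,
                                         artifact_spec(seed = seed))
  expect_identical(mk(7L), mk(7L))
  expect_false(identical(mk(7L)$frames, mk(8L)$frames))
  # rician noise keeps signal non-negative
  artr <- artifact_spec(noise_model = "rician", seed = 3L)
  sigr <- synthesize_signal(gt$concentration, gt$t1_map, gt$brain_mask, acq,
                            artr)
  expect_gte(min(sigr$frames), 0)
})

test_that("synthesize_signal validates inputs", {
  gt <- small_ground_truth()
  neg <- conc_series(array(-1, c(dim(gt$t1_map), 1)), 10,
                     gt$spec$voxel_size)
  expect_error(synthesize_signal(neg, gt$t1_map, gt$brain_mask,
                                 acquisition_params()), ">= 0")
  t1bad <- gt$t1_map
  t1bad[which(gt$brain_mask)[1]] <- NA
  okc <- conc_series(array(0, c(dim(gt$t1_map), 1)), 10, gt$spec$voxel_size)
  expect_error(synthesize_signal(okc, t1bad, gt$brain_mask,
                                 acquisition_params()), "missing")
})
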