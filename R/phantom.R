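# Synthetic digital brain phantom: an ellipsoidal brain with artery /
# periarterial / ventricle / brain-tissue subdomains, tissue-dependent
# baseline T1, a cisterna-magna-style infusion near the caudal ventral
# surface, subdomain-dependent transport, measurement noise and T2/T2*
# signal dropout. Everything downstream of DCE-MRI acquisition can be
# validated against this known ground truth.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Geometry and tissue parameters of the synthetic brain. The default is a
#' scaled-down brain: ellipsoid of semi-axes 2.9 x 2.9 x 2.1 mm in a
#' 64 x 64 x 48 grid of 0.1 mm voxels, one surface artery following the
#' ventral midline, two branching arteries rising dorsally, and two lateral
#' ventricles. Baseline T1 values must stay in the physiological 500-4500 ms
#' band, with artery T1 strictly below the default artery segmentation
#' threshold (1200 ms) and ventricle T1 above the ventricle threshold
#' (3000 ms) so that segmentation is recoverable by construction.
#'
#' @param grid_shape voxel counts per axis; default c(64, 64, 48).
#' @param voxel_size voxel edge (mm); default 0.1.
#' @param brain_semi_axes ellipsoid semi-axes (mm).
#' @param artery_paths list of arteries, each a list with `points` (n x 3
#'   matrix of polyline vertices, mm), `radius` (mm) and `class`
#'   (`"surface"` or `"branching"`).
#' @param pas_shell_voxels named integer vector: Chebyshev reach of the PAS
#'   shell around each artery class; defaults `c(surface = 7, branching =
#'   3)`, matching the segmentation distance bounds.
#' @param ventricle_centers_radii list of ellipsoids, each `list(center,
#'   radii)` in mm.
#' @param t1_by_tissue named T1_0 values (ms) per tissue.
#' @param t1_jitter within-tissue T1 standard deviation (ms); default 0.
#' @param injection_site world coordinates (mm) of the infusion point;
#'   `NULL` places it near the caudal ventral surface on the surface-artery
#'   path.
#' @param seed RNG seed for the T1 jitter.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48), voxel_size = 0.1,
                         brain_semi_axes = c(2.9, 2.9, 2.1),
                         artery_paths = NULL,
                         pas_shell_voxels = c(surface = 7L, branching = 3L),
                         ventricle_centers_radii = NULL,
                         t1_by_tissue = c(BT = 1800, PAS_Surf = 1900,
                                          PAS_Branch = 1900, Artery = 800,
                                          Ventricle = 4000),
                         t1_jitter = 0, injection_site = NULL, seed = 1L) {
  centre <- grid_shape * voxel_size / 2
  if (is.null(artery_paths))
    artery_paths <- default_artery_paths(centre, brain_semi_axes)
  if (is.null(ventricle_centers_radii)) {
    voff <- c(0.34 * brain_semi_axes[1], 0.17 * brain_semi_axes[2],
              0.24 * brain_semi_axes[3])
    vrad <- c(0.12 * brain_semi_axes[1], 0.17 * brain_semi_axes[2],
              0.17 * brain_semi_axes[3])
    ventricle_centers_radii <- list(
      list(center = centre + c(-voff[1], voff[2], voff[3]), radii = vrad),
      list(center = centre + c(voff[1], voff[2], voff[3]), radii = vrad))
  }
  if (any(brain_semi_axes <= 0)) stop_bt("brain semi-axes must be positive")
  for (v in ventricle_centers_radii)
    if (any(v$radii <= 0)) stop_bt("ventricle radii must be positive")
  for (a in artery_paths) {
    if (a$radius <= 0) stop_bt("artery radius must be positive")
    if (!a$class %in% c("surface", "branching"))
      stop_bt("artery class must be 'surface' or 'branching'")
  }
  rng <- range(t1_by_tissue)
  if (rng[1] < 500 || rng[2] > 4500)
    stop_bt("tissue T1 values must lie in 500-4500 ms")
  if (t1_by_tissue[["Artery"]] >= 1200)
    stop_bt("artery T1 must be below the artery threshold (1200 ms)")
  if (t1_by_tissue[["Ventricle"]] <= 3000)
    stop_bt("ventricle T1 must be above the ventricle threshold (3000 ms)")
  if (is.null(injection_site)) {
    p0 <- if (length(artery_paths))
      artery_paths[[1]]$points[1, ]          # caudal end of first artery
    else centre - c(0, 0.8 * brain_semi_axes[2], 0.8 * brain_semi_axes[3])
    injection_site <- p0 + c(0, 0.09 * brain_semi_axes[2],
                             0.12 * brain_semi_axes[3])
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, centre = centre,
                 brain_semi_axes = brain_semi_axes,
                 artery_paths = artery_paths,
                 pas_shell_voxels = pas_shell_voxels,
                 ventricle_centers_radii = ventricle_centers_radii,
                 t1_by_tissue = t1_by_tissue, t1_jitter = t1_jitter,
                 injection_site = injection_site, seed = as.integer(seed)),
            class = "phantom_spec")
}

# ventral midline surface artery + two branching arteries; all offsets are
# fractions of the brain semi-axes so the geometry scales with the phantom.
# The surface artery hugs the ventral ellipsoid surface slightly inside it;
# branching arteries leave it laterally/dorsally like penetrating vessels.
default_artery_paths <- function(centre, semi) {
  margin <- min(0.35, semi[3] / 3)
  ys <- seq(-0.8 * semi[2], 0.8 * semi[2], length.out = 33)
  zs <- -(semi[3] - margin) * sqrt(pmax(0, 1 - (ys / semi[2])^2))
  surf <- cbind(centre[1], centre[2] + ys, centre[3] + zs)
  branch_from <- function(yfrac, xsgn) {
    yoff <- yfrac * semi[2]
    z0 <- -(semi[3] - margin) * sqrt(pmax(0, 1 - yfrac^2))
    t <- seq(0, 1, length.out = 17)
    cbind(centre[1] + xsgn * 0.45 * semi[1] * t,
          centre[2] + yoff,
          centre[3] + z0 + t * (0.45 * semi[3] - z0))
  }
  list(
    list(points = surf, radius = 0.12, class = "surface"),
    list(points = branch_from(-0.31, -1), radius = 0.1, class = "branching"),
    list(points = branch_from(0.31, 1), radius = 0.1, class = "branching"))
}

# mark voxels whose center lies within `radius` of the polyline
rasterize_path <- function(points, radius, dims, voxel_size) {
  mask <- array(FALSE, dims)
  step <- voxel_size / 2
  for (s in seq_len(nrow(points) - 1)) {
    p <- points[s, ]; qd <- points[s + 1, ]
    len <- sqrt(sum((qd - p)^2))
    n <- max(2, ceiling(len / step) + 1)
    for (tt in seq(0, 1, length.out = n)) {
      x <- p + tt * (qd - p)
      lo <- pmax(1, floor((x - radius) / voxel_size - 0.5) + 1)
      hi <- pmin(dims, ceiling((x + radius) / voxel_size + 0.5))
      if (any(lo > hi)) next               # sample entirely off the grid
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      cx <- voxel_center(xs, voxel_size) - x[1]
      cy <- voxel_center(ys, voxel_size) - x[2]
      cz <- voxel_center(zs, voxel_size) - x[3]
      d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
      sub <- mask[xs, ys, zs, drop = FALSE]
      mask[xs, ys, zs] <- sub | (d2 <= radius^2)
    }
  }
  mask
}

ellipsoid_mask <- function(dims, voxel_size, centre, radii) {
  xs <- (voxel_center(seq_len(dims[1]), voxel_size) - centre[1]) / radii[1]
  ys <- (voxel_center(seq_len(dims[2]), voxel_size) - centre[2]) / radii[2]
  zs <- (voxel_center(seq_len(dims[3]), voxel_size) - centre[3]) / radii[3]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 1
}

#' Build the phantom: labels and baseline T1 map
#'
#' Rasterizes the geometry onto the voxel grid. Arteries are drawn along
#' their centerline polylines, PAS shells as Chebyshev-annular shells of
#' the stated reach around each artery class, ventricles as ellipsoids;
#' the rest of the brain ellipsoid is BT. The T1 map takes the per-tissue
#' value with optional Gaussian within-tissue jitter.
#'
#' @param spec a [phantom_spec()].
#' @return A `ground_truth` object: list with `labels`
#'   ([subdomain_labels]), `t1_map` (3D array, ms, NA outside brain),
#'   `brain_mask`, `artery_class_map` (1 = surface, 2 = branching),
#'   `spec`, and `overlap_count` (artery voxels that overwrote ventricle).
#' @export
build_phantom <- function(spec) {
  d <- spec$grid_shape
  vs <- spec$voxel_size
  brain <- ellipsoid_mask(d, vs, spec$centre, spec$brain_semi_axes)
  surf_art <- array(FALSE, d)
  branch_art <- array(FALSE, d)
  for (a in spec$artery_paths) {
    m <- rasterize_path(a$points, a$radius, d, vs)
    if (any(m & !brain))
      stop_bt("artery path exits the brain ellipsoid (%d voxels outside)",
              sum(m & !brain))
    if (a$class == "surface") surf_art <- surf_art | m
    else branch_art <- branch_art | m
  }
  artery <- surf_art | branch_art
  vent <- array(FALSE, d)
  for (v in spec$ventricle_centers_radii)
    vent <- vent | ellipsoid_mask(d, vs, v$center, v$radii)
  vent <- vent & brain
  overlap_count <- sum(artery & vent)
  vent <- vent & !artery                      # artery wins overlaps
  reach_s <- spec$pas_shell_voxels[["surface"]]
  reach_b <- spec$pas_shell_voxels[["branching"]]
  pas_surf <- array(FALSE, d)
  pas_branch <- array(FALSE, d)
  if (any(surf_art) && reach_s >= 1) {
    ds <- mask_distance(surf_art, reach_s)
    pas_surf <- ds >= 1 & ds <= reach_s & brain & !artery & !vent
  }
  if (any(branch_art) && reach_b >= 1) {
    db <- mask_distance(branch_art, reach_b)
    pas_branch <- db >= 1 & db <= reach_b & brain & !artery & !vent
  }
  pas_surf <- pas_surf & !pas_branch          # both -> PAS_Branch
  labels <- compose_labels(brain, artery, vent, pas_surf, pas_branch, vs,
                           provenance = list(origin = "phantom"))
  t1 <- array(NA_real_, d)
  for (nm in names(spec$t1_by_tissue)) {
    idx <- labels$data == label_codes()[[nm]]
    t1[idx] <- spec$t1_by_tissue[[nm]]
  }
  if (spec$t1_jitter > 0) {
    t1 <- with_seed(spec$seed, {
      jit <- array(stats::rnorm(prod(d), 0, spec$t1_jitter), d)
      t1 + jit
    })
    t1 <- pmin(pmax(t1, 500), 4500)
    t1[!brain] <- NA_real_
  }
  class_map <- array(0L, d)
  class_map[surf_art] <- 1L
  class_map[branch_art & !surf_art] <- 2L
  structure(list(labels = labels, t1_map = t1, brain_mask = brain,
                 artery_class_map = class_map, spec = spec,
                 overlap_count = overlap_count,
                 true_params = NULL, concentration = NULL),
            class = "ground_truth")
}

#' Simulate ground-truth concentration dynamics
#'
#' Runs the finite-volume transport solver on a mesh built from the phantom
#' labels and samples the solution back to the voxel grid. Total injected
#' amount equals `rate * (stop - start)` and is conserved after the source
#' switches off (no-flux boundary).
#'
#' @param gt a `ground_truth` from [build_phantom()].
#' @param params a [transport_params()] object (must cover every
#'   subdomain).
#' @param source a [source_spec()]; `NULL` uses the phantom injection site
#'   with the default infusion.
#' @param frame_times output frame times (min, >= 0).
#' @param mesh_factor integer coarsening for the simulation mesh (1 =
#'   voxel resolution).
#' @param cfg a [solver_config()].
#' @return The `ground_truth` with `concentration` ([conc_series]) and
#'   `true_params` filled; the mesh and nodal series are attached as
#'   attributes `mesh` and `nodal`.
#' @export
simulate_truth <- function(gt, params = transport_params(), source = NULL,
                           frame_times = seq(0, 80, by = 10),
                           mesh_factor = 1L, cfg = solver_config()) {
  if (any(frame_times < 0)) stop_bt("frame times must be >= 0")
  if (is.null(source)) source <- source_spec(gt$spec$injection_site)
  mesh <- build_mesh(gt$brain_mask, gt$spec$voxel_size, factor = mesh_factor)
  mesh <- tag_subdomains(mesh, gt$labels)
  nodal <- solve_transport(mesh, params, source, frame_times, cfg)
  conc <- sample_to_voxels(nodal, mesh)
  gt$concentration <- conc
  gt$true_params <- params
  attr(gt, "mesh") <- mesh
  attr(gt, "nodal") <- nodal
  attr(gt, "source") <- source
  gt
}

#' Measurement artifact specification
#'
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param noise_sigma noise SD as a fraction of the mean in-brain baseline
#'   signal; default 0.02.
#' @param surface_dropout_voxels thickness (voxels, 0-3) of the surface
#'   shell whose post-contrast signal is suppressed by skull-proximity
#'   T2/T2* interference; default 2.
#' @param injection_dropout concentration (mM) above which post-contrast
#'   signal is suppressed (high local gadoteridol shortens T2*); default
#'   50.
#' @param dropout_factor multiplicative suppression applied to affected
#'   voxels; default 0.1.
#' @param seed RNG seed for the noise.
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(noise_model = c("gaussian", "rician"),
                          noise_sigma = 0.02, surface_dropout_voxels = 2L,
                          injection_dropout = 50, dropout_factor = 0.1,
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop_bt("noise_sigma must be >= 0")
  if (surface_dropout_voxels < 0 || surface_dropout_voxels > 3)
    stop_bt("surface_dropout_voxels must be in [0, 3]")
  structure(list(noise_model = noise_model, noise_sigma = noise_sigma,
                 surface_dropout_voxels = as.integer(surface_dropout_voxels),
                 injection_dropout = injection_dropout,
                 dropout_factor = dropout_factor, seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Synthesize a DCE-MRI signal series from concentration and T1
#'
#' Baselines at the two flip angles follow the SPGR signal equation with
#' the per-voxel baseline T1. Post-contrast frames use the linearized
#' contrast relationship `S = S0 (1 + r1 T1_0 c-bar)` -- the exact inverse
#' of the concentration calculation, so a noiseless synthesize-then-invert
#' round trip is the identity. Dropout multiplies post-contrast signal by
#' `dropout_factor` in the surface shell and wherever concentration exceeds
#' `injection_dropout`; noise (Gaussian or Rician) is added to baselines
#' and frames with a fixed seed.
#'
#' @param conc a [conc_series] of ground-truth superficial concentration
#'   (must be non-negative).
#' @param t1_map 3D baseline T1 array (ms; NA allowed only outside the
#'   brain mask).
#' @param brain_mask 3D logical array.
#' @param acq an [acquisition_params()].
#' @param art an [artifact_spec()].
#' @param m0 equilibrium signal scale; default 1000.
#' @return A [signal_series].
#' @export
synthesize_signal <- function(conc, t1_map, brain_mask, acq,
                              art = artifact_spec(noise_sigma = 0),
                              m0 = 1000) {
  if (any(conc$data < 0)) stop_bt("ground-truth concentration must be >= 0")
  if (any(is.na(t1_map) & brain_mask))
    stop_bt("T1 map has missing values inside the brain")
  d <- dim(t1_map)
  t1f <- ifelse(brain_mask, t1_map, NA_real_)
  base_low <- array(0, d)
  base_high <- array(0, d)
  ib <- which(brain_mask)
  base_low[ib] <- spgr_signal(m0, acq$flip_angles[1], t1f[ib], acq$tr)
  base_high[ib] <- spgr_signal(m0, acq$flip_angles[2], t1f[ib], acq$tr)
  nt <- dim(conc$data)[4]
  frames <- array(0, c(d, nt))
  shell <- array(FALSE, d)
  if (art$surface_dropout_voxels >= 1) {
    douter <- mask_distance(!brain_mask, art$surface_dropout_voxels)
    shell <- brain_mask & douter <= art$surface_dropout_voxels
  }
  for (k in seq_len(nt)) {
    ck <- conc$data[, , , k]
    fk <- array(0, d)
    fk[ib] <- concentration_to_signal(ck[ib], base_high[ib], t1f[ib], acq$r1)
    drop <- shell | (ck > art$injection_dropout & brain_mask)
    fk[drop] <- fk[drop] * art$dropout_factor
    frames[, , , k] <- fk
  }
  if (art$noise_sigma > 0) {
    sd_abs <- art$noise_sigma * mean(base_high[ib])
    noisy <- with_seed(art$seed, {
      add_noise <- function(x) {
        n1 <- array(stats::rnorm(length(x), 0, sd_abs), dim(x))
        if (art$noise_model == "gaussian") x + n1
        else {
          n2 <- array(stats::rnorm(length(x), 0, sd_abs), dim(x))
          sqrt((x + n1)^2 + n2^2)
        }
      }
      list(bl = add_noise(base_low), bh = add_noise(base_high),
           fr = add_noise(frames))
    })
    base_low <- noisy$bl; base_high <- noisy$bh; frames <- noisy$fr
    if (art$noise_model == "gaussian") {
      base_low[base_low < 0] <- 0
      base_high[base_high < 0] <- 0
    }
  }
  signal_series(frames, base_low, base_high, conc$times, conc$voxel_size,
                acq)
}
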