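#' Segmentation thresholds for the transport subdomains
#'
#' Arteries are identified from the pre-contrast T1 map (blood has short
#' T1), ventricles from long T1 (CSF), and periarterial spaces from high
#' early-time contrast concentration close to major arteries.
#'
#' @param artery_t1_max arteries: T1_0 below this (ms). Default 1200
#'   (subject-dependent range 1000-1400).
#' @param ventricle_t1_min ventricles: T1_0 above this (ms). Default 3000.
#' @param pas_conc_min PAS concentration threshold (mM) at `pas_time`;
#'   default 0.15.
#' @param pas_time time (min) of the frame used for PAS segmentation;
#'   nearest frame is used and recorded. Default 20.
#' @param surf_max_dist,branch_max_dist maximum distance (voxels) from
#'   surface-class / branching-class artery voxels; defaults 7 and 3.
#' @param metric voxel distance metric, `"chebyshev"` (default) or
#'   `"euclidean"`.
#' @return A `segmentation_thresholds` object.
#' @export
segmentation_thresholds <- function(artery_t1_max = 1200,
                                    ventricle_t1_min = 3000,
                                    pas_conc_min = 0.15, pas_time = 20,
                                    surf_max_dist = 7L, branch_max_dist = 3L,
                                    metric = c("chebyshev", "euclidean")) {
  if (artery_t1_max >= ventricle_t1_min)
    stop_bt("artery_t1_max must be below ventricle_t1_min")
  if (surf_max_dist < 1 || branch_max_dist < 1)
    stop_bt("distance bounds must be positive integers")
  structure(list(artery_t1_max = artery_t1_max,
                 ventricle_t1_min = ventricle_t1_min,
                 pas_conc_min = pas_conc_min, pas_time = pas_time,
                 surf_max_dist = as.integer(surf_max_dist),
                 branch_max_dist = as.integer(branch_max_dist),
                 metric = match.arg(metric)),
            class = "segmentation_thresholds")
}

# shift a 3D array by integer offsets, zero (FALSE) padded
shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
  out
}

#' Voxel distance from a mask, capped
#'
#' Distance (in voxels) of every voxel from the nearest `TRUE` voxel of
#' `mask`, computed only up to `maxd`; farther voxels get `maxd + 1`.
#' Chebyshev distance grows by one 26-neighbour dilation per step; the
#' Euclidean variant scans all integer offsets with norm <= `maxd` (use on
#' small problems).
#'
#' @param mask 3D logical array.
#' @param maxd maximum distance of interest (voxels).
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @return Numeric array: 0 on the mask, capped at `maxd + 1`.
#' @export
mask_distance <- function(mask, maxd, metric = "chebyshev") {
  d <- dim(mask)
  dist <- array(maxd + 1, d)
  dist[mask] <- 0
  if (!any(mask) || maxd < 1) return(dist)
  if (metric == "chebyshev") {
    cur <- mask
    for (k in seq_len(maxd)) {
      nxt <- cur
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nxt <- nxt | shift3(cur, dx, dy, dz)
      }
      dist[nxt & dist > k] <- k
      cur <- nxt
    }
  } else {
    r <- ceiling(maxd)
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      nrm <- sqrt(dx^2 + dy^2 + dz^2)
      if (nrm == 0 || nrm > maxd) next
      hit <- shift3(mask, dx, dy, dz)
      dist[hit & dist > nrm] <- nrm
    }
  }
  dist
}

# 6-connected components of a 3D logical mask; returns integer array
# (0 outside mask) and the component count
connected_components <- function(mask) {
  d <- dim(mask)
  comp <- integer(prod(d))
  strides <- c(1L, d[1], d[1] * d[2])
  msk <- as.vector(mask)
  idx_all <- which(msk)
  ncomp <- 0L
  for (seed in idx_all) {
    if (comp[seed] != 0L) next
    ncomp <- ncomp + 1L
    frontier <- seed
    comp[seed] <- ncomp
    while (length(frontier)) {
      ci <- arrayInd(frontier, d)
      nbrs <- integer(0)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        ok <- ci[, ax] + s >= 1L & ci[, ax] + s <= d[ax]
        nbrs <- c(nbrs, frontier[ok] + s * strides[ax])
      }
      nbrs <- unique(nbrs)
      nbrs <- nbrs[msk[nbrs] & comp[nbrs] == 0L]
      comp[nbrs] <- ncomp
      frontier <- nbrs
    }
  }
  list(labels = array(comp, d), n = ncomp)
}

#' Segment arteries from the pre-contrast T1 map
#'
#' Artery voxels are in-brain voxels with T1_0 below `thr$artery_t1_max`.
#' Classes (surface vs branching) come from `artery_class_map`, an
#' annotation volume (1 = surface, 2 = branching, 0 = unannotated) supplied
#' by the phantom ground truth or by anatomical knowledge for real data;
#' unannotated voxels inherit the majority class of their connected
#' component, and a fully unannotated component is an error.
#'
#' @param t1 a `t1_map` or a plain 3D T1 array (ms).
#' @param brain_mask 3D logical array.
#' @param thr a [segmentation_thresholds()] object.
#' @param artery_class_map integer 3D array annotating artery classes.
#' @return List with logical masks `surface` and `branching` and the
#'   combined `artery` mask.
#' @export
segment_arteries <- function(t1, brain_mask, thr, artery_class_map) {
  t1a <- if (inherits(t1, "t1_map")) t1$t1 else t1
  stopifnot(identical(dim(t1a), dim(brain_mask)))
  artery <- !is.na(t1a) & t1a < thr$artery_t1_max & brain_mask
  if (!any(artery)) {
    warn_bt("no voxels below artery T1 threshold %g ms", thr$artery_t1_max)
    empty <- array(FALSE, dim(brain_mask))
    return(list(artery = empty, surface = empty, branching = empty))
  }
  if (sum(artery) == sum(brain_mask))
    warn_bt("artery T1 threshold flags the entire brain; check threshold")
  # per-voxel annotation where given; unannotated voxels inherit the
  # majority class of their connected component (the vasculature is one
  # connected tree, so a purely per-component rule cannot separate surface
  # from branching segments)
  surface <- artery & artery_class_map == 1L
  branching <- artery & artery_class_map == 2L
  todo <- artery & artery_class_map == 0L
  if (any(todo)) {
    cc <- connected_components(artery)
    unclass_comp <- integer(0)
    for (k in seq_len(cc$n)) {
      vox <- cc$labels == k & todo
      if (!any(vox)) next
      cls <- artery_class_map[cc$labels == k]
      cls <- cls[cls > 0]
      if (!length(cls)) {
        unclass_comp <- c(unclass_comp, k)
        next
      }
      mode_cls <- as.integer(names(which.max(table(cls))))
      if (mode_cls == 1L) surface[vox] <- TRUE else branching[vox] <- TRUE
    }
    if (length(unclass_comp))
      stop_bt("artery components without class annotation: %s",
              paste(unclass_comp, collapse = ", "))
  }
  list(artery = artery, surface = surface, branching = branching)
}

#' Segment ventricles from the pre-contrast T1 map
#'
#' CSF-filled ventricles have long T1; voxels with T1_0 above
#' `thr$ventricle_t1_min` inside the brain are flagged.
#'
#' @inheritParams segment_arteries
#' @return Logical 3D mask.
#' @export
segment_ventricles <- function(t1, brain_mask, thr) {
  t1a <- if (inherits(t1, "t1_map")) t1$t1 else t1
  !is.na(t1a) & t1a > thr$ventricle_t1_min & brain_mask
}

#' Segment periarterial spaces from early-time concentration
#'
#' PAS voxels combine high contrast concentration at `thr$pas_time`
#' (nearest frame used, recorded in the result) with proximity to major
#' arteries: within `surf_max_dist` voxels of surface-class arteries for
#' PAS_Surf, within `branch_max_dist` of branching-class for PAS_Branch.
#' Artery voxels themselves are excluded; voxels qualifying for both classes
#' go to PAS_Branch.
#'
#' @param conc a [conc_series].
#' @param arteries result of [segment_arteries()].
#' @param thr a [segmentation_thresholds()] object.
#' @return List with logical masks `pas_surf`, `pas_branch`, and the frame
#'   `time_used`.
#' @export
segment_pas <- function(conc, arteries, thr) {
  fr <- nearest_frame(conc, thr$pas_time)
  hot <- fr$volume > thr$pas_conc_min
  ds <- mask_distance(arteries$surface, thr$surf_max_dist, thr$metric)
  db <- mask_distance(arteries$branching, thr$branch_max_dist, thr$metric)
  pas_surf <- hot & ds >= 1 & ds <= thr$surf_max_dist & !arteries$artery
  pas_branch <- hot & db >= 1 & db <= thr$branch_max_dist & !arteries$artery
  pas_surf <- pas_surf & !pas_branch      # tie-break: both -> PAS_Branch
  list(pas_surf = pas_surf, pas_branch = pas_branch, time_used = fr$time)
}

#' Compose subdomain masks into a label volume
#'
#' Overlaps are resolved by fixed precedence
#' Artery > Ventricle > PAS_Branch > PAS_Surf > BT; every in-brain voxel
#' gets a label, out-of-brain voxels are Background.
#'
#' @param brain_mask 3D logical array.
#' @param artery,ventricle,pas_surf,pas_branch logical masks (same grid).
#' @param voxel_size voxel edge (mm).
#' @param provenance optional list recorded on the result.
#' @return A [subdomain_labels] object.
#' @export
compose_labels <- function(brain_mask, artery, ventricle, pas_surf,
                           pas_branch, voxel_size, provenance = list()) {
  d <- dim(brain_mask)
  stopifnot(identical(d, dim(artery)), identical(d, dim(ventricle)),
            identical(d, dim(pas_surf)), identical(d, dim(pas_branch)))
  codes <- label_codes()
  lab <- array(codes[["Background"]], d)
  lab[brain_mask] <- codes[["BT"]]
  lab[brain_mask & pas_surf] <- codes[["PAS_Surf"]]
  lab[brain_mask & pas_branch] <- codes[["PAS_Branch"]]
  lab[brain_mask & ventricle] <- codes[["Ventricle"]]
  lab[brain_mask & artery] <- codes[["Artery"]]
  subdomain_labels(lab, voxel_size, provenance)
}

#' Full threshold segmentation of the transport subdomains
#'
#' Convenience wrapper running artery, ventricle and PAS segmentation and
#' composing the label volume.
#'
#' @inheritParams segment_arteries
#' @param conc a [conc_series].
#' @return A [subdomain_labels] object; provenance records thresholds and
#'   the PAS frame time used.
#' @export
segment_transport_regions <- function(t1, conc, brain_mask, thr,
                                      artery_class_map) {
  art <- segment_arteries(t1, brain_mask, thr, artery_class_map)
  vent <- segment_ventricles(t1, brain_mask, thr)
  pas <- segment_pas(conc, art, thr)
  compose_labels(brain_mask, art$artery, vent, pas$pas_surf, pas$pas_branch,
                 conc$voxel_size,
                 provenance = list(thresholds = unclass(thr),
                                   pas_time_used = pas$time_used))
}
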