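#' Build a structured hexahedral mesh over a voxel mask
#'
#' Desk-scale replacement for surface extraction + tetrahedral meshing: the
#' mesh is a cell-centered hexahedral grid obtained by integer coarsening of
#' the voxel lattice. A coarse cell (an `f x f x f` block of voxels, edge
#' `h = f * voxel_size`) is included when at least half of its voxels lie in
#' the mask, which keeps the mesh volume an unbiased estimate of the mask
#' volume. Fields live at cell centers; faces between neighbouring cells
#' carry the diffusive fluxes, and faces with no neighbour form the closed
#' no-flux boundary.
#'
#' @param brain_mask 3D logical array (one connected component).
#' @param voxel_size voxel edge (mm).
#' @param target_cells desired number of cells; the integer coarsening
#'   factor is chosen to approximate it (within 2x). Ignored when `factor`
#'   is given.
#' @param factor explicit integer coarsening factor (1 = one cell per
#'   voxel).
#' @return A `brain_mesh` object.
#' @export
build_mesh <- function(brain_mask, voxel_size, target_cells = NULL,
                       factor = NULL) {
  if (!any(brain_mask)) stop_bt("build_mesh: empty mask")
  cc <- connected_components(brain_mask)
  if (cc$n != 1L)
    stop_bt("build_mesh: mask has %d connected components (need 1)", cc$n)
  d <- dim(brain_mask)
  nmask <- sum(brain_mask)
  if (is.null(factor)) {
    factor <- if (is.null(target_cells)) 1L else
      max(1L, as.integer(round((nmask / target_cells)^(1 / 3))))
  }
  f <- as.integer(factor)
  h <- f * voxel_size
  nc <- ceiling(d / f)
  # in-mask voxel fraction per coarse block
  frac <- array(0, nc)
  cnt <- array(0, nc)
  blk <- lapply(d, function(n) ceiling(seq_len(n) / f))
  bid <- array(0L, d)
  bx <- blk[[1]]; by <- blk[[2]]; bz <- blk[[3]]
  # accumulate counts by coarse index
  idx3 <- cbind(rep(bx, times = d[2] * d[3]),
                rep(rep(by, each = d[1]), times = d[3]),
                rep(bz, each = d[1] * d[2]))
  lin <- (idx3[, 3] - 1) * nc[1] * nc[2] + (idx3[, 2] - 1) * nc[1] + idx3[, 1]
  frac <- array(tapply(as.vector(brain_mask), lin, sum), nc)
  cnt <- array(tapply(rep(1L, length(lin)), lin, sum), nc)
  frac[is.na(frac)] <- 0
  include <- frac >= pmax(1, cnt / 2)   # majority of the block's voxels
  if (!any(include)) stop_bt("build_mesh: no cells selected; mask too sparse")
  cell_id <- array(0L, nc)
  cell_id[include] <- seq_len(sum(include))
  ncell <- sum(include)
  ijk <- arrayInd(which(include), nc)
  nodes <- (ijk - 0.5) * h                      # cell-center world coords, mm
  # face-neighbour pairs along each axis
  pairs <- NULL
  for (ax in 1:3) {
    nb <- ijk
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= nc[ax]
    id2 <- cell_id[nb[ok, , drop = FALSE]]
    id1 <- cell_id[ijk[ok, , drop = FALSE]]
    keep <- id2 > 0L
    pairs <- rbind(pairs, cbind(id1[keep], id2[keep]))
  }
  n_boundary <- 6L * ncell - 2L * nrow(pairs)
  structure(list(
    dims = nc, h = h, factor = f, fine_dims = d, voxel_size = voxel_size,
    nodes = nodes, cell_ijk = ijk, cell_id = cell_id, vol = h^3,
    pairs = pairs, n_boundary_facets = n_boundary,
    tags = rep(NA_integer_, ncell),
    quality = list(aspect_ratio_min = 1, aspect_ratio_median = 1,
                   n_cells = ncell, h_mm = h)),
    class = "brain_mesh")
}

#' @export
print.brain_mesh <- function(x, ...) {
  cat("<brain_mesh>", nrow(x$nodes), "hexahedral cells, h =", x$h, "mm,",
      x$n_boundary_facets, "boundary facets\n")
  if (!all(is.na(x$tags))) {
    tb <- table(label_name(x$tags))
    cat("tags:", paste(names(tb), as.integer(tb), sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Total mesh volume (mm^3)
#' @param mesh a `brain_mesh`.
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh) nrow(mesh$nodes) * mesh$vol

#' Tag mesh cells with subdomain labels
#'
#' Each cell takes the label of the voxel at its centroid; when the
#' coarsening factor is even (centroid on a voxel corner) or the centroid
#' voxel is Background, the majority label over the cell's voxel block is
#' used, ties resolved by subdomain precedence
#' (Artery > Ventricle > PAS_Branch > PAS_Surf > BT). Cells whose block
#' holds no in-brain voxel fall back to BT (they only arise hugging the
#' mask surface).
#'
#' @param mesh a `brain_mesh`.
#' @param labels a [subdomain_labels] on the fine voxel grid.
#' @return The mesh with `tags` filled (integer label codes per cell).
#' @export
tag_subdomains <- function(mesh, labels) {
  stopifnot(identical(dim(labels$data), mesh$fine_dims))
  codes <- label_codes()
  precedence <- c(codes[["Artery"]], codes[["Ventricle"]],
                  codes[["PAS_Branch"]], codes[["PAS_Surf"]], codes[["BT"]])
  f <- mesh$factor
  d <- mesh$fine_dims
  tags <- integer(nrow(mesh$nodes))
  if (f %% 2L == 1L) {
    ctr <- (mesh$cell_ijk - 1L) * f + (f + 1L) %/% 2L
    for (ax in 1:3) ctr[, ax] <- pmin(ctr[, ax], d[ax])
    tags <- labels$data[ctr]
  }
  need_majority <- f %% 2L == 0L
  for (i in seq_len(nrow(mesh$nodes))) {
    if (!need_majority && tags[i] != codes[["Background"]]) next
    ijk <- mesh$cell_ijk[i, ]
    xs <- ((ijk[1] - 1L) * f + 1L):min(ijk[1] * f, d[1])
    ys <- ((ijk[2] - 1L) * f + 1L):min(ijk[2] * f, d[2])
    zs <- ((ijk[3] - 1L) * f + 1L):min(ijk[3] * f, d[3])
    blk <- labels$data[xs, ys, zs]
    blk <- blk[blk != codes[["Background"]]]
    if (!length(blk)) { tags[i] <- codes[["BT"]]; next }
    tb <- table(blk)
    best <- as.integer(names(tb)[tb == max(tb)])
    tags[i] <- precedence[match(TRUE, precedence %in% best)]
  }
  mesh$tags <- as.integer(tags)
  mesh
}

#' Interpolate a voxel field onto mesh nodes (inverse-distance weighted)
#'
#' Gaussian-kernel inverse-distance weighting: each node value is the
#' normalized weighted mean of voxel values within `radius_vox` voxels,
#' weights `exp(-d^2 / (2 sigma_vox^2))` with `d` the node-to-voxel-center
#' distance in voxel units. Weights are positive and normalized, so nodal
#' values obey the max principle (they stay within the range of the
#' contributing voxels). Acts as a mild Gaussian smoother of the data.
#'
#' @param volume 3D voxel array, or a [conc_series] (interpolated per
#'   frame).
#' @param mesh a `brain_mesh`.
#' @param sigma_vox Gaussian kernel width (voxels); default 1.
#' @param radius_vox kernel truncation radius (voxels); default `3 *
#'   sigma_vox`.
#' @return For a 3D input, a numeric vector over cells (a nodal field);
#'   for a series, a `nodal_series` (list with `values` cells x frames and
#'   `times`). The number of nodes that needed the nearest-voxel fallback is
#'   attached as attribute `n_fallback`.
#' @export
interpolate_idw <- function(volume, mesh, sigma_vox = 1,
                            radius_vox = 3 * sigma_vox) {
  if (inherits(volume, "conc_series")) {
    nt <- length(volume$times)
    vals <- matrix(0, nrow(mesh$nodes), nt)
    for (k in seq_len(nt))
      vals[, k] <- interpolate_idw(volume$data[, , , k], mesh, sigma_vox,
                                   radius_vox)
    return(structure(list(values = vals, times = volume$times),
                     class = "nodal_series"))
  }
  d <- dim(volume)
  stopifnot(identical(d, mesh$fine_dims))
  vs <- mesh$voxel_size
  # node position in (fractional, 1-based) voxel index coordinates
  np <- sweep(mesh$nodes, 2, vs, "/") + 0.5
  n0 <- round(np)                       # nearest voxel per node
  fracs <- np - n0                      # identical across nodes (lattice)
  r <- ceiling(radius_vox)
  num <- numeric(nrow(np)); den <- numeric(nrow(np))
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    off <- c(dx, dy, dz)
    dist2 <- sum((off - fracs[1, ])^2)
    if (dist2 > radius_vox^2) next
    w <- exp(-dist2 / (2 * sigma_vox^2))
    vx <- n0[, 1] + dx; vy <- n0[, 2] + dy; vz <- n0[, 3] + dz
    ok <- vx >= 1 & vx <= d[1] & vy >= 1 & vy <= d[2] & vz >= 1 & vz <= d[3]
    idx <- (vz[ok] - 1) * d[1] * d[2] + (vy[ok] - 1) * d[1] + vx[ok]
    num[ok] <- num[ok] + w * volume[idx]
    den[ok] <- den[ok] + w
  }
  out <- num / den
  fallback <- which(den == 0)
  if (length(fallback)) {
    for (i in fallback) {
      v <- pmin(pmax(n0[i, ], 1), d)
      out[i] <- volume[v[1], v[2], v[3]]
    }
  }
  attr(out, "n_fallback") <- length(fallback)
  out
}

#' Save / load a mesh as JSON
#'
#' Persists the structured mesh (cell index triplets, tags, geometry) so
#' pipeline stages can be re-run individually; connectivity is rebuilt on
#' load.
#'
#' @param mesh a `brain_mesh`.
#' @param path JSON path.
#' @return `path` invisibly; `load_mesh` returns the `brain_mesh`.
#' @export
save_mesh <- function(mesh, path) {
  x <- list(dims = mesh$dims, h = mesh$h, factor = mesh$factor,
            fine_dims = mesh$fine_dims, voxel_size = mesh$voxel_size,
            cell_ijk = mesh$cell_ijk, tags = mesh$tags)
  jsonlite::write_json(x, path, digits = NA)
  invisible(path)
}

#' @rdname save_mesh
#' @export
load_mesh <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nc <- as.integer(x$dims)
  ijk <- matrix(as.integer(x$cell_ijk), ncol = 3)
  cell_id <- array(0L, nc)
  cell_id[ijk] <- seq_len(nrow(ijk))
  pairs <- NULL
  for (ax in 1:3) {
    nb <- ijk
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= nc[ax]
    id2 <- cell_id[nb[ok, , drop = FALSE]]
    id1 <- cell_id[ijk[ok, , drop = FALSE]]
    keep <- id2 > 0L
    pairs <- rbind(pairs, cbind(id1[keep], id2[keep]))
  }
  ncell <- nrow(ijk)
  structure(list(
    dims = nc, h = x$h, factor = as.integer(x$factor),
    fine_dims = as.integer(x$fine_dims), voxel_size = x$voxel_size,
    nodes = (ijk - 0.5) * x$h, cell_ijk = ijk, cell_id = cell_id,
    vol = x$h^3, pairs = pairs,
    n_boundary_facets = 6L * ncell - 2L * nrow(pairs),
    tags = as.integer(x$tags),
    quality = list(aspect_ratio_min = 1, aspect_ratio_median = 1,
                   n_cells = ncell, h_mm = x$h)),
    class = "brain_mesh")
}
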