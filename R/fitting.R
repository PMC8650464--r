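#' Error-mask specification for the rms fit
#'
#' Which (cell, frame) residuals enter the rms objective: artery and
#' ventricle cells are excluded (no tracer exchange), as is a ball around
#' the injection site (T2/T2* interference corrupts the data there), and
#' frames after `max_time` (to limit sensitivity to the no-efflux
#' assumption).
#'
#' @param exclude_tags subdomain names excluded; default Artery, Ventricle.
#' @param injection_radius exclusion radius around the source (mm);
#'   default 0.5.
#' @param max_time last frame time included (min); default 52.
#' @return An `error_mask_spec` object.
#' @export
error_mask_spec <- function(exclude_tags = c("Artery", "Ventricle"),
                            injection_radius = 0.5, max_time = 52) {
  if (injection_radius < 0) stop_bt("injection_radius must be >= 0")
  structure(list(exclude_tags = exclude_tags,
                 injection_radius = injection_radius, max_time = max_time),
            class = "error_mask_spec")
}

# logical vector over mesh cells included in the error calculation
fit_cell_mask <- function(mesh, mask_spec, source) {
  codes <- label_codes()
  keep <- !(mesh$tags %in% unname(codes[mask_spec$exclude_tags]))
  if (mask_spec$injection_radius > 0 && !is.null(source)) {
    d2 <- colSums((t(mesh$nodes) - source$location)^2)
    keep <- keep & d2 > mask_spec$injection_radius^2
  }
  keep
}

#' Root-mean-square mismatch between simulation and data
#'
#' `rms = sqrt( sum_(included cell,frame) (c_data - c_sim)^2 / T )` with
#' `T` the number of included residuals. Frames at t = 0 (identically zero
#' on both sides) and after `max_time` are dropped.
#'
#' @param sim,data `nodal_series` objects on the same mesh with matching
#'   frame times.
#' @param cells logical or index vector of included cells (see
#'   [error_mask_spec()]); default all.
#' @param max_time last included frame time (min); default Inf.
#' @return rms (mM), with attribute `n` = number of residuals.
#' @export
rms_error <- function(sim, data, cells = NULL, max_time = Inf) {
  stopifnot(nrow(sim$values) == nrow(data$values))
  if (!isTRUE(all.equal(sim$times, data$times)))
    stop_bt("sim and data frame times differ")
  frames <- which(sim$times > 0 & sim$times <= max_time)
  if (is.null(cells)) cells <- seq_len(nrow(sim$values))
  rs <- sim$values[cells, frames, drop = FALSE] -
        data$values[cells, frames, drop = FALSE]
  n <- length(rs)
  if (n == 0) stop_bt("rms_error: no residuals included")
  structure(sqrt(sum(rs^2) / n), n = n)
}

#' Log-spaced diffusivity grid around a center triplet
#'
#' @param center named triplet (BT, PAS_Surf, PAS_Branch), mm^2/min.
#' @param factor multiplicative spacing between neighbouring grid values.
#' @param n points per axis (odd keeps the center on the grid).
#' @return data.frame with columns `deff_bt`, `deff_surf`, `deff_branch`,
#'   one row per triplet (full factorial).
#' @export
deff_grid <- function(center = c(BT = 0.10, PAS_Surf = 95, PAS_Branch = 60),
                      factor = 3, n = 3) {
  ax <- function(v) v * factor^(seq_len(n) - (n + 1) / 2)
  g <- expand.grid(deff_bt = ax(center[["BT"]]),
                   deff_surf = ax(center[["PAS_Surf"]]),
                   deff_branch = ax(center[["PAS_Branch"]]))
  g[order(g$deff_bt, g$deff_surf, g$deff_branch), , drop = FALSE]
}

#' Grid search for the optimal subdomain diffusivities
#'
#' One forward transport solve per candidate triplet; the rms error surface
#' is returned in full, and the optimum is the minimal-rms triplet with a
#' deterministic tie-break (lexicographically smallest triplet). Failed
#' solves are marked and excluded. A previous partial surface can be passed
#' to resume.
#'
#' @param data a `nodal_series` of measured concentration interpolated onto
#'   the mesh (see [interpolate_idw()]).
#' @param mesh a tagged `brain_mesh`.
#' @param grid data.frame from [deff_grid()] (or same columns).
#' @param source a [source_spec()].
#' @param cfg a [solver_config()].
#' @param mask_spec an [error_mask_spec()].
#' @param blocked_fraction passed to [transport_params()].
#' @param resume optional previous `fit_result` on the same grid layout;
#'   rows already computed are reused.
#' @return A `fit_result`: list with `surface` (grid + rms + n_points +
#'   failed), `optimum` (named triplet), `rms_min`, and `frame_rms`
#'   (per-frame rms at the optimum).
#' @export
grid_search <- function(data, mesh, grid, source, cfg = solver_config(),
                        mask_spec = error_mask_spec(),
                        blocked_fraction = 1e-8, resume = NULL) {
  if (nrow(grid) == 0) stop_bt("empty diffusivity grid")
  cells <- fit_cell_mask(mesh, mask_spec, source)
  if (!any(cells)) stop_bt("error mask excludes every cell")
  surface <- grid
  surface$rms <- NA_real_
  surface$n_points <- NA_integer_
  surface$failed <- FALSE
  key <- function(df) sprintf("%.10g|%.10g|%.10g", df$deff_bt, df$deff_surf,
                              df$deff_branch)
  prev <- if (!is.null(resume)) resume$surface else NULL
  prev_keys <- if (!is.null(prev)) key(prev) else character(0)
  best_nodal <- NULL
  for (r in seq_len(nrow(surface))) {
    k <- key(surface[r, ])
    hit <- match(k, prev_keys)
    if (!is.na(hit) && !prev$failed[hit]) {
      surface$rms[r] <- prev$rms[hit]
      surface$n_points[r] <- prev$n_points[hit]
      next
    }
    params <- transport_params(c(BT = surface$deff_bt[r],
                                 PAS_Surf = surface$deff_surf[r],
                                 PAS_Branch = surface$deff_branch[r]),
                               blocked_fraction = blocked_fraction)
    sim <- tryCatch(
      solve_transport(mesh, params, source, data$times, cfg),
      error = function(e) e)
    if (inherits(sim, "error")) {
      surface$failed[r] <- TRUE
      next
    }
    rr <- rms_error(sim, data, cells = cells, max_time = mask_spec$max_time)
    surface$rms[r] <- as.numeric(rr)
    surface$n_points[r] <- attr(rr, "n")
  }
  ok <- which(!surface$failed)
  if (!length(ok)) stop_bt("all grid solves failed")
  o <- ok[order(surface$rms[ok], surface$deff_bt[ok], surface$deff_surf[ok],
                surface$deff_branch[ok])][1]
  optimum <- c(BT = surface$deff_bt[o], PAS_Surf = surface$deff_surf[o],
               PAS_Branch = surface$deff_branch[o])
  # per-frame rms at the optimum
  params <- transport_params(optimum, blocked_fraction = blocked_fraction)
  sim <- solve_transport(mesh, params, source, data$times, cfg)
  frames <- which(data$times > 0 & data$times <= mask_spec$max_time)
  frame_rms <- vapply(frames, function(k) {
    sqrt(mean((sim$values[cells, k] - data$values[cells, k])^2))
  }, numeric(1))
  structure(list(surface = surface, optimum = optimum,
                 rms_min = surface$rms[o],
                 frame_rms = data.frame(time_min = data$times[frames],
                                        rms = frame_rms)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", nrow(x$surface), "triplets; optimum:\n")
  print(round(x$optimum, 4))
  cat("rms at optimum:", format(x$rms_min, digits = 4), "mM\n")
  invisible(x)
}
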