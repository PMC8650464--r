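#' Physical transport constants
#'
#' Reference values for deriving physical quantities from fitted effective
#' diffusivities, for gadoteridol (~550 Da) in adult brain tissue.
#'
#' @param d_free free diffusivity D (mm^2/min); default 0.016.
#' @param lambda tissue tortuosity; default 1.73 (literature spans
#'   1.6-1.85; all selectable).
#' @param phi porosity (void fraction); default 0.20.
#' @param d_disp dispersion coefficient rule: taken equal to the apparent
#'   diffusivity unless overridden.
#' @param round_d_app use the 1-significant-figure apparent diffusivity
#'   (0.005 for the defaults) in all derived quantities, matching the
#'   conventional reporting of D/lambda^2; set `FALSE` for the exact value.
#' @param pvs_volume_fraction perivascular fraction of brain volume;
#'   default 0.03.
#' @param char_lengths characteristic transport lengths (mm) per
#'   subdomain: caudal-rostral extent for PAS_Surf, ventral-dorsal for
#'   PAS_Branch, inter-vessel spacing scale for BT.
#' @return A `transport_constants` object.
#' @export
transport_constants <- function(d_free = 0.016, lambda = 1.73, phi = 0.20,
                                d_disp = NULL, pvs_volume_fraction = 0.03,
                                char_lengths = c(PAS_Surf = 12,
                                                 PAS_Branch = 5, BT = 0.5),
                                round_d_app = TRUE) {
  if (lambda < 1) stop_bt("tortuosity lambda must be >= 1")
  if (d_free <= 0 || phi <= 0 || pvs_volume_fraction <= 0)
    stop_bt("constants must be positive")
  d_app <- d_free / lambda^2
  if (round_d_app) d_app <- signif(d_app, 1)
  if (is.null(d_disp)) d_disp <- d_app
  structure(list(d_free = d_free, lambda = lambda, phi = phi,
                 d_app = d_app, d_disp = d_disp,
                 pvs_volume_fraction = pvs_volume_fraction,
                 char_lengths = char_lengths),
            class = "transport_constants")
}

#' Apparent diffusivity D / lambda^2
#'
#' Free diffusivity reduced by tissue tortuosity. The default constants
#' give 0.016 / 1.73^2 = 0.005 mm^2/min (to one significant figure, the
#' reporting convention).
#'
#' @param d_free free diffusivity (mm^2/min).
#' @param lambda tortuosity (>= 1).
#' @return List with `value` (exact) and `reported` (1 significant
#'   figure).
#' @export
apparent_diffusivity <- function(d_free = 0.016, lambda = 1.73) {
  if (lambda < 1) stop_bt("tortuosity lambda must be >= 1")
  v <- d_free / lambda^2
  list(value = v, reported = signif(v, 1))
}

#' Peclet number from effective diffusivity
#'
#' `Pe = (Deff - D_ref - D_disp) / D_ref`: the convective excess of the
#' lumped transport coefficient over diffusion (and dispersion), relative
#' to the diffusive reference. Porous-medium transport uses `D_ref =
#' D_app`; open-channel transport uses the free diffusivity. Values >=
#' 1000 are additionally reported rounded to the nearest thousand (the
#' reporting convention).
#'
#' @param deff effective diffusivity (mm^2/min).
#' @param d_ref diffusive reference (mm^2/min, > 0).
#' @param d_disp dispersion coefficient (mm^2/min).
#' @return List with `value`, `reported` (rounded), and `flagged_negative`.
#' @export
peclet <- function(deff, d_ref, d_disp = 0) {
  if (d_ref <= 0) stop_bt("d_ref must be positive")
  v <- (deff - d_ref - d_disp) / d_ref
  reported <- if (abs(v) >= 1000) round(v / 1000) * 1000 else round(v)
  list(value = v, reported = reported, flagged_negative = v < 0)
}

#' Mean velocity from effective diffusivity and characteristic length
#'
#' `v = Deff / L`: equating the characteristic convection time `L / v`
#' with the observed transport time `L^2 / Deff`. Reproduces the reported
#' velocities (e.g. 60/5 = 12 mm/min for PAS_Branch). The variant
#' subtracting the diffusive reference first (`Pe * D_ref / L`) is
#' available via `correct_for`.
#'
#' @param deff effective diffusivity (mm^2/min).
#' @param length characteristic length (mm, > 0).
#' @param correct_for optional diffusive reference to subtract (D_ref +
#'   D_disp) before dividing.
#' @return List with `value` (mm/min) and `reported` (Table-precision
#'   rounding: 1 decimal below 1, integer above).
#' @export
mean_velocity <- function(deff, length, correct_for = 0) {
  if (length <= 0) stop_bt("characteristic length must be positive")
  v <- (deff - correct_for) / length
  reported <- if (abs(v) >= 1) round(v) else round(v, 1)
  list(value = v, reported = reported)
}

#' Effective diffusivity attributable to small-PVS convection
#'
#' The brain-tissue Deff averages transport over interstitium and the
#' perivascular spaces of unresolved small vessels. Subtracting the
#' diffusion-scale contributions of interstitial convection and dispersion
#' (each ~ D_app) and attributing the remainder to the PVS volume fraction
#' gives the transport rate inside the small PVS:
#' `(Deff_BT - D_app - D_app) / pvs_fraction`.
#'
#' @param deff_bt brain-tissue effective diffusivity (mm^2/min).
#' @param d_app apparent diffusivity (mm^2/min).
#' @param pvs_fraction perivascular volume fraction in (0, 1).
#' @return List with `value` (mm^2/min; 0 with a warning if the numerator
#'   is not positive), `ratio_to_dapp`, and `flagged`.
#' @export
small_pvs_deff <- function(deff_bt, d_app = 0.005, pvs_fraction = 0.03) {
  if (pvs_fraction <= 0 || pvs_fraction >= 1)
    stop_bt("pvs_fraction must be in (0, 1)")
  num <- deff_bt - 2 * d_app
  if (num <= 0) {
    warn_bt("brain-tissue Deff fully explained by diffusion-scale terms")
    return(list(value = 0, ratio_to_dapp = 0, flagged = TRUE))
  }
  v <- num / pvs_fraction
  list(value = v, ratio_to_dapp = v / d_app, flagged = FALSE)
}

#' Transport enhancement ratio Deff / D_app
#'
#' How many times faster the lumped transport is than hindered diffusion.
#'
#' @param deff effective diffusivity (mm^2/min).
#' @param d_app apparent diffusivity (> 0).
#' @return Numeric ratio.
#' @export
enhancement_ratio <- function(deff, d_app = 0.005) {
  if (d_app <= 0) stop_bt("d_app must be positive")
  deff / d_app
}

#' Full per-subdomain transport metrics report
#'
#' Derives, for each fitted subdomain, the open- and porous-reference
#' Peclet numbers, mean velocity, and enhancement ratio, plus the
#' small-PVS decomposition of the brain-tissue value.
#'
#' @param deff named triplet (BT, PAS_Surf, PAS_Branch) of fitted
#'   effective diffusivities (mm^2/min), e.g. `fit$optimum`.
#' @param constants a [transport_constants()] object.
#' @return A `metrics_report` object (list; serializable with
#'   [write_metrics_report()]).
#' @export
metrics_report <- function(deff, constants = transport_constants()) {
  stopifnot(all(fitted_subdomains() %in% names(deff)))
  cst <- constants
  per <- lapply(fitted_subdomains(), function(sd) {
    de <- deff[[sd]]
    pe_por <- peclet(de, cst$d_app, cst$d_disp)
    pe_open <- peclet(de, cst$d_free, cst$d_disp)
    vel <- mean_velocity(de, cst$char_lengths[[sd]])
    list(subdomain = sd, deff = de,
         pe_porous = pe_por$value, pe_porous_reported = pe_por$reported,
         pe_open = pe_open$value, pe_open_reported = pe_open$reported,
         char_length = cst$char_lengths[[sd]],
         velocity = vel$value, velocity_reported = vel$reported,
         enhancement = enhancement_ratio(de, cst$d_app))
  })
  names(per) <- fitted_subdomains()
  spvs <- small_pvs_deff(deff[["BT"]], cst$d_app, cst$pvs_volume_fraction)
  structure(list(subdomains = per, small_pvs = spvs,
                 constants = unclass(cst)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Transport metrics (Deff in mm^2/min, v in mm/min)\n")
  df <- do.call(rbind, lapply(x$subdomains, function(s)
    data.frame(subdomain = s$subdomain, deff = s$deff,
               pe_open = s$pe_open_reported,
               pe_porous = s$pe_porous_reported,
               L_mm = s$char_length, velocity = s$velocity_reported,
               enhancement = round(s$enhancement))))
  print(df, row.names = FALSE)
  cat(sprintf("small-PVS Deff: %.3g mm^2/min (%.0fx D_app)\n",
              x$small_pvs$value, x$small_pvs$ratio_to_dapp))
  invisible(x)
}

#' Serialize / restore a metrics report (lossless JSON round trip)
#' @param report a `metrics_report`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_metrics_report` returns the report.
#' @export
write_metrics_report <- function(report, path) {
  x <- unclass(report)
  x$constants$char_lengths <- as.list(x$constants$char_lengths)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$constants$char_lengths <- unlist(x$constants$char_lengths)
  structure(x, class = "metrics_report")
}
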