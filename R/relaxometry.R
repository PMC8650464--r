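#' Acquisition parameters for spoiled gradient-echo DCE-MRI
#'
#' @param tr repetition time (ms); default 16.
#' @param flip_angles pre-contrast baseline flip angles (degrees); the second
#'   (higher) angle is the imaging flip angle used for the dynamic frames.
#' @param r1 contrast-agent longitudinal relaxivity, L/(mmol*ms); gadoteridol
#'   default 3.2e-3.
#' @param frame_times dynamic acquisition times (min).
#' @return An `acquisition_params` object.
#' @export
acquisition_params <- function(tr = 16, flip_angles = c(3, 15), r1 = 3.2e-3,
                               frame_times = seq(0, 80, by = 10)) {
  if (tr <= 0) stop_bt("TR must be positive")
  if (length(flip_angles) != 2 || flip_angles[1] == flip_angles[2])
    stop_bt("two distinct flip angles required")
  if (any(flip_angles <= 0 | flip_angles >= 90))
    stop_bt("flip angles must lie in (0, 90) degrees")
  if (r1 <= 0) stop_bt("relaxivity r1 must be positive")
  structure(list(tr = tr, flip_angles = sort(flip_angles), r1 = r1,
                 frame_times = frame_times),
            class = "acquisition_params")
}

#' Spoiled gradient-echo (SPGR/FLASH) steady-state signal
#'
#' S = M0 sin(a) (1 - E1) / (1 - cos(a) E1) with E1 = exp(-TR/T1).
#' Forward model for the variable-flip-angle baselines.
#'
#' @param m0 equilibrium signal scale (arbitrary units).
#' @param alpha_deg flip angle (degrees).
#' @param t1 longitudinal relaxation time (ms).
#' @param tr repetition time (ms).
#' @return Signal, same shape as inputs (recycled).
#' @export
spgr_signal <- function(m0, alpha_deg, t1, tr) {
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Two-point variable-flip-angle T1 estimation
#'
#' Solves the SPGR signal equation exactly from two baseline volumes at
#' distinct flip angles (DESPOT1 linearization: y = S/sin(a), x = S/tan(a);
#' E1 is the slope through the two points, T1 = -TR/log(E1)). Voxels whose
#' implied E1 falls outside (0, 1), or with zero signal at both angles, are
#' masked invalid rather than erroring.
#'
#' @param baseline_low,baseline_high 3D arrays: baselines at the lower and
#'   higher flip angle of `acq$flip_angles`.
#' @param acq an [acquisition_params()] object.
#' @return A `t1_map` object: list with `t1` (ms, NA where invalid), `m0`,
#'   and logical `valid`.
#' @export
fit_t1_vfa <- function(baseline_low, baseline_high, acq) {
  stopifnot(identical(dim(baseline_low), dim(baseline_high)))
  if (any(baseline_low < 0, na.rm = TRUE) ||
      any(baseline_high < 0, na.rm = TRUE))
    stop_bt("baseline signals must be non-negative")
  a <- acq$flip_angles * pi / 180
  y1 <- baseline_low / sin(a[1]);  x1 <- baseline_low / tan(a[1])
  y2 <- baseline_high / sin(a[2]); x2 <- baseline_high / tan(a[2])
  e1 <- (y2 - y1) / (x2 - x1)
  valid <- is.finite(e1) & e1 > 0 & e1 < 1
  t1 <- array(NA_real_, dim(baseline_low))
  m0 <- array(NA_real_, dim(baseline_low))
  t1[valid] <- -acq$tr / log(e1[valid])
  # intercept of the DESPOT1 line is M0 (1 - E1)
  m0[valid] <- (y1[valid] - e1[valid] * x1[valid]) / (1 - e1[valid])
  valid <- valid & t1 > 0 & t1 < 10000
  t1[!valid] <- NA_real_
  structure(list(t1 = t1, m0 = m0, valid = valid), class = "t1_map")
}

#' Convert post-contrast signal to superficial concentration
#'
#' Applies the linearized signal relation
#' c-bar = (1 / (r1 * T1_0)) * (S_Gd - S0) / S0, with S0 the pre-contrast
#' baseline at the imaging (higher) flip angle. Negative concentrations
#' arising from noise are retained and flagged by default; clamping to zero
#' would bias the rms fit downstream.
#'
#' @param series a [signal_series] object.
#' @param t1 a `t1_map` from [fit_t1_vfa()] (or a ground-truth map).
#' @param acq an [acquisition_params()] object.
#' @param porosity void fraction recorded on the output series.
#' @param clamp_negative if `TRUE`, negative values are set to 0.
#' @return A [conc_series] with `mask` = valid T1 and nonzero baseline.
#' @export
signal_to_concentration <- function(series, t1, acq,
                                    porosity = 0.20,
                                    clamp_negative = FALSE) {
  s0 <- series$baseline_high
  stopifnot(identical(dim(s0), dim(t1$t1)))
  if (!identical(dim(series$frames)[1:3], dim(s0)))
    stop_bt("signal frames and baseline shapes differ")
  valid <- t1$valid & s0 > 0
  nt <- dim(series$frames)[4]
  out <- array(0, dim(series$frames))
  denom <- acq$r1 * t1$t1
  for (k in seq_len(nt)) {
    f <- series$frames[, , , k]
    ck <- array(0, dim(s0))
    ck[valid] <- (f[valid] - s0[valid]) / s0[valid] / denom[valid]
    out[, , , k] <- ck
  }
  n_neg <- sum(out < 0)
  if (clamp_negative) out[out < 0] <- 0
  cs <- conc_series(out, series$times, series$voxel_size,
                    porosity = porosity, mask = valid)
  attr(cs, "n_negative") <- n_neg
  cs
}

# inverse of signal_to_concentration for the phantom forward model:
# S_Gd = S0 * (1 + r1 * T1_0 * cbar)
concentration_to_signal <- function(cbar, s0, t1, r1) {
  s0 * (1 + r1 * t1 * cbar)
}
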