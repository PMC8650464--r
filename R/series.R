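#' 4D signal series container
#'
#' Houses the DCE-MRI signal: two pre-contrast spoiled-gradient-echo
#' baselines acquired at distinct flip angles plus the post-contrast frames
#' acquired at the imaging flip angle (the higher of the two).
#'
#' @param frames 4D numeric array (x, y, z, time) of post-contrast signal.
#' @param baseline_low,baseline_high 3D arrays: pre-contrast baselines at the
#'   low and high flip angle.
#' @param times acquisition times of `frames` (min).
#' @param voxel_size voxel edge (mm).
#' @param acq an [acquisition_params()] object.
#' @return A `signal_series` object.
#' @export
signal_series <- function(frames, baseline_low, baseline_high, times,
                          voxel_size, acq) {
  stopifnot(length(dim(frames)) == 4, dim(frames)[4] == length(times))
  stopifnot(identical(dim(baseline_low), dim(frames)[1:3]),
            identical(dim(baseline_high), dim(frames)[1:3]))
  if (is.unsorted(times)) stop_bt("frame times must be non-decreasing")
  structure(list(frames = frames, baseline_low = baseline_low,
                 baseline_high = baseline_high, times = times,
                 voxel_size = voxel_size, acq = acq),
            class = "signal_series")
}

#' 4D concentration series container
#'
#' Per-voxel, per-frame superficial gadoteridol concentration c-bar (mM),
#' the porous-media convention c-bar = c * phi with phi the extracellular
#' void fraction (~0.20 in adult brain tissue). All transport calculations
#' work with the superficial concentration, so amounts are c-bar times total
#' voxel volume with no extra porosity factor.
#'
#' @param data 4D numeric array (x, y, z, time), mM.
#' @param times frame times (min).
#' @param voxel_size voxel edge (mm).
#' @param porosity void fraction phi in (0, 1]; default 0.20.
#' @param mask optional 3D logical array of valid voxels.
#' @return A `conc_series` object.
#' @export
conc_series <- function(data, times, voxel_size, porosity = 0.20,
                        mask = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] == length(times))
  if (is.unsorted(times)) stop_bt("frame times must be non-decreasing")
  if (porosity <= 0 || porosity > 1) stop_bt("porosity must be in (0, 1]")
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(data)[1:3]))
  structure(list(data = data, times = times, voxel_size = voxel_size,
                 porosity = porosity, mask = mask),
            class = "conc_series")
}

#' Extract the frame nearest a requested time
#' @param conc a [conc_series] object.
#' @param time requested time (min).
#' @return List with `volume` (3D array), `time` (actual frame time) and
#'   `index`.
#' @export
nearest_frame <- function(conc, time) {
  i <- which.min(abs(conc$times - time))
  list(volume = conc$data[, , , i, drop = TRUE], time = conc$times[i],
       index = i)
}

#' Total tracer amount per frame
#'
#' Sums superficial concentration over a mask and converts to amount:
#' 1 mM = 1 nmol/mm^3, so amount_nmol = sum(c-bar) * voxel volume; reported
#' in umol. Serves as the no-flux diagnostic: on clean data the curve rises
#' during infusion and stays flat afterwards.
#'
#' @param conc a [conc_series] object.
#' @param brain_mask 3D logical array of voxels to include.
#' @return data.frame with columns `time_min`, `amount_umol`.
#' @export
total_amount <- function(conc, brain_mask) {
  stopifnot(identical(dim(brain_mask), dim(conc$data)[1:3]))
  if (!any(brain_mask)) stop_bt("total_amount: empty brain mask")
  vvol <- conc$voxel_size^3                      # mm^3
  idx <- which(brain_mask)
  nt <- length(conc$times)
  amt <- vapply(seq_len(nt), function(t) {
    sum(conc$data[, , , t][idx]) * vvol / 1000   # nmol -> umol
  }, numeric(1))
  data.frame(time_min = conc$times, amount_umol = amt)
}
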