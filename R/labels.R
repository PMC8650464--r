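#' Subdomain label codes
#'
#' Integer codes for the five transport subdomains plus background used
#' throughout the package. Voxels outside the brain are `Background`;
#' in-brain voxels belong to exactly one of brain tissue (`BT`), surface
#' periarterial space (`PAS_Surf`), branching periarterial space
#' (`PAS_Branch`), `Artery` or `Ventricle`.
#'
#' @return Named integer vector mapping label name to code.
#' @export
label_codes <- function() {
  c(Background = 0L, BT = 1L, PAS_Surf = 2L, PAS_Branch = 3L,
    Artery = 4L, Ventricle = 5L)
}

#' Names of the fitted transport subdomains
#'
#' The three subdomains whose effective diffusivities are estimated
#' (arteries and ventricles are tied to BT by a blocked fraction).
#' @return Character vector.
#' @export
fitted_subdomains <- function() c("BT", "PAS_Surf", "PAS_Branch")

label_name <- function(code) {
  codes <- label_codes()
  names(codes)[match(code, codes)]
}

stop_bt <- function(...) stop(sprintf(...), call. = FALSE)
warn_bt <- function(...) warning(sprintf(...), call. = FALSE)

# voxel-center world coordinate (mm) of 1-based index i along an axis
voxel_center <- function(i, voxel_size) (i - 0.5) * voxel_size

#' Create a subdomain label volume
#'
#' Wraps an integer array of label codes with provenance. Used by both the
#' phantom generator and the segmentation pipeline.
#'
#' @param arr integer 3D array of codes from [label_codes()].
#' @param voxel_size voxel edge length (mm).
#' @param provenance optional list recording thresholds / origin.
#' @return A `subdomain_labels` object.
#' @export
subdomain_labels <- function(arr, voxel_size, provenance = list()) {
  stopifnot(length(dim(arr)) == 3)
  bad <- setdiff(unique(as.vector(arr)), unname(label_codes()))
  if (length(bad)) stop_bt("unknown label codes: %s", paste(bad, collapse = ", "))
  structure(list(data = arr, voxel_size = voxel_size, provenance = provenance),
            class = "subdomain_labels")
}

#' @export
print.subdomain_labels <- function(x, ...) {
  cat("<subdomain_labels>", paste(dim(x$data), collapse = "x"),
      "voxels @", x$voxel_size, "mm\n")
  tb <- table(factor(label_name(as.vector(x$data)),
                     levels = names(label_codes())))
  print(tb)
  invisible(x)
}

#' Per-label voxel counts
#' @param labels a [subdomain_labels] object.
#' @return Named integer vector over all label names.
#' @export
label_counts <- function(labels) {
  tb <- table(factor(label_name(as.vector(labels$data)),
                     levels = names(label_codes())))
  stats::setNames(as.integer(tb), names(tb))
}
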