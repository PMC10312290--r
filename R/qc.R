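#' Framewise displacement from rigid-body motion parameters
#'
#' FD at frame t is the sum of the absolute backward differences of the three
#' translations plus the three rotations converted to arc length on a sphere
#' of radius `head_radius` (the conventional 50 mm). The first frame has no
#' predecessor and is defined as FD = 0.
#'
#' @param motion A [motion_trace()].
#' @param head_radius Sphere radius (mm) for the rotation-to-displacement
#'   conversion.
#' @return Numeric vector of per-frame FD in mm.
#' @examples
#' m <- motion_trace(matrix(0, 5, 3), matrix(0, 5, 3))
#' compute_fd(m)  # all zero
#' @export
compute_fd <- function(motion, head_radius = 50) {
  stopifnot(inherits(motion, "cc_motion"))
  check_scalar_number(head_radius, "head_radius", positive = TRUE)
  n <- nrow(motion$translations)
  if (n < 2) stop_invalid("FD requires at least 2 frames")
  dtrans <- abs(diff(motion$translations))
  drot <- abs(diff(motion$rotations)) * head_radius
  c(0, rowSums(dtrans) + rowSums(drot))
}

#' DVARS: root-mean-square frame-to-frame signal change
#'
#' DVARS at frame t is the root mean square over parcels of the signal
#' difference between frames t and t-1, expressed as a percentage of the grand
#' mean signal so the conventional 2.5% threshold applies to arbitrary-unit
#' data. The first frame is defined as DVARS = 0.
#'
#' @param bold A [parcellated_bold()] object.
#' @return Numeric vector of per-frame DVARS in percent.
#' @export
compute_dvars <- function(bold) {
  stopifnot(inherits(bold, "cc_bold"))
  if (nrow(bold$data) < 2) stop_invalid("DVARS requires at least 2 frames")
  gm <- mean(bold$data)
  if (!is.finite(gm) || abs(gm) < .Machine$double.eps * 100)
    stop_degenerate("grand mean signal is zero; DVARS percent scale undefined")
  d <- diff(bold$data)
  c(0, sqrt(rowMeans(d^2)) / abs(gm) * 100)
}

#' Motion quality-control flags and subject exclusion rule
#'
#' A frame is flagged when FD strictly exceeds `fd_thresh` or DVARS strictly
#' exceeds `dvars_thresh`; a subject is excluded when the flagged fraction
#' strictly exceeds `exclusion_fraction`.
#'
#' @param fd Per-frame FD (mm).
#' @param dvars Per-frame DVARS (%), same length as `fd`.
#' @param fd_thresh FD threshold in mm (default 0.25).
#' @param dvars_thresh DVARS threshold in percent (default 2.5).
#' @param exclusion_fraction Flagged-fraction threshold for exclusion
#'   (default 0.10).
#' @return A list of class `cc_qc` with `fd`, `dvars`, `flagged` (logical per
#'   frame), `n_flagged`, and `exclude_subject`.
#' @export
qc_flags <- function(fd, dvars, fd_thresh = 0.25, dvars_thresh = 2.5,
                     exclusion_fraction = 0.10) {
  if (length(fd) != length(dvars))
    stop_invalid("fd and dvars must have equal length (", length(fd), " vs ",
                 length(dvars), ")")
  if (any(fd < 0) || any(dvars < 0))
    stop_invalid("fd and dvars must be non-negative")
  flagged <- fd > fd_thresh | dvars > dvars_thresh
  structure(list(
    fd = fd, dvars = dvars, flagged = flagged,
    n_flagged = sum(flagged),
    exclude_subject = mean(flagged) > exclusion_fraction
  ), class = "cc_qc")
}

#' @export
print.cc_qc <- function(x, ...) {
  cat(sprintf("<cc_qc> %d/%d frames flagged; exclude_subject = %s\n",
              x$n_flagged, length(x$flagged), x$exclude_subject))
  invisible(x)
}
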