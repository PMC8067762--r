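#' Group stress tensor from per-atom stress*volume output
#'
#' Sums the per-atom stress*volume tensors of a member group, divides by the
#' group's occupied (Voronoi) volume, negates the virial-pressure sign so
#' tension is positive, and converts atm to GPa:
#' \deqn{\sigma = -\frac{\sum_{i \in g} (s v)_i}{\sum_{i \in g} v_i}
#'   \times 1.01325\times10^{-4}}
#'
#' @param frame an [atom_frame] (stress*volume in atm*A^3).
#' @param member_ids atom ids of the group; must all be present in the frame.
#' @param volumes per-atom volumes (A^3) in the frame's id order, e.g. from
#'   [voronoi_volumes()].
#' @return named length-6 numeric (xx, yy, zz, xy, xz, yz), GPa.
#' @export
group_stress <- function(frame, member_ids, volumes) {
  member_ids <- as.integer(member_ids)
  if (length(member_ids) == 0L) stop_param("member set must be non-empty")
  idx <- match(member_ids, frame$ids)
  if (anyNA(idx))
    stop_param("member ids not in frame: ",
               paste(member_ids[is.na(idx)], collapse = ", "))
  if (length(volumes) != length(frame$ids))
    stop_param("volumes must be given for every atom in the frame")
  s <- colSums(frame$stress_pv[idx, , drop = FALSE])
  v <- sum(volumes[idx])
  if (v <= 0) stop_param("group volume must be positive")
  setNames(-s / v * ATM_TO_GPA, TENSOR_COMPONENTS)
}

#' Group stress time series from a trajectory
#'
#' Applies [voronoi_volumes()] and [group_stress()] frame by frame to build a
#' [group_stress_series()]; times are `timestep * dt_ps`.
#'
#' @param frames list of [atom_frame].
#' @param member_ids group atom ids.
#' @param dt_ps ps per timestep unit.
#' @param axis pulling axis for the reported axial component.
#' @param periodic passed to [voronoi_volumes()].
#' @return a [group_stress_series()].
#' @export
extract_group_stress <- function(frames, member_ids, dt_ps = 1, axis = "x",
                                 periodic = TRUE) {
  if (length(frames) == 0L) stop_param("no frames given")
  tens <- t(vapply(frames, function(fr) {
    vols <- voronoi_volumes(fr, periodic = periodic)
    group_stress(fr, member_ids, vols)
  }, numeric(6)))
  time <- vapply(frames, function(fr) fr$timestep, integer(1)) * dt_ps
  group_stress_series(time, tens, axis = axis)
}

#' Engineering strain series from atomic displacement
#'
#' Strain at each frame is the mean displacement of the pulled group along
#' the pulling axis, measured from the first frame, divided by the reference
#' length: \eqn{\epsilon(t) = \bar{u}_{axis}(t) / L_0}. Coordinates are
#' treated as unwrapped (wrapped input is unwrapped on read when image flags
#' are present).
#'
#' @param frames list of [atom_frame].
#' @param pulled_ids atom ids of the pulled group; must be present in every
#'   frame.
#' @param axis pulling axis, `"x"`, `"y"` or `"z"`; prefix with `-` (e.g.
#'   `"-x"`) to measure displacement toward the negative direction.
#' @param reference_length reference length \eqn{L_0} (Angstrom), > 0.
#' @param dt_ps ps per timestep unit.
#' @return a [strain_series_df()].
#' @export
strain_series <- function(frames, pulled_ids, axis = "x", reference_length,
                          dt_ps = 1) {
  check_scalar(reference_length, "reference_length", positive = TRUE)
  if (length(frames) == 0L) stop_param("no frames given")
  sgn <- if (startsWith(axis, "-")) -1 else 1
  ax <- match(sub("^-", "", axis), c("x", "y", "z"))
  if (is.na(ax)) stop_param("axis must be x, y, z or -x, -y, -z")
  pulled_ids <- as.integer(pulled_ids)
  pos <- vapply(frames, function(fr) {
    idx <- match(pulled_ids, fr$ids)
    if (anyNA(idx))
      stop_param("pulled atom(s) absent in frame at timestep ", fr$timestep,
                 ": ", paste(pulled_ids[is.na(idx)], collapse = ", "))
    mean(fr$coords[idx, ax])
  }, numeric(1))
  time <- vapply(frames, function(fr) fr$timestep, integer(1)) * dt_ps
  strain_series_df(time, sgn * (pos - pos[1]) / reference_length)
}

#' Von Mises equivalent stress of a tensor series
#'
#' Optional scalar stress measure for curves where a single invariant is
#' preferred over the axial normal component.
#'
#' @param series a [group_stress_series()].
#' @return numeric vector (GPa).
#' @export
von_mises <- function(series) {
  s <- as.matrix(series[, TENSOR_COMPONENTS])
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}
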