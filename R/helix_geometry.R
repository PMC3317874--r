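# Kinked-helix descriptors: bend angle, wobble angle and face shift of the
# post-kink segment relative to the pre-kink segment. The paper-style triple
# (bend, wobble, face shift) summarises how a proline (or Gly/Ser/Thr) hinge
# redirects a transmembrane helix; the exact mathematical conventions are
# declared here so that the values are self-consistent and recoverable from
# synthetic constructions.

#' Least-squares axis of a helical C-alpha trace
#'
#' The axis direction is estimated by the bisector construction: for each
#' interior C-alpha the sum of the two unit bonds pointing back to it,
#' \eqn{(p_i - p_{i+1}) + (p_{i+2} - p_{i+1})}, points radially at the helix
#' axis, and the cross product of successive bisectors gives the axis
#' direction (exact for an ideal helix, and far more stable on short
#' segments than a principal-component fit). The axis line position is then
#' a least-squares circle fit of the points projected onto the normal plane.
#' Oriented N-terminus to C-terminus; deterministic; needs at least four
#' points.
#'
#' @param ca_coords n x 3 matrix of ordered C-alpha coordinates (n >= 4).
#' @return list with unit `axis` (3-vector, N->C) and `centroid` (a point on
#'   the axis line at the mean axial height of the segment).
#' @export
fit_axis <- function(ca_coords) {
  ca <- as.matrix(ca_coords)
  n <- nrow(ca)
  if (n < 4L) stop("need at least 4 C-alpha positions to fit an axis")
  bis <- t(vapply(seq_len(n - 2L), function(i)
    vunit((ca[i, ] - ca[i + 1L, ]) + (ca[i + 2L, ] - ca[i + 1L, ])),
    numeric(3L)))
  axes <- t(vapply(seq_len(n - 3L), function(i) {
    a <- vcross(bis[i, ], bis[i + 1L, ])
    if (vnorm(a) < 1e-9)
      stop("degenerate (collinear) trace: cannot determine a helix axis")
    vunit(a)
  }, numeric(3L)))
  # align signs to the first estimate before averaging
  ref <- axes[1L, ]
  for (i in seq_len(nrow(axes)))
    if (sum(axes[i, ] * ref) < 0) axes[i, ] <- -axes[i, ]
  axis <- vunit(colMeans(axes))
  if (sum(axis * (ca[n, ] - ca[1L, ])) < 0) axis <- -axis
  # axis line position: least-squares circle in the plane normal to axis
  e1 <- vunit(vcross(axis, if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- vcross(axis, e1)
  px <- ca %*% e1; py <- ca %*% e2
  A <- cbind(2 * px, 2 * py, 1)
  b <- px^2 + py^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  center2 <- if (is.null(sol)) c(mean(px), mean(py)) else sol[1:2]
  h <- mean(ca %*% axis)
  centroid <- as.numeric(center2[1L] * e1 + center2[2L] * e2 + h * axis)
  list(axis = axis, centroid = centroid)
}

# perpendicular offset of a point from the axis line (centroid, axis)
axis_offset <- function(p, fit) {
  d <- p - fit$centroid
  d - sum(d * fit$axis) * fit$axis
}

#' Bend, wobble and face shift of a kinked helix
#'
#' Segments of `window` residues on either side of the flexible span are
#' fitted independently; the flexible span `flex_residue - 4 ... flex_residue`
#' is excluded from both fits. The descriptors are:
#' \describe{
#'   \item{bend}{angle between the pre- and post-segment axes, degrees
#'     in [0, 180).}
#'   \item{wobble}{azimuth of the post-segment axis about the pre-segment
#'     axis. Zero reference: the direction from the pre-segment axis to the
#'     flex residue's C-alpha; counterclockwise positive looking N->C
#'     (right-hand rule about the pre-axis). Degrees in (-180, 180].}
#'   \item{face shift}{change in helical phase of the first post-segment
#'     C-alpha relative to the unkinked extrapolation of the pre-segment:
#'     the pre-segment azimuths (about the pre-axis) are unwrapped, fitted
#'     linearly in residue index and extrapolated to the first post-segment
#'     residue; the reference frame is transported onto the post axis by the
#'     minimal rotation between the two axes; the face shift is the measured
#'     minus the extrapolated azimuth, wrapped to (-180, 180]. A pure
#'     rigid-body bend therefore has face shift ~ 0, and an additional twist
#'     of the post segment about its own axis appears directly as face
#'     shift.}
#' }
#'
#' @param helix a `helix_conformation` or an n x 3 C-alpha matrix.
#' @param flex_residue sequence number of the hinge residue (e.g. the
#'   proline).
#' @param window residues per fitted segment. Default 7.
#' @return list of class `helix_geometry`: `bend_deg`, `wobble_deg`,
#'   `face_shift_deg`, `flex_residue`.
#' @export
kink_geometry <- function(helix, flex_residue, window = 7L) {
  ca <- helix_ca(helix)
  n <- nrow(ca)
  pre_idx <- (flex_residue - 4L - window):(flex_residue - 5L)
  post_idx <- (flex_residue + 1L):(flex_residue + window)
  if (pre_idx[1L] < 1L || post_idx[length(post_idx)] > n)
    stop("insufficient residues around flex residue ", flex_residue,
         " for window ", window)
  fit_pre <- fit_axis(ca[pre_idx, , drop = FALSE])
  fit_post <- fit_axis(ca[post_idx, , drop = FALSE])
  a1 <- fit_pre$axis; a2 <- fit_post$axis
  bend <- rad2deg(acos(min(1, max(-1, sum(a1 * a2)))))

  # wobble: azimuth of the post axis about the pre axis, zero at the
  # direction from the pre axis to the flex C-alpha
  ref <- axis_offset(ca[flex_residue, ], fit_pre)
  wobble <- if (bend < 1e-6) 0 else signed_angle_about(ref, a2, a1)

  # face shift: extrapolated vs measured helical phase of the first
  # post-segment residue
  u <- vunit(ref)
  phases <- vapply(pre_idx, function(i)
    signed_angle_about(u, axis_offset(ca[i, ], fit_pre), a1), numeric(1L))
  unwrapped <- cumsum(c(phases[1L], wrap_angle(diff(phases))))
  coef <- stats::lm.fit(cbind(1, pre_idx), unwrapped)$coefficients
  phase_pred <- wrap_angle(coef[1L] + coef[2L] * post_idx[1L])
  u2 <- as.numeric(rotation_between(a1, a2) %*% u)
  phase_act <- signed_angle_about(u2, axis_offset(ca[post_idx[1L], ], fit_post),
                                  a2)
  structure(list(bend_deg = bend,
                 wobble_deg = wrap_angle(wobble),
                 face_shift_deg = wrap_angle(phase_act - phase_pred),
                 flex_residue = flex_residue),
            class = "helix_geometry")
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf(
    "helix kink at residue %d: bend %.1f deg, wobble %.1f deg, face shift %.1f deg\n",
    x$flex_residue, x$bend_deg, x$wobble_deg, x$face_shift_deg))
  invisible(x)
}

#' Tabulate kink descriptors for several helices
#'
#' @param helices named list of helices (or C-alpha matrices).
#' @param flex_residues integer vector of hinge residues, recycled.
#' @param window residues per fitted segment.
#' @return data frame with columns `helix`, `flex_residue`, `bend_deg`,
#'   `wobble_deg`, `face_shift_deg`.
#' @export
kink_geometry_table <- function(helices, flex_residues, window = 7L) {
  flex_residues <- rep_len(flex_residues, length(helices))
  rows <- lapply(seq_along(helices), function(i) {
    g <- kink_geometry(helices[[i]], flex_residues[i], window)
    data.frame(helix = names(helices)[i] %||% as.character(i),
               flex_residue = g$flex_residue, bend_deg = g$bend_deg,
               wobble_deg = g$wobble_deg, face_shift_deg = g$face_shift_deg)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
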