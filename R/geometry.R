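# Rigid-body geometry: quaternion superposition, rotation decomposition,
# axis-constrained spin angles, membrane frames and helix axes.

#' Construct a rigid transform
#'
#' A rigid transform acts on row-vector coordinates as `p -> R p + t`, with
#' the rotation stored as a unit quaternion `(w, x, y, z)` under the
#' convention `w >= 0`.
#'
#' @param quaternion Numeric length-4 vector `(w, x, y, z)`; normalised and
#'   sign-fixed on construction.
#' @param translation Numeric length-3 translation, in Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0),
                            translation = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  t <- as.numeric(translation)
  stopifnot(length(q) == 4L, length(t) == 3L, all(is.finite(q)),
            all(is.finite(t)))
  nq <- sqrt(sum(q^2))
  if (nq < 1e-12) stop("quaternion has zero norm")
  q <- q / nq
  if (q[1] < 0) q <- -q
  structure(list(q = q, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_angle_axis(x)
  cat(sprintf("rigid transform: rotation %.3f deg", aa$angle_deg))
  if (aa$defined)
    cat(sprintf(" about (%.3f, %.3f, %.3f)", aa$axis[1], aa$axis[2],
                aa$axis[3]))
  cat(sprintf("; translation (%.3f, %.3f, %.3f) A\n",
              x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Rotation matrix of a unit quaternion
#' @param q Numeric length-4 unit quaternion `(w, x, y, z)`.
#' @return 3x3 proper rotation matrix `R` with `R p` rotating column vector
#'   `p`.
#' @export
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w * w + x * x - y * y - z * z, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w * w - x * x + y * y - z * z, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w * w - x * x - y * y + z * z
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion of a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return Numeric length-4 unit quaternion with non-negative scalar part.
#' @export
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  # Shepperd's method: pick the largest diagonal pivot for stability
  m <- which.max(c(tr, R[1, 1], R[2, 2], R[3, 3]))
  if (m == 1L) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (m == 2L) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (m == 3L) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Hamilton product of two quaternions
#' @param a,b Numeric length-4 quaternions `(w, x, y, z)`.
#' @return Their Hamilton product `a * b`.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion for a rotation about an axis
#' @param angle_deg Rotation angle in degrees.
#' @param axis Numeric length-3 rotation axis (normalised internally).
#' @return Unit quaternion `(w, x, y, z)`.
#' @export
axis_angle_quat <- function(angle_deg, axis) {
  a <- as.numeric(axis)
  a <- a / sqrt(sum(a^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * a)
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param coords An n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates with the same shape.
#' @export
apply_transform <- function(transform, coords) {
  R <- quat_to_mat(transform$q)
  vec <- is.null(dim(coords))
  if (vec) coords <- matrix(coords, nrow = 1)
  out <- coords %*% t(R)
  out <- sweep(out, 2, transform$t, "+")
  if (vec) out[1, ] else out
}

#' Compose two rigid transforms
#' @param first,second Rigid transforms; the result applies `first` then
#'   `second`.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(second, first) {
  q <- quat_multiply(second$q, first$q)
  t <- apply_transform(second, first$t)
  rigid_transform(q, t)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return Its inverse.
#' @export
invert_transform <- function(transform) {
  qc <- c(transform$q[1], -transform$q[2:4])
  Rt <- t(quat_to_mat(transform$q))
  rigid_transform(qc, -as.numeric(Rt %*% transform$t))
}

#' Membrane reference frame
#'
#' An orthonormal right-handed frame whose z axis is the membrane normal.
#' The y axis is rebuilt as `z x x` so the result is exactly right-handed;
#' `x` is orthogonalised against `z` first.
#'
#' @param origin Frame origin (Angstrom), default the global origin.
#' @param z_axis Membrane normal direction.
#' @param x_axis In-plane reference direction.
#' @return An object of class `membrane_frame` with unit `x_axis`, `y_axis`,
#'   `z_axis` and `origin`.
#' @export
membrane_frame <- function(origin = c(0, 0, 0), z_axis = c(0, 0, 1),
                           x_axis = c(1, 0, 0)) {
  z <- as.numeric(z_axis); x <- as.numeric(x_axis)
  stopifnot(length(origin) == 3L, length(z) == 3L, length(x) == 3L)
  z <- z / sqrt(sum(z^2))
  x <- x - sum(x * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("x_axis is parallel to z_axis")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(origin = as.numeric(origin), x_axis = x, y_axis = y,
                 z_axis = z), class = "membrane_frame")
}

# shared degenerate-geometry guard for point sets entering a rotational fit
check_fit_geometry <- function(mobile, reference) {
  if (!is.matrix(mobile)) mobile <- as.matrix(mobile)
  if (!is.matrix(reference)) reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate sets must be n x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop("coordinate sets differ in atom count: ", nrow(mobile), " vs ",
         nrow(reference))
  if (nrow(mobile) < 3L)
    stop("degenerate geometry: need at least 3 atoms, got ", nrow(mobile))
  for (m in list(mobile, reference)) {
    mc <- sweep(m, 2, colMeans(m))
    sv <- svd(mc, nu = 0, nv = 0)$d
    if (sv[2] < 1e-8 * max(sv[1], 1))
      stop("degenerate geometry: atom set is collinear")
  }
  list(mobile = mobile, reference = reference)
}

# Horn quaternion fit of centered coordinates; returns the unit quaternion
# whose rotation takes the (centered) mobile set onto the (centered)
# reference in the least-squares sense.
horn_quaternion <- function(mobile_c, reference_c, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(mobile_c))
  S <- t(mobile_c * w) %*% reference_c
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  if (q[1] < 0) q <- -q
  q
}

weighted_centroid <- function(coords, w = NULL) {
  if (is.null(w)) return(colMeans(coords))
  as.numeric(colSums(coords * w) / sum(w))
}

#' Least-squares rigid superposition (quaternion method)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired coordinate sets, using the quaternion
#' eigenvalue formulation.  The returned transform maps `mobile` onto
#' `reference`.
#'
#' @param mobile n x 3 coordinates to be moved.
#' @param reference n x 3 target coordinates, paired row-by-row.
#' @param weights Optional per-atom weights (e.g. masses); unweighted by
#'   default.
#' @return An object of class `superposition`: fields `transform`
#'   (`rigid_transform`), `rmsd` (Angstrom), `rotation_angle` (degrees, in
#'   `[0, 180]`), `rotation_axis` (unit vector or `NA` when the angle is
#'   below 1e-6 degrees), `axis_defined`, and `n_atoms`.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  g <- check_fit_geometry(mobile, reference)
  mobile <- g$mobile; reference <- g$reference
  n <- nrow(mobile)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  }
  cm <- weighted_centroid(mobile, weights)
  cr <- weighted_centroid(reference, weights)
  mc <- sweep(mobile, 2, cm)
  rc <- sweep(reference, 2, cr)
  q <- horn_quaternion(mc, rc, weights)
  R <- quat_to_mat(q)
  tr <- rigid_transform(q, cr - as.numeric(R %*% cm))
  moved <- apply_transform(tr, mobile)
  d2 <- rowSums((moved - reference)^2)
  w <- if (is.null(weights)) rep(1, n) else weights
  rmsd <- sqrt(sum(w * d2) / sum(w))
  aa <- rotation_angle_axis(tr)
  structure(list(transform = tr, rmsd = rmsd,
                 rotation_angle = aa$angle_deg, rotation_axis = aa$axis,
                 axis_defined = aa$defined, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition of %d atoms: rmsd %.4f A, rotation %.3f deg\n",
              x$n_atoms, x$rmsd, x$rotation_angle))
  invisible(x)
}

#' Angle/axis decomposition of a rigid transform
#'
#' @param transform A `rigid_transform` (or unit quaternion).
#' @return List with `angle_deg` in `[0, 180]`, unit `axis` (sign chosen so
#'   the angle is positive; `NA` with `defined = FALSE` when the rotation
#'   angle is below 1e-6 degrees), and `defined`.
#' @export
rotation_angle_axis <- function(transform) {
  q <- if (inherits(transform, "rigid_transform")) transform$q
       else as.numeric(transform)
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  angle <- 2 * atan2(vn, q[1]) * 180 / pi
  if (angle < 1e-6) {
    list(angle_deg = angle, axis = rep(NA_real_, 3), defined = FALSE)
  } else {
    list(angle_deg = angle, axis = q[2:4] / vn, defined = TRUE)
  }
}

#' Spin angle of a group about a fixed axis
#'
#' The rotational progress of an atom group about a predefined axis,
#' measured relative to a reference configuration: after removing both
#' centroids, the optimal unconstrained superposition quaternion
#' `q = (w, v)` rotating the reference onto the group is computed, and the
#' spin is `2 * atan2(v . axis, w)` mapped to `(-180, 180]` degrees.  When
#' the optimal rotation is exactly about `axis`, this equals the signed
#' rotation angle.
#'
#' @param group n x 3 coordinates of the group in its current configuration.
#' @param reference n x 3 coordinates of the same atoms in the reference
#'   configuration.
#' @param axis Numeric length-3 spin axis (normalised internally).
#' @param weights Optional per-atom weights.
#' @return Spin angle in degrees, in `(-180, 180]`.
#' @export
spin_angle <- function(group, reference, axis, weights = NULL) {
  g <- check_fit_geometry(group, reference)
  a <- as.numeric(axis); a <- a / sqrt(sum(a^2))
  gc <- sweep(g$mobile, 2, weighted_centroid(g$mobile, weights))
  rc <- sweep(g$reference, 2, weighted_centroid(g$reference, weights))
  # quaternion rotating reference onto group: fit reference -> group
  q <- horn_quaternion(rc, gc, weights)
  ang <- 2 * atan2(sum(q[2:4] * a), q[1]) * 180 / pi
  wrap_angle(ang)
}

# map degrees to (-180, 180]
wrap_angle <- function(deg) {
  m <- deg %% 360
  ifelse(m > 180, m - 360, m)
}

#' Signed centroid separation along the membrane normal
#'
#' @param group_a,group_b n x 3 coordinate matrices (any sizes >= 1).
#' @param frame A `membrane_frame`; the projection axis is `frame$z_axis`.
#' @param weights_a,weights_b Optional per-atom weights for the centroids.
#' @return `(centroid(a) - centroid(b)) . z`, signed Angstrom.
#' @export
distance_z <- function(group_a, group_b, frame,
                       weights_a = NULL, weights_b = NULL) {
  if (is.null(dim(group_a))) group_a <- matrix(group_a, ncol = 3)
  if (is.null(dim(group_b))) group_b <- matrix(group_b, ncol = 3)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L)
    stop("distance_z: empty atom group")
  ca <- weighted_centroid(group_a, weights_a)
  cb <- weighted_centroid(group_b, weights_b)
  sum((ca - cb) * frame$z_axis)
}

#' Fit a helix axis by principal component
#'
#' The axis is the largest-variance principal direction of the centered
#' C-alpha coordinates, with its sign fixed so it points from the N- to the
#' C-terminus (`axis . (last - first) > 0`).
#'
#' @param ca_coords n x 3 C-alpha coordinates in N-to-C order, n >= 4.
#' @return An object of class `helix_segment`: `axis` (unit), `centroid`,
#'   `length` (extent of the projections, Angstrom) and `n_atoms`.
#' @export
fit_helix_axis <- function(ca_coords) {
  x <- as.matrix(ca_coords)
  if (nrow(x) < 4L)
    stop("helix axis fit needs at least 4 CA atoms, got ", nrow(x))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0)
  if (sv$d[1] < 1e-8)
    stop("degenerate helix: all points coincident")
  axis <- sv$v[, 1]
  span <- x[nrow(x), ] - x[1, ]
  if (sum(axis * span) < 0) axis <- -axis
  proj <- xc %*% axis
  structure(list(axis = as.numeric(axis), centroid = ctr,
                 length = max(proj) - min(proj), n_atoms = nrow(x)),
            class = "helix_segment")
}

#' Angle between two helix axes
#'
#' Uses the signed N-to-C axes, so parallel helices give 0 degrees and
#' antiparallel 180.
#'
#' @param h1,h2 `helix_segment` objects (or bare length-3 axis vectors).
#' @return Angle in degrees, `[0, 180]`.
#' @export
interhelix_angle <- function(h1, h2) {
  a1 <- if (inherits(h1, "helix_segment")) h1$axis else as.numeric(h1)
  a2 <- if (inherits(h2, "helix_segment")) h2$axis else as.numeric(h2)
  a1 <- a1 / sqrt(sum(a1^2)); a2 <- a2 / sqrt(sum(a2^2))
  acos(max(-1, min(1, sum(a1 * a2)))) * 180 / pi
}
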