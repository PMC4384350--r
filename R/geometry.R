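# Coordinate mathematics for the branch-and-prune embedding: recursion
# matrices, sphere intersection, interval discretization, torsion/distance
# conversion, peptide-plane oxygen and C-beta placement, dihedrals, RMSD.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking along the `p2 -> p3` axis, the angle is
#' positive when the far bond rotates clockwise from the near bond. A
#' planar cis arrangement gives 0, planar trans gives pi. Mirroring all
#' points through any plane flips the sign.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return signed angle in radians, in `(-pi, pi]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- v_cross(b1, b2)
  n2 <- v_cross(b2, b3)
  if (v_norm(n1) < 1e-10 || v_norm(n2) < 1e-10) {
    stop("degenerate geometry: collinear triple in dihedral", call. = FALSE)
  }
  m1 <- v_cross(n1, b2 / v_norm(b2))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Planar angle at the middle point
#'
#' @param p1,p2,p3 coordinates; the angle is measured at `p2`.
#' @return angle in radians, in `[0, pi]`.
#' @export
point_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(clamp_cos(sum(v1 * v2) / (v_norm(v1) * v_norm(v2)), what = "angle"))
}

#' Intersection of three spheres
#'
#' Computes the (generically two) points at distances `d1`, `d2`, `d3`
#' from centers `p1`, `p2`, `p3`. The two roots are mirror images through
#' the plane of the centers; they are returned in a deterministic order
#' (positive side of the center-plane normal `(p2-p1) x (p3-p1)` first).
#'
#' @param p1,p2,p3 sphere centers (must not be collinear).
#' @param d1,d2,d3 radii (Angstrom, non-negative).
#' @param tol numeric slack on the discriminant before the intersection is
#'   declared empty.
#' @return list of 0, 1 or 2 coordinate vectors.
#' @export
trilaterate <- function(p1, p2, p3, d1, d2, d3, tol = 1e-9) {
  if (any(c(d1, d2, d3) < 0)) stop("negative radius", call. = FALSE)
  ex <- p2 - p1
  d <- v_norm(ex)
  if (d < 1e-10) stop("degenerate geometry: coincident centers", call. = FALSE)
  ex <- ex / d
  i <- sum(ex * (p3 - p1))
  eyv <- p3 - p1 - i * ex
  j <- v_norm(eyv)
  if (j < 1e-10) stop("degenerate geometry: collinear centers", call. = FALSE)
  ey <- eyv / j
  ez <- v_cross(ex, ey)
  x <- (d1^2 - d2^2 + d^2) / (2 * d)
  y <- (d1^2 - d3^2 + i^2 + j^2 - 2 * i * x) / (2 * j)
  z2 <- d1^2 - x^2 - y^2
  if (z2 < -tol) return(list())
  z <- sqrt(max(z2, 0))
  base <- p1 + x * ex + y * ey
  if (z < 1e-9) return(list(base))
  list(base + z * ez, base - z * ez)
}

#' Uniform discretization of an interval distance
#'
#' Samples `b` values `l + (t - 1) (u - l) / b`, `t = 1, ..., b`: the lower
#' endpoint is always included and, for a proper interval, the upper
#' endpoint is not. Setting `include_upper = TRUE` switches to `b` evenly
#' spaced values spanning both endpoints.
#'
#' @param lower,upper interval bounds (Angstrom), `lower <= upper`.
#' @param b number of samples, integer `>= 1`.
#' @param include_upper logical; sample the closed interval instead.
#' @return ascending numeric vector; a degenerate interval yields a single
#'   value whatever `b`.
#' @export
discretize_interval <- function(lower, upper, b, include_upper = FALSE) {
  if (!is_count(b)) stop("'b' must be a positive integer", call. = FALSE)
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    stop("invalid interval", call. = FALSE)
  }
  if (upper - lower < 1e-12) return(lower)
  if (include_upper && b > 1L) {
    lower + (seq_len(b) - 1) * (upper - lower) / (b - 1)
  } else {
    lower + (seq_len(b) - 1) * (upper - lower) / b
  }
}

#' Distance across a torsion angle
#'
#' For a quadruple of points `i, j, k, l` with known distances
#' `d(i,j), d(j,k), d(k,l), d(i,k), d(l,j)`, the remaining distance
#' `d(i,l)` is a function of the torsion angle `xi` around the `j-k` axis
#' alone:
#' `d_il^2 = d_ij^2 + d_lj^2 - 2 (cos(xi) sqrt(e f) + b c) d_ij d_lj`
#' with `b = (d_lj^2 + d_jk^2 - d_lk^2) / (2 d_lj d_jk)`,
#' `c = (d_ij^2 + d_jk^2 - d_ik^2) / (2 d_ij d_jk)`, `e = 1 - b^2`,
#' `f = 1 - c^2`. It is even in `xi` and increasing on `[0, pi]`.
#'
#' @param xi torsion angle (radians).
#' @param d_ij,d_jk,d_kl,d_ik,d_lj known distances (Angstrom).
#' @return `d(i, l)` in Angstrom.
#' @export
torsion_distance <- function(xi, d_ij, d_jk, d_kl, d_ik, d_lj) {
  b <- (d_lj^2 + d_jk^2 - d_kl^2) / (2 * d_lj * d_jk)
  cc <- (d_ij^2 + d_jk^2 - d_ik^2) / (2 * d_ij * d_jk)
  b <- clamp_cos(b, what = "b")
  cc <- clamp_cos(cc, what = "c")
  e <- 1 - b^2
  f <- 1 - cc^2
  d2 <- d_ij^2 + d_lj^2 - 2 * (cos(xi) * sqrt(e * f) + b * cc) * d_ij * d_lj
  sqrt(pmax(d2, 0))
}

# inverse of torsion_distance: |cos xi| may exceed 1, signalling an empty
# sphere intersection; callers decide. Returns NA when the torsion is
# undefined because the quadruple is degenerate (sin of a flank angle ~ 0).
torsion_cosine <- function(d_il, d_ij, d_jk, d_kl, d_ik, d_lj) {
  b <- (d_lj^2 + d_jk^2 - d_kl^2) / (2 * d_lj * d_jk)
  cc <- (d_ij^2 + d_jk^2 - d_ik^2) / (2 * d_ij * d_jk)
  b <- clamp_cos(b, what = "b")
  cc <- clamp_cos(cc, what = "c")
  e <- 1 - b^2
  f <- 1 - cc^2
  if (e * f < 1e-20) return(NA_real_)
  ((d_ij^2 + d_lj^2 - d_il^2) / (2 * d_ij * d_lj) - b * cc) / sqrt(e * f)
}

#' Distance bounds implied by a torsion-angle domain
#'
#' Envelope of [torsion_distance()] over an [angle_domain()]. The distance
#' depends on the torsion only through its cosine, so extrema occur at
#' sub-interval endpoints or where the domain crosses 0 or +/- pi.
#'
#' @param dom an [angle_domain()] for the torsion.
#' @param d_ij,d_jk,d_kl,d_ik,d_lj known distances as in
#'   [torsion_distance()].
#' @return list with `lower`, `upper` (Angstrom) and `signs`, a named
#'   logical vector saying whether the domain admits negative and/or
#'   positive torsions (used as an additional pruning criterion).
#' @export
torsion_domain_bounds <- function(dom, d_ij, d_jk, d_kl, d_ik, d_lj) {
  stopifnot(inherits(dom, "angle_domain"))
  cr <- domain_cos_range(dom)
  # distance decreases as cos(xi) increases
  lo <- torsion_distance(acos(clamp_cos(cr[2L])), d_ij, d_jk, d_kl, d_ik, d_lj)
  hi <- torsion_distance(acos(clamp_cos(cr[1L])), d_ij, d_jk, d_kl, d_ik, d_lj)
  list(lower = lo, upper = hi, signs = domain_signs(dom))
}

#' Initial placement of the first three vertices
#'
#' Places vertex 1 at the origin, vertex 2 on the negative x axis at
#' distance `d21`, and vertex 3 in the `z = 0` plane with
#' `||x3 - x2|| = d32` and angle `theta3` at vertex 2, via the initial
#' recursion matrices `B1, B2, B3`. Also returns the accumulated transform
#' `Q3 = B1 B2 B3` that seeds the recursive embedding.
#'
#' @param d21,d32 distances (Angstrom, positive).
#' @param theta3 planar angle at vertex 2 (radians, in `(0, pi)`).
#' @return list with `x1`, `x2`, `x3` (coordinates) and `Q3` (4x4).
#' @export
initial_placement <- function(d21, d32, theta3) {
  if (d21 <= 0 || d32 <= 0) stop("invalid geometry: non-positive distance", call. = FALSE)
  if (theta3 <= 0 || theta3 >= pi) stop("invalid geometry: degenerate angle", call. = FALSE)
  B1 <- diag(4)
  B2 <- matrix(c(-1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, -1, 0,
                 -d21, 0, 0, 1), 4, 4)
  # the (2,4) entry carries sin(theta3): the distance contract
  # ||x3 - x2|| = d32 is the authoritative requirement
  B3 <- matrix(c(-cos(theta3), sin(theta3), 0, 0,
                 -sin(theta3), -cos(theta3), 0, 0,
                 0, 0, 1, 0,
                 -d32 * cos(theta3), d32 * sin(theta3), 0, 1), 4, 4)
  Q3 <- B1 %*% B2 %*% B3
  list(x1 = c(0, 0, 0), x2 = c(-d21, 0, 0), x3 = Q3[1:3, 4L], Q3 = Q3)
}

#' Branching geometry for one vertex
#'
#' Bundle of the quantities defining the two candidate embeddings of a
#' vertex `k` from its three immediate predecessors: the planar angle
#' `theta2` at `k-1`, the torsion `omega3` over `{k, k-1, k-2, k-3}`
#' (determined up to sign by the distance `d(k, k-3)`), the branch sign
#' `sigma`, and the distance `d(k, k-1)`.
#'
#' @param theta2 angle in radians, in `(0, pi)`.
#' @param omega3 torsion in radians.
#' @param sigma branch sign, `+1` or `-1`.
#' @param d distance `d(k, k-1)` in Angstrom.
#' @return object of class `branch_geometry`.
#' @export
branch_geometry <- function(theta2, omega3, sigma = 1, d = 1) {
  if (!sigma %in% c(-1, 1)) stop("sigma must be +1 or -1", call. = FALSE)
  if (theta2 < 0 || theta2 > pi) stop("theta2 outside [0, pi]", call. = FALSE)
  structure(list(theta2 = theta2, omega3 = omega3, sigma = sigma, d = d),
            class = "branch_geometry")
}

#' Recursion matrix for one vertex
#'
#' The 4x4 homogeneous transform `B_k(d, sigma)`; its fourth column is
#' `(-d cos(theta2), sigma d sin(theta2) cos(omega3),
#'   sigma d sin(theta2) sin(omega3), 1)`.
#' Note that only `sigma = +1` combined with a signed `omega3` realizes
#' the two sphere-intersection roots as mirror images through the
#' predecessor plane; the search engine therefore branches over the sign
#' of `omega3` (see the methods vignette).
#'
#' @param g a [branch_geometry()].
#' @return 4x4 numeric matrix; the 3x3 block is orthonormal.
#' @export
branch_matrix <- function(g) {
  stopifnot(inherits(g, "branch_geometry"))
  th <- g$theta2; om <- g$omega3; s <- g$sigma; d <- g$d
  matrix(c(-cos(th), s * sin(th) * cos(om), s * sin(th) * sin(om), 0,
           -s * sin(th), -cos(th) * cos(om), -cos(th) * sin(om), 0,
           0, -sin(om), cos(om), 0,
           -d * cos(th), s * d * sin(th) * cos(om), s * d * sin(th) * sin(om), 1),
         4, 4)
}

#' Apply the embedding recursion for one vertex
#'
#' Computes the candidate position of vertex `k` as the fourth column of
#' `Q_{k-1} B_k`, and optionally the full accumulated transform `Q_k`.
#' In the search engine the full product is formed lazily, only once the
#' candidate has survived all pruning devices.
#'
#' @param Q_prev accumulated 4x4 transform `Q_{k-1}`.
#' @param B 4x4 recursion matrix `B_k`.
#' @param position_only logical; skip the full matrix product.
#' @return list with `position` (length-3) and `Q` (4x4 or `NULL`).
#' @export
place_vertex <- function(Q_prev, B, position_only = FALSE) {
  pos <- (Q_prev %*% B[, 4L])[1:3]
  list(position = pos, Q = if (position_only) NULL else Q_prev %*% B)
}

#' Peptide-plane carbonyl oxygen placement
#'
#' Solves for the carbonyl oxygen O of residue `i-1` from the three atoms
#' C(i-1), N(i), H(i) of the same peptide plane: three sphere equations
#' plus the coplanarity condition reduce to a 3x3 linear system (two
#' sphere differences and the plane equation). The trans/cis choice of the
#' peptide torsion omega is encoded in the input distances.
#'
#' @param vC,vN,vH coordinates of the plane atoms (non-collinear).
#' @param dk1,dk2,dk3 distances O-C, O-N, O-H (Angstrom).
#' @param plane_normal optional normal of the peptide plane; computed from
#'   the three atoms when `NULL`.
#' @param check logical; verify the sphere residuals.
#' @return coordinate vector of O.
#' @export
place_peptide_oxygen <- function(vC, vN, vH, dk1, dk2, dk3,
                                 plane_normal = NULL, check = TRUE) {
  n <- plane_normal %||% v_cross(vN - vC, vH - vC)
  if (v_norm(n) < 1e-8) stop("degenerate geometry: collinear plane atoms", call. = FALSE)
  A <- rbind(2 * (vN - vC), 2 * (vH - vC), n)
  rhs <- c(dk1^2 - dk2^2 - sum(vC^2) + sum(vN^2),
           dk1^2 - dk3^2 - sum(vC^2) + sum(vH^2),
           sum(n * vC))
  if (rcond(A) < 1e-10) stop("degenerate geometry: singular peptide-plane system", call. = FALSE)
  k <- as.numeric(solve(A, rhs))
  if (check) {
    res <- abs(c(v_norm(k - vC) - dk1, v_norm(k - vN) - dk2, v_norm(k - vH) - dk3))
    if (max(res) > 1e-6) {
      stop(sprintf("inconsistent oxygen distances (max residual %.2e A)", max(res)),
           call. = FALSE)
    }
  }
  k
}

#' C-beta placement from four exact distances
#'
#' Solves for the C-beta position from the four atoms CA, HA, N, C of the
#' same residue and its exact distances to them. The five atoms are not
#' coplanar, so the 3x3 linear system of sphere differences has a unique
#' solution.
#'
#' @param vCA,vHA,vN,vC anchor coordinates.
#' @param dk1,dk2,dk3,dk4 distances CB-CA, CB-HA, CB-N, CB-C (Angstrom).
#' @param check logical; verify the four sphere residuals.
#' @return coordinate vector of CB.
#' @export
place_cbeta <- function(vCA, vHA, vN, vC, dk1, dk2, dk3, dk4, check = TRUE) {
  vol <- abs(sum(v_cross(vHA - vCA, vN - vCA) * (vC - vCA)))
  if (vol < 1e-6) stop("degenerate geometry: coplanar C-beta anchors", call. = FALSE)
  A <- rbind(2 * (vHA - vCA), 2 * (vN - vCA), 2 * (vC - vCA))
  rhs <- c(dk1^2 - dk2^2 - sum(vCA^2) + sum(vHA^2),
           dk1^2 - dk3^2 - sum(vCA^2) + sum(vN^2),
           dk1^2 - dk4^2 - sum(vCA^2) + sum(vC^2))
  if (rcond(A) < 1e-10) stop("degenerate geometry: singular C-beta system", call. = FALSE)
  k <- as.numeric(solve(A, rhs))
  if (check) {
    res <- abs(c(v_norm(k - vCA) - dk1, v_norm(k - vHA) - dk2,
                 v_norm(k - vN) - dk3, v_norm(k - vC) - dk4))
    if (max(res) > 1e-6) {
      stop(sprintf("inconsistent C-beta distances (max residual %.2e A)", max(res)),
           call. = FALSE)
    }
  }
  k
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Minimal least-squares root-mean-square deviation between two coordinate
#' sets over all rigid rotations and translations, computed by singular
#' value decomposition with the proper-rotation (determinant) correction:
#' reflections are not allowed, so a mirror image generally has non-zero
#' RMSD.
#'
#' @param A,B n x 3 coordinate matrices with matching rows, `n >= 3`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L || nrow(A) < 3L) {
    stop("coordinate sets must be matching n x 3 matrices with n >= 3", call. = FALSE)
  }
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Bc, Ac))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((Ac - Bc %*% R)^2) / nrow(A))
}

# mirror a coordinate matrix through the z = 0 plane (global reflection)
mirror_coords <- function(X) {
  X[, 3L] <- -X[, 3L]
  X
}
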