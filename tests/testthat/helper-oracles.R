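# Independent oracles used against the implementation. These deliberately
# avoid the code paths they check: exhaustive sign-vector enumeration via
# sphere intersection for the tree search, grid scans for torsion
# envelopes, numeric minimization for superposition and the oxygen solve,
# and igraph shortest paths for the bound refinement.

# exhaustive BP oracle for exact abstract instances: enumerate all
# 2^(n-3) sign choices of the trilateration roots, filter by the pruning
# edges. Returns the list of coordinate matrices (same initial frame as
# the engine, so coordinates are directly comparable).
bp_enumerate_oracle <- function(instance, tol = 1e-6) {
  ord <- instance$order
  n <- nrow(ord)
  stopifnot(all(vapply(instance$d3[4:n], length, 0L) == 1L), !any(ord$dup))
  d21 <- instance$d1[2L]; d32 <- instance$d1[3L]; d31 <- instance$d2[3L]
  th3 <- acos((d21^2 + d32^2 - d31^2) / (2 * d21 * d32))
  ini <- initial_placement(d21, d32, th3)
  sols <- list()
  ep <- instance$ep
  ia <- match(ep$a, ord$key); ib <- match(ep$b, ord$key)
  recur <- function(X, v) {
    if (v > n) {
      ok <- TRUE
      if (nrow(ep)) {
        d <- sqrt(rowSums((X[ia, , drop = FALSE] - X[ib, , drop = FALSE])^2))
        ok <- all(d >= ep$lower - tol & d <= ep$upper + tol)
      }
      if (ok) sols[[length(sols) + 1L]] <<- X
      return(invisible(NULL))
    }
    roots <- trilaterate(X[v - 1L, ], X[v - 2L, ], X[v - 3L, ],
                         instance$d1[v], instance$d2[v], instance$d3[[v]][1L])
    for (r in roots) recur(rbind(X, r), v + 1L)
    invisible(NULL)
  }
  recur(rbind(ini$x1, ini$x2, ini$x3), 4L)
  sols
}

# random non-degenerate quadruple of points with its six distances
random_quadruple <- function() {
  repeat {
    P <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    ok <- TRUE
    for (tri in list(c(1, 2, 3), c(2, 3, 4))) {
      v1 <- P[tri[1], ] - P[tri[2], ]; v2 <- P[tri[3], ] - P[tri[2], ]
      s <- sqrt(sum((v1 / sqrt(sum(v1^2)) + v2 / sqrt(sum(v2^2)))^2))
      if (s < 0.2 || s > 1.8) ok <- FALSE
    }
    if (ok) return(P)
  }
}

pdist <- function(p, q) sqrt(sum((p - q)^2))

# brute-force RMSD minimization over rotations (Euler angles + centering)
rmsd_bruteforce <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rotmat <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(sum((Ac - Bc %*% rotmat(a))^2) / nrow(A))
  best <- Inf
  for (s in 1:20) {
    st <- stats::runif(3, -pi, pi)
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# fixture helix with slightly varied torsions (soundness test surface)
varied_fixture <- function(n, phi, psi, w = 0) {
  spec <- fixture_spec(n_residues = n, phi = phi, psi = psi, w = w)
  conf <- build_ideal_helix(spec)
  list(spec = spec, conf = conf, inst = derive_instance(conf, spec))
}

expect_power_of_two_or_zero <- function(x) {
  testthat::expect_true(x == 0 || bitwAnd(x, x - 1L) == 0,
                        label = sprintf("solution count %d is 0 or a power of two", x))
}

# minimum mirror-aware backbone RMSD of stored solutions to a reference
best_backbone_rmsd <- function(res, conf, atoms) {
  bb <- atoms$key[atoms$name %in% c("N", "CA", "C")]
  vapply(res$solutions, function(s) {
    min(kabsch_rmsd(s$xyz[bb, , drop = FALSE], conf$xyz[bb, , drop = FALSE]),
        kabsch_rmsd(ibpenum:::mirror_coords(s$xyz[bb, , drop = FALSE]),
                    conf$xyz[bb, , drop = FALSE]))
  }, 0)
}
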