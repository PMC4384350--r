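# Coordinate mathematics: recursion matrices, sphere intersection,
# discretization, torsion/distance conversion, placements, RMSD.

test_that("initial placement satisfies its distance and angle contract", {
  expect_error(initial_placement(-1, 1, 1), "non-positive")
  expect_error(initial_placement(1, 1, pi), "degenerate")
  set.seed(1)
  for (r in 1:25) {
    d21 <- runif(1, 0.8, 2); d32 <- runif(1, 0.8, 2); th3 <- runif(1, 0.3, 2.8)
    ini <- initial_placement(d21, d32, th3)
    expect_equal(ini$x1, c(0, 0, 0))
    expect_equal(ini$x2, c(-d21, 0, 0))
    expect_equal(pdist(ini$x2, ini$x1), d21, tolerance = 1e-12)
    expect_equal(pdist(ini$x3, ini$x2), d32, tolerance = 1e-12)
    expect_equal(point_angle(ini$x1, ini$x2, ini$x3), th3, tolerance = 1e-12)
    expect_equal(ini$x3[3L], 0)                     # z = 0 plane
    expect_equal(ini$Q3[1:3, 4L], ini$x3)
  }
})

test_that("branch matrix has the printed fourth column and orthonormal block", {
  g <- branch_geometry(pi / 2, 0, 1, d = 1)
  expect_equal(branch_matrix(g)[, 4L], c(0, 1, 0, 1))
  set.seed(2)
  for (r in 1:50) {
    th <- runif(1, 0.1, 3); om <- runif(1, -pi, pi); d <- runif(1, 0.5, 2)
    s <- sample(c(-1, 1), 1L)
    B <- branch_matrix(branch_geometry(th, om, s, d))
    R <- B[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_equal(B[4L, ], c(0, 0, 0, 1))
    # both sigma branches preserve the distance to the predecessor
    expect_equal(sqrt(sum(B[1:3, 4L]^2)), d, tolerance = 1e-12)
  }
})

test_that("chained placement reproduces the trilateration roots", {
  # the sigma = +1 matrix with signed omega3 realizes both sphere roots;
  # checked against the independent three-sphere intersection for many
  # random geometries
  set.seed(3)
  for (r in 1:200) {
    d21 <- runif(1, 1, 2); d32 <- runif(1, 1, 2); th3 <- runif(1, 0.5, 2.6)
    ini <- initial_placement(d21, d32, th3)
    th2 <- runif(1, 0.4, 2.7); om <- runif(1, 0.1, pi - 0.1); d <- runif(1, 1, 2)
    pp <- place_vertex(ini$Q3, branch_matrix(branch_geometry(th2, om, 1, d)))
    pm <- place_vertex(ini$Q3, branch_matrix(branch_geometry(th2, -om, 1, d)),
                       position_only = TRUE)
    expect_null(pm$Q)
    r1 <- pdist(pp$position, ini$x3)
    r2 <- pdist(pp$position, ini$x2)
    r3 <- pdist(pp$position, ini$x1)
    roots <- trilaterate(ini$x3, ini$x2, ini$x1, r1, r2, r3)
    expect_length(roots, 2L)
    d_p <- min(pdist(pp$position, roots[[1L]]), pdist(pp$position, roots[[2L]]))
    d_m <- min(pdist(pm$position, roots[[1L]]), pdist(pm$position, roots[[2L]]))
    expect_lt(d_p, 1e-6)
    expect_lt(d_m, 1e-6)
    # the two branches are the two distinct roots
    expect_gt(pdist(pp$position, pm$position), 1e-6)
    # full transform column equals the position
    expect_equal(pp$Q[1:3, 4L], pp$position)
  }
})

test_that("matrix products associate in the embedding recursion", {
  ini <- initial_placement(1.2, 1.4, 1.9)
  B4 <- branch_matrix(branch_geometry(1.8, 0.7, 1, 1.5))
  B5 <- branch_matrix(branch_geometry(1.2, -2.1, 1, 1.3))
  o <- c(0, 0, 0, 1)
  left <- (ini$Q3 %*% B4) %*% (B5 %*% o)
  right <- ini$Q3 %*% (B4 %*% (B5 %*% o))
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("trilateration handles the degenerate and empty cases", {
  roots <- trilaterate(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 1, sqrt(2), sqrt(2))
  expect_length(roots, 2L)
  expect_equal(roots[[1L]], c(0, 0, 1))
  expect_equal(roots[[2L]], c(0, 0, -1))
  # zero first radius pins the point at the first center
  one <- trilaterate(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 0, 1, 1)
  expect_length(one, 1L)
  expect_equal(one[[1L]], c(0, 0, 0))
  # inconsistent radii
  expect_length(trilaterate(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 0.1, 0.1, 1), 0L)
  expect_error(trilaterate(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1, 1, 1),
               "collinear")
})

test_that("interval discretization follows the sampling rule", {
  expect_equal(discretize_interval(0, 5, 5L), c(0, 1, 2, 3, 4))
  expect_equal(discretize_interval(2, 2, 7L), 2)
  expect_equal(discretize_interval(1.5, 3.5, 1L), 1.5)
  expect_equal(discretize_interval(0, 1, 4L, include_upper = TRUE),
               c(0, 1 / 3, 2 / 3, 1))
  expect_error(discretize_interval(3, 2, 4L), "invalid interval")
  expect_error(discretize_interval(0, 1, 0L), "positive integer")
  set.seed(4)
  for (r in 1:20) {
    l <- runif(1, 0, 3); u <- l + runif(1, 0, 2); b <- sample(1:8, 1L)
    v <- discretize_interval(l, u, b)
    expect_length(v, b)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= l - 1e-12 & v <= u + 1e-12))
    expect_equal(v[1L], l)
    if (u > l && b > 1L) expect_lt(max(v), u)
  }
})

test_that("torsion-to-distance conversion matches coordinate geometry", {
  set.seed(5)
  for (r in 1:200) {
    P <- random_quadruple()
    xi <- dihedral_angle(P[1, ], P[2, ], P[3, ], P[4, ])
    d <- torsion_distance(xi,
                          d_ij = pdist(P[1, ], P[2, ]),
                          d_jk = pdist(P[2, ], P[3, ]),
                          d_kl = pdist(P[3, ], P[4, ]),
                          d_ik = pdist(P[1, ], P[3, ]),
                          d_lj = pdist(P[4, ], P[2, ]))
    expect_equal(d, pdist(P[1, ], P[4, ]), tolerance = 1e-8)
  }
  # right-angle reduction: b = c = 0 gives the plain law of cosines
  for (xi in seq(0, pi, length.out = 7)) {
    expect_equal(torsion_distance(xi, 1, 1, sqrt(2), sqrt(2), 1),
                 sqrt(2 - 2 * cos(xi)), tolerance = 1e-12)
  }
  # monotone in |xi|: d(0) <= d(xi) <= d(pi)
  P <- random_quadruple()
  args <- list(d_ij = pdist(P[1, ], P[2, ]), d_jk = pdist(P[2, ], P[3, ]),
               d_kl = pdist(P[3, ], P[4, ]), d_ik = pdist(P[1, ], P[3, ]),
               d_lj = pdist(P[4, ], P[2, ]))
  dg <- vapply(seq(-pi, pi, length.out = 41),
               function(x) do.call(torsion_distance, c(list(x), args)), 0)
  expect_lte(do.call(torsion_distance, c(list(0), args)) - 1e-12, min(dg))
  expect_gte(do.call(torsion_distance, c(list(pi), args)) + 1e-12, max(dg))
  # unrealizable flank triangles raise an infeasibility error
  expect_error(torsion_distance(1, 1, 1, 3, 1, 1), "infeasible")
})

test_that("torsion-domain envelope matches a fine grid scan", {
  set.seed(6)
  for (r in 1:20) {
    P <- random_quadruple()
    args <- list(d_ij = pdist(P[1, ], P[2, ]), d_jk = pdist(P[2, ], P[3, ]),
                 d_kl = pdist(P[3, ], P[4, ]), d_ik = pdist(P[1, ], P[3, ]),
                 d_lj = pdist(P[4, ], P[2, ]))
    dom <- angle_domain(rbind(c(-170, -60), c(20, 110)), degrees = TRUE)
    env <- do.call(torsion_domain_bounds, c(list(dom), args))
    grid <- c(seq(-170 * pi / 180, -60 * pi / 180, length.out = 600),
              seq(20 * pi / 180, 110 * pi / 180, length.out = 600))
    dv <- vapply(grid, function(x) do.call(torsion_distance, c(list(x), args)), 0)
    expect_equal(env$lower, min(dv), tolerance = 1e-6)
    expect_equal(env$upper, max(dv), tolerance = 1e-6)
    expect_true(env$signs[["neg"]] && env$signs[["pos"]])
    # singleton domain gives a degenerate interval
    env1 <- do.call(torsion_domain_bounds,
                    c(list(angle_domain(singletons = 0.7)), args))
    expect_equal(env1$lower, env1$upper)
    expect_equal(env1$lower, do.call(torsion_distance, c(list(0.7), args)))
    # the full half-circle [0, pi] spans d(0)..d(pi)
    env2 <- do.call(torsion_domain_bounds,
                    c(list(angle_domain(c(0, pi))), args))
    expect_equal(env2$lower, do.call(torsion_distance, c(list(0), args)))
    expect_equal(env2$upper, do.call(torsion_distance, c(list(pi), args)))
  }
})

test_that("dihedral angle follows the sign convention", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)      # cis
  expect_equal(dihedral_angle(p1, p2, p3, c(-1, 1, 0)), pi)    # trans
  set.seed(7)
  for (r in 1:20) {
    P <- random_quadruple()
    xi <- dihedral_angle(P[1, ], P[2, ], P[3, ], P[4, ])
    M <- P; M[, 3L] <- -M[, 3L]                                # mirror
    xm <- dihedral_angle(M[1, ], M[2, ], M[3, ], M[4, ])
    expect_equal(sin(xm), -sin(xi), tolerance = 1e-9)
    expect_equal(cos(xm), cos(xi), tolerance = 1e-9)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("peptide oxygen placement solves the plane-constrained spheres", {
  geom <- covalent_geometry()
  dk <- ibpenum:::oxygen_distances(geom)
  conf <- build_ideal_helix(fixture_spec(n_residues = 5))
  X <- conf$xyz
  vC <- X["2:C", ]; vN <- X["3:N", ]; vH <- X["3:H", ]
  o <- place_peptide_oxygen(vC, vN, vH, dk[[1L]], dk[[2L]], dk[[3L]])
  expect_lt(abs(pdist(o, vC) - dk[[1L]]), 1e-6)
  expect_lt(abs(pdist(o, vN) - dk[[2L]]), 1e-6)
  expect_lt(abs(pdist(o, vH) - dk[[3L]]), 1e-6)
  n <- ibpenum:::v_cross(vN - vC, vH - vC)
  expect_lt(abs(sum(n * (vC - o))) / sqrt(sum(n^2)), 1e-8)     # coplanar
  # nonlinear least-squares oracle on the full system
  obj <- function(k) {
    (pdist(k, vC) - dk[[1L]])^2 + (pdist(k, vN) - dk[[2L]])^2 +
      (pdist(k, vH) - dk[[3L]])^2 + (sum(n * (vC - k)) / sqrt(sum(n^2)))^2
  }
  fit <- optim(o + rnorm(3, sd = 0.05), obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 5000))
  expect_lt(pdist(fit$par, o), 1e-5)
  expect_error(place_peptide_oxygen(vC, vC + c(1, 0, 0), vC + c(2, 0, 0),
                                    dk[[1L]], dk[[2L]], dk[[3L]]),
               "degenerate|singular")
})

test_that("C-beta placement is exact and rejects coplanar anchors", {
  geom <- covalent_geometry()
  dk <- ibpenum:::cbeta_distances(geom)
  conf <- build_ideal_helix(fixture_spec(n_residues = 4))
  X <- conf$xyz
  vCA <- X["2:CA", ]; vHA <- X["2:HA", ]; vN <- X["2:N", ]; vC <- X["2:C", ]
  cb <- place_cbeta(vCA, vHA, vN, vC, dk[[1L]], dk[[2L]], dk[[3L]], dk[[4L]])
  expect_lt(abs(pdist(cb, vCA) - dk[[1L]]), 1e-6)
  expect_lt(abs(pdist(cb, vHA) - dk[[2L]]), 1e-6)
  expect_lt(abs(pdist(cb, vN) - dk[[3L]]), 1e-6)
  expect_lt(abs(pdist(cb, vC) - dk[[4L]]), 1e-6)
  expect_equal(cb, X["2:CB", ], tolerance = 1e-6)
  # resulting geometry passes the L-form chirality rule
  expect_true(chi_check(vC, vN, cb, vHA)$accepted)
  expect_error(place_cbeta(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                           1, 1, 1, 1), "coplanar")
})

test_that("superposition RMSD matches invariances and a brute-force oracle", {
  set.seed(8)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(A, A), 0)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  B <- A %*% R + matrix(rep(c(3, -1, 2), each = 10), 10)
  expect_lt(kabsch_rmsd(A, B), 1e-9)
  expect_equal(kabsch_rmsd(A, B), kabsch_rmsd(B, A), tolerance = 1e-9)
  # three-atom case against numeric minimization over rotations
  A3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  B3 <- A3; B3[3L, ] <- B3[3L, ] + c(0, 0, 1)
  expect_equal(kabsch_rmsd(A3, B3), rmsd_bruteforce(A3, B3), tolerance = 1e-4)
  expect_error(kabsch_rmsd(A3, matrix(0, 4, 3)), "matching")
})
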