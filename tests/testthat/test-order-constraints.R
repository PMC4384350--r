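# Atom order and instance construction: vertex counts, adjacency,
# covalent/steric/hydrogen-bond/torsion constraints, bound smoothing,
# instance partition invariants.

test_that("the repetition order has 7n+2 vertices with flagged duplicates", {
  for (n in c(1L, 2L, 5L, 15L, 24L, 51L)) {
    ord <- build_atom_order(n)
    expect_equal(nrow(ord), 7L * n + 2L)
    expect_true(all(ord$dup == (ord$rank > match(ord$key, ord$key))))
    expect_true(all(is.na(ord$dup_of[!ord$dup])))
    expect_true(all(ord$dup_of[ord$dup] < ord$rank[ord$dup]))
  }
  expect_error(build_atom_order(0), "positive integer")
})

test_that("every vertex beyond the third is tied to three predecessors", {
  # assembling an instance validates the adjacency contract: exact
  # {v,v-1}, {v,v-2} edges and a distance set on {v,v-3} for every v > 3
  inst <- build_protein_instance(6, helices = list(c(1, 6)))
  nr <- nrow(inst$order)
  expect_false(anyNA(inst$d1[2:nr]))
  expect_false(anyNA(inst$d2[3:nr]))
  expect_true(all(vapply(inst$d3[4:nr], length, 0L) >= 1L))
  # discretized levels carry b samples inside the declared interval
  bidx <- which(vapply(inst$d3, length, 0L) > 1L)
  expect_true(all(inst$kind[bidx] %in% c("phi", "psi")))
  for (v in bidx) {
    expect_length(inst$d3[[v]], inst$config$b)
    expect_true(all(inst$d3[[v]] >= inst$d3_lu[v, 1L] - 1e-12 &
                      inst$d3[[v]] <= inst$d3_lu[v, 2L] + 1e-12))
  }
})

test_that("covalent constraints cover bonds, angles and fixed 1-4 pairs", {
  geom <- covalent_geometry()
  atoms <- ibpenum:::atoms_table(parse_sequence(3))
  cc <- covalent_constraints(atoms, geom)
  expect_true(all(cc$lower == cc$upper))
  look <- function(a, b) {
    r <- cc[(cc$a == a & cc$b == b) | (cc$a == b & cc$b == a), ]
    expect_equal(nrow(r), 1L)
    r$lower
  }
  expect_equal(look("1:N", "1:H"), 1.01)
  # 1-3 law of cosines: N-CA-C with 1.458, 1.525 A and 111.2 degrees
  expect_equal(look("1:N", "1:C"),
               sqrt(1.458^2 + 1.525^2 - 2 * 1.458 * 1.525 * cos(111.2 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(round(look("1:N", "1:C"), 3), 2.462)
  # fixed 1-4 across the trans peptide plane exist
  expect_equal(nrow(cc[cc$a == "1:CA" & cc$b == "2:CA", ]), 1L)
  # free 1-4 pairs (phi/psi-dependent) are not claimed exact
  expect_equal(nrow(cc[(cc$a == "1:C" & cc$b == "2:C"), ]), 0L)
})

test_that("steric lower bounds follow the radius sums and yield to larger bounds", {
  atoms <- ibpenum:::atoms_table(parse_sequence(4))
  vt <- vdw_table(sigma = 0.85)
  vb <- vdw_bounds(atoms, vt)
  expect_true(all(is.infinite(vb$upper)))
  pick <- function(a, b) {
    r <- vb[(vb$a == a & vb$b == b) | (vb$a == b & vb$b == a), ]
    if (nrow(r)) r$lower else NA_real_
  }
  # C..N pair >= 3 bonds apart: 0.85 (1.7 + 1.5) = 2.72
  expect_equal(pick("1:C", "2:C"), 0.85 * (1.7 + 1.7))
  expect_equal(pick("1:CB", "2:N"), 0.85 * (1.7 + 1.5))
  expect_equal(pick("1:H", "2:H"), 0.85 * (1.0 + 1.0))
  # a pair already holding a larger lower bound is left alone
  existing <- data.frame(a = "1:H", b = "2:H", lower = 3.0, upper = 5.0,
                         source = "nmr")
  vb2 <- vdw_bounds(atoms, vt, existing = existing)
  expect_equal(nrow(vb2[vb2$a == "1:H" & vb2$b == "2:H", ]), 0L)
  expect_lt(nrow(vb2), nrow(vb))
  # bonded and 1-2-separated pairs are never bounded
  expect_equal(nrow(vb[vb$a == "1:N" & vb$b == "1:H", ]), 0L)
})

test_that("helix hydrogen-bond constraints enumerate (i-4, i) pairs", {
  h <- helix_definition(c(1, 15))
  hb <- helix_hbond_constraints(h, 15L)
  expect_equal(nrow(hb), 11L)
  expect_equal(hb$a[1L], "1:O")
  expect_equal(hb$b[1L], "5:H")
  expect_true(all(hb$lower == 1.9 & hb$upper == 3.0))
  expect_null(helix_hbond_constraints(helix_definition(c(2, 5)), 10L))
  # pairs must lie fully inside one range
  h2 <- helix_definition(list(c(1, 6), c(8, 12)))
  hb2 <- helix_hbond_constraints(h2, 12L)
  expect_equal(nrow(hb2), 2L + 1L)
})

test_that("torsion-derived 1-4 bounds contain the measured helix distances", {
  conf <- build_ideal_helix(fixture_spec(n_residues = 6))
  hd <- default_torsion_domains(helix = TRUE)
  tc <- torsion_constraints(rep(list(hd$phi), 6), rep(list(hd$psi), 6), 6L)
  X <- conf$xyz
  for (r in seq_len(nrow(tc))) {
    d <- pdist(X[tc$a[r], ], X[tc$b[r], ])
    expect_gte(d, tc$lower[r] - 1e-9)
    expect_lte(d, tc$upper[r] + 1e-9)
  }
  # singleton domains give exact 1-4 distances
  sing <- angle_domain(singletons = -57 * pi / 180)
  tc1 <- torsion_constraints(rep(list(sing), 6), vector("list", 6), 6L)
  expect_true(all(abs(tc1$lower - tc1$upper) < 1e-12))
  # widening the domain never shrinks the interval
  wide <- default_torsion_domains(helix = FALSE)
  tcw <- torsion_constraints(rep(list(wide$phi), 6), rep(list(wide$psi), 6), 6L)
  expect_true(all(tcw$lower <= tc$lower + 1e-12))
  expect_true(all(tcw$upper >= tc$upper - 1e-12))
})

test_that("shortest-path refinement tightens bounds and is idempotent", {
  U <- matrix(Inf, 3, 3)
  U[1, 2] <- U[2, 1] <- 1
  U[2, 3] <- U[3, 2] <- 1
  U[1, 3] <- U[3, 1] <- 5
  R <- floyd_warshall_refine(U)
  expect_equal(R[1, 3], 2)
  expect_true(all(R <= U + 1e-12))
  expect_equal(floyd_warshall_refine(R), R)
  # triangle inequality holds for every triple
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    expect_lte(R[i, k], R[i, j] + R[j, k] + 1e-12)
  }
  # against the independent all-pairs shortest-path oracle (igraph)
  set.seed(11)
  for (rep in 1:10) {
    m <- 12L
    W <- matrix(Inf, m, m)
    for (e in 1:30) {
      ij <- sample(m, 2L)
      w <- runif(1, 0.5, 4)
      W[ij[1L], ij[2L]] <- W[ij[2L], ij[1L]] <- min(W[ij[1L], ij[2L]], w)
    }
    R2 <- floyd_warshall_refine(W)
    A <- W; A[is.infinite(A)] <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    D <- igraph::distances(g, weights = igraph::E(g)$weight)
    expect_equal(unname(R2), unname(D), tolerance = 1e-9)
  }
})

test_that("assembled instances satisfy the edge-partition invariants", {
  # fully exact abstract instance: singleton distance sets, no pruning edges
  ri <- random_chain_instance(7, n_prune = 0, seed = 2)
  expect_true(all(vapply(ri$instance$d3[4:7], length, 0L) == 1L))
  expect_equal(nrow(ri$instance$ep), 0L)
  # a long-range pair lands among the pruning edges
  ri2 <- random_chain_instance(9, n_prune = 2, seed = 3)
  expect_true(all(ri2$instance$ep$source == "nmr"))
  expect_gte(nrow(ri2$instance$ep), 1L)
  # an interval {v, v-3} edge is pre-discretized into b samples
  ord <- ri$instance$order
  cs <- ri$instance$constraints
  mid <- cs$a == "v7" & cs$b == "v4"
  cs$upper[mid] <- cs$upper[mid] + 0.4
  inst <- assemble_instance(ord, cs, tolerance_config(b = 4))
  expect_length(inst$d3[[7L]], 4L)
  # missing third-predecessor edge is an infeasible-order error naming v
  cs2 <- ri$instance$constraints
  inst_err <- try(assemble_instance(ord, cs2[!(cs2$a == "v7" & cs2$b == "v4"), ],
                                    tolerance_config()), silent = TRUE)
  expect_true(inherits(inst_err, "try-error"))
  expect_match(attr(inst_err, "condition")$message, "7")
  # protein instance: E_P never overlaps the order edges
  pin <- build_protein_instance(5, helices = list(c(1, 5)))
  adj <- character(0)
  for (j in 1:3) {
    v <- (j + 1L):nrow(pin$order)
    adj <- c(adj, ibpenum:::pair_key(pin$order$key[v], pin$order$key[v - j]))
  }
  expect_false(any(ibpenum:::pair_key(pin$ep$a, pin$ep$b) %in% adj))
})

test_that("proline is rejected and glycine handled without a C-beta", {
  expect_error(parse_sequence("AAPA"), "proline", ignore.case = TRUE)
  inst <- build_protein_instance("AGA", helices = NULL)
  expect_false("2:CB" %in% inst$atoms$key)
  expect_true("1:CB" %in% inst$atoms$key)
  cb_aux <- Filter(function(a) a$type == "CB", inst$aux)
  expect_length(cb_aux, 2L)
})
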