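# Tree search: branching, duplicate re-embedding, completeness against an
# exhaustive oracle, counting properties, determinism, solution storage.

test_that("an exact unpruned chain enumerates the complete binary tree", {
  ri <- random_chain_instance(5, n_prune = 0, seed = 3)
  res <- ibp_search(ri$instance, max_saved = 100, rmsd_filter = NULL)
  expect_equal(res$saved, 4L)          # 2^(5-3) leaves
  expect_equal(res$leaves, 4L)
  # contradictory bounds prune everything
  cs <- ri$instance$constraints
  cs$lower[cs$a == "v5" & cs$b == "v2"] <- 9
  cs$upper[cs$a == "v5" & cs$b == "v2"] <- 9
  bad <- assemble_instance(ri$instance$order, cs, tolerance_config(eps_x = 1e-6, b = 1))
  res0 <- ibp_search(bad, max_saved = 100, rmsd_filter = NULL)
  expect_equal(res0$saved, 0L)
})

test_that("solutions coincide with the exhaustive sign-vector oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(6:8, 1L)
    ri <- random_chain_instance(n, n_prune = sample(0:2, 1L), seed = seed)
    res <- ibp_search(ri$instance, max_saved = 1000, rmsd_filter = NULL,
                      devices = "ddf")
    oracle <- bp_enumerate_oracle(ri$instance)
    expect_equal(res$saved, length(oracle))
    if (length(oracle)) {
      keys <- ri$instance$order$key
      got <- lapply(res$solutions, function(s) s$xyz[keys, ])
      matched <- vapply(oracle, function(O) {
        any(vapply(got, function(G) max(abs(G - O)) < 1e-6, TRUE))
      }, TRUE)
      expect_true(all(matched))
    }
  }
})

test_that("solution counts on pruned exact chains are zero or powers of two", {
  counts <- integer(0)
  for (seed in 1:20) {
    set.seed(seed)
    ri <- random_chain_instance(sample(6:9, 1L), n_prune = sample(1:3, 1L),
                                seed = 100 + seed)
    res <- ibp_search(ri$instance, max_saved = 2000, rmsd_filter = NULL)
    counts <- c(counts, res$saved)
    expect_power_of_two_or_zero(res$saved)
  }
  expect_gte(max(counts), 1L)   # the generating realization is always found
})

test_that("candidate generation is ordered and satisfies predecessor distances", {
  ri <- random_chain_instance(6, seed = 5)
  cs <- ri$instance$constraints
  on4 <- cs$a == "v4" & cs$b == "v1"
  cs$upper[on4] <- cs$upper[on4] + 0.5   # make {4,1} an interval edge
  inst <- assemble_instance(ri$instance$order, cs, tolerance_config(b = 5))
  expect_length(inst$d3[[4L]], 5L)
  d21 <- inst$d1[2L]; d32 <- inst$d1[3L]; d31 <- inst$d2[3L]
  ini <- initial_placement(d21, d32,
                           acos((d21^2 + d32^2 - d31^2) / (2 * d21 * d32)))
  cands <- branch_candidates(inst, 4L, ini$Q3)
  expect_lte(length(cands), 10L)         # at most 2 b
  expect_gte(length(cands), 2L)
  ss <- vapply(cands, `[[`, 0, "sample")
  expect_true(all(diff(ss) >= 0))        # samples ascending
  sg <- vapply(cands, `[[`, 0, "sigma")
  expect_true(all(sg[which(!duplicated(ss))] == 1))  # sigma = +1 first
  xs <- list(ini$x3, ini$x2, ini$x1)
  for (cc in cands) {
    expect_lt(abs(pdist(cc$position, xs[[1L]]) - inst$d1[4L]), 1e-6)
    expect_lt(abs(pdist(cc$position, xs[[2L]]) - inst$d2[4L]), 1e-6)
    expect_lt(abs(pdist(cc$position, xs[[3L]]) - cc$sample), 1e-6)
  }
  # radii inconsistent with the predecessor triangle give no candidates
  cs2 <- ri$instance$constraints
  cs2$lower[on4] <- 50; cs2$upper[on4] <- 50
  inst2 <- assemble_instance(ri$instance$order, cs2, tolerance_config(b = 1))
  expect_length(branch_candidates(inst2, 4L, ini$Q3), 0L)
})

test_that("duplicate vertices re-embed onto their original coordinates", {
  spec <- fixture_spec(n_residues = 5)
  conf <- build_ideal_helix(spec)
  inst <- derive_instance(conf, spec)
  res <- ibp_search(inst, max_saved = 1, rmsd_filter = NULL)
  expect_gte(res$saved, 1L)
  expect_equal(unname(res$prune_counts["dup_drift"]), 0)
  # direct contract: nearest branch matches the original to high precision
  d21 <- inst$d1[2L]; d32 <- inst$d1[3L]; d31 <- inst$d2[3L]
  ini <- initial_placement(d21, d32,
                           acos((d21^2 + d32^2 - d31^2) / (2 * d21 * d32)))
  orig <- conf$xyz["1:N", ]
  # align: vertex 4 is the repeated N(1); its original in the search frame
  # is the vertex-1 position (0, 0, 0)
  re <- reembed_duplicate(inst, 4L, ini$Q3, c(0, 0, 0))
  expect_true(re$accepted)
  expect_lt(re$drift, 1e-9)
  # a corrupted original farther than eps_dup is pruned as drift
  re2 <- reembed_duplicate(inst, 4L, ini$Q3, c(0.5, 0.5, 0.5))
  expect_false(re2$accepted)
})

test_that("tree-size bound and matrix-count bound hold on instrumented runs", {
  expect_equal(tree_size_bound(2, 1, 4), 19)
  expect_equal(tree_size_bound(3, 0, 4), 3 + 8)
  for (seed in 1:4) {
    set.seed(seed)
    ri <- random_chain_instance(7, n_prune = sample(0:2, 1L), seed = 200 + seed)
    res <- ibp_search(ri$instance, max_saved = 1000, rmsd_filter = NULL)
    width_bound <- 2^res$l * ri$instance$config$b^res$k
    expect_lte(max(res$widths), width_bound)
    expect_lte(res$leaves, width_bound)
    expect_lte(res$b_built, 2 * nrow(ri$instance$order) * ri$instance$config$b)
  }
  # a discretized protein instance obeys the same matrix bound
  spec <- fixture_spec(n_residues = 5, w = 0.3, config = tolerance_config(b = 3))
  inst <- derive_instance(build_ideal_helix(spec), spec)
  res <- ibp_search(inst, max_saved = 5)
  expect_lte(res$b_built, 2 * nrow(inst$order) * 3)
})

test_that("two identical runs produce byte-identical stored ensembles", {
  spec <- fixture_spec(n_residues = 6, w = 0.3)
  inst <- derive_instance(build_ideal_helix(spec), spec)
  r1 <- ibp_search(inst, max_saved = 10, rmsd_filter = NULL)
  r2 <- ibp_search(inst, max_saved = 10, rmsd_filter = NULL)
  expect_identical(lapply(r1$solutions, `[[`, "xyz"),
                   lapply(r2$solutions, `[[`, "xyz"))
  expect_identical(r1$prune_counts, r2$prune_counts)
  expect_identical(r1$nodes, r2$nodes)
})

test_that("the solution store filters by RMSD to the last stored conformation", {
  A <- matrix(rnorm(30), 10, 3, dimnames = list(paste0(1:10, ":CA"), NULL))
  far <- A; far[, 1L] <- far[, 1L] + c(rep(4, 5), rep(-4, 5))
  st <- solution_store(max_saved = 2L, rmsd_filter = 1.5)
  accept_solution(st, A)
  expect_equal(st$saved, 1L)            # first conformation always stored
  accept_solution(st, A)                # identical repeat: counted, not stored
  expect_equal(st$generated, 2L)
  expect_equal(st$saved, 1L)
  accept_solution(st, far)
  expect_equal(st$saved, 2L)
  expect_true(st$stopped)               # capacity reached stops the search
  accept_solution(st, A)
  expect_equal(st$saved, 2L)
})

test_that("finalized conformations satisfy the placement contracts", {
  spec <- fixture_spec(n_residues = 6)
  conf <- build_ideal_helix(spec)
  inst <- derive_instance(conf, spec)
  res <- ibp_search(inst, max_saved = 1, rmsd_filter = NULL)
  X <- res$solutions[[1L]]$xyz
  expect_false(anyNA(X))
  # atom roster: 5 backbone atoms per residue + O (n-1) + CB (non-Gly)
  n <- 6L
  expect_equal(nrow(X), 5L * n + (n - 1L) + n)
  for (ax in inst$aux) {
    resid <- vapply(seq_along(ax$anchors), function(i) {
      abs(pdist(X[ax$key, ], X[ax$anchors[i], ]) - ax$dists[[i]])
    }, 0)
    expect_lt(max(resid), 1e-6)
    if (ax$type == "O") {
      vC <- X[ax$anchors[1L], ]; vN <- X[ax$anchors[2L], ]; vH <- X[ax$anchors[3L], ]
      nrm <- ibpenum:::v_cross(vN - vC, vH - vC)
      expect_lt(abs(sum(nrm * (vC - X[ax$key, ]))) / sqrt(sum(nrm^2)), 1e-8)
    }
  }
  # finalize_conformation reproduces the in-search placements
  fc <- finalize_conformation(X[inst$order$key[!inst$order$dup], ], inst)
  expect_equal(fc$xyz, X, tolerance = 1e-9)
})
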