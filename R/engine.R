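# The recursive depth-first branch-and-prune search: branching by
# recursion matrices over the discretized third-predecessor distances,
# duplicate re-embedding, pruning-device orchestration, incremental
# carbonyl-oxygen / C-beta placement, and RMSD-filtered solution storage.

#' Worst-case tree size bound
#'
#' `3 + 2^l b^k`, where `l` is the number of 2-branching levels (exact
#' third-predecessor distance), `k` the number of b-branching levels
#' (discretized interval) and `b` the discretization factor.
#'
#' @param l,k level counts (`>= 0`).
#' @param b discretization factor (`>= 1`).
#' @return numeric (may exceed integer range).
#' @export
tree_size_bound <- function(l, k, b) {
  stopifnot(l >= 0, k >= 0, b >= 1)
  3 + 2^l * b^k
}

#' Create a solution store
#'
#' Accumulates enumerated conformations with the RMSD filter: a new
#' conformation is stored only when its backbone RMSD to the previously
#' stored one exceeds the threshold (the first is always stored), and the
#' search stops once `max_saved` conformations are stored.
#'
#' @param max_saved stop after storing this many conformations.
#' @param rmsd_filter RMSD threshold in Angstrom between successively
#'   stored conformations; `NULL` stores every solution.
#' @param bb_keys atom keys used for the RMSD (default: all shared rows).
#' @return an environment of class `solution_store` with fields `confs`,
#'   `generated`, `saved`, `stopped`.
#' @export
solution_store <- function(max_saved = 10000L, rmsd_filter = 1.5,
                           bb_keys = NULL) {
  st <- new.env(parent = emptyenv())
  st$confs <- list()
  st$generated <- 0L
  st$saved <- 0L
  st$max_saved <- max_saved
  st$rmsd_filter <- rmsd_filter
  st$bb_keys <- bb_keys
  st$stopped <- FALSE
  class(st) <- "solution_store"
  st
}

#' @export
print.solution_store <- function(x, ...) {
  cat("solution store:", x$saved, "saved /", x$generated, "generated",
      if (x$stopped) "(capacity reached)" else "", "\n")
  invisible(x)
}

#' Offer a finalized conformation to the store
#'
#' Always increments the generated-conformation counter; stores the
#' conformation iff it is the first one or its backbone RMSD to the last
#' stored conformation exceeds the filter threshold. Sets the store's
#' `stopped` flag once capacity is reached.
#'
#' @param store a [solution_store()].
#' @param conf a `conformation` or a coordinate matrix with row names.
#' @return the store, invisibly.
#' @export
accept_solution <- function(store, conf) {
  stopifnot(inherits(store, "solution_store"))
  store$generated <- store$generated + 1L
  if (store$stopped) return(invisible(store))
  X <- if (inherits(conf, "conformation")) conf$xyz else as.matrix(conf)
  take <- TRUE
  if (!is.null(store$rmsd_filter) && length(store$confs)) {
    last <- store$confs[[length(store$confs)]]
    lastX <- if (inherits(last, "conformation")) last$xyz else as.matrix(last)
    bb <- store$bb_keys %||% intersect(rownames(X), rownames(lastX))
    r <- kabsch_rmsd(X[bb, , drop = FALSE], lastX[bb, , drop = FALSE])
    take <- r > store$rmsd_filter
  }
  if (take) {
    store$confs[[length(store$confs) + 1L]] <- conf
    store$saved <- store$saved + 1L
    if (store$saved >= store$max_saved) store$stopped <- TRUE
  }
  invisible(store)
}

# Precompute, for every rank v > 3, the branching data that depends only
# on the instance distances (never on the partial embedding): theta2 and,
# per discretized sample, the torsion magnitude and the +/- recursion
# matrices. The total number of matrices built is bounded by 2 |P_ato| b.
precompute_branches <- function(instance) {
  nr <- nrow(instance$order)
  out <- vector("list", nr)
  built <- 0L
  for (v in 4:nr) {
    d_ij <- instance$d1[v]; d_jk <- instance$d1[v - 1L]
    d_kl <- instance$d1[v - 2L]; d_ik <- instance$d2[v]
    d_lj <- instance$d2[v - 1L]
    cth <- (d_ij^2 + d_jk^2 - d_ik^2) / (2 * d_ij * d_jk)
    if (abs(cth) > 1 + 1e-8) { out[[v]] <- list(); next }
    th2 <- acos(clamp_cos(cth))
    samples <- instance$d3[[v]]
    cands <- list()
    for (s in samples) {
      co <- torsion_cosine(s, d_ij, d_jk, d_kl, d_ik, d_lj)
      if (is.na(co)) {            # flat triangle at the predecessor: the
        om <- 0                    # position is torsion-independent
      } else {
        if (abs(co) > 1 + 1e-8) next   # empty sphere intersection
        om <- acos(clamp_cos(co, tol = 1e-7))
      }
      # the two roots are 2 d sin(theta2) sin(omega3) apart; collapse them
      # when they coincide to numerical precision (planar/fixed torsions)
      two <- 2 * d_ij * sin(th2) * sin(om) > 1e-5
      Bp <- branch_matrix(branch_geometry(th2, om, 1, d_ij))
      built <- built + 1L
      Bm <- NULL
      if (two) {
        Bm <- branch_matrix(branch_geometry(th2, -om, 1, d_ij))
        built <- built + 1L
      }
      cands[[length(cands) + 1L]] <- list(sample = s, Bp = Bp, Bm = Bm)
    }
    out[[v]] <- cands
  }
  attr(out, "built") <- built
  out
}

#' Candidate embeddings for a vertex
#'
#' Generates the candidate positions of vertex `k` from the accumulated
#' transform of its predecessor: for each discretized third-predecessor
#' distance (ascending) at most two positions, the `sigma = +1` branch
#' before the `sigma = -1` branch. Every candidate satisfies the three
#' predecessor distances (up to numerical precision); an empty list means
#' the sphere intersection is empty for all samples.
#'
#' @param instance a `dgp_instance`.
#' @param k vertex rank (`> 3`).
#' @param Q_prev accumulated 4x4 transform of vertex `k - 1`.
#' @return list of candidates, each with `position`, `B`, `sample`,
#'   `sigma`.
#' @export
branch_candidates <- function(instance, k, Q_prev) {
  if (k <= 3) stop("branching starts at vertex 4", call. = FALSE)
  pre <- precompute_branches_rank(instance, k)
  out <- list()
  for (cand in pre) {
    pp <- (Q_prev %*% cand$Bp[, 4L])[1:3]
    out[[length(out) + 1L]] <- list(position = pp, B = cand$Bp,
                                    sample = cand$sample, sigma = 1)
    if (!is.null(cand$Bm)) {
      pm <- (Q_prev %*% cand$Bm[, 4L])[1:3]
      out[[length(out) + 1L]] <- list(position = pm, B = cand$Bm,
                                      sample = cand$sample, sigma = -1)
    }
  }
  out
}

# single-rank version of precompute_branches (for the exported helpers)
precompute_branches_rank <- function(instance, v) {
  d_ij <- instance$d1[v]; d_jk <- instance$d1[v - 1L]
  d_kl <- instance$d1[v - 2L]; d_ik <- instance$d2[v]
  d_lj <- instance$d2[v - 1L]
  cth <- (d_ij^2 + d_jk^2 - d_ik^2) / (2 * d_ij * d_jk)
  if (abs(cth) > 1 + 1e-8) return(list())
  th2 <- acos(clamp_cos(cth))
  cands <- list()
  for (s in instance$d3[[v]]) {
    co <- torsion_cosine(s, d_ij, d_jk, d_kl, d_ik, d_lj)
    if (!is.na(co) && abs(co) > 1 + 1e-8) next
    om <- if (is.na(co)) 0 else acos(clamp_cos(co, tol = 1e-7))
    two <- 2 * d_ij * sin(th2) * sin(om) > 1e-5
    Bp <- branch_matrix(branch_geometry(th2, om, 1, d_ij))
    Bm <- if (two) branch_matrix(branch_geometry(th2, -om, 1, d_ij))
    cands[[length(cands) + 1L]] <- list(sample = s, Bp = Bp, Bm = Bm)
  }
  cands
}

#' Re-embed a repeated atom
#'
#' A repeated vertex is re-embedded with the same recursion machinery;
#' of the two branch candidates the one closest to the original
#' coordinates of the atom is kept, and the node is rejected when even
#' that one drifts farther than `eps_dup`.
#'
#' @param instance a `dgp_instance`.
#' @param k rank of the repeated vertex.
#' @param Q_prev accumulated transform of vertex `k - 1`.
#' @param original original coordinates of the atom.
#' @param eps_dup drift tolerance (Angstrom).
#' @return list with `position`, `B`, `drift`, `accepted`.
#' @export
reembed_duplicate <- function(instance, k, Q_prev, original,
                              eps_dup = instance$config$eps_dup) {
  cands <- branch_candidates(instance, k, Q_prev)
  if (!length(cands)) return(list(position = NULL, drift = Inf, accepted = FALSE))
  dr <- vapply(cands, function(cc) v_norm(cc$position - original), 0)
  bi <- which.min(dr)
  list(position = cands[[bi]]$position, B = cands[[bi]]$B,
       drift = dr[bi], accepted = dr[bi] <= eps_dup)
}

#' Interval branch-and-prune search
#'
#' Depth-first enumeration of all embeddings of the instance's vertex
#' order that satisfy the distance constraints and survive the pruning
#' devices. Carbonyl oxygens and C-beta atoms, which are not part of the
#' order, are placed by their linear systems as soon as their anchor atoms
#' are embedded, so that the chirality and helix devices can prune early.
#' The search is deterministic: candidates are visited samples-ascending,
#' `sigma = +1` first.
#'
#' @param instance a `dgp_instance` from [build_protein_instance()],
#'   [derive_instance()] or [assemble_instance()].
#' @param max_saved stop after storing this many filtered conformations.
#' @param rmsd_filter backbone RMSD threshold between successively stored
#'   conformations (Angstrom); `NULL` stores every solution found.
#' @param devices character subset of
#'   `c("ddf", "taf", "dsp", "chi", "helix")`.
#' @param use_refined_bounds also check realized distances against the
#'   Floyd-Warshall-refined upper bounds within the distance-feasibility
#'   device (a valid strengthening; see the methods vignette).
#' @return list with `store` (a [solution_store()]), per-device prune
#'   counters, node statistics (`nodes`, `leaves`, `widths`,
#'   `candidates`), the number of recursion matrices built (`b_built`) and
#'   the 2-/b-branching level counts `l` and `k`.
#' @export
ibp_search <- function(instance,
                       max_saved = 10000L,
                       rmsd_filter = 1.5,
                       devices = c("ddf", "taf", "dsp", "chi", "helix"),
                       use_refined_bounds = TRUE) {
  order <- instance$order
  nr <- nrow(order)
  atoms <- instance$atoms
  m <- nrow(atoms)
  aidx <- instance$aidx
  cfg <- instance$config
  eps_x <- cfg$eps_x
  eps_t <- deg2rad(cfg$eps_t)
  eps_dup <- cfg$eps_dup
  use_ddf <- "ddf" %in% devices
  use_taf <- "taf" %in% devices && !is.null(instance$domains)
  use_dsp <- "dsp" %in% devices
  use_chi <- "chi" %in% devices
  use_helix <- "helix" %in% devices && !is.null(instance$helix_checks)

  LO <- instance_lower_matrix(instance)
  HI <- instance_upper_matrix(instance)
  UP <- NULL
  if (use_dsp || use_refined_bounds) {
    UP <- instance$u_plus %||% floyd_warshall_refine(instance)
    if (use_refined_bounds) HI <- pmin(HI, UP)
  }

  branches <- precompute_branches(instance)
  n_samp <- vapply(instance$d3, length, 0L)
  lvl_l <- sum(n_samp[4:nr] == 1L)
  lvl_k <- sum(n_samp[4:nr] > 1L)

  aux_by_rank <- vector("list", nr)
  for (ax in instance$aux %||% list()) {
    ax$aidx <- match(ax$key, atoms$key)
    ax$anchor_idx <- match(ax$anchors, atoms$key)
    if (ax$type == "CB") {
      res <- sub(":.*$", "", ax$key)
      ax$chi_idx <- match(paste0(res, ":", c("C", "N", "CB", "HA")), atoms$key)
    }
    aux_by_rank[[ax$trigger]] <- c(aux_by_rank[[ax$trigger]], list(ax))
  }
  helix_by_rank <- vector("list", nr)
  for (hc in instance$helix_checks %||% list()) {
    hc$idx <- match(c(hc$o, hc$c, hc$n, hc$h), atoms$key)
    helix_by_rank[[hc$trigger]] <- c(helix_by_rank[[hc$trigger]], list(hc))
  }

  bb_keys <- NULL
  if (!all(is.na(atoms$res))) {
    bb_keys <- atoms$key[atoms$name %in% c("N", "CA", "C")]
  }
  store <- solution_store(max_saved = max_saved, rmsd_filter = rmsd_filter,
                          bb_keys = bb_keys)

  coords <- matrix(0, m, 3L, dimnames = list(atoms$key, NULL))
  placed <- rep(FALSE, m)
  Qs <- vector("list", nr)
  counters <- c(ddf = 0, taf = 0, dsp = 0, chi = 0, helix = 0,
                dup_drift = 0, aux_degenerate = 0, empty_branch = 0)
  widths <- integer(nr)
  candidates <- 0L
  nodes <- 0L
  leaves <- 0L

  # initial triangle
  d21 <- instance$d1[2L]; d32 <- instance$d1[3L]; d31 <- instance$d2[3L]
  th3 <- acos(clamp_cos((d21^2 + d32^2 - d31^2) / (2 * d21 * d32), what = "theta3"))
  ini <- initial_placement(d21, d32, th3)
  coords[aidx[1L], ] <- ini$x1
  coords[aidx[2L], ] <- ini$x2
  coords[aidx[3L], ] <- ini$x3
  placed[aidx[1:3]] <- TRUE
  Qs[[3L]] <- ini$Q3
  widths[1:3] <- 1L
  nodes <- 3L

  ddf_ok <- function(ai, pos) {
    p <- which(placed)
    p <- p[p != ai]
    if (!length(p)) return(TRUE)
    dx <- coords[p, 1L] - pos[1L]
    dy <- coords[p, 2L] - pos[2L]
    dz <- coords[p, 3L] - pos[3L]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    !any(d < LO[p, ai] - eps_x - 1e-9 | d > HI[p, ai] + eps_x + 1e-9)
  }

  # max over embedded j of (||x_i - x_j|| - u+(j, a)): the shortest-path
  # pruning floor on any known distance d(pred, a)
  dsp_floor <- function(ai, pred_ai) {
    p <- which(placed)
    p <- p[p != ai]
    if (!length(p)) return(-Inf)
    xi <- coords[pred_ai, ]
    dx <- coords[p, 1L] - xi[1L]
    dy <- coords[p, 2L] - xi[2L]
    dz <- coords[p, 3L] - xi[3L]
    max(sqrt(dx * dx + dy * dy + dz * dz) - UP[p, ai])
  }

  recurse <- function(v) {
    if (store$stopped) return(invisible(NULL))
    if (v > nr) {
      leaves <<- leaves + 1L
      xyz <- coords
      xyz[!placed, ] <- NA_real_
      conf <- structure(list(xyz = xyz, atoms = atoms,
                             sequence = instance$sequence %||% NULL),
                        class = "conformation")
      accept_solution(store, conf)
      return(invisible(NULL))
    }
    a <- aidx[v]
    is_dup <- order$dup[v]
    pre <- branches[[v]]
    if (!length(pre)) {
      counters["empty_branch"] <<- counters["empty_branch"] + 1
      return(invisible(NULL))
    }
    # shortest-path pruning, independent of the candidate position
    s1 <- s2 <- s3 <- -Inf
    if (use_dsp && !is_dup) {
      s1 <- dsp_floor(a, aidx[v - 1L])
      s2 <- dsp_floor(a, aidx[v - 2L])
      s3 <- dsp_floor(a, aidx[v - 3L])
      if (s1 > instance$d1[v] || s2 > instance$d2[v]) {
        counters["dsp"] <<- counters["dsp"] + length(pre)
        return(invisible(NULL))
      }
    }
    Q_prev <- Qs[[v - 1L]]
    dom <- if (use_taf) instance$domains[[v]]
    if (is_dup) {
      orig <- coords[a, ]
      best <- NULL; bestd <- Inf
      for (cand in pre) {
        for (B in list(cand$Bp, cand$Bm)) {
          if (is.null(B)) next
          candidates <<- candidates + 1L
          pp <- (Q_prev %*% B[, 4L])[1:3]
          dd <- v_norm(pp - orig)
          if (dd < bestd) { bestd <- dd; best <- B }
        }
      }
      if (bestd > eps_dup) {
        counters["dup_drift"] <<- counters["dup_drift"] + 1
        return(invisible(NULL))
      }
      Qs[[v]] <<- Q_prev %*% best
      nodes <<- nodes + 1L
      widths[v] <<- widths[v] + 1L
      recurse(v + 1L)
      return(invisible(NULL))
    }
    x1 <- coords[aidx[v - 1L], ]; x2 <- coords[aidx[v - 2L], ]
    x3 <- coords[aidx[v - 3L], ]
    for (cand in pre) {
      if (store$stopped) break
      if (use_dsp && s3 > cand$sample) {
        counters["dsp"] <<- counters["dsp"] + 1
        next
      }
      for (B in list(cand$Bp, cand$Bm)) {
        if (is.null(B)) next
        if (store$stopped) break
        candidates <<- candidates + 1L
        pos <- (Q_prev %*% B[, 4L])[1:3]
        if (use_taf && !is.null(dom)) {
          xi <- tryCatch(dihedral_angle(pos, x1, x2, x3), error = function(e) NULL)
          if (is.null(xi) || !domain_contains(dom, xi, tol = eps_t)) {
            counters["taf"] <<- counters["taf"] + 1
            next
          }
        }
        if (use_ddf && !ddf_ok(a, pos)) {
          counters["ddf"] <<- counters["ddf"] + 1
          next
        }
        coords[a, ] <<- pos
        placed[a] <<- TRUE
        newly <- a
        ok <- TRUE
        for (ax in aux_by_rank[[v]] %||% list()) {
          anch <- coords[ax$anchor_idx, , drop = FALSE]
          apos <- tryCatch(
            if (ax$type == "O") {
              place_peptide_oxygen(anch[1L, ], anch[2L, ], anch[3L, ],
                                   ax$dists[[1L]], ax$dists[[2L]], ax$dists[[3L]])
            } else {
              place_cbeta(anch[1L, ], anch[2L, ], anch[3L, ],  anch[4L, ],
                          ax$dists[[1L]], ax$dists[[2L]], ax$dists[[3L]],
                          ax$dists[[4L]])
            }, error = function(e) NULL)
          if (is.null(apos)) {
            counters["aux_degenerate"] <<- counters["aux_degenerate"] + 1
            ok <- FALSE; break
          }
          if (use_ddf && !ddf_ok(ax$aidx, apos)) {
            counters["ddf"] <<- counters["ddf"] + 1
            ok <- FALSE; break
          }
          coords[ax$aidx, ] <<- apos
          placed[ax$aidx] <<- TRUE
          newly <- c(newly, ax$aidx)
          if (use_chi && ax$type == "CB") {
            ci <- ax$chi_idx
            if (dihedral_angle(coords[ci[1L], ], coords[ci[2L], ],
                               coords[ci[3L], ], coords[ci[4L], ]) <= 0) {
              counters["chi"] <<- counters["chi"] + 1
              ok <- FALSE; break
            }
          }
        }
        if (ok && use_helix) {
          for (hc in helix_by_rank[[v]] %||% list()) {
            hres <- helix_check_atoms(coords[hc$idx[1L], ], coords[hc$idx[2L], ],
                                      coords[hc$idx[3L], ], coords[hc$idx[4L], ],
                                      instance$helix, eps_x = eps_x, eps_t = eps_t)
            if (!hres$accepted) {
              counters["helix"] <<- counters["helix"] + 1
              ok <- FALSE; break
            }
          }
        }
        if (ok) {
          Qs[[v]] <<- Q_prev %*% B
          nodes <<- nodes + 1L
          widths[v] <<- widths[v] + 1L
          recurse(v + 1L)
        }
        placed[newly] <<- FALSE
      }
    }
    invisible(NULL)
  }
  recurse(4L)
  placed[aidx[1:3]] <- FALSE

  list(store = store,
       solutions = store$confs,
       generated = store$generated,
       saved = store$saved,
       prune_counts = counters,
       nodes = nodes, leaves = leaves, widths = widths,
       candidates = candidates,
       b_built = attr(branches, "built"),
       l = lvl_l, k = lvl_k,
       bound = tree_size_bound(lvl_l, lvl_k, instance$config$b))
}

#' Finalize a backbone embedding into a conformation
#'
#' Collapses repeated vertices to single atoms (first embedding
#' authoritative) and places the carbonyl oxygens (one per peptide plane,
#' trans unless configured cis) and the C-beta atoms from their exact
#' distance systems. [ibp_search()] performs these placements
#' incrementally during the search; this function reproduces them for an
#' externally supplied embedding.
#'
#' @param embedding named list or matrix of backbone coordinates keyed
#'   `"res:atom"` covering the atoms of the order.
#' @param instance the `dgp_instance` the embedding realizes.
#' @return a `conformation` (list with `xyz`, `atoms`, `sequence`).
#' @export
finalize_conformation <- function(embedding, instance) {
  atoms <- instance$atoms
  X <- matrix(NA_real_, nrow(atoms), 3L, dimnames = list(atoms$key, NULL))
  E <- if (is.matrix(embedding)) embedding else do.call(rbind, embedding)
  ks <- intersect(rownames(E), atoms$key)
  X[ks, ] <- E[ks, ]
  for (ax in instance$aux %||% list()) {
    anch <- X[ax$anchors, , drop = FALSE]
    if (anyNA(anch)) stop("embedding misses anchors for ", ax$key, call. = FALSE)
    X[ax$key, ] <- if (ax$type == "O") {
      place_peptide_oxygen(anch[1L, ], anch[2L, ], anch[3L, ],
                           ax$dists[[1L]], ax$dists[[2L]], ax$dists[[3L]])
    } else {
      place_cbeta(anch[1L, ], anch[2L, ], anch[3L, ], anch[4L, ],
                  ax$dists[[1L]], ax$dists[[2L]], ax$dists[[3L]], ax$dists[[4L]])
    }
  }
  structure(list(xyz = X, atoms = atoms, sequence = instance$sequence %||% NULL),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  n <- if (!is.null(x$sequence)) length(x$sequence) else NA
  cat("conformation:", nrow(x$xyz), "atoms",
      if (!is.na(n)) paste0("(", n, " residues)"), "\n")
  invisible(x)
}
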