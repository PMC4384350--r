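# Synthetic test surface: ideal-helix construction from the covalent
# table, derivation of DGP instances whose constraints are measured on a
# known structure (so that round-trip recovery can be asserted), and the
# input-degradation protocol used for robustness checks.

# place atom x bonded to c with |x - c| = bond, angle(x, c, b) = theta and
# dihedral(a, b, c, x) = tau (standard internal-coordinate construction)
nerf_place <- function(a, b, c, bond, theta, tau) {
  bc <- v_unit(c - b)
  n <- v_unit(v_cross(b - a, bc))
  mm <- v_cross(n, bc)
  c + bond * (-cos(theta) * bc +
                sin(theta) * (cos(tau) * mm - sin(tau) * n))
}

# backbone + H + HA + CB + O coordinates for uniform or per-residue
# phi/psi and a common omega; row names are "res:atom" keys
build_backbone_atoms <- function(aa, phi, psi, omega = pi,
                                 geom = covalent_geometry()) {
  n <- length(aa)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  lb <- function(k) bond_length(geom, k)
  ab <- function(k) bond_angle(geom, k)
  frame <- local_ca_frame(geom)
  X <- list()
  put <- function(key, p) X[[key]] <<- p
  gx <- function(key) X[[key]]
  place_side <- function(i) {
    ca <- gx(paste0(i, ":CA"))
    un <- v_unit(gx(paste0(i, ":N")) - ca)
    uc <- v_unit(gx(paste0(i, ":C")) - ca)
    # rotation taking the canonical frame onto the actual N/C directions
    e1 <- frame$n; e2 <- v_unit(frame$c - sum(frame$c * e1) * e1); e3 <- v_cross(e1, e2)
    f1 <- un; f2 <- v_unit(uc - sum(uc * f1) * f1); f3 <- v_cross(f1, f2)
    R <- cbind(f1, f2, f3) %*% t(cbind(e1, e2, e3))
    put(paste0(i, ":HA"), ca + lb("CA-HA") * as.numeric(R %*% frame$ha))
    if (aa[i] != "G") {
      put(paste0(i, ":CB"), ca + lb("CA-CB") * as.numeric(R %*% frame$cb))
    }
  }
  put("1:N", c(0, 0, 0))
  put("1:CA", c(lb("N-CA"), 0, 0))
  anc <- ab("N-CA-C")
  put("1:C", gx("1:CA") + lb("CA-C") * c(-cos(anc), sin(anc), 0))
  put("1:H", nerf_place(gx("1:C"), gx("1:CA"), gx("1:N"),
                        lb("N-H"), ab("H-N-CA"), wrap_angle(phi[1L] + pi)))
  place_side(1L)
  for (i in seq_len(n)[-1L]) {
    p <- i - 1L
    put(paste0(i, ":N"),
        nerf_place(gx(paste0(p, ":N")), gx(paste0(p, ":CA")), gx(paste0(p, ":C")),
                   lb("C-+N"), ab("CA-C-+N"), psi[p]))
    put(paste0(i, ":CA"),
        nerf_place(gx(paste0(p, ":CA")), gx(paste0(p, ":C")), gx(paste0(i, ":N")),
                   lb("N-CA"), ab("C-N-CA"), omega))
    put(paste0(i, ":H"),
        nerf_place(gx(paste0(p, ":CA")), gx(paste0(p, ":C")), gx(paste0(i, ":N")),
                   lb("N-H"), ab("C-N-H"), wrap_angle(omega + pi)))
    put(paste0(i, ":C"),
        nerf_place(gx(paste0(p, ":C")), gx(paste0(i, ":N")), gx(paste0(i, ":CA")),
                   lb("CA-C"), ab("N-CA-C"), phi[i]))
    place_side(i)
    om_d <- oxygen_distances(geom, omega = omega)
    put(paste0(p, ":O"),
        place_peptide_oxygen(gx(paste0(p, ":C")), gx(paste0(i, ":N")),
                             gx(paste0(i, ":H")),
                             om_d[[1L]], om_d[[2L]], om_d[[3L]]))
  }
  do.call(rbind, X)
}

#' Fixture specification
#'
#' Parameters of the synthetic ideal-helix test systems: uniform backbone
#' torsions, the width of the derived third-predecessor intervals, and the
#' number of extra long-range pruning constraints.
#'
#' @param n_residues chain length (`>= 4`).
#' @param sequence optional one-letter sequence (default: polyalanine).
#' @param phi,psi backbone torsions in degrees (ideal alpha-helix:
#'   -57, -47).
#' @param w width (Angstrom) of the intervals placed around the measured
#'   phi/psi-dependent `{v, v-3}` distances; 0 gives an exact instance.
#' @param n_long number of extra long-range CA-CA pruning constraints.
#' @param lr_width total width (Angstrom) of those long-range intervals.
#' @param seed seed for the random choice of long-range pairs.
#' @param geom a [covalent_geometry()].
#' @param config a [tolerance_config()].
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 10L, sequence = NULL, phi = -57,
                         psi = -47, w = 0, n_long = 0L, lr_width = 1.0,
                         seed = 1L, geom = covalent_geometry(),
                         config = tolerance_config()) {
  if (!is_count(n_residues) || n_residues < 4) stop("need at least 4 residues")
  if (w < 0) stop("interval width must be non-negative")
  structure(list(n_residues = as.integer(n_residues),
                 sequence = parse_sequence(sequence %||% as.integer(n_residues)),
                 phi = phi, psi = psi, w = w, n_long = as.integer(n_long),
                 lr_width = lr_width, seed = as.integer(seed),
                 geom = geom, config = config),
            class = "fixture_spec")
}

#' Build an ideal alpha-helix conformation
#'
#' Full backbone with amide hydrogens, HA, C-beta (non-glycine) and
#' carbonyl oxygens (all but the C-terminal residue), built from the
#' covalent table with uniform phi/psi and trans peptide planes.
#'
#' @param spec a [fixture_spec()] (or a residue count).
#' @return a `conformation`.
#' @export
build_ideal_helix <- function(spec = fixture_spec()) {
  if (is.numeric(spec)) spec <- fixture_spec(spec)
  stopifnot(inherits(spec, "fixture_spec"))
  aa <- spec$sequence
  X <- build_backbone_atoms(aa, deg2rad(spec$phi), deg2rad(spec$psi),
                            omega = pi, geom = spec$geom)
  atoms <- atoms_table(aa)
  structure(list(xyz = X[atoms$key, , drop = FALSE], atoms = atoms,
                 sequence = aa, phi = spec$phi, psi = spec$psi),
            class = "conformation")
}

#' Derive a DGP instance from a known conformation
#'
#' Measures every order-edge distance on the conformation, replaces the
#' phi/psi-dependent third-predecessor distances by intervals of width `w`
#' centered on the measured value, attaches helix hydrogen-bond windows,
#' steric lower bounds and optional random long-range CA-CA intervals, and
#' refines the upper bounds. Every derived constraint contains the
#' measured value, so the generating conformation is feasible by
#' construction.
#'
#' @param conf a `conformation` (typically [build_ideal_helix()]).
#' @param spec the [fixture_spec()] used to build it.
#' @param helices a [helix_definition()] or residue ranges; defaults to
#'   the full chain.
#' @return a `dgp_instance`.
#' @export
derive_instance <- function(conf, spec = fixture_spec(), helices = NULL) {
  stopifnot(inherits(conf, "conformation"))
  aa <- conf$sequence
  n <- length(aa)
  geom <- spec$geom
  config <- spec$config
  helix <- if (is.null(helices)) helix_definition(c(1L, n))
           else if (inherits(helices, "helix_definition")) helices
           else helix_definition(helices)
  order <- build_atom_order(n)
  kind <- order_edge_kind(order)
  atoms <- conf$atoms
  X <- conf$xyz
  dist_keys <- function(k1, k2) v_norm(X[k1, ] - X[k2, ])
  off <- order_torsion_offsets(geom)
  in_helix <- rep(FALSE, n)
  for (r in helix$ranges) in_helix[r[1L]:r[2L]] <- TRUE
  phi_domains <- lapply(seq_len(n), function(i) default_torsion_domains(in_helix[i])$phi)
  psi_domains <- lapply(seq_len(n), function(i) default_torsion_domains(in_helix[i])$psi)

  rows <- list()
  add <- function(a, b, lower, upper, source) {
    rows[[length(rows) + 1L]] <<- data.frame(a = a, b = b, lower = lower,
                                             upper = upper, source = source,
                                             stringsAsFactors = FALSE)
  }
  nr <- nrow(order)
  domains <- vector("list", nr)
  seen <- character(0)
  for (v in seq_len(nr)) {
    for (j in 1:3) {
      if (v - j < 1L) next
      k1 <- order$key[v]; k2 <- order$key[v - j]
      if (k1 == k2) next
      pk <- pair_key(k1, k2)
      if (pk %in% seen) next
      d <- dist_keys(k1, k2)
      if (j == 3L && kind[v] %in% c("phi", "psi")) {
        add(k1, k2, max(d - spec$w / 2, 0), d + spec$w / 2, "torsion-order")
      } else {
        add(k1, k2, d, d, "covalent")
      }
      seen <- c(seen, pk)
    }
    if (v > 3L) {
      qk <- order$key[v - (0:3)]
      tau <- tryCatch(dihedral_angle(X[qk[1L], ], X[qk[2L], ], X[qk[3L], ],
                                     X[qk[4L], ]), error = function(e) NULL)
      domains[v] <- list(switch(kind[v],
        phi = domain_shift(phi_domains[[order$res[v]]], off$phi),
        psi = domain_shift(psi_domains[[order$res[v] - 1L]], off$psi),
        exact = if (!is.null(tau)) angle_domain(singletons = tau),
        chi = if (!is.null(tau)) angle_domain(singletons = c(-abs(tau), abs(tau))),
        NULL))
    }
  }
  hb <- helix_hbond_constraints(helix, n)
  if (!is.null(hb)) for (r in seq_len(nrow(hb))) add(hb$a[r], hb$b[r], hb$lower[r], hb$upper[r], "hbond")
  tor <- torsion_constraints(phi_domains, psi_domains, n, geom)
  if (!is.null(tor)) for (r in seq_len(nrow(tor))) add(tor$a[r], tor$b[r], tor$lower[r], tor$upper[r], "torsion")
  if (spec$n_long > 0L && n > 5L) {
    set.seed(spec$seed)
    all_pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i > 4),
                       arr.ind = TRUE)
    take <- all_pairs[sample(nrow(all_pairs), min(spec$n_long, nrow(all_pairs))), ,
                      drop = FALSE]
    for (r in seq_len(nrow(take))) {
      k1 <- paste0(take[r, 1L], ":CA"); k2 <- paste0(take[r, 2L], ":CA")
      d <- dist_keys(k1, k2)
      add(k1, k2, max(d - spec$lr_width / 2, 0), d + spec$lr_width / 2, "nmr")
    }
  }
  base <- do.call(rbind, rows)
  vdw <- vdw_bounds(atoms, vdw_table(sigma = config$sigma_vdw), existing = base)
  constraints <- rbind(base, vdw)

  inst <- assemble_instance(order, constraints, config, domains = domains,
                            atoms = atoms)
  inst$kind <- kind
  inst$geom <- geom
  inst$helix <- helix
  inst$sequence <- aa
  aux <- protein_aux_specs(aa, geom)
  # measured auxiliary-placement distances (consistent with the fixture)
  inst$aux <- lapply(aux, function(ax) {
    ax$dists <- vapply(ax$anchors, function(k) dist_keys(ax$key, k), 0)
    ax
  })
  inst$helix_checks <- protein_helix_checks(helix, n)
  inst$u_plus <- floyd_warshall_refine(inst)
  inst
}

#' Degrade instance inputs (robustness protocol)
#'
#' Shrinks every declared helix by one residue at each extremity (ranges
#' falling below 3 residues are dropped with a warning) and widens every
#' long-range (NMR-tagged) pruning interval by 0.5 Angstrom on each side,
#' flooring lower bounds at zero. The degraded instance's constraints
#' contain the originals.
#'
#' @param instance a `dgp_instance` carrying a helix definition.
#' @return a degraded `dgp_instance`.
#' @export
degrade_inputs <- function(instance) {
  if (is.null(instance$helix)) stop("instance carries no helix definition")
  old <- instance$helix
  n <- max(instance$order$res)
  ranges <- list()
  for (r in old$ranges) {
    rr <- c(r[1L] + 1L, r[2L] - 1L)
    if (rr[2L] - rr[1L] + 1L < 3L) {
      warning(sprintf("helix %d-%d too short after shrinking; dropped",
                      r[1L], r[2L]))
    } else {
      ranges[[length(ranges) + 1L]] <- rr
    }
  }
  helix <- old
  helix$ranges <- ranges
  cs <- instance$constraints
  cs <- cs[cs$source != "hbond", , drop = FALSE]
  nm <- cs$source == "nmr"
  cs$lower[nm] <- pmax(cs$lower[nm] - 0.5, 0)
  cs$upper[nm] <- cs$upper[nm] + 0.5
  hb <- if (length(ranges)) helix_hbond_constraints(helix, n)
  cs <- rbind(cs, hb)
  out <- assemble_instance(instance$order, cs, instance$config,
                           domains = instance$domains, atoms = instance$atoms)
  out$kind <- instance$kind
  out$geom <- instance$geom
  out$sequence <- instance$sequence
  out$helix <- if (length(ranges)) helix
  out$aux <- instance$aux
  out$helix_checks <- if (length(ranges)) protein_helix_checks(helix, n)
  out$u_plus <- floyd_warshall_refine(out)
  out
}

#' Random exact chain instances (theory test surface)
#'
#' Generates a random realizable chain of `n` abstract vertices with exact
#' distances to the three predecessors, plus `n_prune` random exact
#' pruning edges measured on the generating realization. With no pruning
#' edges the search tree is the complete binary tree with `2^(n-3)`
#' leaves.
#'
#' @param n number of vertices (`>= 4`).
#' @param n_prune number of random long-range exact pruning edges.
#' @param seed RNG seed.
#' @return list with `instance` (a `dgp_instance`) and `truth` (the
#'   generating n x 3 coordinate matrix).
#' @export
random_chain_instance <- function(n = 6L, n_prune = 0L, seed = 1L) {
  stopifnot(n >= 4L)
  set.seed(seed)
  # random chain with generic geometry: unit-ish bonds, random angles
  X <- matrix(0, n, 3L)
  X[2L, ] <- c(stats::runif(1, 1, 1.8), 0, 0)
  repeat {
    X[3L, ] <- X[2L, ] + stats::runif(1, 1, 1.8) *
      v_unit(c(stats::rnorm(2), 0))
    a <- point_angle(X[1L, ], X[2L, ], X[3L, ])
    if (a > 0.4 && a < 2.7) break
  }
  for (v in 4:n) {
    repeat {
      th <- stats::runif(1, 0.5, 2.6)
      ta <- stats::runif(1, -pi, pi)
      d <- stats::runif(1, 1, 1.8)
      p <- nerf_place(X[v - 3L, ], X[v - 2L, ], X[v - 1L, ], d, th, ta)
      if (abs(sin(ta)) > 0.1) break   # keep branches well separated
    }
    X[v, ] <- p
  }
  keys <- paste0("v", seq_len(n))
  rownames(X) <- keys
  order <- data.frame(rank = seq_len(n), key = keys, dup = FALSE,
                      dup_of = NA_integer_, stringsAsFactors = FALSE)
  rows <- list()
  for (v in seq_len(n)) {
    for (j in 1:3) {
      if (v - j < 1L) next
      d <- v_norm(X[v, ] - X[v - j, ])
      rows[[length(rows) + 1L]] <- data.frame(a = keys[v], b = keys[v - j],
                                              lower = d, upper = d,
                                              source = "exact",
                                              stringsAsFactors = FALSE)
    }
  }
  if (n_prune > 0L) {
    pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i > 3),
                   arr.ind = TRUE)
    if (nrow(pairs)) {
      take <- pairs[sample(nrow(pairs), min(n_prune, nrow(pairs))), , drop = FALSE]
      for (r in seq_len(nrow(take))) {
        i <- take[r, 1L]; j <- take[r, 2L]
        d <- v_norm(X[i, ] - X[j, ])
        rows[[length(rows) + 1L]] <- data.frame(a = keys[i], b = keys[j],
                                                lower = d, upper = d,
                                                source = "nmr",
                                                stringsAsFactors = FALSE)
      }
    }
  }
  constraints <- do.call(rbind, rows)
  inst <- assemble_instance(order, constraints,
                            tolerance_config(eps_x = 1e-6, b = 1))
  list(instance = inst, truth = X)
}
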