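# Assembly of discretizable distance-geometry instances: the vertex order
# plus the edge partition E_D' (exact distances to the first and second
# predecessor), E_D'' (exact or b-discretized distances to the third
# predecessor) and E_P (general interval pruning edges).

#' Tolerances and discretization parameters
#'
#' @param eps_x position tolerance in Angstrom, applied additively and
#'   inclusively to distance windows.
#' @param eps_t angle tolerance in degrees, applied additively to torsion
#'   windows.
#' @param b discretization factor: number of values sampled from each
#'   interval `{v, v-3}` distance.
#' @param sigma_vdw scale applied to van der Waals radius sums.
#' @param eps_dup maximum drift allowed when a repeated atom is
#'   re-embedded, in Angstrom.
#' @param include_upper logical, see [discretize_interval()].
#' @return a list of class `tolerance_config`.
#' @export
tolerance_config <- function(eps_x = 0.2, eps_t = 2, b = 4, sigma_vdw = 0.85,
                             eps_dup = 0.1, include_upper = FALSE) {
  stopifnot(eps_x >= 0, eps_t >= 0, is_count(b), sigma_vdw >= 0,
            sigma_vdw <= 1, eps_dup >= 0)
  structure(list(eps_x = eps_x, eps_t = eps_t, b = as.integer(b),
                 sigma_vdw = sigma_vdw, eps_dup = eps_dup,
                 include_upper = isTRUE(include_upper)),
            class = "tolerance_config")
}

#' Default backbone torsion domains
#'
#' Helical residues get narrow phi/psi windows around the ideal helix;
#' all other residues get broad Ramachandran-like windows. These defaults
#' are a modeling choice of this package, exposed so they can be replaced.
#'
#' @param helix logical: helical residue?
#' @return list with `phi` and `psi` [angle_domain()]s.
#' @export
default_torsion_domains <- function(helix = FALSE) {
  if (helix) {
    list(phi = angle_domain(c(-90, -30), degrees = TRUE),
         psi = angle_domain(c(-77, -17), degrees = TRUE))
  } else {
    list(phi = angle_domain(c(-180, -30), degrees = TRUE),
         psi = angle_domain(rbind(c(-90, -10), c(50, 180), c(-180, -170)),
                            degrees = TRUE))
  }
}

# Constant offsets between the torsions branched over in the atom order
# and the backbone phi/psi, plus the fixed torsion values of the
# peptide-planarity vertices and the chirality improper magnitude. All are
# functions of the covalent table only; measured once on a reference
# two-residue construction.
order_torsion_offsets <- function(geom) {
  phi0 <- -1.1; psi0 <- -0.9
  ref <- build_backbone_atoms(c("A", "A"), phi = rep(phi0, 2),
                              psi = rep(psi0, 2), omega = pi, geom = geom)
  cref <- build_backbone_atoms(c("A", "A"), phi = rep(phi0, 2),
                               psi = rep(psi0, 2), omega = 0, geom = geom)
  at <- function(x, k) x[k, ]
  off <- list(
    phi = wrap_angle(dihedral_angle(at(ref, "2:HA"), at(ref, "2:N"),
                                    at(ref, "2:CA"), at(ref, "2:H")) - phi0),
    psi = wrap_angle(dihedral_angle(at(ref, "2:N"), at(ref, "1:C"),
                                    at(ref, "1:CA"), at(ref, "1:HA")) - psi0),
    h_trans = dihedral_angle(at(ref, "2:H"), at(ref, "2:N"),
                             at(ref, "1:C"), at(ref, "1:CA")),
    ca_trans = dihedral_angle(at(ref, "2:CA"), at(ref, "2:H"),
                              at(ref, "2:N"), at(ref, "1:C")),
    h_cis = dihedral_angle(at(cref, "2:H"), at(cref, "2:N"),
                           at(cref, "1:C"), at(cref, "1:CA")),
    ca_cis = dihedral_angle(at(cref, "2:CA"), at(cref, "2:H"),
                            at(cref, "2:N"), at(cref, "1:C")),
    chi_abs = abs(dihedral_angle(at(ref, "2:C"), at(ref, "2:CA"),
                                 at(ref, "2:HA"), at(ref, "2:N")))
  )
  off
}

# sorted-pair key for constraint lookup
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Assemble a discretizable DGP instance
#'
#' Partitions a constraint set over an ordered vertex list into the exact
#' predecessor distances (`{v, v-1}`, `{v, v-2}`), the third-predecessor
#' distance sets (exact values, or intervals pre-discretized into `b`
#' samples), and the general-interval pruning edges, verifying the
#' partition invariants.
#'
#' @param order a [build_atom_order()] result, or any data frame with
#'   columns `rank`, `key`, `dup` (vertices in embedding order; repeated
#'   atoms share a `key`).
#' @param constraints data frame with columns `a`, `b` (keys), `lower`,
#'   `upper`, `source`.
#' @param config a [tolerance_config()].
#' @param domains optional list (by rank) of [angle_domain()]s for the
#'   branch torsion over `{v, v-1, v-2, v-3}`, used by the torsion-angle
#'   feasibility device.
#' @param atoms optional atom table; derived from the order keys when
#'   `NULL`.
#' @return object of class `dgp_instance`.
#' @export
assemble_instance <- function(order, constraints, config = tolerance_config(),
                              domains = NULL, atoms = NULL) {
  nr <- nrow(order)
  if (is.null(atoms)) {
    keys <- unique(order$key)
    atoms <- data.frame(key = keys, res = NA_integer_,
                        name = keys, element = NA_character_,
                        stringsAsFactors = FALSE)
  }
  aidx <- match(order$key, atoms$key)
  if (anyNA(aidx)) stop("order refers to atoms missing from the atom table")
  # combined bounds per pair (max of lowers, min of uppers)
  ck <- pair_key(constraints$a, constraints$b)
  lo <- tapply(constraints$lower, ck, max)
  hi <- tapply(constraints$upper, ck, min)
  if (any(lo[names(hi)] > hi + 1e-9)) {
    bad <- names(which(lo[names(hi)] > hi + 1e-9))[1L]
    stop("contradictory constraints on pair ", bad)
  }
  lookup <- function(k1, k2) {
    if (k1 == k2) return(c(0, 0))
    k <- pair_key(k1, k2)
    if (!k %in% names(lo)) return(NULL)
    c(lo[[k]], hi[[k]])
  }
  d1 <- d2 <- rep(NA_real_, nr)
  d3 <- vector("list", nr)
  d3_lu <- matrix(NA_real_, nr, 2L)
  need_exact <- function(v, j) {
    w <- lookup(order$key[v], order$key[v - j])
    if (is.null(w) || w[2L] - w[1L] > 1e-9) {
      stop(sprintf("vertex %d lacks an exact distance to predecessor %d (%s, %s)",
                   v, v - j, order$key[v], order$key[v - j]), call. = FALSE)
    }
    w[1L]
  }
  for (v in seq_len(nr)) {
    if (v >= 2) d1[v] <- need_exact(v, 1L)
    if (v >= 3) d2[v] <- need_exact(v, 2L)
    if (v >= 4) {
      w <- lookup(order$key[v], order$key[v - 3L])
      if (is.null(w)) {
        stop(sprintf("infeasible order: vertex %d has no distance to its third predecessor (%s, %s)",
                     v, order$key[v], order$key[v - 3L]), call. = FALSE)
      }
      d3_lu[v, ] <- w
      d3[[v]] <- discretize_interval(w[1L], w[2L], config$b,
                                     include_upper = config$include_upper)
    }
  }
  # pruning edges: every constrained pair that is not an order-adjacent
  # ({v, v-1}, {v, v-2} or {v, v-3}) pair of distinct atoms
  adj <- character(0)
  for (j in 1:3) {
    v <- (j + 1L):nr
    adj <- c(adj, pair_key(order$key[v], order$key[v - j]))
  }
  selfpair <- constraints$a == constraints$b
  ep <- constraints[!(ck %in% adj) & !selfpair &
                      constraints$a %in% atoms$key &
                      constraints$b %in% atoms$key, , drop = FALSE]
  structure(list(order = order, atoms = atoms, aidx = aidx,
                 d1 = d1, d2 = d2, d3 = d3, d3_lu = d3_lu,
                 domains = domains, ep = ep, constraints = constraints,
                 aux = NULL, helix_checks = NULL, helix = NULL,
                 geom = NULL, config = config, u_plus = NULL),
            class = "dgp_instance")
}

#' @export
print.dgp_instance <- function(x, ...) {
  nr <- nrow(x$order)
  nb <- sum(vapply(x$d3, function(s) length(s) > 1L, TRUE))
  cat("Discretizable DGP instance\n")
  cat("  vertices:       ", nr, " (", length(unique(x$order$key)), " atoms)\n", sep = "")
  cat("  b-branching levels:", nb, " of factor", x$config$b, "\n")
  cat("  pruning edges:  ", nrow(x$ep), "\n", sep = "")
  if (!is.null(x$helix)) {
    cat("  helix ranges:   ",
        paste(vapply(x$helix$ranges, function(r) paste(r, collapse = "-"), ""),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# upper-bound matrix over distinct atoms from every constraint row
instance_upper_matrix <- function(instance) {
  atoms <- instance$atoms
  m <- nrow(atoms)
  U <- matrix(Inf, m, m, dimnames = list(atoms$key, atoms$key))
  cs <- instance$constraints
  ia <- match(cs$a, atoms$key); ib <- match(cs$b, atoms$key)
  keep <- !is.na(ia) & !is.na(ib) & is.finite(cs$upper)
  for (r in which(keep)) {
    u <- cs$upper[r]
    if (u < U[ia[r], ib[r]]) U[ia[r], ib[r]] <- U[ib[r], ia[r]] <- u
  }
  diag(U) <- 0
  U
}

# lower-bound matrix (used for the direct distance feasibility device)
instance_lower_matrix <- function(instance) {
  atoms <- instance$atoms
  m <- nrow(atoms)
  L <- matrix(0, m, m, dimnames = list(atoms$key, atoms$key))
  cs <- instance$constraints
  ia <- match(cs$a, atoms$key); ib <- match(cs$b, atoms$key)
  keep <- !is.na(ia) & !is.na(ib) & cs$lower > 0
  for (r in which(keep)) {
    l <- cs$lower[r]
    if (l > L[ia[r], ib[r]]) L[ia[r], ib[r]] <- L[ib[r], ia[r]] <- l
  }
  diag(L) <- 0
  L
}

#' Build a protein backbone DGP instance
#'
#' High-level constructor: from a sequence, helix definition and optional
#' long-range restraints, builds the repetition atom order, all covalent
#' and angular exact distances, phi/psi-derived discretization intervals
#' and branch-torsion domains, hydrogen-bond and steric pruning edges, and
#' the Floyd-Warshall-refined upper bounds.
#'
#' @param sequence one-letter sequence string or residue count.
#' @param helices a [helix_definition()], a list of residue ranges, or
#'   `NULL`.
#' @param restraints data frame of long-range restraints (columns `res1`,
#'   `atom1`, `res2`, `atom2`, `lower`, `upper`), e.g. from
#'   [parse_restraints()], or `NULL`.
#' @param config a [tolerance_config()].
#' @param geom a [covalent_geometry()].
#' @param phi_domains,psi_domains optional per-residue lists of
#'   [angle_domain()]s overriding the defaults.
#' @param cis integer vector of residues starting a cis peptide bond.
#' @return a `dgp_instance` ready for [ibp_search()].
#' @export
build_protein_instance <- function(sequence, helices = NULL, restraints = NULL,
                                   config = tolerance_config(),
                                   geom = covalent_geometry(),
                                   phi_domains = NULL, psi_domains = NULL,
                                   cis = integer(0)) {
  aa <- parse_sequence(sequence)
  n <- length(aa)
  helix <- NULL
  if (!is.null(helices)) {
    helix <- if (inherits(helices, "helix_definition")) helices else helix_definition(helices)
    for (r in helix$ranges) if (r[2L] > n) stop("helix range beyond sequence end")
  }
  order <- build_atom_order(n)
  kind <- order_edge_kind(order)
  atoms <- atoms_table(aa)
  in_helix <- rep(FALSE, n)
  if (!is.null(helix)) for (r in helix$ranges) in_helix[r[1L]:r[2L]] <- TRUE
  if (is.null(phi_domains)) {
    phi_domains <- lapply(seq_len(n), function(i) default_torsion_domains(in_helix[i])$phi)
  }
  if (is.null(psi_domains)) {
    psi_domains <- lapply(seq_len(n), function(i) default_torsion_domains(in_helix[i])$psi)
  }
  off <- order_torsion_offsets(geom)
  lb <- function(k) bond_length(geom, k)
  cpd <- function(r1, n1, r2, n2, om = pi) covalent_pair_distance(geom, r1, n1, r2, n2, omega = om)

  cov <- covalent_constraints(atoms, geom, cis = cis)
  tor <- torsion_constraints(phi_domains, psi_domains, n, geom)
  hb <- if (!is.null(helix)) helix_hbond_constraints(helix, n)
  nmr <- NULL
  if (!is.null(restraints) && nrow(restraints)) {
    nmr <- data.frame(a = paste0(restraints$res1, ":", restraints$atom1),
                      b = paste0(restraints$res2, ":", restraints$atom2),
                      lower = restraints$lower, upper = restraints$upper,
                      source = "nmr", stringsAsFactors = FALSE)
    miss <- setdiff(c(nmr$a, nmr$b), atoms$key)
    if (length(miss)) {
      stop("restraint names atoms absent from the chain: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  # order-edge intervals for the phi/psi discretization edges
  edge_rows <- list()
  domains <- vector("list", nrow(order))
  for (v in which(kind %in% c("phi", "psi", "exact", "chi"))) {
    i <- order$res[v]
    pos <- ((v - 1L) %% 7L) + 1L
    if (kind[v] == "phi") {
      dom <- domain_shift(phi_domains[[i]], off$phi)
      env <- torsion_domain_bounds(dom,
                                   d_ij = cpd(i, "HA", i, "N"), d_jk = lb("N-CA"),
                                   d_kl = cpd(i, "CA", i, "H"),
                                   d_ik = lb("CA-HA"), d_lj = lb("N-H"))
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        a = paste0(i, ":HA"), b = paste0(i, ":H"),
        lower = env$lower, upper = env$upper, source = "torsion-order",
        stringsAsFactors = FALSE)
      domains[[v]] <- dom
    } else if (kind[v] == "psi") {
      dom <- domain_shift(psi_domains[[i - 1L]], off$psi)
      env <- torsion_domain_bounds(dom,
                                   d_ij = lb("C-+N"), d_jk = lb("CA-C"),
                                   d_kl = lb("CA-HA"),
                                   d_ik = cpd(i - 1L, "CA", i, "N"),
                                   d_lj = cpd(i - 1L, "HA", i - 1L, "C"))
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        a = paste0(i, ":N"), b = paste0(i - 1L, ":HA"),
        lower = env$lower, upper = env$upper, source = "torsion-order",
        stringsAsFactors = FALSE)
      domains[[v]] <- dom
    } else if (kind[v] == "exact") {
      om_cis <- (i - 1L) %in% cis
      domains[[v]] <- if (pos == 2L) {
        angle_domain(singletons = if (om_cis) off$h_cis else off$h_trans)
      } else {
        angle_domain(singletons = if (om_cis) off$ca_cis else off$ca_trans)
      }
    } else if (kind[v] == "chi") {
      domains[[v]] <- angle_domain(singletons = c(-off$chi_abs, off$chi_abs))
    }
  }
  base <- rbind(cov, tor, hb, nmr, do.call(rbind, edge_rows))
  vdw <- vdw_bounds(atoms, vdw_table(sigma = config$sigma_vdw), existing = base)
  constraints <- rbind(base, vdw)

  inst <- assemble_instance(order, constraints, config, domains = domains,
                            atoms = atoms)
  inst$kind <- kind
  inst$geom <- geom
  inst$helix <- helix
  inst$sequence <- aa
  inst$aux <- protein_aux_specs(aa, geom, cis)
  inst$helix_checks <- protein_helix_checks(helix, n)
  inst$u_plus <- floyd_warshall_refine(inst)
  inst
}

# auxiliary placements: carbonyl O of residue i once H(i+1) is embedded;
# CB of residue i once C(i) is embedded (with the chirality check).
protein_aux_specs <- function(aa, geom, cis = integer(0)) {
  n <- length(aa)
  aux <- list()
  for (i in seq_len(n - 1L)) {
    om <- if (i %in% cis) 0 else pi
    aux[[length(aux) + 1L]] <- list(
      type = "O", key = paste0(i, ":O"),
      trigger = 7L * i + 2L,   # rank of H(i+1)
      anchors = paste0(c(i, i + 1L, i + 1L), ":", c("C", "N", "H")),
      dists = oxygen_distances(geom, omega = om))
  }
  for (i in seq_len(n)) {
    if (aa[i] == "G") next
    aux[[length(aux) + 1L]] <- list(
      type = "CB", key = paste0(i, ":CB"),
      trigger = 7L * i,        # rank of C(i)
      anchors = paste0(i, ":", c("CA", "HA", "N", "C")),
      dists = cbeta_distances(geom))
  }
  aux
}

# helix hydrogen-bond checks, fired when H(i) is embedded
protein_helix_checks <- function(helix, n) {
  if (is.null(helix)) return(NULL)
  hp <- helix_pairs(helix, n)
  if (is.null(hp)) return(NULL)
  lapply(seq_len(nrow(hp)), function(r) {
    j <- hp[r, 1L]; i <- hp[r, 2L]
    list(pair = c(j, i), trigger = 7L * (i - 1L) + 2L,  # rank of H(i)
         o = paste0(j, ":O"), c = paste0(j, ":C"),
         n = paste0(i, ":N"), h = paste0(i, ":H"))
  })
}
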