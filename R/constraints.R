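# Construction of the distance-constraint set over the physical atoms:
# covalent exact distances, steric lower bounds, helix hydrogen-bond
# intervals, torsion-derived 1-4 bounds, and shortest-path refinement of
# upper bounds.

# physical atoms of the modelled chain: backbone + amide H + HA per
# residue, carbonyl O for residues 1..n-1 (the C-terminal carbonyl has no
# following peptide plane to define it), CB for non-glycine residues.
atoms_table <- function(aa) {
  n <- length(aa)
  res <- integer(0); name <- character(0)
  for (i in seq_len(n)) {
    nm <- c("N", "H", "CA", "HA", "C")
    if (i < n) nm <- c(nm, "O")
    if (aa[i] != "G") nm <- c(nm, "CB")
    res <- c(res, rep(i, length(nm)))
    name <- c(name, nm)
  }
  data.frame(key = paste0(res, ":", name), res = res, name = name,
             element = vapply(name, atom_element, ""),
             stringsAsFactors = FALSE)
}

# covalent bond list (pairs of atom keys)
bond_list <- function(atoms) {
  ab <- list()
  n <- max(atoms$res)
  has <- function(k) k %in% atoms$key
  add <- function(a, b) if (has(a) && has(b)) ab[[length(ab) + 1L]] <<- c(a, b)
  for (i in seq_len(n)) {
    add(paste0(i, ":N"), paste0(i, ":H"))
    add(paste0(i, ":N"), paste0(i, ":CA"))
    add(paste0(i, ":CA"), paste0(i, ":HA"))
    add(paste0(i, ":CA"), paste0(i, ":C"))
    add(paste0(i, ":CA"), paste0(i, ":CB"))
    add(paste0(i, ":C"), paste0(i, ":O"))
    if (i < n) add(paste0(i, ":C"), paste0(i + 1L, ":N"))
  }
  do.call(rbind, ab)
}

# matrix of covalent bond-path lengths up to 'maxd' (Inf beyond), by BFS
bond_separation <- function(atoms, maxd = 3L) {
  m <- nrow(atoms)
  bl <- bond_list(atoms)
  adj <- vector("list", m)
  ia <- match(bl[, 1L], atoms$key); ib <- match(bl[, 2L], atoms$key)
  for (r in seq_along(ia)) {
    adj[[ia[r]]] <- c(adj[[ia[r]]], ib[r])
    adj[[ib[r]]] <- c(adj[[ib[r]]], ia[r])
  }
  sep <- matrix(Inf, m, m, dimnames = list(atoms$key, atoms$key))
  diag(sep) <- 0
  for (s in seq_len(m)) {
    frontier <- s
    for (d in seq_len(maxd)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[sep[s, nxt] > d]
      if (!length(nxt)) break
      sep[s, nxt] <- d
      frontier <- nxt
    }
  }
  sep
}

#' Covalent exact distance constraints
#'
#' Exact distances for every bonded pair (bond-length table), every pair
#' two bonds apart (law of cosines over the table angle), and the 1-4
#' pairs across the peptide bond whose torsion is fixed by plane planarity
#' (CA-CA', CA-H', O-H', O-CA' at the configured omega).
#'
#' @param atoms atom table as built internally from a sequence (data frame
#'   with `key`, `res`, `name`); see [build_protein_instance()].
#' @param geom a [covalent_geometry()].
#' @param cis integer vector of residues i whose peptide bond i -> i+1 is
#'   cis (omega = 0); all others are trans.
#' @return data frame with columns `a`, `b` (atom keys), `lower`, `upper`
#'   (equal, Angstrom) and `source = "covalent"`.
#' @export
covalent_constraints <- function(atoms, geom = covalent_geometry(), cis = integer(0)) {
  sep <- bond_separation(atoms)
  m <- nrow(atoms)
  rows <- vector("list", 256L); nr <- 0L
  fixed14 <- c("CA-+H", "O-+H", "O-+CA", "CA-+CA")
  for (p in seq_len(m - 1L)) {
    for (q in (p + 1L):m) {
      s <- sep[p, q]
      if (!is.finite(s) || s > 3) next
      r1 <- atoms$res[p]; n1 <- atoms$name[p]
      r2 <- atoms$res[q]; n2 <- atoms$name[q]
      if (abs(r1 - r2) > 1) next
      om <- if (min(r1, r2) %in% cis) 0 else pi
      if (s == 3) {
        lo <- min(r1, r2)
        nms <- if (r1 <= r2) c(n1, n2) else c(n2, n1)
        if (r1 == r2 || !paste0(nms[1L], "-+", nms[2L]) %in% fixed14) next
      }
      d <- covalent_pair_distance(geom, r1, n1, r2, n2, omega = om)
      if (is.na(d)) {
        if (s <= 2) {
          stop(sprintf("no covalent table entry for pair %s %s", atoms$key[p],
                       atoms$key[q]), call. = FALSE)
        }
        next
      }
      nr <- nr + 1L
      rows[[nr]] <- data.frame(a = atoms$key[p], b = atoms$key[q],
                               lower = d, upper = d, source = "covalent",
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(nr)])
}

#' Steric (van der Waals) lower bounds
#'
#' For every pair of atoms at least three covalent bonds apart, adds the
#' lower bound `sigma * (r_i + r_j)` with no upper bound. The steric bound
#' is a fallback: it is omitted when the pair already carries a lower
#' bound at least as large, and also when the pair is the subject of an
#' explicit distance constraint (an NMR restraint or a hydrogen-bond
#' window), since such pairs are exactly the ones allowed to approach
#' below the scaled radius sum.
#'
#' @param atoms atom table (see [covalent_constraints()]).
#' @param table a [vdw_table()].
#' @param existing data frame of constraints already in force.
#' @return data frame of constraints with `source = "vdw"` and
#'   `upper = Inf`.
#' @export
vdw_bounds <- function(atoms, table = vdw_table(), existing = NULL) {
  sep <- bond_separation(atoms)
  m <- nrow(atoms)
  r <- table$radii[atoms$element]
  B <- table$sigma * outer(r, r, `+`)
  Lex <- matrix(-Inf, m, m)
  if (!is.null(existing) && nrow(existing)) {
    ia <- match(existing$a, atoms$key); ib <- match(existing$b, atoms$key)
    expl <- existing$source %in% c("nmr", "hbond")
    keep <- which(!is.na(ia) & !is.na(ib))
    for (i in keep) {
      l <- if (expl[i]) Inf else existing$lower[i]
      if (l > Lex[ia[i], ib[i]]) Lex[ia[i], ib[i]] <- Lex[ib[i], ia[i]] <- l
    }
  }
  pick <- which(upper.tri(B) & sep >= 3 & Lex < B, arr.ind = TRUE)
  if (!nrow(pick)) return(NULL)
  data.frame(a = atoms$key[pick[, 1L]], b = atoms$key[pick[, 2L]],
             lower = B[pick], upper = Inf, source = "vdw",
             stringsAsFactors = FALSE)
}

#' Alpha-helix definition
#'
#' Residue ranges declared helical, together with the hydrogen-bond
#' distance window, the DSSP-style energy acceptance threshold and
#' constants, and the three directionality angle windows (degrees).
#'
#' @param ranges list of integer pairs `c(first, last)` (or a single
#'   pair).
#' @param hbond O(i-4)..H(i) distance window in Angstrom.
#' @param energy_threshold acceptance threshold for the electrostatic
#'   hydrogen-bond energy (DSSP convention units).
#' @param q1,q2,f energy constants.
#' @param theta,theta1,theta2 angle windows in degrees for the angles
#'   theta (C->O vs O->H), theta' (N->H vs H->O) and theta'' (angle at H
#'   in O..H-N).
#' @return object of class `helix_definition`.
#' @export
helix_definition <- function(ranges,
                             hbond = c(1.9, 3.0),
                             energy_threshold = -0.5,
                             q1 = 0.42, q2 = 0.2, f = 332,
                             theta = c(0, 70), theta1 = c(0, 90),
                             theta2 = c(110, 180)) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  for (r in ranges) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1) stop("invalid helix range")
  }
  stopifnot(hbond[1L] <= hbond[2L], theta[1L] <= theta[2L],
            theta1[1L] <= theta1[2L], theta2[1L] <= theta2[2L])
  structure(list(ranges = ranges, hbond = hbond,
                 energy_threshold = energy_threshold, q1 = q1, q2 = q2, f = f,
                 theta = theta, theta1 = theta1, theta2 = theta2),
            class = "helix_definition")
}

# (i-4, i) residue pairs fully inside one helix range
helix_pairs <- function(helix, n) {
  out <- NULL
  for (r in helix$ranges) {
    hi <- min(r[2L], n)
    if (hi - r[1L] >= 4) {
      i <- seq(r[1L] + 4L, hi)
      out <- rbind(out, cbind(i - 4L, i))
    }
  }
  out
}

#' Helix hydrogen-bond interval constraints
#'
#' One O(i-4)..H(i) distance interval per residue pair `(i-4, i)` lying
#' fully inside a declared helix range.
#'
#' @param helix a [helix_definition()].
#' @param n number of residues in the chain.
#' @return data frame of constraints with `source = "hbond"`, or `NULL`
#'   when no pair qualifies.
#' @export
helix_hbond_constraints <- function(helix, n) {
  hp <- helix_pairs(helix, n)
  if (is.null(hp)) return(NULL)
  data.frame(a = paste0(hp[, 1L], ":O"), b = paste0(hp[, 2L], ":H"),
             lower = helix$hbond[1L], upper = helix$hbond[2L],
             source = "hbond", stringsAsFactors = FALSE)
}

#' Distance constraints derived from phi/psi torsion domains
#'
#' For each residue, converts the allowed phi domain into an interval on
#' the 1-4 distance C(i-1)..C(i) and the allowed psi domain into an
#' interval on N(i)..N(i+1), using the torsion-to-distance envelope.
#'
#' @param phi_domains,psi_domains lists of [angle_domain()]s indexed by
#'   residue (entries may be `NULL`).
#' @param n number of residues.
#' @param geom a [covalent_geometry()].
#' @return data frame of constraints with `source = "torsion"`, or `NULL`.
#' @export
torsion_constraints <- function(phi_domains, psi_domains, n,
                                geom = covalent_geometry()) {
  rows <- list()
  lb <- function(k) bond_length(geom, k)
  cpd <- function(r1, n1, r2, n2) covalent_pair_distance(geom, r1, n1, r2, n2)
  for (i in seq_len(n)) {
    if (i >= 2 && !is.null(phi_domains[[i]])) {
      # quadruple C(i-1), N(i), CA(i), C(i); torsion = phi
      env <- torsion_domain_bounds(phi_domains[[i]],
                                   d_ij = lb("C-+N"), d_jk = lb("N-CA"),
                                   d_kl = lb("CA-C"),
                                   d_ik = cpd(i - 1L, "C", i, "CA"),
                                   d_lj = cpd(i, "C", i, "N"))
      rows[[length(rows) + 1L]] <- data.frame(
        a = paste0(i - 1L, ":C"), b = paste0(i, ":C"),
        lower = env$lower, upper = env$upper, source = "torsion",
        stringsAsFactors = FALSE)
    }
    if (i < n && !is.null(psi_domains[[i]])) {
      # quadruple N(i), CA(i), C(i), N(i+1); torsion = psi
      env <- torsion_domain_bounds(psi_domains[[i]],
                                   d_ij = lb("N-CA"), d_jk = lb("CA-C"),
                                   d_kl = lb("C-+N"),
                                   d_ik = cpd(i, "N", i, "C"),
                                   d_lj = cpd(i, "CA", i + 1L, "N"))
      rows[[length(rows) + 1L]] <- data.frame(
        a = paste0(i, ":N"), b = paste0(i + 1L, ":N"),
        lower = env$lower, upper = env$upper, source = "torsion",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Refine upper distance bounds by all-pairs shortest paths
#'
#' In the graph whose edge weights are upper distance bounds, the shortest
#' path between two atoms is a valid over-estimate of their distance in
#' any feasible realization (triangle-inequality bound smoothing). The
#' refinement is computed with the Floyd-Warshall algorithm and is
#' idempotent.
#'
#' @param x either a square matrix of upper bounds (`Inf` where unknown)
#'   or a `dgp_instance`, in which case the matrix is assembled from all
#'   of the instance's constraints (interval edges contribute their upper
#'   endpoint) over the distinct physical atoms.
#' @return matrix of refined upper bounds `u+ <= u` satisfying
#'   `u+(i,k) <= u+(i,j) + u+(j,k)` for all triples.
#' @export
floyd_warshall_refine <- function(x) {
  U <- if (inherits(x, "dgp_instance")) instance_upper_matrix(x) else as.matrix(x)
  if (nrow(U) != ncol(U)) stop("upper-bound matrix must be square")
  U <- pmin(U, t(U))
  diag(U) <- 0
  for (k in seq_len(nrow(U))) {
    U <- pmin(U, outer(U[, k], U[k, ], `+`))
  }
  U
}
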