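# The pruning devices. Each device is a pure predicate over a (partial)
# embedding, returning an accept/reject result with a human-readable
# reason; the search engine applies vectorized internal equivalents.

#' Pruning device result
#'
#' @param accepted logical.
#' @param device device tag (`"ddf"`, `"taf"`, `"dsp"`, `"chi"`,
#'   `"helix"`, ...).
#' @param reason character; required (non-empty) when rejected.
#' @return object of class `prune_result`.
#' @export
prune_result <- function(accepted, device, reason = "") {
  if (!accepted && !nzchar(reason)) stop("a rejection needs a reason")
  structure(list(accepted = accepted, device = device, reason = reason),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("[%s] %s%s\n", x$device,
              if (x$accepted) "accept" else "reject",
              if (nzchar(x$reason)) paste0(": ", x$reason) else ""))
  invisible(x)
}

#' Direct distance feasibility (DDF)
#'
#' Accepts a candidate position iff every constrained distance from the
#' new atom to the already-embedded atoms lies within its bounds, widened
#' additively and inclusively by the position tolerance.
#'
#' @param x_k candidate position (length 3).
#' @param others n x 3 matrix of embedded atom positions.
#' @param lower,upper bound vectors aligned with the rows of `others`
#'   (use 0 / `Inf` where unconstrained).
#' @param eps_x position tolerance (Angstrom).
#' @param labels optional row labels for the rejection reason.
#' @return a [prune_result()].
#' @export
ddf_check <- function(x_k, others, lower, upper, eps_x = 0, labels = NULL) {
  others <- matrix(others, ncol = 3L)
  d <- sqrt(colSums((t(others) - x_k)^2))
  bad <- which(d < lower - eps_x - 1e-12 | d > upper + eps_x + 1e-12)
  if (!length(bad)) return(prune_result(TRUE, "ddf"))
  b <- bad[1L]
  lab <- if (!is.null(labels)) labels[b] else paste("pair", b)
  prune_result(FALSE, "ddf",
               sprintf("%s: d = %.3f outside [%.3f, %.3f] +/- %.3g",
                       lab, d[b], lower[b], upper[b], eps_x))
}

#' Torsion-angle feasibility (TAF)
#'
#' Accepts iff the signed dihedral of the quadruple lies in the domain
#' expanded by the angle tolerance. The sign is respected: an angle whose
#' mirror image would fit the domain is still rejected.
#'
#' @param p1,p2,p3,p4 quadruple coordinates.
#' @param dom an [angle_domain()].
#' @param eps_t angle tolerance in radians.
#' @return a [prune_result()].
#' @export
taf_check <- function(p1, p2, p3, p4, dom, eps_t = 0) {
  xi <- tryCatch(dihedral_angle(p1, p2, p3, p4), error = function(e) NULL)
  if (is.null(xi)) return(prune_result(FALSE, "taf", "degenerate quadruple"))
  if (domain_contains(dom, xi, tol = eps_t)) return(prune_result(TRUE, "taf"))
  prune_result(FALSE, "taf",
               sprintf("torsion %.2f deg outside permitted domain", rad2deg(xi)))
}

#' Shortest-path distance pruning (DSP)
#'
#' For an embedded pair (i, j) and a new atom k whose distance to i is
#' known, the embedding of k is infeasible when
#' `||x_i - x_j|| - d_ik > u_jk` (strictly), `u_jk` being the refined
#' upper bound from [floyd_warshall_refine()].
#'
#' @param d_ij realized distance between the embedded atoms i and j.
#' @param d_ik known distance from k to i.
#' @param u_jk refined upper bound on the (j, k) distance.
#' @return a [prune_result()].
#' @export
dsp_check <- function(d_ij, d_ik, u_jk) {
  if (d_ij - d_ik > u_jk) {
    return(prune_result(FALSE, "dsp",
                        sprintf("||xi - xj|| - d_ik = %.3f exceeds u+ = %.3f",
                                d_ij - d_ik, u_jk)))
  }
  prune_result(TRUE, "dsp")
}

#' Amino-acid chirality (CHI)
#'
#' CORN-rule check restated as a signed torsion: the L-form requires the
#' dihedral over C, N, CB, HA to be positive, the D-form the dihedral over
#' C, CB, N, HA. Glycine has no C-beta and is accepted trivially.
#'
#' @param vC,vN,vCB,vHA atom coordinates; `vCB = NULL` for glycine.
#' @param form `"L"` or `"D"`.
#' @return a [prune_result()].
#' @export
chi_check <- function(vC, vN, vCB, vHA, form = c("L", "D")) {
  form <- match.arg(form)
  if (is.null(vCB)) return(prune_result(TRUE, "chi"))
  xi <- if (form == "L") dihedral_angle(vC, vN, vCB, vHA)
        else dihedral_angle(vC, vCB, vN, vHA)
  if (xi > 0) return(prune_result(TRUE, "chi"))
  prune_result(FALSE, "chi",
               sprintf("%s-form torsion %.1f deg not positive", form, rad2deg(xi)))
}

#' DSSP-style electrostatic hydrogen-bond energy
#'
#' `E = q1 q2 (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) f` for the carbonyl
#' (C=O) of the acceptor residue and the amide (N-H) of the donor residue.
#' A well-aligned backbone hydrogen bond gives a markedly negative value.
#'
#' @param d_on,d_ch,d_oh,d_cn the four inter-atomic distances (Angstrom,
#'   positive).
#' @param q1,q2,f constants (DSSP convention: partial charges 0.42 and
#'   0.2, conversion factor 332; energy in kcal/mol).
#' @return energy value.
#' @export
hbond_energy <- function(d_on, d_ch, d_oh, d_cn, q1 = 0.42, q2 = 0.2, f = 332) {
  d <- c(d_on, d_ch, d_oh, d_cn)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("hydrogen-bond distances must be positive", call. = FALSE)
  }
  q1 * q2 * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn) * f
}

# core of the alpha-helix device given the four placed atoms
helix_check_atoms <- function(xO, xC, xN, xH, helix, eps_x = 0, eps_t = 0) {
  d_oh <- v_norm(xO - xH)
  if (d_oh < helix$hbond[1L] - eps_x - 1e-12 ||
      d_oh > helix$hbond[2L] + eps_x + 1e-12) {
    return(prune_result(FALSE, "helix",
                        sprintf("O..H distance %.3f outside [%.2f, %.2f]",
                                d_oh, helix$hbond[1L], helix$hbond[2L])))
  }
  en <- hbond_energy(v_norm(xO - xN), v_norm(xC - xH), d_oh, v_norm(xC - xN),
                     helix$q1, helix$q2, helix$f)
  if (en >= helix$energy_threshold) {
    return(prune_result(FALSE, "helix",
                        sprintf("H-bond energy %.3f not below %.2f", en,
                                helix$energy_threshold)))
  }
  ang <- function(u, v) acos(clamp_cos(sum(u * v) / (v_norm(u) * v_norm(v))))
  th <- rad2deg(ang(xO - xC, xH - xO))   # C->O vs O->H
  th1 <- rad2deg(ang(xH - xN, xO - xH))  # N->H vs H->O
  th2 <- rad2deg(point_angle(xO, xH, xN))
  et <- rad2deg(eps_t)
  win <- function(x, w) x >= w[1L] - et - 1e-9 && x <= w[2L] + et + 1e-9
  if (!win(th, helix$theta)) {
    return(prune_result(FALSE, "helix",
                        sprintf("theta = %.1f deg outside [%g, %g]", th,
                                helix$theta[1L], helix$theta[2L])))
  }
  if (!win(th1, helix$theta1)) {
    return(prune_result(FALSE, "helix",
                        sprintf("theta' = %.1f deg outside [%g, %g]", th1,
                                helix$theta1[1L], helix$theta1[2L])))
  }
  if (!win(th2, helix$theta2)) {
    return(prune_result(FALSE, "helix",
                        sprintf("theta'' = %.1f deg outside [%g, %g]", th2,
                                helix$theta2[1L], helix$theta2[2L])))
  }
  prune_result(TRUE, "helix")
}

#' Alpha-helix geometry device
#'
#' Four criteria for an `(i-4, i)` residue pair declared helical: (i) the
#' O(i-4)..H(i) distance lies in the hydrogen-bond window; (ii) the
#' DSSP-style electrostatic energy of the bond falls below the acceptance
#' threshold; (iii) the phi/psi torsions of the two residues pass the
#' torsion-angle device (checked when all defining atoms are available);
#' (iv) the three directionality angles theta, theta', theta'' lie in
#' their windows.
#'
#' @param conf a `conformation` (see [build_ideal_helix()]) or any matrix
#'   of coordinates with row names `"res:atom"`.
#' @param pair integer pair `c(i - 4, i)`.
#' @param helix a [helix_definition()].
#' @param eps_x position tolerance (Angstrom).
#' @param eps_t angle tolerance (degrees at this interface).
#' @param phi_domains,psi_domains per-residue [angle_domain()] lists for
#'   criterion (iii); defaults to the helical windows.
#' @return a [prune_result()].
#' @export
helix_check <- function(conf, pair, helix, eps_x = 0, eps_t = 0,
                        phi_domains = NULL, psi_domains = NULL) {
  X <- if (inherits(conf, "conformation")) conf$xyz else as.matrix(conf)
  gx <- function(k) {
    if (!k %in% rownames(X)) stop("missing atom ", k, call. = FALSE)
    X[k, ]
  }
  j <- pair[1L]; i <- pair[2L]
  if (i - j != 4L) stop("helix device applies to (i-4, i) pairs", call. = FALSE)
  res <- helix_check_atoms(gx(paste0(j, ":O")), gx(paste0(j, ":C")),
                           gx(paste0(i, ":N")), gx(paste0(i, ":H")),
                           helix, eps_x = eps_x, eps_t = deg2rad(eps_t))
  if (!res$accepted) return(res)
  # criterion (iii): phi/psi of the two residues, where computable
  hd <- default_torsion_domains(helix = TRUE)
  for (r in c(j, i)) {
    phi <- backbone_torsion(X, r, "phi")
    if (!is.null(phi)) {
      dom <- hd$phi
      if (!is.null(phi_domains) && length(phi_domains) >= r &&
          !is.null(phi_domains[[r]])) dom <- phi_domains[[r]]
      if (!domain_contains(dom, phi, tol = deg2rad(eps_t))) {
        return(prune_result(FALSE, "helix",
                            sprintf("phi(%d) = %.1f deg outside its domain",
                                    r, rad2deg(phi))))
      }
    }
    psi <- backbone_torsion(X, r, "psi")
    if (!is.null(psi)) {
      dom <- hd$psi
      if (!is.null(psi_domains) && length(psi_domains) >= r &&
          !is.null(psi_domains[[r]])) dom <- psi_domains[[r]]
      if (!domain_contains(dom, psi, tol = deg2rad(eps_t))) {
        return(prune_result(FALSE, "helix",
                            sprintf("psi(%d) = %.1f deg outside its domain",
                                    r, rad2deg(psi))))
      }
    }
  }
  prune_result(TRUE, "helix")
}

# phi or psi of residue r from a coordinate matrix with "res:atom" row
# names; NULL when a defining atom is absent
backbone_torsion <- function(X, r, which = c("phi", "psi")) {
  which <- match.arg(which)
  ks <- if (which == "phi") {
    c(paste0(r - 1L, ":C"), paste0(r, ":N"), paste0(r, ":CA"), paste0(r, ":C"))
  } else {
    c(paste0(r, ":N"), paste0(r, ":CA"), paste0(r, ":C"), paste0(r + 1L, ":N"))
  }
  if (!all(ks %in% rownames(X))) return(NULL)
  dihedral_angle(X[ks[1L], ], X[ks[2L], ], X[ks[3L], ], X[ks[4L], ])
}
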