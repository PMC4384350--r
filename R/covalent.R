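# Standard backbone covalent geometry (Engh/Huber-class small-molecule
# values) and quantities derived from it: 1-3 distances, fixed-torsion 1-4
# distances, the tetrahedral C-alpha frame used for HA/CB placement, and
# the exact distance sets fed to the oxygen and C-beta linear solves.

#' Default covalent geometry tables
#'
#' Bond lengths (Angstrom) and bond angles (degrees) for the protein
#' backbone and C-beta, plus the peptide torsion convention. Any entry may
#' be overridden. Atom names follow PDB v3 (`H` is the backbone amide
#' hydrogen); `+`-prefixed names refer to the next residue.
#'
#' @param bonds named numeric vector of overrides, names like `"CA-C"`.
#' @param angles named numeric vector of overrides (degrees), names like
#'   `"N-CA-C"`.
#' @return object of class `covalent_geometry` with elements `bonds`,
#'   `angles` (radians) and `angles_deg`.
#' @export
covalent_geometry <- function(bonds = NULL, angles = NULL) {
  b <- c("N-H" = 1.01, "N-CA" = 1.458, "CA-C" = 1.525, "C-+N" = 1.329,
         "C-O" = 1.231, "CA-HA" = 1.090, "CA-CB" = 1.521)
  a <- c("C-N-CA" = 121.7, "N-CA-C" = 111.2, "CA-C-+N" = 116.2,
         "CA-C-O" = 120.8, "H-N-CA" = 118.2, "N-CA-HA" = 108.0,
         "C-CA-HA" = 109.3, "N-CA-CB" = 110.4, "C-CA-CB" = 110.5)
  if (!is.null(bonds)) {
    unknown <- setdiff(names(bonds), names(b))
    if (length(unknown)) stop("unknown bond override: ", paste(unknown, collapse = ", "))
    b[names(bonds)] <- bonds
  }
  if (!is.null(angles)) {
    unknown <- setdiff(names(angles), names(a))
    if (length(unknown)) stop("unknown angle override: ", paste(unknown, collapse = ", "))
    a[names(angles)] <- angles
  }
  if (any(b <= 0.8 | b >= 2.0)) stop("bond lengths must lie in (0.8, 2.0) A")
  if (any(a <= 90 | a >= 135)) stop("bond angles must lie in (90, 135) degrees")
  # sp2 closures around the amide N and the carbonyl C
  a2 <- c(a, "C-N-H" = 360 - a[["C-N-CA"]] - a[["H-N-CA"]],
          "O-C-+N" = 360 - a[["CA-C-+N"]] - a[["CA-C-O"]])
  structure(list(bonds = b, angles = deg2rad(a2), angles_deg = a2),
            class = "covalent_geometry")
}

#' Van der Waals radius table
#'
#' Element radii (Angstrom) and the scale factor applied to radius sums to
#' form steric lower bounds `sigma * (r_i + r_j)` on non-bonded pairs.
#'
#' @param sigma scale factor in `[0, 1]` (typically around 0.85).
#' @param radii named numeric overrides.
#' @return object of class `vdw_table`.
#' @export
vdw_table <- function(sigma = 0.85, radii = NULL) {
  r <- c(O = 1.4, H = 1.0, C = 1.7, N = 1.5)
  if (!is.null(radii)) r[names(radii)] <- radii
  if (any(r <= 0)) stop("radii must be positive")
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  structure(list(radii = r, sigma = sigma), class = "vdw_table")
}

bond_length <- function(geom, key) {
  v <- geom$bonds[key]
  if (anyNA(v)) stop("no bond-length entry for ", key[is.na(v)][1L], call. = FALSE)
  unname(v)
}

bond_angle <- function(geom, key) {
  v <- geom$angles[key]
  if (anyNA(v)) stop("no bond-angle entry for ", key[is.na(v)][1L], call. = FALSE)
  unname(v)
}

# 1-3 distance across two bonds via the law of cosines
pair13_distance <- function(len_ab, len_bc, angle_abc) {
  sqrt(len_ab^2 + len_bc^2 - 2 * len_ab * len_bc * cos(angle_abc))
}

# Exact distance between two backbone atoms of the same or adjacent
# residue, from the covalent table: bonds, 1-3 angles, and 1-4 pairs whose
# torsion is fixed by peptide planarity. Returns NA for pairs whose
# distance depends on a free torsion (phi/psi).
# a and b are lists(res=, name=); res2 - res1 must be 0 or 1.
covalent_pair_distance <- function(geom, res1, name1, res2, name2,
                                   omega = pi) {
  if (res1 > res2) {
    tmp <- res1; res1 <- res2; res2 <- tmp
    tmp <- name1; name1 <- name2; name2 <- tmp
  }
  same <- res1 == res2
  lb <- function(k) bond_length(geom, k)
  ab <- function(k) bond_angle(geom, k)
  if (same) {
    # try both orientations of the unordered same-residue pair
    key <- paste0(name1, "-", name2)
    alt <- paste0(name2, "-", name1)
    lookup <- function(key) switch(key,
      "H-N" = , "N-H" = lb("N-H"),
      "CA-N" = , "N-CA" = lb("N-CA"),
      "CA-C" = lb("CA-C"),
      "CA-HA" = lb("CA-HA"),
      "CA-CB" = lb("CA-CB"),
      "C-O" = lb("C-O"),
      "HA-N" = , "N-HA" = pair13_distance(lb("N-CA"), lb("CA-HA"), ab("N-CA-HA")),
      "CA-H" = , "H-CA" = pair13_distance(lb("N-H"), lb("N-CA"), ab("H-N-CA")),
      "C-HA" = , "HA-C" = pair13_distance(lb("CA-C"), lb("CA-HA"), ab("C-CA-HA")),
      "C-N" = , "N-C" = pair13_distance(lb("N-CA"), lb("CA-C"), ab("N-CA-C")),
      "C-CB" = , "CB-C" = pair13_distance(lb("CA-C"), lb("CA-CB"), ab("C-CA-CB")),
      "CB-N" = , "N-CB" = pair13_distance(lb("N-CA"), lb("CA-CB"), ab("N-CA-CB")),
      "CA-O" = , "O-CA" = pair13_distance(lb("CA-C"), lb("C-O"), ab("CA-C-O")),
      # HA..CB measured on the consistent tetrahedral C-alpha frame
      "CB-HA" = , "HA-CB" = unname(cbeta_distances(geom)[["dk2"]]),
      NA_real_
    )
    d <- lookup(key)
    if (is.na(d) && alt != key) d <- lookup(alt)
    d
  } else {
    key <- paste0(name1, "-+", name2)
    switch(key,
      "C-+N" = lb("C-+N"),
      "C-+H" = pair13_distance(lb("C-+N"), lb("N-H"), ab("C-N-H")),
      "C-+CA" = pair13_distance(lb("C-+N"), lb("N-CA"), ab("C-N-CA")),
      "CA-+N" = pair13_distance(lb("CA-C"), lb("C-+N"), ab("CA-C-+N")),
      "O-+N" = pair13_distance(lb("C-O"), lb("C-+N"), ab("O-C-+N")),
      # 1-4 across the peptide bond, fixed by planarity: H(i+1) is trans
      # to CA(i) for a trans peptide (torsion CA-C-N-H = omega - pi)
      "CA-+H" = torsion_distance(
        wrap_angle(omega - pi),
        d_ij = lb("CA-C"), d_jk = lb("C-+N"), d_kl = lb("N-H"),
        d_ik = covalent_pair_distance(geom, res1, "CA", res2, "N"),
        d_lj = covalent_pair_distance(geom, res2, "H", res1, "C")),
      # O(i) is cis to H(i+1) for a trans peptide (torsion O-C-N-H = omega)
      "O-+H" = torsion_distance(
        omega,
        d_ij = lb("C-O"), d_jk = lb("C-+N"), d_kl = lb("N-H"),
        d_ik = covalent_pair_distance(geom, res1, "O", res2, "N"),
        d_lj = covalent_pair_distance(geom, res2, "H", res1, "C")),
      # torsion CA-C-N-CA' is the peptide omega itself
      "CA-+CA" = torsion_distance(
        omega,
        d_ij = lb("CA-C"), d_jk = lb("C-+N"), d_kl = lb("N-CA"),
        d_ik = covalent_pair_distance(geom, res1, "CA", res2, "N"),
        d_lj = covalent_pair_distance(geom, res1, "C", res2, "CA")),
      # torsion O-C-N-CA' = omega + pi (O opposite CA within the plane)
      "O-+CA" = torsion_distance(
        wrap_angle(omega + pi),
        d_ij = lb("C-O"), d_jk = lb("C-+N"), d_kl = lb("N-CA"),
        d_ik = covalent_pair_distance(geom, res1, "O", res2, "N"),
        d_lj = covalent_pair_distance(geom, res1, "C", res2, "CA")),
      NA_real_
    )
  }
}

# Unit directions from CA to N, C, HA and CB for an L-form residue, from
# the angle table. HA and CB directions are solved from their two angles
# to the N and C directions; the side split is fixed so that the CORN
# torsion dihedral(C, N, CB, HA) is positive (L-form).
local_ca_frame <- function(geom) {
  anc <- bond_angle(geom, "N-CA-C")
  n_hat <- c(1, 0, 0)
  c_hat <- c(cos(anc), sin(anc), 0)
  solve_dir <- function(cos_n, cos_c, side) {
    M <- rbind(c(1, cos(anc)), c(cos(anc), 1))
    ab <- solve(M, c(cos_n, cos_c))
    g2 <- 1 - (ab[1L]^2 + ab[2L]^2 + 2 * ab[1L] * ab[2L] * cos(anc))
    if (g2 < 0) stop("inconsistent tetrahedral angles", call. = FALSE)
    ab[1L] * n_hat + ab[2L] * c_hat + side * sqrt(g2) * c(0, 0, 1)
  }
  mk <- function(side) {
    ha <- solve_dir(cos(bond_angle(geom, "N-CA-HA")),
                    cos(bond_angle(geom, "C-CA-HA")), side)
    cb <- solve_dir(cos(bond_angle(geom, "N-CA-CB")),
                    cos(bond_angle(geom, "C-CA-CB")), -side)
    list(ha = ha, cb = cb)
  }
  for (side in c(1, -1)) {
    f <- mk(side)
    xCA <- c(0, 0, 0)
    xN <- bond_length(geom, "N-CA") * n_hat
    xC <- bond_length(geom, "CA-C") * c_hat
    xHA <- bond_length(geom, "CA-HA") * f$ha
    xCB <- bond_length(geom, "CA-CB") * f$cb
    if (dihedral_angle(xC, xN, xCB, xHA) > 0) {
      return(list(n = n_hat, c = c_hat, ha = f$ha, cb = f$cb))
    }
  }
  stop("could not orient an L-form C-alpha frame", call. = FALSE)
}

# Exact distances for the carbonyl-oxygen linear solve: O to C (bond), to
# N(i+1) (1-3) and to H(i+1) (planar 1-4 at the fixed peptide torsion).
oxygen_distances <- function(geom, omega = pi) {
  c(dk1 = bond_length(geom, "C-O"),
    dk2 = covalent_pair_distance(geom, 1L, "O", 2L, "N"),
    dk3 = covalent_pair_distance(geom, 1L, "O", 2L, "H", omega = omega))
}

# Exact distances for the C-beta linear solve: CB to CA (bond), HA
# (measured on the consistent tetrahedral frame), N and C (1-3 angles).
cbeta_distances <- function(geom) {
  fr <- local_ca_frame(geom)
  d_ha <- v_norm(bond_length(geom, "CA-CB") * fr$cb -
                 bond_length(geom, "CA-HA") * fr$ha)
  c(dk1 = bond_length(geom, "CA-CB"),
    dk2 = d_ha,
    dk3 = covalent_pair_distance(geom, 1L, "CB", 1L, "N"),
    dk4 = covalent_pair_distance(geom, 1L, "C", 1L, "CB"))
}

# element of a backbone atom name
atom_element <- function(name) substr(sub("^([0-9]*)", "", name), 1L, 1L)
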