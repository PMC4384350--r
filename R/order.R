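# The repetition order of backbone atoms parsed by the tree search. Each
# residue contributes the seven vertices
#   N, H, CA, N*, HA, CA*, C        (* = repeated atom)
# and the chain is closed by the two trailing duplicates HA(n)*, CA(n)**,
# giving 7 n + 2 vertices in total. The repetitions guarantee that every
# vertex v > 3 is tied to its three immediate predecessors v-1, v-2, v-3 by
# exact distances ({v,v-1}, {v,v-2}: bonds or bond angles) together with a
# {v,v-3} distance that is exact (duplicates, angle- or omega-derived) or a
# phi/psi torsion interval. See the methods vignette for the full
# derivation of the adjacency structure.

#' Parse a one-letter amino-acid sequence
#'
#' Glycine is handled specially downstream (no C-beta, no chirality
#' check); proline is rejected because the ring constrains phi in a way
#' the backbone order does not represent.
#'
#' @param seq one-letter sequence string, or an integer residue count (all
#'   alanine).
#' @return character vector of one-letter codes.
#' @export
parse_sequence <- function(seq) {
  if (is.numeric(seq)) {
    if (!is_count(seq)) stop("residue count must be a positive integer", call. = FALSE)
    return(rep("A", seq))
  }
  aa <- strsplit(toupper(gsub("\\s", "", seq)), "")[[1L]]
  valid <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1L]]
  if (any(aa == "P")) {
    stop("proline is not supported: its ring constrains the backbone in a way ",
         "the atom order does not represent (substitute alanine)", call. = FALSE)
  }
  bad <- setdiff(aa, valid)
  if (length(bad)) stop("unknown residue code: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(aa) < 1L) stop("empty sequence", call. = FALSE)
  aa
}

#' Build the repetition atom order
#'
#' Constructs the ordered vertex list over which the branch-and-prune
#' recursion runs: `7 n + 2` vertices for `n` residues, each vertex v > 3
#' constrained to its three immediate predecessors. Repeated atoms are
#' flagged and point back to the rank of their first occurrence.
#'
#' @param n_residues number of residues (`>= 1`).
#' @return data frame of class `vertex_order` with columns `rank`, `res`,
#'   `atom` (PDB v3 name), `key` (`"res:atom"`), `dup` (logical) and
#'   `dup_of` (rank of first occurrence, `NA` for first appearances).
#' @examples
#' nrow(build_atom_order(15))  # 107 vertices
#' @export
build_atom_order <- function(n_residues) {
  if (!is_count(n_residues)) stop("n_residues must be a positive integer", call. = FALSE)
  n <- as.integer(n_residues)
  block <- c("N", "H", "CA", "N", "HA", "CA", "C")
  dupblk <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  atom <- c(rep(block, n), "HA", "CA")
  res <- c(rep(seq_len(n), each = 7L), n, n)
  dup <- c(rep(dupblk, n), TRUE, TRUE)
  key <- paste0(res, ":", atom)
  rank <- seq_along(atom)
  first <- match(key, key)
  dup_of <- ifelse(rank > first, first, NA_integer_)
  stopifnot(identical(dup, rank > first))
  out <- data.frame(rank = rank, res = res, atom = atom, key = key,
                    dup = dup, dup_of = as.integer(dup_of),
                    stringsAsFactors = FALSE)
  class(out) <- c("vertex_order", "data.frame")
  out
}

# classification of the {v, v-3} edge for each rank of the repetition
# order: what determines the distance to the third predecessor.
#   "dup"    duplicate vertex (distance set known, re-embedded)
#   "exact"  fixed by bonds/angles/peptide planarity
#   "phi"    depends on the backbone torsion phi of this residue
#   "psi"    depends on psi of the previous residue
#   "chi"    chirality improper at C (fixed magnitude, both signs)
#   "init"   ranks 1..3 (no third predecessor)
order_edge_kind <- function(order) {
  n <- max(order$res)
  kind <- character(nrow(order))
  pos <- ((order$rank - 1L) %% 7L) + 1L   # position within the residue block
  kind[pos == 1L] <- "psi"    # N(i) ~ HA(i-1)
  kind[pos == 2L] <- "exact"  # H(i) ~ CA(i-1), fixed peptide torsion
  kind[pos == 3L] <- "exact"  # CA(i) ~ C(i-1), 1-3 angle
  kind[pos == 4L] <- "dup"    # N(i)*
  kind[pos == 5L] <- "phi"    # HA(i) ~ H(i)
  kind[pos == 6L] <- "dup"    # CA(i)*
  kind[pos == 7L] <- "chi"    # C(i) ~ N(i)*, chirality improper
  kind[order$rank > 7L * n] <- "dup"  # trailing HA(n)*, CA(n)**
  kind[order$rank <= 3L] <- "init"
  kind
}
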