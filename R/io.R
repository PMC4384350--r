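# File formats and reports: the whitespace-delimited restraint format,
# multi-model PDB output (and a minimal reader for the check subcommand),
# run configuration serialization, and the violation report.

allowed_atom_names <- c("N", "H", "CA", "HA", "C", "O", "CB")

aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL", W = "TRP",
         Y = "TYR")

#' Parse distance restraints
#'
#' Whitespace-delimited records `res1 atom1 res2 atom2 lower upper [tag]`,
#' one per line; `#` starts a comment. Residues are 1-based, distances in
#' Angstrom, atoms restricted to the backbone/C-beta roster.
#'
#' @param text character vector of lines, a single string with embedded
#'   newlines, or a file path (see [read_restraints()]).
#' @return data frame with columns `res1`, `atom1`, `res2`, `atom2`,
#'   `lower`, `upper`, `tag`.
#' @examples
#' parse_restraints(system.file("extdata", "example_restraints.txt",
#'                              package = "ibpenum"))
#' @export
parse_restraints <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  out <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    f <- strsplit(s, "[[:space:]]+")[[1L]]
    if (length(f) < 6L || length(f) > 7L) {
      stop(sprintf("line %d: expected 'res1 atom1 res2 atom2 lower upper [tag]'", ln),
           call. = FALSE)
    }
    r1 <- suppressWarnings(as.integer(f[1L])); r2 <- suppressWarnings(as.integer(f[3L]))
    lo <- suppressWarnings(as.numeric(f[5L])); up <- suppressWarnings(as.numeric(f[6L]))
    if (anyNA(c(r1, r2, lo, up)) || r1 < 1L || r2 < 1L) {
      stop(sprintf("line %d: malformed numeric field", ln), call. = FALSE)
    }
    a1 <- toupper(f[2L]); a2 <- toupper(f[4L])
    for (a in c(a1, a2)) {
      if (!a %in% allowed_atom_names) {
        stop(sprintf("line %d: unknown atom name '%s'", ln, a), call. = FALSE)
      }
    }
    if (lo > up) stop(sprintf("line %d: lower bound exceeds upper bound", ln), call. = FALSE)
    if (lo < 0) stop(sprintf("line %d: negative lower bound", ln), call. = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      res1 = r1, atom1 = a1, res2 = r2, atom2 = a2, lower = lo, upper = up,
      tag = if (length(f) == 7L) f[7L] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(res1 = integer(0), atom1 = character(0),
                      res2 = integer(0), atom2 = character(0),
                      lower = numeric(0), upper = numeric(0),
                      tag = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @rdname parse_restraints
#' @param path file path.
#' @export
read_restraints <- function(path) parse_restraints(readLines(path))

#' Write conformations as a multi-model PDB file
#'
#' Standard fixed-column PDB v3 output: one `MODEL`/`ENDMDL` block per
#' conformation, `ATOM` records with 1-based residue numbers, chain `A`,
#' occupancy 1.00, B-factor 0.00 and the element column filled;
#' coordinates are written at 0.001 Angstrom precision.
#'
#' @param x a `conformation`, a list of conformations, or a
#'   [solution_store()].
#' @param path output file.
#' @return invisibly, the number of models written; an empty input writes
#'   no file and raises a warning.
#' @export
write_pdb <- function(x, path) {
  confs <- if (inherits(x, "solution_store")) x$confs
           else if (inherits(x, "conformation")) list(x)
           else x
  confs <- Filter(Negate(is.null), confs)
  if (!length(confs)) {
    warning("no conformations to write; file not created")
    return(invisible(0L))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(confs)) {
    cf <- confs[[mi]]
    X <- if (inherits(cf, "conformation")) cf$xyz else as.matrix(cf)
    atoms <- if (inherits(cf, "conformation")) cf$atoms else NULL
    seqc <- if (inherits(cf, "conformation")) cf$sequence else NULL
    writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (r in seq_len(nrow(X))) {
      if (anyNA(X[r, ])) next
      key <- rownames(X)[r]
      res <- as.integer(sub(":.*$", "", key))
      name <- sub("^.*:", "", key)
      serial <- serial + 1L
      resname <- if (!is.null(seqc)) aa3[[seqc[res]]] else "ALA"
      el <- if (!is.null(atoms)) atoms$element[match(key, atoms$key)] else atom_element(name)
      writeLines(sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         serial, name, resname, "A", res,
                         X[r, 1L], X[r, 2L], X[r, 3L], 1, 0, el), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(length(confs))
}

# minimal fixed-column reader for files written by write_pdb (first model)
read_pdb_coords <- function(path) {
  lines <- readLines(path)
  atom <- grep("^ATOM", lines, value = TRUE)
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) {
    first_end <- endm[1L]
    atom <- grep("^ATOM", lines[seq_len(first_end)], value = TRUE)
  }
  if (!length(atom)) stop("no ATOM records in ", path, call. = FALSE)
  name <- trimws(substr(atom, 13L, 16L))
  res <- as.integer(substr(atom, 23L, 26L))
  X <- cbind(as.numeric(substr(atom, 31L, 38L)),
             as.numeric(substr(atom, 39L, 46L)),
             as.numeric(substr(atom, 47L, 54L)))
  rownames(X) <- paste0(res, ":", name)
  X
}

#' Restraint violation report
#'
#' The violation of a restraint with bounds `[l, u]` and realized distance
#' `d` is `max(0, d - u, l - d)`. Reports the number of restraints
#' violated beyond the threshold, the maximum violation, and a
#' per-restraint table.
#'
#' @param conf a `conformation` or coordinate matrix with `"res:atom"` row
#'   names.
#' @param restraints data frame as from [parse_restraints()].
#' @param threshold violation threshold in Angstrom (default 1.0).
#' @return list with `count`, `max_violation` and `table`.
#' @export
violation_report <- function(conf, restraints, threshold = 1.0) {
  X <- if (inherits(conf, "conformation")) conf$xyz else as.matrix(conf)
  k1 <- paste0(restraints$res1, ":", restraints$atom1)
  k2 <- paste0(restraints$res2, ":", restraints$atom2)
  miss <- setdiff(c(k1, k2), rownames(X))
  if (length(miss)) stop("missing atom: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- sqrt(rowSums((X[k1, , drop = FALSE] - X[k2, , drop = FALSE])^2))
  viol <- pmax(0, d - restraints$upper, restraints$lower - d)
  tab <- cbind(restraints[, c("res1", "atom1", "res2", "atom2", "lower", "upper")],
               distance = d, violation = viol)
  list(count = sum(viol > threshold), max_violation = if (length(viol)) max(viol) else 0,
       table = tab)
}

#' Run configuration
#'
#' User-level parameters of an enumeration run, serializable to YAML.
#'
#' @param sequence one-letter sequence (or `NULL` with `n_residues`).
#' @param n_residues residue count (polyalanine) when no sequence given.
#' @param helices list of `c(first, last)` residue ranges.
#' @param b,eps_x,eps_t,sigma_vdw,eps_dup see [tolerance_config()].
#' @param max_saved,rmsd_filter see [ibp_search()].
#' @param cis residues starting a cis peptide bond.
#' @param restraints_file optional restraint file path.
#' @param out_prefix output path prefix.
#' @return list of class `run_config`.
#' @export
run_config <- function(sequence = NULL, n_residues = NULL, helices = list(),
                       b = 4L, eps_x = 0.2, eps_t = 2, sigma_vdw = 0.85,
                       eps_dup = 0.1, max_saved = 10000L, rmsd_filter = 1.5,
                       cis = integer(0), restraints_file = NULL,
                       out_prefix = "ibp_out") {
  if (is.null(sequence) && is.null(n_residues)) {
    stop("give a sequence or a residue count")
  }
  n <- if (!is.null(sequence)) length(parse_sequence(sequence)) else n_residues
  if (is.numeric(helices)) helices <- list(helices)
  for (h in helices) {
    if (length(h) != 2L || h[1L] > h[2L] || h[2L] > n) stop("invalid helix range")
  }
  structure(list(sequence = sequence, n_residues = n_residues,
                 helices = helices, b = as.integer(b), eps_x = eps_x,
                 eps_t = eps_t, sigma_vdw = sigma_vdw, eps_dup = eps_dup,
                 max_saved = as.integer(max_saved), rmsd_filter = rmsd_filter,
                 cis = as.integer(cis), restraints_file = restraints_file,
                 out_prefix = out_prefix),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[!vapply(y, is.null, TRUE)])
}
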