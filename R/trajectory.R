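## standard atomic masses (amu) by element symbol
.ATOMIC_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, F = 18.998, CL = 35.45, BR = 79.904,
                  I = 126.904, NA. = 22.990, MG = 24.305, K = 39.098,
                  CA = 40.078, FE = 55.845, ZN = 65.38, MN = 54.938,
                  CU = 63.546, SE = 78.971)

.element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ATOMIC_MASS[key]
  if (anyNA(m))
    .stopf("unknown element(s): %s; supply masses explicitly",
           paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

## element symbol from a PDB atom name ("C1", "O5", "H61", "1HB" ...)
.element_from_name <- function(name) {
  s <- sub("^[0-9']*", "", trimws(name))
  two <- toupper(substr(s, 1, 2))
  one <- toupper(substr(s, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "FE", "ZN", "CA", "MN", "CU", "SE") &
           !grepl("^C[0-9]|^N[0-9]|^O[0-9]|^S[0-9]", toupper(s)),
         two, one)
}

#' Molecular-dynamics trajectory container
#'
#' Per-frame Cartesian coordinates (Angstrom) over a fixed atom list, with
#' residue/atom annotations, optional per-monosaccharide ring maps and
#' glycosidic-linkage definitions.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param atoms data frame with columns `name`, `resno`, `resname`,
#'   `chain`; optional `element` (derived from `name` when absent),
#'   `mass` (standard atomic mass by element when absent), `b` (B-factor).
#' @param rings named list of length-6 integer atom-index vectors ordered
#'   O5, C1, C2, C3, C4, C5, keyed by residue (`"chain:resno"`); see
#'   [annotate_rings()].
#' @param linkages list of glycosidic-linkage definitions; see
#'   [define_linkage()].
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, atoms, rings = list(), linkages = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  na <- dim(coords)[1]
  if (nrow(atoms) != na) .stopf("atoms table (%d) does not match coords (%d atoms)",
                                nrow(atoms), na)
  need <- c("name", "resno", "resname", "chain")
  if (!all(need %in% names(atoms)))
    .stopf("atoms needs columns %s", paste(need, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  for (key in names(rings)) {
    r <- rings[[key]]
    if (length(r) != 6L || any(r < 1L) || any(r > na))
      .stopf("ring map '%s' must reference 6 existing atoms", key)
  }
  structure(list(coords = coords, atoms = atoms,
                 rings = rings, linkages = linkages),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms, %d frames, %d chains, %d annotated rings, %d linkages\n",
              n_atoms(x), n_frames(x), length(unique(x$atoms$chain)),
              length(x$rings), length(x$linkages)))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' @rdname md_trajectory
#' @param i frame number (1-based).
#' @return `frame_coords` returns the `n_atoms x 3` coordinate matrix of
#'   frame `i`.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$resno, sep = ":")

## resolve an atom reference "chain:resno:name" (or index) to an index
.resolve_atom <- function(traj, ref) {
  if (is.numeric(ref)) return(as.integer(ref))
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) .stopf("atom reference must be 'chain:resno:name', got '%s'", ref)
  hit <- which(traj$atoms$chain == parts[1] &
                 traj$atoms$resno == as.integer(parts[2]) &
                 trimws(traj$atoms$name) == parts[3])
  if (length(hit) != 1L) .stopf("atom reference '%s' matches %d atoms", ref, length(hit))
  hit
}

#' Annotate pyranose ring atoms
#'
#' Attaches per-monosaccharide ring maps (atom indices ordered
#' O5, C1, C2, C3, C4, C5). With `config = NULL` every residue containing
#' all six standard ring atom names is annotated automatically. A config
#' (list or YAML file) may map residue names or `"chain:resno"` keys to a
#' character vector of six atom names.
#'
#' @param traj an [md_trajectory()].
#' @param config `NULL`, a named list, or path to a YAML file.
#' @return the trajectory with `rings` filled in.
#' @export
annotate_rings <- function(traj, config = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  std <- c("O5", "C1", "C2", "C3", "C4", "C5")
  keys <- .residue_key(traj$atoms)
  rings <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    resname <- traj$atoms$resname[idx[1]]
    wanted <- std
    if (!is.null(config)) {
      wanted <- config[[key]]
      if (is.null(wanted)) wanted <- config[[resname]]
      if (is.null(wanted)) next
      if (length(wanted) != 6L) .stopf("ring config for '%s' must list 6 atom names", key)
    }
    pos <- match(wanted, trimws(traj$atoms$name[idx]))
    if (anyNA(pos)) {
      if (!is.null(config)) .stopf("residue %s lacks ring atoms %s", key,
                                   paste(wanted[is.na(pos)], collapse = ","))
      next
    }
    rings[[key]] <- idx[pos]
  }
  traj$rings <- rings
  traj
}

#' Define a glycosidic linkage
#'
#' Registers the phi/psi torsion atom quadruples of one glycosidic bond.
#' Atom references are `"chain:resno:name"` strings or raw indices.
#'
#' @param traj an [md_trajectory()].
#' @param linkage_id identifier, e.g. `"2-1"` (residues joined).
#' @param phi,psi character or integer vectors of four atom references.
#' @return the trajectory with the linkage appended.
#' @export
define_linkage <- function(traj, linkage_id, phi, psi) {
  stopifnot(inherits(traj, "md_trajectory"), length(phi) == 4L, length(psi) == 4L)
  lk <- list(linkage_id = linkage_id,
             phi = vapply(phi, function(r) .resolve_atom(traj, r), integer(1)),
             psi = vapply(psi, function(r) .resolve_atom(traj, r), integer(1)))
  traj$linkages <- c(traj$linkages, list(lk))
  traj
}

#' Standard GAG linkage quadruples for consecutive residues
#'
#' Builds the phi/psi definitions used for GAG chains, with residue
#' numbering 1-based from the reducing toward the nonreducing end: for a
#' 1->4 bond phi = O5(n+1)-C1(n+1)-O4(n)-C4(n) and
#' psi = C1(n+1)-O4(n)-C4(n)-C3(n); for a 1->3 bond the O3/C3/C2 variants.
#'
#' @param traj an [md_trajectory()].
#' @param chain GAG chain id.
#' @param types character vector (recycled) of bond types `"1-4"` or
#'   `"1-3"`, one per consecutive residue pair `(n, n+1)`.
#' @return the trajectory with one linkage per consecutive residue pair.
#' @export
gag_linkages <- function(traj, chain, types = "1-4") {
  stopifnot(inherits(traj, "md_trajectory"))
  resnos <- sort(unique(traj$atoms$resno[traj$atoms$chain == chain]))
  if (length(resnos) < 2L) .stopf("chain %s has fewer than 2 residues", chain)
  npair <- length(resnos) - 1L
  types <- rep_len(types, npair)
  for (p in seq_len(npair)) {
    n0 <- resnos[p]; n1 <- resnos[p + 1L]
    at <- function(res, name) sprintf("%s:%d:%s", chain, res, name)
    if (types[p] == "1-4") {
      phi <- c(at(n1, "O5"), at(n1, "C1"), at(n0, "O4"), at(n0, "C4"))
      psi <- c(at(n1, "C1"), at(n0, "O4"), at(n0, "C4"), at(n0, "C3"))
    } else if (types[p] == "1-3") {
      phi <- c(at(n1, "O5"), at(n1, "C1"), at(n0, "O3"), at(n0, "C3"))
      psi <- c(at(n1, "C1"), at(n0, "O3"), at(n0, "C3"), at(n0, "C2"))
    } else .stopf("unknown linkage type '%s'", types[p])
    traj <- define_linkage(traj, sprintf("%d-%d", n1, n0), phi, psi)
  }
  traj
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()]; MODEL blocks become
#' frames. Elements come from the element column, falling back to atom-name
#' heuristics; B-factors are kept in `atoms$b`.
#'
#' @param path PDB file path.
#' @return an [md_trajectory()] (rings/linkages unannotated; see
#'   [annotate_rings()]).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  if (nf < 1L || na < 1L) .stopf("no models/atoms in %s", path)
  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  a <- pdb$atom
  element <- a$elesy
  bad <- is.na(element) | trimws(element) == ""
  element[bad] <- .element_from_name(a$elety[bad])
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(name = trimws(a$elety), element = trimws(element),
                      resno = a$resno, resname = trimws(a$resid),
                      chain = chain, b = a$b)
  atoms$mass <- .element_mass(atoms$element)
  md_trajectory(coords, atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-column ATOM records, one MODEL block per frame; B-factors from
#' `atoms$b` (0 when absent). Output re-reads with [read_structure()].
#'
#' @param traj an [md_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$atoms
  b <- if (is.null(a$b)) rep(0, nrow(a)) else a$b
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(a)),
                     ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
                     substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resno,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1.0, b, toupper(a$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selections
#'
#' `select_atoms` evaluates a selection against the atom table and returns
#' atom indices. A selection may be `NULL` (all atoms), a logical or
#' integer vector, a function of the atom data frame returning a logical,
#' or one of the named shortcuts `"heavy"` (non-hydrogen), `"calpha"`,
#' `"backbone"`, or `"chain <id>"`.
#'
#' @param traj an [md_trajectory()].
#' @param selection see Description.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(traj, selection = NULL) {
  a <- traj$atoms
  if (is.null(selection)) return(seq_len(nrow(a)))
  if (is.function(selection)) return(which(selection(a)))
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  if (selection == "heavy") return(which(toupper(a$element) != "H"))
  if (selection == "calpha") return(which(a$name == "CA"))
  if (selection == "backbone") return(which(a$name %in% c("N", "CA", "C", "O")))
  if (grepl("^chain ", selection))
    return(which(a$chain == sub("^chain ", "", selection)))
  .stopf("unknown selection '%s'", selection)
}
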