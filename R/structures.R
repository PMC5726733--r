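#' @section Residue identity:
#' Residues are identified by the triple (chain, author number, insertion
#' code), exactly as printed in the source PDB file; internal node indices
#' are 1..n in file order. All user-facing output (paths, matrix labels,
#' neighbour lists) uses author numbering.
#' @name pathnull-structures
#' @keywords internal
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# non-standard residues mapped to their standard parent and retained
DEFAULT_AA_ALIASES <- c(
  MSE = "MET", CYX = "CYS", CYM = "CYS",
  HID = "HIS", HIE = "HIS", HIP = "HIS", HSD = "HIS", HSE = "HIS", HSP = "HIS",
  ASH = "ASP", GLH = "GLU", LYN = "LYS", ARN = "ARG"
)

residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  chain <- ifelse(is.na(chain) | chain == " ", "", chain)
  paste0(chain, ":", resno, insert)
}

#' Construct a structure object from flat atom vectors
#'
#' Low-level constructor shared by the PDB reader and the synthetic
#' generators. Atoms must be grouped so that all atoms of a residue are
#' contiguous and residues appear in chain order.
#'
#' @param source_id identifier for provenance (PDB code or file name).
#' @param chain,resno,insert,resname per-atom residue identity vectors.
#' @param xyz numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param atom_name per-atom labels (e.g. "CA").
#' @param element per-atom element symbols.
#' @return An object of class `pn_structure` with components `residues`
#'   (data frame: chain, resno, insert, name, key), `rep_xyz` (n x 3 matrix
#'   of representative coordinates: the alpha-carbon when present, else the
#'   atom centroid), `axyz`, `atom_res`, `atom_name`, `atom_elem`.
#' @export
new_structure <- function(source_id, chain, resno, insert, resname, xyz,
                          atom_name, element) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) == 0L)
    pn_stop("pathnull_empty_structure", "structure '%s' has zero atoms", source_id)
  if (!all(is.finite(xyz)))
    pn_stop("pathnull_input_error", "non-finite atom coordinates in '%s'", source_id)
  key <- residue_key(chain, resno, insert)
  # residues in first-occurrence (file) order
  first <- !duplicated(key)
  ukey <- key[first]
  if (anyDuplicated(ukey))
    pn_stop("pathnull_input_error",
            "residue key repeats non-contiguously in '%s'", source_id)
  atom_res <- match(key, ukey)
  residues <- data.frame(
    chain = chain[first], resno = as.integer(resno[first]),
    insert = ifelse(is.na(insert[first]) | insert[first] == " ", "", insert[first]),
    name = resname[first], key = ukey,
    stringsAsFactors = FALSE
  )
  n <- nrow(residues)
  rep_xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ix <- which(atom_res == i)
    ca <- ix[atom_name[ix] == "CA"]
    rep_xyz[i, ] <- if (length(ca)) xyz[ca[1L], ] else colMeans(xyz[ix, , drop = FALSE])
  }
  structure(
    list(source_id = source_id, residues = residues, rep_xyz = rep_xyz,
         axyz = xyz, atom_res = atom_res,
         atom_name = as.character(atom_name), atom_elem = as.character(element)),
    class = "pn_structure"
  )
}

#' @export
print.pn_structure <- function(x, ...) {
  cat(sprintf("<pn_structure> %s: %d residues, %d atoms, chains: %s\n",
              x$source_id, nrow(x$residues), nrow(x$axyz),
              paste(unique(x$residues$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `pn_structure`.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Map a residue identity to its internal node index
#'
#' @param structure a `pn_structure`.
#' @param chain chain identifier ("" for chainless synthetic beads is
#'   normalised like a blank PDB chain field).
#' @param resno author residue number.
#' @param insert insertion code, default empty.
#' @return 1-based internal index; error if the residue is absent.
#' @export
index_of <- function(structure, chain, resno, insert = "") {
  i <- match(residue_key(chain, resno, insert), structure$residues$key)
  if (is.na(i))
    pn_stop("pathnull_input_error", "residue %s not found in '%s'",
            residue_key(chain, resno, insert), structure$source_id)
  i
}

#' Atom coordinates of one residue
#' @param structure a `pn_structure`.
#' @param i internal residue index.
#' @return matrix (n_atoms x 3).
#' @export
residue_atoms <- function(structure, i) {
  structure$axyz[structure$atom_res == i, , drop = FALSE]
}

is_hydrogen <- function(elem, name) {
  e <- toupper(trimws(elem))
  known <- !is.na(e) & nzchar(e)
  h <- e %in% c("H", "D")
  # fall back to the atom-name convention when the element field is blank
  nm <- toupper(trimws(name))
  h[!known] <- grepl("^[0-9]*[HD]", nm[!known])
  h
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}, keeps the first model only,
#' resolves alternate locations by highest occupancy (ties: first
#' occurrence), and drops hydrogens unless asked to keep them. Author
#' chain/residue numbering and insertion codes are preserved.
#'
#' @param path PDB file.
#' @param keep_hydrogens keep hydrogen (and deuterium) atoms. Default FALSE:
#'   crystal structures rarely resolve them, and contact maps built from
#'   heavy atoms are reproducible from raw PDB files.
#' @return a [new_structure()] object containing every residue in the file
#'   (including waters and hetero groups; see [filter_protein()]).
#' @export
read_structure <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path))
    pn_stop("pathnull_input_error", "structure file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      pn_stop("pathnull_input_error", "cannot parse PDB file %s: %s",
              path, conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    pn_stop("pathnull_empty_structure", "no ATOM/HETATM records in %s", path)
  # first model only: bio3d with multi = FALSE already returns model 1 rows
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) elem[bad] <- ""
  if (!keep_hydrogens) {
    keep <- !is_hydrogen(elem, at$elety)
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  if (nrow(at) == 0L)
    pn_stop("pathnull_empty_structure", "no atoms left after filtering in %s", path)
  # alternate locations: within each (residue, atom name) group keep the
  # highest-occupancy conformer, ties broken by first occurrence
  alt <- at$alt
  alt[is.na(alt)] <- ""
  has_alt <- alt != "" & alt != " "
  if (any(has_alt)) {
    gid <- paste(residue_key(at$chain, at$resno, at$insert), at$elety)
    occ <- at$o
    occ[is.na(occ)] <- 1
    keep <- rep(TRUE, nrow(at))
    for (g in unique(gid[has_alt])) {
      ix <- which(gid == g)
      if (length(ix) > 1L) keep[ix[-which.max(occ[ix])]] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  new_structure(
    source_id = basename(path),
    chain = at$chain, resno = at$resno, insert = at$insert,
    resname = trimws(at$resid), xyz = cbind(at$x, at$y, at$z),
    atom_name = trimws(at$elety), element = trimws(elem)
  )
}

#' Keep only protein residues (and optionally selected chains)
#'
#' Retains standard amino acids; waters, nucleic acids, ions, ligands and
#' other hetero groups are dropped. Non-standard amino acids named in
#' `aliases` (default includes selenomethionine and common protonation
#' variants) are renamed to their standard parent and retained. Internal
#' indices are recomputed; the operation is idempotent.
#'
#' @param structure a `pn_structure`.
#' @param chains optional character vector restricting to these chain ids.
#' @param aliases named character vector mapping non-standard residue names
#'   to the standard name under which they are kept.
#' @return filtered `pn_structure`.
#' @export
filter_protein <- function(structure, chains = NULL,
                           aliases = DEFAULT_AA_ALIASES) {
  res <- structure$residues
  name <- res$name
  mapped <- !is.na(match(name, names(aliases)))
  name[mapped] <- unname(aliases[name[mapped]])
  keep <- name %in% STANDARD_AA
  if (!is.null(chains)) keep <- keep & res$chain %in% chains
  if (!any(keep))
    pn_stop("pathnull_empty_structure",
            "no protein residues left in '%s' after filtering", structure$source_id)
  kept_idx <- which(keep)
  amask <- structure$atom_res %in% kept_idx
  ar <- structure$atom_res[amask]
  new_structure(
    source_id = structure$source_id,
    chain = res$chain[ar], resno = res$resno[ar], insert = res$insert[ar],
    resname = name[ar],
    xyz = structure$axyz[amask, , drop = FALSE],
    atom_name = structure$atom_name[amask],
    element = structure$atom_elem[amask]
  )
}
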