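# shared fixtures: all built in code, no binary data

# straight bead chain along x with given spacing
bead_chain <- function(n, spacing = 3.8, start_resno = 1L, chain = "A") {
  xyz <- cbind(spacing * (seq_len(n) - 1), 0, 0)
  pathnull::new_structure(
    sprintf("chain%d", n), rep(chain, n),
    seq.int(start_resno, length.out = n), rep("", n), rep("GLY", n),
    xyz, rep("CA", n), rep("C", n)
  )
}

# arbitrary bead structure from a coordinate matrix
bead_structure <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A") {
  n <- nrow(xyz)
  pathnull::new_structure(
    "beads", rep(chain, n), resno, rep("", n), rep("GLY", n),
    xyz, rep("CA", n), rep("C", n)
  )
}

# hand-rolled PDB text fixture with mixed content (protein incl. MSE,
# water, DNA, an ion, and an alternate-location pair)
write_mixed_pdb <- function(path) {
  fmt <- function(serial, name, alt, resn, chain, resno, x, y, z, occ,
                  type = "ATOM", elem = substr(trimws(name), 1, 1)) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
  }
  lines <- character(0)
  s <- 1
  # 10 amino acids (9 standard + 1 MSE) along x, CA + CB each
  resn <- c("ALA", "GLY", "MSE", "LEU", "SER", "THR", "VAL", "PHE", "LYS", "ASP")
  for (i in 1:10) {
    lines <- c(lines, fmt(s, " CA ", "", resn[i], "A", 100 + i,
                          3.8 * i, 0, 0, 1)); s <- s + 1
    lines <- c(lines, fmt(s, " CB ", "", resn[i], "A", 100 + i,
                          3.8 * i, 1.5, 0, 1, elem = "C")); s <- s + 1
  }
  # alternate locations for residue 111: B has higher occupancy
  lines <- c(lines,
             fmt(s, " CA ", "A", "GLY", "A", 111, 50, 0, 0, 0.3),
             fmt(s + 1, " CA ", "B", "GLY", "A", 111, 60, 0, 0, 0.7))
  s <- s + 2
  # hydrogens on residue 101
  lines <- c(lines, fmt(s, " HA ", "", "ALA", "A", 101, 3.8, 0.5, 0.5, 1,
                        elem = "H")); s <- s + 1
  # hetero groups: waters, a DNA nucleotide, an ion, ADP-like ligand
  lines <- c(lines,
             fmt(s, " O  ", "", "HOH", "W", 1, 20, 20, 20, 1, "HETATM", "O"),
             fmt(s + 1, " O  ", "", "HOH", "W", 2, 22, 20, 20, 1, "HETATM", "O"),
             fmt(s + 2, " P  ", "", " DA", "B", 1, 30, 0, 0, 1, "ATOM", "P"),
             fmt(s + 3, "MG  ", "", " MG", "C", 1, 40, 0, 0, 1, "HETATM", "MG"),
             fmt(s + 4, " PA ", "", "ADP", "D", 1, 45, 0, 0, 1, "HETATM", "P"))
  writeLines(c(lines, "END"), path)
  path
}

# brute-force all-simple-paths minimum hop count (exhaustive, tiny graphs)
brute_min_hops <- function(adj, nodes, start, end) {
  best <- Inf
  recurse <- function(v, seen, len) {
    if (v == end) { best <<- min(best, len); return(invisible()) }
    for (w in adj[[v]]) {
      if (!(w %in% seen)) recurse(w, c(seen, w), len + 1)
    }
  }
  recurse(start, start, 1)
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

# random graph over n nodes with edge prob p, as a pn_graph-compatible
# structure via a synthetic distance matrix trick
random_bead_graph <- function(n, p) {
  a <- matrix(runif(n * n) < p, n, n)
  a <- a & upper.tri(a)
  a <- a | t(a)
  adj <- lapply(seq_len(n), function(i) which(a[i, ]))
  coords <- matrix(runif(n * 3, 0, 20), n, 3)
  structure(list(cutoff = NA_real_, n = n, nodes = seq_len(n), adj = adj,
                 labels = as.character(seq_len(n)), rep_xyz = coords),
            class = "pn_graph")
}

# resolve a real benchmark structure if the user has provided one locally;
# tests that need crystal structures fail cleanly when it is absent
benchmark_structure_path <- function(code) {
  dirs <- c(getOption("pathnull.structure_dir", ""),
            system.file("extdata", "structures", package = "pathnull"))
  for (d in dirs) {
    if (nzchar(d)) {
      p <- file.path(d, paste0(code, ".pdb"))
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}
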