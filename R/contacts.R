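#' Minimum inter-atomic distance between two residues
#'
#' The residue-residue distance used throughout the package is the minimum
#' Euclidean distance over all atom pairs, one atom from each residue.
#'
#' @param atoms_a,atoms_b coordinate matrices (n_atoms x 3) as returned by
#'   [residue_atoms()].
#' @return distance in Angstrom.
#' @export
residue_min_distance <- function(atoms_a, atoms_b) {
  atoms_a <- as.matrix(atoms_a); atoms_b <- as.matrix(atoms_b)
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L)
    pn_stop("pathnull_input_error", "residue with empty atom list")
  d2 <- outer(rowSums(atoms_a^2), rowSums(atoms_b^2), "+") -
    2 * atoms_a %*% t(atoms_b)
  sqrt(max(0, min(d2)))
}

#' Residue-by-residue minimum distance matrix
#'
#' Computes the symmetric n x n matrix whose (i, j) entry is the minimum
#' inter-atomic distance between residues i and j over all retained atoms.
#' Single-atom-per-residue structures (synthetic beads) take a direct
#' `dist()` fast path; multi-atom structures are evaluated in column blocks
#' of atoms so that large systems (about 12,000 atoms for a MutS-sized
#' protein) never materialise the full atom-pair tensor. Both routes are
#' exact minima, not approximations.
#'
#' @param structure a `pn_structure`.
#' @param block_size atoms per evaluation block for the multi-atom route.
#' @return object of class `pn_distmat`: list(n, labels, d) with `d` the
#'   matrix in Angstrom and `labels` the residue keys; residue
#'   representative coordinates are carried along as `rep_xyz` for the
#'   search heuristics.
#' @export
build_distance_matrix <- function(structure, block_size = 2000L) {
  n <- n_residues(structure)
  if (n == 0L) pn_stop("pathnull_empty_structure", "empty structure")
  ar <- structure$atom_res
  if (length(ar) == n && all(ar == seq_len(n))) {
    d <- as.matrix(dist(structure$axyz))
  } else {
    o <- order(ar)
    axyz <- structure$axyz[o, , drop = FALSE]
    ra <- ar[o]
    rs <- match(seq_len(n), ra)              # first atom row of residue i
    re <- c(rs[-1L] - 1L, length(ra))        # last atom row
    m <- nrow(axyz)
    sq <- rowSums(axyz^2)
    d <- matrix(Inf, n, n)
    for (cb in split(seq_len(m), ceiling(seq_len(m) / block_size))) {
      # atom-block cross squared distances to all atoms: m x |cb|
      d2 <- outer(sq, sq[cb], "+") - 2 * axyz %*% t(axyz[cb, , drop = FALSE])
      # reduce block columns to their residues by pmin
      rb <- ra[cb]
      for (j in seq_along(cb)) {
        jr <- rb[j]
        d[, jr] <- pmin(d[, jr], vapply(seq_len(n), function(i)
          min(d2[rs[i]:re[i], j]), numeric(1)))
      }
    }
    d <- sqrt(pmax(d, 0))
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2   # enforce exact symmetry against fp noise
  dimnames(d) <- list(structure$residues$key, structure$residues$key)
  structure(list(n = n, labels = structure$residues$key, d = d,
                 rep_xyz = structure$rep_xyz),
            class = "pn_distmat")
}

#' @export
print.pn_distmat <- function(x, ...) {
  cat(sprintf("<pn_distmat> %d residues, max %.1f A\n", x$n, max(x$d)))
  invisible(x)
}

#' Contact graph at a distance cutoff
#'
#' Nodes are residues; an edge joins residues i != j when their minimum
#' inter-atomic distance satisfies d[i, j] <= cutoff (closed threshold; the
#' boundary convention is fixed so tests are exact).
#'
#' @param dm a `pn_distmat`.
#' @param cutoff_c cutoff in Angstrom (>= 0).
#' @return object of class `pn_graph`: list(cutoff, n, nodes, adj, labels,
#'   rep_xyz); `adj` is a length-n list of sorted neighbour index vectors.
#' @export
neighbor_map <- function(dm, cutoff_c) {
  if (!is.numeric(cutoff_c) || length(cutoff_c) != 1L || is.na(cutoff_c) ||
      cutoff_c < 0)
    pn_stop("pathnull_input_error", "cutoff must be a single non-negative number")
  A <- unname(dm$d) <= cutoff_c
  diag(A) <- FALSE
  adj <- lapply(seq_len(dm$n), function(i) which(A[i, ]))
  structure(list(cutoff = cutoff_c, n = dm$n, nodes = seq_len(dm$n),
                 adj = adj, labels = dm$labels, rep_xyz = dm$rep_xyz),
            class = "pn_graph")
}

#' @export
print.pn_graph <- function(x, ...) {
  cat(sprintf("<pn_graph> cutoff %.2f A, %d/%d nodes, %d edges\n",
              x$cutoff, length(x$nodes), x$n,
              sum(lengths(x$adj)) / 2))
  invisible(x)
}

#' Subgraph induced by a residue selection
#'
#' Restricts the node set to the selection; an edge survives iff both of
#' its endpoints are selected. Original node indices are preserved so paths
#' remain reportable in author numbering.
#'
#' @param graph a `pn_graph`.
#' @param selection a `pn_selection` (see [sample_selection()]) or an
#'   integer vector of node indices.
#' @return a `pn_graph` whose `nodes` are the selection.
#' @export
induced_subgraph <- function(graph, selection) {
  members <- if (inherits(selection, "pn_selection")) selection$members
             else as.integer(selection)
  if (length(members) == 0L ||
      any(is.na(members)) || any(members < 1L) || any(members > graph$n))
    pn_stop("pathnull_input_error", "selection members out of node range")
  members <- sort(unique(members))
  mask <- logical(graph$n)
  mask[members] <- TRUE
  adj <- vector("list", graph$n)
  for (i in seq_len(graph$n)) adj[[i]] <- integer(0)
  for (i in members) {
    nb <- graph$adj[[i]]
    adj[[i]] <- nb[mask[nb]]
  }
  structure(list(cutoff = graph$cutoff, n = graph$n, nodes = members,
                 adj = adj, labels = graph$labels, rep_xyz = graph$rep_xyz),
            class = "pn_graph")
}

#' Write a distance matrix as TSV
#'
#' Residue keys head the rows and columns; values in Angstrom with 3
#' decimals.
#' @param dm a `pn_distmat`.
#' @param path output file.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- format(round(dm$d, 3), nsmall = 3, trim = TRUE)
  df <- data.frame(residue = dm$labels, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("residue", dm$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a contact graph as JSON (residue key -> sorted neighbour keys)
#' @param graph a `pn_graph`.
#' @param path output file.
#' @export
write_contact_graph <- function(graph, path) {
  obj <- setNames(
    lapply(graph$nodes, function(i) graph$labels[graph$adj[[i]]]),
    graph$labels[graph$nodes]
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
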