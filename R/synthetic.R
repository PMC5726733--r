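#' Synthetic bead structures
#'
#' Single-atom "bead" residues on a self-avoiding chain stand in for real
#' proteins in tests and simulations: a compact globule mimics a
#' single-domain protein, and several globules joined by thin straight
#' linkers mimic a multidomain architecture whose inter-domain connectivity
#' is bottlenecked through the linker beads. With one atom per residue the
#' minimum inter-atomic residue distance degenerates to the bead distance,
#' which keeps every downstream oracle exact.
#'
#' The bead spacing defaults to 3.8 Angstrom (the alpha-carbon virtual bond
#' length), so a 6 Angstrom contact cutoff connects sequence neighbours just
#' as it does in real structures.
#'
#' @name pathnull-synthetic
#' @keywords internal
NULL

# confinement radius of a globule: R = GLOBULE_COMPACTNESS * spacing * n^(1/3).
# 0.8 puts the mean contact degree of a 100-bead globule at a 6 A cutoff
# in the 4-10 range typical of residue contact graphs.
GLOBULE_COMPACTNESS <- 0.8

random_unit_vector <- function() {
  repeat {
    v <- runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-8 && n2 <= 1) return(v / sqrt(n2))
  }
}

# grow one self-avoiding confined chain; returns n x 3 matrix or NULL
grow_chain <- function(n, spacing, radius, min_sep) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- random_unit_vector() * runif(1, 0, radius / 2)
  i <- 2L
  backtracks <- 0L
  while (i <= n) {
    placed <- FALSE
    for (try in seq_len(120L)) {
      cand <- pos[i - 1L, ] + spacing * random_unit_vector()
      if (sum(cand^2) > radius^2) next
      if (i > 2L) {
        prev <- pos[seq_len(i - 2L), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (min(d2) < min_sep^2) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) {
      i <- i + 1L
    } else {
      backtracks <- backtracks + 1L
      if (backtracks > 400L) return(NULL)
      i <- max(2L, i - 5L)
    }
  }
  pos
}

beads_to_structure <- function(xyz, source_id, chain = "A", start_resno = 1L) {
  n <- nrow(xyz)
  new_structure(
    source_id = source_id,
    chain = rep(chain, n),
    resno = seq.int(start_resno, length.out = n),
    insert = rep("", n),
    resname = rep("GLY", n),
    xyz = xyz,
    atom_name = rep("CA", n),
    element = rep("C", n)
  )
}

#' Generate a compact globular bead chain
#'
#' A self-avoiding chain of `n_residues` single-atom residues with exact
#' consecutive spacing `bead_spacing`, grown inside a confining sphere of
#' radius `0.8 * bead_spacing * n^(1/3)` so the chain collapses like a
#' globular domain. No two non-consecutive beads come closer than
#' `0.9 * bead_spacing`. Deterministic given `seed`.
#'
#' @param n_residues number of beads (>= 3).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param bead_spacing consecutive bead distance in Angstrom (default 3.8,
#'   the alpha-carbon virtual bond).
#' @param chain,start_resno chain id and first author residue number.
#' @return a `pn_structure` of single-atom residues.
#' @export
make_globule <- function(n_residues, seed, bead_spacing = 3.8,
                         chain = "A", start_resno = 1L) {
  if (n_residues < 3L)
    pn_stop("pathnull_input_error", "a globule needs at least 3 residues")
  if (bead_spacing <= 0)
    pn_stop("pathnull_input_error", "bead_spacing must be positive")
  radius <- GLOBULE_COMPACTNESS * bead_spacing * n_residues^(1 / 3)
  xyz <- with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(50L)) {
      out <- grow_chain(n_residues, bead_spacing, radius, 0.9 * bead_spacing)
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(xyz))
    pn_stop("pathnull_generation_error",
            "could not pack %d beads at spacing %.2f within radius %.2f",
            n_residues, bead_spacing, radius)
  beads_to_structure(xyz, sprintf("globule_n%d_seed%d", n_residues, seed),
                     chain = chain, start_resno = start_resno)
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_onto <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

min_crossdist <- function(A, B) {
  # exact minimum distance between two bead sets (small n)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Generate a multidomain bead chain with thin linkers
#'
#' Builds one globule per entry of `domain_sizes`, orients each so that its
#' chain ends face the neighbouring domain, and joins consecutive domains by
#' straight linkers of `linker_length` beads. Domains are pushed apart until
#' every inter-domain bead pair is farther than 6.2 Angstrom, so at the
#' default 6 Angstrom contact cutoff all inter-domain connectivity is forced
#' through the linker beads (a geometric bottleneck). Linker bead spacing is
#' kept in [bead_spacing, 5.9] Angstrom so the chain itself stays connected
#' at that cutoff.
#'
#' @param domain_sizes integer vector (length >= 2) of beads per domain.
#' @param linker_length beads per linker (>= 1).
#' @inheritParams make_globule
#' @return a `pn_structure` with `sum(domain_sizes) +
#'   (length(domain_sizes)-1) * linker_length` residues, numbered
#'   sequentially along the chain.
#' @export
make_multidomain <- function(domain_sizes, linker_length, seed,
                             bead_spacing = 3.8, chain = "A",
                             start_resno = 1L) {
  if (length(domain_sizes) < 2L)
    pn_stop("pathnull_input_error", "need at least 2 domains")
  if (linker_length < 1L)
    pn_stop("pathnull_input_error", "linker_length must be >= 1")
  ndom <- length(domain_sizes)
  doms <- vector("list", ndom)
  for (d in seq_len(ndom)) {
    g <- make_globule(domain_sizes[d], seed = sub_seed(seed, d),
                      bead_spacing = bead_spacing)
    xyz <- g$rep_xyz
    xyz <- sweep(xyz, 2, colMeans(xyz))
    # orient: entry (first bead) toward -x, then align exit (last bead)
    # as +x as the remaining about-x freedom allows
    if (d > 1L) {
      R1 <- rotation_onto(xyz[1, ], c(-1, 0, 0))
      xyz <- xyz %*% t(R1)
    } else {
      R1 <- rotation_onto(xyz[nrow(xyz), ], c(1, 0, 0))
      xyz <- xyz %*% t(R1)
    }
    ex <- xyz[nrow(xyz), ]
    yz <- ex[2:3]
    if (d < ndom && sqrt(sum(yz^2)) > 1e-9) {
      # rotate about x to put the exit bead in the +y half-plane, a
      # deterministic choice that keeps exits pointing away from entries
      th <- atan2(ex[3], ex[2])
      Rx <- matrix(c(1, 0, 0, 0, cos(-th), sin(-th), 0, -sin(-th), cos(-th)), 3, 3)
      xyz <- xyz %*% t(Rx)
    }
    doms[[d]] <- xyz
  }
  placed <- doms[[1]]
  pieces <- list(placed)
  guard <- 6.2
  for (d in 2L:ndom) {
    nxt <- doms[[d]]
    exit_anchor <- pieces[[length(pieces)]][nrow(pieces[[length(pieces)]]), ]
    gap <- (linker_length + 1) * bead_spacing
    offset <- exit_anchor + c(gap, 0, 0) - nxt[1, ]
    cand <- sweep(nxt, 2, offset, "+")
    prev_all <- do.call(rbind, pieces)
    push <- 0
    while (min_crossdist(prev_all, cand) <= guard && push < 400) {
      cand <- sweep(cand, 2, c(0.5, 0, 0), "+")
      push <- push + 0.5
    }
    entry_anchor <- cand[1, ]
    seg <- entry_anchor - exit_anchor
    span <- sqrt(sum(seg^2))
    lsp <- span / (linker_length + 1)
    if (lsp > 5.9)
      pn_stop("pathnull_generation_error",
              "linker of %d beads cannot bridge the %.1f A inter-domain gap at <= 5.9 A spacing; increase linker_length",
              linker_length, span)
    linker <- t(vapply(seq_len(linker_length),
                       function(j) exit_anchor + seg * j / (linker_length + 1),
                       numeric(3)))
    pieces[[length(pieces) + 1L]] <- linker
    pieces[[length(pieces) + 1L]] <- cand
  }
  xyz <- do.call(rbind, pieces)
  st <- beads_to_structure(
    xyz,
    sprintf("multidomain_%s_l%d_seed%d", paste(domain_sizes, collapse = "-"),
            linker_length, seed),
    chain = chain, start_resno = start_resno
  )
  st$linker_residues <- linker_indices(domain_sizes, linker_length)
  st
}

#' Indices of the linker beads of a multidomain structure
#' @param domain_sizes,linker_length as in [make_multidomain()].
#' @return integer vector of internal residue indices occupied by linkers.
#' @export
linker_indices <- function(domain_sizes, linker_length) {
  out <- integer(0)
  at <- 0L
  for (d in seq_along(domain_sizes)) {
    at <- at + domain_sizes[d]
    if (d < length(domain_sizes)) {
      out <- c(out, seq.int(at + 1L, at + linker_length))
      at <- at + linker_length
    }
  }
  out
}

#' Write a structure to a PDB file
#'
#' Serialises ATOM records (via \pkg{bio3d}) preserving chain ids, author
#' residue numbers and insertion codes; coordinates are written at the PDB
#' format's 3-decimal precision, so [read_structure()] on the output
#' round-trips residue keys and coordinates to that precision.
#'
#' @param structure a `pn_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (n_residues(structure) == 0L)
    pn_stop("pathnull_empty_structure", "refusing to write an empty structure")
  res <- structure$residues
  ar <- structure$atom_res
  ok <- tryCatch({
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.vector(t(structure$axyz)),
      type = rep("ATOM", length(ar)),
      resno = res$resno[ar],
      resid = res$name[ar],
      insert = ifelse(nzchar(res$insert[ar]), res$insert[ar], ""),
      chain = ifelse(nzchar(res$chain[ar]), res$chain[ar], " "),
      elety = structure$atom_name,
      eleno = seq_along(ar),
      o = rep(1, length(ar)), b = rep(0, length(ar))
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    pn_stop("pathnull_io_error", "cannot write %s: %s", path,
            conditionMessage(ok))
  invisible(path)
}
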