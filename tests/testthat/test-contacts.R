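test_that("residue_min_distance matches brute force and trivial cases", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(residue_min_distance(a, b), 5)           # 3-4-5 triangle
  expect_equal(residue_min_distance(a, a), 0)
  set.seed(42)
  for (rep in 1:20) {
    A <- matrix(rnorm(15, sd = 4), 5, 3)
    B <- matrix(rnorm(15, sd = 4), 5, 3)
    brute <- min(vapply(1:5, function(i)
      min(sqrt(colSums((t(B) - A[i, ])^2))), 1))
    expect_equal(residue_min_distance(A, B), brute, tolerance = 1e-12)
  }
  expect_error(residue_min_distance(A[0, , drop = FALSE], B),
               class = "pathnull_input_error")
})

test_that("distance matrix is exact, symmetric and label-complete", {
  st <- bead_chain(3)
  dm <- build_distance_matrix(st)
  expect_equal(sort(unique(dm$d[upper.tri(dm$d)])), c(3.8, 7.6))
  one <- build_distance_matrix(bead_chain(1))
  expect_equal(one$d, matrix(0, 1, 1, dimnames = list("A:1", "A:1")))
  # 20-bead globule vs O(n^2) brute-force recomputation elementwise
  g <- make_globule(20, seed = 3)
  dm <- build_distance_matrix(g)
  brute <- as.matrix(dist(g$rep_xyz))
  dimnames(brute) <- dimnames(dm$d)
  expect_equal(dm$d, brute, tolerance = 1e-12)
  expect_identical(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
})

test_that("multi-atom blocked evaluation equals the per-pair brute force", {
  # random multi-atom residues exercise the blocked route
  set.seed(7)
  n_res <- 12
  natoms <- sample(1:6, n_res, replace = TRUE)
  xyz <- matrix(rnorm(sum(natoms) * 3, sd = 8), ncol = 3)
  st <- pathnull::new_structure(
    "multi", rep("A", sum(natoms)), rep(seq_len(n_res), natoms),
    rep("", sum(natoms)), rep("ALA", sum(natoms)), xyz,
    unlist(lapply(natoms, function(k) c("CA", paste0("C", seq_len(k - 1)))[seq_len(k)])),
    rep("C", sum(natoms))
  )
  dm <- build_distance_matrix(st, block_size = 7)  # force several blocks
  for (i in 1:n_res) for (j in 1:n_res) {
    expect_equal(dm$d[i, j],
                 if (i == j) 0 else
                   residue_min_distance(residue_atoms(st, i),
                                        residue_atoms(st, j)),
      tolerance = 1e-9)
  }
})

test_that("distance matrix is invariant to atom order within residues", {
  set.seed(8)
  natoms <- rep(3, 6)
  xyz <- matrix(rnorm(18 * 3, sd = 6), ncol = 3)
  res <- rep(1:6, each = 3)
  mk <- function(ord) pathnull::new_structure(
    "m", rep("A", 18)[ord], res[ord], rep("", 18), rep("ALA", 18),
    xyz[ord, ], rep(c("CA", "CB", "CG"), 6)[ord], rep("C", 18))
  ord2 <- unlist(lapply(split(1:18, res), sample))
  d1 <- build_distance_matrix(mk(1:18))$d
  d2 <- build_distance_matrix(mk(ord2))$d
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("neighbor_map honours the closed cutoff and saturates", {
  dm <- build_distance_matrix(bead_chain(5))
  g0 <- neighbor_map(dm, 0)
  expect_true(all(lengths(g0$adj) == 0))
  gfull <- neighbor_map(dm, max(dm$d))   # closed threshold: d <= c
  expect_true(all(lengths(gfull$adj) == 4))
  gc <- neighbor_map(dm, 3.8)            # boundary included
  expect_equal(gc$adj[[2]], c(1L, 3L))
  expect_error(neighbor_map(dm, -1), class = "pathnull_input_error")
  # monotonicity in cutoff on a random structure
  dm2 <- build_distance_matrix(make_globule(30, seed = 12))
  e1 <- neighbor_map(dm2, 5)$adj
  e2 <- neighbor_map(dm2, 8)$adj
  for (i in 1:30) expect_true(all(e1[[i]] %in% e2[[i]]))
})

test_that("induced subgraph equals a brute-force edge filter", {
  set.seed(5)
  g <- neighbor_map(build_distance_matrix(make_globule(30, seed = 6)), 7)
  sel <- sort(sample(30, 12))
  sub <- induced_subgraph(g, sel)
  expect_identical(sub$nodes, sel)
  for (i in sel)
    expect_identical(sub$adj[[i]], intersect(g$adj[[i]], sel))
  for (i in setdiff(1:30, sel))
    expect_length(sub$adj[[i]], 0)
  # identity on the full node set; isolated endpoints when far apart
  idg <- induced_subgraph(g, 1:30)
  expect_identical(idg$adj, g$adj)
  expect_error(induced_subgraph(g, c(1, 99)), class = "pathnull_input_error")
})

test_that("distance matrix and contact graph serialise to documented formats", {
  dm <- build_distance_matrix(bead_chain(4, start_resno = 301))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, tsv)
  tab <- read.delim(tsv, check.names = FALSE)
  expect_equal(names(tab), c("residue", dm$labels))
  expect_equal(tab[[2]][1], 0)
  expect_equal(tab[["A:302"]][1], 3.8)
  js <- withr::local_tempfile(fileext = ".json")
  write_contact_graph(neighbor_map(dm, 4), js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj[["A:302"]], c("A:301", "A:303"))
})
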