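---
title: "The pathway null model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pathway null model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathnull)
```

## The question and the model

Predictions of allosteric signalling pathways — for example the coevolving
residue "sectors" produced by statistical coupling analysis, which
typically cover on the order of 20% of a protein — are usually presented
as contiguous chains of residues in mutual contact linking an allosteric
site to an active site. `pathnull` quantifies the baseline against which
such a finding should be judged: the probability that a *random* residue
subset of the same size already contains some contiguous path between the
two sites.

The model has three ingredients.

**Contact graph.** For residues $i, j$ let $d(i,j)$ be the minimum
Euclidean distance over all atom pairs with one atom in each residue
(heavy atoms by default; see below). The contact graph at cutoff $c$ has
the residues as nodes and an edge wherever $d(i,j) \le c$, $i \ne j$. The
threshold is *closed* ($\le$, not $<$): on real coordinates the boundary
is a measure-zero event, but a fixed convention makes unit tests exact.
Sequence-adjacent residues receive edges like any other pair — at the
default $c = 6$ Å they always qualify — and no bonded-neighbour exclusion
is applied.

**Null model.** A selection of size $k = \mathrm{round}(f \cdot n)$
(rounding half away from zero) always contains the two endpoint residues;
the other $k - 2$ members are drawn uniformly without replacement from the
remaining $n - 2$. The count $k$ *includes* the endpoints: for a
115-residue PDZ domain at $f = 0.2$ this gives $k = 23$, i.e. endpoints
plus 21 free members and $\binom{113}{21}$ possible selections, which is
the convention consistent with published worked selections of that system.
A selection succeeds when the subgraph induced by it (edges kept only when
both endpoints of the edge are selected) connects the two sites.

**Estimation.** The success rate is the fraction of successful selections.
It is estimated by Monte Carlo over $S$ selections per trial and $T$
independent trials, or computed exactly for small systems by enumerating
all $\binom{n-2}{k-2}$ selections (`exact_success_probability()`, refused
above a configurable limit of $10^6$ combinations). Convergence of an
experiment is declared when the sample standard deviation of the trial
rates is at or below a tolerance, default 1 percentage point. This is the
simplest criterion consistent with rate-vs-$S$ curves that flatten as $S$
grows; published trial spreads of a fraction of a percentage point at
$S = 10^5$ match the binomial prediction
$100\sqrt{p(1-p)/S} \approx 0.16$ pp at $p \approx 0.5$, so reported
"stdev" values are interpreted as percentage points throughout.

## Search: existence, not optimality

Only path *existence* feeds the null model; if any path exists, the
shortest one exists too, so nothing is lost by using fast searches.

* `find_path_astar()` — best-first on $f = g + h$ where $g$ accumulates
  Euclidean step lengths between representative coordinates (the
  alpha-carbon when present, else the atom centroid) and $h$ is the
  straight-line distance to the end residue. With these units $h$ is
  admissible and consistent, and A\* on a finite graph is complete, so the
  found flag is exact regardless of heuristic quality.
* `find_path_dfs()` — depth-first with children explored closest-to-end
  first. Implemented with an explicit stack rather than recursion: a
  MutS-sized run (about 1,530 residues, 306-node subgraphs) can produce
  paths deep enough to threaten R's call stack.
* `connected_oracle()` — plain breadth-first connectivity with no
  heuristic and no shared code path with the two searches above, kept as
  an internal reference; the test suite asserts three-way agreement of the
  found flag on tens of thousands of random induced subgraphs.
* `shortest_path()` — fewest-hop BFS, used for reporting worked examples.

All tie-breaks (equal $f$, equal distance-to-end, BFS discovery order) are
by node index, so a fixed seed reproduces runs bit-exactly. When either
endpoint has no selected neighbour the selection is failed without
searching; because the other endpoint is itself always selected, this
fast-fail is exactly equivalent to running the search, and the test suite
asserts that equivalence rather than assuming it.

## Distances and structure handling

The residue–residue minimum distance is exact, never approximate: for
multi-atom residues the all-pairs minimum is evaluated in atom blocks so a
MutS-sized distance matrix (~12,000 atoms) never materialises the full
atom-pair tensor; single-atom bead structures short-circuit to a plain
`dist()`. The matrix is computed once per structure and reused across all
cutoffs and selections.

PDB handling follows common crystal-structure practice: first model only;
alternate locations resolved to the highest-occupancy conformer with ties
going to the first listed; hydrogens dropped by default (raw crystal
files rarely resolve them; force-field preparation pipelines add them, so
`keep_hydrogens = TRUE` is available to probe the sensitivity of neighbour
sets to that choice); selenomethionine and common protonation-state
variants mapped to their standard parents via a configurable alias table;
waters, nucleic acids, ions and ligands removed by `filter_protein()`.
Author chain/residue numbering and insertion codes are preserved end to
end — a pathway is reported as, e.g., `376 -> 367 -> 388 -> 313`.

For MutS-like systems the deposited crystal structure is not the
biologically relevant assembly; published analyses applied unspecified
manual adjustments. The package therefore accepts any user-prepared
coordinate file and makes no attempt to reproduce such edits; headline
rates for that system are correspondingly expected to match only loosely.

## Synthetic structures: what they emulate and what they do not

`make_globule(n, seed)` grows a self-avoiding chain of single-atom
residues with exact 3.8 Å consecutive spacing (the alpha-carbon virtual
bond) inside a confining sphere of radius $0.8 \cdot 3.8 \cdot n^{1/3}$ Å,
with non-consecutive beads kept at least $0.9 \times 3.8$ Å apart. The
compactness constant 0.8 was fixed once so that a 100-bead globule at a
6 Å cutoff has a mean contact degree in the 4–10 band typical of residue
contact graphs. `make_multidomain(sizes, linker_length, seed)` joins such
globules by straight linkers of evenly spaced beads; domains are rotated
so their chain ends face each other and pushed apart until every
inter-domain bead pair exceeds 6.2 Å, which *guarantees* that at the 6 Å
cutoff all inter-domain connectivity runs through the linker — the
bottleneck geometry that depresses pathway rates in multidomain proteins.
Linker spacing is kept within [3.8, 5.9] Å so the chain itself stays
connected; geometries that cannot satisfy both constraints raise a
generation error rather than silently degrading.

Both generators are pure functions of their arguments (the global RNG
stream is saved and restored), so fixtures are reproducible bit-exactly.

What the beads do *not* emulate: side-chain geometry and atom-level
packing (every residue is one bead, so minimum-atomic and representative
distances coincide), secondary structure, chemically realistic surface
texture, and crystallographic artefacts (alternate locations, missing
loops). Tests passing on beads therefore validate the graph, sampling and
statistical machinery — not structure chemistry. That is intentional: the
chemistry enters only through the distance matrix, which has its own
exact brute-force oracles in the test suite.

## The 5PL cutoff curve

Success rate versus cutoff is summarised with the asymmetric
five-parameter logistic
$$y = d + \frac{a - d}{\left[1 + (x/c)^b\right]^m},$$
where $a$ is the value at $x = 0$, $d$ the asymptote as $x \to \infty$
(when $b, m > 0$), $c$ a location scale in Å, $b$ a slope exponent and $m$
an asymmetry exponent. (Published renderings of this family sometimes
garble the formula typographically; the form above is the one whose
$x = 0$ and $x \to \infty$ limits reproduce the printed fit constants of
the benchmark systems, which is the algebraic check used to pin it down.)

Numerical choices:

* **Evaluation** is done in log space,
  $y = d + (a - d)\,e^{-m\,\mathrm{log1p}((x/c)^b)}$, with the inner
  $\mathrm{log1p}(e^t)$ switching to $t$ for large $t$. Published fits of
  this family can carry $m \sim 2.5 \times 10^7$; naive evaluation
  overflows where the log-space form is exact to machine precision
  (reference values in the tests were frozen from 50-digit arithmetic).
  At $x = 0$ the value is exactly $a$ by construction.
* **Fitting** uses Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  residuals with $b, c, m$ log-parameterised (positivity without
  constrained optimisation). Initialisation is deterministic:
  $a = \min y$, $d = \max y$, $c$ = the first $x$ crossing the half
  range, $b = 5$, $m = 1$. Constant data returns a flagged degenerate fit
  ($a \approx d$) instead of an error; iteration-capped fits are accepted
  only when the residual sum of squares is already negligible relative to
  the data scale (step-like data push $m \to \infty$ while the predicted
  curve is long converged). Because extreme exponents make the parameter
  *tuple* non-identifiable even when the *curve* is sharp, all quality
  checks compare predicted values, never parameter values.
* **Sweeps** reuse one selection stream per trial across every cutoff
  (common random numbers). Edge sets are nested in $c$, so per-selection
  success is monotone and the per-trial rate sequence is non-decreasing
  *exactly* — the tests assert it as an identity, not statistically. The
  sweep grid is user configuration; no canonical grid is assumed.

## Seeding and reproducibility

A single experiment seed deterministically derives one sub-seed per trial
(`(seed * 7919 + trial * 104729) mod (2^31 - 1)`), giving independent
streams and bit-identical reruns; every output directory receives a JSON
record of the fully resolved configuration including the seed. Selection
sampling inside a trial uses R's global RNG, so `run_trial()` alone is
reproducible by seeding before the call.

## Problem sizes used by the tests

The suite exercises the machinery at sizes chosen to keep the oracles
exhaustive and the runs quick while still probing every contract:
tri-algorithm agreement on 10,000 induced subgraphs of a 60-bead globule
and a two-domain (25+25+4-linker) chain; Monte Carlo vs exact enumeration
on toys with at most $\binom{14}{4} = 1001$ combinations at
$S = 10^4$ selections and 40 seeds; shortest-path checks against
brute-force simple-path enumeration on graphs of up to 9 nodes; 5PL
recovery on 20-point curves over 100 noise replicates. A straight 12-bead
chain with endpoints at beads 1 and 4 and $k = 6$ provides a closed-form
anchor: at a 6 Å cutoff only consecutive beads touch, so success requires
beads 2 and 3 and the exact probability is
$\binom{8}{2}/\binom{10}{4} = 2/15$.

## Known limitations

* The null model treats all non-endpoint residues as exchangeable; it
  does not condition on burial, secondary structure or residue identity.
* Success is binary path existence. No weighting by path length, contact
  strength or energetic plausibility is attempted, and no variance
  reduction is applied to the Monte Carlo estimate.
* Headline rates for real systems depend on structure preparation
  (hydrogens, assembly corrections, modelled termini); the package
  reproduces preparation only up to what a raw PDB file contains.
* The qualitative border/interior picture of why complex geometries
  suppress pathways (a Markov-chain view of path extension) motivates the
  multidomain generator but is not itself implemented: no transition
  rates are published to parameterise it.
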