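---
title: "Scoring tree shape statistics on NNI tree space"
author: "saless package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tree shape statistics on NNI tree space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saless)
```

## The problem

A tree shape statistic compresses the topology of a rooted bifurcating
phylogenetic tree into one number — the Colless and Sackin imbalance indices
are the classic examples.  Such statistics are used to test diversification
models and, more recently, as features in phylodynamic inference, so it
matters which ones actually *discriminate*: a useful statistic should take
similar values on trees that are a small topological perturbation apart, and
different values on trees that are many perturbations apart.

This package operationalizes that idea on the *complete* space of unlabeled
rooted bifurcating tree shapes with $l$ leaves.  Leaf labels and branch
lengths are deliberately ignored throughout: only the shape matters.

## Tree space and the NNI Cayley graph

`enumerateShapes(l)` lists every isomorphism class once, via the recursion
"a shape on $l$ leaves is an unordered pair of shapes on $k$ and $l-k$
leaves".  The number of classes is the Wedderburn–Etherington number
(11 at $l=7$, 24,631 at $l=17$) and grows like $b^l l^{-3/2}$ with
$b \approx 2.48$, which is what ultimately limits exhaustive work to a
couple of dozen leaves.

Every shape is stored in a canonical form — children ordered by (subtree
leaf count, canonical key) — so isomorphism is plain string equality, and
the space is sorted by that key.  This fixes the coordinate order of every
vector and matrix in the package, making runs byte-for-byte reproducible.

Two shapes are adjacent when a single nearest-neighbour-interchange (NNI)
move converts one into the other.  The move is applied to the *rooted*
shape: for each internal edge (both endpoints internal), the sibling of the
lower endpoint is exchanged with one of that endpoint's two children — two
candidate rearrangements per internal edge, hence at most $2(l-2)$
neighbors.  Moves whose result is isomorphic to the source are dropped; the
graph is simple and, on every space we construct, connected.  The tests
cross-check the neighbor sets against `phangorn::nni()` and an independent
list-surgery implementation.

```{r graph}
g <- buildCayleyGraph(enumerateShapes(7))
g
```

## Two resolution functions

Let $y_f$ hold one statistic's values over the $n$ shapes, and
$x_f = H y_f / \lVert H y_f \rVert$ its centered unit version
($H = I - \tfrac1n \mathbf{1}\mathbf{1}^t$).  A constant statistic has no
discriminatory content and is rejected rather than scored.

**Distance resolution** (higher is better):
$$R_D(f) = -\tfrac12\, x_f^t D_s x_f,$$
with $D_s$ the elementwise square of the all-pairs NNI distance matrix
(breadth-first search from every vertex).  Far-apart tree pairs with
opposite-signed statistic values drive it up.  For centered vectors this is
the quadratic form of the classical MDS matrix
$X_D = -\tfrac12 H D_s H$.

**Laplacian resolution** (lower is better):
$$R_L(f) = x_f^t L x_f = \sum_{i \sim j} \big((x_f)_i - (x_f)_j\big)^2,$$
the Dirichlet energy of the statistic across graph edges, with
$L = \mathrm{Diag}(\deg) - A$.  It examines only adjacent pairs, which is
why it needs $O(n \log n)$ memory where $R_D$ needs $O(n^2)$ — the practical
reason to prefer it at large $l$.

Both are Rayleigh quotients, so the Courant–Fischer theorem brackets them by
extreme eigenvalues: $X_D$'s smallest and largest for $R_D$; the Fiedler
value (second-smallest eigenvalue; the smallest is 0 with constant
eigenvector on a connected graph) and largest eigenvalue of $L$ for $R_L$.
The linear map $x \mapsto (x - \min)/(\max - \min)$ then puts every score in
$[0,1]$ — the *scaled resolution*, which is what the package reports and
what makes statistics comparable across leaf counts.  Scores are reported on
their own scale (for $R_L$ lower remains better); nothing is flipped.

```{r resolve}
scaledResolution(g, "colless", "distance")
scaledResolution(g, "colless", "laplacian")
```

## Optimal linear combinations and the Saless index

For two statistics with centered value vectors $a$ and $b$, the combination
$v(\lambda) = \lambda a + b$ has Rayleigh quotient
$R(\lambda) = v^t M v / v^t v$ ($M$ being $X_D$ or $L$).  Setting
$R'(\lambda) = 0$ gives a single quadratic,
$$(p t - q s)\lambda^2 + (p u - r s)\lambda + (q u - r t) = 0,$$
in the six scalars $p = a^t M a$, $q = a^t M b$, $r = b^t M b$,
$s = a^t a$, $t = a^t b$, $u = b^t b$.  Because $(M, I)$ restricted to the
plane spanned by $a, b$ is a symmetric–definite pencil, the roots are always
real; they are the global optimum and pessimum of $R$ over the $\lambda$
line, so the optimum always weakly dominates both constituents (the
$\lambda \to 0$ and $\lambda \to \infty$ limits).  `optimalLambda()` solves
the quadratic, evaluates both roots, picks by sense (maximize under $R_D$,
minimize under $R_L$; ties toward smaller $|\lambda|$), and re-verifies
against a dense grid over $\lambda$ as an internal guard.

The *Saless index* is the combination of Sackin and Colless,
$\lambda \bar N + I_c$, at the $R_D$-optimal $\lambda$:

```{r saless}
optimalCombination(g, "sackin", "colless", "distance")
```

A negative optimal $\lambda$ (common for other pairs under $R_L$) is
reported as-is and merely flagged `not plausible` — the resolution machinery
is indifferent to the sign, but a mixture with a negative weight is harder
to motivate as a standalone index.

### Statistic scales and where $\lambda$ lives

Scaled resolutions of a single statistic are invariant under affine maps of
the statistic (the quotient normalizes them away), so it is immaterial
whether Colless is used with its $2/((n-1)(n-2))$ normalization or as the
bare sum $\sum_i |r_i - s_i|$.  Combination *coefficients* are not
invariant: $\lambda$ rescales inversely with the relative scale of the two
statistics.  The package therefore distinguishes a `"printed"` scale (the
defining formulas, with their normalizations) from an `"aggregate"` scale
(bare sums: Colless $\sum|r-s|$, Sackin $\sum_j N_j$, and analogously for
$\sigma^2$ and $I_2$), and `optimalCombination()` works on the aggregate
scale by default.  That is the scale on which the reference values this
package reproduces are quoted, and tests pin the choice down: the $l=7$
Saless coefficient is 5.77 on the aggregate scale and 2.69 under printed
normalizations — only the former matches the published table, while the
scaled resolution (0.931) is identical either way.  For the same reason the
Laplacian-optimal "Saless" column of the pairwise-combination table carries
its $\lambda$ on Colless ($\lambda I_c + \bar N$), which is how
`combinationTable()`'s default pairs are set up.

## Statistics implemented

For a shape with $n$ leaves, leaf depths $N_j$, internal-node subtree
heights $M_i$ and child leaf counts $r_i, s_i$:

| name       | definition (printed scale)                                   | range     |
|------------|---------------------------------------------------------------|-----------|
| `colless`  | $\frac{2}{(n-1)(n-2)} \sum_{i \in I} \lvert r_i - s_i \rvert$          | $[0,1]$   |
| `sackin`   | $\frac1n \sum_{j \in L} N_j$                                   | mean depth |
| `sigma2`   | $\frac1n \sum_{j \in L} (N_j - \bar N)^2$                      | $\ge 0$   |
| `i2`       | $\frac{1}{n-2} \sum_{i:\, r_i+s_i>2} \frac{|r_i-s_i|}{r_i+s_i-2}$ | $[0,1]$ |
| `b1`       | $\sum_{i \in I \setminus \{\mathrm{root}\}} 1/M_i$             | $\ge 0$   |
| `b2`       | $\sum_{j \in L} N_j / 2^{N_j}$                                 | $\ge 0$   |
| `cherries` | internal nodes with two leaf children                          | $1..\lfloor l/2\rfloor$ |

Two definitional choices deserve a note, since the literature typesets both
ambiguously.  $B_1$ excludes the root (the Shao–Sokal convention): with the
root included, the scaled Laplacian resolutions no longer agree with the
reference values this package reproduces, so the exclusion is pinned by the
tests rather than by taste.  $I_2$ sums over *all* internal nodes passing
$r_i + s_i > 2$, root included; on the 4-leaf caterpillar both the $(1,3)$
root and the $(1,2)$ node qualify and $I_2 = 1$.

## Numerical choices

* **Eigenvalues.**  Spaces up to 1500 shapes use a dense symmetric
  eigensolve.  Larger Laplacians use ARPACK Lanczos iterations (through
  igraph): `which = "LA"` for the top of the spectrum and `which = "SA"`,
  `nev = 2` for the bottom, verifying that the smallest eigenvalue is
  numerically zero and that the Fiedler pair's residual
  $\lVert Lv - \lambda_2 v\rVert$ is below $10^{-6}\lambda_{\max}$ —
  non-convergence is an error, not a warning.  A shift-invert transform is
  the textbook accelerator for small eigenvalues, but these Cayley graphs
  are expander-like and their sparse Cholesky factors fill in almost
  densely; plain SA Lanczos converges in under a second even at 24,631
  shapes, so it is the better tool here.
* **$X_D$ bounds and the memory guard.**  $R_D$ needs all-pairs distances.
  The dense distance matrix is guarded at 2500 shapes (every space up to 14
  leaves) and the guard must be raised explicitly beyond that; the $X_D$
  eigen-bounds are computed densely within the guard.  Past it, the package
  still computes *raw* $R_D$ quadratic forms exactly, via `dsCrossprod()`,
  which streams one BFS row at a time and never materializes $D_s$.  Since
  the $[0,1]$ map is increasing and common to all statistics at fixed $l$,
  raw values rank statistics identically to scaled ones, which is how the
  package compares statistics under $R_D$ on spaces of 15–17 leaves without
  a quadratic-memory object.
* **Degenerate inputs.**  Constant statistic vectors, disconnected graphs
  (impossible for NNI spaces, but checked — a disconnection would signal a
  neighbor-generation bug and is reported with component sizes), and
  combinations of linearly dependent statistic vectors are all hard errors.
  Combination root selection breaks exact ties toward smaller $|\lambda|$.
* **Problem sizes.**  The test suite exercises full tables at $l = 7..13$
  for the distance resolution and $l = 7..17$ for the Laplacian one, the
  statistic ranking at $l = 10..17$, and property checks (neighbor symmetry,
  metric axioms, oracle equality) exhaustively at $l \le 10$.  These sizes
  were chosen so the whole suite runs in minutes on one core while still
  covering the regime where dense and sparse code paths both engage.

## Random shapes and what the generators do (and do not) emulate

`randomShape()` draws from the two standard null models: **Yule** (grow from
one lineage, split a uniformly chosen extant lineage until $l$ tips) and
**PDA** (every labeled rooted topology equally likely, generated by uniform
sequential attachment over the $2k-1$ insertion positions and dropping
labels).  Both use R's RNG, so `set.seed()` gives reproducibility.  Tests
validate the induced shape frequencies against exact probabilities (at
$l=4$: balanced shape has probability $1/3$ under Yule and $3/15$ under
PDA).

These generators are test instruments and convenience tools for sampling
tree space — they emulate the standard neutral models, not empirical
phylogenies: no extinction, no sampling fraction, no branch lengths, no
label structure.  Passing tests therefore say the *machinery* is right on
the complete shape space; they say nothing about how any statistic behaves
on trees inferred from data.

## Known limitations

* Exhaustive enumeration is inherently exponential; the package is
  comfortable to $l \approx 20$ for Laplacian work and $l \approx 14$ for
  dense distance work on one core.  Beyond that, sampling approaches (e.g.
  MCMC over NNI moves) would be needed, which this package does not
  implement.
* Only the NNI metric is implemented.  SPR or TBR rearrangements would give
  different — coarser — geometries.
* Unrooted or multifurcating trees are rejected, not resolved.
* Combinations are limited to pairs; optimizing more than two statistics at
  once is a different (multi-coefficient) optimization problem.

## Reproducing the summary tables

`runTable()` regenerates the four standard tables (optimal Saless
coefficients by leaf count; scaled $R_D$ by statistic; scaled $R_L$ by
statistic; Laplacian-optimal pairwise combinations) as deterministic TSVs,
and `inst/cli/treeshape.R` exposes the same operations as shell
subcommands.  `scripts/acceptance.R` at the repository root recomputes the
headline values end to end and writes them as JSON.

```{r table3, eval = FALSE}
runTable("t3", leaves = 7:17, out = "table3.tsv")
```
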