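# saless

Resolution of tree shape statistics on NNI tree space.

Tree shape statistics — Colless, Sackin and their relatives — summarize the
topology of a rooted bifurcating phylogenetic tree as a single number, and
are widely used to test diversification models and as phylodynamic features.
`saless` measures how well such a statistic *discriminates* between tree
shapes, by evaluating it on the complete space of unlabeled rooted
bifurcating shapes with `l` leaves and scoring it against the geometry of
nearest-neighbour-interchange (NNI) rearrangements.

The package:

* enumerates all shapes on `l` leaves in canonical form (11 shapes at
  `l = 7`, 24,631 at `l = 17`) and builds the **NNI Cayley graph** — one
  vertex per shape, an edge between shapes one rooted NNI move apart;
* computes two **resolution functions** for a statistic vector `y` with
  centered unit form `x = Hy/‖Hy‖`, `H = I − (1/n)11ᵗ`:
  - distance resolution `R_D(f) = −½ xᵗ D_s x` over squared NNI distances
    (higher is better),
  - Laplacian resolution `R_L(f) = xᵗ L x = Σ_{i∼j} (x_i − x_j)²`, the
    Dirichlet energy over graph edges (lower is better, and far cheaper:
    `L` is sparse while `D_s` is dense);
* rescales both to `[0, 1]` by their extreme Rayleigh-quotient eigenvalues
  (the min/max eigenvalues of `X_D = −½ H D_s H`, or the Fiedler value and
  largest eigenvalue of `L`);
* finds the **optimal linear combination** `λ·f + g` of two statistics in
  closed form (the stationarity condition of the Rayleigh quotient is a
  quadratic in `λ`), including the **Saless index** `λ·Sackin + Colless`;
* embeds tree space by classical MDS, and samples random shapes under the
  Yule and PDA null models.

Seven statistics are built in: `colless`, `sackin`, `sigma2` (variance of
leaf depths), `i2`, `b1`, `b2`, `cherries`.

## Worked example

```r
library(saless)

space <- enumerateShapes(7)    # all 11 shapes on 7 leaves
graph <- buildCayleyGraph(space)
graph
#> NNI CayleyGraph on 11 shapes ( 7 leaves ), 24 edges

scaledResolution(graph, "colless", "distance")
#> ResolutionReport: colless under distance resolution (l = 7, n = 11)
#>   raw 6.29069 in [-2.53428, 7.00558], scaled 0.9251 (higher is better)

scaledResolution(graph, "colless", "laplacian")
#> ResolutionReport: colless under laplacian resolution (l = 7, n = 11)
#>   raw 2.52683 in [1.97203, 7.6126], scaled 0.0984 (lower is better)

optimalCombination(graph, "sackin", "colless", "distance")
#> CombinationResult: 5.7653 * sackin + colless (aggregate scale) under distance resolution
#>   raw 6.34593, scaled 0.9309, discriminant 3.721e+05, plausible
```

Reading the numbers: of the full `[0, 1]` range that any centered unit
vector could achieve on this space, the Colless index realizes 92.5% of the
distance-based separation, and its Dirichlet energy sits only 9.8% of the
way up from the theoretical floor (the Fiedler value) — by both measures an
excellent discriminator.  Combining it with the Sackin index (coefficient
`λ = 5.77` on the unnormalized-sum scale) pushes the distance resolution to
0.931: the Saless index, which stays the top-ranked statistic at every leaf
count the package explores.

`resolutionTable()` and `combinationTable()` tabulate these scores over
ranges of leaf counts, `runTable()` writes the four standard summary tables
as TSV, and the same operations are available from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/treeshape.R", package="saless"))')" \
    resolve --leaves 7..12 --function laplacian --out report.tsv
```

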