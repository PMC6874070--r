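setOldClass("phylo")

# S4 classes. The canonical key of a shape is its unlabeled newick string
# (leaf = empty, children ordered by (leaf count, key)), ';'-terminated; two
# rooted bifurcating trees are isomorphic iff their keys are equal.

#' TreeShape: an unlabeled rooted bifurcating tree
#'
#' A single tree shape in canonical form.  Leaf labels and branch lengths of
#' the tree it came from are discarded: only the topology matters.
#'
#' @slot key canonical unlabeled newick string (see [canonicalKey()]).
#' @slot nLeaves number of leaves.
#'
#' @seealso [treeShape()], [caterpillarShape()], [balancedShape()],
#'   [randomShape()]
#' @export
setClass("TreeShape",
         representation(key = "character", nLeaves = "integer"))

setValidity("TreeShape", function(object) {
  if (length(object@key) != 1L) return("key must be a single string")
  l <- object@nLeaves
  if (length(l) != 1L || is.na(l) || l < 1L)
    return("nLeaves must be a positive integer")
  # canonical key of an l-leaf shape has 3(l-1) structural characters + ';'
  if (nchar(object@key) != 3L * (l - 1L) + 1L)
    return("key length inconsistent with nLeaves")
  TRUE
})

#' ShapeSpace: all tree shapes on a fixed number of leaves
#'
#' The exhaustively enumerated, deterministically ordered set of isomorphism
#' classes of rooted bifurcating tree shapes on `leafCount` leaves.  All
#' vectors and matrices produced by the package (statistic vectors, the
#' Cayley graph adjacency, distance matrices) are indexed in this order,
#' which is the byte-lexicographic order of the canonical keys.
#'
#' @slot leafCount number of leaves l.
#' @slot keys canonical keys of the n shapes, sorted.
#'
#' @seealso [enumerateShapes()]
#' @export
setClass("ShapeSpace",
         representation(leafCount = "integer", keys = "character"))

setValidity("ShapeSpace", function(object) {
  l <- object@leafCount
  if (length(l) != 1L || is.na(l) || l < 1L)
    return("leafCount must be a positive integer")
  k <- object@keys
  if (anyDuplicated(k)) return("keys must be pairwise distinct")
  if (!identical(unname(k), sort(k, method = "radix")))
    return("keys must be in canonical (byte-lexicographic) order")
  if (any(nchar(k) != 3L * (l - 1L) + 1L))
    return("some keys are inconsistent with leafCount")
  TRUE
})

#' CayleyGraph: the NNI graph over a shape space
#'
#' One vertex per shape, an undirected edge between any two shapes exactly
#' one NNI move apart.  The graph Laplacian and the all-pairs NNI distance
#' matrix both derive from it.
#'
#' @slot space the [ShapeSpace-class] the graph is built on.
#' @slot adjacency symmetric sparse 0/1 adjacency matrix.
#' @slot degrees integer vertex degrees.
#'
#' @seealso [buildCayleyGraph()], [laplacianMatrix()], [distanceMatrix()]
#' @export
setClass("CayleyGraph",
         representation(space = "ShapeSpace", adjacency = "sparseMatrix",
                        degrees = "integer"))

setValidity("CayleyGraph", function(object) {
  n <- length(object@space@keys)
  A <- object@adjacency
  if (!all(dim(A) == c(n, n))) return("adjacency dimensions do not match space")
  if (any(Matrix::diag(A) != 0)) return("self-loops are not allowed")
  if (!Matrix::isSymmetric(A)) return("adjacency must be symmetric")
  if (length(object@degrees) != n) return("degrees length does not match space")
  TRUE
})

#' StatVector: a statistic evaluated over a whole shape space
#'
#' Holds the raw values `y` of one statistic on every shape of a space
#' (index-aligned with it) together with the centered unit vector
#' `x = H y / ||H y||`, where `H = I - (1/n) 11^t` is the centering matrix.
#' `x` is what both resolution functions consume.
#'
#' @slot name statistic identifier.
#' @slot scale `"printed"` (the normalizations of the defining formulas) or
#'   `"aggregate"` (unnormalized sums, the scale on which combination
#'   coefficients are reported).
#' @slot values raw values, one per shape.
#' @slot centered centered, unit-norm values.
#' @slot leafCount leaf count of the space the vector belongs to.
#'
#' @seealso [statisticVector()]
#' @export
setClass("StatVector",
         representation(name = "character", scale = "character",
                        values = "numeric", centered = "numeric",
                        leafCount = "integer"))

setValidity("StatVector", function(object) {
  if (length(object@values) != length(object@centered))
    return("values and centered must have equal length")
  x <- object@centered
  if (abs(sum(x)) > 1e-8) return("centered vector must have zero mean")
  if (abs(sum(x^2) - 1) > 1e-8) return("centered vector must have unit norm")
  TRUE
})

#' SpectralBounds: extreme eigenvalues bounding a resolution
#'
#' For the Laplacian resolution the bounds are the Fiedler value (second
#' smallest eigenvalue of L; the smallest is 0 on a connected graph) and the
#' largest eigenvalue of L.  For the distance resolution they are the extreme
#' eigenvalues of X_D = -1/2 H Ds H.
#'
#' @slot role `"laplacian"` or `"distance"`.
#' @slot lower,upper the bounding eigenvalues.
#'
#' @seealso [spectralBounds()]
#' @export
setClass("SpectralBounds",
         representation(role = "character", lower = "numeric",
                        upper = "numeric"))

#' ResolutionReport: one statistic scored under one resolution function
#'
#' @slot statistic statistic name.
#' @slot kind `"distance"` (higher raw value is better) or `"laplacian"`
#'   (lower is better).
#' @slot raw the resolution value.
#' @slot lower,upper the spectral bounds.
#' @slot scaled `(raw - lower) / (upper - lower)`, in [0, 1].
#' @slot leafCount,nShapes size of the space.
#'
#' @seealso [scaledResolution()]
#' @export
setClass("ResolutionReport",
         representation(statistic = "character", kind = "character",
                        raw = "numeric", lower = "numeric", upper = "numeric",
                        scaled = "numeric", leafCount = "integer",
                        nShapes = "integer"))

setValidity("ResolutionReport", function(object) {
  tol <- 1e-7 * max(1, abs(object@upper - object@lower))
  if (object@raw < object@lower - tol || object@raw > object@upper + tol)
    return("raw resolution outside its spectral bounds")
  TRUE
})

#' CombinationResult: the optimal linear combination of two statistics
#'
#' The combination is `lambda * f + g` over centered statistic vectors; the
#' optimal `lambda` is a root of the quadratic stationarity condition of the
#' Rayleigh quotient.
#'
#' @slot statF,statG names of the scaled (f) and base (g) statistic.
#' @slot scale statistic scale the coefficient refers to.
#' @slot kind resolution function used.
#' @slot sense `"max"` (distance) or `"min"` (laplacian).
#' @slot lambda the optimal coefficient.
#' @slot raw Rayleigh quotient at the optimum.
#' @slot scaled scaled resolution at the optimum (NA if bounds not computed).
#' @slot lower,upper spectral bounds used for scaling.
#' @slot discriminant discriminant of the stationarity quadratic.
#' @slot roots both stationary points.
#' @slot plausible TRUE when lambda >= 0 (a nonnegative mixture).
#'
#' @seealso [optimalCombination()], [salessIndex()]
#' @export
setClass("CombinationResult",
         representation(statF = "character", statG = "character",
                        scale = "character", kind = "character",
                        sense = "character", lambda = "numeric",
                        raw = "numeric", scaled = "numeric",
                        lower = "numeric", upper = "numeric",
                        discriminant = "numeric", roots = "numeric",
                        plausible = "logical"))

# ------------------------------------------------------------- show methods

#' @export
setMethod("show", "TreeShape", function(object) {
  cat("TreeShape on", object@nLeaves, "leaves:", object@key, "\n")
})

#' @export
setMethod("show", "ShapeSpace", function(object) {
  cat("ShapeSpace:", length(object@keys), "shapes on", object@leafCount,
      "leaves\n")
})

#' @export
setMethod("show", "CayleyGraph", function(object) {
  cat("NNI CayleyGraph on", length(object@space@keys), "shapes (",
      object@space@leafCount, "leaves ),",
      sum(object@degrees) / 2, "edges\n")
})

#' @export
setMethod("show", "StatVector", function(object) {
  cat("StatVector '", object@name, "' (", object@scale, " scale) over ",
      length(object@values), " shapes on ", object@leafCount, " leaves\n",
      sep = "")
})

#' @export
setMethod("show", "SpectralBounds", function(object) {
  cat(sprintf("SpectralBounds (%s): [%.6g, %.6g]\n", object@role,
              object@lower, object@upper))
})

#' @export
setMethod("show", "ResolutionReport", function(object) {
  cat(sprintf(
    "ResolutionReport: %s under %s resolution (l = %d, n = %d)\n  raw %.6g in [%.6g, %.6g], scaled %.4f (%s is better)\n",
    object@statistic, object@kind, object@leafCount, object@nShapes,
    object@raw, object@lower, object@upper, object@scaled,
    if (object@kind == "distance") "higher" else "lower"))
})

#' @export
setMethod("show", "CombinationResult", function(object) {
  cat(sprintf(
    "CombinationResult: %g * %s + %s (%s scale) under %s resolution\n  raw %.6g, scaled %s, discriminant %.4g, %splausible\n",
    object@lambda, object@statF, object@statG, object@scale, object@kind,
    object@raw,
    if (is.na(object@scaled)) "NA" else sprintf("%.4f", object@scaled),
    object@discriminant, if (object@plausible) "" else "not "))
})
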