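# The NNI Cayley graph over a shape space and the matrices derived from it.

#' Shapes one NNI move away
#'
#' A nearest-neighbour-interchange move acts on an internal edge (both
#' endpoints internal nodes): the sibling of the lower endpoint is exchanged
#' with one of its two children, giving two alternative configurations per
#' internal edge.  Moves are applied to the rooted shape; results are
#' canonicalized, deduplicated, and the input shape itself (a move that is a
#' no-op up to isomorphism) is dropped.  A shape with `l` leaves has `l - 2`
#' internal edges and hence at most `2(l - 2)` neighbors.
#'
#' @param x a [TreeShape-class] or newick string.
#' @param keys if `TRUE` return canonical keys instead of shapes.
#' @param ... unused.
#' @return list of [TreeShape-class] (or character keys); empty for shapes
#'   with fewer than 3 leaves.
#' @examples
#' nniNeighbors(caterpillarShape(4))   # the balanced 4-leaf shape
#' nniNeighbors(treeShape("(,);"))     # none: no internal edge
#' @export
setMethod("nniNeighbors", "TreeShape", function(x, keys = FALSE, ...) {
  ks <- cpp_nni_neighbors(x@key)
  if (keys) ks else lapply(ks, .TreeShape)
})

#' @export
setMethod("nniNeighbors", "character", function(x, keys = FALSE, ...) {
  nniNeighbors(treeShape(x), keys = keys)
})

#' Build the NNI Cayley graph
#'
#' One vertex per shape of the space, an edge wherever a single NNI move
#' turns one shape into the other.  Every generated neighbor is looked up in
#' the space index; a missing neighbor aborts (it would mean enumeration and
#' move generation disagree).  NNI moves are reversible, so the edge set is
#' symmetric by construction; this is re-checked, not assumed.
#'
#' @param space a [ShapeSpace-class] with `leafCount >= 3`.
#' @return a [CayleyGraph-class].
#' @examples
#' g <- buildCayleyGraph(enumerateShapes(7))
#' nodeDegrees(g)
#' @export
buildCayleyGraph <- function(space) {
  stopifnot(is(space, "ShapeSpace"))
  if (space@leafCount < 3L)
    stop("the Cayley graph needs at least 3 leaves (no NNI moves below that)")
  el <- cpp_cayley_edges(space@keys)
  n <- length(space@keys)
  A <- Matrix::sparseMatrix(i = el[, 1], j = el[, 2], x = 1,
                            dims = c(n, n), symmetric = TRUE)
  A <- as(forceSymmetric(A), "generalMatrix")
  deg <- as.integer(Matrix::rowSums(A))
  new("CayleyGraph", space = space, adjacency = A, degrees = deg)
}

#' @export
setMethod("shapeSpace", "CayleyGraph", function(x) x@space)

#' @export
setMethod("adjacencyMatrix", "CayleyGraph", function(x) x@adjacency)

#' @export
setMethod("nodeDegrees", "CayleyGraph", function(x) x@degrees)

#' @export
setMethod("nShapes", "CayleyGraph", function(x) length(x@space@keys))

#' @export
setMethod("nLeaves", "CayleyGraph", function(x) x@space@leafCount)

.edge_matrix <- function(graph) {
  A <- graph@adjacency
  TT <- as(Matrix::triu(A), "TsparseMatrix")
  cbind(TT@i + 1L, TT@j + 1L)
}

#' Edge list of a Cayley graph
#'
#' @param graph a [CayleyGraph-class].
#' @return data.frame `from`, `to` (1-based shape indices, `from < to`).
#' @export
edgeTable <- function(graph) {
  stopifnot(is(graph, "CayleyGraph"))
  el <- .edge_matrix(graph)
  data.frame(from = el[, 1], to = el[, 2])
}

#' Graph Laplacian of the Cayley graph
#'
#' `L = Diag(degrees) - Adjacency`: symmetric, positive semidefinite, row
#' sums zero.  Its quadratic form is the Dirichlet energy
#' `x' L x = sum over edges (x_i - x_j)^2`.
#'
#' @param x a [CayleyGraph-class].
#' @return sparse symmetric matrix (`dsCMatrix`).
#' @export
setMethod("laplacianMatrix", "CayleyGraph", function(x) {
  forceSymmetric(Diagonal(x = as.numeric(x@degrees)) - x@adjacency)
})

#' All-pairs NNI distances
#'
#' Unweighted shortest-path lengths between every pair of shapes, by breadth-
#' first search from each vertex: the unlabeled NNI distance.  Dense storage
#' grows quadratically with the number of shapes, so sizes above `maxShapes`
#' are refused unless the guard is raised explicitly; quadratic forms in the
#' squared distances can always be computed without the matrix via
#' [dsCrossprod()].
#'
#' @param x a [CayleyGraph-class]; must be connected.
#' @param maxShapes dense-matrix memory guard (default 2500, enough for all
#'   shape spaces up to 14 leaves).
#' @param ... unused.
#' @return integer matrix of NNI distances.
#' @export
setMethod("distanceMatrix", "CayleyGraph", function(x, maxShapes = 2500, ...) {
  n <- length(x@space@keys)
  if (n > maxShapes)
    stop("space has ", n, " shapes; a dense distance matrix needs ~", n,
         "^2 entries. Raise 'maxShapes' explicitly, or use dsCrossprod().")
  D <- cpp_bfs_distances(n, .edge_matrix(x))
  if (anyNA(D)) {
    comp <- .components(x)
    stop("Cayley graph is disconnected (", max(comp),
         " components of sizes ", paste(tabulate(comp), collapse = ", "),
         "); this indicates a neighbor-generation bug")
  }
  D
})

.components <- function(graph) {
  el <- .edge_matrix(graph)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nShapes(graph) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Is the Cayley graph connected?
#'
#' @param graph a [CayleyGraph-class].
#' @export
isConnected <- function(graph) {
  stopifnot(is(graph, "CayleyGraph"))
  max(.components(graph)) == 1L
}

#' Quadratic forms in the squared NNI distance matrix, streamed
#'
#' Computes `Y' Ds Y`, where `Ds` is the elementwise square of the all-pairs
#' NNI distance matrix, one BFS row at a time, so `Ds` (the memory bottleneck
#' of the distance resolution) is never materialized.  This makes raw
#' distance resolutions available for spaces far beyond the dense guard.
#'
#' @param graph a connected [CayleyGraph-class].
#' @param Y numeric matrix (or vector) with one row per shape.
#' @return `t(Y) %*% Ds %*% Y` (symmetric, k x k).
#' @export
dsCrossprod <- function(graph, Y) {
  stopifnot(is(graph, "CayleyGraph"))
  Y <- as.matrix(Y)
  M <- cpp_ds_crossprod(nShapes(graph), .edge_matrix(graph), Y)
  dimnames(M) <- list(colnames(Y), colnames(Y))
  M
}
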