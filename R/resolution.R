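# The two resolution functions and their [0,1] scaling.

#' Raw resolution values
#'
#' `resolutionD(x, Ds) = -1/2 x' Ds x` scores a centered unit statistic
#' vector against the squared NNI distances: pairs of far-apart trees with
#' opposite-signed statistic values push it up, so higher means the statistic
#' separates dissimilar trees better.  `resolutionL(x, L) = x' L x` is the
#' Dirichlet energy of the statistic across graph edges,
#' `sum over edges (x_i - x_j)^2`: a good statistic assigns similar values to
#' adjacent (similar) trees, so lower is better.
#'
#' @param x centered unit vector (see [centerUnit()], [statisticVector()]).
#' @param Ds squared distance matrix.
#' @param L graph Laplacian (dense or sparse).
#' @return scalar.
#' @export
resolutionD <- function(x, Ds) {
  .check_centered_unit(x)
  if (length(x) != nrow(Ds)) stop("dimension mismatch between x and Ds")
  -0.5 * drop(crossprod(x, as.matrix(Ds) %*% x))
}

#' @rdname resolutionD
#' @export
resolutionL <- function(x, L) {
  .check_centered_unit(x)
  if (length(x) != nrow(L)) stop("dimension mismatch between x and L")
  drop(crossprod(x, as.numeric(L %*% x)))
}

.check_centered_unit <- function(x) {
  if (abs(sum(x)) > 1e-6 || abs(sum(x^2) - 1) > 1e-6)
    stop("'x' must be centered (zero mean) and unit-norm; see centerUnit()")
  invisible(x)
}

#' Scaled resolution of a statistic on a shape space
#'
#' Computes the raw resolution of one statistic under the chosen function and
#' rescales it to [0, 1] by the extreme Rayleigh-quotient eigenvalues:
#' `scaled = (raw - lower) / (upper - lower)`.  Under the distance resolution
#' higher scaled values are better; under the Laplacian resolution lower ones
#' are (the value is reported on its own scale, never flipped).
#'
#' @param graph a connected [CayleyGraph-class].
#' @param stat statistic name (see [statisticVector()]) or a
#'   [StatVector-class].
#' @param fun `"distance"` or `"laplacian"`.
#' @param bounds optional precomputed [SpectralBounds-class] (recomputed
#'   otherwise).
#' @param ... passed to [spectralBounds()].
#' @return a [ResolutionReport-class].
#' @examples
#' g <- buildCayleyGraph(enumerateShapes(7))
#' scaledResolution(g, "colless", "distance")   # scaled 0.925
#' @export
scaledResolution <- function(graph, stat, fun = c("distance", "laplacian"),
                             bounds = NULL, ...) {
  stopifnot(is(graph, "CayleyGraph"))
  fun <- match.arg(fun)
  sv <- if (is(stat, "StatVector")) stat
        else statisticVector(graph@space, stat)
  x <- sv@centered
  if (is.null(bounds)) bounds <- spectralBounds(graph, fun, ...)
  stopifnot(is(bounds, "SpectralBounds"), bounds@role == fun)
  raw <- if (fun == "laplacian") resolutionL(x, laplacianMatrix(graph))
         else resolutionD(x, distanceMatrix(graph, ...)^2)
  .make_report(sv@name, fun, raw, bounds, graph)
}

.make_report <- function(name, fun, raw, bounds, graph) {
  if (bounds@upper <= bounds@lower)
    stop("degenerate spectrum: upper bound does not exceed lower bound")
  new("ResolutionReport", statistic = name, kind = fun, raw = raw,
      lower = bounds@lower, upper = bounds@upper,
      scaled = (raw - bounds@lower) / (bounds@upper - bounds@lower),
      leafCount = graph@space@leafCount,
      nShapes = length(graph@space@keys))
}

#' Classical MDS embedding of tree space
#'
#' Embeds the shapes in `dims` Euclidean dimensions from the top eigenpairs
#' of `X_D` (classical multidimensional scaling, via [stats::cmdscale()]), so
#' that Euclidean distances approximate the NNI distances.  If fewer than
#' `dims` positive eigenvalues exist the remaining coordinates are zero and a
#' warning reports the reduced rank.
#'
#' @param D distance matrix (from [distanceMatrix()]).
#' @param dims embedding dimension.
#' @return list with `points` (n x dims matrix) and `eig` (all eigenvalues of
#'   `X_D`).
#' @examples
#' g <- buildCayleyGraph(enumerateShapes(7))
#' emb <- mdsEmbed(distanceMatrix(g))
#' @export
mdsEmbed <- function(D, dims = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(dims >= 1, dims <= n - 1)
  fit <- suppressWarnings(cmdscale(D, k = dims, eig = TRUE))
  pts <- fit$points
  # count genuinely positive eigenvalues (rank of the Gram matrix X_D)
  pos <- sum(fit$eig > 1e-9 * max(abs(fit$eig)))
  if (pos < dims) {
    warning("only ", pos, " positive eigenvalues: embedding has ",
            "reduced rank; padding with zero coordinates")
    keep <- pts[, seq_len(min(pos, ncol(pts))), drop = FALSE]
    pts <- cbind(keep, matrix(0, n, dims - ncol(keep)))
  }
  list(points = pts, eig = fit$eig)
}

#' Quartile bands of a statistic
#'
#' Splits values into the lower quartile, the inter-quartile interval and the
#' upper quartile, the coloring used to eyeball whether a statistic clusters
#' similar trees in an MDS picture of tree space.
#'
#' @param values numeric vector.
#' @return factor with levels `lower`, `mid`, `upper`.
#' @export
quartileBand <- function(values) {
  q <- quantile(values, c(0.25, 0.75))
  factor(ifelse(values < q[1], "lower", ifelse(values > q[2], "upper", "mid")),
         levels = c("lower", "mid", "upper"))
}

#' Scatter plot of an MDS embedding colored by a statistic
#'
#' @param embedding output of [mdsEmbed()] (or a two-column matrix).
#' @param values statistic values used for the quartile coloring (blue =
#'   lower quartile, red = inter-quartile, green = upper quartile).
#' @param ... passed to [graphics::plot()].
#' @export
plotShapeEmbedding <- function(embedding, values, ...) {
  pts <- if (is.list(embedding)) embedding$points else embedding
  band <- quartileBand(values)
  cols <- c(lower = "blue", mid = "red", upper = "green3")[as.character(band)]
  graphics::plot(pts[, 1], pts[, 2], col = cols, pch = 19,
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  invisible(band)
}
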