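# The seven tree shape statistics.
#
# For a shape with n leaves, leaf set L and internal node set I (the root
# included), with N_i the depth of node i, M_i the height of internal node i
# and r_i, s_i the leaf counts of the two child subtrees of i:
#
#   Colless   I_c    = 2/((n-1)(n-2)) * sum_{i in I} |r_i - s_i|
#   Sackin    Nbar   = (1/n) * sum_{j in L} N_j
#   sigma2           = (1/n) * sum_{j in L} (Nbar - N_j)^2
#   I2               = 1/(n-2) * sum_{i in I, r_i+s_i > 2} |r_i-s_i|/(r_i+s_i-2)
#   B1               = sum_{i in I, i != root} 1 / M_i
#   B2               = sum_{j in L} N_j / 2^N_j
#   cherries         = #{i in I : both children of i are leaves}
#
# The "aggregate" scale drops the normalizing constants (Colless -> the bare
# imbalance sum, Sackin -> the depth sum, sigma2 -> the centered sum of
# squares, I2 -> the bare sum); it is the scale on which the published
# combination coefficients live.  Scaled resolutions are identical on either
# scale (they are Rayleigh quotients).

.stat_from_raw <- function(raw, stat, scale = c("printed", "aggregate")) {
  scale <- match.arg(scale)
  l <- raw[, "leaves"]
  switch(stat,
    colless = if (scale == "printed")
      2 * raw[, "sum_imb"] / ((l - 1) * (l - 2)) else raw[, "sum_imb"],
    sackin = if (scale == "printed")
      raw[, "sum_depth"] / l else raw[, "sum_depth"],
    sigma2 = {
      v <- raw[, "sum_depth2"] / l - (raw[, "sum_depth"] / l)^2
      if (scale == "printed") v else v * l
    },
    i2 = if (scale == "printed")
      raw[, "i2_sum"] / (l - 2) else raw[, "i2_sum"],
    b1 = raw[, "b1"],
    b2 = raw[, "b2"],
    cherries = raw[, "cherries"],
    stop("unknown statistic '", stat, "'")
  )
}

.keys_of <- function(x) {
  if (is(x, "ShapeSpace")) x@keys
  else if (is(x, "TreeShape")) x@key
  else if (is.character(x)) canonicalKey(x)
  else if (inherits(x, "phylo")) treeShape(x)@key
  else stop("expected a TreeShape, ShapeSpace, phylo or newick character")
}

.one_stat <- function(x, stat, min_leaves = 1L) {
  keys <- .keys_of(x)
  raw <- cpp_shape_stats(keys)
  if (any(raw[, "leaves"] < min_leaves))
    stop(sprintf("'%s' requires at least %d leaves", stat, min_leaves))
  unname(.stat_from_raw(raw, stat))
}

#' Tree shape statistics
#'
#' Seven classical summaries of the imbalance of a rooted bifurcating tree
#' shape.  All accept a [TreeShape-class], a [ShapeSpace-class] (vectorized
#' over all shapes, in space order), a newick string, or a `phylo` tree
#' (labels and branch lengths ignored).
#'
#' `collessIndex` is the normalized sum of per-node imbalances |r - s|, 0 for
#' the maximally balanced shape and 1 for the caterpillar (needs >= 3
#' leaves).  `sackinIndex` is the mean root-to-leaf depth and
#' `depthVariance` its population variance.  `i2Index` is imbalance
#' inversely weighted by subtree size, in [0, 1] (needs >= 3 leaves).
#' `b1Index` sums reciprocal subtree heights over non-root internal nodes and
#' `b2Index` sums `N/2^N` over leaf depths `N`.  `nCherries` counts internal
#' nodes with two leaf children.
#'
#' @param x the shape(s).
#' @return numeric (or integer for `nCherries`) vector, one value per shape.
#' @examples
#' collessIndex(caterpillarShape(7))      # 1
#' sackinIndex(balancedShape(8))          # 3
#' b1Index(caterpillarShape(7))           # 1/5 + 1/4 + 1/3 + 1/2 + 1
#' shapeStatistics(enumerateShapes(5))
#' @export
setGeneric("collessIndex", function(x) standardGeneric("collessIndex"))

#' @rdname collessIndex
#' @export
setGeneric("sackinIndex", function(x) standardGeneric("sackinIndex"))

#' @rdname collessIndex
#' @export
setGeneric("depthVariance", function(x) standardGeneric("depthVariance"))

#' @rdname collessIndex
#' @export
setGeneric("i2Index", function(x) standardGeneric("i2Index"))

#' @rdname collessIndex
#' @export
setGeneric("b1Index", function(x) standardGeneric("b1Index"))

#' @rdname collessIndex
#' @export
setGeneric("b2Index", function(x) standardGeneric("b2Index"))

#' @rdname collessIndex
#' @export
setGeneric("nCherries", function(x) standardGeneric("nCherries"))

.stat_classes <- c("TreeShape", "ShapeSpace", "character", "phylo")
for (.cl in .stat_classes) {
  setMethod("collessIndex", .cl, function(x) .one_stat(x, "colless", 3L))
  setMethod("sackinIndex", .cl, function(x) .one_stat(x, "sackin"))
  setMethod("depthVariance", .cl, function(x) .one_stat(x, "sigma2"))
  setMethod("i2Index", .cl, function(x) .one_stat(x, "i2", 3L))
  setMethod("b1Index", .cl, function(x) .one_stat(x, "b1", 2L))
  setMethod("b2Index", .cl, function(x) .one_stat(x, "b2"))
  setMethod("nCherries", .cl, function(x) as.integer(.one_stat(x, "cherries")))
}

#' All statistics over a set of shapes
#'
#' @param x shapes as in [collessIndex()].
#' @param scale `"printed"` or `"aggregate"` (see [statisticVector()]).
#' @return data.frame with one row per shape: `newick` plus one column per
#'   statistic.
#' @export
shapeStatistics <- function(x, scale = c("printed", "aggregate")) {
  scale <- match.arg(scale)
  keys <- .keys_of(x)
  raw <- cpp_shape_stats(keys)
  cols <- lapply(.stat_names, function(s) unname(.stat_from_raw(raw, s, scale)))
  names(cols) <- .stat_names
  data.frame(newick = keys, cols, row.names = NULL)
}

#' Statistic vector over a shape space
#'
#' Evaluates one statistic on every shape of a space and stores, next to the
#' raw values `y`, the centered unit vector `x = H y / ||H y||` that both
#' resolution functions operate on.  The statistic must not be constant on
#' the space.
#'
#' On the `"aggregate"` scale Colless and Sackin (and sigma2, I2) are the
#' bare sums without normalizing constants.  Resolutions of a single
#' statistic are identical on either scale; combination coefficients are not,
#' and published ones refer to the aggregate scale.
#'
#' @param space a [ShapeSpace-class].
#' @param stat one of `"colless"`, `"sackin"`, `"sigma2"`, `"i2"`, `"b1"`,
#'   `"b2"`, `"cherries"`.
#' @param scale `"printed"` or `"aggregate"`.
#' @return a [StatVector-class].
#' @export
statisticVector <- function(space, stat = .stat_names,
                            scale = c("printed", "aggregate")) {
  stopifnot(is(space, "ShapeSpace"))
  stat <- match.arg(stat)
  scale <- match.arg(scale)
  raw <- cpp_shape_stats(space@keys)
  y <- unname(.stat_from_raw(raw, stat, scale))
  new("StatVector", name = stat, scale = scale, values = y,
      centered = centerUnit(y, stat), leafCount = space@leafCount)
}

#' Center and normalize a statistic vector
#'
#' Applies the centering matrix H = I - (1/n) 11^t and rescales to unit
#' Euclidean norm.  Errors on a constant vector (zero after centering), for
#' which no resolution is defined.
#'
#' @param y numeric vector.
#' @param label statistic name used in the error message.
#' @return centered unit vector.
#' @export
centerUnit <- function(y, label = "statistic") {
  z <- y - mean(y)
  nrm <- sqrt(sum(z^2))
  if (nrm <= 1e-12 * max(1, sqrt(sum(y^2))))
    stop("degenerate statistic: '", label,
         "' is constant over the shape space")
  z / nrm
}

#' The Saless index of a single shape
#'
#' `lambda * Sackin + Colless`.  On the default `"printed"` scale the
#' constituents carry their defining normalizations; on the `"aggregate"`
#' scale (bare sums) `lambda` is comparable with coefficients estimated by
#' [optimalCombination()].
#'
#' @param x shape(s) as in [collessIndex()]; >= 3 leaves.
#' @param lambda finite coefficient.
#' @param scale `"printed"` or `"aggregate"`.
#' @return numeric vector.
#' @examples
#' salessIndex(caterpillarShape(7), 1)   # 27/7 + 1
#' salessIndex(balancedShape(8), 2)      # 2*3 + 0
#' @export
salessIndex <- function(x, lambda, scale = c("printed", "aggregate")) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  scale <- match.arg(scale)
  keys <- .keys_of(x)
  raw <- cpp_shape_stats(keys)
  if (any(raw[, "leaves"] < 3))
    stop("the Saless index requires at least 3 leaves")
  unname(lambda * .stat_from_raw(raw, "sackin", scale) +
           .stat_from_raw(raw, "colless", scale))
}
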