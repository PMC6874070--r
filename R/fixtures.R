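# Reference shapes: the two extremes of imbalance.

#' Caterpillar and maximally balanced shapes
#'
#' The caterpillar (completely asymmetric shape) is the unique shape in which
#' every internal node has a leaf child; it maximizes the Colless and I2
#' indices.  The maximally balanced (completely symmetric) shape is the
#' unique shape with |r - s| <= 1 at every internal node, obtained by
#' recursively splitting l into ceiling(l/2) and floor(l/2); it minimizes
#' them.
#'
#' @param l number of leaves (>= 1).
#' @return a [TreeShape-class].
#' @examples
#' caterpillarShape(7)
#' balancedShape(8)    # the perfect binary tree of depth 3
#' @export
caterpillarShape <- function(l) {
  stopifnot(length(l) == 1L, l >= 1, l == as.integer(l))
  key <- ""
  for (i in seq_len(l - 1)) key <- paste0("(,", key, ")")
  .TreeShape(paste0(key, ";"))
}

#' @rdname caterpillarShape
#' @export
balancedShape <- function(l) {
  stopifnot(length(l) == 1L, l >= 1, l == as.integer(l))
  rec <- function(m) {
    if (m == 1L) return("")
    a <- rec(ceiling(m / 2))
    b <- rec(floor(m / 2))
    paste0("(", b, ",", a, ")")  # floor half first (fewer leaves)
  }
  # run through the canonicalizer: equal-size halves need key ordering
  .TreeShape(cpp_canonical_newick(paste0(rec(l), ";")))
}
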