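# Enumeration, canonicalization and serialization of tree shapes.

.TreeShape <- function(key) {
  new("TreeShape", key = key, nLeaves = (nchar(key) + 2L) %/% 3L)
}

#' Enumerate all tree shapes on l leaves
#'
#' Builds the complete set of isomorphism classes of unlabeled rooted
#' bifurcating trees with `l` leaves, by the recursive rule that every shape
#' is an unordered pair of smaller shapes whose leaf counts sum to `l`.  The
#' number of shapes is the Wedderburn-Etherington number of `l` (11 for
#' l = 7, 24631 for l = 17) and grows roughly like 2.48^l.
#'
#' Shapes are returned sorted by canonical key, so the coordinate order of
#' every downstream vector and matrix is reproducible run to run.
#'
#' @param l number of leaves (positive integer).
#' @return a [ShapeSpace-class].
#' @examples
#' enumerateShapes(7)           # 11 shapes
#' shapeKeys(enumerateShapes(4))
#' @export
enumerateShapes <- function(l) {
  if (length(l) != 1L || is.na(l) || !is.numeric(l) || l != as.integer(l) ||
      l < 1)
    stop("'l' must be a single positive integer")
  new("ShapeSpace", leafCount = as.integer(l),
      keys = cpp_enumerate_shapes(as.integer(l)))
}

#' Wedderburn-Etherington numbers
#'
#' Counts of unlabeled rooted bifurcating tree shapes by leaf number, from
#' the classical recurrence; used as an independent cross-check on
#' [enumerateShapes()].
#'
#' @param l maximum leaf count.
#' @return numeric vector `w` with `w[k]` = number of shapes on `k` leaves.
#' @export
wedderburnEtherington <- function(l) {
  w <- numeric(l)
  w[1] <- 1
  for (m in seq_len(l)[-1]) {
    h <- (m - 1) %/% 2
    w[m] <- sum(w[seq_len(h)] * w[m - seq_len(h)])
    if (m %% 2 == 0) w[m] <- w[m] + w[m / 2] * (w[m / 2] + 1) / 2
  }
  w
}

#' Canonical form of a rooted bifurcating tree
#'
#' `treeShape()` turns a newick string or an [ape::phylo] tree into a
#' [TreeShape-class].  Leaf labels and branch lengths are ignored; children
#' are recursively ordered by (subtree leaf count, canonical key), so two
#' inputs get the same key exactly when they are isomorphic as unlabeled
#' rooted trees.  Multifurcating (including unrooted, which newick encodes as
#' a basal trifurcation) input is an error.
#'
#' @param x a newick string (labels/branch lengths tolerated and discarded)
#'   or a rooted binary `phylo` object.
#' @return a [TreeShape-class].
#' @examples
#' treeShape("((A:1,B:2),(C,D));")   # balanced 4-leaf shape
#' treeShape("(,(,(,)));")           # 4-leaf caterpillar
#' @export
treeShape <- function(x) {
  if (inherits(x, "phylo")) x <- ape::write.tree(x)
  if (!is.character(x) || length(x) != 1L)
    stop("'x' must be a single newick string or a 'phylo' tree")
  .TreeShape(cpp_canonical_newick(x))
}

#' @describeIn treeShape the canonical key (unlabeled newick string) of a
#'   shape.
#' @export
setMethod("canonicalKey", "TreeShape", function(x) x@key)

#' @export
setMethod("canonicalKey", "character", function(x) {
  vapply(x, cpp_canonical_newick, "", USE.NAMES = FALSE)
})

#' @export
setMethod("nLeaves", "TreeShape", function(x) x@nLeaves)

#' @export
setMethod("nLeaves", "ShapeSpace", function(x) x@leafCount)

#' @export
setMethod("shapeKeys", "ShapeSpace", function(x) x@keys)

#' @export
setMethod("nShapes", "ShapeSpace", function(x) length(x@keys))

#' @export
setMethod("length", "ShapeSpace", function(x) length(x@keys))

#' Extract one shape from a space
#' @param x a [ShapeSpace-class].
#' @param i index.
#' @export
setMethod("[[", "ShapeSpace", function(x, i) .TreeShape(x@keys[[i]]))

#' Write a shape as unlabeled newick
#'
#' The writer emits the canonical key itself: unlabeled, no branch lengths,
#' semicolon-terminated (e.g. `"((,),(,(,)));"`).  Round-tripping through
#' [treeShape()] is the identity on isomorphism classes.
#'
#' @param x a [TreeShape-class].
#' @param ... unused.
#' @export
setMethod("writeNewick", "TreeShape", function(x, ...) x@key)

#' Export / import shape lists
#'
#' One canonical newick per line, in space order, so that matrix coordinates
#' can be reconstructed exactly.
#'
#' @param space a [ShapeSpace-class].
#' @param file path.
#' @return `exportShapes` returns `file` invisibly; `readShapeFile` returns a
#'   list of [TreeShape-class] (canonicalizing whatever newick it finds).
#' @export
exportShapes <- function(space, file) {
  stopifnot(is(space, "ShapeSpace"))
  writeLines(space@keys, file)
  invisible(file)
}

#' @rdname exportShapes
#' @export
readShapeFile <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, treeShape)
}

#' Convert a shape to an ape phylo tree
#'
#' Attaches placeholder tip labels (`t1`, `t2`, ...) so the shape can be fed
#' to ape/phangorn functions.
#'
#' @param shape a [TreeShape-class].
#' @return a `phylo` object.
#' @export
shapePhylo <- function(shape) {
  stopifnot(is(shape, "TreeShape"))
  txt <- shape@key
  n <- shape@nLeaves
  if (n == 1L) return(ape::read.tree(text = "(t1);"))
  # label leaves left to right: a leaf position is a '(' or ',' followed by
  # ',' or ')'
  out <- character(0)
  chars <- strsplit(txt, "")[[1]]
  cnt <- 0L
  for (i in seq_along(chars)) {
    out <- c(out, chars[i])
    if (chars[i] %in% c("(", ",") && chars[i + 1L] %in% c(",", ")")) {
      cnt <- cnt + 1L
      out <- c(out, paste0("t", cnt))
    }
  }
  ape::read.tree(text = paste(out, collapse = ""))
}

#' Random tree shapes under the Yule or PDA model
#'
#' Under the Yule (equal-rates Markov) model the tree grows from a single
#' lineage and at each step a uniformly chosen extant lineage splits, until
#' `l` tips.  Under the PDA model every labeled rooted topology on `l` tips
#' is equally likely (generated by uniform sequential attachment) and labels
#' are then dropped, so each shape's probability is proportional to its
#' number of labeled representatives.  Both generators draw from R's RNG, so
#' `set.seed()` makes them reproducible.
#'
#' @param l number of leaves (>= 1).
#' @param model `"yule"` or `"pda"`.
#' @return `randomShape` returns a single [TreeShape-class];
#'   `randomShapeKeys` returns `n` canonical keys (efficient for large
#'   replicate counts).
#' @examples
#' set.seed(1)
#' randomShape(8, "yule")
#' table(randomShapeKeys(4, 1000, "pda"))
#' @export
randomShape <- function(l, model = c("yule", "pda")) {
  model <- match.arg(model)
  .TreeShape(cpp_random_shapes(as.integer(l), model, 1L)[[1L]])
}

#' @rdname randomShape
#' @param n number of independent draws.
#' @export
randomShapeKeys <- function(l, n, model = c("yule", "pda")) {
  model <- match.arg(model)
  cpp_random_shapes(as.integer(l), model, as.integer(n))
}
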