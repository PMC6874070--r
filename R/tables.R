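# Table emitters: whole-space summaries over a range of leaf counts.

.classical_stats <- c("colless", "sackin", "sigma2", "i2", "b1", "b2")

.graph_for <- function(l) buildCayleyGraph(enumerateShapes(l))

#' Resolution table over a range of leaf counts
#'
#' Scores each statistic on every shape space in `leaves` under one
#' resolution function; with `"saless"` among the statistics, the row reports
#' the optimally combined Sackin/Colless statistic (coefficient on the
#' aggregate scale) under that same function.
#'
#' @param leaves integer vector of leaf counts (each >= 4).
#' @param statistics statistic names; default: the six classical statistics,
#'   plus `"saless"` under the distance resolution.
#' @param fun `"distance"` or `"laplacian"`.
#' @param verbose log progress (per leaf count) to standard error.
#' @param ... passed to [spectralBounds()] / [distanceMatrix()] (e.g.
#'   `maxShapes` to raise the dense guard).
#' @return data.frame with columns `l`, `n`, `statistic`, `raw`, `lower`,
#'   `upper`, `scaled`, `lambda` (NA except for `"saless"`).
#' @examples
#' resolutionTable(7, fun = "laplacian")
#' @export
resolutionTable <- function(leaves, statistics = NULL,
                            fun = c("distance", "laplacian"),
                            verbose = FALSE, ...) {
  fun <- match.arg(fun)
  if (is.null(statistics))
    statistics <- if (fun == "distance") c(.classical_stats, "saless")
                  else .classical_stats
  if (length(statistics) == 0) stop("no statistics requested")
  rows <- list()
  for (l in leaves) {
    t0 <- proc.time()[3]
    graph <- .graph_for(l)
    bounds <- spectralBounds(graph, fun, ...)
    for (st in statistics) {
      if (st == "saless") {
        cmb <- optimalCombination(graph, "sackin", "colless", fun,
                                  bounds = bounds, ...)
        rep <- list(raw = cmb@raw, lower = cmb@lower, upper = cmb@upper,
                    scaled = cmb@scaled, lambda = cmb@lambda)
      } else {
        r <- scaledResolution(graph, st, fun, bounds = bounds, ...)
        rep <- list(raw = r@raw, lower = r@lower, upper = r@upper,
                    scaled = r@scaled, lambda = NA_real_)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(l = l, n = nShapes(graph), statistic = st, raw = rep$raw,
                   lower = rep$lower, upper = rep$upper, scaled = rep$scaled,
                   lambda = rep$lambda)
    }
    if (verbose)
      message(sprintf(
        "l = %d: n = %d, %d edges, bounds [%.4g, %.4g], %.1fs", l,
        nShapes(graph), sum(nodeDegrees(graph)) / 2, bounds@lower,
        bounds@upper, proc.time()[3] - t0))
  }
  do.call(rbind, rows)
}

#' Optimal-combination table over a range of leaf counts
#'
#' One row per leaf count and statistic pair, reporting the optimal
#' coefficient (`lambda` multiplies the first statistic of the pair, on the
#' aggregate scale) and the scaled resolution at the optimum.
#'
#' @param leaves integer vector of leaf counts.
#' @param pairs list of 2-element character vectors `c(f, g)`.  Default: the
#'   three combinations `lambda*Colless + B2`, `lambda*B2 + B1` and
#'   `lambda*Colless + Sackin` studied under the Laplacian resolution.
#' @param fun `"distance"` or `"laplacian"`.
#' @param verbose log progress to standard error.
#' @param ... passed to [spectralBounds()].
#' @return data.frame with columns `l`, `n`, `pair`, `lambda`, `raw`,
#'   `scaled`, `discriminant`, `plausible`.
#' @examples
#' combinationTable(8, pairs = list(c("sackin", "colless")), fun = "distance")
#' @export
combinationTable <- function(leaves,
                             pairs = list(c("colless", "b2"),
                                          c("b2", "b1"),
                                          c("colless", "sackin")),
                             fun = c("distance", "laplacian"),
                             verbose = FALSE, ...) {
  fun <- match.arg(fun)
  if (!is.list(pairs)) pairs <- list(pairs)
  rows <- list()
  for (l in leaves) {
    graph <- .graph_for(l)
    bounds <- spectralBounds(graph, fun, ...)
    for (pr in pairs) {
      stopifnot(length(pr) == 2L)
      cmb <- optimalCombination(graph, pr[1], pr[2], fun, bounds = bounds, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(l = l, n = nShapes(graph),
                   pair = paste(pr, collapse = ":"), lambda = cmb@lambda,
                   raw = cmb@raw, scaled = cmb@scaled,
                   discriminant = cmb@discriminant,
                   plausible = cmb@plausible)
    }
    if (verbose) message(sprintf("l = %d done (n = %d)", l, nShapes(graph)))
  }
  do.call(rbind, rows)
}

#' Per-shape statistic table
#'
#' One row per shape of the space (canonical newick) with the requested
#' statistics as columns; the row order fixes the coordinate system of all
#' matrices.
#'
#' @param space a [ShapeSpace-class].
#' @param statistics subset of the statistic names.
#' @param scale `"printed"` or `"aggregate"`.
#' @return data.frame.
#' @export
statTable <- function(space, statistics = .stat_names,
                      scale = c("printed", "aggregate")) {
  statistics <- match.arg(statistics, .stat_names, several.ok = TRUE)
  df <- shapeStatistics(space, scale)
  df[, c("newick", statistics)]
}

#' Regenerate a summary table and write it as TSV
#'
#' `which = "t1"` writes the optimal Saless coefficients and scaled distance
#' resolutions by leaf count; `"t2"` the scaled distance resolutions of the
#' classical statistics plus Saless; `"t3"` the scaled Laplacian resolutions
#' of the classical statistics; `"t4"` the optimal pairwise combinations
#' under the Laplacian resolution.  Output is deterministic: identical
#' configurations give byte-identical files.
#'
#' @param which `"t1"`, `"t2"`, `"t3"` or `"t4"`.
#' @param leaves leaf counts; defaults: 7:13 for t1/t2 (dense distance
#'   matrices), 7:17 for t3/t4.
#' @param out output TSV path (created), or NULL to skip writing.
#' @param digits rounding applied to the written table (full precision is
#'   returned invisibly); 3 for t2, 4 for t3/t4 scaled values, 2 for lambdas.
#' @param verbose log progress to standard error.
#' @param ... passed down (e.g. `maxShapes`).
#' @return the full-precision data.frame, invisibly.
#' @export
runTable <- function(which = c("t1", "t2", "t3", "t4"), leaves = NULL,
                     out = NULL, digits = NULL, verbose = TRUE, ...) {
  which <- match.arg(which)
  if (is.null(leaves)) leaves <- if (which %in% c("t1", "t2")) 7:13 else 7:17
  wide <- function(df, value) {
    out <- do.call(rbind, lapply(split(df, df$l), function(d) {
      v <- d[[value]]
      names(v) <- if ("statistic" %in% names(d)) d$statistic else d$pair
      data.frame(l = d$l[1], n = d$n[1], t(v), check.names = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  res <- switch(which,
    t1 = {
      df <- combinationTable(leaves, list(c("sackin", "colless")),
                             fun = "distance", verbose = verbose, ...)
      data.frame(l = df$l, n = df$n, lambda = df$lambda, scaledRD = df$scaled)
    },
    t2 = wide(resolutionTable(leaves, fun = "distance", verbose = verbose,
                              ...), "scaled"),
    t3 = wide(resolutionTable(leaves, fun = "laplacian", verbose = verbose,
                              ...), "scaled"),
    t4 = {
      df <- combinationTable(leaves, fun = "laplacian", verbose = verbose,
                             ...)
      a <- wide(df, "scaled")
      b <- wide(df, "lambda")
      names(b)[-(1:2)] <- paste0("lambda.", names(b)[-(1:2)])
      cbind(a, b[, -(1:2), drop = FALSE])
    })
  if (!is.null(out)) {
    w <- res
    if (is.null(digits)) digits <- if (which == "t2") 3 else 4
    num <- vapply(w, is.numeric, TRUE) & !(names(w) %in% c("l", "n"))
    lamcol <- grepl("lambda", names(w))
    w[num & !lamcol] <- lapply(w[num & !lamcol], round, digits)
    w[num & lamcol] <- lapply(w[num & lamcol], round, 2)
    write.table(w, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
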