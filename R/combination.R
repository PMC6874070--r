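# Optimal linear combinations of two statistics.
#
# For centered vectors a (statistic f) and b (statistic g), the combination
# v(lambda) = lambda*a + b has Rayleigh quotient
#   R(lambda) = (p lambda^2 + 2 q lambda + r) / (s lambda^2 + 2 t lambda + u)
# with p = a'Aa, q = a'Ab, r = b'Ab, s = a'a, t = a'b, u = b'b and A the
# quadratic form of the chosen resolution (X_D or L).  Setting the derivative
# of the quotient to zero gives the quadratic
#   (p t - q s) lambda^2 + (p u - r s) lambda + (q u - r t) = 0
# whose roots are the stationary points; the one with the better objective in
# the requested sense is the optimum.  R(lambda) is invariant under a common
# rescaling of v, so scaled resolutions do not depend on the statistic scale;
# lambda itself does.

.rayleigh_coef <- function(lambda, p, q, r, s, t, u) {
  (p * lambda^2 + 2 * q * lambda + r) / (s * lambda^2 + 2 * t * lambda + u)
}

#' Optimal combination coefficient from precomputed quadratic forms
#'
#' Low-level solver used by [optimalCombination()]; useful when the quadratic
#' form matrix is too large to materialize and `P` was obtained from
#' [dsCrossprod()] instead.
#'
#' @param P 2x2 matrix of quadratic forms `[a'Aa, a'Ab; a'Ab, b'Ab]` for
#'   centered statistic vectors `a` (scaled by lambda) and `b`.
#' @param S 2x2 Gram matrix `[a'a, a'b; a'b, b'b]`.
#' @param sense `"max"` or `"min"`.
#' @return list with `lambda`, `value` (Rayleigh quotient at the optimum),
#'   `roots`, `discriminant`, and the Rayleigh limits `atZero` (= R of g
#'   alone) and `atInf` (= R of f alone).
#' @export
optimalLambdaFromForms <- function(P, S, sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- P[1, 1]; q <- P[1, 2]; r <- P[2, 2]
  s <- S[1, 1]; t <- S[1, 2]; u <- S[2, 2]
  if (s <= 0 || u <= 0 || s * u - t * t <= 1e-12 * s * u)
    stop("degenerate combination: centered statistic vectors are (nearly) ",
         "linearly dependent, the Rayleigh quotient is constant in lambda")
  A <- p * t - q * s
  B <- p * u - r * s
  C <- q * u - r * t
  disc <- B^2 - 4 * A * C
  if (disc < 0)
    stop(sprintf(
      "stationarity quadratic has complex roots (discriminant %.4g < 0)",
      disc))
  roots <- if (abs(A) < 1e-14 * max(abs(B), abs(C), 1)) -C / B
           else (-B + c(1, -1) * sqrt(disc)) / (2 * A)
  vals <- .rayleigh_coef(roots, p, q, r, s, t, u)
  ord <- order(if (sense == "max") -vals else vals, abs(roots))
  best <- ord[1]
  lam <- roots[best]
  val <- vals[best]
  # internal cross-check: a coarse grid over lambda must not beat the root
  grid <- c(seq(-100, 100, length.out = 4001),
            lam + seq(-1, 1, length.out = 201))
  gvals <- .rayleigh_coef(grid, p, q, r, s, t, u)
  gap <- if (sense == "max") max(gvals) - val else val - min(gvals)
  if (gap > 1e-8 * max(1, abs(val)))
    stop("internal check failed: grid search found a better lambda than the ",
         "stationarity roots")
  list(lambda = lam, value = val, roots = roots, discriminant = disc,
       atZero = r / u, atInf = p / s)
}

#' Optimal combination coefficient from vectors and a matrix
#'
#' @param f,g numeric statistic vectors (raw; centered internally, not
#'   individually normalized) or [StatVector-class] objects.
#' @param A the quadratic-form matrix: the Laplacian, or `X_D` (see
#'   [xdMatrix()]).
#' @param sense `"max"` or `"min"`.
#' @return as [optimalLambdaFromForms()].
#' @export
optimalLambda <- function(f, g, A, sense = c("max", "min")) {
  if (is(f, "StatVector")) f <- f@values
  if (is(g, "StatVector")) g <- g@values
  a <- f - mean(f)
  b <- g - mean(g)
  Aa <- as.numeric(A %*% a)
  Ab <- as.numeric(A %*% b)
  P <- matrix(c(sum(a * Aa), sum(a * Ab), sum(a * Ab), sum(b * Ab)), 2, 2)
  S <- matrix(c(sum(a * a), sum(a * b), sum(a * b), sum(b * b)), 2, 2)
  optimalLambdaFromForms(P, S, sense)
}

#' Optimal linear combination of two statistics on a shape space
#'
#' Finds the coefficient `lambda` for which `lambda * f + g` has the best
#' resolution: maximal under the distance resolution, minimal under the
#' Laplacian one.  Statistic vectors are centered but not individually
#' normalized, and by default taken on the `"aggregate"` (unnormalized sum)
#' scale, the scale on which published coefficients are reported -- the
#' Saless index, `lambda * Sackin + Colless`, corresponds to
#' `f = "sackin", g = "colless"` under `fun = "distance"`.  The combination
#' is always at least as well resolved as either constituent (the limits
#' `lambda -> 0` and `lambda -> Inf`); negative optimal `lambda` is allowed
#' and only flagged as implausible, not an error.
#'
#' @param graph a connected [CayleyGraph-class].
#' @param f,g statistic names; `lambda` multiplies `f`.
#' @param fun `"distance"` (maximize) or `"laplacian"` (minimize).
#' @param scale statistic scale for both constituents.
#' @param bounds optional precomputed [SpectralBounds-class]; set
#'   `bounds = NA` to skip scaling (raw optimum only, no eigensolve).
#' @param ... passed to [spectralBounds()] / [distanceMatrix()].
#' @return a [CombinationResult-class].
#' @examples
#' g7 <- buildCayleyGraph(enumerateShapes(7))
#' optimalCombination(g7, "sackin", "colless", "distance")  # the Saless index
#' @export
optimalCombination <- function(graph, f, g, fun = c("distance", "laplacian"),
                               scale = c("aggregate", "printed"),
                               bounds = NULL, ...) {
  stopifnot(is(graph, "CayleyGraph"))
  fun <- match.arg(fun)
  scale <- match.arg(scale)
  sense <- if (fun == "distance") "max" else "min"
  yf <- statisticVector(graph@space, f, scale)@values
  yg <- statisticVector(graph@space, g, scale)@values
  a <- yf - mean(yf)
  b <- yg - mean(yg)
  if (fun == "laplacian") {
    opt <- optimalLambda(a, b, laplacianMatrix(graph), sense)
  } else {
    M <- dsCrossprod(graph, cbind(a, b))
    # for centered vectors, v' X_D v = -1/2 v' Ds v
    opt <- optimalLambdaFromForms(-0.5 * M,
                                  crossprod(cbind(a, b)), sense)
  }
  scaled <- lower <- upper <- NA_real_
  skip_scaling <- is.logical(bounds) && length(bounds) == 1L && is.na(bounds)
  if (!skip_scaling) {
    if (is.null(bounds)) bounds <- spectralBounds(graph, fun, ...)
    stopifnot(is(bounds, "SpectralBounds"), bounds@role == fun)
    lower <- bounds@lower
    upper <- bounds@upper
    scaled <- (opt$value - lower) / (upper - lower)
  }
  new("CombinationResult", statF = f, statG = g, scale = scale, kind = fun,
      sense = sense, lambda = opt$lambda, raw = opt$value, scaled = scaled,
      lower = lower, upper = upper, discriminant = opt$discriminant,
      roots = opt$roots, plausible = opt$lambda >= 0)
}
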