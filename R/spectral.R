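# Extreme eigenvalues bounding the two resolution functions.
#
# Laplacian: on a connected graph 0 is a simple eigenvalue of L (constant
# eigenvector), so over centered vectors the Rayleigh quotient of L ranges
# between the Fiedler value (second smallest eigenvalue) and the largest
# eigenvalue. Distance: the Rayleigh quotient of X_D = -1/2 H Ds H ranges
# between its extreme eigenvalues (Courant-Fischer).
#
# Small problems use a dense symmetric eigensolve; large Laplacians use
# ARPACK Lanczos iterations (via igraph): the largest eigenvalue with
# which = "LA", the two smallest with which = "SA".  The smallest must be ~0
# with a ~constant eigenvector (connectedness); the second smallest is the
# Fiedler value.  The Fiedler eigenvector's residual is verified rather than
# trusted.  (A shift-invert transform is the textbook accelerator here, but
# the Cayley graph is expander-like and its Cholesky factor fills in almost
# densely, while plain "SA" Lanczos converges in well under a second even at
# 25k shapes.)

.DENSE_EIG_LIMIT <- 1500L

.arpack_sym <- function(matvec, n, nev, which, tol) {
  igraph::arpack(function(x, extra) matvec(x), sym = TRUE,
                 options = list(n = n, nev = nev, ncv = max(30, 4 * nev),
                                which = which, maxiter = 30000, tol = tol))
}

.laplacian_bounds_sparse <- function(L, tol = 1e-9) {
  n <- nrow(L)
  mv <- function(x) as.numeric(L %*% x)
  lmax <- .arpack_sym(mv, n, 1L, "LA", tol)$values[1]
  bot <- .arpack_sym(mv, n, 2L, "SA", tol)
  vals <- sort(bot$values)
  if (abs(vals[1]) > 1e-7 * max(1, lmax))
    stop("smallest Laplacian eigenvalue is not ~0; input is not a Laplacian")
  fiedler <- vals[2]
  v <- bot$vectors[, order(bot$values)[2]]
  v <- v - mean(v)  # deflate the constant direction explicitly
  v <- v / sqrt(sum(v^2))
  resid <- sqrt(sum((mv(v) - fiedler * v)^2))
  if (!is.finite(fiedler) || resid > 1e-6 * max(1, lmax))
    stop(sprintf(
      "Fiedler eigensolve did not converge (residual %.3g, tolerance %.3g)",
      resid, 1e-6 * max(1, lmax)))
  if (fiedler <= 1e-8 * lmax)
    stop("Fiedler value is numerically zero: the graph looks disconnected")
  c(lower = fiedler, upper = lmax)
}

.laplacian_bounds_dense <- function(L) {
  ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  n <- length(ev)
  if (abs(ev[n]) > 1e-8 * max(1, ev[1]))
    stop("smallest Laplacian eigenvalue is not ~0; input is not a Laplacian")
  if (ev[n - 1] <= 1e-8 * max(1, ev[1]))
    stop("Fiedler value is numerically zero: the graph looks disconnected")
  c(lower = ev[n - 1], upper = ev[1])
}

.xd_matrix <- function(Ds) {
  n <- nrow(Ds)
  cm <- colMeans(Ds)
  # H Ds H applied densely: subtract row means, column means, add grand mean
  X <- -0.5 * (Ds - matrix(cm, n, n, byrow = TRUE) - matrix(cm, n, n) +
                 mean(Ds))
  (X + t(X)) / 2
}

#' The MDS matrix X_D
#'
#' `X_D = -1/2 H Ds H` with `H` the centering matrix and `Ds` the
#' elementwise-squared distance matrix; the Gram matrix of classical
#' multidimensional scaling.  For centered `x`, `x' X_D x = -1/2 x' Ds x`.
#'
#' @param D integer/numeric matrix of NNI distances (not squared).
#' @return dense symmetric matrix.
#' @export
xdMatrix <- function(D) .xd_matrix(as.matrix(D)^2)

#' Spectral bounds for a resolution function
#'
#' For `kind = "laplacian"` returns the Fiedler value and the largest
#' eigenvalue of the Cayley-graph Laplacian; for `kind = "distance"` the
#' extreme eigenvalues of `X_D`.  Method `"auto"` uses a dense symmetric
#' solve up to 1500 shapes and sparse ARPACK iterations (shift-invert for the
#' Fiedler value) above; `X_D` is always dense and is guarded by the
#' distance-matrix memory guard.
#'
#' @param x a [CayleyGraph-class], or a matrix already of the right role
#'   (the Laplacian itself, or the *squared* distance matrix `Ds`).
#' @param kind `"laplacian"` or `"distance"`.
#' @param method `"auto"`, `"dense"` or `"sparse"` (Laplacian only).
#' @param tol ARPACK convergence tolerance.
#' @param ... passed to [distanceMatrix()] (e.g. `maxShapes`).
#' @return a [SpectralBounds-class].
#' @examples
#' g <- buildCayleyGraph(enumerateShapes(7))
#' spectralBounds(g, "laplacian")
#' @export
setMethod("spectralBounds", "CayleyGraph",
          function(x, kind = c("laplacian", "distance"), method = "auto",
                   tol = 1e-9, ...) {
  kind <- match.arg(kind)
  if (kind == "laplacian")
    return(spectralBounds(laplacianMatrix(x), "laplacian", method = method,
                          tol = tol))
  Ds <- distanceMatrix(x, ...)^2
  spectralBounds(Ds, "distance")
})

#' @export
setMethod("spectralBounds", "ANY",
          function(x, kind = c("laplacian", "distance"), method = "auto",
                   tol = 1e-9, ...) {
  kind <- match.arg(kind)
  if (!(is.matrix(x) || is(x, "Matrix")))
    stop("'x' must be a CayleyGraph or a matrix")
  if (nrow(x) != ncol(x)) stop("matrix must be square")
  if (kind == "laplacian") {
    method <- match.arg(method, c("auto", "dense", "sparse"))
    n <- nrow(x)
    b <- if (method == "dense" || (method == "auto" && n <= .DENSE_EIG_LIMIT))
      .laplacian_bounds_dense(x)
    else
      .laplacian_bounds_sparse(as(as(x, "CsparseMatrix"), "symmetricMatrix"),
                               tol)
    return(new("SpectralBounds", role = "laplacian",
               lower = unname(b["lower"]), upper = unname(b["upper"])))
  }
  # x is Ds (squared distances), dense route
  ev <- eigen(.xd_matrix(as.matrix(x)), symmetric = TRUE,
              only.values = TRUE)$values
  new("SpectralBounds", role = "distance", lower = min(ev), upper = max(ev))
})
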