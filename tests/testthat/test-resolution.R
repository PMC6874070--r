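# Resolution functions, spectral bounds, scaling, MDS.

test_that("two-point distance resolution has the closed-form value 1/2", {
  Ds <- matrix(c(0, 1, 1, 0), 2)
  x <- c(1, -1) / sqrt(2)
  expect_equal(resolutionD(x, Ds), 0.5)
  # X_D of this configuration has eigenvalues {0, 1/2}
  b <- spectralBounds(Ds, "distance")
  expect_equal(b@lower, 0, tolerance = 1e-12)
  expect_equal(b@upper, 0.5, tolerance = 1e-12)
})

test_that("R_D equals the X_D quadratic form for centered vectors", {
  set.seed(3)
  Ds <- c_dist(9)^2
  XD <- xdMatrix(c_dist(9))
  for (rep in 1:5) {
    x <- centerUnit(rnorm(nrow(Ds)))
    expect_equal(resolutionD(x, Ds), drop(crossprod(x, XD %*% x)),
                 tolerance = 1e-10)
  }
})

test_that("naive double-loop oracles agree with the matrix forms", {
  sp <- c_space(8)
  g <- c_graph(8)
  D <- c_dist(8)
  L <- laplacianMatrix(g)
  x <- statisticVector(sp, "sackin")@centered
  # R_D by explicit summation over ordered pairs
  rd <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    rd <- rd - 0.5 * D[i, j]^2 * x[i] * x[j]
  expect_equal(resolutionD(x, D^2), rd, tolerance = 1e-10)
  # R_L by explicit summation over edges
  el <- edgeTable(g)
  expect_equal(resolutionL(x, L), sum((x[el$from] - x[el$to])^2),
               tolerance = 1e-10)
})

test_that("resolution inputs are validated", {
  x <- centerUnit(rnorm(11))
  expect_error(resolutionD(x, matrix(0, 5, 5)), "dimension mismatch")
  expect_error(resolutionL(x, matrix(0, 5, 5)), "dimension mismatch")
  expect_error(resolutionD(rep(1, 11) / sqrt(11), c_dist(7)^2), "centered")
})

test_that("the 3-path Laplacian has eigenvalues {0, 1, 3}", {
  L3 <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3)
  b <- spectralBounds(L3, "laplacian")
  expect_equal(b@lower, 1, tolerance = 1e-10)
  expect_equal(b@upper, 3, tolerance = 1e-10)
})

test_that("dense and sparse Laplacian bounds agree", {
  L <- laplacianMatrix(c_graph(12))
  bd <- spectralBounds(L, "laplacian", method = "dense")
  bs <- spectralBounds(L, "laplacian", method = "sparse")
  expect_equal(bd@lower, bs@lower, tolerance = 1e-8)
  expect_equal(bd@upper, bs@upper, tolerance = 1e-8)
})

test_that("a disconnected graph is rejected by the bounds computation", {
  L <- as.matrix(Matrix::bdiag(matrix(c(1, -1, -1, 1), 2),
                               matrix(c(1, -1, -1, 1), 2)))
  expect_error(spectralBounds(L, "laplacian"), "disconnected")
})

test_that("the Fiedler value is positive for every space up to 12 leaves", {
  for (l in 5:12) expect_gt(c_lap_bounds(l)@lower, 0)
})

test_that("eigenvector statistics attain the scaled endpoints 0 and 1", {
  g <- c_graph(7)
  L <- as.matrix(laplacianMatrix(g))
  eg <- eigen(L, symmetric = TRUE)
  n <- nrow(L)
  b <- c_lap_bounds(7)
  sc <- function(x) (resolutionL(centerUnit(x), L) - b@lower) /
    (b@upper - b@lower)
  expect_equal(sc(eg$vectors[, n - 1]), 0, tolerance = 1e-9)  # Fiedler vector
  expect_equal(sc(eg$vectors[, 1]), 1, tolerance = 1e-9)      # top vector
})

test_that("scaled resolutions sit inside [0,1] with Rayleigh bracketing", {
  for (l in 7:10) {
    for (fun in c("distance", "laplacian")) {
      b <- if (fun == "distance") c_dist_bounds(l) else c_lap_bounds(l)
      for (st in c("colless", "sackin", "sigma2", "i2", "b1", "b2")) {
        r <- scaledResolution(c_graph(l), st, fun, bounds = b)
        expect_lte(r@lower, r@raw + 1e-9)
        expect_lte(r@raw, r@upper + 1e-9)
        expect_gte(r@scaled, 0)
        expect_lte(r@scaled, 1)
      }
    }
  }
})

test_that("scaled resolution is invariant under sign flip and affine maps", {
  g <- c_graph(8)
  bL <- c_lap_bounds(8)
  bD <- c_dist_bounds(8)
  y <- statisticVector(c_space(8), "b2")@values
  mk <- function(v) new("StatVector", name = "b2", scale = "printed",
                        values = v, centered = centerUnit(v), leafCount = 8L)
  for (fun in c("distance", "laplacian")) {
    b <- if (fun == "distance") bD else bL
    ref <- scaledResolution(g, mk(y), fun, bounds = b)@scaled
    expect_equal(scaledResolution(g, mk(-y), fun, bounds = b)@scaled, ref,
                 tolerance = 1e-9)
    expect_equal(scaledResolution(g, mk(4 * y - 7), fun, bounds = b)@scaled,
                 ref, tolerance = 1e-9)
  }
})

test_that("classical MDS reproduces closed-form configurations", {
  # two points at distance 3 -> +-1.5 on one axis
  emb <- mdsEmbed(matrix(c(0, 3, 3, 0), 2), dims = 1)
  expect_equal(sort(emb$points[, 1]), c(-1.5, 1.5), tolerance = 1e-9)
  # three points pairwise 1 -> unit equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  emb3 <- mdsEmbed(D3, dims = 2)
  expect_equal(unname(as.matrix(dist(emb3$points))), D3, tolerance = 1e-9)
  # collinear points: rank 1, dims = 2 pads with zeros and warns
  D4 <- abs(outer(1:4, 1:4, "-"))
  expect_warning(emb4 <- mdsEmbed(D4, dims = 2), "reduced rank")
  expect_equal(emb4$points[, 2], rep(0, 4))
})

test_that("embedding strain decreases with added dimensions", {
  D <- c_dist(9)
  strain <- vapply(1:3, function(k) {
    E <- as.matrix(dist(mdsEmbed(D, dims = k)$points))
    sum((D - E)^2)
  }, 0)
  expect_true(all(diff(strain) <= 1e-9))
})

test_that("quartile bands split values as lower / mid / upper", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  band <- quartileBand(v)
  expect_identical(levels(band), c("lower", "mid", "upper"))
  expect_identical(as.character(band[c(1, 8)]), c("lower", "upper"))
  expect_true(all(band[4:5] == "mid"))
})
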