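# Shared per-run cache: spaces, graphs and spectral bounds are reused across
# test files (graph construction at 17 leaves is the long pole).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

c_space <- function(l) memo(paste0("space", l), enumerateShapes(l))

c_graph <- function(l) memo(paste0("graph", l), buildCayleyGraph(c_space(l)))

c_dist <- function(l) memo(paste0("dist", l), distanceMatrix(c_graph(l)))

c_lap_bounds <- function(l)
  memo(paste0("lb", l), spectralBounds(c_graph(l), "laplacian"))

c_dist_bounds <- function(l)
  memo(paste0("db", l), spectralBounds(c_dist(l)^2, "distance"))

# centered unit vectors of the six classical statistics (printed scale) plus
# centered aggregate sackin/colless, as one matrix
c_stat_mat <- function(l) memo(paste0("sm", l), {
  sp <- c_space(l)
  cls <- c("colless", "sackin", "sigma2", "i2", "b1", "b2")
  X <- vapply(cls, function(s) statisticVector(sp, s)@centered,
              numeric(nShapes(sp)))
  agg <- vapply(c("sackin", "colless"), function(s) {
    y <- statisticVector(sp, s, scale = "aggregate")@values
    y - mean(y)
  }, numeric(nShapes(sp)))
  colnames(agg) <- c("sackin_agg", "colless_agg")
  cbind(X, agg)
})

# Y' Ds Y for the matrix above, streamed (no dense distance matrix)
c_ds_cross <- function(l)
  memo(paste0("dc", l), dsCrossprod(c_graph(l), c_stat_mat(l)))
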