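# Independent pure-R oracles: nested-list tree shapes, recursive statistics,
# NNI moves.  These deliberately do not reuse the package's compiled code, so
# they can arbitrate it.

o_leaf <- "L"
o_is_leaf <- function(x) identical(x, o_leaf)
o_nl <- function(x) if (o_is_leaf(x)) 1L else attr(x, "nl")
o_key <- function(x) if (o_is_leaf(x)) "" else attr(x, "key")

o_pair <- function(a, b) {
  if (o_nl(a) > o_nl(b) || (o_nl(a) == o_nl(b) && o_key(a) > o_key(b))) {
    tmp <- a; a <- b; b <- tmp
  }
  z <- list(a, b)
  attr(z, "nl") <- o_nl(a) + o_nl(b)
  attr(z, "key") <- paste0("(", o_key(a), ",", o_key(b), ")")
  z
}

# raw (non-canonicalizing) pair, for building scrambled child orders
o_pair_raw <- function(a, b) {
  z <- list(a, b)
  attr(z, "nl") <- o_nl(a) + o_nl(b)
  z
}

o_enumerate <- function(l) {
  memo <- list(list(o_leaf))
  rec <- function(m) {
    if (m <= length(memo) && !is.null(memo[[m]])) return(memo[[m]])
    out <- list()
    for (k in 1:(m %/% 2)) {
      A <- rec(k); B <- rec(m - k)
      for (i in seq_along(A)) {
        js <- if (k == m - k) i:length(B) else seq_along(B)
        for (j in js) out[[length(out) + 1L]] <- o_pair(A[[i]], B[[j]])
      }
    }
    memo[[m]] <<- out
    out
  }
  rec(l)
}

# emit newick (optionally with scrambled child order and dummy labels)
o_newick <- function(x, scramble = FALSE, label = FALSE) {
  cnt <- 0L
  rec <- function(node) {
    if (o_is_leaf(node)) {
      if (!label) return("")
      cnt <<- cnt + 1L
      return(paste0("t", cnt))
    }
    i <- if (scramble && stats::runif(1) < 0.5) c(2L, 1L) else c(1L, 2L)
    paste0("(", rec(node[[i[1]]]), ",", rec(node[[i[2]]]), ")")
  }
  paste0(rec(x), ";")
}

# independent recursive parse of an unlabeled-or-labeled newick string
o_parse <- function(txt) {
  txt <- gsub("[ \t]", "", txt)
  pos <- 1L
  nc <- nchar(txt)
  at <- function() substr(txt, pos, pos)
  skip_label <- function() {
    while (pos <= nc && !(at() %in% c(",", ")", ";"))) pos <<- pos + 1L
  }
  rec <- function() {
    if (at() == "(") {
      pos <<- pos + 1L
      a <- rec()
      stopifnot(at() == ",")
      pos <<- pos + 1L
      b <- rec()
      stopifnot(at() == ")")
      pos <<- pos + 1L
      skip_label()
      o_pair(a, b)
    } else {
      skip_label()
      o_leaf
    }
  }
  rec()
}

# per-node annotation and the seven statistics, printed normalizations
o_annotate <- function(x, depth = 0L) {
  if (o_is_leaf(x)) return(list(ld = depth, rs = NULL, ht = 0L, M = NULL))
  a <- o_annotate(x[[1]], depth + 1L)
  b <- o_annotate(x[[2]], depth + 1L)
  ht <- max(a$ht, b$ht) + 1L
  list(ld = c(a$ld, b$ld),
       rs = rbind(a$rs, b$rs, c(o_nl(x[[1]]), o_nl(x[[2]]))),
       ht = ht,
       M = c(a$M, b$M, ht))  # root's height is last
}

o_stats <- function(x) {
  an <- o_annotate(x)
  n <- o_nl(x)
  imb <- abs(an$rs[, 1] - an$rs[, 2])
  tot <- an$rs[, 1] + an$rs[, 2]
  q <- tot > 2
  c(colless = if (n >= 3) 2 * sum(imb) / ((n - 1) * (n - 2)) else NA,
    sackin = mean(an$ld),
    sigma2 = mean((an$ld - mean(an$ld))^2),
    i2 = if (n >= 3) sum(imb[q] / (tot[q] - 2)) / (n - 2) else NA,
    b1 = sum(1 / utils::head(an$M, -1)),   # root excluded
    b2 = sum(an$ld / 2^an$ld),
    cherries = sum(an$rs[, 1] == 1 & an$rs[, 2] == 1))
}

# all NNI neighbors (canonical keys, ';'-terminated), by list surgery
o_nni_keys <- function(x) {
  found <- character(0)
  rec <- function(node, rebuild) {
    if (o_is_leaf(node)) return(invisible())
    for (ci in 1:2) {
      v <- node[[ci]]
      w <- node[[3 - ci]]
      if (!o_is_leaf(v)) {
        a <- v[[1]]; b <- v[[2]]
        t1 <- rebuild(o_pair(a, o_pair(w, b)))
        t2 <- rebuild(o_pair(b, o_pair(a, w)))
        found <<- c(found, o_key(t1), o_key(t2))
      }
      local({
        w0 <- w
        rec(v, function(sub) rebuild(o_pair(sub, w0)))
      })
    }
  }
  rec(x, identity)
  paste0(setdiff(unique(found), o_key(x)), ";")
}

# Wedderburn-Etherington numbers, written as a convolution (kept separate
# from the package's implementation on purpose)
o_we <- function(lmax) {
  a <- c(1, rep(0, lmax - 1))
  for (m in 2:lmax) {
    conv <- sum(a[1:(m - 1)] * a[(m - 1):1])
    a[m] <- if (m %% 2 == 0) (conv + a[m / 2]) / 2 else conv / 2
  }
  a
}

# independent oracle: dense grid over lambda + local refinement with
# optimize().  The quotient (lambda a + b)' A (lambda a + b) / |lambda a + b|^2
# is evaluated through its quadratic coefficients so the grid stays cheap;
# the *optimizer* (grid + golden section), not the root formula, is what this
# cross-checks.
grid_lambda <- function(a, b, A, sense) {
  Aa <- as.numeric(A %*% a)
  Ab <- as.numeric(A %*% b)
  p <- sum(a * Aa); q <- sum(a * Ab); r <- sum(b * Ab)
  s <- sum(a * a); t <- sum(a * b); u <- sum(b * b)
  ray <- function(lm) (p * lm^2 + 2 * q * lm + r) /
    (s * lm^2 + 2 * t * lm + u)
  grid <- seq(-100, 100, by = 0.01)
  vals <- ray(grid)
  i <- if (sense == "max") which.max(vals) else which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ray, c(lo, hi), maximum = (sense == "max"),
                         tol = 1e-10)
  if (sense == "max") c(lambda = opt$maximum, value = opt$objective)
  else c(lambda = opt$minimum, value = opt$objective)
}

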