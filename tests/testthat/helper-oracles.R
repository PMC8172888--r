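# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# Brownian covariance by brute-force enumeration of shared root-to-tip edges.
shared_path_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nn <- max(tree$edge)
  parent <- integer(nn)
  elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- lapply(seq_len(n), function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v)
      v <- parent[v]
    }
    nodes # edges identified by their child node
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(elen[intersect(path_edges[[i]], path_edges[[j]])])
    }
  }
  ord <- order(rownames(C))
  C[ord, ord]
}

# GLS via explicit Cholesky whitening followed by ordinary least squares.
oracle_gls <- function(y, X, C, se = "unbiased") {
  L <- t(chol(C))
  yw <- solve(L, y)
  Xw <- solve(L, as.matrix(X))
  f <- stats::lm.fit(Xw, yw)
  n <- length(y)
  k <- ncol(Xw)
  rss <- sum(f$residuals^2)
  sigma2 <- rss / n
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  ll <- -0.5 * (n * log(2 * pi * sigma2) + ld + n)
  s2 <- if (se == "ml") sigma2 else rss / (n - k)
  list(beta = unname(f$coefficients),
       se = unname(sqrt(diag(s2 * solve(crossprod(Xw))))),
       sigma2 = sigma2, logLik = ll)
}

# ML lambda by exhaustive fine grid search, each point through oracle_gls.
oracle_lambda_grid <- function(y, X, C, step = 1e-4) {
  lams <- seq(0, 1, by = step)
  d <- diag(C)
  ll <- vapply(lams, function(l) {
    Cl <- l * C
    diag(Cl) <- d
    oracle_gls(y, X, Cl)$logLik
  }, numeric(1))
  i <- which.max(ll)
  list(lambda = lams[i], logLik = ll[i])
}

# One-way ANOVA ICC via base aov(), with the unbalanced n0 correction.
oracle_icc <- function(val, grp) {
  sm <- summary(stats::aov(val ~ factor(grp)))[[1]]
  ms_a <- sm$`Mean Sq`[1]
  ms_w <- sm$`Mean Sq`[2]
  sizes <- as.numeric(table(grp))
  N <- length(val)
  a <- length(sizes)
  n0 <- (N - sum(sizes^2) / N) / (a - 1)
  s2a <- (ms_a - ms_w) / n0
  s2a / (s2a + ms_w)
}

# Brownian motion simulated recursively along branches (increment per edge).
oracle_bm_tips <- function(tree, sigma2 = 1) {
  tr <- stats::reorder(tree, "cladewise")
  x <- numeric(max(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    x[ch] <- x[p] + stats::rnorm(1, 0, sqrt(sigma2 * tr$edge.length[e]))
  }
  stats::setNames(x[seq_along(tr$tip.label)], tr$tip.label)
}

# Random small rooted tree with strictly positive branch lengths.
random_small_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
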