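# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles deliberately avoid the package's own algorithms.

# Rooted PD by explicit union of root-to-tip node paths (ape::nodepath),
# summing the lengths of the distinct edges touched.
pd_bruteforce <- function(tree, present) {
  if (!length(present)) return(0)
  root <- length(tree$tip.label) + 1L
  edges <- character()
  for (sp in present) {
    tip <- match(sp, tree$tip.label)
    np <- ape::nodepath(tree, from = root, to = tip)
    edges <- union(edges, paste(np[-length(np)], np[-1]))
  }
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[match(edges, key)])
}

# PE by per-branch enumeration: each branch length divided by the count of
# cells holding any descendant tip, credited to each of those cells.
pe_bruteforce <- function(tree, occ) {
  root <- length(tree$tip.label) + 1L
  pe <- stats::setNames(numeric(nrow(occ)), rownames(occ))
  for (e in seq_len(nrow(tree$edge))) {
    chd <- tree$edge[e, 2]
    tips <- if (chd <= length(tree$tip.label)) tree$tip.label[chd]
            else ape::extract.clade(tree, chd)$tip.label
    tips <- intersect(tips, colnames(occ))
    if (!length(tips)) next
    cells <- rownames(occ)[rowSums(occ[, tips, drop = FALSE]) > 0]
    if (!length(cells)) next
    pe[cells] <- pe[cells] + tree$edge.length[e] / length(cells)
  }
  pe
}

# Moran's I and its normal-approximation moments by naive double loops
# over a dense weight matrix.
moran_bruteforce <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  s0 <- 0; num <- 0; s1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s0 <- s0 + W[i, j]
    num <- num + W[i, j] * z[i] * z[j]
    s1 <- s1 + 0.5 * (W[i, j] + W[j, i])^2
  }
  s2 <- 0
  for (i in seq_len(n)) s2 <- s2 + (sum(W[i, ]) + sum(W[, i]))^2
  I <- (n / s0) * num / sum(z^2)
  e_i <- -1 / (n - 1)
  v <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  list(I = I, expected = e_i, variance = v)
}

# Spatial-error log-likelihood by dense linear algebra: explicit
# A = I - lambda W, log-determinant from determinant(), GLS in long form.
sar_loglik_dense <- function(y, X, W, lambda) {
  n <- length(y)
  A <- diag(n) - lambda * W
  ys <- A %*% y
  Xs <- A %*% X
  beta <- solve(t(Xs) %*% Xs, t(Xs) %*% ys)
  res <- ys - Xs %*% beta
  s2 <- sum(res^2) / n
  as.numeric(determinant(A, logarithm = TRUE)$modulus) -
    (n / 2) * (log(2 * pi * s2) + 1)
}

dense_W <- function(w) {
  W <- matrix(0, w$n, w$n)
  W[cbind(w$i, w$j)] <- w$w
  W
}

# VIF by explicit normal-equations least squares.
vif_bruteforce <- function(panel) {
  panel <- as.matrix(panel)
  sapply(seq_len(ncol(panel)), function(j) {
    X <- cbind(1, panel[, -j, drop = FALSE])
    b <- solve(t(X) %*% X, t(X) %*% panel[, j])
    r <- panel[, j] - X %*% b
    1 / (sum(r^2) / sum((panel[, j] - mean(panel[, j]))^2))
  })
}

# PCA instability in long form: correlation-matrix eigendecomposition,
# manual projection, manual distances.
instability_bruteforce <- function(periods, aggregate = "mean") {
  cur <- periods[[length(periods)]]
  mu <- colMeans(cur)
  sd <- apply(cur, 2, stats::sd)
  std <- function(m) sweep(sweep(m, 2, mu), 2, sd, "/")
  S <- stats::cov(std(cur))
  eig <- eigen(S, symmetric = TRUE)
  rot <- eig$vectors[, 1:2, drop = FALSE]
  sc <- lapply(periods, function(m) std(m) %*% rot)
  steps <- sapply(seq_len(length(periods) - 1), function(t)
    sqrt(rowSums((sc[[t + 1]] - sc[[t]])^2)))
  steps <- matrix(steps, nrow = nrow(cur))
  switch(aggregate, mean = rowMeans(steps), sum = rowSums(steps),
         sd = apply(steps, 1, stats::sd))
}

# Small random fixtures ------------------------------------------------

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

random_dataset <- function(n_species = 8, nx = 6, ny = 5, seed = 1) {
  set.seed(seed)
  g <- make_grid(nx, ny)
  tr <- random_tree(n_species, seed + 1)
  m <- matrix(0L, nrow(g), n_species,
              dimnames = list(g$cell_id, tr$tip.label))
  repeat {
    m[] <- rbinom(length(m), 1, 0.3)
    if (all(colSums(m) > 0)) break
  }
  list(grid = g, tree = tr, occ = phyloscape:::as_ps_occ(m, g))
}

tiny_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

tiny_occ <- function(tree = tiny_tree()) {
  g <- make_grid(2, 1)
  read_occurrences(
    data.frame(cell_id = c("c00001", "c00001", "c00002", "c00002"),
               species = c("A", "B", "B", "C")), g, tree)
}
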