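# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with mxprop's own algorithms: dense
# matrices, direct solves, exhaustive enumeration.

# Random unweighted layer for property tests.
random_layer <- function(n_nodes, p = 0.15, seed = 1, name = "rnd") {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  layer(name, pairs[keep, , drop = FALSE])
}

random_weighted_layer <- function(n_nodes, p = 0.4, seed = 1, name = "rndw") {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  layer(name, pairs, weights = runif(nrow(pairs), 0.01, 1))
}

# Dense supra-transition operator of the informed walk, built independently
# from first principles (explicit states, explicit loops). Returns the
# column-stochastic matrix T where T[to, from], the restart vector, and the
# state labels. Dangling intra-layer mass is redirected to the restart
# vector, matching the package's documented convention.
dense_supra_operator <- function(m, kernel, seeds) {
  genes <- m$universe
  layers <- kernel$layers
  N <- length(genes)
  L <- length(layers)
  state <- function(g, l) (l - 1L) * N + g
  seeds <- seeds / sum(seeds)
  p0 <- numeric(N * L)
  for (l in seq_len(L)) {
    p0[state(match(names(seeds), genes), l)] <- seeds / L
  }
  adj <- lapply(layers, function(nm) {
    l <- m$layers[[nm]]
    A <- matrix(0, N, N)
    for (e in seq_len(nrow(l$edges))) {
      i <- match(l$edges[e, 1], genes)
      j <- match(l$edges[e, 2], genes)
      A[i, j] <- A[j, i] <- 1
    }
    A
  })
  Tm <- matrix(0, N * L, N * L)
  for (n in seq_len(L)) {
    deg <- colSums(adj[[n]])
    for (g in seq_len(N)) {
      from <- state(g, n)
      # inter-layer jumps to the same gene
      for (mm in seq_len(L)) {
        if (mm != n) Tm[state(g, mm), from] <- kernel$t[n, mm]
      }
      # intra-layer move; dangling mass -> restart vector
      if (deg[g] > 0) {
        nb <- which(adj[[n]][, g] > 0)
        Tm[state(nb, n), from] <- Tm[state(nb, n), from] +
          kernel$t[n, n] / deg[g]
      } else {
        Tm[, from] <- Tm[, from] + kernel$t[n, n] * p0
      }
    }
  }
  list(T = Tm, p0 = p0, genes = genes, layers = layers)
}

# Stationary solution of p = (1 - r) T p + r p0 by direct linear solve.
solve_rwr_direct <- function(m, kernel, seeds, r = 0.7) {
  op <- dense_supra_operator(m, kernel, seeds)
  n <- length(op$p0)
  p <- solve(diag(n) - (1 - r) * op$T, r * op$p0)
  matrix(p, nrow = length(op$genes),
         dimnames = list(op$genes, op$layers))
}

# Uninformed multiplex RWR: equal probability 1/L for every layer move,
# iterated densely. Independent of mxprop's sparse implementation.
uninformed_rwr_dense <- function(m, seeds, r = 0.7, tol = 1e-12,
                                 max_iter = 10000) {
  layers <- names(m$layers)
  L <- length(layers)
  kernel <- list(t = matrix(1 / L, L, L, dimnames = list(layers, layers)),
                 layers = layers, pi = rep(1 / L, L))
  op <- dense_supra_operator(m, kernel, seeds)
  p <- op$p0
  for (it in seq_len(max_iter)) {
    p_new <- (1 - r) * (op$T %*% p) + r * op$p0
    if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  matrix(as.numeric(p), nrow = length(op$genes),
         dimnames = list(op$genes, op$layers))
}

# Exhaustive null distribution of LCC sizes over all node subsets of a layer.
exhaustive_lcc_null <- function(l, subset_size) {
  nodes <- layer_nodes(l)
  subsets <- combn(nodes, subset_size)
  apply(subsets, 2, function(s) lcc_size(l, s))
}

# Two 4-cliques joined by one bridge (8 nodes).
two_clique_bridge <- function() {
  clique <- function(nodes) t(combn(nodes, 2))
  a <- sprintf("a%d", 1:4)
  b <- sprintf("b%d", 1:4)
  layer("bridge", rbind(clique(a), clique(b), c("a1", "b1")))
}

# Direct per-edge disparity evaluation: for every edge and each endpoint,
# (1 - w/strength)^(deg - 1), keep when both sides < alpha. Written against
# a plain data-frame representation, independent of disparity_filter().
brute_force_disparity <- function(l, alpha, or_rule = FALSE) {
  e <- data.frame(a = l$edges[, 1], b = l$edges[, 2], w = l$weights,
                  stringsAsFactors = FALSE)
  side <- function(node, w) {
    inc <- e$w[e$a == node | e$b == node]
    k <- length(inc)
    if (k == 1) return(1)
    (1 - w / sum(inc))^(k - 1)
  }
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    pa <- side(e$a[i], e$w[i])
    pb <- side(e$b[i], e$w[i])
    keep[i] <- if (or_rule) (pa < alpha || pb < alpha)
               else (pa < alpha && pb < alpha)
  }
  sort(paste(e$a[keep], e$b[keep], sep = "-"))
}

layer_edge_ids <- function(l) sort(paste(l$edges[, 1], l$edges[, 2], sep = "-"))

# Seeded evaluation of an expression without touching the caller's RNG.
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Shared toy ontology: root R with children A, B; A has leaves a1, a2.
toy_ontology <- function() {
  ontology(list(A = "R", B = "R", a1 = "A", a2 = "A"), root = "R")
}
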