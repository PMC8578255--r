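# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points funnel through this so results are
# bitwise reproducible given (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Sentinel for statistics that are undefined on the given input (zero degree
# variance, constant vectors, ...). NA_real_ keeps arithmetic honest while
# remaining distinguishable from a computed 0.
undefined_stat <- function() NA_real_

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest connected component size from an integer edge list over nodes
# 1..n_sub. Isolated nodes count as components of size 1. Plain union-find;
# subgraphs here are tiny (disease-module scale) so an R loop is fine.
lcc_from_int_edges <- function(ei, ej, n_sub) {
  if (n_sub == 0L) return(0L)
  parent <- seq_len(n_sub)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ei)) {
    ri <- find(ei[e]); rj <- find(ej[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n_sub), find, integer(1))
  max(tabulate(roots, nbins = n_sub))
}
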