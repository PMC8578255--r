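#' Layer relevance scores from LCC z-scores
#'
#' Layers whose disease-module z-score reaches the informativeness threshold
#' (default 1.645, the 95% one-sided normal quantile) are *informative*; the
#' relevance score of an informative layer is its z-score normalized over all
#' informative layers, \eqn{\pi_m = z_m / \sum_m z_m}, and 0 elsewhere. When
#' no layer passes the threshold the profile falls back to uniform weights
#' over all layers (documented fallback; the propagation then reduces to the
#' uninformed all-layers walk).
#'
#' @param z Named numeric vector of per-layer z-scores (`NA` allowed: treated
#'   as not informative).
#' @param threshold Informativeness threshold (default `qnorm(0.95)` rounded
#'   to 1.645, as conventionally quoted).
#' @return A list of class `mxp_relevance`: `pi` (named, sums to 1),
#'   `informative` (layer names with `pi > 0`), `z_source`, `fallback`
#'   (logical).
#' @export
relevance_scores <- function(z, threshold = 1.645) {
  stopifnot(is.numeric(z), length(z) >= 1L, !is.null(names(z)))
  inf <- !is.na(z) & z >= threshold
  pi <- stats::setNames(numeric(length(z)), names(z))
  fallback <- !any(inf)
  if (fallback) {
    pi[] <- 1 / length(z)
    informative <- names(z)
  } else {
    pi[inf] <- z[inf] / sum(z[inf])
    informative <- names(z)[inf]
  }
  structure(list(pi = pi, informative = informative, z_source = z,
                 fallback = fallback),
            class = "mxp_relevance")
}

#' @rdname relevance_scores
#' @param layers Character vector of layer names.
#' @return `uniform_relevance()` returns an `mxp_relevance` with equal weight
#'   on every layer (the uninformed all-layers regime).
#' @export
uniform_relevance <- function(layers) {
  z <- stats::setNames(rep(NA_real_, length(layers)), layers)
  r <- relevance_scores(z)
  r
}

#' Metropolis layer-transition kernel
#'
#' Builds the layer-switching kernel of the informed walk over the
#' informative layers. For L informative layers, the probability of moving
#' from layer n to layer m (m != n) is
#' \deqn{p(m|n) = (1/L)\,\min(1, \pi_m / \pi_n)}
#' and the stay probability is \eqn{p(n|n) = 1 - \sum_{m \ne n} p(m|n)}.
#' This Metropolis construction satisfies detailed balance
#' \eqn{\pi_n p(m|n) = \pi_m p(n|m)}, so \eqn{\pi} is the stationary
#' distribution of the kernel: the walk visits layers proportionally to their
#' relevance.
#'
#' @param p An `mxp_relevance` profile.
#' @return A list of class `mxp_kernel`: `t` (L x L row-stochastic matrix,
#'   rows = source layer), `layers` (informative layer names, in order),
#'   `pi` (stationary distribution over those layers).
#' @export
layer_transition_kernel <- function(p) {
  stopifnot(inherits(p, "mxp_relevance"))
  layers <- p$informative
  L <- length(layers)
  pi <- p$pi[layers]
  t <- matrix(0, L, L, dimnames = list(layers, layers))
  for (n in seq_len(L)) {
    for (m in seq_len(L)) {
      if (m != n) t[n, m] <- (1 / L) * min(1, pi[m] / pi[n])
    }
    t[n, n] <- 1 - sum(t[n, -n])
  }
  structure(list(t = t, layers = layers, pi = pi), class = "mxp_kernel")
}

#' Informed multiplex random walk with restart
#'
#' Iterates \eqn{p_{t+1} = (1 - r)\,\tilde{S} p_t + r\,p_0} over the state
#' space (gene, informative layer), where the informed supra-transition
#' operator \eqn{\tilde S} moves, from state (g, n), with probability
#' `t[n,n]` along a uniformly chosen layer-n edge of g and with probability
#' `t[n,m]` to the copy of g in layer m. Mass that would move intra-layer
#' from a gene with no layer-n edges is redirected to the restart
#' distribution (keeping the operator stochastic); `dangling = "stay"`
#' keeps it in place instead. The initial/restart distribution spreads each
#' seed's weight uniformly across the informative layers.
#'
#' @param m An `mxp_multiplex`.
#' @param kernel An `mxp_kernel` from [layer_transition_kernel()]; its layer
#'   names must exist in `m`.
#' @param seeds Named non-negative numeric vector of seed weights over genes
#'   (normalized internally), or a character vector of seed genes (uniform
#'   weights).
#' @param r Restart probability in (0, 1]; default 0.7.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap; default 10000.
#' @param dangling `"restart"` (default) or `"stay"`.
#' @return A list of class `mxp_propagation`: `visiting` (genes x layers
#'   matrix of converged visiting probabilities, summing to 1), `aggregated`
#'   (named per-gene mean over layers), `iterations`, `residual`, `converged`,
#'   `seeds` (the normalized seed vector).
#' @export
informed_rwr <- function(m, kernel, seeds, r = 0.7, tol = 1e-8,
                         max_iter = 10000L, dangling = c("restart", "stay")) {
  stopifnot(inherits(m, "mxp_multiplex"), inherits(kernel, "mxp_kernel"),
            r > 0, r <= 1)
  dangling <- match.arg(dangling)
  if (is.character(seeds)) {
    seeds <- stats::setNames(rep(1, length(seeds)), seeds)
  }
  if (is.null(names(seeds)) || any(seeds < 0) || sum(seeds) == 0) {
    stop("`seeds` must be named non-negative weights with positive sum",
         call. = FALSE)
  }
  seeds <- seeds[names(seeds) %in% m$universe]
  if (length(seeds) == 0L || sum(seeds) == 0) {
    stop("no seed gene is present in the multiplex universe", call. = FALSE)
  }
  seeds <- seeds / sum(seeds)
  missing_layers <- setdiff(kernel$layers, names(m$layers))
  if (length(missing_layers) > 0L) {
    stop("kernel layers absent from the multiplex: ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }

  genes <- m$universe
  N <- length(genes)
  L <- length(kernel$layers)
  K <- kernel$t

  # column-stochastic intra-layer walk matrices (neighbors equally likely)
  col_norm_adj <- function(l) {
    i1 <- match(l$edges[, 1], genes)
    i2 <- match(l$edges[, 2], genes)
    A <- Matrix::sparseMatrix(i = c(i1, i2), j = c(i2, i1), x = 1,
                              dims = c(N, N))
    deg <- Matrix::colSums(A)
    scale <- ifelse(deg > 0, 1 / deg, 0)
    A %*% Matrix::Diagonal(N, scale)
  }
  P_list <- lapply(kernel$layers, function(nm) col_norm_adj(m$layers[[nm]]))
  deg0 <- lapply(kernel$layers, function(nm) {
    l <- m$layers[[nm]]
    i1 <- match(l$edges[, 1], genes)
    i2 <- match(l$edges[, 2], genes)
    tabulate(c(i1, i2), nbins = N) == 0L
  })

  # supra operator: diagonal blocks K[n,n] * P_n, off-diagonal K[n,m] * I
  blocks <- vector("list", L)
  for (mm in seq_len(L)) {
    row_blocks <- vector("list", L)
    for (nn in seq_len(L)) {
      row_blocks[[nn]] <- if (mm == nn) K[nn, nn] * P_list[[nn]]
                          else K[nn, mm] * Matrix::Diagonal(N)
    }
    blocks[[mm]] <- do.call(cbind, row_blocks)
  }
  W <- do.call(rbind, blocks)

  # per-state mass lost to dangling intra-layer moves
  d_vec <- unlist(lapply(seq_len(L), function(nn) {
    ifelse(deg0[[nn]], K[nn, nn], 0)
  }), use.names = FALSE)

  p0 <- as.vector(vapply(seq_len(L), function(nn) {
    v <- numeric(N)
    v[match(names(seeds), genes)] <- seeds / L
    v
  }, numeric(N)))

  p <- p0
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- as.numeric(W %*% p)
    lost <- sum(d_vec * p)
    if (dangling == "restart") {
      moved <- moved + p0 * lost
    } else {
      moved <- moved + d_vec * p
    }
    p_new <- (1 - r) * moved + r * p0
    residual <- sum(abs(p_new - p))
    p <- p_new
    if (residual < tol) break
  }
  converged <- residual < tol
  if (!converged) {
    warning(sprintf("propagation did not converge in %d iterations (L1 residual %.3g)",
                    max_iter, residual), call. = FALSE)
  }

  visiting <- matrix(p, nrow = N, ncol = L,
                     dimnames = list(genes, kernel$layers))
  structure(
    list(visiting = visiting, aggregated = rowMeans(visiting),
         iterations = iter, residual = residual, converged = converged,
         seeds = seeds),
    class = "mxp_propagation"
  )
}

#' Rank genes from a propagation result
#'
#' Scores each gene by its mean visiting probability across the informative
#' layers, removes the seed genes (they trivially dominate), optionally
#' restricts to a candidate set, and breaks score ties deterministically by
#' gene identifier.
#'
#' @param res An `mxp_propagation` result.
#' @param seeds Seed genes to omit (default: the seeds stored in `res`).
#' @param restrict_to Optional candidate gene set to rank within.
#' @param keep_seeds Retain seed genes in the ranking (used for patient
#'   candidate lists where the causal gene may itself be phenotype-annotated).
#' @return Data frame `gene`, `score`, `rank` in decreasing score order; a
#'   restriction set disjoint from the universe yields an empty ranking with
#'   a warning.
#' @export
aggregate_and_rank <- function(res, seeds = NULL, restrict_to = NULL,
                               keep_seeds = FALSE) {
  stopifnot(inherits(res, "mxp_propagation"))
  seeds <- seeds %||% names(res$seeds)
  score <- res$aggregated
  genes <- names(score)
  if (!keep_seeds) genes <- setdiff(genes, seeds)
  if (!is.null(restrict_to)) {
    restrict_to <- as.character(restrict_to)
    if (length(intersect(restrict_to, names(score))) == 0L) {
      warning("restriction set is disjoint from the universe", call. = FALSE)
    }
    genes <- intersect(genes, restrict_to)
  }
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), score = numeric(0),
                      rank = integer(0)))
  }
  s <- score[genes]
  ord <- order(-s, genes)
  data.frame(gene = genes[ord], score = unname(s[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
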