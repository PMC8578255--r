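#' Edge-overlap similarity between two layers
#'
#' Similarity of two network layers A and B measured as the size of their
#' shared edge set relative to the smaller layer:
#' \deqn{S_{AB} = |E_A \cap E_B| / \min(|E_A|, |E_B|)}
#' Edges are compared as unordered gene pairs on the raw edge sets.
#'
#' @param a,b Layers (see [layer()]); each must contain at least one edge.
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @examples
#' la <- layer("A", rbind(c("a","b"), c("b","c"), c("c","d")))
#' lb <- layer("B", rbind(c("a","b"), c("d","e")))
#' edge_overlap_similarity(la, lb)  # 1 / min(3, 2) = 0.5
#' @export
edge_overlap_similarity <- function(a, b) {
  stopifnot(inherits(a, "mxp_layer"), inherits(b, "mxp_layer"))
  if (n_edges(a) == 0L || n_edges(b) == 0L) {
    stop("edge overlap is undefined for an empty layer", call. = FALSE)
  }
  ka <- edge_keys(a)
  kb <- edge_keys(b)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Permutation significance of the edge overlap of two layers
#'
#' Compares the observed overlap \eqn{S_{AB}} to a null distribution obtained
#' by permuting node indices: each layer's node labels are shuffled within its
#' own node set (preserving its degree sequence) `n_perm_per_net` times, and
#' the overlap is computed for all `n_perm_per_net^2` pairings of permuted
#' copies (10 permutations per network, hence 100 per pair, at the default).
#'
#' The empirical p-value uses the add-one correction
#' \eqn{p = (\#\{null \ge obs\} + 1) / (n^2 + 1)} so it is never exactly 0.
#' When the null distribution is degenerate (sd = 0) the z-score is reported
#' as `NA` and only the count-based p-value is meaningful.
#'
#' @inheritParams edge_overlap_similarity
#' @param n_perm_per_net Number of node-label permutations per layer (>= 2).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A list of class `mxp_overlap` with elements `similarity`, `z`,
#'   `p_empirical`, `n_permutations` (the number of null pairings, n^2),
#'   `null_mean` and `null_sd`.
#' @export
overlap_significance <- function(a, b, n_perm_per_net = 10L, seed = 1L) {
  if (!is_count(n_perm_per_net, min = 2L)) {
    stop("`n_perm_per_net` must be an integer >= 2", call. = FALSE)
  }
  observed <- edge_overlap_similarity(a, b)
  na <- layer_nodes(a)
  nb <- layer_nodes(b)
  if (length(intersect(na, nb)) < 2L) {
    stop("layers must share at least two nodes", call. = FALSE)
  }

  permute_keys <- function(l, nodes) {
    perm <- stats::setNames(sample(nodes), nodes)
    e1 <- unname(perm[l$edges[, 1]])
    e2 <- unname(perm[l$edges[, 2]])
    swap <- e1 > e2
    k1 <- ifelse(swap, e2, e1)
    k2 <- ifelse(swap, e1, e2)
    paste(k1, k2, sep = "\r")
  }

  n <- as.integer(n_perm_per_net)
  min_edges <- min(n_edges(a), n_edges(b))
  null <- with_seed(seed, {
    keys_a <- replicate(n, permute_keys(a, na), simplify = FALSE)
    keys_b <- replicate(n, permute_keys(b, nb), simplify = FALSE)
    as.vector(vapply(keys_a, function(ka) {
      vapply(keys_b, function(kb) {
        length(intersect(ka, kb)) / min_edges
      }, numeric(1))
    }, numeric(n)))
  })

  mu <- mean(null)
  sdv <- stats::sd(null)
  z <- if (sdv > 0) (observed - mu) / sdv else undefined_stat()
  p <- (sum(null >= observed) + 1) / (length(null) + 1)
  structure(
    list(similarity = observed, z = z, p_empirical = p,
         n_permutations = length(null), null_mean = mu, null_sd = sdv),
    class = "mxp_overlap"
  )
}

#' Pairwise layer dissimilarity matrix
#'
#' Dissimilarity between every pair of layers of a multiplex network, defined
#' as \eqn{d_{AB} = 1 - S_{AB}} with \eqn{S_{AB}} the edge-overlap similarity.
#' This matrix is the standard input to a non-metric MDS layout of layers.
#'
#' @param m A multiplex network with at least two non-empty layers.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = layer
#'   names, values in `[0, 1]`.
#' @export
dissimilarity_matrix <- function(m) {
  stopifnot(inherits(m, "mxp_multiplex"))
  if (length(m$layers) < 2L) stop("need at least two layers", call. = FALSE)
  nms <- names(m$layers)
  d <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms)) {
    for (j in seq_len(i - 1L)) {
      s <- edge_overlap_similarity(m$layers[[i]], m$layers[[j]])
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  d
}
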