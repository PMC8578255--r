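#' Structural summary of a network layer
#'
#' Node and edge counts, edge density, global clustering (transitivity:
#' 3 triangles / connected triples) and degree assortativity (Pearson
#' correlation of excess degrees over directed edge ends). Statistics that
#' are undefined on the input — assortativity when all degrees are equal,
#' clustering when there are no connected triples — are reported as `NA`
#' rather than 0.
#'
#' All quantities are computed from first principles here; see the test suite
#' for the cross-check against an independent graph library.
#'
#' @param l An `mxp_layer` with at least two nodes.
#' @return A list of class `mxp_layer_summary`: `name`, `n_nodes`, `n_edges`,
#'   `density`, `clustering`, `assortativity`.
#' @export
layer_summary <- function(l) {
  stopifnot(inherits(l, "mxp_layer"))
  nodes <- layer_nodes(l)
  n <- length(nodes)
  m <- n_edges(l)
  if (n < 2L) stop("layer must have at least two nodes", call. = FALSE)

  i1 <- match(l$edges[, 1], nodes)
  i2 <- match(l$edges[, 2], nodes)
  deg <- tabulate(c(i1, i2), nbins = n)

  A <- Matrix::sparseMatrix(i = c(i1, i2), j = c(i2, i1), x = 1,
                            dims = c(n, n))
  triangles <- sum(Matrix::diag(A %*% A %*% A)) / 6
  triples <- sum(deg * (deg - 1) / 2)
  clustering <- if (triples > 0) 3 * triangles / triples else undefined_stat()

  # excess degrees at the two ends of each directed edge
  xs <- c(deg[i1], deg[i2]) - 1
  ys <- c(deg[i2], deg[i1]) - 1
  assortativity <- if (stats::sd(xs) > 0) stats::cor(xs, ys) else undefined_stat()

  structure(
    list(name = l$name, n_nodes = n, n_edges = m,
         density = 2 * m / (n * (n - 1)),
         clustering = clustering, assortativity = assortativity),
    class = "mxp_layer_summary"
  )
}

#' @export
print.mxp_layer_summary <- function(x, ...) {
  cat(sprintf("<layer '%s': n=%d m=%d density=%.4f clustering=%s assortativity=%s>\n",
              x$name, x$n_nodes, x$n_edges, x$density,
              format(x$clustering, digits = 4),
              format(x$assortativity, digits = 4)))
  invisible(x)
}

#' Local (node-level) assortativity
#'
#' Decomposes the degree assortativity of a layer into per-node
#' contributions:
#' \deqn{\rho_v = j_v (j_v + 1)(\bar{k}_v - \mu_q) / (2 M \sigma_q^2)}
#' where \eqn{j_v} is the excess degree of v, \eqn{\bar{k}_v} the mean excess
#' degree of v's neighbours, M the edge count, and \eqn{\mu_q},
#' \eqn{\sigma_q^2} the mean and (population) variance of the excess-degree
#' distribution over edge ends. The node values sum to the global
#' assortativity — this is the property that pins down the definition, and it
#' is asserted to 1e-9 in the test suite.
#'
#' @param l An `mxp_layer` whose degree sequence is not constant.
#' @return A list of class `mxp_local_assort`: `rho` (named numeric,
#'   per node), `mu_q`, `sigma_q2`, `k_bar` (mean excess degree), `m_edges`.
#' @export
local_assortativity <- function(l) {
  stopifnot(inherits(l, "mxp_layer"))
  nodes <- layer_nodes(l)
  n <- length(nodes)
  m <- n_edges(l)
  i1 <- match(l$edges[, 1], nodes)
  i2 <- match(l$edges[, 2], nodes)
  deg <- tabulate(c(i1, i2), nbins = n)

  ends <- c(deg[i1], deg[i2]) - 1          # excess degree at each edge end
  mu_q <- mean(ends)
  sigma_q2 <- mean((ends - mu_q)^2)        # population variance
  if (sigma_q2 == 0) {
    stop("degree variance is zero; assortativity undefined", call. = FALSE)
  }

  # mean excess degree of each node's neighbours
  nb_sum <- numeric(n)
  tmp <- tapply(c(deg[i2], deg[i1]) - 1, c(i1, i2), sum)
  nb_sum[as.integer(names(tmp))] <- tmp
  k_bar_v <- ifelse(deg > 0, nb_sum / deg, 0)

  j <- deg - 1
  rho <- j * (j + 1) * (k_bar_v - mu_q) / (2 * m * sigma_q2)
  names(rho) <- nodes
  structure(
    list(rho = rho, mu_q = mu_q, sigma_q2 = sigma_q2,
         k_bar = mu_q, m_edges = m),
    class = "mxp_local_assort"
  )
}

#' Annotation (literature) bias of a layer
#'
#' Spearman correlation between each gene's degree in the layer and an
#' external per-gene count (e.g. number of publications mentioning the gene),
#' over the genes present in both. A strong positive value indicates that the
#' layer mostly recapitulates well-studied genes.
#'
#' @param l An `mxp_layer`.
#' @param counts Named non-negative numeric vector (gene -> count).
#' @return Spearman correlation in `[-1, 1]`, or `NA` when either variable is
#'   constant over the shared genes.
#' @export
annotation_bias <- function(l, counts) {
  stopifnot(inherits(l, "mxp_layer"), !is.null(names(counts)))
  nodes <- layer_nodes(l)
  shared <- intersect(nodes, names(counts))
  if (length(shared) < 3L) {
    stop("need at least 3 genes present in both layer and counts", call. = FALSE)
  }
  i1 <- match(l$edges[, 1], nodes)
  i2 <- match(l$edges[, 2], nodes)
  deg <- tabulate(c(i1, i2), nbins = length(nodes))
  names(deg) <- nodes
  d <- deg[shared]
  x <- as.numeric(counts[shared])
  if (stats::sd(d) == 0 || stats::sd(x) == 0) return(undefined_stat())
  stats::cor(d, x, method = "spearman")
}

#' Edge-conservation profile against a marked gene set
#'
#' For each conservation level c (number of layers an edge occurs in), the
#' fraction of edges at that level whose two endpoints are both in `marked`
#' (e.g. essential genes). Levels with no edges are absent from the result,
#' not reported as zero.
#'
#' @param layers List of at least two `mxp_layer` objects.
#' @param marked Character vector of marked genes.
#' @return Data frame with columns `conservation` (1..number of layers,
#'   populated levels only), `n_edges`, `fraction_marked`.
#' @export
edge_conservation_profile <- function(layers, marked) {
  stopifnot(is.list(layers), length(layers) >= 2L,
            all(vapply(layers, inherits, logical(1), "mxp_layer")))
  marked <- unique(as.character(marked))
  keys <- unlist(lapply(layers, edge_keys), use.names = FALSE)
  counts <- table(keys)
  ends <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  both <- ends[, 1] %in% marked & ends[, 2] %in% marked
  lev <- as.integer(counts)
  out <- lapply(sort(unique(lev)), function(c) {
    sel <- lev == c
    data.frame(conservation = c, n_edges = sum(sel),
               fraction_marked = mean(both[sel]))
  })
  do.call(rbind, out)
}
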