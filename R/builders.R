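#' Build a co-expression layer from an expression matrix
#'
#' Computes Spearman's rank correlation for all gene pairs and keeps pairs
#' with \eqn{|\rho|} strictly above `rho_cutoff` as weighted edges (weight =
#' \eqn{|\rho|}). Genes with zero variance across samples are excluded before
#' correlation (their rank correlation is undefined). The resulting weighted
#' layer is typically passed through [disparity_filter()] to extract its
#' backbone.
#'
#' @param x An expression matrix as returned by [read_expression()] or
#'   [make_expression()]: numeric genes x samples matrix with gene rownames.
#' @param rho_cutoff Absolute-correlation cutoff in (0, 1); pairs with
#'   \eqn{|\rho| \le} `rho_cutoff` are discarded. Default 0.75.
#' @param name,scale Passed to [layer()].
#' @return A weighted `mxp_layer`.
#' @export
build_coexpression <- function(x, rho_cutoff = 0.75, name = "coexpression",
                               scale = "transcriptome") {
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("expression matrix must have unique gene rownames", call. = FALSE)
  }
  stopifnot(rho_cutoff > 0, rho_cutoff < 1)
  v <- apply(x, 1L, stats::var)
  keep <- v > 0
  if (!any(keep)) {
    warning("all genes are constant across samples; empty layer", call. = FALSE)
    return(layer(name, matrix(character(0), ncol = 2), scale = scale))
  }
  x <- x[keep, , drop = FALSE]
  rho <- stats::cor(t(x), method = "spearman")
  rho[lower.tri(rho, diag = TRUE)] <- NA_real_
  hit <- which(abs(rho) > rho_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(layer(name, matrix(character(0), ncol = 2), scale = scale))
  }
  genes <- rownames(x)
  layer(name,
        cbind(genes[hit[, 1]], genes[hit[, 2]]),
        weights = abs(rho[hit]),
        scale = scale)
}

#' Disparity-filter backbone of a weighted layer
#'
#' For each node i with degree k and incident weights normalized to sum 1,
#' the significance of edge (i, j) from i's side is
#' \deqn{p_{ij} = (1 - w_{ij})^{k - 1}}
#' An edge is kept when **both** \eqn{p_{ij} < \alpha} and
#' \eqn{p_{ji} < \alpha} (the AND rule); set `or_rule = TRUE` for the
#' more permissive one-sided rule of the original disparity-filter
#' literature.
#'
#' Degree-1 convention: a pendant node has normalized weight 1 and
#' \eqn{(1-1)^0} is defined as 1, i.e. never significant — pendant edges can
#' only survive under `or_rule = TRUE` via their other endpoint. This
#' convention is deliberate and means the AND rule always removes pendant
#' edges.
#'
#' @param weighted A weighted `mxp_layer`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param or_rule Keep an edge when *either* endpoint is significant
#'   (default `FALSE`, i.e. both must be).
#' @return An unweighted `mxp_layer` whose edge set is a subset of the input
#'   edges; the result is monotone in `alpha`.
#' @export
disparity_filter <- function(weighted, alpha = 0.05, or_rule = FALSE) {
  stopifnot(inherits(weighted, "mxp_layer"), alpha > 0, alpha < 1)
  if (is.null(weighted$weights)) {
    stop("disparity filter requires a weighted layer", call. = FALSE)
  }
  p <- disparity_pvalues(weighted)
  keep <- if (or_rule) p$p_ij < alpha | p$p_ji < alpha
          else p$p_ij < alpha & p$p_ji < alpha
  layer(weighted$name, weighted$edges[keep, , drop = FALSE],
        scale = weighted$scale)
}

#' @rdname disparity_filter
#' @return `disparity_pvalues()` returns a data frame with one row per
#'   canonical edge: `from`, `to`, `p_ij` (from the first endpoint's side),
#'   `p_ji` (from the second's).
#' @export
disparity_pvalues <- function(weighted) {
  stopifnot(inherits(weighted, "mxp_layer"))
  if (is.null(weighted$weights)) {
    stop("disparity p-values require a weighted layer", call. = FALSE)
  }
  e <- weighted$edges
  w <- weighted$weights
  if (nrow(e) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      p_ij = numeric(0), p_ji = numeric(0)))
  }
  nodes <- layer_nodes(weighted)
  i1 <- match(e[, 1], nodes)
  i2 <- match(e[, 2], nodes)
  strength <- as.vector(tapply(c(w, w), c(i1, i2), sum))
  degree <- tabulate(c(i1, i2), nbins = length(nodes))

  side_p <- function(idx) {
    wn <- ifelse(strength[idx] > 0, w / strength[idx], 1)
    k <- degree[idx]
    # (1 - w)^(k - 1) with (1-1)^0 := 1: pendant edges are never significant
    p <- (1 - wn)^(k - 1)
    p[k == 1L] <- 1
    p
  }
  data.frame(from = e[, 1], to = e[, 2],
             p_ij = side_p(i1), p_ji = side_p(i2),
             stringsAsFactors = FALSE)
}

#' Split tissue layers into core and tissue-specific edges
#'
#' Edges present in at least `min_count` of the input layers form the *core*
#' layer; each input layer minus the core edges is returned as its
#' tissue-specific counterpart.
#'
#' @param layers List of at least two `mxp_layer` objects.
#' @param min_count Minimum number of layers an edge must appear in to be
#'   core (default 5).
#' @param core_name Name for the returned core layer.
#' @return A list with elements `core` (an `mxp_layer`) and `specific` (a
#'   list of layers parallel to the input).
#' @export
split_core_and_specific <- function(layers, min_count = 5L,
                                    core_name = "core") {
  stopifnot(is.list(layers), length(layers) >= 2L,
            all(vapply(layers, inherits, logical(1), "mxp_layer")),
            is_count(min_count))
  keys_per_layer <- lapply(layers, edge_keys)
  counts <- table(unlist(keys_per_layer, use.names = FALSE))
  core_keys <- names(counts)[counts >= min_count]
  core_edges <- do.call(rbind, strsplit(core_keys, "\r", fixed = TRUE))
  if (is.null(core_edges)) core_edges <- matrix(character(0), ncol = 2)
  core <- layer(core_name, core_edges, scale = "transcriptome")
  specific <- lapply(layers, function(l) {
    keep <- !(edge_keys(l) %in% core_keys)
    layer(l$name, l$edges[keep, , drop = FALSE], scale = l$scale)
  })
  list(core = core, specific = specific)
}
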