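#' Disease groups
#'
#' A disease group is an identifier plus the set of genes associated with the
#' disease (e.g. one Orphanet disease group).
#'
#' @param id Identifier string.
#' @param genes Character vector of associated genes (at least one).
#' @param label Human-readable label.
#' @return An object of class `mxp_disease_group`.
#' @export
disease_group <- function(id, genes, label = id) {
  genes <- sort(unique(as.character(genes)))
  stopifnot(is.character(id), length(id) == 1L, length(genes) >= 1L)
  structure(list(id = id, label = label, genes = genes),
            class = "mxp_disease_group")
}

#' Size of a disease module in a layer
#'
#' The disease module of a gene set in one layer is the subgraph induced by
#' the genes present in the layer; its size is the number of nodes in the
#' largest connected component (LCC). Genes absent from the layer are
#' ignored; an empty intersection gives 0.
#'
#' @param l An `mxp_layer`.
#' @param genes Character vector of genes.
#' @return Integer LCC size.
#' @export
lcc_size <- function(l, genes) {
  stopifnot(inherits(l, "mxp_layer"))
  nodes <- layer_nodes(l)
  sub <- intersect(unique(as.character(genes)), nodes)
  if (length(sub) == 0L) return(0L)
  idx <- match(l$edges[, 1], sub)
  jdx <- match(l$edges[, 2], sub)
  keep <- !is.na(idx) & !is.na(jdx)
  lcc_from_int_edges(idx[keep], jdx[keep], length(sub))
}

#' Significance of a disease module in one layer
#'
#' Compares the observed disease-module LCC size to the null distribution of
#' LCC sizes of `n_rand` uniformly sampled node sets of the same size, drawn
#' without replacement from the layer's own node set. The z-score uses the
#' null sample mean and sample standard deviation; the empirical p-value uses
#' the add-one correction \eqn{(\#\{null \ge obs\} + 1)/(n\_rand + 1)}. When
#' the null is degenerate (e.g. on a complete graph) the z-score is `NA` and
#' the p-value comes from counts alone.
#'
#' @param l An `mxp_layer`.
#' @param genes Character vector of disease genes; at least two must map to
#'   the layer.
#' @param n_rand Number of null samples (>= 100; default 1000).
#' @param seed Integer seed.
#' @return A list of class `mxp_module_significance`: `lcc_observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, `n_in_layer`, `n_rand`.
#' @export
lcc_significance <- function(l, genes, n_rand = 1000L, seed = 1L) {
  stopifnot(inherits(l, "mxp_layer"))
  if (!is_count(n_rand, min = 100L)) {
    stop("`n_rand` must be an integer >= 100", call. = FALSE)
  }
  nodes <- layer_nodes(l)
  sub <- intersect(unique(as.character(genes)), nodes)
  n_in <- length(sub)
  if (n_in < 2L) {
    stop("fewer than two disease genes map to the layer", call. = FALSE)
  }
  observed <- lcc_size(l, sub)

  n <- length(nodes)
  i1 <- match(l$edges[, 1], nodes)
  i2 <- match(l$edges[, 2], nodes)
  null <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      s <- sample.int(n, n_in)
      mem <- integer(n)
      mem[s] <- seq_len(n_in)
      a <- mem[i1]; b <- mem[i2]
      keep <- a > 0L & b > 0L
      lcc_from_int_edges(a[keep], b[keep], n_in)
    }, integer(1))
  })

  mu <- mean(null)
  sdv <- stats::sd(null)
  z <- if (sdv > 0) (observed - mu) / sdv else undefined_stat()
  p <- (sum(null >= observed) + 1) / (n_rand + 1)
  structure(
    list(lcc_observed = observed, null_mean = mu, null_sd = sdv, z = z,
         p_empirical = p, n_in_layer = n_in, n_rand = as.integer(n_rand)),
    class = "mxp_module_significance"
  )
}

#' Disease x layer relevance table
#'
#' Runs [lcc_significance()] for every disease group on every layer of a
#' multiplex network and adjusts the empirical p-values with
#' Benjamini-Hochberg across the whole table (set `per_layer_adjust = TRUE`
#' to correct within each layer instead). Cells where fewer than two disease
#' genes map to the layer are reported as not testable (`NA` statistics).
#'
#' @param m An `mxp_multiplex`.
#' @param groups List of `mxp_disease_group` objects.
#' @param n_rand,seed Passed to [lcc_significance()]; the seed is varied
#'   deterministically per cell.
#' @param per_layer_adjust Correct within layers rather than over the full
#'   table.
#' @return Data frame with one row per (group, layer): `group`, `layer`,
#'   `n_in_layer`, `lcc`, `null_mean`, `null_sd`, `z`, `p_empirical`,
#'   `p_adjusted`, `stars`.
#' @export
relevance_table <- function(m, groups, n_rand = 1000L, seed = 1L,
                            per_layer_adjust = FALSE) {
  stopifnot(inherits(m, "mxp_multiplex"), is.list(groups),
            all(vapply(groups, inherits, logical(1), "mxp_disease_group")))
  rows <- list()
  cell <- 0L
  for (g in groups) {
    for (lname in names(m$layers)) {
      cell <- cell + 1L
      l <- m$layers[[lname]]
      n_in <- length(intersect(g$genes, layer_nodes(l)))
      if (n_in < 2L) {
        rows[[cell]] <- data.frame(
          group = g$id, layer = lname, n_in_layer = n_in,
          lcc = NA_integer_, null_mean = NA_real_, null_sd = NA_real_,
          z = NA_real_, p_empirical = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ms <- lcc_significance(l, g$genes, n_rand = n_rand,
                             seed = seed + 7919L * cell)
      rows[[cell]] <- data.frame(
        group = g$id, layer = lname, n_in_layer = ms$n_in_layer,
        lcc = ms$lcc_observed, null_mean = ms$null_mean, null_sd = ms$null_sd,
        z = ms$z, p_empirical = ms$p_empirical, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (per_layer_adjust) {
    tab$p_adjusted <- NA_real_
    for (lname in unique(tab$layer)) {
      sel <- tab$layer == lname
      tab$p_adjusted[sel] <- stats::p.adjust(tab$p_empirical[sel], "BH")
    }
  } else {
    tab$p_adjusted <- stats::p.adjust(tab$p_empirical, "BH")
  }
  tab$stars <- significance_stars(tab$p_adjusted)
  tab
}

# star thresholds matching the relevance heatmap convention
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 0.01) "**" else if (x < 0.05) "*" else ""
  }, character(1))
}
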