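#' Network layers and multiplex networks
#'
#' A *layer* is one network of undirected gene-gene relationships at a single
#' biological scale (co-expression, physical interaction, pathway
#' co-membership, semantic similarity, ...). A *multiplex network* is an
#' ordered collection of layers sharing one gene universe; a gene is
#' represented by one node copy per layer.
#'
#' Edges are canonicalized on construction: self-loops are dropped (with a
#' warning when present), each unordered pair is stored once with its
#' endpoints in a fixed order, and duplicates are collapsed. Weights, when
#' given, must be non-negative and present for every edge.
#'
#' @param name Layer identifier (unique within a multiplex).
#' @param edges Two-column character matrix or data frame of gene pairs.
#' @param weights Optional numeric vector of non-negative edge weights,
#'   parallel to the rows of `edges`.
#' @param scale One of `"genome"`, `"transcriptome"`, `"proteome"`,
#'   `"pathway"`, `"function"`, `"phenotype"`, `"other"`.
#' @return An object of class `mxp_layer`: a list with elements `name`,
#'   `scale`, `edges` (canonical two-column character matrix) and `weights`
#'   (numeric vector or `NULL`).
#' @examples
#' l <- layer("toy", rbind(c("a", "b"), c("b", "c")))
#' layer_nodes(l)
#' @export
layer <- function(name, edges, weights = NULL,
                  scale = c("other", "genome", "transcriptome", "proteome",
                            "pathway", "function", "phenotype")) {
  scale <- match.arg(scale)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  edges <- matrix(as.character(edges), ncol = 2)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(edges)) {
      stop("`weights` must have one value per edge", call. = FALSE)
    }
    if (anyNA(weights) || any(weights < 0)) {
      stop("edge weights must be non-negative and non-missing", call. = FALSE)
    }
  }

  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("layer '%s': dropped %d self-loop(s)", name, sum(loops)),
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[!loops]
  }

  # canonical endpoint order, then de-duplicate
  swap <- edges[, 1] > edges[, 2]
  if (any(swap)) {
    tmp <- edges[swap, 1]
    edges[swap, 1] <- edges[swap, 2]
    edges[swap, 2] <- tmp
  }
  keys <- paste(edges[, 1], edges[, 2], sep = "\r")
  dup <- duplicated(keys)
  if (any(dup)) {
    edges <- edges[!dup, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[!dup]
  }

  structure(
    list(name = name, scale = scale, edges = edges, weights = weights),
    class = "mxp_layer"
  )
}

#' @rdname layer
#' @param l A layer.
#' @export
layer_nodes <- function(l) {
  stopifnot(inherits(l, "mxp_layer"))
  sort(unique(as.vector(l$edges)))
}

#' @rdname layer
#' @export
n_edges <- function(l) nrow(l$edges)

# canonical edge keys, internal
edge_keys <- function(l) paste(l$edges[, 1], l$edges[, 2], sep = "\r")

#' @export
print.mxp_layer <- function(x, ...) {
  cat(sprintf("<mxp_layer '%s' [%s]: %d nodes, %d edges%s>\n",
              x$name, x$scale, length(layer_nodes(x)), nrow(x$edges),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' @export
print.mxp_multiplex <- function(x, ...) {
  cat(sprintf("<mxp_multiplex: %d layers over %d genes>\n",
              length(x$layers), length(x$universe)))
  for (l in x$layers) print(l)
  invisible(x)
}

#' @param layers List of `mxp_layer` objects with unique names.
#' @param universe Optional character vector of gene identifiers; defaults to
#'   the union of all layer node sets. Every edge endpoint must be contained
#'   in it.
#' @return `multiplex()` returns an object of class `mxp_multiplex`: a list
#'   with a named list `layers` and character vector `universe`.
#' @rdname layer
#' @export
multiplex <- function(layers, universe = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "mxp_layer")))
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("layer names must be unique", call. = FALSE)
  names(layers) <- nms
  all_nodes <- sort(unique(unlist(lapply(layers, layer_nodes), use.names = FALSE)))
  if (is.null(universe)) {
    universe <- all_nodes
  } else {
    universe <- sort(unique(as.character(universe)))
    missing <- setdiff(all_nodes, universe)
    if (length(missing) > 0L) {
      stop("edge endpoints outside the universe: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(layers = layers, universe = universe),
            class = "mxp_multiplex")
}

# igraph view of a layer over an explicit vertex set (defaults to the layer's
# own nodes). Used for component queries; never for the statistics that
# igraph also implements, so cross-checks against igraph stay independent.
layer_igraph <- function(l, vertices = NULL) {
  vertices <- vertices %||% layer_nodes(l)
  igraph::graph_from_data_frame(
    as.data.frame(l$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE)
  )
}
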