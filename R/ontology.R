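#' Ontology DAG and gene annotations
#'
#' A minimal ontology representation: terms linked to parent terms by `is_a`
#' relations, forming a DAG rooted at a single term. Gene annotations map
#' genes to the terms that directly annotate them.
#'
#' @param parents Named list mapping each non-root term to a character vector
#'   of its parent terms.
#' @param root Root term identifier.
#' @return `ontology()` returns an object of class `mxp_ontology` with
#'   elements `terms`, `parents`, `root`.
#' @export
ontology <- function(parents, root) {
  stopifnot(is.list(parents), is.character(root), length(root) == 1L)
  terms <- sort(unique(c(root, names(parents),
                         unlist(parents, use.names = FALSE))))
  if (root %in% names(parents)) {
    stop("the root term must not have parents", call. = FALSE)
  }
  o <- structure(
    list(terms = terms, parents = parents, root = root,
         .anc = new.env(parent = emptyenv())),
    class = "mxp_ontology"
  )
  # validates acyclicity + reachability as a side effect
  for (t in terms) term_ancestors(o, t)
  o
}

#' @rdname ontology
#' @param o An `mxp_ontology`.
#' @param term A term identifier.
#' @return `term_ancestors()` returns the ancestor closure of `term`,
#'   *including the term itself*, as a character vector.
#' @export
term_ancestors <- function(o, term) {
  stopifnot(inherits(o, "mxp_ontology"))
  if (!term %in% o$terms) stop("unknown term: ", term, call. = FALSE)
  walk <- function(t, path) {
    cached <- o$.anc[[t]]
    if (!is.null(cached)) return(cached)
    if (t %in% path) stop("cycle in ontology at term: ", t, call. = FALSE)
    ps <- o$parents[[t]]
    anc <- if (is.null(ps) || length(ps) == 0L) {
      if (t != o$root) {
        stop("term does not reach the root: ", t, call. = FALSE)
      }
      t
    } else {
      unique(c(t, unlist(lapply(ps, walk, path = c(path, t)),
                         use.names = FALSE)))
    }
    if (!o$root %in% anc) stop("term does not reach the root: ", t, call. = FALSE)
    assign(t, anc, envir = o$.anc)
    anc
  }
  walk(term, character(0))
}

#' @rdname ontology
#' @param direct Named list mapping genes to character vectors of directly
#'   annotated terms; every term must exist in the ontology when validated
#'   with `annotations(direct, o)`.
#' @return `annotations()` returns an object of class `mxp_annotations`.
#' @export
annotations <- function(direct, o = NULL) {
  stopifnot(is.list(direct))
  direct <- lapply(direct, function(ts) sort(unique(as.character(ts))))
  if (!is.null(o)) {
    unknown <- setdiff(unlist(direct, use.names = FALSE), o$terms)
    if (length(unknown) > 0L) {
      stop("annotated terms missing from the ontology: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(direct, class = "mxp_annotations")
}

#' Topology-based information content of ontology terms
#'
#' The information content of term t is \eqn{IC(t) = -\log(n_t / N)} (natural
#' log), where \eqn{n_t} is the number of descendants of t *including t
#' itself* and N the descendant count of the root. Hence IC(root) = 0 and
#' leaves are maximally informative; the IC of a term is never less than the
#' IC of any of its ancestors.
#'
#' @param o An `mxp_ontology`.
#' @return Named numeric vector of information contents (nats), one per term.
#' @examples
#' o <- ontology(list(A = "R", B = "R", a1 = "A", a2 = "A"), root = "R")
#' term_information_content(o)["A"]  # -log(3/5)
#' @export
term_information_content <- function(o) {
  stopifnot(inherits(o, "mxp_ontology"))
  closures <- lapply(o$terms, function(t) term_ancestors(o, t))
  counts <- table(factor(unlist(closures, use.names = FALSE), levels = o$terms))
  n <- as.numeric(counts)
  names(n) <- o$terms
  -log(n / n[[o$root]])
}

#' Semantic similarity of two ontology terms
#'
#' Resnik similarity is the information content of the most informative
#' common ancestor (MICA) of the two terms; Lin similarity normalizes it as
#' \eqn{2\,IC(MICA) / (IC(t_1) + IC(t_2)) \in [0,1]}. Ancestor sets include
#' the terms themselves, so `term_similarity(o, ic, t, t, "resnik") == ic[t]`.
#' Lin similarity of the root with itself is defined as 0.
#'
#' @param o An `mxp_ontology`.
#' @param ic Information-content vector from [term_information_content()].
#' @param t1,t2 Term identifiers.
#' @param method `"resnik"` or `"lin"`.
#' @return Non-negative similarity; Lin values lie in `[0, 1]`.
#' @export
term_similarity <- function(o, ic, t1, t2, method = c("resnik", "lin")) {
  method <- match.arg(method)
  common <- intersect(term_ancestors(o, t1), term_ancestors(o, t2))
  mica_ic <- max(ic[common])
  if (method == "resnik") return(mica_ic)
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) 0 else 2 * mica_ic / denom
}

#' Gene-level semantic similarity
#'
#' Combines term similarities into a gene similarity. For the best-match
#' average (BMA) methods, S is the m x n matrix of pairwise term similarities
#' over the genes' *direct* annotations and
#' \deqn{sim_{BMA} = (\sum colmax(S) + \sum rowmax(S)) / (m + n).}
#' The frequency method counts shared annotations after ancestor closure:
#' \eqn{sim_{freq} = |T_{g_1} \cap T_{g_2}|} with \eqn{T_g} the direct terms
#' of g plus all their ancestors.
#'
#' @param g1,g2 Gene identifiers; both must carry at least one annotation.
#' @param a An `mxp_annotations` object.
#' @param o An `mxp_ontology`.
#' @param ic Information-content vector from [term_information_content()].
#' @param method One of `"resnik_bma"`, `"lin_bma"`, `"frequency"`.
#' @return Non-negative similarity, symmetric in `g1`, `g2`.
#' @export
gene_semantic_similarity <- function(g1, g2, a, o, ic,
                                     method = c("resnik_bma", "lin_bma",
                                                "frequency")) {
  method <- match.arg(method)
  t1 <- a[[g1]]
  t2 <- a[[g2]]
  if (is.null(t1) || length(t1) == 0L || is.null(t2) || length(t2) == 0L) {
    stop("both genes must be annotated with at least one term", call. = FALSE)
  }
  if (method == "frequency") {
    c1 <- unique(unlist(lapply(t1, term_ancestors, o = o), use.names = FALSE))
    c2 <- unique(unlist(lapply(t2, term_ancestors, o = o), use.names = FALSE))
    return(length(intersect(c1, c2)))
  }
  tm <- if (method == "resnik_bma") "resnik" else "lin"
  S <- outer(seq_along(t1), seq_along(t2),
             Vectorize(function(i, j) term_similarity(o, ic, t1[i], t2[j], tm)))
  (sum(apply(S, 2L, max)) + sum(apply(S, 1L, max))) / (length(t1) + length(t2))
}

#' Build a semantic-similarity layer from gene annotations
#'
#' Computes the all-pairs gene similarity over annotated genes, removes pairs
#' whose only common ancestor is the root term (such pairs carry no shared
#' information), and extracts the backbone of the remaining weighted graph
#' with the disparity filter.
#'
#' @param a An `mxp_annotations` object with at least two annotated genes
#'   (a layer built from fewer is empty).
#' @param o An `mxp_ontology`.
#' @param method Similarity combination, see [gene_semantic_similarity()].
#' @param alpha Disparity-filter significance level.
#' @param name,scale Passed to [layer()].
#' @return An unweighted `mxp_layer`.
#' @export
build_ontology_layer <- function(a, o, method = "resnik_bma", alpha = 0.05,
                                 name = "ontology", scale = "function") {
  stopifnot(inherits(a, "mxp_annotations"), inherits(o, "mxp_ontology"))
  genes <- names(a)[vapply(a, length, integer(1)) > 0L]
  if (length(genes) < 2L) {
    return(layer(name, matrix(character(0), ncol = 2), scale = scale))
  }
  ic <- term_information_content(o)
  pairs <- utils::combn(sort(genes), 2L)
  w <- numeric(ncol(pairs))
  root_only <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    g1 <- pairs[1, p]; g2 <- pairs[2, p]
    # MICA exclusively the root <=> every term-pair MICA has IC 0 <=> Resnik BMA 0
    res <- gene_semantic_similarity(g1, g2, a, o, ic, "resnik_bma")
    root_only[p] <- res == 0
    w[p] <- if (method == "resnik_bma") res
            else gene_semantic_similarity(g1, g2, a, o, ic, method)
  }
  keep <- !root_only
  weighted <- layer(name, t(pairs[, keep, drop = FALSE]),
                    weights = w[keep], scale = scale)
  disparity_filter(weighted, alpha = alpha)
}

#' Build a pathway co-membership layer
#'
#' Connects two genes when at least `min_shared` gene sets (pathways) contain
#' both of them.
#'
#' @param sets Named list of character vectors (e.g. from [read_gene_sets()]).
#' @param min_shared Minimum number of shared sets (default 5).
#' @param name,scale Passed to [layer()].
#' @return An unweighted `mxp_layer` (empty for an empty collection).
#' @export
build_pathway_layer <- function(sets, min_shared = 5L, name = "pathway",
                                scale = "pathway") {
  stopifnot(is.list(sets), is_count(min_shared))
  pair_keys <- unlist(lapply(sets, function(members) {
    members <- sort(unique(as.character(members)))
    if (length(members) < 2L) return(character(0))
    p <- utils::combn(members, 2L)
    paste(p[1, ], p[2, ], sep = "\r")
  }), use.names = FALSE)
  if (length(pair_keys) == 0L) {
    return(layer(name, matrix(character(0), ncol = 2), scale = scale))
  }
  counts <- table(pair_keys)
  hit <- names(counts)[counts >= min_shared]
  edges <- do.call(rbind, strsplit(hit, "\r", fixed = TRUE))
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  layer(name, edges, scale = scale)
}
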