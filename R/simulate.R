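#' Simulate a multiplex network with a planted disease module
#'
#' Generates a multiplex of Erdős–Rényi background layers over a shared gene
#' universe and plants a disease module — a gene subset wired at a higher
#' edge probability — into the layers flagged *relevant*. With
#' `guarantee_connected = TRUE` (default) a random spanning tree over the
#' module genes is added in each relevant layer, so the module's LCC equals
#' the module size there. In non-relevant layers the module genes behave like
#' background.
#'
#' The default dimensions (300 genes, 6 layers of which 3 are relevant,
#' module of 20 genes, background edge probability 0.02, within-module edge
#' probability 0.3) are a desk-scale analogue of a genome-scale multiplex
#' with a minimally sized disease module; see the package vignette for the
#' rationale.
#'
#' @param n_genes Universe size.
#' @param n_layers Number of layers.
#' @param n_relevant Number of layers carrying the planted module (the first
#'   `n_relevant` layers).
#' @param module_size Number of module (disease) genes.
#' @param p_background Background edge probability in (0, 1).
#' @param p_module Within-module edge probability in (0, 1) for relevant
#'   layers.
#' @param guarantee_connected Add a spanning tree over module genes in
#'   relevant layers.
#' @param degree_background Use a heterogeneous-degree background (each
#'   node's attachment propensity drawn from an exponential) instead of the
#'   homogeneous Erdős–Rényi background; same expected density.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list of class `mxp_fixture`: `multiplex` (an `mxp_multiplex`),
#'   `group` (an `mxp_disease_group` holding the module genes),
#'   `relevant_layers` (character vector), `seed`.
#' @export
make_multiplex <- function(n_genes = 300L, n_layers = 6L, n_relevant = 3L,
                           module_size = 20L, p_background = 0.02,
                           p_module = 0.3, guarantee_connected = TRUE,
                           degree_background = FALSE, seed = 1L) {
  stopifnot(is_count(n_genes, 10L), is_count(n_layers), is_count(module_size),
            module_size < n_genes, n_relevant <= n_layers,
            p_background > 0, p_background < 1, p_module > 0, p_module < 1)
  genes <- sprintf("g%04d", seq_len(n_genes))

  with_seed(seed, {
    module <- sort(sample(genes, module_size))
    pairs <- utils::combn(genes, 2L)
    module_pair <- pairs[1, ] %in% module & pairs[2, ] %in% module

    prop <- if (degree_background) {
      w <- stats::rexp(n_genes)
      names(w) <- genes
      pw <- w[pairs[1, ]] * w[pairs[2, ]]
      pmin(1 - 1e-9, p_background * pw / mean(pw))
    } else {
      rep(p_background, ncol(pairs))
    }

    layers <- lapply(seq_len(n_layers), function(i) {
      relevant <- i <= n_relevant
      keep <- stats::runif(ncol(pairs)) < prop
      if (relevant) {
        keep <- keep | (module_pair & stats::runif(ncol(pairs)) < p_module)
      }
      edges <- t(pairs[, keep, drop = FALSE])
      if (relevant && guarantee_connected) {
        # random spanning tree: connect each module gene to one earlier gene
        perm <- sample(module)
        tree <- cbind(perm[-1],
                      vapply(2:length(perm), function(k) {
                        perm[sample.int(k - 1L, 1L)]
                      }, character(1)))
        edges <- rbind(edges, tree)
      }
      layer(sprintf("L%02d", i), edges)
    })

    list_out <- list(
      multiplex = multiplex(layers, universe = genes),
      group = disease_group("planted", module, label = "planted module"),
      relevant_layers = sprintf("L%02d", seq_len(n_relevant)),
      seed = as.integer(seed)
    )
    structure(list_out, class = "mxp_fixture")
  })
}

#' Simulate a block-correlated expression matrix
#'
#' Each block of genes shares one latent sample profile; gene values are
#' \eqn{\sqrt{c}\,latent + \sqrt{1-c}\,\sigma\,\varepsilon} exponentiated to
#' a non-negative TPM-like scale, where `latent_corr` = c is the target
#' *pairwise* correlation between two genes of the same block (at
#' `noise_sd = 1`). Genes from different blocks are independent.
#'
#' @param n_blocks Number of co-expression blocks.
#' @param genes_per_block Genes per block.
#' @param n_samples Number of samples (>= 10).
#' @param latent_corr Target within-block inter-gene correlation in (0, 1).
#' @param noise_sd Noise standard deviation (values above 1 dilute the
#'   correlation below `latent_corr`).
#' @param seed Integer seed.
#' @return Numeric genes x samples matrix with rownames `b<block>_g<idx>` and
#'   colnames `s<idx>`; attribute `blocks` maps genes to block indices.
#' @export
make_expression <- function(n_blocks = 2L, genes_per_block = 10L,
                            n_samples = 100L, latent_corr = 0.9,
                            noise_sd = 1, seed = 1L) {
  stopifnot(is_count(n_blocks), is_count(genes_per_block),
            is_count(n_samples, 10L), latent_corr > 0, latent_corr < 1,
            noise_sd >= 0)
  with_seed(seed, {
    rows <- list()
    blocks <- integer(0)
    for (b in seq_len(n_blocks)) {
      latent <- stats::rnorm(n_samples)
      for (g in seq_len(genes_per_block)) {
        val <- sqrt(latent_corr) * latent +
          sqrt(1 - latent_corr) * noise_sd * stats::rnorm(n_samples)
        rows[[sprintf("b%d_g%02d", b, g)]] <- exp(val)
      }
      blocks <- c(blocks, rep(b, genes_per_block))
    }
    x <- do.call(rbind, rows)
    colnames(x) <- sprintf("s%03d", seq_len(n_samples))
    attr(x, "blocks") <- stats::setNames(blocks, rownames(x))
    x
  })
}

#' Simulate a toy ontology with gene annotations
#'
#' Builds a balanced tree ontology (`branching^d` terms at depth d, root at
#' depth 0) and annotates `genes_per_leaf` genes to each leaf term; each gene
#' may additionally be annotated to extra random leaves with probability
#' `extra_prob`.
#'
#' @param branching Children per internal term (>= 2).
#' @param depth Tree depth (>= 2).
#' @param genes_per_leaf Genes annotated per leaf.
#' @param extra_prob Probability that a gene gets one extra random leaf.
#' @param prefix Gene-name prefix.
#' @param seed Integer seed.
#' @return A list: `ontology` (an `mxp_ontology`), `annotations`
#'   (an `mxp_annotations`), `leaves` (character vector of leaf terms).
#' @export
make_toy_ontology <- function(branching = 3L, depth = 3L, genes_per_leaf = 5L,
                              extra_prob = 0, prefix = "tg", seed = 1L) {
  stopifnot(is_count(branching, 2L), is_count(depth, 2L),
            is_count(genes_per_leaf), extra_prob >= 0, extra_prob <= 1)
  root <- "T:R"
  parents <- list()
  level <- root
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      kids <- sprintf("%s.%d", sub("^T:", "", p), seq_len(branching))
      kids <- paste0("T:", kids)
      for (k in kids) parents[[k]] <- p
      nxt <- c(nxt, kids)
    }
    level <- nxt
  }
  o <- ontology(parents, root = root)
  leaves <- level
  with_seed(seed, {
    direct <- list()
    idx <- 0L
    for (leaf in leaves) {
      for (g in seq_len(genes_per_leaf)) {
        idx <- idx + 1L
        nm <- sprintf("%s%04d", prefix, idx)
        ts <- leaf
        if (extra_prob > 0 && stats::runif(1) < extra_prob) {
          ts <- c(ts, sample(leaves, 1L))
        }
        direct[[nm]] <- ts
      }
    }
    list(ontology = o, annotations = annotations(direct, o), leaves = leaves)
  })
}

#' Simulate a solved patient case on a planted-module fixture
#'
#' Builds phenotype annotations over the fixture's gene universe, samples a
#' causal gene from the planted module, and assembles a candidate list of the
#' causal gene plus off-module decoys — emulating a solved rare-disease case
#' after variant filtering.
#'
#' Phenotype annotations: every module gene is annotated with 2 leaves from a
#' small pool of `n_disease_leaves` "disease" leaves (so module genes share
#' phenotypes); every background gene gets 2 random leaves. The patient's
#' term set is deliberately imperfect: one of the causal gene's leaves plus
#' `n_noise_terms` random non-disease leaves, so phenotype matching alone
#' identifies the causal gene only partially and network propagation has
#' headroom to improve on it.
#'
#' @param fx A fixture from [make_multiplex()].
#' @param onto A toy ontology from [make_toy_ontology()] (its leaves are the
#'   phenotype vocabulary; its gene annotations are ignored).
#' @param n_candidates Candidate-list size (causal + decoys); decoys never
#'   intersect the planted module.
#' @param n_disease_leaves Size of the disease-phenotype leaf pool.
#' @param n_noise_terms Number of noise terms in the patient's term set.
#' @param seed Integer seed.
#' @return A list: `case` (an `mxp_patient_case` with known `causal`),
#'   `annotations` (an `mxp_annotations` of phenotype terms over the
#'   universe), `disease_leaves`.
#' @export
make_patient_case <- function(fx, onto, n_candidates = 50L,
                              n_disease_leaves = 3L, n_noise_terms = 2L,
                              seed = 1L) {
  stopifnot(inherits(fx, "mxp_fixture"), is_count(n_candidates, 2L))
  genes <- fx$multiplex$universe
  module <- fx$group$genes
  decoy_pool <- setdiff(genes, module)
  if (n_candidates - 1L > length(decoy_pool)) {
    stop("not enough off-module genes for the requested candidate count",
         call. = FALSE)
  }
  leaves <- onto$leaves
  stopifnot(length(leaves) > n_disease_leaves + n_noise_terms)

  with_seed(seed, {
    disease_leaves <- sample(leaves, n_disease_leaves)
    other_leaves <- setdiff(leaves, disease_leaves)
    direct <- list()
    for (g in genes) {
      direct[[g]] <- if (g %in% module) {
        sample(disease_leaves, 2L)
      } else {
        sample(other_leaves, 2L)
      }
    }
    causal <- sample(module, 1L)
    terms <- c(sample(direct[[causal]], 1L),
               sample(other_leaves, n_noise_terms))
    decoys <- sample(decoy_pool, n_candidates - 1L)
    case <- patient_case(
      id = sprintf("case_seed%d", as.integer(seed)),
      phenotype_terms = terms,
      candidates = c(causal, decoys),
      causal = causal,
      disease_group = fx$group$id
    )
    list(case = case,
         annotations = annotations(direct, onto$ontology),
         disease_leaves = disease_leaves)
  })
}
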