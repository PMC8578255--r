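#' Rank-based AUROC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a uniformly chosen positive outscores a uniformly chosen
#' negative, with ties counting 1/2. Invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores Named numeric vector of scores.
#' @param positives,negatives Non-empty, disjoint item sets; every item must
#'   have a score.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  items <- c(positives, negatives)
  missing <- setdiff(items, names(scores))
  if (length(missing) > 0L) {
    stop("items without scores: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  s <- scores[items]
  rk <- rank(s)   # average ranks handle ties -> 1/2 contribution
  np <- length(positives)
  nn <- length(negatives)
  (sum(rk[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated disease gene retrieval
#'
#' k-fold cross-validation of gene retrieval by informed propagation. The
#' disease genes present in the universe are shuffled deterministically into
#' k folds; for each fold the remaining genes seed the walk and the held-out
#' genes are the positives, scored against all universe genes not associated
#' with the disease (seeds are omitted from the ranking). Four layer-selection
#' regimes are supported:
#' \describe{
#'   \item{`relevant_layers`}{relevance-weighted walk over the informative
#'     layers (pi from the relevance profile).}
#'   \item{`all_layers`}{uniform weights over every layer (uninformed walk).}
#'   \item{`best_single`}{the single layer with the largest z-score.}
#'   \item{`ppi_only`}{a caller-designated reference layer
#'     (`reference_layer`), e.g. the physical-interaction layer.}
#' }
#'
#' @param m An `mxp_multiplex`.
#' @param group An `mxp_disease_group` with at least `k` genes in the
#'   universe.
#' @param relevance An `mxp_relevance` for the group (required for the
#'   `relevant_layers` and `best_single` regimes).
#' @param k Number of folds (default 10).
#' @param regime One of `"relevant_layers"`, `"all_layers"`, `"best_single"`,
#'   `"ppi_only"`.
#' @param seed Integer seed for the fold assignment.
#' @param reference_layer Layer name for the `ppi_only` regime.
#' @param r,tol Propagation parameters, see [informed_rwr()].
#' @return A list of class `mxp_cv`: `group`, `regime`, `fold_auroc`
#'   (length k), `median_auroc`, `k`, `seed`.
#' @export
kfold_retrieval <- function(m, group, relevance = NULL, k = 10L,
                            regime = c("relevant_layers", "all_layers",
                                       "best_single", "ppi_only"),
                            seed = 1L, reference_layer = NULL,
                            r = 0.7, tol = 1e-8) {
  regime <- match.arg(regime)
  stopifnot(inherits(m, "mxp_multiplex"), inherits(group, "mxp_disease_group"))
  genes <- intersect(group$genes, m$universe)
  if (length(genes) < k) stop("fewer mappable disease genes than folds",
                              call. = FALSE)

  profile <- switch(
    regime,
    relevant_layers = {
      stopifnot(inherits(relevance, "mxp_relevance"))
      relevance
    },
    all_layers = uniform_relevance(names(m$layers)),
    best_single = {
      stopifnot(inherits(relevance, "mxp_relevance"))
      z <- relevance$z_source
      best <- names(z)[which.max(z)]
      single_layer_relevance(best, names(m$layers))
    },
    ppi_only = {
      if (is.null(reference_layer) || !reference_layer %in% names(m$layers)) {
        stop("`reference_layer` must name a layer of the multiplex",
             call. = FALSE)
      }
      single_layer_relevance(reference_layer, names(m$layers))
    }
  )
  kernel <- layer_transition_kernel(profile)

  shuffled <- with_seed(seed, sample(genes))
  fold_id <- rep_len(seq_len(k), length(shuffled))
  negatives <- setdiff(m$universe, group$genes)

  fold_auroc <- vapply(seq_len(k), function(f) {
    held_out <- shuffled[fold_id == f]
    seeds <- setdiff(shuffled, held_out)
    res <- informed_rwr(m, kernel, seeds, r = r, tol = tol)
    ranking <- aggregate_and_rank(res, seeds = seeds)
    scores <- stats::setNames(ranking$score, ranking$gene)
    auroc(scores, positives = held_out, negatives = negatives)
  }, numeric(1))

  structure(
    list(group = group$id, regime = regime, fold_auroc = fold_auroc,
         median_auroc = stats::median(fold_auroc), k = as.integer(k),
         seed = as.integer(seed)),
    class = "mxp_cv"
  )
}

# degenerate relevance profile: all weight on one layer
single_layer_relevance <- function(layer_name, all_layers) {
  z <- stats::setNames(rep(0, length(all_layers)), all_layers)
  z[layer_name] <- 10
  relevance_scores(z)
}

#' Gene-level baseline rankings
#'
#' Ranks candidate genes by a single gene-level property: number of pathways
#' (`pathway_count`), expression level (`expression`), literature counts
#' (`literature`) — all supplied through `features` — or phenotypic
#' similarity (`phenotype_similarity`), which scores each candidate by the
#' best-match-average semantic similarity between the candidate's phenotype
#' annotations and the patient's term set. Candidates without a feature value
#' (or without annotations) rank below all scored candidates; ties break
#' lexicographically.
#'
#' @param candidates Character vector of candidate genes.
#' @param features Named numeric vector of feature values (ignored for
#'   `phenotype_similarity`).
#' @param mode One of `"pathway_count"`, `"expression"`, `"literature"`,
#'   `"phenotype_similarity"`.
#' @param patient_terms Patient phenotype terms (phenotype mode).
#' @param a,o,ic Annotations, ontology and IC table (phenotype mode).
#' @return Data frame `gene`, `score` (`NA` for unscored), `rank`.
#' @export
baseline_rank <- function(candidates, features = NULL,
                          mode = c("pathway_count", "expression",
                                   "literature", "phenotype_similarity"),
                          patient_terms = NULL, a = NULL, o = NULL, ic = NULL) {
  mode <- match.arg(mode)
  candidates <- unique(as.character(candidates))
  if (mode == "phenotype_similarity") {
    stopifnot(!is.null(patient_terms), inherits(a, "mxp_annotations"),
              inherits(o, "mxp_ontology"), is.numeric(ic))
    score <- vapply(candidates, function(g) {
      ts <- a[[g]]
      if (is.null(ts) || length(ts) == 0L) return(NA_real_)
      # BMA between the gene's direct terms and the patient's term set
      S <- outer(seq_along(ts), seq_along(patient_terms),
                 Vectorize(function(i, j)
                   term_similarity(o, ic, ts[i], patient_terms[j], "resnik")))
      (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) /
        (length(ts) + length(patient_terms))
    }, numeric(1))
  } else {
    stopifnot(is.numeric(features), !is.null(names(features)))
    score <- unname(features[candidates])
    names(score) <- candidates
  }
  if (all(is.na(score))) {
    stop("no candidate has a feature value in mode '", mode, "'", call. = FALSE)
  }
  ord <- order(-replace(score, is.na(score), -Inf), candidates)
  data.frame(gene = candidates[ord], score = unname(score[ord]),
             rank = seq_along(candidates), stringsAsFactors = FALSE)
}

#' Patient case
#'
#' A patient record for candidate-gene prioritization: observed phenotype
#' terms, the candidate genes left after variant filtering, and (for
#' benchmarking solved cases) the confirmed causal gene.
#'
#' @param id Case identifier.
#' @param phenotype_terms Character vector of phenotype term identifiers.
#' @param candidates Non-empty character vector of candidate genes.
#' @param causal Optional causal gene; must be among the candidates.
#' @param disease_group Optional disease-group identifier the case maps to.
#' @return An object of class `mxp_patient_case`.
#' @export
patient_case <- function(id, phenotype_terms, candidates, causal = NULL,
                         disease_group = NULL) {
  candidates <- unique(as.character(candidates))
  stopifnot(length(candidates) >= 1L, length(phenotype_terms) >= 1L)
  if (!is.null(causal) && !causal %in% candidates) {
    stop("the causal gene must be among the candidates", call. = FALSE)
  }
  structure(list(id = id, phenotype_terms = unique(as.character(phenotype_terms)),
                 candidates = candidates, causal = causal,
                 disease_group = disease_group),
            class = "mxp_patient_case")
}

#' Patient-specific candidate prioritization
#'
#' Seeds the informed walk with the genes annotated to the patient's
#' phenotype terms, weighting each seed by the number of patient terms that
#' annotate it (a gene matching two patient phenotypes gets twice the weight
#' of one matching one), normalized to sum 1. The walk uses the layer
#' relevance profile of the patient's disease group; the resulting ranking is
#' restricted to the candidate genes. Candidates that are themselves seeds
#' are retained by default (the causal gene of a solved case is often
#' phenotype-annotated); set `keep_seeds = FALSE` to drop them.
#'
#' @param m An `mxp_multiplex`.
#' @param case An `mxp_patient_case`.
#' @param relevance An `mxp_relevance` for the case's disease group.
#' @param pheno_annotations An `mxp_annotations` mapping genes to phenotype
#'   terms.
#' @param r,tol Propagation parameters.
#' @param keep_seeds Keep seed genes in the candidate ranking (default TRUE).
#' @return A list of class `mxp_prioritization`: `ranking` (data frame),
#'   `seed_weights`, and — when the causal gene is known — `causal_rank`,
#'   `top5`, `top10`, `top20`.
#' @export
prioritize_patient <- function(m, case, relevance, pheno_annotations,
                               r = 0.7, tol = 1e-8, keep_seeds = TRUE) {
  stopifnot(inherits(m, "mxp_multiplex"), inherits(case, "mxp_patient_case"),
            inherits(relevance, "mxp_relevance"),
            inherits(pheno_annotations, "mxp_annotations"))
  terms <- case$phenotype_terms
  counts <- vapply(names(pheno_annotations), function(g) {
    length(intersect(pheno_annotations[[g]], terms))
  }, integer(1))
  counts <- counts[counts > 0L]
  counts <- counts[names(counts) %in% m$universe]
  if (length(counts) == 0L) {
    stop("no seeds derivable: no gene in the universe is annotated with any ",
         "of the patient's phenotype terms", call. = FALSE)
  }
  seeds <- counts / sum(counts)

  kernel <- layer_transition_kernel(relevance)
  res <- informed_rwr(m, kernel, seeds, r = r, tol = tol)

  if (!keep_seeds && all(case$candidates %in% names(seeds))) {
    warning("all candidates are seeds; ranking by seed weight", call. = FALSE)
    ord <- order(-seeds[case$candidates], case$candidates)
    ranking <- data.frame(gene = case$candidates[ord],
                          score = unname(seeds[case$candidates][ord]),
                          rank = seq_along(ord), stringsAsFactors = FALSE)
  } else {
    ranking <- aggregate_and_rank(res, restrict_to = case$candidates,
                                  keep_seeds = keep_seeds)
  }

  out <- list(ranking = ranking, seed_weights = seeds, case = case$id)
  if (!is.null(case$causal)) {
    cr <- ranking$rank[ranking$gene == case$causal]
    out$causal_rank <- if (length(cr) == 1L) cr else NA_integer_
    out$top5 <- isTRUE(out$causal_rank <= 5L)
    out$top10 <- isTRUE(out$causal_rank <= 10L)
    out$top20 <- isTRUE(out$causal_rank <= 20L)
  }
  structure(out, class = "mxp_prioritization")
}
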