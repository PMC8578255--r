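test_that("auroc matches the Mann-Whitney definition with tie handling", {
  s <- c(p1 = 0.9, p2 = 0.8, n1 = 0.7, n2 = 0.1)
  expect_equal(auroc(s, c("p1", "p2"), c("n1", "n2")), 1)
  expect_equal(auroc(s, c("n1", "n2"), c("p1", "p2")), 0)
  tie <- c(a = 0.8, b = 0.8)
  expect_equal(auroc(tie, "a", "b"), 0.5)
  expect_error(auroc(s, character(0), "n1"), "non-empty")
  expect_error(auroc(s, "p1", "missing"), "without scores")

  # invariance under strictly monotone transforms
  set.seed(3)
  sc <- setNames(runif(30), sprintf("i%02d", 1:30))
  pos <- names(sc)[1:10]; neg <- names(sc)[11:30]
  a0 <- auroc(sc, pos, neg)
  expect_equal(auroc(exp(5 * sc), pos, neg), a0)
  expect_equal(auroc(rank(sc), pos, neg), a0)
})

test_that("kfold assignment partitions the disease genes", {
  fx <- make_multiplex(n_genes = 100, n_layers = 3, n_relevant = 2,
                       module_size = 15, p_background = 0.05, seed = 6)
  tab <- relevance_table(fx$multiplex, list(fx$group), n_rand = 200, seed = 6)
  rel <- relevance_scores(setNames(tab$z, tab$layer))
  cv <- kfold_retrieval(fx$multiplex, fx$group, relevance = rel, k = 5,
                        regime = "relevant_layers", seed = 6)
  expect_length(cv$fold_auroc, 5L)
  expect_true(all(cv$fold_auroc >= 0 & cv$fold_auroc <= 1))
  expect_equal(cv$median_auroc, median(cv$fold_auroc))
  # determinism
  cv2 <- kfold_retrieval(fx$multiplex, fx$group, relevance = rel, k = 5,
                         regime = "relevant_layers", seed = 6)
  expect_identical(cv$fold_auroc, cv2$fold_auroc)
  expect_error(kfold_retrieval(fx$multiplex, fx$group, relevance = rel,
                               k = 50), "fewer")
  expect_error(kfold_retrieval(fx$multiplex, fx$group, regime = "ppi_only",
                               k = 5), "reference_layer")
})

test_that("retrieval is strong on relevant layers, near chance off-module", {
  fx <- make_multiplex(seed = 13)
  tab <- relevance_table(fx$multiplex, list(fx$group), n_rand = 300, seed = 13)
  rel <- relevance_scores(setNames(tab$z, tab$layer))
  cv_rel <- kfold_retrieval(fx$multiplex, fx$group, relevance = rel,
                            regime = "relevant_layers", seed = 13)
  expect_gt(cv_rel$median_auroc, 0.9)
  irrelevant <- setdiff(names(fx$multiplex$layers), fx$relevant_layers)[1]
  cv_bad <- kfold_retrieval(fx$multiplex, fx$group, regime = "ppi_only",
                            reference_layer = irrelevant, seed = 13)
  expect_lt(abs(cv_bad$median_auroc - 0.5), 0.25)
  cv_best <- kfold_retrieval(fx$multiplex, fx$group, relevance = rel,
                             regime = "best_single", seed = 13)
  expect_gt(cv_best$median_auroc, 0.8)
})

test_that("baseline rankings sort by feature with deterministic ties", {
  feats <- c(g1 = 7, g2 = 3, g3 = 0)
  rk <- baseline_rank(c("g3", "g1", "g2"), feats, mode = "pathway_count")
  expect_equal(rk$gene, c("g1", "g2", "g3"))
  # equal values: lexicographic
  rk_tie <- baseline_rank(c("b", "a", "c"), c(a = 1, b = 1, c = 1),
                          mode = "literature")
  expect_equal(rk_tie$gene, c("a", "b", "c"))
  # missing feature ranks last
  rk_na <- baseline_rank(c("a", "b", "zz"), c(a = 2, b = 5), mode = "expression")
  expect_equal(rk_na$gene, c("b", "a", "zz"))
  expect_true(is.na(rk_na$score[3]))
  expect_error(baseline_rank("a", c(b = 1), mode = "expression"), "no candidate")
})

test_that("phenotype-similarity baseline scores by BMA to the patient terms", {
  o <- toy_ontology()
  ic <- term_information_content(o)
  a <- annotations(list(match = "a1", near = "a2", far = "B"), o)
  rk <- baseline_rank(c("far", "near", "match"), mode = "phenotype_similarity",
                      patient_terms = "a1", a = a, o = o, ic = ic)
  expect_equal(rk$gene, c("match", "near", "far"))
  expect_equal(rk$score[1], ic[["a1"]])   # exact term match
  expect_equal(rk$score[2], ic[["A"]])    # sibling: MICA is A
  expect_equal(rk$score[3], 0)            # root-only
})

test_that("patient seed weights are proportional to matched term counts", {
  # g2 matches 2 of the patient's 3 terms, g1 matches 1 -> weights 2:1
  o <- toy_ontology()
  a <- annotations(list(g1 = "a1", g2 = c("a2", "B"), g3 = "A"), o)
  l <- layer("L", rbind(c("g1", "g2"), c("g2", "g3"), c("g1", "g3")))
  m <- multiplex(list(l))
  case <- patient_case("p1", phenotype_terms = c("a1", "a2", "B"),
                       candidates = c("g1", "g2", "g3"))
  pr <- prioritize_patient(m, case, relevance_scores(c(L = 3)), a)
  expect_equal(unname(pr$seed_weights["g2"] / pr$seed_weights["g1"]), 2)
  expect_equal(sum(pr$seed_weights), 1)
  expect_equal(nrow(pr$ranking), 3L)  # seeds retained by default

  expect_error(prioritize_patient(
    m, patient_case("p2", "zz", c("g1", "g2")),
    relevance_scores(c(L = 3)),
    annotations(list(g1 = "a1"), o)), "no seeds derivable")
})

test_that("patient_case enforces its invariants", {
  expect_error(patient_case("x", "t1", c("g1", "g2"), causal = "g9"),
               "among the candidates")
  pc <- patient_case("x", c("t1", "t1"), c("g1", "g2", "g1"), causal = "g1")
  expect_equal(pc$candidates, c("g1", "g2"))
  expect_equal(pc$phenotype_terms, "t1")
})

test_that("simulated solved cases rank the causal gene highly", {
  onto <- make_toy_ontology(seed = 2)
  hits <- vapply(1:3, function(s) {
    fx <- make_multiplex(seed = s)
    tab <- relevance_table(fx$multiplex, list(fx$group), n_rand = 200, seed = s)
    rel <- relevance_scores(setNames(tab$z, tab$layer))
    pc <- make_patient_case(fx, onto, n_candidates = 50, seed = s)
    pr <- prioritize_patient(fx$multiplex, pc$case, rel, pc$annotations)
    pr$causal_rank
  }, numeric(1))
  expect_true(all(hits <= 5))
})
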