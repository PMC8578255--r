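test_that("relevance scores normalize z over informative layers", {
  p <- relevance_scores(c(L1 = 3.29, L2 = 1.0, L3 = 6.58))
  expect_setequal(p$informative, c("L1", "L3"))
  expect_equal(unname(p$pi["L1"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(p$pi["L2"]), 0)
  expect_equal(unname(p$pi["L3"]), 2 / 3, tolerance = 1e-12)
  expect_equal(sum(p$pi), 1, tolerance = 1e-12)
  expect_false(p$fallback)

  single <- relevance_scores(c(A = 0.2, B = 5))
  expect_equal(unname(single$pi["B"]), 1)

  # no layer informative: documented uniform fallback
  fb <- relevance_scores(c(A = 0.1, B = 0.5, C = NA))
  expect_true(fb$fallback)
  expect_equal(unname(fb$pi), rep(1 / 3, 3))
})

test_that("Metropolis layer kernel matches hand evaluation", {
  p <- relevance_scores(c(A = 7.5, B = 2.5))  # pi = (0.75, 0.25)
  k <- layer_transition_kernel(p)
  expect_equal(k$t["A", "B"], 1 / 6, tolerance = 1e-15)
  expect_equal(k$t["B", "A"], 1 / 2, tolerance = 1e-15)
  expect_equal(k$t["A", "A"], 5 / 6, tolerance = 1e-15)
  expect_equal(k$t["B", "B"], 1 / 2, tolerance = 1e-15)
  # stationarity flow check: 0.75 * 1/6 == 0.25 * 1/2
  expect_equal(0.75 * k$t["A", "B"], 0.25 * k$t["B", "A"], tolerance = 1e-15)

  u <- layer_transition_kernel(uniform_relevance(c("a", "b", "c", "d")))
  expect_true(all(abs(u$t - 1 / 4) < 1e-15))

  one <- layer_transition_kernel(relevance_scores(c(solo = 3)))
  expect_equal(one$t, matrix(1, 1, 1, dimnames = list("solo", "solo")))
})

test_that("kernel is row-stochastic with detailed balance and stationarity", {
  set.seed(99)
  for (i in 1:100) {
    L <- sample(2:8, 1)
    z <- setNames(runif(L, 1.7, 12), paste0("L", seq_len(L)))
    k <- layer_transition_kernel(relevance_scores(z))
    expect_equal(unname(rowSums(k$t)), rep(1, L), tolerance = 1e-12)
    expect_true(all(diag(k$t) >= 0))
    bal <- outer(k$pi, rep(1, L)) * k$t - t(outer(k$pi, rep(1, L)) * k$t)
    expect_lt(max(abs(bal)), 1e-12)
    expect_lt(max(abs(as.numeric(k$pi %*% k$t) - k$pi)), 1e-12)
  }
})

test_that("r = 1 returns the seed distribution", {
  fx <- make_multiplex(n_genes = 30, n_layers = 2, n_relevant = 1,
                       module_size = 5, p_background = 0.1, seed = 4)
  kernel <- layer_transition_kernel(uniform_relevance(names(fx$multiplex$layers)))
  seeds <- fx$group$genes[1:3]
  res <- informed_rwr(fx$multiplex, kernel, seeds, r = 1)
  expect_equal(sum(res$visiting), 1, tolerance = 1e-9)
  expect_equal(unname(res$aggregated[seeds]), rep(1 / 3 / 2, 3), tolerance = 1e-12)
  expect_equal(sum(res$aggregated[setdiff(names(res$aggregated), seeds)]), 0)
})

test_that("single-layer walk matches a direct linear solve", {
  l <- random_layer(30, p = 0.15, seed = 21)
  m <- multiplex(list(l))
  kernel <- layer_transition_kernel(relevance_scores(c(rnd = 5)))
  seeds <- layer_nodes(l)[1:3]
  res <- informed_rwr(m, kernel, seeds, tol = 1e-12)
  direct <- solve_rwr_direct(m, kernel,
                             setNames(rep(1 / 3, 3), seeds), r = 0.7)
  expect_lt(max(abs(res$visiting - direct)), 1e-8)
})

test_that("iterative informed walk matches the dense linear-system oracle", {
  for (s in 1:8) {
    set.seed(s)
    n_genes <- sample(10:20, 1)
    L <- sample(2:3, 1)
    fx <- make_multiplex(n_genes = n_genes, n_layers = L, n_relevant = 1,
                         module_size = 4, p_background = 0.15,
                         p_module = 0.5, seed = s)
    z <- setNames(runif(L, 2, 9), names(fx$multiplex$layers))
    kernel <- layer_transition_kernel(relevance_scores(z))
    seeds <- setNames(runif(3) + 0.1, fx$multiplex$universe[1:3])
    res <- informed_rwr(fx$multiplex, kernel, seeds, tol = 1e-13)
    direct <- solve_rwr_direct(fx$multiplex, kernel, seeds, r = 0.7)
    expect_lt(max(abs(res$visiting - direct)), 1e-8)
    expect_equal(sum(res$visiting), 1, tolerance = 1e-9)
    # converged point satisfies the fixed-point equation
    op <- dense_supra_operator(fx$multiplex, kernel, seeds)
    p <- as.numeric(res$visiting)
    expect_lt(sum(abs(p - ((1 - 0.7) * op$T %*% p + 0.7 * op$p0))), 1e-11)
  }
})

test_that("uniform-pi informed walk equals the uninformed multiplex walk", {
  for (s in 1:5) {
    fx <- make_multiplex(n_genes = 15, n_layers = 3, n_relevant = 1,
                         module_size = 4, p_background = 0.15, seed = s + 40)
    kernel <- layer_transition_kernel(uniform_relevance(names(fx$multiplex$layers)))
    seeds <- fx$multiplex$universe[1:2]
    res <- informed_rwr(fx$multiplex, kernel, seeds, tol = 1e-14)
    ref <- uninformed_rwr_dense(fx$multiplex,
                                setNames(rep(0.5, 2), seeds), r = 0.7)
    expect_lt(max(abs(res$visiting - ref)), 1e-10)
  }
})

test_that("pi = (1, 0) ranks in-layer neighbors above other-layer neighbors", {
  # seed s: neighbors n1 (layer A only) and n2 (layer B only)
  la <- layer("A", rbind(c("s", "n1"), c("n1", "x"), c("n2", "x")))
  lb <- layer("B", rbind(c("s", "n2"), c("n2", "x"), c("n1", "x")))
  m <- multiplex(list(la, lb))
  kernel <- layer_transition_kernel(relevance_scores(c(A = 5, B = 0)))
  res <- informed_rwr(m, kernel, "s")
  rk <- aggregate_and_rank(res)
  expect_lt(which(rk$gene == "n1"), which(rk$gene == "n2"))
})

test_that("dangling mass is redirected and the operator stays stochastic", {
  # gene 'iso' has edges only in layer B; in layer A it is dangling
  la <- layer("A", rbind(c("a", "b")))
  lb <- layer("B", rbind(c("a", "b"), c("a", "iso")))
  m <- multiplex(list(la, lb))
  kernel <- layer_transition_kernel(uniform_relevance(c("A", "B")))
  res <- informed_rwr(m, kernel, "a", tol = 1e-12)
  expect_equal(sum(res$visiting), 1, tolerance = 1e-9)
  res_stay <- informed_rwr(m, kernel, "a", tol = 1e-12, dangling = "stay")
  expect_equal(sum(res_stay$visiting), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(res$visiting, res_stay$visiting)))
})

test_that("seed handling: errors, aggregation, ranking rules", {
  l <- layer("A", rbind(c("a", "b"), c("b", "c")))
  m <- multiplex(list(l))
  kernel <- layer_transition_kernel(relevance_scores(c(A = 3)))
  expect_error(informed_rwr(m, kernel, "zz"), "universe")

  res <- informed_rwr(m, kernel, "a")
  expect_equal(res$aggregated, rowMeans(res$visiting))
  rk <- aggregate_and_rank(res)
  expect_false("a" %in% rk$gene)      # seeds omitted
  expect_equal(rk$rank, seq_len(nrow(rk)))

  # all candidates are seeds -> empty ranking
  rk0 <- aggregate_and_rank(res, restrict_to = "a")
  expect_equal(nrow(rk0), 0L)
  expect_warning(aggregate_and_rank(res, restrict_to = "not_here"), "disjoint")

  # deterministic lexicographic tie-break: b and c symmetric around seed? no -
  # use a star so both leaves tie
  star <- multiplex(list(layer("A", rbind(c("s", "u"), c("s", "v")))))
  res2 <- informed_rwr(star, layer_transition_kernel(relevance_scores(c(A = 3))), "s")
  rk2 <- aggregate_and_rank(res2)
  expect_equal(rk2$gene, c("u", "v"))
  expect_equal(rk2$score[1], rk2$score[2], tolerance = 1e-12)
})
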