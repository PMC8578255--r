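test_that("layer summary matches hand values on canonical small graphs", {
  tri <- layer("tri", rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  s <- layer_summary(tri)
  expect_equal(s$density, 1)
  expect_equal(s$clustering, 1)

  path3 <- layer("p3", rbind(c("a", "b"), c("b", "c")))
  expect_equal(layer_summary(path3)$clustering, 0)

  cyc4 <- layer("c4", rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_true(is.na(layer_summary(cyc4)$assortativity))  # zero degree variance
})

test_that("layer summary agrees with igraph on random graphs", {
  for (s in 1:50) {
    l <- random_layer(sample(5:30, 1), p = 0.25, seed = s)
    if (n_edges(l) < 2) next
    g <- igraph::graph_from_edgelist(l$edges, directed = FALSE)
    s_pkg <- layer_summary(l)
    expect_equal(s_pkg$density, igraph::edge_density(g), tolerance = 1e-12)
    ig_cl <- igraph::transitivity(g, type = "global")
    if (!is.nan(ig_cl)) expect_equal(s_pkg$clustering, ig_cl, tolerance = 1e-12)
    ig_as <- igraph::assortativity_degree(g)
    if (!is.nan(ig_as)) {
      expect_equal(s_pkg$assortativity, ig_as, tolerance = 1e-9)
    } else {
      expect_true(is.na(s_pkg$assortativity))
    }
  }
})

test_that("local assortativity sums to the global assortativity", {
  star <- layer("star", rbind(c("h", "x"), c("h", "y"), c("h", "z")))
  la <- local_assortativity(star)
  expect_equal(sum(la$rho), -1, tolerance = 1e-9)
  expect_equal(unname(la$rho["h"]), -1, tolerance = 1e-9)
  expect_equal(unname(la$rho["x"]), 0)

  for (s in 1:50) {
    l <- random_layer(sample(6:25, 1), p = 0.3, seed = s + 500)
    if (n_edges(l) < 3) next
    glob <- layer_summary(l)$assortativity
    if (is.na(glob)) {
      expect_error(local_assortativity(l), "variance")
    } else {
      expect_equal(sum(local_assortativity(l)$rho), glob, tolerance = 1e-9)
    }
  }

  two_edges <- layer("deg1", rbind(c("a", "b"), c("c", "d")))
  expect_error(local_assortativity(two_edges), "variance")
})

test_that("annotation bias is the degree/count Spearman correlation", {
  l <- layer("t", rbind(c("n1", "n2"), c("n2", "n3"), c("n3", "n4"),
                        c("n3", "n1"), c("n4", "n1"), c("n4", "n2"),
                        c("n4", "n5")))
  nodes <- layer_nodes(l)
  deg <- vapply(nodes, function(v) sum(l$edges == v), numeric(1))
  expect_equal(annotation_bias(l, deg), 1)
  expect_equal(annotation_bias(l, max(deg) + 1 - deg), -1)

  # average-rank tie handling, verified against stats::cor on ranks
  l4 <- layer("t4", rbind(c("g1", "g2"), c("g2", "g3"), c("g3", "g4"),
                          c("g3", "g1"), c("g4", "g1"), c("g4", "g2")))
  # degrees g1..g4 = 3,3,3,3 (constant) -> sentinel
  expect_true(is.na(annotation_bias(l4, c(g1 = 1, g2 = 2, g3 = 3, g4 = 4))))
  chain <- layer("chain", rbind(c("g1", "g2"), c("g2", "g3"), c("g3", "g4"),
                                c("g2", "g4"), c("g3", "g1"), c("g4", "g1"),
                                c("g4", "g5"), c("g5", "g3"), c("g5", "g4")))
  deg5 <- vapply(layer_nodes(chain), function(v) sum(chain$edges == v), numeric(1))
  counts <- c(g1 = 10, g2 = 10, g3 = 30, g4 = 20, g5 = 15)
  expect_equal(annotation_bias(chain, counts),
               cor(deg5, counts[names(deg5)], method = "spearman"))
})

test_that("degree(1,2,3,4) vs counts(10,10,30,20) gives Spearman 0.7379", {
  # graph with degree sequence 1,2,3,4 on genes d1..d4 (plus helpers)
  l <- layer("t", rbind(c("d4", "d1"), c("d4", "d2"), c("d4", "d3"),
                        c("d4", "h1"), c("d3", "d2"), c("d3", "h1")))
  nodes <- layer_nodes(l)
  deg <- vapply(nodes, function(v) sum(l$edges == v), numeric(1))
  expect_equal(unname(deg[c("d1", "d2", "d3", "d4")]), c(1, 2, 3, 4))
  counts <- c(d1 = 10, d2 = 10, d3 = 30, d4 = 20)
  # independent oracle: R's average-rank Spearman
  expect_equal(annotation_bias(l, counts), 0.7378648, tolerance = 1e-6)
})

test_that("edge conservation profile counts marked endpoints per level", {
  l1 <- layer("t1", rbind(c("u", "v"), c("p", "q")))
  l2 <- layer("t2", rbind(c("u", "v"), c("r", "s")))
  prof <- edge_conservation_profile(list(l1, l2), marked = c("u", "v"))
  expect_equal(prof$conservation, c(1L, 2L))
  expect_equal(prof$fraction_marked, c(0, 1))
  expect_equal(prof$n_edges, c(2L, 1L))

  all_marked <- edge_conservation_profile(list(l1, l2),
                                          marked = c("u", "v", "p", "q", "r", "s"))
  expect_true(all(all_marked$fraction_marked == 1))
  none <- edge_conservation_profile(list(l1, l2), marked = character(0))
  expect_true(all(none$fraction_marked == 0))

  # absent levels are dropped, not reported as zero
  l3 <- layer("t3", rbind(c("u", "v")))
  prof3 <- edge_conservation_profile(list(l3, layer("t4", rbind(c("u", "v")))),
                                     marked = "u")
  expect_equal(prof3$conservation, 2L)
})
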