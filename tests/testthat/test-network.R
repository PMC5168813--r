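test_that("Spearman matrix handles monotone, reversed and tied inputs", {
  x <- cbind(a = 1:5, b = c(2, 4, 6, 8, 10), c = 5:1)
  sp <- spearman_matrix(x)
  expect_equal(sp$r["a", "b"], 1)
  expect_equal(sp$r["a", "c"], -1)

  y <- cbind(u = c(1, 2, 3, 4), v = c(2, 1, 4, 3))
  expect_equal(spearman_matrix(y)$r["u", "v"], 0.6)
})

test_that("Spearman p-values agree with the t-approximation reference", {
  set.seed(4)
  m <- matrix(rnorm(200), 40, 5)
  sp <- spearman_matrix(m)
  for (i in 1:4) for (j in (i + 1):5) {
    ref <- cor.test(m[, i], m[, j], method = "spearman", exact = FALSE)
    expect_equal(sp$r[i, j], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(sp$p[i, j], ref$p.value, tolerance = 1e-10)
  }
})

test_that("constant columns are excluded and reported", {
  m <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  sp <- spearman_matrix(m)
  expect_equal(attr(sp, "excluded"), "b")
  expect_true(all(is.na(sp$r["b", c("a", "c")])))
})

test_that("BH adjustment matches the step-up hand calculation and reference", {
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.42), 0.42)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))^2
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  p_na <- c(0.01, NA, 0.5)
  expect_equal(bh_fdr(p_na), p.adjust(p_na, "BH"))
})

test_that("edge retention respects both thresholds and drops isolated nodes", {
  set.seed(6)
  grp <- rep(c(1, -1), each = 4)
  base <- rnorm(30)
  m <- sapply(grp, function(s) s * base + rnorm(30, sd = 0.3))
  colnames(m) <- sprintf("v%d", 1:8)
  m <- cbind(m, lone = rnorm(30))
  sp <- spearman_matrix(m)

  net <- build_network(sp, r_min = 0.4, q = 0.05)
  expect_false("lone" %in% igraph::V(net)$name)
  expect_true(all(abs(igraph::E(net)$r) >= 0.4))
  expect_true(all(igraph::E(net)$p_adj < 0.05))
  # negative edges only run between the planted anticorrelated halves
  ep <- igraph::as_edgelist(net)
  sgn <- igraph::E(net)$sign
  side <- grp[match(ep, colnames(m))]
  dim(side) <- dim(ep)
  expect_true(all((side[, 1] == side[, 2]) == (sgn > 0)))

  # r_min = 1 keeps only perfectly correlated pairs
  m2 <- cbind(a = 1:20, b = (1:20) * 2, c = rnorm(20))
  net2 <- build_network(spearman_matrix(m2), r_min = 1, q = 0.05)
  expect_equal(sort(igraph::V(net2)$name), c("a", "b"))

  # q = 0 gives an empty graph
  net3 <- build_network(sp, r_min = 0.4, q = 0)
  expect_equal(igraph::vcount(net3), 0)
})

test_that("network attributes satisfy the closed-form identities", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  a <- network_attributes(tri)
  expect_equal(a$density, 1)
  expect_equal(a$transitivity, 1)
  expect_equal(a$diameter, 1)
  expect_equal(a$avg_path_length, 1)

  path4 <- igraph::make_graph(~ a - b, b - c, c - d)
  p <- network_attributes(path4)
  expect_equal(p$diameter, 3)
  expect_equal(p$density, 0.5)
  expect_equal(p$transitivity, 0)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]
  s <- network_attributes(star)
  expect_equal(s$avg_degree, 1.6)
  expect_equal(s$edge_node_ratio, 4 / 5)
  expect_equal(s$transitivity, 0)
})

test_that("threshold scan is monotone and consistent with direct builds", {
  set.seed(9)
  m <- matrix(rnorm(600), 50, 12) + rnorm(50)
  colnames(m) <- sprintf("v%d", 1:12)
  sp <- spearman_matrix(m)
  scan <- threshold_scan(sp, thresholds = c(0, 0.2, 0.4, 0.6, 0.8))
  expect_true(all(diff(scan$n_edges[!is.na(scan$n_edges)]) <= 0))
  direct <- network_attributes(build_network(sp, r_min = 0.4))
  expect_equal(scan$density[scan$r_min == 0.4], direct$density)
  # threshold 0: all FDR-significant pairs present
  all_sig <- sum(bh_fdr(sp$p[upper.tri(sp$p)]) < 0.05)
  expect_equal(scan$n_edges[scan$r_min == 0], all_sig)
})

test_that("Walktrap separates two cliques and keeps uniform graphs whole", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- sprintf("n%d", 1:8)
  igraph::E(g)$weight <- 1
  memb <- walktrap_communities(g)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:4])), 1)
  expect_equal(length(unique(memb[5:8])), 1)
  expect_false(memb[1] == memb[5])

  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- sprintf("n%d", 1:6)
  igraph::E(full)$weight <- 1
  expect_equal(length(unique(walktrap_communities(full))), 1)

  # disjoint cliques are returned exactly
  dj <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(4),
                               igraph::make_full_graph(3))
  igraph::V(dj)$name <- sprintf("n%d", 1:12)
  igraph::E(dj)$weight <- 1
  md <- walktrap_communities(dj)
  expect_equal(adjusted_rand_index(md, rep(1:3, c(5, 4, 3))), 1)
})

signed_graph <- function(edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, sign = edges$s,
               weight = abs(edges$w), r = edges$w * edges$s),
    directed = FALSE,
    vertices = unique(c(edges$from, edges$to)))
}

test_that("signed bipartition solves the canonical small cases", {
  # all-positive: one subset, frustration 0
  gp <- signed_graph(data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a"),
                                w = 1, s = 1L))
  bp <- signed_bipartition(gp)
  expect_equal(bp$frustration, 0)
  expect_true(length(bp$A) == 0 || length(bp$B) == 0)

  # alternating 4-cycle is balanced with the unique split {1,2} | {3,4}
  g4 <- signed_graph(data.frame(from = c("n1", "n2", "n3", "n4"),
                                to = c("n2", "n3", "n4", "n1"),
                                w = 1, s = c(1L, -1L, 1L, -1L)))
  bp4 <- signed_bipartition(g4)
  expect_equal(bp4$frustration, 0)
  split <- sort(sapply(list(bp4$A, bp4$B), paste, collapse = "+"))
  expect_true(setequal(split, c("n1+n2", "n3+n4")))

  # unbalanced triad (+,+,-) has minimum frustration 1
  g3 <- signed_graph(data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a"),
                                w = 1, s = c(1L, 1L, -1L)))
  expect_equal(signed_bipartition(g3, weighted = FALSE)$frustration, 1)
})

test_that("greedy bipartition equals the exact optimum on random graphs", {
  set.seed(13)
  for (i in 1:40) {
    rg <- random_signed_graph(sample(5:12, 1))
    if (is.null(rg)) next
    exact <- signed_bipartition(rg$g, exact_limit = 15)
    greedy <- signed_bipartition(rg$g, exact_limit = 0)
    oracle <- exhaustive_frustration(rg$edges, rg$n)
    expect_equal(exact$frustration, oracle, tolerance = 1e-9)
    expect_equal(greedy$frustration, oracle, tolerance = 1e-9)
  }
})

test_that("metabolite sets are assembled and oriented by germination", {
  # two communities, each split +/- , consistent global structure:
  # ms1 candidates {a1, b1} (negative to percent), ms2 {a2, b2}
  ed <- data.frame(
    from = c("a1", "a2", "b1", "b2", "a1", "a2", "a1", "a2", "percent",
             "percent"),
    to   = c("a2", "b1", "b2", "a1", "b1", "b2", "percent", "percent",
             "b1", "b2"),
    w = 1,
    s = c(-1L, -1L, -1L, -1L, 1L, 1L, -1L, 1L, -1L, 1L))
  g <- signed_graph(ed)
  memb <- setNames(rep(1L, igraph::vcount(g)), igraph::V(g)$name)
  sets <- assemble_metabolite_sets(g, memb)
  s <- setNames(sets$sets$set, sets$sets$node)
  expect_equal(sets$orientation, "germination_anchored")
  expect_equal(unname(s[c("a1", "b1")]), c("ms1", "ms1"))
  expect_equal(unname(s[c("a2", "b2")]), c("ms2", "ms2"))
  expect_equal(sets$frustration, 0)

  # flipping every sign swaps the sets (orientation follows germination)
  ed2 <- ed; ed2$s <- -ed2$s
  sets2 <- assemble_metabolite_sets(signed_graph(ed2), memb)
  s2 <- setNames(sets2$sets$set, sets2$sets$node)
  expect_equal(unname(s2[c("a2", "b2")]), c("ms1", "ms1"))

  rep <- germination_edge_report(g, sets)
  expect_equal(nrow(rep), 4)
  expect_equal(attr(rep, "consistency"), 1)
})

test_that("a hand-built network yields the documented germination report", {
  ed <- data.frame(from = c("m1", "m2", "m1", "t50"),
                   to = c("percent", "percent", "m2", "m1"),
                   w = c(0.8, 0.6, 0.5, 0.7), s = c(-1L, 1L, -1L, 1L))
  g <- signed_graph(ed)
  memb <- setNames(rep(1L, igraph::vcount(g)), igraph::V(g)$name)
  sets <- assemble_metabolite_sets(g, memb)
  rep <- germination_edge_report(g, sets)
  expect_setequal(rep$metabolite, c("m1", "m2"))
  m1_rows <- rep[rep$metabolite == "m1", ]
  expect_equal(m1_rows$expected_set[m1_rows$trait == "percent"], "ms1")
  expect_equal(m1_rows$expected_set[m1_rows$trait == "t50"], "ms1")
  expect_equal(attr(rep, "consistency"), 1)
})
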