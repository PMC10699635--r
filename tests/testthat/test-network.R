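test_that("locus weights are inverse to allele variance, scaled and clamped", {
  # equal variability -> equal weights
  m <- cbind(L1 = c(10L, 11L, 10L, 11L), L2 = c(14L, 15L, 14L, 15L))
  w <- compute_str_weights(make_profiles(m))
  expect_identical(unname(w[1]), unname(w[2]))

  # variance ratio 4 -> weight ratio 4 before clamping
  m2 <- cbind(A = c(10L, 14L, 10L, 14L), B = c(10L, 12L, 10L, 12L))
  w2 <- compute_str_weights(make_profiles(m2))
  expect_identical(unname(w2[["A"]]), 1L)
  expect_identical(unname(w2[["B"]]), 4L)

  # 3-locus toy: variances 8/3, 2/3, 0 -> weights 1, 4, 99
  m3 <- cbind(X = c(10L, 12L, 14L, 12L), Y = c(10L, 11L, 12L, 11L),
              Z = c(13L, 13L, 13L, 13L))
  w3 <- compute_str_weights(make_profiles(m3))
  expect_identical(unname(w3), c(1L, 4L, 99L))

  expect_identical(unname(compute_str_weights(make_profiles(m3),
                                              scheme = "uniform")),
                   rep(1L, 3))
  expect_error(compute_str_weights(make_profiles(m3)[0, ]), "empty")
})

test_that("degenerate networks collapse to the expected trivia", {
  m <- matrix(14L, nrow = 6, ncol = 3,
              dimnames = list(NULL, c("L1", "L2", "L3")))
  net <- build_mj_network(make_profiles(m))
  expect_identical(sum(net$kind == "observed"), 1L)
  expect_identical(net$frequency[1], 6L)
  expect_identical(nrow(net$edges), 0L)

  m2 <- rbind(c(14L, 10L), c(15L, 10L))
  colnames(m2) <- c("L1", "L2")
  w <- c(L1 = 3L, L2 = 7L)
  net2 <- build_mj_network(make_profiles(m2), weights = w)
  expect_identical(nrow(net2$edges), 1L)
  expect_identical(net2$edges$d, 3)
  expect_identical(net2$edges$loci, "L1:1")
  expect_error(build_mj_network(make_profiles(m2 + 0.5)), "integer")
})

test_that("a feasible triplet gains exactly one median node and shortens the network", {
  # pairwise distance 2, coordinate-wise median is a Steiner point
  m <- rbind(h1 = c(10L, 10L, 10L),
             h2 = c(11L, 11L, 10L),
             h3 = c(11L, 10L, 11L))
  colnames(m) <- c("L1", "L2", "L3")
  w <- c(L1 = 1, L2 = 1, L3 = 1)
  net <- build_mj_network(make_profiles(m), weights = w)
  expect_identical(sum(net$kind == "median"), 1L)
  med <- net$haplotypes[net$kind == "median", ]
  # exhaustive enumeration over the allele grid: the added point must be
  # an optimal Steiner point
  grid <- expand.grid(10:11, 10:11, 10:11)
  costs <- apply(grid, 1L, function(p) {
    sum(apply(m, 1L, function(h) weighted_l1(h, as.integer(p), w)))
  })
  expect_identical(sum(w * abs(med - as.integer(grid[which.min(costs), ]))), 0)
  total_len <- sum(ylineage::min_spanning_network(net$haplotypes, w)$d)
  # any spanning tree on the three observed nodes costs 4; the star via
  # the median costs 3
  expect_identical(total_len, 3)
  expect_lt(total_len, 4)
})

test_that("the minimum spanning network always contains a minimum spanning tree", {
  set.seed(31)
  for (n_hap in c(4L, 5L, 6L)) {
    for (rep in 1:4) {
      m <- matrix(sample(10:15, n_hap * 4, replace = TRUE), nrow = n_hap)
      m <- m[!duplicated(m), , drop = FALSE]
      if (nrow(m) < 3L) next
      colnames(m) <- sprintf("L%d", 1:4)
      w <- rep(1, 4)
      D <- as.matrix(dist(m, method = "manhattan"))
      oracle <- brute_min_spanning_weight(D)
      msn <- min_spanning_network(m, w, epsilon = 0)
      g <- igraph::make_graph(rbind(msn$i, msn$j), n = nrow(m),
                              directed = FALSE)
      igraph::E(g)$weight <- msn$d
      expect_true(igraph::is_connected(g))
      mst_w <- sum(igraph::E(igraph::mst(g))$weight)
      expect_equal(mst_w, oracle)
      # and every edge of an independently computed MST of the complete
      # graph is present in the MSN
      gc <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                weighted = TRUE)
      mst_ig <- igraph::mst(gc)
      el <- igraph::as_edgelist(mst_ig, names = FALSE)
      msn_keys <- paste(pmin(msn$i, msn$j), pmax(msn$i, msn$j))
      mst_keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      expect_true(all(mst_keys %in% msn_keys))
    }
  }
})

test_that("duplicated haplotypes change frequency but never topology", {
  set.seed(7)
  m <- matrix(sample(12:15, 5 * 4, replace = TRUE), nrow = 5)
  colnames(m) <- sprintf("L%d", 1:4)
  m <- m[!duplicated(m), , drop = FALSE]
  w <- c(L1 = 1, L2 = 2, L3 = 1, L4 = 3)
  net1 <- build_mj_network(make_profiles(m), weights = w)
  net2 <- build_mj_network(make_profiles(rbind(m, m[1, ])), weights = w)
  expect_identical(net1$haplotypes, net2$haplotypes)
  expect_identical(net1$edges$d, net2$edges$d)
  i1 <- which(apply(net1$haplotypes, 1L, function(h) all(h == m[1, ])))
  expect_identical(net2$frequency[i1], net1$frequency[i1] + 1L)
  expect_identical(sum(net2$frequency), nrow(m) + 1L)
})

test_that("raising epsilon only ever adds edges", {
  set.seed(17)
  m <- matrix(sample(10:16, 6 * 5, replace = TRUE), nrow = 6)
  m <- m[!duplicated(m), , drop = FALSE]
  colnames(m) <- sprintf("L%d", seq_len(ncol(m)))
  w <- rep(1, ncol(m))
  e0 <- min_spanning_network(m, w, 0)
  e2 <- min_spanning_network(m, w, 2)
  key <- function(e) paste(e$i, e$j)
  expect_true(all(key(e0) %in% key(e2)))
  expect_gte(nrow(e2), nrow(e0))
})

test_that("node frequencies always sum to the number of input samples", {
  set.seed(23)
  mod <- str_model(loci = sprintf("L%d", 1:6), mu_per_locus_per_gen = 5e-3)
  spec <- genealogy_spec("star", n_samples = 30, age_generations = 50,
                         seed = 3)
  pr <- simulate_star_genealogy(spec, mod)
  net <- build_mj_network(pr, weights = compute_str_weights(pr))
  expect_identical(sum(net$frequency), 30L)
})

test_that("network exports round-trip and keep unique node identifiers", {
  m <- rbind(c(10L, 10L), c(11L, 10L), c(11L, 11L), c(13L, 11L))
  colnames(m) <- c("L1", "L2")
  pops <- c("amazon", "amazon", "andes", "andes")
  net <- build_mj_network(make_profiles(m, population = pops),
                          weights = c(L1 = 1, L2 = 1))

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::vcount(g2), igraph::vcount(net$graph))
  expect_identical(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_setequal(igraph::V(g2)$kind, igraph::V(net$graph)$kind)
  expect_setequal(igraph::V(g2)$frequency, igraph::V(net$graph)$frequency)

  dot <- tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  ids <- igraph::V(net$graph)$name
  expect_false(anyDuplicated(ids) > 0)
  expect_true(file.exists(dot))

  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  lines <- readLines(tsv)
  expect_true(startsWith(lines[1], "#"))
  expect_error(export_network(net, tempfile(), "xml"), "arg")

  # single-node export
  net1 <- build_mj_network(make_profiles(m[1, , drop = FALSE]),
                           weights = c(L1 = 1, L2 = 1))
  gml1 <- tempfile(fileext = ".graphml")
  export_network(net1, gml1, "graphml")
  g1 <- igraph::read_graph(gml1, format = "graphml")
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)
})
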