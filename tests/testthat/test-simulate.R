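test_that("zero-time star genealogy returns the ancestral haplotype everywhere", {
  mod <- str_model()
  spec <- genealogy_spec("star", n_samples = 10, age_generations = 0, seed = 1)
  pr <- simulate_star_genealogy(spec, mod)
  m <- as.matrix(as.data.frame(pr)[, mod$loci])
  expect_true(all(t(m) == mod$ancestral_alleles))
})

test_that("simulators are deterministic given the seed", {
  mod <- str_model()
  spec <- genealogy_spec("star", n_samples = 50, age_generations = 30, seed = 42)
  expect_identical(simulate_star_genealogy(spec, mod),
                   simulate_star_genealogy(spec, mod))
  spec2 <- genealogy_spec("two_level_hierarchy", n_samples = 12,
                          age_generations = 100,
                          group_sizes = list(g1 = c(p1 = 3, p2 = 3),
                                             g2 = c(p3 = 3, p4 = 3)),
                          divergence_generations = c(60, 20), seed = 7)
  expect_identical(simulate_structured_populations(spec2, mod),
                   simulate_structured_populations(spec2, mod))
})

test_that("invalid genealogy and model parameters are rejected", {
  expect_error(genealogy_spec("star", n_samples = 1, age_generations = 10),
               ">= 2")
  expect_error(genealogy_spec("star", n_samples = 10, age_generations = -1),
               "non-negative")
  expect_error(str_model(mu_per_locus_per_gen = 0), "positive")
  expect_error(
    genealogy_spec("two_level_hierarchy", n_samples = 10, age_generations = 10,
                   group_sizes = list(g1 = c(p1 = 4, p2 = 4)),
                   divergence_generations = c(5, 2)),
    "sum to")
})

test_that("per-locus displacement follows the Poisson-compounded single-step law", {
  # mean absolute per-locus displacement over replicates vs the exact
  # compound-Poisson expectation, and a chi-square fit of the step law
  mu <- 6.9e-4
  T_gen <- 426.38 / 25
  lambda <- mu * T_gen
  n <- 500; L <- 15; reps <- 1000
  exact_e_abs <- {
    k <- 0:30
    pk <- stats::dpois(k, lambda)
    e_abs_k <- vapply(k, function(kk) {
      j <- 0:kk
      sum(stats::dbinom(j, kk, 0.5) * abs(2 * j - kk))
    }, numeric(1))
    sum(pk * e_abs_k)
  }
  mod <- str_model()
  set.seed(99)
  rep_means <- vapply(seq_len(reps), function(r) {
    spec <- genealogy_spec("star", n_samples = n, age_generations = T_gen,
                           seed = 1000 + r)
    pr <- simulate_star_genealogy(spec, mod)
    m <- as.matrix(as.data.frame(pr)[, mod$loci])
    mean(abs(t(m) - mod$ancestral_alleles))
  }, numeric(1))
  se <- stats::sd(rep_means) / sqrt(reps)
  expect_lt(abs(mean(rep_means) - exact_e_abs), 2 * se + 1e-6)
  # the exact expectation sits within ~1% of the small-lambda value lambda
  expect_equal(exact_e_abs, 0.01177, tolerance = 0.01)

  # chi-square goodness of fit of displacement counts at a larger rate
  lam2 <- 0.01
  set.seed(123)
  spec2 <- genealogy_spec("star", n_samples = 2000, age_generations = lam2 / mu,
                          seed = 5)
  pr2 <- simulate_star_genealogy(spec2, mod)
  d <- as.vector(t(as.matrix(as.data.frame(pr2)[, mod$loci])) -
                   mod$ancestral_alleles)
  obs <- c(sum(d <= -1), sum(d == 0), sum(d >= 1))
  k_even <- seq(0, 40, by = 2)
  p_zero <- sum(stats::dpois(k_even, lam2) *
                  stats::dbinom(k_even / 2, k_even, 0.5))
  p_pos <- (1 - p_zero) / 2
  gof <- stats::chisq.test(obs, p = c(p_pos, p_zero, p_pos))
  expect_gt(gof$p.value, 0.01)
})

test_that("structured simulation limit cases drive AMOVA to the expected extremes", {
  mod <- str_model()
  # deep between-group divergence, zero within: all variation among groups
  spec <- genealogy_spec("two_level_hierarchy", n_samples = 20,
                         age_generations = 3000,
                         group_sizes = list(g1 = c(p1 = 5, p2 = 5),
                                            g2 = c(p3 = 5, p4 = 5)),
                         divergence_generations = c(3000, 0), seed = 11)
  pr <- simulate_structured_populations(spec, mod)
  res <- amova_two_level(pr, n_permutations = 0)
  expect_false(res$degenerate)
  expect_equal(res$table$percent[1], 100, tolerance = 1e-8)
  expect_equal(res$table$variance[3], 0, tolerance = 1e-12)

  # zero divergence everywhere: haplotypes exchangeable across populations
  spec0 <- genealogy_spec("two_level_hierarchy", n_samples = 60,
                          age_generations = 300,
                          group_sizes = list(g1 = c(p1 = 15, p2 = 15),
                                             g2 = c(p3 = 15, p4 = 15)),
                          divergence_generations = c(0, 0), seed = 12)
  pr0 <- simulate_structured_populations(spec0, mod)
  res0 <- amova_two_level(pr0, n_permutations = 0)
  expect_lt(abs(res0$phi[["Phi_ST"]]), 0.15)
})

test_that("simulated variance ordering Va > Vb is recovered in the majority of replicates", {
  mod <- str_model(loci = sprintf("L%d", 1:10),
                   mu_per_locus_per_gen = 2e-3)
  hits <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    spec <- genealogy_spec("two_level_hierarchy", n_samples = 24,
                           age_generations = 400,
                           group_sizes = list(g1 = c(p1 = 6, p2 = 6),
                                              g2 = c(p3 = 6, p4 = 6)),
                           divergence_generations = c(250, 80),
                           seed = 5000 + r)
    pr <- simulate_structured_populations(spec, mod)
    res <- amova_two_level(pr, n_permutations = 0)
    va <- res$table$variance[1]; vb <- res$table$variance[2]
    if (!is.na(va) && va > vb) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.5)
})

test_that("SNP placement yields perfectly nested derived sets that invert under classification", {
  mod <- str_model()
  tree <- qm3_tree()
  spec <- genealogy_spec("two_level_hierarchy", n_samples = 40,
                         age_generations = 500,
                         group_sizes = list(g1 = c(p1 = 10, p2 = 10),
                                            g2 = c(p3 = 10, p4 = 10)),
                         divergence_generations = c(300, 100), seed = 21)
  pr <- simulate_structured_populations(spec, mod)
  for (s in c(1, 2, 3)) {
    gt <- place_snps_on_genealogy(pr, tree, seed = s)
    # root marker derived in everyone
    expect_true(all(gt[["M242"]] == "D"))
    # nesting: derived(child) subset of derived(parent)
    nodes <- tree$nodes
    for (i in seq_len(nrow(nodes))) {
      if (is.na(nodes$parent[i])) next
      child_mk <- nodes$markers[[i]][1]
      parent_mk <- nodes$markers[[match(nodes$parent[i], nodes$name)]][1]
      expect_true(all(gt$sample_id[gt[[child_mk]] == "D"] %in%
                        gt$sample_id[gt[[parent_mk]] == "D"]))
    }
    # carrier counts match the placement manifest
    pl <- attr(gt, "placement")
    for (mk in names(pl)) {
      expect_identical(sum(gt[[mk]] == "D"), pl[[mk]]$n_carriers)
    }
    # classification inverts placement with zero conflicts
    cls <- classify_haplogroup(gt, tree)
    expect_identical(sum(cls$n_conflicts), 0L)
    depth <- vapply(nodes$name, function(nd) {
      length(ylineage:::tree_path_to_root(tree, nd))
    }, integer(1))
    for (i in seq_len(nrow(gt))) {
      der_nodes <- nodes$name[vapply(seq_len(nrow(nodes)), function(j) {
        all(vapply(nodes$markers[[j]],
                   function(mk) gt[[mk]][i] == "D", logical(1)))
      }, logical(1))]
      expected <- der_nodes[which.max(depth[der_nodes])]
      expect_identical(cls$haplogroup[i], expected)
    }
  }
})

test_that("pinned SNP placements are honoured and still validated for nesting", {
  mod <- str_model()
  tree <- qm3_tree()
  spec <- genealogy_spec("two_level_hierarchy", n_samples = 20,
                         age_generations = 300,
                         group_sizes = list(g1 = c(p1 = 5, p2 = 5),
                                            g2 = c(p3 = 5, p4 = 5)),
                         divergence_generations = c(200, 60), seed = 31)
  pr <- simulate_structured_populations(spec, mod)
  spine <- c("Q-M242", "Q-L56", "Q-M346", "Q-L54", "Q-M3", "Q-M848")
  pins <- c(setNames(rep("root", length(spine)), spine),
            "Q-CO24/CO27" = "g1")
  gt <- place_snps_on_genealogy(pr, tree, seed = 31, fixed_branches = pins)
  for (mk in c("M242", "L56", "M346", "L54", "M3", "M848")) {
    expect_true(all(gt[[mk]] == "D"))
  }
  expect_identical(sort(gt$sample_id[gt$CO24 == "D"]),
                   sort(pr$sample_id[pr$group == "g1"]))
  # sibling of a spine node pinned to the root has nowhere disjoint to go
  expect_true(all(gt$Z780 == "A"))
  # and classification still sees zero conflicts
  cls <- classify_haplogroup(gt, tree)
  expect_identical(sum(cls$n_conflicts), 0L)

  # invalid pins are refused
  expect_error(
    place_snps_on_genealogy(pr, tree, seed = 1,
                            fixed_branches = c("Q-L56" = "nope")),
    "not a genealogy branch")
  expect_error(
    place_snps_on_genealogy(pr, tree, seed = 1,
                            fixed_branches = c("Q-M242" = "root",
                                               "Q-L56" = "g1",
                                               "Q-M346" = "g2")),
    "does not descend")
})

test_that("discovery fixtures plant survivors exactly as their manifest promises", {
  # all clean transversions survive
  fx <- simulate_discovery_input(10, seed = 3)
  out <- filter_candidate_snps(fx$variants, fx$known, fx$mask)
  expect_identical(sort(out$kept$id), sort(fx$manifest$id))

  # pure transitions never survive
  fx2 <- simulate_discovery_input(10, fraction_transition = 1, seed = 3)
  out2 <- filter_candidate_snps(fx2$variants, fx2$known, fx2$mask)
  expect_identical(nrow(out2$kept), 0L)

  # mixed plant: survivor set equals the manifest
  for (s in 1:3) {
    fx3 <- simulate_discovery_input(40, fraction_known = 0.2,
                                    fraction_in_repeat = 0.15,
                                    fraction_near_other = 0.15,
                                    fraction_transition = 0.2, seed = s)
    out3 <- filter_candidate_snps(fx3$variants, fx3$known, fx3$mask)
    expect_identical(sort(out3$kept$id),
                     sort(fx3$manifest$id[fx3$manifest$expect_kept]))
  }

  # contradictory plants are refused
  expect_error(simulate_discovery_input(10, fraction_known = 0.7,
                                        fraction_transition = 0.7),
               "overlap")
})
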