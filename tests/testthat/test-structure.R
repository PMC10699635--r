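toy12 <- function() {
  # 2 groups x 2 populations x 3 samples, fixed alleles
  m <- rbind(
    c(14L, 10L), c(14L, 11L), c(15L, 10L),   # p1
    c(14L, 10L), c(13L, 10L), c(14L, 10L),   # p2
    c(18L, 14L), c(18L, 15L), c(19L, 14L),   # p3
    c(18L, 14L), c(17L, 14L), c(18L, 13L))   # p4
  colnames(m) <- c("L1", "L2")
  make_profiles(m,
                population = rep(c("p1", "p2", "p3", "p4"), each = 3),
                group = rep(c("g1", "g2"), each = 6))
}

test_that("AMOVA components equal the brute-force quadratic-form oracle", {
  pr <- toy12()
  pop <- pr$population; grp <- pr$group
  for (metric in c("pairwise_difference", "sum_squared_size_difference")) {
    res <- amova_two_level(pr, metric = metric, n_permutations = 0)
    D <- ylineage:::str_squared_distance(pr, metric)
    oracle <- naive_amova_ssd(D, pop, grp)
    tab <- res$table
    expect_equal(tab$sum_of_squares[3], oracle$within_pop)
    expect_equal(tab$sum_of_squares[2], oracle$within_grp - oracle$within_pop)
    expect_equal(tab$sum_of_squares[1], oracle$total - oracle$within_grp)
    expect_equal(tab$sum_of_squares[4], oracle$total)
    # balanced-design closed forms for the variance components
    N <- 12; P <- 4; G <- 2; n <- 3; npg <- 2
    Vc <- oracle$within_pop / (N - P)
    MS_AP <- (oracle$within_grp - oracle$within_pop) / (P - G)
    Vb <- (MS_AP - Vc) / n
    MS_AG <- (oracle$total - oracle$within_grp) / (G - 1)
    Va <- (MS_AG - Vc - n * Vb) / (n * npg)
    expect_equal(tab$variance[1:3], c(Va, Vb, Vc))
    expect_equal(tab$df[1:3], c(G - 1, P - G, N - P))
    expect_equal(sum(tab$df[1:3]), N - 1)
  }
})

test_that("for the squared-size metric the SSDs reduce to per-locus ANOVA sums of squares", {
  pr <- toy12()
  res <- amova_two_level(pr, metric = "sum_squared_size_difference",
                         n_permutations = 0)
  m <- cbind(pr$L1, pr$L2)
  ss_within <- function(f) {
    sum(apply(m, 2L, function(x) {
      sum(unlist(lapply(split(x, f), function(v) sum((v - mean(v))^2))))
    }))
  }
  expect_equal(res$table$sum_of_squares[3], ss_within(pr$population))
  expect_equal(res$table$sum_of_squares[4],
               sum(apply(m, 2L, function(x) sum((x - mean(x))^2))))
})

test_that("degenerate and limit AMOVA cases behave as designed", {
  # all haplotypes identical: zero components, flagged degenerate
  m <- matrix(14L, 8, 2, dimnames = list(NULL, c("L1", "L2")))
  pr <- make_profiles(m, population = rep(c("p1", "p2"), each = 4),
                      group = rep(c("g1", "g2"), each = 4))
  res <- amova_two_level(pr, n_permutations = 0)
  expect_true(res$degenerate)
  expect_true(all(res$table$variance == 0))
  expect_true(all(is.na(res$table$percent)))

  # 2 groups x 1 population each, within identical, groups apart
  m2 <- rbind(matrix(10L, 4, 2), matrix(16L, 4, 2))
  colnames(m2) <- c("L1", "L2")
  pr2 <- make_profiles(m2, population = rep(c("p1", "p2"), each = 4),
                       group = rep(c("g1", "g2"), each = 4))
  res2 <- amova_two_level(pr2, n_permutations = 0)
  expect_equal(res2$table$percent[1], 100)

  # single group downgrades to one-level with a warning
  pr3 <- toy12(); pr3$group <- "g1"
  expect_warning(res3 <- amova_two_level(pr3, n_permutations = 0),
                 "one-level")
  expect_true(is.na(res3$table$variance[1]))
  expect_error(amova_two_level(make_profiles(m)), ">= 2 populations")
})

test_that("percent components always total 100 and negatives are preserved", {
  mod <- str_model(loci = sprintf("L%d", 1:8), mu_per_locus_per_gen = 2e-3)
  any_negative <- FALSE
  for (r in 1:25) {
    spec <- genealogy_spec("two_level_hierarchy", n_samples = 24,
                           age_generations = 300,
                           group_sizes = list(g1 = c(p1 = 7, p2 = 5),
                                              g2 = c(p3 = 8, p4 = 4)),
                           divergence_generations = c(200, 10),
                           seed = 600 + r)
    pr <- simulate_structured_populations(spec, mod)
    res <- amova_two_level(pr, n_permutations = 0)
    if (res$degenerate) next
    expect_equal(sum(res$table$percent[1:3]), 100, tolerance = 0.01)
    if (any(res$table$variance[1:3] < 0)) any_negative <- TRUE
  }
  # with near-zero between-population divergence, Vb dips negative in
  # some replicates and must be reported unmodified
  expect_true(any_negative)
})

test_that("making every population its own group collapses to a one-level AMOVA", {
  pr <- toy12()
  own <- setNames(pr$population, pr$population)
  res <- amova_two_level(pr, group_of = own, n_permutations = 0)
  expect_equal(res$table$variance[2], 0)
  expect_equal(sum(res$table$df[1:3]), nrow(pr) - 1)
})

test_that("permutation p-values are uniform under the null", {
  # iid haplotypes, so every Phi_ST label assignment is exchangeable
  set.seed(44)
  n <- 16
  nulls <- 300
  pvals <- numeric(nulls)
  for (b in seq_len(nulls)) {
    m <- matrix(sample(10:16, n * 4, replace = TRUE), nrow = n)
    colnames(m) <- sprintf("L%d", 1:4)
    pr <- make_profiles(m,
                        population = rep(c("p1", "p2", "p3", "p4"), each = 4),
                        group = rep(c("g1", "g2"), each = 8))
    res <- amova_two_level(pr, n_permutations = 99, seed = b)
    pvals[b] <- res$p_values[["Vc"]]
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MCA handles degenerate, anticorrelated and supplementary cases", {
  # all samples identical: zero inertia
  gt0 <- make_genotypes(list(A1 = rep("A", 6), A2 = rep("A", 6)))
  suppressWarnings(res0 <- mca(gt0))
  expect_identical(res0$total_inertia, 0)

  # two perfectly anticorrelated binary markers over balanced blocks:
  # one non-trivial dimension explains everything
  gt <- make_genotypes(list(M1 = rep(c("A", "D"), each = 4),
                            M2 = rep(c("D", "A"), each = 4)))
  res <- mca(gt)
  expect_equal(res$percent_inertia[1], 100, tolerance = 1e-8)
  expect_equal(res$eigenvalues[1], 1, tolerance = 1e-8)
  # eigenvalue sum equals the indicator-matrix total inertia (J/Q - 1 = 1)
  expect_equal(sum(res$eigenvalues), res$total_inertia, tolerance = 1e-10)
  expect_equal(res$total_inertia, 1, tolerance = 1e-10)

  # supplementary labels never influence the active axes
  pops <- rep(c("x", "y"), 4)
  gt$population <- pops
  res_a <- mca(gt, supplementary = "population")
  gt$population <- rev(pops)
  res_b <- mca(gt, supplementary = "population")
  expect_equal(res_a$row_coords, res_b$row_coords)
  expect_equal(res_a$category_coords, res_b$category_coords)
  expect_error(mca(gt, supplementary = "origin"), "not found")

  # constant markers are excluded with a warning
  gt2 <- gt
  gt2$M3 <- "A"
  attr(gt2, "markers") <- c("M1", "M2", "M3")
  expect_warning(mca(gt2), "constant")
})

test_that("MCA agrees with an independent implementation on the leading axis", {
  set.seed(10)
  states <- list(
    M1 = sample(c("A", "D"), 30, replace = TRUE),
    M2 = sample(c("A", "D"), 30, replace = TRUE),
    M3 = sample(c("A", "D"), 30, replace = TRUE))
  # avoid accidental constancy
  states$M1[1:2] <- c("A", "D"); states$M2[1:2] <- c("A", "D")
  states$M3[1:2] <- c("A", "D")
  gt <- make_genotypes(states)
  res <- mca(gt)
  df <- data.frame(lapply(states, factor))
  ref <- MASS::mca(df, nf = 2)
  r <- stats::cor(res$row_coords[, 1], ref$rs[, 1])
  expect_gt(abs(r), 0.999)
})
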