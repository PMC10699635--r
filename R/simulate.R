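# Synthetic-data generators. These produce genealogies, STR haplotypes, SNP
# genotype tables and discovery-stage variant fixtures with the statistical
# structure the downstream analyses assume: star or two-level structured
# male genealogies, Y-STR loci evolving under the symmetric single-step
# stepwise mutation model, and biallelic SNPs placed once on genealogy
# branches (infinite sites), perfectly nested like a haplogroup hierarchy.

# Net repeat-count displacement after a branch of length t generations:
# Poisson(mu*t) mutation events, each +/-1 with probability 1/2.
rdisp <- function(n, lambda) {
  k <- stats::rpois(n, lambda)
  as.integer(2L * stats::rbinom(n, k, 0.5) - k)
}

new_str_profiles <- function(df, loci, excluded = ystr_excluded_default(),
                             genealogy = NULL) {
  rownames(df) <- NULL
  structure(df,
            loci = loci,
            excluded_loci = intersect(excluded, loci),
            genealogy = genealogy,
            class = c("str_profiles", "data.frame"))
}

#' Locus names of an STR profile table
#' @param profiles an `str_profiles` data frame.
#' @return character vector of locus column names.
#' @export
str_loci <- function(profiles) {
  attr(profiles, "loci") %||%
    setdiff(names(profiles), c("sample_id", "population", "group"))
}

#' Excluded loci of an STR profile table
#' @param profiles an `str_profiles` data frame.
#' @return character vector (possibly empty).
#' @export
str_excluded <- function(profiles) {
  attr(profiles, "excluded_loci") %||% character(0)
}

allele_matrix <- function(profiles, loci = NULL) {
  loci <- loci %||% setdiff(str_loci(profiles), str_excluded(profiles))
  m <- as.matrix(as.data.frame(profiles)[, loci, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- profiles$sample_id
  m
}

#' Simulate a star genealogy of Y-STR haplotypes
#'
#' All `n_samples` lineages descend independently from a single founder
#' living `age_generations` ago. Each locus accumulates a
#' Poisson(mu * T) number of +/-1 repeat steps along each lineage
#' (symmetric single-step stepwise mutation model). Deterministic given
#' `spec$seed`.
#'
#' @param spec a [genealogy_spec()] with `topology = "star"`.
#' @param model an [str_model()].
#' @return an `str_profiles` data frame (columns `sample_id`, `population`,
#'   `group`, one integer column per locus) carrying the genealogy (branch
#'   table + branch membership) as an attribute for downstream SNP placement.
#' @export
simulate_star_genealogy <- function(spec, model) {
  stopifnot(inherits(spec, "genealogy_spec"), inherits(model, "str_model"))
  if (spec$topology != "star") stop("`spec$topology` must be 'star'")
  n <- spec$n_samples
  L <- length(model$loci)
  lambda <- model$mu_per_locus_per_gen * spec$age_generations

  set.seed(spec$seed)
  disp <- matrix(rdisp(n * L, lambda), nrow = n, ncol = L)
  alleles <- sweep(disp, 2L, model$ancestral_alleles, `+`)
  alleles[alleles < 1L] <- 1L  # repeat counts are bounded below by 1

  ids <- sprintf("S%04d", seq_len(n))
  df <- data.frame(sample_id = ids, population = "pop1", group = "group1",
                   stringsAsFactors = FALSE)
  df[model$loci] <- as.data.frame(alleles)

  branches <- data.frame(
    branch_id = c("root", ids),
    parent = c(NA_character_, rep("root", n)),
    stringsAsFactors = FALSE
  )
  membership <- c(list(root = ids), stats::setNames(as.list(ids), ids))
  new_str_profiles(df, model$loci,
                   genealogy = list(branches = branches,
                                    membership = membership))
}

#' Simulate two-level structured populations of Y-STR haplotypes
#'
#' Populations are nested in groups. Shared drift is accumulated along a
#' group-ancestor branch of length `divergence_generations[1]`, then a
#' population-ancestor branch of length `divergence_generations[2]`, and
#' finally each sample evolves independently for the residual
#' `age_generations - sum(divergence_generations)` generations (a star
#' within each population). Setting both divergence times to zero makes all
#' haplotypes exchangeable; a larger among-group than among-population time
#' makes the among-group variance component dominate.
#'
#' @inheritParams simulate_star_genealogy
#' @return an `str_profiles` data frame with population and group labels and
#'   the genealogy attached as an attribute.
#' @export
simulate_structured_populations <- function(spec, model) {
  stopifnot(inherits(spec, "genealogy_spec"), inherits(model, "str_model"))
  if (spec$topology != "two_level_hierarchy") {
    stop("`spec$topology` must be 'two_level_hierarchy'")
  }
  L <- length(model$loci)
  mu <- model$mu_per_locus_per_gen
  t_g <- spec$divergence_generations[1]
  t_p <- spec$divergence_generations[2]
  t_s <- spec$age_generations - t_g - t_p

  set.seed(spec$seed)
  rows <- list()
  branches <- data.frame(branch_id = "root", parent = NA_character_,
                         stringsAsFactors = FALSE)
  membership <- list(root = character(0))
  idx <- 0L
  for (g in names(spec$group_sizes)) {
    pops <- spec$group_sizes[[g]]
    if (is.null(names(pops))) {
      names(pops) <- sprintf("%s_pop%d", g, seq_along(pops))
    }
    g_disp <- rdisp(L, mu * t_g)
    branches <- rbind(branches, data.frame(branch_id = g, parent = "root",
                                           stringsAsFactors = FALSE))
    membership[[g]] <- character(0)
    for (p in names(pops)) {
      n_p <- pops[[p]]
      if (n_p == 0L) next
      p_disp <- g_disp + rdisp(L, mu * t_p)
      branches <- rbind(branches, data.frame(branch_id = p, parent = g,
                                             stringsAsFactors = FALSE))
      ids <- sprintf("S%04d", idx + seq_len(n_p))
      idx <- idx + n_p
      s_disp <- matrix(rdisp(n_p * L, mu * t_s), nrow = n_p, ncol = L)
      alleles <- sweep(s_disp, 2L, model$ancestral_alleles + p_disp, `+`)
      alleles[alleles < 1L] <- 1L
      df <- data.frame(sample_id = ids, population = p, group = g,
                       stringsAsFactors = FALSE)
      df[model$loci] <- as.data.frame(alleles)
      rows[[length(rows) + 1L]] <- df
      branches <- rbind(branches, data.frame(branch_id = ids, parent = p,
                                             stringsAsFactors = FALSE))
      membership[[p]] <- ids
      membership[[g]] <- c(membership[[g]], ids)
      membership[["root"]] <- c(membership[["root"]], ids)
      for (s in ids) membership[[s]] <- s
    }
  }
  out <- do.call(rbind, rows)
  new_str_profiles(out, model$loci,
                   genealogy = list(branches = branches,
                                    membership = membership))
}

#' Place nested biallelic SNPs on a simulated genealogy
#'
#' Each haplogroup-tree node's markers are assigned to one genealogy branch
#' (infinite-sites: a SNP arises once). The branch chosen for a child node
#' is always a descendant (or the same branch) of its parent's branch, so
#' derived carriers are perfectly nested: derived(child) is a subset of
#' derived(parent). The tree root's markers go on the genealogy root branch,
#' so every sample is derived there.
#'
#' @param genealogy an `str_profiles` object from a simulator (carries the
#'   genealogy attribute), or the genealogy list itself plus `samples`.
#' @param tree a `haplogroup_tree` (see [load_tree()]).
#' @param seed integer seed controlling branch choice.
#' @param fixed_branches optional named character vector pinning tree nodes
#'   to genealogy branches (`c("Q-M242" = "root", ...)`), e.g. to express a
#'   study design in which the spine markers are carried by every sample.
#'   Pinned branches must still descend from the parent node's branch;
#'   unpinned nodes are sampled as usual around them.
#' @return a `snp_genotypes` data frame (columns `sample_id`, `population`,
#'   `group`, one column per marker with states `"A"`/`"D"`), with a
#'   `placement` attribute mapping each marker to its branch and carrier
#'   count.
#' @export
place_snps_on_genealogy <- function(genealogy, tree, seed = 1L,
                                    fixed_branches = NULL) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  gen <- attr(genealogy, "genealogy")
  if (is.null(gen)) stop("`genealogy` must carry a genealogy attribute (use the simulators)")
  samples <- genealogy[, c("sample_id", "population", "group")]
  branches <- gen$branches
  membership <- gen$membership

  children_of <- split(branches$branch_id, branches$parent)
  descendants <- function(b) {
    out <- character(0)
    queue <- children_of[[b]] %||% character(0)
    while (length(queue)) {
      out <- c(out, queue)
      queue <- unlist(lapply(queue, function(x) children_of[[x]] %||% character(0)))
    }
    out
  }
  branch_path <- function(b) {
    path <- b
    repeat {
      p <- branches$parent[match(path[1], branches$branch_id)]
      if (is.na(p)) break
      path <- c(p, path)
    }
    path
  }
  overlaps <- function(a, b) a %in% branch_path(b) || b %in% branch_path(a)

  set.seed(seed)
  nodes <- tree$nodes
  order_idx <- tree_bfs_order(tree)
  chosen <- stats::setNames(rep(NA_character_, nrow(nodes)), nodes$name)
  for (i in order_idx) {
    nd <- nodes$name[i]
    if (is.na(nodes$parent[i])) {
      chosen[nd] <- if (!is.null(fixed_branches) && nd %in% names(fixed_branches)) {
        fixed_branches[[nd]]
      } else {
        branches$branch_id[is.na(branches$parent)][1]
      }
      next
    }
    pb <- chosen[[nodes$parent[i]]]
    if (is.na(pb)) next  # parent clade empty: this clade is empty too
    if (!is.null(fixed_branches) && nd %in% names(fixed_branches)) {
      fb <- fixed_branches[[nd]]
      if (!fb %in% branches$branch_id) {
        stop(sprintf("fixed branch '%s' for node '%s' is not a genealogy branch",
                     fb, nd))
      }
      if (!pb %in% branch_path(fb)) {
        stop(sprintf("fixed branch '%s' for node '%s' does not descend from its parent's branch '%s'",
                     fb, nd, pb))
      }
      chosen[nd] <- fb
      next
    }
    # sibling haplogroups are disjoint clades: exclude branches on the
    # same root-path as a branch already given (or pinned) to a sibling
    sib <- setdiff(nodes$name[!is.na(nodes$parent) &
                                nodes$parent == nodes$parent[i]], nd)
    taken <- stats::na.omit(c(chosen[sib], fixed_branches[intersect(
      sib, names(fixed_branches))]))
    cand <- c(descendants(pb), pb)
    cand <- cand[vapply(cand, function(b) {
      length(membership[[b]]) > 0 &&
        !any(vapply(taken, overlaps, logical(1), b = b))
    }, logical(1))]
    if (!length(cand)) {
      chosen[nd] <- NA_character_
      next
    }
    # choose branches with probability proportional to clade size, so
    # markers get realistic carrier frequencies instead of collapsing
    # onto single-sample leaf branches
    sizes <- vapply(cand, function(b) length(membership[[b]]), numeric(1))
    chosen[nd] <- cand[sample.int(length(cand), 1L, prob = sizes)]
  }

  gt <- samples
  placement <- list()
  for (i in seq_len(nrow(nodes))) {
    br <- chosen[[nodes$name[i]]]
    carriers <- if (is.na(br)) character(0) else membership[[br]]
    state <- ifelse(samples$sample_id %in% carriers, "D", "A")
    for (mk in nodes$markers[[i]]) {
      gt[[mk]] <- state
      placement[[mk]] <- list(node = nodes$name[i],
                              branch = br,
                              n_carriers = length(carriers))
    }
  }
  structure(gt,
            markers = setdiff(names(gt), c("sample_id", "population", "group")),
            placement = placement,
            class = c("snp_genotypes", "data.frame"))
}

#' Simulate a candidate-variant discovery fixture
#'
#' Plants `n_variants` variants on chrY with known planted fates: a fraction
#' present in the known-variant catalog, a fraction inside a repeat-masked
#' interval, a fraction with a neighbouring indel within the proximity
#' window, a fraction that are transitions, and the remainder clean
#' transversion SNVs expected to survive [filter_candidate_snps()]. Planted
#' variants are spaced far apart (10 kb) so the categories cannot interact;
#' a companion indel is placed 500 nt from each "near" variant.
#'
#' @param n_variants number of primary planted variants.
#' @param fraction_known,fraction_in_repeat,fraction_near_other,fraction_transition
#'   fractions in `[0, 1]`; their sum must not exceed 1 (contradictory
#'   plants are refused).
#' @param seed integer seed.
#' @return a list with elements `variants` (data frame: chrom, pos, id, ref,
#'   alt, vtype), `known` (data frame: chrom, pos), `mask` (data frame:
#'   chrom, start, end; 0-based half-open), and `manifest` (data frame: id,
#'   category, expect_kept).
#' @export
simulate_discovery_input <- function(n_variants,
                                     fraction_known = 0,
                                     fraction_in_repeat = 0,
                                     fraction_near_other = 0,
                                     fraction_transition = 0,
                                     seed = 1L) {
  fr <- c(known = fraction_known, repeat_region = fraction_in_repeat,
          near_other = fraction_near_other, transition = fraction_transition)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  counts <- round(fr * n_variants)
  if (sum(counts) > n_variants) {
    stop("planted fractions overlap: they must sum to at most 1")
  }
  category <- c(rep(names(counts), counts),
                rep("clean", n_variants - sum(counts)))
  set.seed(seed)
  category <- sample(category)

  pos <- 100000L + 10000L * (seq_len(n_variants) - 1L)
  transversion_alt <- c(A = "C", C = "A", G = "T", T = "G")
  transition_alt <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
  alt <- ifelse(category == "transition",
                transition_alt[ref], transversion_alt[ref])
  variants <- data.frame(
    chrom = "chrY", pos = pos,
    id = sprintf("VAR%04d", seq_len(n_variants)),
    ref = ref, alt = unname(alt), vtype = "snv",
    stringsAsFactors = FALSE
  )

  near <- which(category == "near_other")
  if (length(near)) {
    companions <- data.frame(
      chrom = "chrY", pos = pos[near] + 500L,
      id = sprintf("IND%04d", seq_along(near)),
      ref = "AT", alt = "A", vtype = "indel",
      stringsAsFactors = FALSE
    )
    variants <- rbind(variants, companions)
  }
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  known_pos <- pos[category == "known"]
  known <- data.frame(chrom = rep("chrY", length(known_pos)),
                      pos = known_pos)
  rep_pos <- pos[category == "repeat_region"]
  mask <- data.frame(chrom = rep("chrY", length(rep_pos)),
                     start = rep_pos - 1L, end = rep_pos + 9L)
  manifest <- data.frame(
    id = sprintf("VAR%04d", seq_len(n_variants)),
    category = category,
    expect_kept = category == "clean",
    stringsAsFactors = FALSE
  )
  list(variants = variants, known = known, mask = mask, manifest = manifest)
}
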