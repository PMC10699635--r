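# Shared fixtures and independent oracles.

# Build an str_profiles object from an allele matrix.
make_profiles <- function(m, loci = colnames(m),
                          population = rep("pop1", nrow(m)),
                          group = rep("group1", nrow(m))) {
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(m)))
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(m))),
                   population = population, group = group,
                   stringsAsFactors = FALSE)
  df[loci] <- as.data.frame(m)
  structure(df, loci = loci, excluded_loci = character(0),
            class = c("str_profiles", "data.frame"))
}

weighted_l1 <- function(x, y, w) sum(w * abs(x - y))

# Exhaustive minimum spanning tree weight via Prufer-sequence enumeration
# (all n^(n-2) labelled trees; keep n <= 6).
brute_min_spanning_weight <- function(D) {
  n <- nrow(D)
  if (n == 2L) return(D[1, 2])
  prufer_to_edges <- function(seq) {
    n <- length(seq) + 2L
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (k in seq_along(seq)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, seq[k])
      degree[leaf] <- 0L
      degree[seq[k]] <- degree[seq[k]] - 1L
    }
    edges[n - 1L, ] <- which(degree == 1L)
    edges
  }
  grid <- expand.grid(rep(list(seq_len(n)), n - 2L))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    ed <- prufer_to_edges(as.integer(grid[r, ]))
    w <- sum(D[ed])
    if (w < best) best <- w
  }
  best
}

# Naive double-loop AMOVA sums of squares from a squared-distance matrix.
naive_amova_ssd <- function(D, pop, grp) {
  N <- nrow(D)
  within_sum <- function(f) {
    tot <- 0
    for (lv in unique(f)) {
      ix <- which(f == lv)
      s <- 0
      for (i in ix) for (j in ix) s <- s + D[i, j]
      tot <- tot + s / (2 * length(ix))
    }
    tot
  }
  all_sum <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) all_sum <- all_sum + D[i, j]
  list(total = all_sum / (2 * N),
       within_pop = within_sum(pop),
       within_grp = within_sum(grp))
}

# Deterministic toy genotype table builder: states per marker per sample.
make_genotypes <- function(states_by_marker, sample_ids = NULL,
                           population = NULL, group = NULL) {
  n <- length(states_by_marker[[1]])
  df <- data.frame(
    sample_id = sample_ids %||% sprintf("S%03d", seq_len(n)),
    population = population %||% rep("pop1", n),
    group = group %||% rep("group1", n),
    stringsAsFactors = FALSE)
  for (mk in names(states_by_marker)) df[[mk]] <- states_by_marker[[mk]]
  structure(df, markers = names(states_by_marker),
            class = c("snp_genotypes", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
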