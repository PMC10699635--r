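# Weighted median-joining networks over Y-STR haplotypes.
#
# Distances are weighted L1 on repeat counts (single-step model): each
# edge's length is the weighted number of single-repeat mutational steps.
# The algorithm follows the classic median-joining construction: collapse
# identical haplotypes, compute the minimum-spanning network (the union of
# all minimum spanning trees, relaxed by a tolerance epsilon), add
# quasi-median (coordinate-wise median) vectors of feasible triplets, and
# iterate until stable, finally deleting obsolete median vectors.

#' Inverse-variance locus weights for network construction
#'
#' Assigns each microsatellite an integer weight inversely proportional to
#' its allele variance across the profiles, scaled so the most variable
#' locus gets `w_min` and clamped to `[1, 99]` (the convention of network
#' software weight fields). Loci with zero variance get the maximum weight.
#' `scheme = "uniform"` gives every locus weight 1.
#'
#' @param profiles an `str_profiles` data frame.
#' @param scheme `"inverse_variance"` (default) or `"uniform"`.
#' @param w_min weight of the most variable locus (default 1).
#' @return named integer vector of weights over retained loci.
#' @export
compute_str_weights <- function(profiles,
                                scheme = c("inverse_variance", "uniform"),
                                w_min = 1) {
  scheme <- match.arg(scheme)
  if (is.null(profiles) || nrow(profiles) == 0L) {
    stop("cannot compute weights from an empty profile set")
  }
  m <- allele_matrix(profiles)
  if (scheme == "uniform") {
    return(stats::setNames(rep(1L, ncol(m)), colnames(m)))
  }
  v <- apply(m, 2L, stats::var)
  if (nrow(m) < 2L || all(v == 0)) {
    return(stats::setNames(rep(99L, ncol(m)), colnames(m)))
  }
  vmax <- max(v)
  w <- ifelse(v == 0, 99, round(w_min * vmax / v))
  w <- pmin(pmax(w, 1L), 99L)
  stats::setNames(as.integer(w), colnames(m))
}

weighted_l1_dist <- function(m, w) {
  as.matrix(stats::dist(sweep(m, 2L, w, `*`), method = "manhattan"))
}

# Deterministic Prim MST on a full distance matrix. Ties break to the
# smallest (i, j) pair, so callers wanting lexicographic determinism sort
# their rows beforehand. Returns edges (i, j, d) and the total length.
prim_mst <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(list(edges = data.frame(i = integer(0), j = integer(0),
                                              d = numeric(0)), length = 0))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best_d <- D[1L, ]
  best_from <- rep(1L, n)
  edges <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[order(best_d[cand], best_from[cand], cand)][1]
    i <- best_from[j]
    edges[[k]] <- c(min(i, j), max(i, j), D[i, j])
    in_tree[j] <- TRUE
    upd <- !in_tree & D[j, ] < best_d
    best_d[upd] <- D[j, upd]
    best_from[upd] <- j
  }
  em <- do.call(rbind, edges)
  list(edges = data.frame(i = em[, 1], j = em[, 2], d = em[, 3]),
       length = sum(em[, 3]))
}

# Minimax connection distance between all pairs, from an MST: the largest
# edge on the unique tree path. O(n^2) via one DFS per source.
minimax_from_mst <- function(mst_edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(mst_edges))) {
    i <- mst_edges$i[r]; j <- mst_edges$j[r]; d <- mst_edges$d[r]
    adj[[i]] <- rbind(adj[[i]], c(j, d))
    adj[[j]] <- rbind(adj[[j]], c(i, d))
  }
  mm <- matrix(0, n, n)
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n); visited[s] <- TRUE
    stack <- list(c(s, 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      u <- top[1]; dmax <- top[2]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        vtx <- nb[r, 1]
        if (visited[vtx]) next
        visited[vtx] <- TRUE
        d2 <- max(dmax, nb[r, 2])
        mm[s, vtx] <- d2
        stack[[length(stack) + 1L]] <- c(vtx, d2)
      }
    }
  }
  mm
}

#' Minimum spanning network of haplotype vectors
#'
#' An edge (u, v) belongs to the network iff its weighted single-step
#' distance does not exceed the minimax connection distance of u and v
#' plus `epsilon`. At `epsilon = 0` this is exactly the union of all
#' minimum spanning trees; larger epsilon only adds edges.
#'
#' @param m integer matrix, one haplotype per row.
#' @param w positive locus weights (one per column).
#' @param epsilon non-negative relaxation tolerance.
#' @return data frame of edges `i`, `j`, `d`.
#' @export
min_spanning_network <- function(m, w, epsilon = 0) {
  n <- nrow(m)
  if (n == 1L) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  D <- weighted_l1_dist(m, w)
  mst <- prim_mst(D)
  mm <- minimax_from_mst(mst$edges, n)
  pairs <- which(upper.tri(D) & D <= mm + epsilon + 1e-9, arr.ind = TRUE)
  data.frame(i = pairs[, 1], j = pairs[, 2],
             d = D[pairs])
}

# coordinate-wise median of three integer vectors
triplet_median <- function(a, b, c) {
  apply(rbind(a, b, c), 2L, function(x) sort(x)[2])
}

#' Build a weighted median-joining network
#'
#' Collapses identical haplotypes into frequency-weighted nodes, computes
#' the minimum spanning network under the weighted single-step distance,
#' iteratively adds quasi-median (coordinate-wise median) vectors of
#' triplets consisting of a network link plus a third node whenever the
#' median shortens the local three-point connection (the cheapest medians,
#' within `epsilon`, are added each round), and finally deletes obsolete
#' median vectors (inferred nodes of degree <= 2 whose removal does not
#' lengthen the minimum spanning tree).
#'
#' @param profiles an `str_profiles` data frame; DYS385a/b are excluded
#'   automatically (with a notice) when present.
#' @param weights named locus weights from [compute_str_weights()];
#'   `NULL` computes inverse-variance weights from the profiles.
#' @param epsilon non-negative tolerance (default 0).
#' @return an `mj_network`: list with `haplotypes` (integer matrix, one row
#'   per node), `kind` (`"observed"`/`"median"`), `frequency`, `members`
#'   (list of sample ids), `populations` (list of tables), `edges`
#'   (data frame `i`, `j`, `d`, `steps`, `loci`), `weights`, `graph`
#'   (an igraph object).
#' @export
build_mj_network <- function(profiles, weights = NULL, epsilon = 0) {
  if (is.null(profiles) || nrow(profiles) == 0L) stop("no profiles")
  if (epsilon < 0) stop("`epsilon` must be >= 0")
  excl <- intersect(ystr_excluded_default(), str_loci(profiles))
  if (length(excl) && !all(excl %in% str_excluded(profiles))) {
    message(sprintf("excluding duplicated loci from the network: %s",
                    paste(excl, collapse = ", ")))
  }
  loci <- setdiff(str_loci(profiles), union(str_excluded(profiles), excl))
  m_all <- as.matrix(as.data.frame(profiles)[, loci, drop = FALSE])
  if (any(m_all != round(m_all)) || anyNA(m_all)) {
    stop("allele repeat counts must be integers")
  }
  storage.mode(m_all) <- "integer"
  if (is.null(weights)) {
    weights <- compute_str_weights(profiles)
  }
  if (!all(loci %in% names(weights))) stop("weights must cover every locus")
  w <- as.numeric(weights[loci])

  # collapse identical haplotypes, lexicographic node order for determinism
  key <- apply(m_all, 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  m <- m_all[uniq, , drop = FALSE]
  ord <- do.call(order, as.data.frame(m))
  m <- m[ord, , drop = FALSE]
  ukey <- apply(m, 1L, paste, collapse = ",")
  grp <- match(key, ukey)
  members <- split(profiles$sample_id, grp)
  pops <- split(profiles$population, grp)
  freq <- as.integer(lengths(members))

  kind <- rep("observed", nrow(m))
  n_obs <- nrow(m)

  max_rounds <- 100L
  for (round_i in seq_len(max_rounds)) {
    msn <- min_spanning_network(m, w, epsilon)
    if (!nrow(msn)) break
    # candidate quasi-medians: link (u, v) plus any third node t
    cand_key <- character(0)
    cand_vec <- list()
    cand_cost <- numeric(0)
    existing <- apply(m, 1L, paste, collapse = ",")
    D <- weighted_l1_dist(m, w)
    for (e in seq_len(nrow(msn))) {
      u <- msn$i[e]; v <- msn$j[e]
      for (t in seq_len(nrow(m))) {
        if (t == u || t == v) next
        med <- triplet_median(m[u, ], m[v, ], m[t, ])
        mk <- paste(med, collapse = ",")
        if (mk %in% existing || mk %in% cand_key) next
        cost <- sum(w * abs(med - m[u, ])) + sum(w * abs(med - m[v, ])) +
          sum(w * abs(med - m[t, ]))
        # only medians that shorten the local three-point connection
        trip <- c(D[u, v], D[u, t], D[v, t])
        mst3 <- sum(trip) - max(trip)
        if (cost >= mst3) next
        cand_key <- c(cand_key, mk)
        cand_vec[[length(cand_vec) + 1L]] <- med
        cand_cost <- c(cand_cost, cost)
      }
    }
    if (!length(cand_cost)) break
    lambda <- min(cand_cost)
    add <- which(cand_cost <= lambda + epsilon + 1e-9)
    m <- rbind(m, do.call(rbind, cand_vec[add]))
    kind <- c(kind, rep("median", length(add)))
    if (round_i == max_rounds) {
      warning("median addition did not stabilise; network may be incomplete")
    }
  }

  # obsolete median deletion
  repeat {
    msn <- min_spanning_network(m, w, epsilon)
    deg <- tabulate(c(msn$i, msn$j), nbins = nrow(m))
    cand <- which(kind == "median" & deg <= 2L)
    if (!length(cand)) break
    L_with <- prim_mst(weighted_l1_dist(m, w))$length
    dropped <- FALSE
    for (x in cand) {
      keep <- setdiff(seq_len(nrow(m)), x)
      if (length(keep) < 1L) next
      L_without <- prim_mst(weighted_l1_dist(m[keep, , drop = FALSE], w))$length
      if (L_without <= L_with + 1e-9) {
        m <- m[keep, , drop = FALSE]
        kind <- kind[keep]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  msn <- min_spanning_network(m, w, epsilon)
  # per-edge locus step labels and unweighted step counts
  loci_lab <- character(nrow(msn))
  steps <- integer(nrow(msn))
  for (e in seq_len(nrow(msn))) {
    diffv <- abs(m[msn$i[e], ] - m[msn$j[e], ])
    hit <- which(diffv > 0)
    loci_lab[e] <- paste(sprintf("%s:%d", loci[hit], diffv[hit]),
                         collapse = ";")
    steps[e] <- sum(diffv)
  }
  msn$steps <- steps
  msn$loci <- loci_lab

  frequency <- integer(nrow(m))
  node_members <- vector("list", nrow(m))
  node_pops <- vector("list", nrow(m))
  frequency[seq_len(n_obs)] <- freq
  node_members[seq_len(n_obs)] <- members
  node_pops[seq_len(n_obs)] <- lapply(pops, table)
  for (x in seq_len(nrow(m))[-seq_len(n_obs)]) {
    node_members[[x]] <- character(0)
    node_pops[[x]] <- table(character(0))
  }

  node_names <- character(nrow(m))
  node_names[kind == "observed"] <- sprintf("H%d", seq_len(sum(kind == "observed")))
  node_names[kind == "median"] <- sprintf("mv%d", seq_len(sum(kind == "median")))

  g <- igraph::make_empty_graph(n = nrow(m), directed = FALSE)
  igraph::V(g)$name <- node_names
  igraph::V(g)$kind <- kind
  igraph::V(g)$frequency <- frequency
  igraph::V(g)$haplotype <- apply(m, 1L, paste, collapse = ",")
  igraph::V(g)$populations <- vapply(node_pops, function(tb) {
    if (!length(tb)) "" else paste(sprintf("%s:%d", names(tb), as.integer(tb)),
                                   collapse = ";")
  }, character(1))
  if (nrow(msn)) {
    g <- igraph::add_edges(g, rbind(msn$i, msn$j))
    igraph::E(g)$weight <- msn$d
    igraph::E(g)$steps <- msn$steps
    igraph::E(g)$loci <- msn$loci
  }

  structure(list(haplotypes = m, kind = kind, frequency = frequency,
                 members = node_members, populations = node_pops,
                 edges = msn, weights = stats::setNames(w, loci),
                 epsilon = epsilon, graph = g),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("median-joining network: %d observed + %d median nodes, %d edges (epsilon=%g)\n",
              sum(x$kind == "observed"), sum(x$kind == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Export a median-joining network
#'
#' Writes GraphML or DOT (via igraph) carrying node kind, frequency,
#' haplotype and population composition plus per-edge locus step labels,
#' or a plain TSV edge list.
#'
#' @param net an `mj_network`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot", "tsv")) {
  format <- match.arg(format)
  if (format %in% c("graphml", "dot")) {
    igraph::write_graph(net$graph, path, format = format)
  } else {
    nm <- igraph::V(net$graph)$name
    ed <- net$edges
    df <- data.frame(from = nm[ed$i], to = nm[ed$j],
                     weighted_length = ed$d, steps = ed$steps,
                     loci = ed$loci, stringsAsFactors = FALSE)
    writeLines(c(provenance_header(list(epsilon = net$epsilon)),
                 paste(names(df), collapse = "\t"),
                 do.call(paste, c(df, sep = "\t"))), path)
  }
  invisible(path)
}
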