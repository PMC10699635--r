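# Haplogroup tree handling and hierarchical classification.
#
# A haplogroup tree is a rooted hierarchy of named nodes, each defined by
# one or more phyloequivalent SNP markers. A sample's haplogroup is the
# deepest node on a root-descending path at which it carries the derived
# allele. The package ships an encoding of the Q-M3 subtree (spine
# M242 > L56 > M346 > L54 > M3 > M848 with CO15-CO27 sublineages and
# literature markers) under inst/extdata/qm3_tree.yaml.

new_haplogroup_tree <- function(nodes, root) {
  structure(list(nodes = nodes, root = root), class = "haplogroup_tree")
}

#' Construct a haplogroup tree from a node table
#'
#' @param name character vector of node names.
#' @param markers list of character vectors: the SNP markers defining each
#'   node (phyloequivalent markers share a node).
#' @param parent character vector of parent node names (`NA` for the root).
#' @return a validated `haplogroup_tree`.
#' @export
haplogroup_tree <- function(name, markers, parent) {
  if (!is.list(markers)) markers <- as.list(markers)
  nodes <- data.frame(name = name, parent = parent, stringsAsFactors = FALSE)
  nodes$markers <- lapply(markers, as.character)
  validate_tree(new_haplogroup_tree(nodes, root = name[is.na(parent)][1]))
}

validate_tree <- function(tree) {
  nodes <- tree$nodes
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1L) {
    stop(sprintf("tree must have exactly one root, found %d (%s)",
                 length(roots), paste(roots, collapse = ", ")))
  }
  if (anyDuplicated(nodes$name)) {
    stop(sprintf("duplicate node name: %s",
                 nodes$name[duplicated(nodes$name)][1]))
  }
  all_markers <- unlist(nodes$markers)
  if (anyDuplicated(all_markers)) {
    stop(sprintf("duplicate marker across nodes: %s",
                 all_markers[duplicated(all_markers)][1]))
  }
  missing_parent <- setdiff(stats::na.omit(nodes$parent), nodes$name)
  if (length(missing_parent)) {
    stop(sprintf("parent '%s' is not a node", missing_parent[1]))
  }
  # reachability from root doubles as the cycle check
  reached <- tree$root
  repeat {
    nxt <- nodes$name[!is.na(nodes$parent) & nodes$parent %in% reached]
    nxt <- setdiff(nxt, reached)
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  orphan <- setdiff(nodes$name, reached)
  if (length(orphan)) {
    stop(sprintf("node '%s' unreachable from root (cycle or disconnection)",
                 orphan[1]))
  }
  tree$root <- roots
  tree
}

# node indices in breadth-first (root-down) order
tree_bfs_order <- function(tree) {
  nodes <- tree$nodes
  ord <- integer(0)
  queue <- which(is.na(nodes$parent))
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    queue <- c(queue, which(!is.na(nodes$parent) &
                              nodes$parent == nodes$name[i]))
  }
  ord
}

tree_path_to_root <- function(tree, node) {
  nodes <- tree$nodes
  path <- node
  while (!is.na(nodes$parent[match(path[1], nodes$name)])) {
    path <- c(nodes$parent[match(path[1], nodes$name)], path)
  }
  path
}

#' Load a haplogroup tree from a YAML or JSON file
#'
#' The file holds a list of node records, each with `name`, `markers`
#' (string or list) and `parent` (absent/null for the root). A packaged
#' Q-M3 tree is available via
#' `system.file("extdata", "qm3_tree.yaml", package = "ylineage")`.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return a validated `haplogroup_tree`.
#' @export
load_tree <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(recs)) stop("tree file contains no nodes")
  haplogroup_tree(
    name = vapply(recs, function(r) r$name, character(1)),
    markers = lapply(recs, function(r) unlist(r$markers)),
    parent = vapply(recs, function(r) r$parent %||% NA_character_, character(1))
  )
}

#' Packaged Q-M3 haplogroup tree
#' @return a `haplogroup_tree`.
#' @export
qm3_tree <- function() {
  load_tree(system.file("extdata", "qm3_tree.yaml", package = "ylineage"))
}

# node genotype status for one sample given its marker states
# states: named character vector, values in {"A", "D", "."}
node_status <- function(states, markers) {
  st <- states[intersect(markers, names(states))]
  st <- st[!is.na(st)]
  typed <- st[st != "."]
  if (!length(typed)) return(list(status = "missing", conflict = FALSE))
  has_d <- any(typed == "D")
  has_a <- any(typed == "A")
  if (has_d && !has_a) return(list(status = "derived", conflict = FALSE))
  if (has_a && !has_d) return(list(status = "ancestral", conflict = FALSE))
  # phyloequivalent markers disagree
  list(status = "ancestral", conflict = TRUE)
}

#' Classify samples onto a haplogroup tree
#'
#' Descends the tree from the root, following nodes at which the sample is
#' derived (any typed defining marker derived, none ancestral). Descent
#' stops at the first ancestral node. A node with all defining markers
#' missing stops descent under `policy = "strict"`; under
#' `policy = "permissive"` descent continues through missing nodes when a
#' deeper derived node exists below them. A sample derived at a node whose
#' root-path contains an explicitly ancestral node is reported as a
#' conflict (a nesting violation). Samples ancestral at the root classify
#' as `"not <root>"`; samples with every marker missing classify as
#' `"unknown"`.
#'
#' @param genotypes a `snp_genotypes` data frame (states `"A"`, `"D"`,
#'   `"."`), e.g. from [place_snps_on_genealogy()] or [read_genotypes()].
#' @param tree a `haplogroup_tree`.
#' @param policy `"strict"` or `"permissive"` missing-data handling.
#' @return a data frame with one row per sample: `sample_id`, `haplogroup`,
#'   `path` (root-to-terminal, `>`-separated), `n_conflicts`,
#'   `missing_on_path`; the per-sample conflict pairs are in the
#'   `conflicts` attribute (data frame sample_id/ancestral_node/derived_node).
#' @export
classify_haplogroup <- function(genotypes, tree,
                                policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  markers <- attr(genotypes, "markers") %||%
    setdiff(names(genotypes), c("sample_id", "population", "group"))
  tree_markers <- unlist(tree$nodes$markers)
  unknown <- setdiff(markers, tree_markers)
  if (length(unknown)) {
    warning(sprintf("ignoring %d marker(s) not in the tree: %s",
                    length(unknown), paste(unknown, collapse = ", ")))
    markers <- setdiff(markers, unknown)
  }
  nodes <- tree$nodes
  children_of <- split(nodes$name, nodes$parent)

  res <- vector("list", nrow(genotypes))
  conflict_rows <- list()
  for (i in seq_len(nrow(genotypes))) {
    states <- vapply(markers, function(m) as.character(genotypes[[m]][i]),
                     character(1))
    names(states) <- markers
    status <- lapply(seq_len(nrow(nodes)), function(j) {
      node_status(states, nodes$markers[[j]])
    })
    names(status) <- nodes$name
    stat_of <- vapply(status, `[[`, character(1), "status")

    if (all(states == "." | is.na(states)) || !length(states)) {
      terminal <- "unknown"; path <- character(0)
    } else {
      # deepest node reachable from the root through derived
      # (or, permissively, missing-with-derived-below) nodes
      has_derived_below <- function(nd) {
        kids <- children_of[[nd]] %||% character(0)
        any(vapply(kids, function(k) {
          stat_of[[k]] == "derived" || has_derived_below(k)
        }, logical(1)))
      }
      descend <- function(nd) {
        kids <- children_of[[nd]] %||% character(0)
        for (k in kids) {
          ok <- stat_of[[k]] == "derived" ||
            (policy == "permissive" && stat_of[[k]] == "missing" &&
               has_derived_below(k))
          if (ok) return(c(k, descend(k)))
        }
        character(0)
      }
      root_ok <- stat_of[[tree$root]] == "derived" ||
        (policy == "permissive" && stat_of[[tree$root]] == "missing" &&
           has_derived_below(tree$root))
      if (!root_ok) {
        terminal <- if (stat_of[[tree$root]] == "ancestral") {
          paste0("not ", tree$root)
        } else "unknown"
        path <- character(0)
      } else {
        path <- c(tree$root, descend(tree$root))
        # report the deepest *derived* node, not a permissively
        # traversed missing one
        der <- path[vapply(path, function(nd) stat_of[[nd]] == "derived",
                           logical(1))]
        terminal <- if (length(der)) der[length(der)] else path[length(path)]
      }
    }

    # nesting violations anywhere in the tree
    for (j in seq_len(nrow(nodes))) {
      nd <- nodes$name[j]
      if (stat_of[[nd]] != "derived") next
      anc <- setdiff(tree_path_to_root(tree, nd), nd)
      bad <- anc[vapply(anc, function(a) stat_of[[a]] == "ancestral",
                        logical(1))]
      for (b in bad) {
        conflict_rows[[length(conflict_rows) + 1L]] <- data.frame(
          sample_id = genotypes$sample_id[i],
          ancestral_node = b, derived_node = nd,
          stringsAsFactors = FALSE)
      }
    }
    equiv_conflicts <- sum(vapply(status, `[[`, logical(1), "conflict"))
    n_conf <- sum(vapply(conflict_rows, function(r) {
      r$sample_id[1] == genotypes$sample_id[i]
    }, logical(1))) + equiv_conflicts

    miss <- if (length(path)) {
      path[vapply(path, function(nd) stat_of[[nd]] == "missing", logical(1))]
    } else character(0)
    res[[i]] <- data.frame(
      sample_id = genotypes$sample_id[i],
      haplogroup = terminal,
      path = paste(path, collapse = ">"),
      n_conflicts = n_conf,
      missing_on_path = paste(miss, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "conflicts") <- if (length(conflict_rows)) {
    do.call(rbind, conflict_rows)
  } else {
    data.frame(sample_id = character(0), ancestral_node = character(0),
               derived_node = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Per-marker derived-carrier frequency table
#'
#' Counts derived carriers and genotyped (non-missing) samples per marker,
#' overall and within each level of a grouping label, with percentages
#' rounded half-up to one decimal (the convention of published frequency
#' tables, e.g. 153 of 231 prints as 66.2).
#'
#' @param genotypes a `snp_genotypes` data frame.
#' @param grouping column name to stratify by (`"population"`, `"group"`),
#'   or `NULL` for totals only.
#' @return a data frame with columns `marker`, `stratum`, `n_derived`,
#'   `n_genotyped`, `percent` (NA when nothing is genotyped).
#' @export
carrier_frequency_table <- function(genotypes, grouping = NULL) {
  markers <- attr(genotypes, "markers") %||%
    setdiff(names(genotypes), c("sample_id", "population", "group"))
  if (!is.null(grouping) && !grouping %in% names(genotypes)) {
    stop(sprintf("grouping label '%s' not found", grouping))
  }
  strata <- if (is.null(grouping)) {
    list(total = rep(TRUE, nrow(genotypes)))
  } else {
    c(list(total = rep(TRUE, nrow(genotypes))),
      lapply(split(seq_len(nrow(genotypes)), genotypes[[grouping]]),
             function(ix) seq_len(nrow(genotypes)) %in% ix))
  }
  rows <- list()
  for (mk in markers) {
    st <- as.character(genotypes[[mk]])
    for (s in names(strata)) {
      sel <- strata[[s]]
      n_der <- sum(st[sel] == "D", na.rm = TRUE)
      n_gen <- sum(st[sel] %in% c("A", "D"), na.rm = TRUE)
      pct <- if (n_gen > 0) round_half_up(100 * n_der / n_gen, 1) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, stratum = s, n_derived = n_der, n_genotyped = n_gen,
        percent = pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
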