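# Population structure: two-level hierarchical AMOVA with permutation
# significance, and multiple correspondence analysis of SNP states.

str_squared_distance <- function(profiles,
                                 metric = c("pairwise_difference",
                                            "sum_squared_size_difference")) {
  metric <- match.arg(metric)
  m <- allele_matrix(profiles)
  if (metric == "pairwise_difference") {
    # number of differing loci
    D <- matrix(0, nrow(m), nrow(m))
    for (l in seq_len(ncol(m))) {
      D <- D + outer(m[, l], m[, l], `!=`)
    }
    D
  } else {
    as.matrix(stats::dist(m))^2
  }
}

# sum over levels of f of (sum of D within the level) / (2 * level size)
ssd_within <- function(D, f) {
  f <- factor(f)
  agg <- rowsum(t(rowsum(D, f)), f)  # levels x levels block sums
  n <- as.numeric(table(f))
  sum(diag(agg) / (2 * n))
}

amova_components <- function(D, pop, grp) {
  pop <- as.character(pop); grp <- as.character(grp)
  N <- nrow(D)
  pops <- unique(pop)
  P <- length(pops)
  G <- length(unique(grp))
  grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], character(1))
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  n_g <- vapply(unique(grp), function(g) sum(grp == g), numeric(1))
  names(n_g) <- unique(grp)

  SSD_total <- sum(D) / (2 * N)
  SSD_WP <- ssd_within(D, pop)
  SSD_WG <- ssd_within(D, grp)
  SSD_AP <- SSD_WG - SSD_WP
  SSD_AG <- SSD_total - SSD_WG

  df_AG <- G - 1
  df_AP <- P - G
  df_WP <- N - P
  Vc <- SSD_WP / df_WP

  sum_np2_by_g <- vapply(unique(grp), function(g) {
    sum(n_p[grp_of_pop == g]^2) / n_g[[g]]
  }, numeric(1))
  if (df_AP > 0) {
    n_coef <- (N - sum(sum_np2_by_g)) / df_AP
    Vb <- (SSD_AP / df_AP - Vc) / n_coef
  } else {
    # every population its own group: the decomposition collapses to
    # one level, with no among-populations-within-groups component
    Vb <- 0
  }

  if (G > 1) {
    nprime <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_AG
    nprime2 <- (N - sum(n_g^2) / N) / df_AG
    Va <- (SSD_AG / df_AG - Vc - nprime * Vb) / nprime2
  } else {
    Va <- NA_real_
  }
  list(SSD = c(among_groups = SSD_AG, among_pops = SSD_AP, within = SSD_WP,
               total = SSD_total),
       df = c(among_groups = df_AG, among_pops = df_AP, within = df_WP),
       Va = Va, Vb = Vb, Vc = Vc)
}

#' Two-level hierarchical AMOVA
#'
#' Partitions the total molecular variance among groups (Va), among
#' populations within groups (Vb), and within populations (Vc), from the
#' matrix of pairwise inter-haplotype distances, using the standard
#' expected-mean-square coefficients for unbalanced designs. Percentages
#' are 100 * component / total; negative components are reported as-is,
#' never truncated. Phi statistics: `Phi_CT = Va/total`,
#' `Phi_SC = Vb/(Vb+Vc)`, `Phi_ST = (Va+Vb)/total`. Significance is
#' assessed by seeded permutation: whole populations among groups for Va,
#' samples among populations within groups for Vb, samples among
#' populations (whole dataset) for Vc/Phi_ST.
#'
#' @param profiles an `str_profiles` data frame with `population` (and
#'   `group`, unless `group_of` is given) labels.
#' @param group_of optional named vector mapping population -> group,
#'   overriding the `group` column.
#' @param metric `"pairwise_difference"` (number of differing loci) or
#'   `"sum_squared_size_difference"` (squared repeat-count differences,
#'   R_ST-like).
#' @param n_permutations permutations for p-values (default 9999; 0 skips).
#' @param seed integer seed for the permutations.
#' @return an `amova_result`: list with `table` (source, df,
#'   sum_of_squares, variance, percent), `phi`, `p_values`,
#'   `n_permutations`, `metric`, `degenerate`.
#' @export
amova_two_level <- function(profiles, group_of = NULL,
                            metric = c("pairwise_difference",
                                       "sum_squared_size_difference"),
                            n_permutations = 9999, seed = 1L) {
  metric <- match.arg(metric)
  pop <- as.character(profiles$population)
  grp <- if (!is.null(group_of)) {
    unname(group_of[pop])
  } else {
    as.character(profiles$group)
  }
  if (anyNA(grp)) stop("every population must be assigned to a group")
  keep <- !is.na(pop)
  if (length(unique(pop)) < 2L) stop("AMOVA needs >= 2 populations")
  single_group <- length(unique(grp)) < 2L
  if (single_group) {
    warning("single group: reporting a one-level AMOVA (Va undefined)")
  }

  D <- str_squared_distance(profiles, metric)
  comp <- amova_components(D, pop, grp)
  total_var <- sum(c(comp$Va, comp$Vb, comp$Vc), na.rm = TRUE)
  degenerate <- isTRUE(all.equal(total_var, 0)) || total_var == 0
  pct <- if (degenerate) rep(NA_real_, 3) else {
    100 * c(comp$Va, comp$Vb, comp$Vc) / total_var
  }
  phi <- if (degenerate) {
    c(Phi_CT = NA_real_, Phi_SC = NA_real_, Phi_ST = NA_real_)
  } else {
    c(Phi_CT = comp$Va / total_var,
      Phi_SC = comp$Vb / (comp$Vb + comp$Vc),
      Phi_ST = sum(c(comp$Va, comp$Vb), na.rm = TRUE) / total_var)
  }

  p_values <- c(Va = NA_real_, Vb = NA_real_, Vc = NA_real_)
  if (n_permutations > 0 && !degenerate) {
    set.seed(seed)
    pops <- unique(pop)
    grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], character(1))
    stat_obs <- c(Va = comp$Va, Vb = comp$Vb,
                  Vc = phi[["Phi_ST"]])
    hits <- c(Va = 0, Vb = 0, Vc = 0)
    for (b in seq_len(n_permutations)) {
      # Va: permute populations among groups
      if (!single_group) {
        g_perm_pop <- sample(grp_of_pop)
        names(g_perm_pop) <- pops
        cA <- amova_components(D, pop, unname(g_perm_pop[pop]))
        if (!is.na(cA$Va) && cA$Va >= stat_obs[["Va"]]) {
          hits[["Va"]] <- hits[["Va"]] + 1
        }
      }
      # Vb: permute samples among populations within groups
      pop_permB <- pop
      for (g in unique(grp)) {
        ix <- which(grp == g)
        pop_permB[ix] <- pop[ix][sample.int(length(ix))]
      }
      cB <- amova_components(D, pop_permB, grp)
      if (cB$Vb >= stat_obs[["Vb"]]) hits[["Vb"]] <- hits[["Vb"]] + 1
      # Vc / Phi_ST: permute samples among populations over the whole set
      perm <- sample.int(length(pop))
      cC <- amova_components(D, pop[perm], grp[perm])
      tvC <- sum(c(cC$Va, cC$Vb, cC$Vc), na.rm = TRUE)
      phiC <- if (tvC == 0) Inf else sum(c(cC$Va, cC$Vb), na.rm = TRUE) / tvC
      if (phiC >= stat_obs[["Vc"]]) hits[["Vc"]] <- hits[["Vc"]] + 1
    }
    p_values <- (hits + 1) / (n_permutations + 1)
    if (single_group) p_values[["Va"]] <- NA_real_
  }

  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(comp$df[["among_groups"]], comp$df[["among_pops"]],
           comp$df[["within"]], sum(comp$df)),
    sum_of_squares = c(comp$SSD[["among_groups"]], comp$SSD[["among_pops"]],
                       comp$SSD[["within"]], comp$SSD[["total"]]),
    variance = c(comp$Va, comp$Vb, comp$Vc, total_var),
    percent = c(pct, if (degenerate) NA_real_ else sum(pct)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, phi = phi, p_values = p_values,
                 n_permutations = n_permutations, metric = metric,
                 degenerate = degenerate),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s, %d permutations)%s\n", x$metric, x$n_permutations,
              if (x$degenerate) " [degenerate: zero total variance]" else ""))
  print(x$table, row.names = FALSE)
  cat("Phi: ", paste(sprintf("%s=%.4f", names(x$phi), x$phi), collapse = "  "),
      "\n")
  invisible(x)
}

#' Multiple correspondence analysis of SNP genotype states
#'
#' Indicator-matrix MCA: builds the 0/1 indicator over
#' (marker x state) categories (missing `"."` becomes its own category),
#' applies correspondence-analysis scaling and extracts the singular value
#' decomposition. Inertia percentages are raw (Benzecri-uncorrected) by
#' default. A supplementary label (e.g. sample origin) is projected onto
#' the axes without influencing them. Constant markers are excluded with a
#' warning.
#'
#' @param snp_table a `snp_genotypes` data frame.
#' @param active_markers markers to use (default: all marker columns).
#' @param supplementary optional column name (e.g. `"population"`) whose
#'   categories are projected as supplementary points.
#' @param n_dims number of dimensions to keep (default 2).
#' @param benzecri if `TRUE`, report Benzecri-corrected inertia percents.
#' @return an `mca_result`: list with `eigenvalues`, `percent_inertia`,
#'   `cumulative_percent`, `total_inertia`, `row_coords`,
#'   `category_coords`, `supplementary_coords`, `n_dims`.
#' @export
mca <- function(snp_table, active_markers = NULL, supplementary = NULL,
                n_dims = 2L, benzecri = FALSE) {
  markers <- active_markers %||% (attr(snp_table, "markers") %||%
    setdiff(names(snp_table), c("sample_id", "population", "group")))
  states <- lapply(markers, function(mk) as.character(snp_table[[mk]]))
  names(states) <- markers
  n_states <- vapply(states, function(s) length(unique(s)), integer(1))
  const <- markers[n_states < 2L]
  if (length(const)) {
    warning(sprintf("excluding constant marker(s): %s",
                    paste(const, collapse = ", ")))
    markers <- setdiff(markers, const)
  }
  if (!length(markers)) {
    # fully constant table: zero inertia, nothing to ordinate
    return(structure(list(
      eigenvalues = numeric(0), percent_inertia = numeric(0),
      cumulative_percent = numeric(0), total_inertia = 0,
      row_coords = matrix(0, nrow(snp_table), 0,
                          dimnames = list(snp_table$sample_id, NULL)),
      category_coords = matrix(0, 0, 0), supplementary_coords = NULL,
      n_dims = 0L), class = "mca_result"))
  }
  if (length(markers) < 2L) stop("MCA needs >= 2 non-constant markers")

  n <- nrow(snp_table)
  blocks <- lapply(markers, function(mk) {
    f <- factor(states[[mk]])
    z <- stats::model.matrix(~ f - 1)
    colnames(z) <- paste(mk, levels(f), sep = "=")
    z
  })
  Z <- do.call(cbind, blocks)

  P <- Z / sum(Z)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1L, sqrt(r), `/`), 2L, sqrt(cc), `/`)
  sv <- svd(S)
  pos <- sv$d > 1e-12
  d <- sv$d[pos]
  eig <- d^2
  total_inertia <- sum(sv$d^2)
  k <- min(n_dims, length(d))

  pct <- if (benzecri) {
    Q <- length(markers)
    lam <- eig[eig > 1 / Q]
    adj <- ((Q / (Q - 1)) * (lam - 1 / Q))^2
    c(100 * adj / sum(adj), rep(0, length(eig) - length(lam)))[seq_along(eig)]
  } else {
    100 * eig / total_inertia
  }

  F_row <- sweep(sv$u[, pos, drop = FALSE] %*% diag(d, length(d)),
                 1L, sqrt(r), `/`)
  G_col <- sweep(sv$v[, pos, drop = FALSE] %*% diag(d, length(d)),
                 1L, sqrt(cc), `/`)
  rownames(F_row) <- snp_table$sample_id
  rownames(G_col) <- colnames(Z)
  colnames(F_row) <- colnames(G_col) <- sprintf("dim%d", seq_along(d))

  supp <- NULL
  if (!is.null(supplementary)) {
    if (!supplementary %in% names(snp_table)) {
      stop(sprintf("supplementary column '%s' not found", supplementary))
    }
    f <- factor(as.character(snp_table[[supplementary]]))
    supp <- do.call(rbind, lapply(levels(f), function(lv) {
      prof <- as.numeric(f == lv)
      prof <- prof / sum(prof)
      colSums(prof * F_row) / d
    }))
    rownames(supp) <- paste(supplementary, levels(f), sep = "=")
    colnames(supp) <- colnames(F_row)
    supp <- supp[, seq_len(k), drop = FALSE]
  }

  structure(list(
    eigenvalues = eig,
    percent_inertia = pct,
    cumulative_percent = cumsum(pct),
    total_inertia = total_inertia,
    row_coords = F_row[, seq_len(k), drop = FALSE],
    category_coords = G_col[, seq_len(k), drop = FALSE],
    supplementary_coords = supp,
    n_dims = k
  ), class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("MCA: total inertia %.4f; dims 1-%d explain %.2f%%\n",
              x$total_inertia, x$n_dims,
              x$cumulative_percent[min(x$n_dims, length(x$cumulative_percent))]))
  invisible(x)
}
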