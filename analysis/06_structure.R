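#!/usr/bin/env Rscript
# Stage 6: population structure.
#
# Two-level hierarchical AMOVA under both grouping designs (two regions:
# Amazon vs Andes+Caribbean; three regions: Amazon / Andes / Caribbean)
# with permutation significance, and a multiple correspondence analysis
# of the SNP states with sample origin projected as a supplementary
# variable.

library(ylineage)

out <- "results"
seed <- 20260106L
pr <- read_str_table(file.path(out, "cohort_str.tsv"))
gt <- read_genotypes(file.path(out, "cohort_genotypes.tsv"))

pops <- unique(pr$population)
grp_three <- setNames(pr$group[match(pops, pr$population)], pops)
grp_two <- ifelse(grp_three == "amazon", "amazon", "other")
names(grp_two) <- pops

for (design in c("two", "three")) {
  gmap <- if (design == "two") grp_two else grp_three
  res <- amova_two_level(pr, group_of = gmap, n_permutations = 999,
                         seed = seed)
  write_tsv_provenance(res$table,
                       file.path(out, sprintf("amova_%s_regions.tsv", design)),
                       params = list(seed = seed, perms = 999,
                                     phi = sprintf("%.5f", res$phi),
                                     p = sprintf("%.4f", res$p_values)))
  cat(sprintf("\nAMOVA, %s-region design:\n", design))
  print(res)
  cat("p-values: ", paste(sprintf("%s=%.4f", names(res$p_values),
                                  res$p_values), collapse = "  "), "\n")
}

mres <- mca(gt, supplementary = "population")
co <- rbind(
  data.frame(point = rownames(mres$category_coords), type = "category",
             mres$category_coords, check.names = FALSE),
  data.frame(point = rownames(mres$supplementary_coords),
             type = "supplementary", mres$supplementary_coords,
             check.names = FALSE))
write_tsv_provenance(co, file.path(out, "mca_coordinates.tsv"),
                     params = list(
                       percent_inertia = sprintf("%.2f",
                                                 mres$percent_inertia[1:2])))
cat(sprintf("\nMCA: dims 1-2 explain %.2f%% of total inertia\n",
            mres$cumulative_percent[min(2, length(mres$cumulative_percent))]))
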