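#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# Emulates a 231-male Y-chromosome sampling design: an Amazonian region
# holding most of the samples, a smaller Andean region, and a small
# Caribbean group, all inside one lineage. Haplotypes carry 17 Y-STR loci
# (DYS385a/b are typed but excluded from distance analyses) evolving under
# the symmetric single-step stepwise mutation model, and SNPs are planted
# on genealogy branches so they nest exactly like the packaged Q-M3 tree.
# Also plants a candidate-variant discovery fixture (VCF + BED mask +
# known catalog) with known expected survivors.

library(ylineage)

seed <- 20260101L
out <- "results"
dir.create(out, showWarnings = FALSE)

model <- str_model(loci = ystr_panel_17())
spec <- genealogy_spec(
  "two_level_hierarchy",
  n_samples = 231,
  age_generations = 550,            # ~13.8 ky at 25 y/gen, the clade depth
  group_sizes = list(
    amazon = c(tucano = 100, kubeo = 50, pisamira = 21),
    andes = c(nasa = 12, pasto = 12, embera = 12),
    caribbean = c(kogui = 12, arhuaco = 12)),
  divergence_generations = c(300, 150),
  seed = seed)

profiles <- simulate_structured_populations(spec, model)

# Study-design facts expressed as pinned placements: the spine markers
# (Q-M242 through Q-M848) are derived in every sample of a Q-M3 cohort,
# and the deepest sublineage clade concentrates in the Amazonian region.
# Sibling branches (Z780/CTS11780, literature Q-M3 sublineages) then get
# null frequency automatically, since no disjoint branch remains.
spine <- c("Q-M242", "Q-L56", "Q-M346", "Q-L54", "Q-M3", "Q-M848")
pins <- c(setNames(rep("root", length(spine)), spine),
          "Q-CO24/CO27" = "amazon")
genotypes <- place_snps_on_genealogy(profiles, qm3_tree(), seed = seed,
                                     fixed_branches = pins)

write_str_table(profiles, file.path(out, "cohort_str.tsv"),
                params = list(seed = seed, n = nrow(profiles)))
write_genotypes(genotypes, file.path(out, "cohort_genotypes.tsv"),
                params = list(seed = seed))

fx <- simulate_discovery_input(40, fraction_known = 0.25,
                               fraction_in_repeat = 0.10,
                               fraction_near_other = 0.15,
                               fraction_transition = 0.25, seed = seed)
write_variants_vcf(fx$variants, file.path(out, "candidates.vcf"))
write_bed_mask(fx$mask, file.path(out, "repeat_mask.bed"))
write_known_catalog(fx$known, file.path(out, "known_catalog.tsv"))
jsonlite::write_json(fx$manifest, file.path(out, "discovery_manifest.json"),
                     dataframe = "rows", auto_unbox = TRUE)

cat(sprintf("cohort: %d samples, %d populations in %d groups\n",
            nrow(profiles), length(unique(profiles$population)),
            length(unique(profiles$group))))
cat(sprintf("planted discovery variants: %d (%d expected to survive)\n",
            nrow(fx$manifest), sum(fx$manifest$expect_kept)))
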