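#!/usr/bin/env Rscript
# Stage 2: candidate Y-SNP discovery filtering.
#
# Applies the five selection rules (SNV, not previously catalogued, not in
# a repeat-masked region, no neighbouring variant inside a 3000-nt field
# of view, transversion) to the planted candidate list and checks the
# survivors against the generator's manifest.

library(ylineage)

out <- "results"
variants <- read_variants(file.path(out, "candidates.vcf"))
mask <- read_bed_mask(file.path(out, "repeat_mask.bed"))
known <- read_known_catalog(file.path(out, "known_catalog.tsv"))

res <- filter_candidate_snps(variants, known, mask, filter_config())
write_variants_vcf(res$kept, file.path(out, "discovery_kept.vcf"))
write_tsv_provenance(res$audit, file.path(out, "discovery_audit.tsv"),
                     params = list(window_nt = 3000))

manifest <- jsonlite::read_json(file.path(out, "discovery_manifest.json"),
                                simplifyVector = TRUE)
agree <- setequal(res$kept$id, manifest$id[manifest$expect_kept])
cat(sprintf("candidates: %d; kept: %d; matches planted manifest: %s\n",
            nrow(variants), nrow(res$kept), agree))
print(table(res$audit$reason))
if (!agree) stop("survivor set disagrees with the planted manifest")
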