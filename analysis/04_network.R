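#!/usr/bin/env Rscript
# Stage 4: weighted median-joining Y-STR haplotype network.
#
# Builds the network over a subsample of the cohort (80 haplotypes keeps
# the quasi-median search comfortably fast while preserving the expansion
# structure), with inverse-variance locus weights and DYS385a/b excluded.

library(ylineage)

out <- "results"
pr <- read_str_table(file.path(out, "cohort_str.tsv"))

set.seed(4L)
keep <- sort(sample.int(nrow(pr), 80))
sub <- pr[keep, ]
attributes(sub)[c("loci", "excluded_loci")] <-
  attributes(pr)[c("loci", "excluded_loci")]
class(sub) <- class(pr)

w <- compute_str_weights(sub)
net <- build_mj_network(sub, weights = w, epsilon = 0)

export_network(net, file.path(out, "network.graphml"), "graphml")
export_network(net, file.path(out, "network_edges.tsv"), "tsv")

cat("locus weights (inverse variance, clamped [1,99]):\n")
print(w)
print(net)
cat(sprintf("haplotype diversity: %d distinct haplotypes among %d samples\n",
            sum(net$kind == "observed"), nrow(sub)))
cat(sprintf("median (inferred) nodes: %d; total weighted length: %.0f\n",
            sum(net$kind == "median"), sum(net$edges$d)))
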