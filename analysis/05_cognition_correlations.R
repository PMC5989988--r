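#!/usr/bin/env Rscript
# Cognition-network correlations: Spearman partial correlations (education
# partialled out) between network indices and the cognitive composites
# (+ motor score for the disease groups), Fisher z transforms, and the
# per-node count matrix of strong (|rho| > 0.5) correlations over the
# significant-node set from step 04.
#
# Reads:  results/cohort/, results/profiles/, results/significant_nodes.txt
# Writes: results/global_correlations.tsv, results/local_correlations.tsv,
#         results/correlation_counts.tsv

suppressPackageStartupMessages(library(streamnet))

cohort <- read.csv("results/cohort/cohort.csv", stringsAsFactors = FALSE)
profiles <- lapply(cohort$subject, function(s)
  read_topology_tsv(file.path("results/profiles", paste0(s, ".tsv"))))
names(profiles) <- cohort$subject
sig_nodes <- readLines("results/significant_nodes.txt")

gcor <- correlate_cohort(profiles, cohort, scope = "global",
                         covariate_name = "education",
                         indices = c("strength", "clustering",
                                     "path_length", "small_worldness"))
write.table(gcor, "results/global_correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("global records flagged |z| > 0.55:")
print(gcor[gcor$strong_z, c("group", "index", "measure", "rho", "z")],
      row.names = FALSE)

node_set <- if (length(sig_nodes)) sig_nodes else NULL
lcor <- suppressWarnings(
  correlate_cohort(profiles, cohort, scope = "local",
                   covariate_name = "education", node_set = node_set))
write.table(lcor, "results/local_correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

counts <- strong_correlation_counts(lcor, threshold = 0.5)
write.table(counts$counts, "results/correlation_counts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
for (g in names(counts$total_evaluated))
  message(sprintf(
    "%s: %d correlations evaluated, %d strong (|rho| > 0.5)",
    g, counts$total_evaluated[[g]],
    sum(counts$counts$n_strong[counts$counts$group == g])))
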