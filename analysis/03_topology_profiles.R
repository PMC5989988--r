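#!/usr/bin/env Rscript
# Per-subject weighted topology: node strength, Zhang-Horvath clustering,
# path strength and small-worldness (20 Erdos-Renyi nulls per subject),
# computed threshold-free from the simulated connectomes of step 02.
#
# Reads:  results/cohort/
# Writes: results/profiles/<id>.tsv, results/global_indices.tsv

suppressPackageStartupMessages(library(streamnet))
seed <- 1L

cohort <- read.csv("results/cohort/cohort.csv", stringsAsFactors = FALSE)
conns <- lapply(cohort$subject, function(s)
  read_connectome_csv(file.path("results/cohort/connectomes",
                                paste0(s, ".csv"))))
names(conns) <- cohort$subject

profiles <- profile_subjects(conns, small_world = TRUE,
                             n_realizations = 20, seed = seed)
dir.create("results/profiles", showWarnings = FALSE)
for (s in names(profiles))
  write_topology_tsv(profiles[[s]],
                     file.path("results/profiles", paste0(s, ".tsv")))

glob <- do.call(rbind, lapply(names(profiles), function(s)
  data.frame(subject = s, t(profiles[[s]]$global))))
glob <- merge(cohort[, c("subject", "group")], glob, by = "subject")
write.table(glob, "results/global_indices.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

agg <- aggregate(glob[, c("density", "strength", "clustering", "path_length",
                          "small_worldness")],
                 by = list(group = glob$group), FUN = mean)
message("group means of the global indices:")
print(format(agg, digits = 3))
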