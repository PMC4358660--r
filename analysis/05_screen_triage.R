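#!/usr/bin/env Rscript
# Triage the duplicate screen: normalize each plate to its negative-control
# median, average replicates, call hits at z < -2.12 against the pooled
# negative controls, then cluster the hits' fingerprints by Jaccard
# distance (average linkage) to expose scaffold families.

library(moanet)

plates <- read_plates("results/fixtures/screen_plates.csv")
hits <- zscore_hits(plates, threshold = -2.12)
cat(sprintf("%d compounds screened; %d hits at z < -2.12 (Z'-separation %.2f)\n",
            nrow(hits), sum(hits$is_hit), attr(hits, "control_separation")))
write_hits(hits, "results/screen_hits.tsv")

fps <- read_fingerprints("results/fixtures/fingerprints.tsv")
cl <- cluster_hits(fps, cut_distance = 0.4)
fam_sizes <- sort(lengths(cl$families), decreasing = TRUE)
cat(sprintf("fingerprints: %d scaffold families (sizes %s), %d singletons\n",
            length(cl$families), paste(fam_sizes, collapse = ", "),
            length(cl$singletons)))

assign_tab <- data.frame(compound_id = names(cl$assignment),
                         cluster = unname(cl$assignment))
write.table(assign_tab, "results/fingerprint_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("tables written to results/\n")
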