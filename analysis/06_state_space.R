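#!/usr/bin/env Rscript
## Neural state-space structure: normalized Mahalanobis distances between
## condition means and average-linkage dendrograms, pooling trials over
## formats (7 exemplar conditions) and split by format (28 conditions).

library(omapop)

rec <- read_recording_set("results/data/main")
cl <- data.table::fread("results/classification_main.csv",
                        colClasses = list(character = "unit_id"))
sel <- cl[main_label == "oma_selective", unit_id]
rec$units <- rec$units[unit_id %in% sel]
rec$spikes <- rec$spikes[unit_id %in% sel]

for (mode in c("format_independent", "format_dependent")) {
  tree <- cluster_exemplars(rec, mode)
  D <- tree$distances
  dd <- data.table::as.data.table(D, keep.rownames = "condition")
  data.table::fwrite(dd, sprintf("results/state_space_distances_%s.csv", mode))
  writeLines(tree$newick, sprintf("results/dendrogram_%s.nwk", mode))
  cat(mode, "leaf order:", paste(tree$leaf_order, collapse = " | "), "\n")
}
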