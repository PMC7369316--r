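#!/usr/bin/env Rscript
## Pseudopopulation decoding: temporal-generalization matrices for OMA
## identity and viewpoint, permutation-null significance masks, and the
## 12 ordered cross-format generalization accuracies.
## Resample/shuffle counts are scaled to desk size (the procedure is the
## standard 50/50 at full scale; see the methods vignette).

library(omapop)

rec <- read_recording_set("results/data/main")
cl <- data.table::fread("results/classification_main.csv",
                        colClasses = list(character = "unit_id"))
sel <- cl[main_label == "oma_selective", unit_id]
rec$units <- rec$units[unit_id %in% sel]
rec$spikes <- rec$spikes[unit_id %in% sel]
cat("decoding from", length(sel), "OMA-selective units\n")

bt <- bin_rates(rec, 0.15, 0.05, c(-0.5, 2.55))
n_runs <- 10; n_shuffles <- 20

for (f in c("exemplar", "viewpoint")) {
  am <- decode_factor(bt, f, n_runs = n_runs, seed = 88)
  dt <- data.table::data.table(train_bin = rep(bt$bin_starts,
                                               length(bt$bin_starts)),
                               test_bin = rep(bt$bin_starts,
                                              each = length(bt$bin_starts)),
                               accuracy = as.vector(am$accuracy))
  data.table::fwrite(dt, sprintf("results/decoding_tg_%s.csv", f))
  pn <- permutation_null(bt, am, f, n_shuffles = n_shuffles, seed = 89)
  diag_dt <- data.table::data.table(bin_start = bt$bin_starts,
                                    accuracy = am$diagonal,
                                    significant = pn$mask)
  data.table::fwrite(diag_dt, sprintf("results/decoding_diagonal_%s.csv", f))
  cat(sprintf("%s decoding: peak %.2f (chance %.2f), onset %s s\n",
              f, max(am$diagonal), am$chance,
              ifelse(is.na(pn$onset_s), "none", pn$onset_s)))
}

## cross-format generalization in the epoch-2 window
bt2 <- bin_rates(rec, 1.2, 1.2, c(0.3, 1.5))
grid <- expand.grid(train = OMA_FORMATS, test = OMA_FORMATS,
                    stringsAsFactors = FALSE)
grid <- grid[grid$train != grid$test, ]
xf <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  a <- cross_format_decode(bt2, grid$train[i], grid$test[i],
                           n_runs = n_runs, seed = 90)
  data.frame(train = grid$train[i], test = grid$test[i],
             accuracy = a$diagonal)
}))
data.table::fwrite(xf, "results/decoding_cross_format.csv")
cat("mean cross-format OMA accuracy:", round(mean(xf$accuracy), 3),
    "(chance 0.143)\n")
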