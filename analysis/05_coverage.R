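#!/usr/bin/env Rscript
# GC-biased expected-coverage profiles: how much sequencing depth the
# GC-rich outlier genes lose relative to background genes under the
# exponential attenuation model.

library(gcscreen)

outliers <- read_fasta("results/data/outliers.fasta")
background <- read_fasta("results/data/background.fasta")

profile_of <- function(records, n) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    simulate_coverage(records[i, ], window = 50, base_depth = 30, beta = 10)
  }))
}
cov_out <- profile_of(outliers, 20)
cov_bg <- profile_of(background, 100)

dir.create("results/coverage", showWarnings = FALSE, recursive = TRUE)
write_coverage(cov_out, "results/coverage/outliers_coverage.tsv",
               comments = "beta=10 base_depth=30 window=50 gc_ref=0.5")
write_coverage(cov_bg, "results/coverage/background_coverage.tsv",
               comments = "beta=10 base_depth=30 window=50 gc_ref=0.5")

message(sprintf("mean expected depth: background %.1fx, outliers %.1fx",
                mean(cov_bg$expected_coverage),
                mean(cov_out$expected_coverage)))
message(sprintf("worst outlier window: %.2fx at GC %.2f",
                min(cov_out$expected_coverage),
                cov_out$window_gc[which.min(cov_out$expected_coverage)]))
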