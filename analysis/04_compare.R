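#!/usr/bin/env Rscript
# Distribution comparisons with the permutation max-ECDF test:
# (a) two same-process "species" groups -- the expected no-difference
#     result for a well-behaved genome's gene set;
# (b) outliers vs background -- the expected strong difference.

library(gcscreen)

a <- simulate_sequence(synthetic_spec(60, 1000, 0.5, 3.2, seed = 20401,
                                      group = "species_a"))
b <- simulate_sequence(synthetic_spec(60, 1000, 0.5, 3.2, seed = 20402,
                                      group = "species_b"))
null_metrics <- composition_metrics(dplyr::bind_rows(a, b))
null_metrics$id <- sprintf("r%03d", seq_len(nrow(null_metrics)))
for (metric in c("gc_fraction", "mean_stretch_len")) {
  run_compare(null_metrics, "species_a", "species_b", metric = metric,
              n_perm = 1000, seed = 20403,
              out_dir = file.path("results/compare", metric))
}

panel_metrics <- read_metrics_table("results/metrics/metrics.tsv")
run_compare(panel_metrics, "background", "outlier",
            metric = "gc_fraction", n_perm = 1000, seed = 20404,
            out_dir = "results/compare/outlier_vs_background")
message("tables under results/compare/")
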