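#!/usr/bin/env Rscript
# Per-gene composition metrics (GC fraction, G/C-stretch statistics) for
# the simulated panel, after the >= 300 nt CDS length filter.

library(gcscreen)

metrics <- run_metrics("results/data/panel.fasta",
                       metadata = "results/data/panel_meta.tsv",
                       out_dir = "results/metrics")

bg <- metrics[metrics$group == "background", ]
out <- metrics[metrics$group == "outlier", ]
message(sprintf("background: GC %.3f +- %.3f, mean stretch %.2f +- %.2f",
                mean(bg$gc_fraction), stats::sd(bg$gc_fraction),
                mean(bg$mean_stretch_len), stats::sd(bg$mean_stretch_len)))
message(sprintf("outliers:   GC %.3f +- %.3f, mean stretch %.2f +- %.2f",
                mean(out$gc_fraction), stats::sd(out$gc_fraction),
                mean(out$mean_stretch_len), stats::sd(out$mean_stretch_len)))
message("table: results/metrics/metrics.tsv")
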