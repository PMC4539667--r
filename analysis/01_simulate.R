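#!/usr/bin/env Rscript
# Generate the synthetic study panel: a RefSeq-like background population
# of moderate-GC CDS-like sequences plus a small set of GC-rich,
# long-stretch outlier genes, written as FASTA + metadata TSV.

library(gcscreen)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

background <- synthetic_spec(n_seqs = 2000, length_nt = 1000,
                             target_gc = 0.50, mean_strong_run = 3.2,
                             seed = 20101)
outliers <- synthetic_spec(n_seqs = 20, length_nt = 1000,
                           target_gc = 0.72, mean_strong_run = 4.5,
                           seed = 20102)
panel <- simulate_panel(background, outliers, n_outliers = 20)

write_fasta(panel[panel$group == "background", ],
            file.path(out, "background.fasta"))
write_fasta(panel[panel$group == "outlier", ],
            file.path(out, "outliers.fasta"))
write_fasta(panel, file.path(out, "panel.fasta"),
            file.path(out, "panel_meta.tsv"))

message(sprintf("panel: %d background + %d outlier sequences of 1 kb",
                sum(panel$group == "background"),
                sum(panel$group == "outlier")))
message("written under ", out)
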