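#!/usr/bin/env Rscript
# G-quadruplex motif density in outlier vs background sequences; hits are
# exported as BED.

library(gcscreen)

outliers <- read_fasta("results/data/outliers.fasta")
background <- read_fasta("results/data/background.fasta")

dir.create("results/quadruplex", showWarnings = FALSE, recursive = TRUE)
hits_out <- scan_quadruplex_set(outliers,
                                "results/quadruplex/outliers_g4.bed")
hits_bg <- scan_quadruplex_set(background,
                               "results/quadruplex/background_g4.bed")

kb_out <- sum(outliers$length) / 1000
kb_bg <- sum(background$length) / 1000
message(sprintf("quadruplex motifs: outliers %.2f /kb, background %.3f /kb",
                nrow(hits_out) / kb_out, nrow(hits_bg) / kb_bg))
message("BED files under results/quadruplex/")
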