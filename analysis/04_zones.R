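#!/usr/bin/env Rscript
# Conserved/variable zone classification of every 10 kb window across the
# granulocyte + CD34+ + AML panel (RED = conserved high, GREEN = conserved
# low, YELLOW = variable), zone genome fractions, and recovery of the
# planted conserved-high block against the simulation truth.

source(file.path("analysis", "00_common.R"))

cfg <- study_config()
pipeline_zones(cfg)
fr <- read.table(file.path(OUT, "zone_fractions.tsv"), header = TRUE)
message(paste(sprintf("%s %.1f%%", fr$zone, fr$pct), collapse = ", "))

genome <- read_chrom_sizes(cfg$chrom_sizes)
truth <- read_truth(file.path(DATA, "truth"), genome)
zones <- read.table(file.path(OUT, "zones.bed"), sep = "\t",
                    col.names = c("chrom", "start", "end", "name"))
red <- zones[zones$name == "RED", , drop = FALSE]
ov <- 0
for (k in seq_len(nrow(truth$red)))
  ov <- ov + sum(pmax(0, pmin(red$end, truth$red$end[k]) -
                        pmax(red$start, truth$red$start[k])) *
                   (red$chrom == truth$red$chrom[k]))
message(sprintf("planted conserved-high block recovered as RED: %.1f%% of %d bp",
                100 * ov / sum(truth$red$end - truth$red$start),
                sum(truth$red$end - truth$red$start)))
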