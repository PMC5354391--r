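#!/usr/bin/env Rscript
# Feature fold-enrichment inside the zone classes and dLOCK sets versus
# the genome average, gene sets of top-scoring dLOCKs and their
# intersection percentages, and the planted-enrichment recovery ensemble.

source(file.path("analysis", "00_common.R"))

cfg <- study_config()
pipeline_enrich(cfg)
enr <- read.table(file.path(OUT, "enrichment.tsv"), header = TRUE)
print(head(enr[order(-enr$fold), ], 8))

genome <- read_chrom_sizes(cfg$chrom_sizes)
sheet <- collapse_replicates(read_sample_sheet(cfg$sample_sheet))
grid <- window_grid(genome,
                    10000, read_interval_bed(cfg$deadzones, genome))
tracks <- read_track_matrix(file.path(OUT, "windows_10k.tsv"), grid)
genes <- read_interval_bed(file.path(DATA, "features", "genes.interval.bed"),
                           genome, "genes")
dls <- suppressWarnings(run_comparisons(tracks, sheet))
gs <- lapply(dls, genes_in_dlocks, genes = genes, genome = genome,
             alpha = 0.90)
pairs <- expand.grid(a = names(gs), b = names(gs),
                     stringsAsFactors = FALSE)
pairs <- subset(pairs, a != b & lengths(gs[a]) > 0)
pairs$pct <- mapply(function(a, b) gene_intersection_pct(gs[[a]], gs[[b]]),
                    pairs$a, pairs$b)
write.table(format(pairs, digits = 4),
            file.path(OUT, "gene_set_intersections.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("gene sets at alpha 0.90: %s",
                paste(sprintf("%s=%d", names(gs), lengths(gs)),
                      collapse = ", ")))

e3 <- feature_enrichment_experiment(n_seeds = 50, k = 3, seed_base = SEED)
message(sprintf("planted 3x enrichment estimated as %.3f (mean of %d seeds)",
                mean(e3$k_hat), nrow(e3)))
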