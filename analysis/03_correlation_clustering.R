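#!/usr/bin/env Rscript
# Genome-wide Pearson correlation of sample and feature-density tracks at
# each resolution, complete-linkage clustering of the samples on
# 1 - Pearson r, and a domain-boundary meta-profile of gene density for
# the first sample (positive offsets point into the domain).

source(file.path("analysis", "00_common.R"))

cfg <- study_config()
pipeline_correlate(cfg)
pipeline_cluster(cfg)
message("dendrogram: ", readLines(file.path(OUT, "samples.nwk"))[1])

genome <- read_chrom_sizes(cfg$chrom_sizes)
sheet <- read_sample_sheet(cfg$sample_sheet)
doms <- read_scored_bed(sheet$path[1], genome, sheet$sample_id[1])
genes <- read_interval_bed(file.path(DATA, "features", "genes.interval.bed"),
                           genome, "genes")
prof <- boundary_metaprofile(doms, genes, genome, flank = 100000,
                             bin = 10000)
write.table(format(prof, digits = 6),
            file.path(OUT, "boundary_profile_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("boundary profile over %d boundaries; inside/outside gene density %.3f / %.3f",
                attr(prof, "n_boundaries"),
                mean(prof$density[prof$offset > 0]),
                mean(prof$density[prof$offset < 0])))
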