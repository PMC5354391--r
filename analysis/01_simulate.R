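#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 3 chromosomes x 20 Mb, granulocyte
# (3), CD34+ (3) and AML cluster A/B (2+2) samples sharing one LOCK
# skeleton with lognormal depth noise; planted structure = one conserved
# high block, one conserved-low gap, one CD34+-elevated differential
# block (log-fold 1), uniform gene intervals and SNV points enriched 3x
# inside the differential block. Ground truth is written alongside.

source(file.path("analysis", "00_common.R"))

fx <- make_fixture("small", DATA, seed = SEED)
tr <- fx$truth
message(sprintf("wrote %d samples, %d skeleton blocks (%d planted)",
                length(list.files(DATA, pattern = "rsegout")),
                nrow(tr$blocks), sum(tr$blocks$type != "background")))
message("planted differential block: ",
        with(tr$diff, sprintf("%s:%d-%d %s delta=%g", chrom, start, end,
                              category, delta)))
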