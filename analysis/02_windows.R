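#!/usr/bin/env Rscript
# Window scoring: map each sample's scored domains onto 10 kb / 50 kb /
# 100 kb grids with deadzone masking, normalize each track by its
# genome-wide mean and average technical replicates. The per-resolution
# samples x windows matrices under results/pipeline are the hand-off
# artifact for every later stage.

source(file.path("analysis", "00_common.R"))

cfg <- study_config()
paths <- pipeline_windows(cfg)
message("window matrices: ", paste(basename(paths), collapse = ", "))
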