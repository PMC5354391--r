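# Shared setup for the analysis drivers: a simulated myeloid cohort
# (granulocyte, CD34+, AML clusters A and B) with planted conserved and
# differential structure, written once under results/data and analyzed by
# the numbered scripts through the package's pipeline stages.

suppressMessages(library(lockscape))

SEED <- 1L
ROOT <- file.path("results")
DATA <- file.path(ROOT, "data")
OUT <- file.path(ROOT, "pipeline")

study_config <- function() {
  if (!file.exists(file.path(DATA, "samples.tsv"))) {
    message("simulating study cohort under ", DATA)
    make_fixture("small", DATA, seed = SEED)
  }
  pipeline_config(
    chrom_sizes = file.path(DATA, "chrom.sizes"),
    deadzones = file.path(DATA, "deadzones.bed"),
    sample_sheet = file.path(DATA, "samples.tsv"),
    feature_dir = file.path(DATA, "features"),
    out_dir = OUT,
    resolutions = c(10000, 50000, 100000),
    seed = SEED)
}
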