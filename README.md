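# lockscape

Genome-wide analysis of **large organized chromatin K9 domains (LOCKs)**
— the broad, multi-hundred-kilobase blocks of H3K9me2 that mark
facultative heterochromatin — and of their **differential blocks
(dLOCKs)** between groups of samples, such as normal myeloid progenitors
(CD34+), differentiated granulocytes and AML blasts. The package takes
scored enriched-domain calls (the output of an HMM broad-domain caller,
one BED-like file per sample) and provides, as tested R functions behind
a staged pipeline:

* **Window scoring** — domains mapped onto 10 kb–1 Mb grids, each domain
  contributing its mean read depth for every non-deadzone nucleotide
  falling in a window; per-track mean normalization; technical-replicate
  averaging.
* **Correlation and clustering** — genome-wide Pearson correlation of
  sample and feature-density tracks; complete-linkage clustering on
  d = 1 − r; domain-boundary meta-profiles of any feature.
* **Conserved/variable zones** — every 10 kb window classified RED
  (conserved high), GREEN (conserved low) or YELLOW (variable) across
  the panel, using the per-window standard deviation as the high/low
  threshold.
* **dLOCK calling** — for an ordered category pair (c1, c2), LOCK bases
  from c1 and the per-window Sum Log Ratio

  SLR(w) = (1/N) Σ_{i∈c1, j∈c2} −log( s_i(w) / s_j(w) ),

  with scores floored at ε = 1e−6, same-sex pairs only on chrX/chrY;
  maximal same-sign runs of SLR become signed dLOCKs scored by their
  summed SLR and flagged against type-7 empirical quantiles of all
  non-chrY dLOCK scores (alpha 0.90/0.95/0.99 and complements).
* **Enrichment and gene sets** — fold enrichment of features inside any
  window set versus the genome average; genes overlapping top-scoring
  dLOCKs; gene-set intersection percentages.
* **A synthetic-data generator** — cohorts with a shared LOCK skeleton,
  lognormal depth noise, and planted conserved, variable and
  differential blocks with known log-fold, so every stage is verifiable
  against ground truth.

## Worked example

A two-minute end-to-end run on a generated 2 Mb cohort (2 granulocyte +
2 CD34+ samples, one 200 kb block elevated e-fold in CD34+):

```r
library(lockscape)
fx  <- make_fixture("tiny", "demo_data", seed = 7)
cfg <- pipeline_config(chrom_sizes = fx$paths$sizes,
                       deadzones   = fx$paths$deadzones,
                       sample_sheet = fx$paths$sheet,
                       feature_dir = fx$paths$features,
                       out_dir = "demo_out",
                       resolutions = c(10000, 50000), seed = 7)
pipeline_all(cfg)
read.table("demo_out/zone_fractions.tsv", header = TRUE)
```

```
    zone      pct
1    RED 58.79397
2 YELLOW  0.00000
3  GREEN 41.20603
```

With only two categories and four concordant samples, every domain
window is conserved-high (RED, 58.8% of unmasked bp) and every
domain-free window conserved-low (GREEN); nothing is variable. The
top dLOCKs of the CD34+ > granulocyte comparison:

```
 chrom   start     end total_score     sign   a99
  chr1 1200000 1400000  -11.082690 negative  TRUE
  chr1 1600000 1690000    3.812757 positive  TRUE
  chr1  350000  590000    3.666361 positive FALSE
```

The strongest block is the planted one (chr1:1,200,000–1,400,000):
negative total score because positive SLR means the *second* category is
higher, and here CD34+ (the first-listed category) carries the planted
elevation. It is flagged at the 1% tail (`a99`). Its per-window SLR,
≈ −0.55 rather than −1.0, reflects mean normalization on a 2 Mb toy
genome where the planted block itself shifts the CD34+ genome mean; on
the calibration-scale genomes below the same estimate is within 2% of
the planted log-fold.

`analysis/01_simulate.R` … `analysis/06_enrichment.R` run the same
stages as a narrated workflow on a 60 Mb three-chromosome cohort with
granulocyte, CD34+ and AML cluster A/B samples, writing tables under
`results/`.

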