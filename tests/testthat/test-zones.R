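# 6-sample panel: two samples in each of the three categories
panel_cat <- rep(c("granulocyte", "cd34", "aml"), each = 2)

test_that("zone rules on hand-worked windows", {
  # all samples agree at 1.0: sigma 0, everyone 'high' (1 > 0), no lows -> RED
  # all zero: sigma 0, everyone 'low' (0 <= 0) -> GREEN
  # half at 2, half at 0 across categories: many high and many low -> YELLOW
  m <- cbind(rep(1, 6), rep(0, 6), c(2, 0, 2, 0, 2, 0))
  z <- zone_labels(m, panel_cat)
  expect_equal(as.character(z$label), c("RED", "GREEN", "YELLOW"))
  expect_equal(z$sigma[1:2], c(0, 0))

  # one outlier high sample: 5 lows -> not RED; 1 high -> GREEN
  m2 <- cbind(c(9, 0, 0, 0, 0, 0))
  expect_equal(as.character(zone_labels(m2, panel_cat)$label), "GREEN")
})

test_that("labels are invariant to permuting samples within categories", {
  set.seed(21)
  m <- matrix(rexp(6 * 50), 6)
  z1 <- zone_labels(m, panel_cat)
  perm <- c(2, 1, 4, 3, 6, 5)
  z2 <- zone_labels(m[perm, ], panel_cat[perm])
  expect_equal(z1$label, z2$label)
})

test_that("label changes are local to the modified window", {
  set.seed(22)
  m <- matrix(rexp(6 * 40), 6)
  z1 <- zone_labels(m, panel_cat)
  w <- which(z1$label == "GREEN")[1]
  m2 <- m
  m2[3, w] <- m2[3, w] + 5
  z2 <- zone_labels(m2, panel_cat)
  expect_equal(z1$label[-w], z2$label[-w])
  expect_true(as.character(z2$label[w]) %in% c("GREEN", "YELLOW", "RED"))
})

test_that("chrY windows are classified from male samples only", {
  sex <- c("M", "F", "M", "F", "M", "F")
  chrom <- c("chr1", "chrY")
  # males all at 1 (RED pattern), females wild; chrY must ignore females
  m <- cbind(rep(1, 6), c(1, 9, 1, 0, 1, 5))
  z <- zone_labels(m, panel_cat, chrom = chrom, sex = sex)
  expect_equal(as.character(z$label), c("RED", "RED"))
  # without any males, chrY stays masked
  expect_warning(
    z2 <- zone_labels(m, panel_cat, chrom = chrom, sex = rep("F", 6)),
    "no male")
  expect_equal(as.character(z2$label[2]), "MASKED")
  expect_error(zone_labels(m, panel_cat, chrom = chrom), "sex needed")
})

test_that("masked and half-masked windows never get a zone label", {
  m <- cbind(rep(1, 6), c(NA, rep(1, 5)), rep(NA, 6))
  z <- zone_labels(m, panel_cat)
  expect_equal(as.character(z$label), c("RED", "MASKED", "MASKED"))
})

test_that("zone fractions are bp-weighted and sum to 100", {
  g <- toy_genome(5e4)
  grid <- window_grid(g, 10000)
  zm <- structure(list(grid = grid,
                       label = factor(c("RED", "RED", "GREEN", "YELLOW",
                                        "MASKED"),
                                      levels = c("RED", "YELLOW", "GREEN",
                                                 "MASKED")),
                       sigma = rep(0, 5)), class = "lk_zonemap")
  fr <- zone_fractions(zm)
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_equal(unname(fr), c(50, 25, 25))

  zm$label <- factor(rep("RED", 5),
                     levels = c("RED", "YELLOW", "GREEN", "MASKED"))
  expect_equal(unname(zone_fractions(zm)), c(100, 0, 0))
})

test_that("zones_to_bed merges adjacent same-label windows only", {
  g <- toy_genome(6e4)
  grid <- window_grid(g, 10000)
  mk <- function(labs) structure(
    list(grid = grid, label = factor(labs, levels = c("RED", "YELLOW",
                                                      "GREEN", "MASKED")),
         sigma = rep(0, 6)), class = "lk_zonemap")
  bed <- zones_to_bed(mk(c("RED", "RED", "RED", "GREEN", "GREEN", "YELLOW")))
  expect_equal(bed$end - bed$start, c(30000, 20000, 10000))
  expect_equal(bed$name, c("RED", "GREEN", "YELLOW"))

  alt <- zones_to_bed(mk(rep(c("RED", "GREEN"), 3)))
  expect_equal(nrow(alt), 6)

  expect_equal(nrow(zones_to_bed(mk(rep("MASKED", 6)))), 0)
  # a masked gap breaks a run
  gap <- zones_to_bed(mk(c("RED", "MASKED", "RED", "RED", "MASKED", "RED")))
  expect_equal(nrow(gap), 3)
})

test_that("classify_zones wires tracks, sheet, chrY and category checks", {
  g <- genome_def(c("chr1", "chrY"), c(4e4, 2e4))
  grid <- window_grid(g, 10000)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:6),
                        category = panel_cat,
                        sex = c("M", "F", "M", "F", "M", "F"))
  set.seed(9)
  m <- matrix(rexp(6 * 6), 6)
  tracks <- tracks_of_matrix(m, grid)
  zm <- classify_zones(tracks, samples)
  expect_s3_class(zm, "lk_zonemap")
  oracle <- vapply(1:4, function(w)
    zone_rule_oracle(m[, w], samples$category), "")
  expect_equal(as.character(zm$label[1:4]), oracle)
  # chrY: male rows only
  oracleY <- vapply(5:6, function(w)
    zone_rule_oracle(m[c(1, 3, 5), w], samples$category[c(1, 3, 5)]), "")
  expect_equal(as.character(zm$label[5:6]), oracleY)

  expect_error(classify_zones(tracks[1:4], samples[1:4, ]), "no samples in")
  expect_error(classify_zones(tracks, samples, categories = "k562_control"),
               "no samples in")
})

test_that("planted conserved-high blocks are recovered as RED", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 2e7,
                    samples = c(granulocyte = 2, cd34 = 2, amlA = 2,
                                amlB = 2),
                    red_blocks = data.frame(chrom = "chr1", start = 5e6,
                                            end = 6e6),
                    sigma = 0.25, seed = 77)
  sim <- simulate_domains(cfg)
  grid <- window_grid(cfg$genome, 10000, sim$deadzones)
  tracks <- lapply(sim$domains, function(d)
    normalize_track(score_windows(d, grid)))
  zm <- classify_zones(tracks, sim$samples)
  w <- grid$windows
  planted <- w$start >= 5e6 & w$end <= 6e6 & !w$masked
  frac_red <- sum((w$end - w$start)[planted & zm$label == "RED"]) /
    sum((w$end - w$start)[planted])
  expect_gte(frac_red, 0.95)
})
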