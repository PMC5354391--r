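test_that("feature density tracks: covered bp and point counts", {
  g <- toy_genome(4e4)
  grid <- window_grid(g, 10000)
  gene <- feature_track(data.frame(chrom = "chr1", start = 5000, end = 15000),
                        g, "gene")
  expect_equal(feature_density_track(gene, grid)$score, c(5000, 5000, 0, 0))

  snv <- feature_track(data.frame(chrom = "chr1", start = c(100, 200, 300, 25000),
                                  end = c(101, 201, 301, 25001)),
                       g, "snv", kind = "point")
  expect_equal(feature_density_track(snv, grid)$score, c(3, 0, 1, 0))

  whole <- feature_track(data.frame(chrom = "chr1", start = 0, end = 4e4),
                         g, "all")
  expect_equal(feature_density_track(whole, grid)$score, rep(10000, 4))

  # deadzone bp and points inside deadzones are excluded
  grid_dz <- window_grid(g, 10000,
                         data.frame(chrom = "chr1", start = 0, end = 5000))
  expect_equal(feature_density_track(whole, grid_dz)$score,
               c(5000, 10000, 10000, 10000))
  expect_equal(feature_density_track(snv, grid_dz)$score, c(0, 0, 1, 0))
})

test_that("pairwise Pearson matches the textbook formula and its edge cases", {
  g <- toy_genome(5e4)
  grid <- window_grid(g, 10000)
  x <- window_track("x", grid, c(1, 2, 3, 4, 5), normalized = TRUE)
  y <- window_track("y", grid, 2 * c(1, 2, 3, 4, 5) + 1, normalized = TRUE)
  z <- window_track("z", grid, c(5, 4, 3, 2, 1), normalized = TRUE)
  cm <- pearson_pairwise(list(x, y, z))
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r["x", "z"], -1)
  expect_identical(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$n["x", "y"], 5)

  set.seed(5)
  a <- runif(5); b <- runif(5)
  two_pass <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cm2 <- pearson_pairwise(list(window_track("a", grid, a, TRUE),
                               window_track("b", grid, b, TRUE)))
  expect_equal(cm2$r["a", "b"], two_pass, tolerance = 1e-12)

  flat <- window_track("f", grid, rep(2, 5), normalized = TRUE)
  expect_true(is.na(pearson_pairwise(list(x, flat))$r["x", "f"]))

  short <- window_track("s", grid, c(1, 2, NA, NA, NA), normalized = TRUE)
  expect_error(pearson_pairwise(list(x, short)), "fewer than 3")
})

test_that("chrX/chrY windows are excluded from correlation by default", {
  g <- genome_def(c("chr1", "chrX"), c(3e4, 3e4))
  grid <- window_grid(g, 10000)
  # identical on chr1, opposite on chrX
  a <- window_track("a", grid, c(1, 2, 3, 1, 2, 3), TRUE)
  b <- window_track("b", grid, c(1, 2, 3, 3, 2, 1), TRUE)
  expect_equal(pearson_pairwise(list(a, b))$r["a", "b"], 1)
  expect_lt(pearson_pairwise(list(a, b), include_xy = TRUE)$r["a", "b"], 1)
})

test_that("complete-linkage clustering agrees with hand agglomeration", {
  g <- toy_genome(6e4)
  grid <- window_grid(g, 10000)
  base <- c(1, 2, 3, 4, 5, 6)
  t1 <- window_track("s1", grid, base, TRUE)
  t2 <- window_track("s2", grid, base, TRUE)          # identical to s1
  t3 <- window_track("s3", grid, rev(base), TRUE)     # anticorrelated
  hc <- hcluster_samples(list(t3, t1, t2))
  # first merge joins the identical pair at height 0; final merge at 1 - (-1)
  expect_equal(hc$height, c(0, 2), tolerance = 1e-12)
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("s1", "s2"))

  # permutation invariance of merge heights
  hc2 <- hcluster_samples(list(t1, t3, t2))
  expect_equal(hc2$height, hc$height)
  expect_equal(hc2$labels[hc2$order], hc$labels[hc$order])

  # three identical tracks: flat cluster, all heights 0
  hc3 <- hcluster_samples(list(t1, t2, window_track("s4", grid, base, TRUE)))
  expect_equal(hc3$height, c(0, 0))

  # newick export contains every leaf
  nwk <- dendrogram_newick(hc)
  for (s in c("s1", "s2", "s3")) expect_match(nwk, s)
})

test_that("region restriction changes the windows clustering sees", {
  g <- toy_genome(6e4)
  grid <- window_grid(g, 10000)
  # agree on the first half, disagree on the second
  t1 <- window_track("s1", grid, c(1, 2, 3, 9, 1, 5), TRUE)
  t2 <- window_track("s2", grid, c(1, 2, 3, 2, 8, 1), TRUE)
  t3 <- window_track("s3", grid, c(3, 2, 1, 9, 1, 5), TRUE)
  whole <- hcluster_samples(list(t1, t2, t3))
  left <- hcluster_samples(list(t1, t2, t3),
                           region = list(chrom = "chr1", start = 0, end = 3e4))
  expect_equal(left$height[1], 0, tolerance = 1e-12)   # s1,s2 identical there
  expect_gt(whole$height[1], 0)
})

test_that("boundary meta-profiles are oriented into the domain", {
  g <- toy_genome(1e6)
  doms <- domain_set(data.frame(chrom = "chr1",
                                start = c(200000, 600000),
                                end = c(400000, 800000),
                                mean_depth = 1), g, "s")
  feat <- feature_track(as.data.frame(doms)[1:3], g, "self")
  bp <- boundary_metaprofile(doms, feat, g, flank = 50000, bin = 10000)
  inside <- bp$density[bp$offset > 0]
  outside <- bp$density[bp$offset < 0]
  expect_true(all(inside == 1))
  expect_true(all(outside == 0))
  expect_equal(attr(bp, "n_boundaries"), 4)
  expect_equal(bp$offset, seq(-45000, 45000, by = 10000))

  # uniform genome-wide feature: flat profile at 1
  uni <- feature_track(data.frame(chrom = "chr1", start = 0, end = 1e6),
                       g, "uni")
  expect_equal(boundary_metaprofile(doms, uni, g, 50000, 10000)$density,
               rep(1, 10))

  # a feature wholly inside one domain appears only at inside offsets
  one <- domain_set(data.frame(chrom = "chr1", start = 500000, end = 700000,
                               mean_depth = 1), g, "s")
  f <- feature_track(data.frame(chrom = "chr1", start = 510000, end = 520000),
                     g, "f")
  prof <- boundary_metaprofile(one, f, g, 50000, 10000)
  expect_true(all(prof$density[prof$offset < 0] == 0))
  expect_gt(sum(prof$density[prof$offset > 0]), 0)

  none <- domain_set(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), mean_depth = numeric()),
                     g, "s")
  expect_error(boundary_metaprofile(none, feat, g, 50000, 10000),
               "no domain boundaries")
})
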