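grid1 <- function(n, chrom_len = n * 1e4) {
  window_grid(toy_genome(chrom_len), 10000)
}

test_that("LOCK bases: positive-run candidates filtered by the per-row rule", {
  g <- grid1(4)
  # candidates end at all-zero windows: (1,1,0,1) gives bases {1,2},{4}
  t1 <- window_track("a", g, c(1, 1, 0, 1), TRUE)
  b <- find_lock_bases(list(t1))
  expect_equal(b$first, c(1, 4))
  expect_equal(b$last, c(2, 4))

  # second sample zero in window 4: candidate {4} fails the 50% rule,
  # candidate {1,2} survives at exactly 50% for sample b
  t2 <- window_track("b", g, c(0, 1, 0, 0), TRUE)
  b2 <- find_lock_bases(list(t1, t2))
  expect_equal(nrow(b2), 1)
  expect_equal(c(b2$first, b2$last), c(1, 2))

  # below 50% anywhere in the candidate rejects it whole (no trimming)
  t3 <- window_track("c", g, c(1, 1, 1, 0), TRUE)
  t4 <- window_track("d", g, c(1, 0, 0, 0), TRUE)
  expect_equal(nrow(find_lock_bases(list(t3, t4))), 0)

  # all-zero chromosome: no bases
  expect_equal(nrow(find_lock_bases(list(window_track("z", g, rep(0, 4), TRUE)))), 0)

  # runs never cross a chromosome boundary
  g2 <- window_grid(genome_def(c("chr1", "chr2"), c(2e4, 2e4)), 10000)
  tr <- window_track("a", g2, c(1, 1, 1, 1), TRUE)
  expect_equal(nrow(find_lock_bases(list(tr))), 2)
})

test_that("LOCK bases under the stretch rule keep zero windows inside", {
  g <- grid1(4)
  # one sample, scores (1,1,0,1) over a 4-window stretch: 3/4 positive
  # >= 50% -> one base of 4 windows, zero window included, no trimming
  t1 <- window_track("a", g, c(1, 1, 0, 1), TRUE)
  b <- find_lock_bases(list(t1), rule = "stretch")
  expect_equal(nrow(b), 1)
  expect_equal(c(b$first, b$last, b$n_windows), c(1, 4, 4))

  # a second sample positive in only 1/4 of the stretch rejects it whole
  t2 <- window_track("b", g, c(0, 1, 0, 0), TRUE)
  expect_equal(nrow(find_lock_bases(list(t1, t2), rule = "stretch")), 0)

  # masked windows delimit stretches
  gm <- window_grid(toy_genome(6e4), 10000,
                    data.frame(chrom = "chr1", start = 3e4, end = 4e4))
  tm <- window_track("a", gm, c(1, 1, 0, NA, 1, 1), TRUE)
  bm <- find_lock_bases(list(tm), rule = "stretch")
  expect_equal(bm$first, c(1, 5))
  expect_equal(bm$last, c(3, 6))
})

test_that("SLR window scores: closed forms, antisymmetry, brute force", {
  g <- grid1(4)
  base_all <- find_lock_bases(list(window_track("x", g, rep(1, 4), TRUE)))

  mk <- function(v, id) window_track(id, g, v, TRUE)
  # equal scores cancel; a single e-fold pair gives exactly 1
  s1 <- slr_window_scores(list(mk(c(2, 1, 4, 1), "i")),
                          list(mk(c(2, exp(1), 4, 1), "j")), base_all)
  expect_equal(s1$score, c(0, 1, 0, 0), tolerance = 1e-12)
  expect_equal(unique(s1$n_pairs), 1L)

  set.seed(31)
  for (rep in 1:5) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1); W <- 20
    gg <- grid1(W)
    m1 <- matrix(rexp(n1 * W), n1); m2 <- matrix(rexp(n2 * W), n2)
    m1[sample(length(m1), 5)] <- 0           # exercise the epsilon floor
    tr1 <- tracks_of_matrix(m1, gg, ids = sprintf("a%d", 1:n1))
    tr2 <- tracks_of_matrix(m2, gg, ids = sprintf("b%d", 1:n2))
    bases <- find_lock_bases(list(window_track("x", gg, rep(1, W), TRUE)))
    fwd <- slr_window_scores(tr1, tr2, bases)
    expect_equal(fwd$score, slr_brute(m1, m2), tolerance = 1e-12)
    rev <- slr_window_scores(tr2, tr1, bases)
    expect_identical(fwd$score, -rev$score)    # exact antisymmetry
    expect_equal(unique(fwd$n_pairs), n1 * n2)
  }
})

test_that("SLR on sex chromosomes uses same-sex pairs only", {
  g <- window_grid(genome_def(c("chr1", "chrX"), c(2e4, 2e4)), 10000)
  m1 <- rbind(c(1, 1, 2, 2), c(1, 1, 8, 8))        # male, female of c1
  m2 <- rbind(c(1, 1, 2 * exp(1), 2 * exp(1)),     # male of c2
              c(1, 1, 8 * exp(2), 8 * exp(2)))     # female of c2
  tr1 <- tracks_of_matrix(m1, g, ids = c("m1", "f1"))
  tr2 <- tracks_of_matrix(m2, g, ids = c("m2", "f2"))
  bases <- find_lock_bases(tr1)
  s <- slr_window_scores(tr1, tr2, bases, sex1 = c("M", "F"),
                         sex2 = c("M", "F"))
  # autosome: all four pairs; chrX: M-M pair gives 1, F-F pair gives 2
  expect_equal(s$n_pairs, c(4L, 4L, 2L, 2L))
  expect_equal(s$score[3:4], c(1.5, 1.5), tolerance = 1e-12)
  expect_warning(
    s2 <- slr_window_scores(tr1, tr2, bases, sex1 = c("M", "M"),
                            sex2 = c("F", "F")),
    "no same-sex pair")
  expect_true(all(is.na(s2$score[3:4])))
})

test_that("sign segmentation splits on sign changes and zeros", {
  g <- grid1(4)
  bases <- find_lock_bases(list(window_track("x", g, rep(1, 4), TRUE)))
  mk_slr <- function(v) structure(
    list(grid = g, score = v, n_pairs = rep(1L, 4), bases = bases,
         epsilon = 1e-6), class = "lk_slr")
  dl <- segment_dlocks(mk_slr(c(1, 2, -1, -3)))
  expect_equal(dl$total_score, c(3, -4))
  expect_equal(dl$sign, c("positive", "negative"))
  expect_equal(dl$n_windows, c(2, 2))

  dl2 <- segment_dlocks(mk_slr(c(1, 1, 2, 1)))
  expect_equal(nrow(dl2), 1)
  expect_equal(dl2$n_windows, 4)

  dl3 <- segment_dlocks(mk_slr(c(1, 0, 1, 0)))
  expect_equal(nrow(dl3), 2)
  expect_equal(dl3$n_windows, c(1, 1))
  expect_equal(dl3$total_score, c(1, 1))
})

test_that("quantile ranking: type-7 thresholds with strict inequalities", {
  dl <- dlocks_of_scores(1:10)
  r <- rank_dlocks(dl, alphas = 0.90)
  thr <- attr(r, "thresholds")
  expect_equal(thr$q_hi, 9.1)   # type-7 quantile of 1..10 at p = 0.9
  expect_equal(thr$q_lo, 1.9)
  expect_equal(which(r$alpha_90), 10)

  # p = 0: the threshold is the minimum, everything above it passes
  r0 <- rank_dlocks(dl, alphas = 0)
  expect_equal(attr(r0, "thresholds")$q_hi, 1)
  expect_equal(which(r0$alpha_00), 2:10)

  # threshold invariance under reordering
  set.seed(41)
  sc <- rnorm(57)
  a <- attr(rank_dlocks(dlocks_of_scores(sc), 0.95), "thresholds")
  b <- attr(rank_dlocks(dlocks_of_scores(sample(sc)), 0.95), "thresholds")
  expect_equal(a, b)

  # chrY dLOCKs inherit autosomal thresholds and never enter them
  dly <- dlocks_of_scores(c(1:10, 100), chrom = c(rep("chr1", 10), "chrY"))
  ry <- rank_dlocks(dly, 0.90)
  expect_equal(attr(ry, "thresholds")$q_hi, 9.1)
  expect_true(ry$alpha_90[11])

  expect_error(rank_dlocks(dlocks_of_scores(numeric())), "no dLOCKs")
})

test_that("positive-significant fraction respects quantile granularity", {
  set.seed(43)
  for (rep in 1:30) {
    n <- sample(20:300, 1)
    r <- rank_dlocks(dlocks_of_scores(rnorm(n)), 0.90)
    frac <- mean(r$alpha_90 & r$sign == "positive")
    expect_lte(frac, 0.10 + 1 / n)
  }
})

test_that("ranking flags are invariant to the logarithm base", {
  set.seed(44)
  sc <- rnorm(80)
  r1 <- rank_dlocks(dlocks_of_scores(sc), c(0.90, 0.99))
  r2 <- rank_dlocks(dlocks_of_scores(sc / log(2)), c(0.90, 0.99))
  expect_identical(r1$alpha_90, r2$alpha_90)
  expect_identical(r1$alpha_99, r2$alpha_99)
})

test_that("dLOCK summaries: coverage, size, genes and density ratio", {
  g <- toy_genome(1e7)
  dl <- dlocks_of_scores(5)
  dl$start <- 2e6; dl$end <- 2.5e6
  genes <- feature_track(
    data.frame(chrom = "chr1", start = c(2.1e6, 2.4e6, 9e6),
               end = c(2.2e6, 2.6e6, 9.1e6),
               name = c("gA", "gB", "gC")), g, "genes")
  s <- summarize_dlocks(dl, genes, g)
  expect_equal(s$pct_genome, 5)
  expect_equal(s$mean_size_bp, 5e5)
  expect_equal(s$n_dlocks, 1L)
  expect_equal(s$n_genes, 2L)   # gB straddles the edge but overlaps >= 1 bp
  expect_equal(s$gene_density_ratio, (2 / 5e5) / (3 / 1e7))

  # uniformly placed genes give density ratio ~ 1
  set.seed(45)
  ratios <- replicate(30, {
    gs <- sort(sample(0:(1e7 - 1000), 400))
    genes <- feature_track(data.frame(chrom = "chr1", start = gs,
                                      end = gs + 1000,
                                      name = sprintf("g%d", seq_along(gs))),
                           g, "genes")
    summarize_dlocks(dl, genes, g)$gene_density_ratio
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(30))

  # no passing dLOCKs: all-zero summary
  r <- rank_dlocks(dlocks_of_scores(c(-1, 1, 2, 3)), 0.90)
  r$alpha_90 <- FALSE
  z <- summarize_dlocks(r, genes, g, alpha = 0.90)
  expect_equal(z$pct_genome, 0)
  expect_equal(z$n_dlocks, 0L)
})

test_that("run_comparisons emits the ten categories and skips absent ones", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 5e6,
                    samples = c(granulocyte = 2, cd34 = 2, amlA = 2,
                                amlB = 2, k562_control = 2,
                                k562_unc0638 = 2),
                    deadzone_fraction = 0, seed = 12)
  sim <- simulate_domains(cfg)
  grid <- window_grid(cfg$genome, 10000)
  tracks <- lapply(sim$domains, function(d)
    normalize_track(score_windows(d, grid)))
  res <- run_comparisons(tracks, sim$samples)
  expect_equal(length(res), 10)
  expect_named(res, dlock_comparisons()$name)
  # reversed comparisons have mirrored sign structure on shared windows
  fwd <- res$cd34_gt_granulocyte
  rev <- res$granulocyte_gt_cd34
  expect_equal(sum(fwd$total_score), -sum(rev$total_score), tolerance = 1e-9)

  # drop one category: its comparisons skip with a warning, rest unaffected
  keep <- sim$samples$category != "k562_control"
  w <- capture_warnings(
    res2 <- run_comparisons(tracks[keep], sim$samples[keep, ]))
  expect_match(w, "skipping", all = TRUE)
  expect_length(w, 2)        # both k562 comparisons need the control
  expect_equal(length(res2), 8)
  expect_equal(res2$cd34_gt_granulocyte$total_score, fwd$total_score)
})
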