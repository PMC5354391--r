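#' Planted differential-block recovery experiment
#'
#' The pipeline's headline calibration study. For each seed a two-category
#' cohort is simulated on a 2 x 50 Mb genome with the shared LOCK skeleton,
#' lognormal depth noise and one planted differential block elevated by
#' exp(delta) in the second category; the full dLOCK path (window scoring,
#' normalization, LOCK bases from the first category, SLR, segmentation,
#' quantile ranking) is run and the planted block's fate is recorded.
#'
#' With `delta = 0` the experiment is a null calibration: the planted
#' block carries no signal and, to make it exchangeable with the skeleton,
#' its length is drawn per seed from the same log-uniform LOCK length
#' distribution instead of being fixed.
#'
#' A recovery means: some dLOCK of the expected (positive) sign, flagged
#' at the `alpha` quantile level, overlaps at least half of the planted
#' block's bp. A null "discovery" means: a dLOCK overlapping the planted
#' block is flagged in the tail matching its own sign.
#'
#' @param n_seeds number of simulation replicates.
#' @param delta planted log-fold (0 for the null calibration).
#' @param sigma lognormal noise sd.
#' @param n1,n2 samples in the first (reference) and second (elevated)
#'   category.
#' @param block_bp planted block length (ignored when `delta = 0`).
#' @param alpha flag level examined.
#' @param seed_base seeds used are `seed_base + 1:n_seeds`.
#' @return data.frame, one row per seed: n_dlocks, mean_slr_block,
#'   recovered, planted_sign, planted_flagged.
#' @export
planted_block_experiment <- function(n_seeds = 200, delta = 1,
                                     sigma = 0.25, n1 = 3, n2 = 3,
                                     block_bp = 5e5, alpha = 0.99,
                                     seed_base = 0) {
  lock_min <- 5e4; lock_max <- 5e5
  res <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    seed <- (seed_base + k) %% 2147483647L
    if (delta == 0) {              # exchangeable null block length
      set.seed(seed)
      block_bp_k <- round(exp(stats::runif(1, log(lock_min),
                                           log(lock_max))))
    } else block_bp_k <- block_bp
    block <- data.frame(chrom = "chr2", start = 2e7,
                        end = 2e7 + block_bp_k,
                        category = "cd34", delta = delta)
    cfg <- sim_config(n_chrom = 2, chrom_length = 5e7,
                      samples = c(granulocyte = n1, cd34 = n2),
                      lock_min = lock_min, lock_max = lock_max,
                      sigma = sigma, diff_blocks = block, seed = seed)
    sim <- simulate_domains(cfg)
    grid <- window_grid(cfg$genome, 10000, sim$deadzones)
    tracks <- lapply(sim$domains, function(d)
      normalize_track(score_windows(d, grid)))
    i1 <- which(sim$samples$category == "granulocyte")
    i2 <- which(sim$samples$category == "cd34")
    bases <- find_lock_bases(tracks[i1])
    slr <- slr_window_scores(tracks[i1], tracks[i2], bases,
                             sex1 = sim$samples$sex[i1],
                             sex2 = sim$samples$sex[i2])
    dl <- rank_dlocks(segment_dlocks(slr), alphas = alpha)
    col <- sprintf("alpha_%02d", round(100 * alpha))
    w <- grid$windows
    in_block <- w$chrom == block$chrom & w$start >= block$start &
      w$end <= block$end
    mean_slr <- mean(slr$score[in_block], na.rm = TRUE)
    ov <- pmin(dl$end, block$end) - pmax(dl$start, block$start)
    ov[dl$chrom != block$chrom] <- 0
    touches <- ov > 0
    recovered <- any(dl[[col]] & dl$sign == "positive" &
                       ov >= 0.5 * block_bp_k)
    planted_flagged <- any(dl[[col]] & touches)
    planted_sign <- if (any(touches))
      dl$sign[which(touches)[which.max(ov[touches])]] else NA_character_
    res[[k]] <- data.frame(seed = seed, n_dlocks = nrow(dl),
                           n_planted_dlocks = sum(touches),
                           mean_slr_block = mean_slr,
                           recovered = recovered,
                           planted_sign = planted_sign,
                           planted_flagged = planted_flagged)
  }
  do.call(rbind, res)
}

#' Planted feature-enrichment recovery experiment
#'
#' Per seed, a feature track is simulated with Poisson intensity k-fold
#' higher inside a fixed 1 Mb block than elsewhere, binned, and its fold
#' enrichment inside the block's windows estimated with
#' [fold_enrichment()].
#'
#' Because fold enrichment is taken against the genome-wide average, which
#' itself contains the enriched block, the raw fold converges to
#' k / (1 + (k - 1) B / G) for a block of B bp in a genome of G bp, not to
#' k. The returned `k_hat = fold (G - B) / (G - fold B)` inverts that
#' relation and is the consistent estimator of the planted factor.
#'
#' @param n_seeds simulation replicates.
#' @param k planted enrichment factor.
#' @param n expected feature count per track.
#' @param kind "point" or "interval".
#' @param seed_base seeds used are `seed_base + 1:n_seeds`.
#' @return data.frame: seed, fold (raw), k_hat (block-share corrected).
#' @export
feature_enrichment_experiment <- function(n_seeds = 100, k = 3, n = 2000,
                                          kind = "point", seed_base = 0) {
  block <- list(chrom = "chr1", start = 1e7, end = 1.1e7)
  res <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- (seed_base + i) %% 2147483647L
    cfg <- sim_config(n_chrom = 2, chrom_length = 2e7,
                      deadzone_fraction = 0,
                      features = list(list(feature_id = "f", kind = kind,
                                           n = n, width = 1000, k = k,
                                           block = block)),
                      seed = seed)
    truth <- structure(list(features = list()), class = "lk_simtruth")
    fe <- simulate_features(cfg, truth)
    grid <- window_grid(cfg$genome, 10000)
    dens <- feature_density_track(fe$features$f, grid)
    w <- grid$windows
    sel <- w$chrom == block$chrom & w$start >= block$start &
      w$end <= block$end
    res[i] <- fold_enrichment(sel, dens)$fold
  }
  G <- 2 * 2e7; B <- block$end - block$start
  data.frame(seed = seed_base + seq_len(n_seeds), fold = res,
             k_hat = res * (G - B) / (G - res * B))
}
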