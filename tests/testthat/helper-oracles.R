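# Shared fixtures and independent oracles, all built in code.

toy_genome <- function(lengths, names = paste0("chr", seq_along(lengths))) {
  genome_def(names, lengths)
}

# non-overlapping random intervals from paired sorted breakpoints
random_intervals <- function(genome, n_per_chrom = 10, depth = TRUE) {
  out <- do.call(rbind, lapply(genome$chrom, function(ch) {
    L <- genome$length[[ch]]
    k <- sample(1:n_per_chrom, 1)
    pts <- sort(sample(0:L, 2 * k))
    keep <- pts[seq(1, 2 * k, 2)] < pts[seq(2, 2 * k, 2)]
    data.frame(chrom = ch, start = pts[seq(1, 2 * k, 2)][keep],
               end = pts[seq(2, 2 * k, 2)][keep])
  }))
  if (depth) out$mean_depth <- round(stats::runif(nrow(out), 0, 5), 3)
  out
}

# per-nucleotide accumulation oracle for window scoring: walks every
# nucleotide, zeroes deadzone positions, sums within windows
nt_oracle <- function(domains, genome, resolution, deadzones = NULL) {
  res <- lapply(genome$chrom, function(ch) {
    L <- genome$length[[ch]]
    v <- numeric(L)
    live <- rep(TRUE, L)
    d <- domains[domains$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(d)))
      v[(d$start[k] + 1):d$end[k]] <-
        v[(d$start[k] + 1):d$end[k]] + d$mean_depth[k]
    if (!is.null(deadzones)) {
      z <- deadzones[deadzones$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(z))) {
        idx <- (z$start[k] + 1):z$end[k]
        v[idx] <- 0
        live[idx] <- FALSE
      }
    }
    win <- floor((seq_len(L) - 1) / resolution)
    list(score = as.numeric(tapply(v, win, sum)),
         nondead = as.numeric(tapply(live, win, sum)))
  })
  list(score = unlist(lapply(res, `[[`, "score")),
       nondead = unlist(lapply(res, `[[`, "nondead")))
}

# intervals -> per-nucleotide boolean vector (single chromosome)
nt_bool <- function(df, L) {
  v <- rep(FALSE, L)
  for (k in seq_len(nrow(df))) v[(df$start[k] + 1):df$end[k]] <- TRUE
  v
}

# independent hand enumeration of the zone rules for one window
zone_rule_oracle <- function(scores, category, sigma = stats::sd(scores)) {
  high <- scores > sigma
  per_high <- tapply(high, category, sum)
  per_low <- tapply(!high, category, sum)
  if (sum(high) <= 2 && all(per_high <= 1)) return("GREEN")
  if (sum(!high) <= 2 && all(per_low <= 1)) return("RED")
  "YELLOW"
}

# brute-force pairwise SLR double loop
slr_brute <- function(m1, m2, eps = 1e-6) {
  vapply(seq_len(ncol(m1)), function(w) {
    terms <- c()
    for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2)))
      terms <- c(terms, -log(max(m1[i, w], eps) / max(m2[j, w], eps)))
    mean(terms)
  }, 0.0)
}

# tracks from the rows of a score matrix
tracks_of_matrix <- function(m, grid, normalized = TRUE,
                             ids = sprintf("s%02d", seq_len(nrow(m)))) {
  lapply(seq_len(nrow(m)), function(i)
    window_track(ids[i], grid, m[i, ], normalized = normalized))
}

# a dLOCK table with given total scores (for quantile/ranking tests)
dlocks_of_scores <- function(scores, chrom = "chr1") {
  n <- length(scores)
  if (n == 0) chrom <- character()
  df <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * 2e4,
                   end = (seq_len(n) - 1) * 2e4 + 1e4,
                   first = seq_len(n), last = seq_len(n),
                   n_windows = rep(1, n),
                   total_score = scores,
                   sign = ifelse(scores > 0, "positive", "negative"),
                   stringsAsFactors = FALSE)
  class(df) <- c("lk_dlocks", "data.frame")
  df
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}
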