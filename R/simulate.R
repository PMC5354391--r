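#' Simulation configuration
#'
#' Describes a synthetic cohort with known planted structure: a LOCK
#' skeleton shared by all samples (category-shared domain geometry),
#' multiplicative lognormal depth noise per sample and domain, planted
#' conserved-high (RED) blocks where every sample is elevated, planted
#' conserved-low (GREEN) gaps with no domains, planted differential blocks
#' where one category's depth is multiplied by exp(delta), random
#' low-alignability deadzones, and feature tracks enriched k-fold inside a
#' chosen block. Defaults reflect the study conditions the recovery
#' properties are stated at: 3 vs 3 samples, delta = 1, sigma = 0.25.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param samples named integer vector: samples per category; names among
#'   granulocyte, cd34, amlA, amlB, k562_control, k562_unc0638.
#' @param lock_fraction fraction of the genome covered by background LOCKs.
#' @param lock_min,lock_max LOCK length bounds (log-uniform draw), bp.
#' @param mu baseline domain mean depth (read count per nucleotide).
#' @param mu_high depth inside planted RED blocks.
#' @param sigma lognormal noise sd per (sample, domain).
#' @param red_blocks,green_gaps,diff_blocks data.frames of planted
#'   intervals (chrom, start, end); `diff_blocks` additionally needs
#'   `category` and `delta` (log-fold) columns. All planted intervals must
#'   be mutually disjoint.
#' @param deadzone_fraction fraction of the genome drawn as deadzones.
#' @param features list of feature specs: list(feature_id, kind
#'   ("interval"/"point"), n expected count, width (intervals), k
#'   enrichment factor, block = interval list(chrom, start, end) or NULL
#'   for uniform placement).
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `lk_simconfig`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 5e7,
                       samples = c(granulocyte = 3, cd34 = 3),
                       lock_fraction = 0.5, lock_min = 5e4, lock_max = 5e5,
                       mu = 2, mu_high = 6, sigma = 0.25,
                       red_blocks = NULL, green_gaps = NULL,
                       diff_blocks = NULL, deadzone_fraction = 0.02,
                       features = list(), seed = 1) {
  stopifnot(lock_fraction >= 0, lock_fraction <= 1,
            deadzone_fraction >= 0, deadzone_fraction < 1,
            sigma >= 0, lock_min > 0, lock_max >= lock_min)
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
              samples = samples, lock_fraction = lock_fraction,
              lock_min = lock_min, lock_max = lock_max, mu = mu,
              mu_high = mu_high, sigma = sigma, red_blocks = red_blocks,
              green_gaps = green_gaps, diff_blocks = diff_blocks,
              deadzone_fraction = deadzone_fraction, features = features,
              seed = as.integer(seed))
  cfg$genome <- genome_def(paste0("chr", seq_len(n_chrom)),
                           rep(chrom_length, n_chrom))
  planted <- rbind(planted_df(red_blocks), planted_df(green_gaps),
                   planted_df(diff_blocks))
  if (nrow(planted) > 0) {
    validate_intervals(planted, cfg$genome, "planted block")
    m <- merge_sorted(planted)
    if (sum(m$end - m$start) < sum(planted$end - planted$start))
      stop("planted intervals must be disjoint")
  }
  structure(cfg, class = "lk_simconfig")
}

planted_df <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(empty_intervals())
  df[c("chrom", "start", "end")]
}

#' Simulate per-sample scored domain sets
#'
#' Draws the shared LOCK skeleton once, then per sample gives each domain a
#' depth mu * exp(N(0, sigma^2)) (mu_high inside planted RED blocks),
#' multiplied by exp(delta) for samples of the category named by a planted
#' differential block. Planted blocks are carved out of the random
#' skeleton with a 20 kb isolation margin so each is exactly one domain;
#' planted GREEN gaps carry no domains. Fully reproducible from the
#' config seed.
#'
#' @param config an `lk_simconfig`.
#' @return list: `domains` (named list of `lk_domains`), `samples` (sheet
#'   data.frame without paths), `deadzones`, `truth` (an `lk_simtruth`:
#'   skeleton with block types, planted blocks, expected noise-free depth
#'   matrix domains x samples).
#' @export
simulate_domains <- function(config) {
  set.seed(config$seed)
  g <- config$genome
  ## deadzones: widths 2-20 kb placed uniformly until the fraction is met
  dz <- empty_intervals()
  if (config$deadzone_fraction > 0) {
    dz <- do.call(rbind, lapply(g$chrom, function(ch) {
      L <- g$length[[ch]]
      target <- config$deadzone_fraction * L
      out <- list(); tot <- 0
      while (tot < target) {
        wdt <- round(stats::runif(1, 2e3, 2e4))
        s <- floor(stats::runif(1, 0, L - wdt))
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = s,
                                             end = s + wdt)
        tot <- tot + wdt
      }
      do.call(rbind, out)
    }))
    dz <- merge_sorted(dz)
  }
  ## background LOCK skeleton: alternating exponential gaps and
  ## log-uniform LOCK lengths, hitting the target coverage in expectation
  lock_mean <- (config$lock_max - config$lock_min) /
    max(log(config$lock_max / config$lock_min), 1e-12)
  gap_mean <- max(lock_mean * (1 - config$lock_fraction) /
                    max(config$lock_fraction, 1e-9), 1e4)
  skel <- do.call(rbind, lapply(g$chrom, function(ch) {
    L <- g$length[[ch]]
    pos <- 0; out <- list()
    repeat {
      gap <- stats::rexp(1, 1 / gap_mean)
      len <- round(exp(stats::runif(1, log(config$lock_min),
                                    log(config$lock_max))))
      s <- round(pos + gap)
      if (s + len > L) break
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = s,
                                           end = s + len)
      pos <- s + len
    }
    if (length(out)) do.call(rbind, out) else empty_intervals()
  }))
  red <- planted_df(config$red_blocks)
  green <- planted_df(config$green_gaps)
  diff <- if (is.null(config$diff_blocks)) NULL else config$diff_blocks
  carve <- rbind(red, green, planted_df(diff))
  if (nrow(carve) > 0 && nrow(skel) > 0) {
    margin <- transform(carve, start = pmax(start - 2e4, 0),
                        end = pmin(end + 2e4, g$length[chrom]))
    skel <- subtract_intervals(skel, margin, g)
    skel <- skel[skel$end - skel$start >= 1e4, , drop = FALSE]
  }
  blocks <- rbind(
    if (nrow(skel)) cbind(skel, type = "background", category = NA,
                          delta = 0),
    if (nrow(red)) cbind(red, type = "red", category = NA, delta = 0),
    if (!is.null(diff) && nrow(diff))
      data.frame(chrom = diff$chrom, start = diff$start, end = diff$end,
                 type = "diff", category = diff$category,
                 delta = diff$delta))
  blocks <- blocks[order(match(blocks$chrom, g$chrom), blocks$start), ,
                   drop = FALSE]
  rownames(blocks) <- NULL
  ## sample sheet: deterministic ids, alternating sex within category
  cats <- names(config$samples)
  sheet <- do.call(rbind, lapply(cats, function(ct) {
    n <- config$samples[[ct]]
    data.frame(
      sample_id = sprintf("%s_%d", ct, seq_len(n)),
      category = if (ct %in% c("amlA", "amlB")) "aml" else ct,
      aml_cluster = if (ct == "amlA") "A" else if (ct == "amlB") "B"
                    else "none",
      sex = rep(c("M", "F"), length.out = n),
      platform = "sim", replicate_group = sprintf("%s_%d", ct, seq_len(n)),
      stringsAsFactors = FALSE)
  }))
  rownames(sheet) <- NULL
  grp <- dlock_group_of(sheet)
  nb <- nrow(blocks); ns <- nrow(sheet)
  base <- ifelse(blocks$type == "red", config$mu_high, config$mu)
  noise <- matrix(stats::rnorm(nb * ns, 0, config$sigma), nb, ns)
  expected <- matrix(base, nb, ns)
  is_diff <- blocks$type == "diff"
  for (j in seq_len(ns)) {
    hit <- is_diff & blocks$category == grp[j]
    expected[hit, j] <- expected[hit, j] * exp(blocks$delta[hit])
  }
  depth <- expected * exp(noise)
  colnames(depth) <- colnames(expected) <- sheet$sample_id
  domains <- lapply(seq_len(ns), function(j)
    domain_set(data.frame(chrom = blocks$chrom, start = blocks$start,
                          end = blocks$end, mean_depth = depth[, j]),
               g, sheet$sample_id[j]))
  names(domains) <- sheet$sample_id
  truth <- structure(list(genome = g, blocks = blocks, red = red,
                          green = green, diff = diff,
                          expected_depth = expected, features = list()),
                     class = "lk_simtruth")
  list(domains = domains, samples = sheet, deadzones = dz, truth = truth)
}

#' Simulate feature tracks with planted enrichment
#'
#' Places features by a homogeneous Poisson process with intensity lambda
#' outside and k * lambda inside a spec's planted block; lambda is set so
#' the expected total count is the spec's `n`. Gene-like specs emit
#' fixed-width named intervals, point specs emit length-1 intervals.
#'
#' @param config an `lk_simconfig` (its `features` list is realized).
#' @param truth the `lk_simtruth` from [simulate_domains()]; enrichment
#'   factors are recorded into it.
#' @return list: `features` (named list of `lk_features`), `truth`.
#' @export
simulate_features <- function(config, truth) {
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  g <- config$genome
  G <- genome_bp(g)
  out <- list()
  for (spec in config$features) {
    k <- if (is.null(spec$k)) 1 else spec$k
    if (k < 0) stop("enrichment factor k must be >= 0")
    width <- if (identical(spec$kind, "point")) 1
             else if (is.null(spec$width)) 5000 else spec$width
    blk <- spec$block
    B <- if (is.null(blk)) 0 else blk$end - blk$start
    lambda <- spec$n / (G - B + k * B)
    place <- function(n_exp, chrom, lo, hi) {
      n <- stats::rpois(1, n_exp)
      if (n == 0) return(empty_intervals())
      s <- floor(stats::runif(n, lo, hi - width))
      data.frame(chrom = chrom, start = sort(s), end = sort(s) + width)
    }
    recs <- do.call(rbind, lapply(g$chrom, function(ch) {
      L <- g$length[[ch]]
      if (!is.null(blk) && blk$chrom == ch) {
        rbind(place(lambda * blk$start, ch, 0, blk$start),
              place(k * lambda * B, ch, blk$start, blk$end),
              place(lambda * (L - blk$end), ch, blk$end, L))
      } else place(lambda * L, ch, 0, L)
    }))
    if (nrow(recs) > 0 && !identical(spec$kind, "point"))
      recs$name <- sprintf("%s_%05d", spec$feature_id, seq_len(nrow(recs)))
    out[[spec$feature_id]] <-
      feature_track(recs, g, spec$feature_id,
                    kind = if (identical(spec$kind, "point")) "point"
                           else "interval")
    truth$features[[spec$feature_id]] <- list(k = k, block = blk,
                                              n = spec$n)
  }
  list(features = out, truth = truth)
}

#' Write / read simulation ground truth as TSV
#'
#' The planted-block table (chrom, start, end, type, category, delta) and
#' the expected noise-free depth matrix round-trip exactly.
#'
#' @param truth an `lk_simtruth`.
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$blocks, file.path(dir, "truth_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- data.frame(block = seq_len(nrow(truth$expected_depth)),
                   truth$expected_depth, check.names = FALSE)
  utils::write.table(format(ed, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     file.path(dir, "truth_expected_depth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @param genome the simulated `lk_genome`.
#' @return `read_truth`: an `lk_simtruth` (without feature specs).
#' @export
read_truth <- function(dir, genome) {
  blocks <- utils::read.table(file.path(dir, "truth_blocks.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  ed <- utils::read.table(file.path(dir, "truth_expected_depth.tsv"),
                          sep = "\t", header = TRUE, check.names = FALSE)
  expected <- as.matrix(ed[, -1, drop = FALSE])
  rownames(expected) <- NULL
  structure(list(genome = genome, blocks = blocks,
                 red = blocks[blocks$type == "red",
                              c("chrom", "start", "end")],
                 green = empty_intervals(),
                 diff = blocks[blocks$type == "diff", , drop = FALSE],
                 expected_depth = expected, features = list()),
            class = "lk_simtruth")
}

#' Write a complete on-disk fixture
#'
#' Generates a synthetic cohort and writes every pipeline input in its
#' standard dialect: per-sample scored domain BEDs, a sample sheet TSV,
#' deadzone BED, chromosome sizes TSV, feature BEDs and the ground truth.
#'
#' `tiny` is 1 chromosome x 2 Mb with 2 granulocyte + 2 CD34+ samples and
#' one planted differential block (seconds to run end to end); `small` is
#' 3 chromosomes x 20 Mb with granulocyte, CD34+ and AML (A/B) samples,
#' planted RED and GREEN blocks and a differential block.
#'
#' @param size "tiny" or "small".
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return list: paths (sheet, sizes, deadzones, features dir, truth dir),
#'   config, truth.
#' @export
make_fixture <- function(size = c("tiny", "small"), dir, seed = 1) {
  size <- match.arg(size)
  cfg <- fixture_config(size, seed)
  sim <- simulate_domains(cfg)
  fe <- simulate_features(cfg, sim$truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$samples
  sheet$path <- sprintf("%s.rsegout.bed", sheet$sample_id)
  for (j in seq_len(nrow(sheet))) {
    d <- sim$domains[[sheet$sample_id[j]]]
    lines <- sprintf("%s\t%d\t%d\tLOCK%d\t%.10g", d$chrom,
                     as.integer(d$start), as.integer(d$end),
                     seq_len(nrow(d)), d$mean_depth)
    writeLines(lines, file.path(dir, sheet$path[j]))
  }
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sizes_path <- file.path(dir, "chrom.sizes")
  write_chrom_sizes(cfg$genome, sizes_path)
  dz_path <- file.path(dir, "deadzones.bed")
  write_bed(sim$deadzones, dz_path)
  feat_dir <- file.path(dir, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  for (fid in names(fe$features)) {
    f <- fe$features[[fid]]
    kind <- attr(f, "kind")
    write_bed(f, file.path(feat_dir,
                           sprintf("%s.%s.bed", fid, kind)))
  }
  truth_dir <- file.path(dir, "truth")
  write_truth(fe$truth, truth_dir)
  list(paths = list(dir = dir, sheet = sheet_path, sizes = sizes_path,
                    deadzones = dz_path, features = feat_dir,
                    truth = truth_dir),
       config = cfg, truth = fe$truth)
}

fixture_config <- function(size, seed) {
  if (size == "tiny") {
    sim_config(
      n_chrom = 1, chrom_length = 2e6,
      samples = c(granulocyte = 2, cd34 = 2),
      lock_fraction = 0.5, lock_min = 3e4, lock_max = 1.5e5,
      sigma = 0.25, deadzone_fraction = 0.02,
      diff_blocks = data.frame(chrom = "chr1", start = 1.2e6, end = 1.4e6,
                               category = "cd34", delta = 1),
      features = list(
        list(feature_id = "genes", kind = "interval", n = 120,
             width = 5000, k = 1, block = NULL)),
      seed = seed)
  } else {
    sim_config(
      n_chrom = 3, chrom_length = 2e7,
      samples = c(granulocyte = 3, cd34 = 3, amlA = 2, amlB = 2),
      lock_fraction = 0.5, lock_min = 5e4, lock_max = 5e5,
      sigma = 0.25, deadzone_fraction = 0.02,
      red_blocks = data.frame(chrom = "chr2", start = 5e6, end = 5.5e6),
      green_gaps = data.frame(chrom = "chr2", start = 1e7, end = 1.05e7),
      diff_blocks = data.frame(chrom = "chr1", start = 1e7, end = 1.05e7,
                               category = "cd34", delta = 1),
      features = list(
        list(feature_id = "genes", kind = "interval", n = 1500,
             width = 5000, k = 1, block = NULL),
        list(feature_id = "snv", kind = "point", n = 2000, k = 3,
             block = list(chrom = "chr1", start = 1e7, end = 1.05e7))),
      seed = seed)
  }
}
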