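#' Find LOCK bases for one sample category
#'
#' A LOCK base is a contiguous stretch of 10 kb windows in which every
#' sample ("row") of the category has a positive score in at least 50% of
#' the stretch's windows. Two candidate delimitations are offered:
#'
#' * `"positive-runs"` (default): candidates are the maximal contiguous
#'   runs of unmasked windows in which at least one sample is positive;
#'   an all-zero window ends a candidate. Deterministic and local — a
#'   base never depends on geometry beyond its flanking zero windows —
#'   and for a single sample it reduces to runs of positive windows.
#' * `"stretch"`: candidates are the maximal contiguous runs of unmasked
#'   windows (all-zero windows allowed inside, counting against the 50%
#'   rule), kept only when they contain a positive value.
#'
#' Either way each candidate is kept or rejected as a whole (no trimming)
#' by the per-row rule: every sample must be positive in at least half of
#' the candidate's windows.
#'
#' @param tracks list of normalized `lk_track`s of one category.
#' @param rule candidate delimitation, see above.
#' @return data.frame of class `lk_bases`: chrom, start, end, first, last
#'   (global window indices), n_windows.
#' @export
find_lock_bases <- function(tracks, rule = c("positive-runs", "stretch")) {
  rule <- match.arg(rule)
  m <- track_matrix(tracks)
  grid <- tracks[[1]]$grid
  w <- grid$windows
  unmasked <- colSums(is.na(m)) == 0
  eligible <- if (rule == "stretch") unmasked
              else unmasked & colSums(m > 0, na.rm = TRUE) > 0
  ## candidate runs: consecutive eligible windows, same chromosome
  newrun <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)])
  newrun <- newrun | !eligible | c(TRUE, !eligible[-length(eligible)])
  run <- cumsum(newrun)
  keep_idx <- which(eligible)
  if (length(keep_idx) == 0) return(empty_bases())
  runs <- split(keep_idx, run[keep_idx])
  ok <- vapply(runs, function(idx) {
    pos <- m[, idx, drop = FALSE] > 0
    any(pos) && all(rowMeans(pos) >= 0.5)
  }, TRUE)
  runs <- runs[ok]
  if (length(runs) == 0) return(empty_bases())
  first <- vapply(runs, min, 0)
  last <- vapply(runs, max, 0)
  out <- data.frame(chrom = w$chrom[first], start = w$start[first],
                    end = w$end[last], first = first, last = last,
                    n_windows = last - first + 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$first), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lk_bases", "data.frame")
  out
}

empty_bases <- function() {
  structure(data.frame(chrom = character(), start = numeric(),
                       end = numeric(), first = numeric(), last = numeric(),
                       n_windows = numeric(), stringsAsFactors = FALSE),
            class = c("lk_bases", "data.frame"))
}

#' Sum-Log-Ratio window scores for a category pair
#'
#' On every window of the first category's LOCK bases, the differential
#' score is the pairwise mean of the negative log ratio of a c1 sample's
#' score to a c2 sample's score:
#' SLR(w) = (1/N) * sum_{i in c1, j in c2} -log(max(s_i(w), eps) /
#' max(s_j(w), eps)), natural log. Positive SLR therefore means the second
#' category is higher. On chrX/chrY only same-sex sample pairs enter the
#' sum; if a window there has no same-sex pair it is reported undefined
#' (NA) with a warning and excluded downstream.
#'
#' @param c1_tracks,c2_tracks normalized `lk_track` lists of the first- and
#'   second-listed category.
#' @param bases `lk_bases` of the first category (see [find_lock_bases()]).
#' @param epsilon floor applied to scores before the log (default 1e-6);
#'   the floor preserves exact antisymmetry under category swap.
#' @param sex1,sex2 per-sample sex vectors ("M"/"F"), needed only when the
#'   grid has chrX/chrY windows inside bases.
#' @return list of class `lk_slr`: grid, `score` per window (NA off-base),
#'   `n_pairs` per window, `bases`.
#' @export
slr_window_scores <- function(c1_tracks, c2_tracks, bases,
                              epsilon = 1e-6, sex1 = NULL, sex2 = NULL) {
  if (length(c1_tracks) == 0 || length(c2_tracks) == 0)
    stop("both categories must be non-empty")
  grid <- c1_tracks[[1]]$grid
  m1 <- track_matrix(c1_tracks)
  m2 <- track_matrix(c2_tracks)
  l1 <- log(pmax(m1, epsilon))
  l2 <- log(pmax(m2, epsilon))
  W <- n_windows(grid)
  score <- rep(NA_real_, W)
  npairs <- rep(0L, W)
  in_base <- rep(FALSE, W)
  for (k in seq_len(nrow(bases))) in_base[bases$first[k]:bases$last[k]] <- TRUE
  is_xy <- grid$windows$chrom %in% c("chrX", "chrY", "X", "Y")
  auto <- in_base & !is_xy
  if (any(auto)) {
    score[auto] <- colMeans(l2[, auto, drop = FALSE]) -
      colMeans(l1[, auto, drop = FALSE])
    npairs[auto] <- nrow(m1) * nrow(m2)
  }
  xy <- in_base & is_xy
  if (any(xy)) {
    if (is.null(sex1) || is.null(sex2))
      stop("sex1/sex2 required for chrX/chrY windows")
    num <- numeric(sum(xy))
    N <- 0L
    for (s in c("M", "F")) {
      i <- sex1 == s; j <- sex2 == s
      if (any(i) && any(j)) {
        num <- num + sum(i) * colSums(l2[j, xy, drop = FALSE]) -
          sum(j) * colSums(l1[i, xy, drop = FALSE])
        N <- N + sum(i) * sum(j)
      }
    }
    if (N == 0) {
      warning("no same-sex pair on chrX/chrY: windows left undefined")
    } else {
      score[xy] <- num / N
      npairs[xy] <- N
    }
  }
  structure(list(grid = grid, score = score, n_pairs = npairs,
                 bases = bases, epsilon = epsilon), class = "lk_slr")
}

#' Segment SLR scores into signed differential blocks (dLOCKs)
#'
#' Within each LOCK base, maximal runs of windows with strictly the same
#' SLR sign become one dLOCK whose total score is the sum of its member
#' window scores; windows with SLR exactly 0 (or undefined) terminate runs
#' and belong to no dLOCK.
#'
#' @param slr an `lk_slr`.
#' @return data.frame of class `lk_dlocks`: chrom, start, end, first, last,
#'   n_windows, total_score, sign ("positive"/"negative").
#' @export
segment_dlocks <- function(slr) {
  w <- slr$grid$windows
  out <- list()
  for (k in seq_len(nrow(slr$bases))) {
    idx <- slr$bases$first[k]:slr$bases$last[k]
    s <- slr$score[idx]
    sgn <- sign(s)
    sgn[is.na(sgn)] <- 0
    usable <- sgn != 0
    if (!any(usable)) next
    newrun <- c(TRUE, sgn[-1] != sgn[-length(sgn)])
    run <- cumsum(newrun)
    for (r in unique(run[usable])) {
      sel <- idx[run == r & usable]
      out[[length(out) + 1]] <- data.frame(
        chrom = w$chrom[sel[1]], start = w$start[sel[1]],
        end = w$end[sel[length(sel)]], first = sel[1],
        last = sel[length(sel)], n_windows = length(sel),
        total_score = sum(slr$score[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     first = numeric(), last = numeric(),
                     n_windows = numeric(), total_score = numeric(),
                     sign = character(), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, out)
    df$sign <- ifelse(df$total_score > 0, "positive", "negative")
  }
  rownames(df) <- NULL
  class(df) <- c("lk_dlocks", "data.frame")
  df
}

#' Flag dLOCKs by empirical quantile thresholds
#'
#' Thresholds are type-7 (linear interpolation) sample quantiles of the
#' total scores of all non-chrY dLOCKs of the comparison: a positive dLOCK
#' passes level p when total_score > Q(p); a negative dLOCK passes when
#' total_score < Q(1-p). Comparisons at thresholds are strict. chrY dLOCKs
#' inherit the autosomal thresholds.
#'
#' @param dlocks an `lk_dlocks`.
#' @param alphas upper-tail levels (default 0.90, 0.95, 0.99; lower tails
#'   are their complements).
#' @return the dLOCK table with one logical column `alpha_<p>` per level
#'   and a `thresholds` attribute (data.frame: alpha, q_hi, q_lo).
#' @export
rank_dlocks <- function(dlocks, alphas = c(0.90, 0.95, 0.99)) {
  if (nrow(dlocks) == 0) stop("no dLOCKs to rank")
  offY <- !(dlocks$chrom %in% c("chrY", "Y"))
  if (sum(offY) < 2) stop("need >= 2 dLOCKs off chrY")
  sc <- dlocks$total_score[offY]
  thr <- data.frame(alpha = alphas,
                    q_hi = vapply(alphas, function(p)
                      unname(stats::quantile(sc, p, type = 7)), 0.0),
                    q_lo = vapply(alphas, function(p)
                      unname(stats::quantile(sc, 1 - p, type = 7)), 0.0))
  for (i in seq_along(alphas)) {
    col <- sprintf("alpha_%02d", round(100 * alphas[i]))
    dlocks[[col]] <- (dlocks$sign == "positive" &
                        dlocks$total_score > thr$q_hi[i]) |
      (dlocks$sign == "negative" & dlocks$total_score < thr$q_lo[i])
  }
  attr(dlocks, "thresholds") <- thr
  dlocks
}

#' Summary statistics for a set of passing dLOCKs
#'
#' The Table-1-style row for one comparison at one alpha level: percent of
#' the genome covered, mean dLOCK size, number of dLOCKs, number of genes
#' overlapping (>= 1 bp) any passing dLOCK, and the gene density inside
#' dLOCKs relative to the genome-wide average.
#'
#' @param dlocks ranked `lk_dlocks`.
#' @param genes `lk_features` with unique names (gene bodies).
#' @param genome an `lk_genome`.
#' @param alpha optional level: keep only dLOCKs whose `alpha_<p>` flag is
#'   set; NULL summarizes all dLOCKs.
#' @return one-row data.frame: alpha, pct_genome, mean_size_bp, n_dlocks,
#'   n_genes, gene_density_ratio.
#' @export
summarize_dlocks <- function(dlocks, genes, genome, alpha = NULL) {
  sel <- dlocks
  if (!is.null(alpha)) {
    col <- sprintf("alpha_%02d", round(100 * alpha))
    if (is.null(sel[[col]])) stop("dlocks not ranked at alpha ", alpha)
    sel <- sel[sel[[col]], , drop = FALSE]
  }
  gbp <- genome_bp(genome)
  if (nrow(sel) == 0)
    return(data.frame(alpha = if (is.null(alpha)) NA_real_ else alpha,
                      pct_genome = 0, mean_size_bp = 0, n_dlocks = 0L,
                      n_genes = 0L, gene_density_ratio = 0))
  bp <- sum(sel$end - sel$start)
  ng <- if (nrow(genes) > 0) {
    hit <- IRanges::overlapsAny(as_gr(genes, genome),
                                as_gr(sel[c("chrom", "start", "end")],
                                      genome))
    length(unique(genes$name[hit]))
  } else 0L
  ntot <- if (nrow(genes) > 0) length(unique(genes$name)) else 0L
  ratio <- if (ntot > 0 && bp > 0) (ng / bp) / (ntot / gbp) else 0
  data.frame(alpha = if (is.null(alpha)) NA_real_ else alpha,
             pct_genome = 100 * bp / gbp,
             mean_size_bp = bp / nrow(sel),
             n_dlocks = nrow(sel), n_genes = as.integer(ng),
             gene_density_ratio = ratio)
}

#' The ten standard dLOCK comparisons
#'
#' Ordered category pairs (first listed = c1, whose LOCK bases are used):
#' CD34+ vs granulocytes both ways, CD34+ and granulocytes vs AML cluster
#' A both ways, CD34+ vs AML cluster B both ways, and K562 control vs
#' UNC0638-treated both ways.
#'
#' @return data.frame with columns c1, c2, name.
#' @export
dlock_comparisons <- function() {
  cmp <- rbind(
    c("cd34", "granulocyte"), c("granulocyte", "cd34"),
    c("cd34", "amlA"), c("amlA", "cd34"),
    c("granulocyte", "amlA"), c("amlA", "granulocyte"),
    c("cd34", "amlB"), c("amlB", "cd34"),
    c("k562_unc0638", "k562_control"), c("k562_control", "k562_unc0638"))
  data.frame(c1 = cmp[, 1], c2 = cmp[, 2],
             name = paste0(cmp[, 1], "_gt_", cmp[, 2]),
             stringsAsFactors = FALSE)
}

dlock_group_of <- function(samples) {
  ifelse(samples$category == "aml",
         paste0("aml", samples$aml_cluster), samples$category)
}

#' Run all dLOCK comparisons for a cohort
#'
#' For every ordered category pair with both categories present: LOCK bases
#' from the first category, SLR window scores, sign segmentation, and
#' quantile ranking at all alpha levels. Missing categories are skipped
#' with a warning. AML samples split into amlA / amlB by their cluster.
#'
#' @param tracks list of normalized `lk_track`s (one per replicate group).
#' @param samples data.frame with sample_id, category, aml_cluster, sex
#'   matching the tracks.
#' @param comparisons comparison table (default [dlock_comparisons()]).
#' @param alphas alpha levels for [rank_dlocks()].
#' @param epsilon score floor for [slr_window_scores()].
#' @param lock_base_rule candidate rule for [find_lock_bases()].
#' @return named list of ranked `lk_dlocks`, one per emitted comparison.
#' @export
run_comparisons <- function(tracks, samples,
                            comparisons = dlock_comparisons(),
                            alphas = c(0.90, 0.95, 0.99),
                            epsilon = 1e-6,
                            lock_base_rule = c("positive-runs", "stretch")) {
  lock_base_rule <- match.arg(lock_base_rule)
  ids <- vapply(tracks, `[[`, "", "sample_id")
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("track without sample sheet row")
  grp <- dlock_group_of(samples)
  out <- list()
  for (k in seq_len(nrow(comparisons))) {
    c1 <- comparisons$c1[k]; c2 <- comparisons$c2[k]
    i1 <- which(grp == c1); i2 <- which(grp == c2)
    if (length(i1) == 0 || length(i2) == 0) {
      warning("skipping ", comparisons$name[k], ": category missing")
      next
    }
    bases <- find_lock_bases(tracks[i1], rule = lock_base_rule)
    if (nrow(bases) == 0) {
      warning("skipping ", comparisons$name[k], ": no LOCK bases")
      next
    }
    slr <- slr_window_scores(tracks[i1], tracks[i2], bases,
                             epsilon = epsilon,
                             sex1 = samples$sex[i1], sex2 = samples$sex[i2])
    dl <- segment_dlocks(slr)
    if (nrow(dl) == 0) next
    out[[comparisons$name[k]]] <- rank_dlocks(dl, alphas)
  }
  out
}

#' Write a ranked dLOCK table as BED-with-extras
#' @param dlocks ranked `lk_dlocks`.
#' @param name comparison name used in the BED name column.
#' @param path output path.
#' @export
write_dlock_bed <- function(dlocks, name, path) {
  df <- dlocks
  df$name <- name
  cols <- c("chrom", "start", "end", "name", "total_score", "sign",
            grep("^alpha_", names(df), value = TRUE))
  out <- df[, cols, drop = FALSE]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  lines <- do.call(paste, c(lapply(out, function(x)
    if (is.numeric(x) && !is.integer(x)) sprintf("%.10g", x)
    else as.character(x)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
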