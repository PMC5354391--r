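#' Bin a feature track onto a window grid
#'
#' Interval features contribute their non-deadzone covered bp per window
#' (overlapping records are collapsed first); point features contribute a
#' count per window, points falling in deadzones excluded. Masking is the
#' grid's, identical to sample tracks.
#'
#' @param feature an `lk_features`.
#' @param grid an `lk_grid`.
#' @return a raw `lk_track` named after the feature.
#' @export
feature_density_track <- function(feature, grid) {
  kind <- attr(feature, "kind")
  score <- numeric(n_windows(grid))
  if (nrow(feature) > 0) {
    if (kind == "point") {
      pts <- feature
      if (nrow(grid$deadzones) > 0) {
        gp <- as_gr(pts, grid$genome)
        dz <- GenomicRanges::reduce(as_gr(grid$deadzones, grid$genome))
        pts <- pts[!IRanges::overlapsAny(gp, dz), , drop = FALSE]
      }
      if (nrow(pts) > 0) {
        idx <- window_index_of(pts$chrom, pts$start, grid)
        tab <- table(idx)
        score[as.integer(names(tab))] <- as.integer(tab)
      }
    } else {
      cov <- GenomicRanges::reduce(as_gr(feature, grid$genome))
      if (nrow(grid$deadzones) > 0) {
        dz <- GenomicRanges::reduce(as_gr(grid$deadzones, grid$genome))
        cov <- GenomicRanges::setdiff(cov, dz)
      }
      if (length(cov) > 0) {
        wg <- grid_gr(grid)
        hits <- GenomicRanges::findOverlaps(cov, wg)
        if (length(hits) > 0) {
          ov <- IRanges::width(IRanges::pintersect(
            cov[S4Vectors::queryHits(hits)],
            wg[S4Vectors::subjectHits(hits)]))
          agg <- rowsum(ov, S4Vectors::subjectHits(hits))
          score[as.integer(rownames(agg))] <- agg[, 1]
        }
      }
    }
  }
  new_track(attr(feature, "feature_id"), grid, score, normalized = FALSE)
}

window_index_of <- function(chrom, pos, grid) {
  w <- grid$windows
  offs <- c(0, cumsum(tapply(rep(1, nrow(w)), factor(w$chrom,
            levels = grid$genome$chrom), sum)))
  names(offs) <- c(grid$genome$chrom, "_end")
  offs[match(chrom, grid$genome$chrom)] +
    floor(pos / grid$resolution) + 1
}

#' Pairwise Pearson correlation of window tracks
#'
#' Standard Pearson r between every pair of tracks, computed over the
#' windows unmasked in both members of each pair. X and Y chromosomes are
#' excluded by default, matching the autosome-only correlation analysis.
#'
#' @param tracks list of >= 2 `lk_track`s on one grid.
#' @param include_xy include chrX/chrY windows.
#' @return list of class `lk_cormat`: `r` (symmetric correlation matrix,
#'   diagonal 1, NA where a track has zero variance), `n` (windows used per
#'   pair), `resolution`.
#' @export
pearson_pairwise <- function(tracks, include_xy = FALSE) {
  if (length(tracks) < 2) stop("need >= 2 tracks")
  m <- track_matrix(tracks)
  if (!include_xy) {
    keep <- !(tracks[[1]]$grid$windows$chrom %in% c("chrX", "chrY", "X", "Y"))
    m <- m[, keep, drop = FALSE]
  }
  k <- nrow(m)
  r <- diag(1, k)
  n <- matrix(0L, k, k)
  dimnames(r) <- dimnames(n) <- list(rownames(m), rownames(m))
  diag(n) <- rowSums(!is.na(m))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3)
      stop("fewer than 3 jointly unmasked windows for ",
           rownames(m)[i], " vs ", rownames(m)[j])
    x <- m[i, ok]; y <- m[j, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
    } else {
      r[i, j] <- r[j, i] <- stats::cor(x, y)
    }
  }
  structure(list(r = r, n = n, resolution = tracks[[1]]$grid$resolution),
            class = "lk_cormat")
}

#' Hierarchical clustering of samples by correlation distance
#'
#' Complete-linkage agglomeration on d = 1 - Pearson r (centered by
#' default; `centered = FALSE` uses the uncentered cosine-style similarity
#' sum(xy)/sqrt(sum(x^2) sum(y^2))). Tracks are ordered by sample id before
#' clustering so leaf order is deterministic and tie-breaks are lexical.
#'
#' @param tracks list of `lk_track`s.
#' @param region optional list(chrom, start, end) restricting windows.
#' @param centered use centered Pearson similarity.
#' @param include_xy include chrX/chrY windows.
#' @return an [stats::hclust] object.
#' @export
hcluster_samples <- function(tracks, region = NULL, centered = TRUE,
                             include_xy = TRUE) {
  ids <- vapply(tracks, `[[`, "", "sample_id")
  tracks <- tracks[order(ids)]
  m <- track_matrix(tracks)
  w <- tracks[[1]]$grid$windows
  keep <- rep(TRUE, nrow(w))
  if (!include_xy) keep <- keep & !(w$chrom %in% c("chrX", "chrY", "X", "Y"))
  if (!is.null(region))
    keep <- keep & w$chrom == region$chrom &
      w$end > region$start & w$start < region$end
  m <- m[, keep, drop = FALSE]
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (ncol(m) < 3) stop("fewer than 3 usable windows")
  if (centered) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  } else {
    num <- m %*% t(m)
    nrm <- sqrt(diag(num))
    cc <- num / outer(nrm, nrm)
  }
  stats::hclust(stats::as.dist(1 - cc), method = "complete")
}

#' Export a dendrogram as a Newick string/file
#' @param hc an [stats::hclust] object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}

#' Feature density meta-profile around domain boundaries
#'
#' For every domain 5' boundary (and, mirrored, every 3' boundary) the
#' feature's covered-bp density is averaged in fixed-width bins over a
#' +/- flank. Positive offsets point into the domain; 3' boundaries are
#' mirrored so the inside direction is consistent, and both boundary sets
#' are pooled. Bins extending past a chromosome end are dropped from that
#' boundary's contribution.
#'
#' @param domains an `lk_domains`.
#' @param feature an `lk_features`.
#' @param genome an `lk_genome`.
#' @param flank half-width of the profile in bp (multiple of `bin`).
#' @param bin bin width in bp.
#' @return data.frame of class `lk_boundary_profile`: offset (bin center,
#'   bp, negative = outside), density (mean covered fraction), n_bins.
#'   Attribute `n_boundaries` records the number of boundaries pooled.
#' @export
boundary_metaprofile <- function(domains, feature, genome, flank = 100000,
                                 bin = 10000) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  if (nrow(domains) == 0) stop("no domain boundaries")
  offs <- seq(-flank, flank - bin, by = bin)       # bin left edges, inside>0
  ## boundary table: position b and inside direction (+1 right / -1 left)
  bnd <- rbind(
    data.frame(chrom = domains$chrom, b = domains$start, dir = 1),
    data.frame(chrom = domains$chrom, b = domains$end, dir = -1))
  bins <- do.call(rbind, lapply(seq_along(offs), function(k) {
    o <- offs[k]
    s <- ifelse(bnd$dir == 1, bnd$b + o, bnd$b - o - bin)
    data.frame(chrom = bnd$chrom, start = s, end = s + bin, k = k)
  }))
  Lc <- genome$length[bins$chrom]
  ok <- bins$start >= 0 & bins$end <= Lc
  bins <- bins[ok, , drop = FALSE]
  cov <- GenomicRanges::reduce(as_gr(feature, genome))
  covered <- numeric(nrow(bins))
  if (length(cov) > 0 && nrow(bins) > 0) {
    gb <- as_gr(bins[c("chrom", "start", "end")], genome)
    hits <- GenomicRanges::findOverlaps(gb, cov)
    if (length(hits) > 0) {
      ov <- IRanges::width(IRanges::pintersect(
        gb[S4Vectors::queryHits(hits)], cov[S4Vectors::subjectHits(hits)]))
      agg <- rowsum(ov, S4Vectors::queryHits(hits))
      covered[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  dens <- tapply(covered / bin, factor(bins$k, levels = seq_along(offs)),
                 mean)
  nb <- tapply(rep(1, nrow(bins)), factor(bins$k, levels = seq_along(offs)),
               sum)
  out <- data.frame(offset = offs + bin / 2,
                    density = as.numeric(dens),
                    n_bins = as.integer(ifelse(is.na(nb), 0, nb)))
  attr(out, "n_boundaries") <- nrow(bnd)
  class(out) <- c("lk_boundary_profile", "data.frame")
  out
}
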