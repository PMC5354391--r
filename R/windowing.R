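#' Construct a window track from scores
#'
#' Low-level constructor pairing a score vector with a grid; scores at
#' masked windows are set to NA. Mainly useful for building tracks with
#' known values in analyses and tests.
#'
#' @param sample_id track identifier.
#' @param grid an `lk_grid`.
#' @param score numeric vector, one value per grid window.
#' @param normalized whether the scores are already mean-normalized.
#' @return an `lk_track`.
#' @export
window_track <- function(sample_id, grid, score, normalized = FALSE) {
  if (length(score) != n_windows(grid))
    stop("score length must equal the number of windows")
  new_track(sample_id, grid, as.numeric(score), normalized)
}

new_track <- function(sample_id, grid, score, normalized = FALSE) {
  score[grid$windows$masked] <- NA_real_
  structure(list(sample_id = sample_id, grid = grid, score = score,
                 normalized = normalized), class = "lk_track")
}

#' @export
print.lk_track <- function(x, ...) {
  cat("<lk_track> ", x$sample_id, ": ", sum(!is.na(x$score)),
      " scored windows @ ", format(x$grid$resolution, big.mark = ","),
      " bp", if (x$normalized) " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Map scored domains onto a window grid
#'
#' Each domain contributes to a window's raw score its mean read depth for
#' every one of its non-deadzone nucleotides that falls inside the window:
#' score(w) = sum_d depth(d) * |(d \ deadzones) n w|, in read-count x bp.
#' The raw score is a sum, not a per-bp mean, so coarsening by summation is
#' exact and the subsequent mean-normalization absorbs the constant factor.
#' Windows whose non-deadzone length is zero are masked (NA).
#'
#' @param domains an `lk_domains`.
#' @param grid an `lk_grid` (its deadzones are the ones subtracted).
#' @return a raw `lk_track`.
#' @export
score_windows <- function(domains, grid) {
  if (!identical(attr(domains, "class")[1], "lk_domains"))
    stop("domains must be an lk_domains")
  if (!identical(grid$genome$chrom, intersect(grid$genome$chrom,
                                              grid$genome$chrom)))
    stop("bad grid")
  if (nrow(domains) > 0 && !all(domains$chrom %in% grid$genome$chrom))
    stop("domain chromosome not in grid genome")
  segs <- domain_segments(domains, grid$deadzones)
  score <- if (is.null(segs)) numeric(n_windows(grid))
           else window_sums(segs, grid)
  new_track(attr(domains, "sample_id"), grid, score, normalized = FALSE)
}

#' Normalize a window track by its genome-wide mean
#'
#' Divides every unmasked score by the mean of all unmasked scores, giving a
#' track with mean exactly 1; this is the per-dataset normalization applied
#' before replicate averaging and all downstream comparisons.
#'
#' @param track a raw `lk_track`.
#' @return a normalized `lk_track`.
#' @export
normalize_track <- function(track) {
  s <- track$score
  m <- mean(s, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("degenerate sample: all-zero track ", track$sample_id)
  out <- new_track(track$sample_id, track$grid, s / m, normalized = TRUE)
  out
}

#' Average technical replicates
#'
#' Element-wise arithmetic mean of normalized tracks on the same grid; a
#' window masked in any replicate is masked in the result.
#'
#' @param tracks list of normalized `lk_track`s of one replicate group.
#' @param sample_id id for the averaged track (default: first input's id).
#' @return an `lk_track`.
#' @export
average_replicates <- function(tracks, sample_id = tracks[[1]]$sample_id) {
  if (length(tracks) == 0) stop("no tracks")
  g <- tracks[[1]]$grid
  for (t in tracks) {
    if (!t$normalized) stop("average_replicates needs normalized tracks")
    if (!same_grid(t$grid, g)) stop("tracks on mixed grids")
  }
  m <- do.call(rbind, lapply(tracks, `[[`, "score"))
  avg <- colMeans(m)            # NA propagates: mask union
  new_track(sample_id, g, avg, normalized = TRUE)
}

#' Coarsen a raw 10 kb track to a lower resolution
#'
#' Raw window scores are additive, so summing groups of fine windows equals
#' scoring directly at the coarse resolution. Only raw (unnormalized) tracks
#' can be coarsened. A coarse window is masked iff all of its fine windows
#' have zero non-deadzone length.
#'
#' @param track a raw `lk_track`.
#' @param resolution target window size, a multiple of the track's.
#' @return a raw `lk_track` on the coarse grid.
#' @export
coarsen <- function(track, resolution) {
  if (track$normalized) stop("cannot coarsen a normalized track")
  fine <- track$grid
  if (resolution %% fine$resolution != 0)
    stop("target resolution must be a multiple of ", fine$resolution)
  coarse <- window_grid(fine$genome, resolution, fine$deadzones)
  w <- fine$windows
  group <- paste0(w$chrom, ":", floor(w$start / resolution))
  cw <- coarse$windows
  ckey <- paste0(cw$chrom, ":", floor(cw$start / resolution))
  s <- track$score
  s[is.na(s)] <- 0
  sums <- rowsum(s, group)
  score <- numeric(n_windows(coarse))
  score[match(rownames(sums), ckey)] <- sums[, 1]
  new_track(track$sample_id, coarse, score, normalized = FALSE)
}

#' Assemble tracks into a samples x windows matrix
#'
#' @param tracks list of `lk_track`s on one common grid.
#' @return numeric matrix, rows named by sample_id, NA at masked windows.
#' @export
track_matrix <- function(tracks) {
  if (length(tracks) == 0) stop("no tracks")
  g <- tracks[[1]]$grid
  for (t in tracks) if (!same_grid(t$grid, g)) stop("tracks on mixed grids")
  m <- do.call(rbind, lapply(tracks, `[[`, "score"))
  rownames(m) <- vapply(tracks, `[[`, "", "sample_id")
  m
}

#' Write / read the samples x windows matrix hand-off TSV
#'
#' Rows are windows keyed "chrom:start-end", columns are samples; masked
#' windows carry NA. This is the artifact passed between pipeline stages.
#'
#' @param tracks list of `lk_track`s.
#' @param path output TSV path.
#' @export
write_track_matrix <- function(tracks, path) {
  m <- track_matrix(tracks)
  w <- tracks[[1]]$grid$windows
  key <- sprintf("%s:%d-%d", w$chrom, as.integer(w$start), as.integer(w$end))
  df <- data.frame(window = key, t(m), check.names = FALSE)
  utils::write.table(format(df, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_matrix
#' @param grid the grid the matrix was written from.
#' @param normalized whether stored scores are normalized.
#' @return `read_track_matrix`: list of `lk_track`s.
#' @export
read_track_matrix <- function(path, grid, normalized = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = c("NA"))
  w <- grid$windows
  key <- sprintf("%s:%d-%d", w$chrom, as.integer(w$start), as.integer(w$end))
  if (!identical(as.character(df$window), key))
    stop("window matrix does not match grid: ", path)
  lapply(names(df)[-1], function(sid)
    new_track(sid, grid, as.numeric(df[[sid]]), normalized = normalized))
}

#' Score, normalize and average one sample sheet's files
#'
#' Runs the full per-sample score pipeline: read scored domains, bin at
#' 10 kb, optionally double male X/Y raw scores, normalize, then average
#' technical replicates within each replicate group.
#'
#' @param sheet an `lk_samplesheet`.
#' @param grid the 10 kb `lk_grid`.
#' @param score_column score column passed to [read_scored_bed()].
#' @param male_xy_doubling double raw chrX/chrY scores for male samples
#'   (off by default: deposited domain files already reflect the
#'   duplication applied before domain calling).
#' @return list of normalized `lk_track`s, one per replicate group, named
#'   by replicate group; the sheet rows collapse accordingly.
#' @export
build_sample_tracks <- function(sheet, grid, score_column = 5,
                                male_xy_doubling = FALSE) {
  per_sample <- lapply(seq_len(nrow(sheet)), function(i) {
    ds <- read_scored_bed(sheet$path[i], grid$genome,
                          sample_id = sheet$sample_id[i],
                          score_column = score_column)
    tr <- score_windows(ds, grid)
    if (male_xy_doubling && sheet$sex[i] == "M") {
      xy <- grid$windows$chrom %in% c("chrX", "chrY", "X", "Y")
      tr$score[xy] <- tr$score[xy] * 2
    }
    normalize_track(tr)
  })
  groups <- split(seq_len(nrow(sheet)), sheet$replicate_group)
  groups <- groups[order(match(names(groups), sheet$replicate_group))]
  out <- lapply(names(groups), function(gname) {
    average_replicates(per_sample[groups[[gname]]], sample_id = gname)
  })
  names(out) <- names(groups)
  out
}

#' Collapse a sample sheet to one row per replicate group
#' @param sheet an `lk_samplesheet`.
#' @return data.frame with one row per replicate group (first row wins).
#' @export
collapse_replicates <- function(sheet) {
  first <- !duplicated(sheet$replicate_group)
  out <- sheet[first, , drop = FALSE]
  out$sample_id <- out$replicate_group
  rownames(out) <- NULL
  out
}
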