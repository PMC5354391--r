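#' Genome coordinate model
#'
#' A genome is an ordered set of chromosomes with lengths. The order is fixed
#' at construction and reused by every window grid built from it, so window
#' indices are comparable across tracks. Coordinates throughout the package
#' are 0-based half-open (BED convention).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp (> 0).
#' @return An object of class `lk_genome`.
#' @examples
#' g <- genome_def(c("chr1", "chr2"), c(2e6, 1e6))
#' genome_bp(g)
#' @export
genome_def <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have equal length")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  structure(list(chrom = chrom, length = setNames(length, chrom)),
            class = "lk_genome")
}

#' @export
print.lk_genome <- function(x, ...) {
  cat("<lk_genome> ", length(x$chrom), " chromosomes, ",
      format(genome_bp(x), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Total genome size in bp
#' @param genome an `lk_genome`.
#' @return numeric, total bp.
#' @export
genome_bp <- function(genome) sum(genome$length)

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chrom and length (no header).
#' @return An `lk_genome`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_def(df$chrom, df$length)
}

#' Write chromosome sizes
#' @param genome an `lk_genome`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(genome$chrom, unname(genome$length)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

seqinfo_of <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$chrom,
                        seqlengths = as.integer(genome$length))
}

## data.frame(chrom,start,end,...) -> GRanges (0-based half-open in, 1-based in GRanges)
as_gr <- function(df, genome) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges(seqinfo = seqinfo_of(genome)))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = genome$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    seqinfo = seqinfo_of(genome))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}

gr_as_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  for (nm in colnames(mc)) df[[nm]] <- mc[[nm]]
  df
}

#' Build a fixed-resolution window grid
#'
#' Tiles every chromosome with consecutive windows of `resolution` bp; only
#' the last window of a chromosome may be shorter. Deadzone (low-alignability)
#' intervals are removed from the effective length of each window; a window
#' whose non-deadzone length is zero is masked and excluded from all
#' statistics downstream.
#'
#' @param genome an `lk_genome`.
#' @param resolution window size in bp (10 kb for zone and dLOCK analyses;
#'   50 kb to 1 Mb grids are used for correlation).
#' @param deadzones optional data.frame(chrom, start, end) of deadzone
#'   intervals.
#' @return An `lk_grid`: window table (chrom, start, end, nondead, masked)
#'   in genome order plus the genome and deadzones used.
#' @export
window_grid <- function(genome, resolution, deadzones = NULL) {
  resolution <- as.numeric(resolution)
  if (!is.finite(resolution) || resolution <= 0) stop("bad resolution")
  wins <- do.call(rbind, lapply(genome$chrom, function(ch) {
    L <- genome$length[[ch]]
    s <- seq(0, L - 1, by = resolution)
    data.frame(chrom = ch, start = s, end = pmin(s + resolution, L),
               stringsAsFactors = FALSE)
  }))
  rownames(wins) <- NULL
  wins$nondead <- wins$end - wins$start
  grid <- structure(list(genome = genome, resolution = resolution,
                         windows = wins, deadzones = empty_intervals()),
                    class = "lk_grid")
  if (!is.null(deadzones) && nrow(deadzones) > 0) {
    deadzones <- validate_intervals(deadzones, genome, "deadzone")
    dz <- merge_sorted(deadzones[c("chrom", "start", "end")])
    dz$value <- 1
    dead_bp <- window_sums(dz, grid)
    grid$windows$nondead <- wins$nondead - dead_bp
    grid$deadzones <- dz[c("chrom", "start", "end")]
  }
  grid$windows$masked <- grid$windows$nondead <= 0
  grid
}

#' @export
print.lk_grid <- function(x, ...) {
  cat("<lk_grid> ", nrow(x$windows), " windows of ",
      format(x$resolution, big.mark = ","), " bp (",
      sum(x$windows$masked), " masked)\n", sep = "")
  invisible(x)
}

n_windows <- function(grid) nrow(grid$windows)

grid_gr <- function(grid) {
  as_gr(grid$windows[c("chrom", "start", "end")], grid$genome)
}

same_grid <- function(a, b) {
  identical(a$resolution, b$resolution) &&
    identical(a$genome$chrom, b$genome$chrom) &&
    identical(unname(a$genome$length), unname(b$genome$length)) &&
    identical(a$windows$masked, b$windows$masked)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

validate_intervals <- function(df, genome, what = "interval") {
  if (nrow(df) == 0) return(df)
  bad <- !(df$chrom %in% genome$chrom)
  if (any(bad))
    stop(what, ": unknown chromosome '", df$chrom[bad][1], "'")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop(what, ": need 0 <= start < end")
  past <- df$end > genome$length[df$chrom]
  if (any(past))
    stop(what, ": record past end of ", df$chrom[past][1], " (",
         df$start[past][1], "-", df$end[past][1], ")")
  df[order(match(df$chrom, genome$chrom), df$start), , drop = FALSE]
}
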