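#' Read a scored domain BED file into a DomainSet
#'
#' Parses the BED dialect used for HMM-called enriched-domain output: tab
#' separated, >= 3 columns, with a per-domain score (the domain's average
#' read count per nucleotide) in a configurable column. Column 5 is the
#' default, with column 4 carrying the domain name/state. Gzipped files are
#' read transparently.
#'
#' Domains of one sample must be non-overlapping within a chromosome; an
#' overlap is a validation error naming the offending pair. Domains with a
#' mean depth of 0 are kept (they contribute 0 signal) so bp accounting
#' stays exact.
#'
#' @param path BED(.gz) file path.
#' @param genome an `lk_genome`; coordinates are validated against it.
#' @param sample_id sample identifier (defaults to the file name).
#' @param score_column 1-based column index of the mean depth (default 5);
#'   use 0 for unscored files (all depths set to 1).
#' @return An `lk_domains` data.frame: chrom, start, end, mean_depth,
#'   sorted in genome order, with the sample id as attribute.
#' @export
read_scored_bed <- function(path, genome, sample_id = basename(path),
                            score_column = 5) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    ds <- empty_intervals()
    ds$mean_depth <- numeric()
    return(domain_set(ds, genome, sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop("malformed BED line ", which(ncols < 3)[1], " in ", path)
  if (score_column > 0 && any(ncols < score_column))
    stop("line ", which(ncols < score_column)[1], " in ", path,
         " lacks score column ", score_column)
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end = as.numeric(vapply(fields, `[`, "", 3)),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-numeric coordinates in ", path)
  df$mean_depth <- if (score_column > 0) {
    d <- suppressWarnings(as.numeric(vapply(fields, `[`, "", score_column)))
    if (anyNA(d)) stop("score column ", score_column,
                       " does not parse as a number in ", path)
    d
  } else rep(1, nrow(df))
  domain_set(df, genome, sample_id)
}

#' Construct a validated DomainSet
#'
#' @param df data.frame with chrom, start, end, mean_depth.
#' @param genome an `lk_genome`.
#' @param sample_id sample identifier.
#' @return `lk_domains` data.frame, sorted, validated.
#' @export
domain_set <- function(df, genome, sample_id) {
  df <- validate_intervals(df, genome, "domain")
  if (is.null(df$mean_depth)) df$mean_depth <- rep(1, nrow(df))
  if (any(df$mean_depth < 0))
    stop("negative mean depth in sample ", sample_id)
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    ovl <- same & df$start[-1] < df$end[-nrow(df)]
    if (any(ovl)) {
      i <- which(ovl)[1]
      stop("overlapping domains in sample ", sample_id, ": ",
           df$chrom[i], ":", df$start[i], "-", df$end[i], " and ",
           df$chrom[i + 1], ":", df$start[i + 1], "-", df$end[i + 1])
    }
  }
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, class = c("lk_domains", "data.frame"))
}

#' Read a plain interval BED file into a FeatureTrack
#'
#' @param path BED(.gz) with >= 3 columns; column 4, when present, is kept
#'   as the feature name (gene symbols etc.).
#' @param genome an `lk_genome`.
#' @param feature_id track identifier (defaults to file name).
#' @param kind "interval" or "point"; points are length-1 intervals and are
#'   binned by count rather than covered bp.
#' @return `lk_features` data.frame: chrom, start, end (+ name), sorted.
#' @export
read_interval_bed <- function(path, genome, feature_id = basename(path),
                              kind = c("interval", "point")) {
  kind <- match.arg(kind)
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(feature_track(empty_intervals(), genome, feature_id, kind))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end = as.numeric(vapply(fields, `[`, "", 3)),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  if (all(lengths(fields) >= 4))
    df$name <- vapply(fields, `[`, "", 4)
  feature_track(df, genome, feature_id, kind)
}

#' Construct a validated FeatureTrack
#' @inheritParams read_interval_bed
#' @param df data.frame with chrom, start, end and optionally name.
#' @return `lk_features` data.frame.
#' @export
feature_track <- function(df, genome, feature_id,
                          kind = c("interval", "point")) {
  kind <- match.arg(kind)
  df <- validate_intervals(df, genome, paste0("feature '", feature_id, "'"))
  rownames(df) <- NULL
  structure(df, feature_id = feature_id, kind = kind,
            class = c("lk_features", "data.frame"))
}

#' Subtract one sorted interval set from another
#'
#' Exact set difference a \ b on genomic intervals (the deadzone-subtraction
#' primitive applied to every dataset before binning). The result is sorted
#' and non-overlapping; an empty result is allowed.
#'
#' @param a,b data.frames with chrom, start, end.
#' @param genome an `lk_genome`.
#' @return data.frame of the remaining intervals.
#' @export
subtract_intervals <- function(a, b, genome) {
  ga <- GenomicRanges::reduce(as_gr(a, genome))
  gb <- GenomicRanges::reduce(as_gr(b, genome))
  res <- GenomicRanges::setdiff(ga, gb)
  gr_as_df(GenomicRanges::sort(res))[, c("chrom", "start", "end")]
}

#' Read the sample sheet
#'
#' TSV with header columns: sample_id, category, aml_cluster, sex, platform,
#' replicate_group, path. Categories are granulocyte, cd34, aml,
#' k562_control, k562_unc0638; `aml_cluster` is A or B for AML samples and
#' "none" otherwise. Paths are resolved relative to the sheet's directory
#' and must exist.
#'
#' @param path sheet path.
#' @param check_paths validate that every referenced file exists.
#' @return data.frame of class `lk_samplesheet`.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sh <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample_id", "category", "aml_cluster", "sex", "platform",
            "replicate_group", "path")
  miss <- setdiff(need, names(sh))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sh$sample_id)) stop("duplicate sample_id in sheet")
  okcat <- c("granulocyte", "cd34", "aml", "k562_control", "k562_unc0638")
  if (!all(sh$category %in% okcat))
    stop("unknown category: ", setdiff(sh$category, okcat)[1])
  if (!all(sh$sex %in% c("M", "F"))) stop("sex must be M or F")
  bad <- xor(sh$category == "aml", sh$aml_cluster != "none")
  if (any(bad))
    stop("aml_cluster must be A/B exactly for AML samples (sample ",
         sh$sample_id[bad][1], ")")
  if (!all(sh$aml_cluster %in% c("A", "B", "none")))
    stop("aml_cluster must be A, B or none")
  sh$path <- ifelse(grepl("^/", sh$path), sh$path,
                    file.path(dirname(path), sh$path))
  if (check_paths) {
    gone <- !file.exists(sh$path)
    if (any(gone)) stop("sample file missing: ", sh$path[gone][1])
  }
  structure(sh, class = c("lk_samplesheet", "data.frame"))
}

#' Write a window track as bedGraph
#'
#' One line per unmasked window; masked windows are omitted. Values are
#' written with enough digits that a round trip preserves them to better
#' than 1e-6 relative.
#'
#' @param track an `lk_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  w <- track$grid$windows
  keep <- !w$masked & !is.na(track$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", track$sample_id), con)
  if (any(keep))
    writeLines(sprintf("%s\t%d\t%d\t%.10g", w$chrom[keep],
                       as.integer(w$start[keep]), as.integer(w$end[keep]),
                       track$score[keep]), con)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back onto its grid
#' @param path bedGraph path.
#' @param grid the `lk_grid` the track was written from.
#' @param sample_id sample identifier.
#' @param normalized whether the stored scores were normalized.
#' @return an `lk_track`.
#' @export
read_bedgraph <- function(path, grid, sample_id = basename(path),
                          normalized = FALSE) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  score <- rep(NA_real_, n_windows(grid))
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    key <- paste0(vapply(f, `[`, "", 1), ":", vapply(f, `[`, "", 2))
    wkey <- paste0(grid$windows$chrom, ":",
                   format(grid$windows$start, scientific = FALSE,
                          trim = TRUE))
    idx <- match(key, wkey)
    if (anyNA(idx)) stop("bedGraph window not on grid: ", key[is.na(idx)][1])
    score[idx] <- as.numeric(vapply(f, `[`, "", 4))
  }
  new_track(sample_id, grid, score, normalized)
}

#' Write labeled intervals as BED
#' @param df data.frame with chrom, start, end and optionally name, score.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "sign"),
                    names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(out, function(x)
      if (is.numeric(x) && !is.integer(x)) sprintf("%.10g", x)
      else as.character(x)), sep = "\t")), con)
  invisible(path)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  readLines(con)
}
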