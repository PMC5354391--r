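#' Pipeline configuration
#'
#' Builds and validates the configuration driving the staged pipeline. All
#' randomness flows from the single `seed`; the window matrices written by
#' the windows stage are the hand-off artifact between stages, so any stage
#' can be re-run in isolation and inspected as plain TSV.
#'
#' @param chrom_sizes,deadzones,sample_sheet,feature_dir input paths
#'   (feature_dir optional: BED files named `<id>.<interval|point>.bed`).
#' @param out_dir output directory.
#' @param resolutions window sizes in bp (the first must be 10000, the
#'   grid zones and dLOCKs are defined on).
#' @param alphas dLOCK alpha levels.
#' @param epsilon SLR score floor.
#' @param sigma_rule zone threshold rule ("per-window" or "global").
#' @param lock_base_rule LOCK-base candidate rule ("positive-runs" or
#'   "stretch"), see [find_lock_bases()].
#' @param include_xy include chrX/chrY in correlations.
#' @param male_xy_doubling double male X/Y raw scores before normalizing.
#' @param score_column score column of the domain BEDs.
#' @param seed integer seed.
#' @return validated list of class `lk_config`.
#' @export
pipeline_config <- function(chrom_sizes, deadzones = NULL, sample_sheet,
                            feature_dir = NULL, out_dir,
                            resolutions = c(10000, 50000, 100000),
                            alphas = c(0.90, 0.95, 0.99), epsilon = 1e-6,
                            sigma_rule = "per-window",
                            lock_base_rule = "positive-runs",
                            include_xy = FALSE,
                            male_xy_doubling = FALSE, score_column = 5,
                            seed = 1) {
  cfg <- list(chrom_sizes = chrom_sizes, deadzones = deadzones,
              sample_sheet = sample_sheet, feature_dir = feature_dir,
              out_dir = out_dir, resolutions = as.numeric(resolutions),
              alphas = as.numeric(alphas), epsilon = epsilon,
              sigma_rule = sigma_rule, lock_base_rule = lock_base_rule,
              include_xy = include_xy,
              male_xy_doubling = male_xy_doubling,
              score_column = score_column, seed = as.integer(seed))
  if (cfg$resolutions[1] != 10000)
    stop("first resolution must be 10000 (the zone/dLOCK grid)")
  if (any(cfg$resolutions %% 10000 != 0))
    stop("resolutions must be multiples of 10 kb")
  if (!sigma_rule %in% c("per-window", "global"))
    stop("invalid config key value: sigma_rule")
  if (!lock_base_rule %in% c("positive-runs", "stretch"))
    stop("invalid config key value: lock_base_rule")
  if (any(cfg$alphas <= 0.5 | cfg$alphas >= 1))
    stop("alphas must lie in (0.5, 1)")
  for (p in c("chrom_sizes", "sample_sheet"))
    if (!file.exists(cfg[[p]])) stop("missing input file: ", cfg[[p]])
  structure(cfg, class = "lk_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; relative paths resolve against the file's
#'   directory.
#' @param out_dir,seed optional overrides.
#' @return an `lk_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("invalid config key: ", bad[1])
  base <- dirname(normalizePath(path))
  for (p in c("chrom_sizes", "deadzones", "sample_sheet", "feature_dir",
              "out_dir"))
    if (!is.null(raw[[p]]) && !grepl("^/", raw[[p]]))
      raw[[p]] <- file.path(base, raw[[p]])
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(seed)) raw$seed <- seed
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(proc.time()[3]) - t0, paste0(...)))
}

load_inputs <- function(cfg) {
  genome <- read_chrom_sizes(cfg$chrom_sizes)
  dz <- if (!is.null(cfg$deadzones) && file.exists(cfg$deadzones)) {
    f <- read_interval_bed(cfg$deadzones, genome, "deadzones")
    f[c("chrom", "start", "end")]
  } else empty_intervals()
  sheet <- read_sample_sheet(cfg$sample_sheet)
  list(genome = genome, deadzones = dz, sheet = sheet)
}

matrix_path <- function(cfg, r) {
  file.path(cfg$out_dir, sprintf("windows_%dk.tsv", as.integer(r / 1000)))
}

need_file <- function(path, hint) {
  if (!file.exists(path))
    stop("missing upstream output: ", path, " (run ", hint, " first)")
  path
}

#' Pipeline stages
#'
#' Each stage reads its inputs, writes its outputs under the config's
#' `out_dir`, and is idempotent: re-running with unchanged inputs and seed
#' produces byte-identical files. `pipeline_all()` chains every stage and
#' writes a run manifest (config echo, input hashes, output row counts).
#'
#' @param cfg an `lk_config`.
#' @return invisibly, the paths written.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_windows <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grids <- lapply(cfg$resolutions, function(r)
    window_grid(inp$genome, r, inp$deadzones))
  names(grids) <- as.character(cfg$resolutions)
  raw10 <- lapply(seq_len(nrow(inp$sheet)), function(i) {
    ds <- read_scored_bed(inp$sheet$path[i], inp$genome,
                          sample_id = inp$sheet$sample_id[i],
                          score_column = cfg$score_column)
    tr <- score_windows(ds, grids[[1]])
    if (cfg$male_xy_doubling && inp$sheet$sex[i] == "M") {
      xy <- grids[[1]]$windows$chrom %in% c("chrX", "chrY", "X", "Y")
      tr$score[xy] <- tr$score[xy] * 2
    }
    tr
  })
  paths <- character()
  for (r in cfg$resolutions) {
    raw <- if (r == 10000) raw10 else lapply(raw10, coarsen, resolution = r)
    norm <- lapply(raw, normalize_track)
    groups <- split(seq_len(nrow(inp$sheet)), inp$sheet$replicate_group)
    groups <- groups[unique(inp$sheet$replicate_group)]
    tracks <- lapply(names(groups), function(gn)
      average_replicates(norm[groups[[gn]]], sample_id = gn))
    p <- matrix_path(cfg, r)
    write_track_matrix(tracks, p)
    paths <- c(paths, p)
  }
  stage_log("windows", t0, nrow(inp$sheet), " samples, ",
            length(cfg$resolutions), " resolutions")
  invisible(paths)
}

pipeline_tracks_10k <- function(cfg, inp) {
  grid <- window_grid(inp$genome, 10000, inp$deadzones)
  read_track_matrix(need_file(matrix_path(cfg, 10000), "pipeline_windows"),
                    grid, normalized = TRUE)
}

load_feature_tracks <- function(cfg, genome) {
  if (is.null(cfg$feature_dir) || !dir.exists(cfg$feature_dir))
    return(list())
  files <- sort(list.files(cfg$feature_dir, pattern = "\\.bed(\\.gz)?$",
                           full.names = TRUE))
  out <- lapply(files, function(f) {
    kind <- if (grepl("\\.point\\.bed(\\.gz)?$", f)) "point" else "interval"
    fid <- sub("\\.(interval|point)\\.bed(\\.gz)?$", "", basename(f))
    fid <- sub("\\.bed(\\.gz)?$", "", fid)
    read_interval_bed(f, genome, feature_id = fid, kind = kind)
  })
  names(out) <- vapply(out, attr, "", "feature_id")
  out
}

#' @rdname pipeline
#' @export
pipeline_correlate <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  inp <- load_inputs(cfg)
  feats <- load_feature_tracks(cfg, inp$genome)
  paths <- character()
  for (r in cfg$resolutions) {
    grid <- window_grid(inp$genome, r, inp$deadzones)
    tracks <- read_track_matrix(
      need_file(matrix_path(cfg, r), "pipeline_windows"), grid,
      normalized = TRUE)
    ftr <- lapply(feats, feature_density_track, grid = grid)
    cm <- pearson_pairwise(c(tracks, unname(ftr)),
                           include_xy = cfg$include_xy)
    p <- file.path(cfg$out_dir,
                   sprintf("correlation_%dk.tsv", as.integer(r / 1000)))
    utils::write.table(round(cm$r, 6), p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  stage_log("correlate", t0, length(cfg$resolutions), " matrices")
  invisible(paths)
}

#' @rdname pipeline
#' @export
pipeline_cluster <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  inp <- load_inputs(cfg)
  tracks <- pipeline_tracks_10k(cfg, inp)
  hc <- hcluster_samples(tracks, include_xy = cfg$include_xy)
  p <- file.path(cfg$out_dir, "samples.nwk")
  dendrogram_newick(hc, p)
  stage_log("cluster", t0, length(tracks), " samples")
  invisible(p)
}

#' @rdname pipeline
#' @export
pipeline_zones <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  inp <- load_inputs(cfg)
  tracks <- pipeline_tracks_10k(cfg, inp)
  sheet <- collapse_replicates(inp$sheet)
  present <- intersect(c("granulocyte", "cd34", "aml"),
                       unique(sheet$category))
  if (length(present) == 0) stop("no zone-eligible samples in sheet")
  zm <- classify_zones(tracks, sheet, sigma_rule = cfg$sigma_rule,
                       categories = present)
  bed <- zones_to_bed(zm)
  p1 <- file.path(cfg$out_dir, "zones.bed")
  write_bed(bed, p1)
  fr <- zone_fractions(zm)
  p2 <- file.path(cfg$out_dir, "zone_fractions.tsv")
  utils::write.table(data.frame(zone = names(fr), pct = sprintf("%.6f", fr)),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("zones", t0, nrow(bed), " zone intervals")
  invisible(c(p1, p2))
}

#' @rdname pipeline
#' @export
pipeline_dlocks <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  inp <- load_inputs(cfg)
  tracks <- pipeline_tracks_10k(cfg, inp)
  sheet <- collapse_replicates(inp$sheet)
  res <- suppressWarnings(
    run_comparisons(tracks, sheet, alphas = cfg$alphas,
                    epsilon = cfg$epsilon,
                    lock_base_rule = cfg$lock_base_rule))
  feats <- load_feature_tracks(cfg, inp$genome)
  genes <- if ("genes" %in% names(feats)) feats$genes
           else feature_track(empty_intervals(), inp$genome, "genes")
  paths <- character()
  summ <- list()
  for (nm in names(res)) {
    p <- file.path(cfg$out_dir, sprintf("dlocks_%s.bed", nm))
    write_dlock_bed(res[[nm]], nm, p)
    paths <- c(paths, p)
    for (a in c(list(NULL), as.list(cfg$alphas))) {
      s <- summarize_dlocks(res[[nm]], genes, inp$genome, alpha = a)
      s <- cbind(comparison = nm, s)
      summ[[length(summ) + 1]] <- s
    }
  }
  if (length(summ)) {
    ps <- file.path(cfg$out_dir, "dlock_summary.tsv")
    df <- do.call(rbind, summ)
    df$pct_genome <- sprintf("%.6f", df$pct_genome)
    df$mean_size_bp <- sprintf("%.2f", df$mean_size_bp)
    df$gene_density_ratio <- sprintf("%.6f", df$gene_density_ratio)
    utils::write.table(df, ps, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, ps)
  }
  stage_log("dlocks", t0, length(res), " comparisons")
  invisible(paths)
}

#' @rdname pipeline
#' @export
pipeline_enrich <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  inp <- load_inputs(cfg)
  feats <- load_feature_tracks(cfg, inp$genome)
  if (length(feats) == 0) {
    stage_log("enrich", t0, "no feature tracks, nothing to do")
    return(invisible(character()))
  }
  grid <- window_grid(inp$genome, 10000, inp$deadzones)
  dens <- lapply(feats, feature_density_track, grid = grid)
  sets <- list()
  zb <- file.path(cfg$out_dir, "zones.bed")
  if (file.exists(zb)) {
    zones <- read_interval_bed(zb, inp$genome, "zones")
    for (lab in c("RED", "YELLOW", "GREEN")) {
      zi <- zones[zones$name == lab, , drop = FALSE]
      if (nrow(zi) == 0) next
      sel <- rep(FALSE, n_windows(grid))
      idx <- window_index_of(zi$chrom, zi$start, grid)
      for (k in seq_len(nrow(zi)))
        sel[idx[k]:(idx[k] + (zi$end[k] - zi$start[k]) / 10000 - 1)] <- TRUE
      sets[[paste0("zone_", lab)]] <- sel
    }
  }
  for (f in sort(list.files(cfg$out_dir, pattern = "^dlocks_.*\\.bed$"))) {
    nm <- sub("\\.bed$", "", sub("^dlocks_", "", f))
    dl <- utils::read.table(file.path(cfg$out_dir, f), sep = "\t",
                            stringsAsFactors = FALSE)
    names(dl)[1:3] <- c("chrom", "start", "end")
    sel <- rep(FALSE, n_windows(grid))
    idx <- window_index_of(dl$chrom, dl$start, grid)
    for (k in seq_len(nrow(dl)))
      sel[idx[k]:(idx[k] + (dl$end[k] - dl$start[k]) / 10000 - 1)] <- TRUE
    sets[[paste0("dlock_", nm)]] <- sel
  }
  rows <- list()
  for (sn in names(sets)) for (dn in names(dens)) {
    sel <- sets[[sn]] & !grid$windows$masked
    if (!any(sel)) next
    e <- fold_enrichment(sel, dens[[dn]])
    rows[[length(rows) + 1]] <-
      data.frame(set = sn, feature = dn, fold = sprintf("%.6f", e$fold),
                 set_bp = e$set_bp, genome_bp = e$genome_bp)
  }
  p <- file.path(cfg$out_dir, "enrichment.tsv")
  utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage_log("enrich", t0, length(rows), " set x feature pairs")
  invisible(p)
}

#' @rdname pipeline
#' @export
pipeline_all <- function(cfg) {
  t0 <- as.numeric(proc.time()[3])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pipeline_windows(cfg), pipeline_correlate(cfg),
             pipeline_cluster(cfg), pipeline_zones(cfg),
             pipeline_dlocks(cfg), pipeline_enrich(cfg))
  inputs <- c(cfg$chrom_sizes, cfg$deadzones, cfg$sample_sheet)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "lockscape",
    version = as.character(utils::packageVersion("lockscape")),
    config = unclass(cfg)[c("resolutions", "alphas", "epsilon",
                            "sigma_rule", "lock_base_rule", "include_xy",
                            "male_xy_doubling", "score_column", "seed")],
    inputs = as.list(tools::md5sum(inputs)),
    outputs = lapply(stats::setNames(paths, basename(paths)), function(p)
      list(md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)))))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("all", t0, length(paths), " artifacts")
  invisible(c(paths, file.path(cfg$out_dir, "manifest.json")))
}
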