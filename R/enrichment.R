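#' Fold enrichment of a feature inside a window set
#'
#' The ratio of the feature's density inside a set of unmasked windows to
#' its genome-wide density, with densities computed per non-deadzone bp:
#' fold = (sum score in set / set bp) / (sum score genome / genome bp).
#' The density track is a binned feature ([feature_density_track()]), so
#' interval features use covered-bp density and point features use counts.
#' By construction the fold of the set of all unmasked windows is exactly 1.
#'
#' @param window_set logical vector (length = number of windows) or integer
#'   window indices selecting the set; masked windows are ignored.
#' @param density a raw `lk_track` from [feature_density_track()].
#' @return one-row data.frame of class `lk_enrichment`: fold, set_bp,
#'   genome_bp, density_in_set, density_genome.
#' @export
fold_enrichment <- function(window_set, density) {
  w <- density$grid$windows
  sel <- if (is.logical(window_set)) window_set
         else seq_len(nrow(w)) %in% window_set
  sel <- sel & !w$masked
  if (!any(sel)) stop("empty window set")
  set_bp <- sum(w$nondead[sel])
  gen_bp <- sum(w$nondead[!w$masked])
  d_set <- sum(density$score[sel]) / set_bp
  d_gen <- sum(density$score[!w$masked]) / gen_bp
  if (d_gen <= 0) stop("feature absent: zero genome-wide density")
  structure(data.frame(feature_id = density$sample_id,
                       fold = d_set / d_gen, set_bp = set_bp,
                       genome_bp = gen_bp, density_in_set = d_set,
                       density_genome = d_gen),
            class = c("lk_enrichment", "data.frame"))
}

#' Window-set helpers for enrichment
#'
#' `windows_of_zones` selects the windows of one zone label;
#' `windows_of_dlocks` selects windows of passing dLOCKs.
#'
#' @param zonemap an `lk_zonemap`.
#' @param label "RED", "YELLOW" or "GREEN".
#' @return logical window selector.
#' @export
windows_of_zones <- function(zonemap, label) {
  zonemap$label == label
}

#' @rdname windows_of_zones
#' @param dlocks ranked `lk_dlocks`.
#' @param grid the `lk_grid`.
#' @param alpha optional alpha level filter (as in [summarize_dlocks()]).
#' @export
windows_of_dlocks <- function(dlocks, grid, alpha = NULL) {
  sel <- dlocks
  if (!is.null(alpha)) {
    col <- sprintf("alpha_%02d", round(100 * alpha))
    if (is.null(sel[[col]])) stop("dlocks not ranked at alpha ", alpha)
    sel <- sel[sel[[col]], , drop = FALSE]
  }
  out <- rep(FALSE, n_windows(grid))
  for (k in seq_len(nrow(sel))) out[sel$first[k]:sel$last[k]] <- TRUE
  out
}

#' Genes overlapping passing dLOCKs
#'
#' A gene belongs to the set when its body overlaps at least 1 bp of any
#' passing dLOCK (half-open coordinates: an abutting gene does not
#' overlap). Each gene is counted once.
#'
#' @param dlocks ranked `lk_dlocks`.
#' @param genes `lk_features` whose `name` column holds unique gene ids.
#' @param genome an `lk_genome`.
#' @param alpha optional alpha level filter.
#' @return character vector of gene ids (a gene set).
#' @export
genes_in_dlocks <- function(dlocks, genes, genome, alpha = NULL) {
  if (is.null(genes$name) || anyNA(genes$name) || any(genes$name == ""))
    stop("gene records must be named")
  sel <- dlocks
  if (!is.null(alpha)) {
    col <- sprintf("alpha_%02d", round(100 * alpha))
    if (is.null(sel[[col]])) stop("dlocks not ranked at alpha ", alpha)
    sel <- sel[sel[[col]], , drop = FALSE]
  }
  if (nrow(sel) == 0 || nrow(genes) == 0) return(character())
  hit <- IRanges::overlapsAny(
    as_gr(genes, genome), as_gr(sel[c("chrom", "start", "end")], genome))
  unique(genes$name[hit])
}

#' Percent of one gene set found in another
#'
#' 100 * |a intersect b| / |a|; the asymmetric intersection percentage used
#' to compare differentiation-associated and disease-associated dLOCK gene
#' sets.
#'
#' @param a,b character vectors of gene ids.
#' @return percentage in [0, 100].
#' @export
gene_intersection_pct <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0) stop("first gene set is empty")
  100 * length(intersect(a, b)) / length(a)
}
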