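#' Zone labels from a score matrix
#'
#' Low-level classifier behind [classify_zones()]. For each window w the
#' panel threshold is sigma(w), the sample standard deviation (n-1
#' denominator) of the samples' normalized scores at w; a sample is 'high'
#' when its score exceeds sigma(w) and 'low' otherwise (score <= sigma).
#' A window is GREEN (conserved-low) when at most 2 samples are high with
#' at most one high per category; RED (conserved-high) when at most 2 are
#' low with at most one low per category; YELLOW otherwise. With
#' `sigma_rule = "global"` a single pooled standard deviation of all
#' unmasked scores replaces the per-window sigma.
#'
#' Consequences of the strict comparisons, kept deliberately: a window
#' where every sample agrees at a positive value has sigma 0, every sample
#' is high, and the window is RED; an all-zero window is GREEN.
#'
#' @param m samples x windows numeric matrix (NA = masked).
#' @param category character vector, one category per row of `m`.
#' @param chrom optional chromosome per column; chrY columns are classified
#'   from male samples only.
#' @param sex optional per-row sex ("M"/"F"), required when `chrom`
#'   contains chrY.
#' @param sigma_rule "per-window" (default) or "global".
#' @return list: `label` factor in RED/YELLOW/GREEN/MASKED per window,
#'   `sigma` the threshold used per window.
#' @export
zone_labels <- function(m, category, chrom = NULL, sex = NULL,
                        sigma_rule = c("per-window", "global")) {
  sigma_rule <- match.arg(sigma_rule)
  if (nrow(m) != length(category)) stop("one category per sample row")
  for (cat in unique(category))
    if (sum(category == cat) == 0) stop("empty category ", cat)
  W <- ncol(m)
  label <- factor(rep("MASKED", W),
                  levels = c("RED", "YELLOW", "GREEN", "MASKED"))
  sigma <- rep(NA_real_, W)
  is_y <- if (is.null(chrom)) rep(FALSE, W) else chrom %in% c("chrY", "Y")
  if (any(is_y)) {
    if (is.null(sex)) stop("sex needed to classify chrY windows")
    if (!any(sex == "M")) {
      warning("no male samples: chrY windows left MASKED")
    }
  }
  global_sd <- if (sigma_rule == "global") stats::sd(m[!is.na(m)]) else NULL
  classify_cols <- function(cols, rows) {
    sub <- m[rows, cols, drop = FALSE]
    ok <- colSums(is.na(sub)) == 0
    cols <- cols[ok]; sub <- sub[, ok, drop = FALSE]
    if (length(cols) == 0) return()
    sg <- if (sigma_rule == "global") rep(global_sd, length(cols))
          else apply(sub, 2, stats::sd)
    high <- sweep(sub, 2, sg, `>`)
    nhigh <- colSums(high)
    nlow <- nrow(sub) - nhigh
    catf <- factor(category[rows])
    per_cat_high <- rowsum(high + 0, catf)         # categories x windows
    per_cat_low <- rowsum((!high) + 0, catf)
    green <- nhigh <= 2 & apply(per_cat_high <= 1, 2, all)
    red <- nlow <= 2 & apply(per_cat_low <= 1, 2, all)
    lab <- ifelse(green, "GREEN", ifelse(red, "RED", "YELLOW"))
    label[cols] <<- lab
    sigma[cols] <<- sg
  }
  if (any(!is_y)) classify_cols(which(!is_y), seq_len(nrow(m)))
  if (any(is_y) && !is.null(sex) && any(sex == "M"))
    classify_cols(which(is_y), which(sex == "M"))
  list(label = label, sigma = sigma)
}

#' Classify conserved / variable zones across a sample panel
#'
#' Labels every 10 kb window as conserved-high (RED), variable (YELLOW) or
#' conserved-low (GREEN) across the granulocyte, CD34+ and AML samples (all
#' AML clusters pooled into one AML category, K562 excluded). chrY is
#' classified from male samples only. See [zone_labels()] for the rules.
#'
#' @param tracks list of normalized `lk_track`s (one per replicate group).
#' @param samples data.frame with sample_id, category, sex matching the
#'   tracks; rows with categories outside `categories` are dropped.
#' @param sigma_rule see [zone_labels()].
#' @param categories the categories entering the classification; each must
#'   have at least one sample. The default is the full three-category
#'   normal+AML panel.
#' @return an `lk_zonemap`: grid, per-window label and sigma.
#' @export
classify_zones <- function(tracks, samples,
                           sigma_rule = c("per-window", "global"),
                           categories = c("granulocyte", "cd34", "aml")) {
  sigma_rule <- match.arg(sigma_rule)
  ids <- vapply(tracks, `[[`, "", "sample_id")
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("track without sample sheet row")
  keep <- samples$category %in% categories
  tracks <- tracks[keep]; samples <- samples[keep, , drop = FALSE]
  for (cat in categories)
    if (sum(samples$category == cat) == 0)
      stop("no samples in category ", cat)
  for (t in tracks) if (!t$normalized) stop("zone tracks must be normalized")
  grid <- tracks[[1]]$grid
  m <- track_matrix(tracks)
  z <- zone_labels(m, samples$category, chrom = grid$windows$chrom,
                   sex = samples$sex, sigma_rule = sigma_rule)
  structure(list(grid = grid, label = z$label, sigma = z$sigma),
            class = "lk_zonemap")
}

#' @export
print.lk_zonemap <- function(x, ...) {
  print(table(x$label))
  invisible(x)
}

#' Genome fractions of the three zones
#'
#' bp-weighted percentages of RED / YELLOW / GREEN over unmasked windows;
#' they sum to 100.
#'
#' @param zonemap an `lk_zonemap`.
#' @return named numeric vector (RED, YELLOW, GREEN), in percent.
#' @export
zone_fractions <- function(zonemap) {
  w <- zonemap$grid$windows
  bp <- w$end - w$start
  ok <- zonemap$label != "MASKED"
  tot <- sum(bp[ok])
  out <- vapply(c("RED", "YELLOW", "GREEN"), function(l)
    100 * sum(bp[ok & zonemap$label == l]) / tot, 0.0)
  out
}

#' Zone map as merged labeled intervals
#'
#' Adjacent windows of the same label within a chromosome are merged;
#' masked windows break runs and are omitted.
#'
#' @param zonemap an `lk_zonemap`.
#' @return data.frame: chrom, start, end, name (the label).
#' @export
zones_to_bed <- function(zonemap) {
  w <- zonemap$grid$windows
  lab <- as.character(zonemap$label)
  keep <- lab != "MASKED"
  if (!any(keep)) return(cbind(empty_intervals(), name = character()))
  w <- w[keep, , drop = FALSE]; lab <- lab[keep]
  newrun <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                w$start[-1] != w$end[-nrow(w)] | lab[-1] != lab[-length(lab)])
  run <- cumsum(newrun)
  data.frame(chrom = tapply(w$chrom, run, `[`, 1),
             start = as.numeric(tapply(w$start, run, min)),
             end = as.numeric(tapply(w$end, run, max)),
             name = tapply(lab, run, `[`, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
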