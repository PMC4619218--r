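#' Abundantly expressed genes of a gestational stage
#'
#' Computes each gene's mean expression across the stage's samples and
#' returns the genes whose mean strictly exceeds the given quantile
#' (linear-interpolation, R type 7) of all gene means in that stage.
#'
#' @param m Expression matrix.
#' @param metadata Sample metadata.
#' @param stage `"PN"`, `"PT"` or `"FT"`.
#' @param quantile Quantile threshold (default top decile).
#' @return Character vector of gene ids.
#' @export
abundant_genes <- function(m, metadata, stage, quantile = 0.90) {
  stage <- match.arg(stage, STAGES)
  ids <- stage_samples(metadata, stage)
  if (!length(ids)) stop("no samples in stage ", stage, call. = FALSE)
  idx <- match_samples(m, ids)
  means <- rowMeans(m[, idx, drop = FALSE])
  thr <- stats::quantile(means, quantile, type = 7, names = FALSE)
  names(means)[means > thr]
}

#' Score genes for tissue specificity against an expression atlas
#'
#' For each gene the candidate tissue is the tissue of maximal atlas
#' expression. The gene is *enriched* in that tissue when its expression
#' there is at least `fold_enriched` times its mean expression across all
#' other tissues, and *specific* when it is additionally the unique maximum
#' and at least `fold_specific` times its expression in any other tissue.
#' Genes absent from the atlas are reported (attribute `"missing"`), not
#' scored; all-zero atlas rows are skipped with a warning.
#'
#' @param genes Character vector of gene ids to score.
#' @param atlas Gene-by-tissue matrix.
#' @param fold_enriched Fold over the mean of the other tissues.
#' @param fold_specific Fold over the maximum of the other tissues.
#' @return Data.frame with `gene_id`, `tissue`, `fold_vs_mean_others`,
#'   `fold_vs_max_other`, `is_enriched`, `is_specific`.
#' @export
score_tissue_specificity <- function(genes, atlas, fold_enriched = 3,
                                     fold_specific = 1.5) {
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(atlas))
  if (length(missing))
    warning(length(missing), " gene(s) absent from the atlas", call. = FALSE)
  genes <- intersect(genes, rownames(atlas))
  sub <- atlas[genes, , drop = FALSE]
  zero <- rowSums(sub) == 0
  if (any(zero)) {
    warning("skipped ", sum(zero), " gene(s) with all-zero atlas rows",
            call. = FALSE)
    sub <- sub[!zero, , drop = FALSE]
  }
  n <- nrow(sub)
  if (n == 0) {
    out <- data.frame(gene_id = character(0), tissue = character(0),
                      fold_vs_mean_others = numeric(0),
                      fold_vs_max_other = numeric(0),
                      is_enriched = logical(0), is_specific = logical(0))
    attr(out, "missing") <- missing
    return(out)
  }
  best <- max.col(sub, ties.method = "first")
  top <- sub[cbind(seq_len(n), best)]
  tied <- rowSums(sub == top) > 1
  sum_others <- rowSums(sub) - top
  mean_others <- sum_others / (ncol(sub) - 1)
  max_other <- vapply(seq_len(n), function(i) max(sub[i, -best[i]]), numeric(1))
  f_mean <- ifelse(mean_others == 0, Inf, top / mean_others)
  f_max <- ifelse(max_other == 0, Inf, top / max_other)
  out <- data.frame(
    gene_id = rownames(sub),
    tissue = colnames(sub)[best],
    fold_vs_mean_others = f_mean,
    fold_vs_max_other = f_max,
    is_enriched = f_mean >= fold_enriched,
    is_specific = f_mean >= fold_enriched & !tied & f_max >= fold_specific,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "missing") <- missing
  out
}

#' Per-tissue specific marker sets derived from an atlas
#'
#' Convenience wrapper: scores every atlas gene and returns, per tissue, the
#' genes called specific for it.
#'
#' @inheritParams score_tissue_specificity
#' @return Named list (tissue -> character vector of specific marker genes);
#'   tissues without specific markers are omitted.
#' @export
atlas_specific_markers <- function(atlas, fold_enriched = 3,
                                   fold_specific = 1.5) {
  calls <- score_tissue_specificity(rownames(atlas), atlas,
                                    fold_enriched, fold_specific)
  calls <- calls[calls$is_specific, , drop = FALSE]
  split(calls$gene_id, calls$tissue)
}

#' Stage profile of tissue-selective marker expression
#'
#' For every tissue with at least one atlas-derived specific marker present
#' in the expression matrix, computes per stage the proportion of those
#' markers detected as abundant ([abundant_genes()]) in that stage — the
#' quantity behind "relative amount of tissue-selective markers expressed"
#' bar profiles.
#'
#' @param m Expression matrix.
#' @param metadata Sample metadata.
#' @param atlas Gene-by-tissue atlas.
#' @param quantile Abundance quantile passed to [abundant_genes()].
#' @inheritParams score_tissue_specificity
#' @return Data.frame with columns `tissue`, `n_markers`, `PN`, `PT`, `FT`
#'   (proportions in \[0, 1\]).
#' @export
stage_marker_profile <- function(m, metadata, atlas, quantile = 0.90,
                                 fold_enriched = 3, fold_specific = 1.5) {
  markers <- atlas_specific_markers(atlas, fold_enriched, fold_specific)
  markers <- lapply(markers, intersect, y = rownames(m))
  markers <- markers[lengths(markers) > 0]
  if (!length(markers))
    return(data.frame(tissue = character(0), n_markers = integer(0),
                      PN = numeric(0), PT = numeric(0), FT = numeric(0)))
  ab <- lapply(stats::setNames(STAGES, STAGES), function(s)
    abundant_genes(m, metadata, s, quantile))
  out <- data.frame(tissue = names(markers), n_markers = lengths(markers),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (s in STAGES)
    out[[s]] <- vapply(markers, function(mk)
      length(intersect(mk, ab[[s]])) / length(mk), numeric(1))
  out
}

#' Marker-set over-representation by the exact hypergeometric test
#'
#' Tests each marker set (intersected with the universe) for
#' over-representation in the query gene list. `fisher_p` is the one-sided
#' exact hypergeometric tail `P(X >= r)`; `z_score` is the normal
#' approximation with finite-population correction,
#' `(r - nR/N) / sqrt(n (R/N)(1 - R/N)(1 - (n-1)/(N-1)))`.
#'
#' @param query_genes Query gene list (must be a subset of the universe).
#' @param universe_genes Background gene universe.
#' @param markers Named list of marker gene sets (see
#'   [read_marker_database()]).
#' @param alpha Significance threshold on `fisher_p`.
#' @return Data.frame with `marker_set`, `overlap` (r), `set_size` (R),
#'   `query_size` (n), `universe_size` (N), `fisher_p`, `z_score`,
#'   `is_enriched`; sets with empty universe intersection are skipped.
#' @export
marker_enrichment <- function(query_genes, universe_genes, markers,
                              alpha = 0.05) {
  query <- unique(toupper(query_genes))
  universe <- unique(toupper(universe_genes))
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query gene(s) not in universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  N <- length(universe); n <- length(query)
  if (N < 2) stop("universe must contain at least 2 genes", call. = FALSE)
  rows <- lapply(names(markers), function(lab) {
    set <- intersect(unique(toupper(markers[[lab]])), universe)
    R <- length(set)
    if (R == 0) return(NULL)
    r <- length(intersect(set, query))
    p <- stats::phyper(r - 1, R, N - R, n, lower.tail = FALSE)
    mu <- n * R / N
    sigma <- sqrt(n * (R / N) * (1 - R / N) * (1 - (n - 1) / (N - 1)))
    z <- if (sigma == 0) 0 else (r - mu) / sigma
    data.frame(marker_set = lab, overlap = r, set_size = R, query_size = n,
               universe_size = N, fisher_p = p, z_score = z,
               is_enriched = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker_set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), fisher_p = numeric(0),
                      z_score = numeric(0), is_enriched = logical(0))
  rownames(out) <- NULL
  out
}

#' Verify fetal origin from XIST and Y-chromosome marker expression
#'
#' Per sample, compares the mean expression of Y-chromosome marker genes to
#' XIST expression: predicted sex is male when the chrY mean exceeds XIST,
#' female otherwise, and unknown when the required markers are absent from
#' the matrix. The prediction is compared with the recorded fetal sex.
#'
#' @param m Expression matrix.
#' @param metadata Sample metadata with a `sex` column.
#' @param xist_gene Gene id of the X-inactivation marker.
#' @param chr_y_genes Y-chromosome marker gene ids.
#' @return Data.frame with `sample_id`, `chry_mean`, `xist`,
#'   `predicted_sex`, `recorded_sex`, `concordant` (NA when either side is
#'   unknown).
#' @export
check_fetal_origin <- function(m, metadata, xist_gene = "XIST",
                               chr_y_genes = c("RPS4Y1", "DDX3Y", "EIF1AY")) {
  have_x <- xist_gene %in% rownames(m)
  chry <- intersect(chr_y_genes, rownames(m))
  if (!have_x || !length(chry))
    warning("sex marker gene(s) absent from matrix; predictions are 'unknown'",
            call. = FALSE)
  idx <- match_samples(m, metadata$sample_id)
  chry_mean <- if (length(chry))
    colMeans(m[chry, idx, drop = FALSE]) else rep(NA_real_, length(idx))
  xist <- if (have_x) m[xist_gene, idx] else rep(NA_real_, length(idx))
  pred <- if (!have_x || !length(chry)) rep("unknown", length(idx)) else
    ifelse(chry_mean > xist, "male", "female")
  rec <- metadata$sex
  conc <- ifelse(pred == "unknown" | rec == "unknown", NA, pred == rec)
  data.frame(sample_id = metadata$sample_id, chry_mean = chry_mean,
             xist = xist, predicted_sex = pred, recorded_sex = rec,
             concordant = conc, stringsAsFactors = FALSE, row.names = NULL)
}
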