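#' @importFrom utils read.delim write.table
NULL

STAGES <- c("PN", "PT", "FT")
MORBIDITIES <- c("respiratory_support", "gavage_feeding")
STAGE_WEEK_RANGES <- list(PN = c(18, 24), PT = c(34, 36), FT = c(39, 40))

validate_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry gene ids (rownames) and sample/tissue ids (colnames)",
         call. = FALSE)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop(what, ": duplicated gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stop(what, ": duplicated column id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(what, ": non-finite or negative value(s), e.g. gene '",
         rownames(m)[bad[1, 1]], "' column '", colnames(m)[bad[1, 2]], "'",
         call. = FALSE)
  invisible(m)
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated table whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values must be finite and
#' non-negative; duplicated gene or sample identifiers are rejected.
#'
#' @param path Path to a TSV file.
#' @param scale Either `"rpkm"` (length/depth-normalized abundances) or
#'   `"count"` (raw counts); stored as the `"scale"` attribute of the result.
#' @return A numeric matrix (genes in rows, samples in columns) with a
#'   `"scale"` attribute.
#' @export
read_expression_matrix <- function(path, scale = c("rpkm", "count")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed expression file '", path,
         "': need a gene-id column plus at least one sample column", call. = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("malformed expression file '", path, "': non-numeric values", call. = FALSE)
  rownames(m) <- genes
  validate_expression_matrix(m)
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path. UTF-8, LF line endings, genes in rows.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-tissue expression atlas
#'
#' Same layout as [read_expression_matrix()]; columns are tissue labels
#' (at least three required).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows, tissues in columns.
#' @export
read_tissue_atlas <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed atlas file '", path, "'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_expression_matrix(m, what = "tissue atlas")
  if (ncol(m) < 3)
    stop("tissue atlas needs at least 3 tissues, got ", ncol(m), call. = FALSE)
  m
}

#' @rdname read_tissue_atlas
#' @param atlas Atlas matrix to write.
#' @export
write_tissue_atlas <- function(atlas, path) {
  validate_expression_matrix(atlas, what = "tissue atlas")
  df <- data.frame(gene_id = rownames(atlas), atlas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_metadata <- function(meta) {
  req <- c("sample_id", "stage", "weeks", "sex", "morbidities")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(meta$stage), STAGES)
  if (length(bad))
    stop("unknown stage value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(meta$sex), c("male", "female", "unknown"))
  if (length(bad))
    stop("unknown sex value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(meta))) {
    w <- meta$weeks[i]
    if (is.na(w)) next
    rng <- STAGE_WEEK_RANGES[[meta$stage[i]]]
    if (w < rng[1] || w > rng[2])
      stop("sample '", meta$sample_id[i], "': gestational weeks ", w,
           " inconsistent with stage ", meta$stage[i],
           " (expected ", rng[1], "-", rng[2], ")", call. = FALSE)
    flags <- morbidity_flags(meta$morbidities[i])
    bad <- setdiff(flags, MORBIDITIES)
    if (length(bad))
      stop("sample '", meta$sample_id[i], "': unknown morbidity flag(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(meta)
}

morbidity_flags <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Read the sample metadata table
#'
#' TSV with columns `sample_id`, `stage` (PN/PT/FT), `weeks` (gestational
#' weeks), `sex` (male/female/unknown) and `morbidities`
#' (semicolon-separated flags among `respiratory_support`, `gavage_feeding`).
#' Weeks are checked against the stage definitions used throughout
#' (PN 18-24, PT 34-36, FT 39-40).
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character")
  meta$weeks <- suppressWarnings(as.numeric(meta$weeks))
  validate_sample_metadata(meta)
  meta
}

#' @rdname read_sample_metadata
#' @param meta Metadata data.frame to write.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_sample_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select samples by gestational stage or morbidity flag
#'
#' @param meta Sample metadata data.frame.
#' @param stage One of `"PN"`, `"PT"`, `"FT"`.
#' @return Character vector of sample ids.
#' @export
stage_samples <- function(meta, stage) {
  stage <- match.arg(stage, STAGES)
  meta$sample_id[meta$stage == stage]
}

#' @rdname stage_samples
#' @param flag Morbidity flag name, e.g. `"gavage_feeding"`.
#' @export
morbidity_samples <- function(meta, flag) {
  flag <- match.arg(flag, MORBIDITIES)
  has <- vapply(meta$morbidities, function(x) flag %in% morbidity_flags(x),
                logical(1))
  meta$sample_id[has]
}

#' Read a marker-set database (GMT dialect)
#'
#' One set per line: label, description, then the member gene symbols, all
#' tab-separated. Gene symbols are upper-cased so matching is
#' case-insensitive; duplicate labels and empty sets are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (label -> gene set).
#' @export
read_marker_database <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  db <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !any(nzchar(parts[-(1:2)])))
      stop("marker set '", parts[1], "' has an empty gene list", call. = FALSE)
    label <- parts[1]
    if (label %in% names(db))
      stop("duplicated marker-set label: ", label, call. = FALSE)
    db[[label]] <- unique(toupper(parts[-(1:2)][nzchar(parts[-(1:2)])]))
  }
  db
}

#' @rdname read_marker_database
#' @param db Named list of gene sets to write.
#' @export
write_marker_database <- function(db, path) {
  if (is.null(names(db)) || any(!nzchar(names(db))) || anyDuplicated(names(db)))
    stop("marker database must have unique non-empty labels", call. = FALSE)
  if (any(lengths(db) == 0))
    stop("marker database contains an empty gene set", call. = FALSE)
  lines <- vapply(names(db), function(lab) {
    paste(c(lab, "na", toupper(db[[lab]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read splice junctions from a BED12 junction file
#'
#' Reads junction records in the BED12 dialect written by spliced aligners:
#' the record spans both exonic anchors as two blocks and the score column
#' holds the junction-spanning read count. Intron coordinates (0-based,
#' half-open) are derived from the anchor blocks. Records with a block count
#' other than two are skipped with a warning (the number skipped is attached
#' as the `"skipped"` attribute); a non-integer score is an error.
#'
#' @param path Path to a BED12 file.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `count`, `sample_id`, sorted by coordinate.
#' @export
read_junctions_bed <- function(path, sample_id) {
  gr <- rtracklayer::import(path, format = "BED")
  empty <- data.frame(chrom = character(0), intron_start = integer(0),
                      intron_end = integer(0), strand = character(0),
                      count = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "skipped") <- 0L
  if (length(gr) == 0) return(empty)
  if (!"blocks" %in% names(S4Vectors::mcols(gr)))
    stop("'", path, "' is not BED12: no block structure", call. = FALSE)
  nb <- S4Vectors::elementNROWS(gr$blocks)
  skipped <- sum(nb != 2L)
  if (skipped > 0)
    warning("skipped ", skipped, " record(s) with block count != 2 in '",
            path, "'", call. = FALSE)
  gr <- gr[nb == 2L]
  if (length(gr) == 0) {
    attr(empty, "skipped") <- as.integer(skipped)
    return(empty)
  }
  sc <- BiocGenerics::score(gr)
  if (any(is.na(sc)) || any(sc != round(sc)) || any(sc < 0))
    stop("non-integer or negative junction read count in '", path, "'",
         call. = FALSE)
  blk <- rtracklayer::blocks(gr)  # absolute 1-based block coordinates
  first_end <- vapply(blk, function(b) BiocGenerics::end(b)[1], numeric(1))
  second_start <- vapply(blk, function(b) BiocGenerics::start(b)[2], numeric(1))
  res <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    intron_start = as.integer(first_end),        # 0-based inclusive
    intron_end = as.integer(second_start - 1L),  # 0-based exclusive
    strand = as.character(BiocGenerics::strand(gr)),
    count = as.integer(sc),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  res$strand[res$strand == "*"] <- "."
  bad <- res$intron_start >= res$intron_end
  if (any(bad))
    stop("junction with non-positive intron length in '", path, "'", call. = FALSE)
  res <- res[order(res$chrom, res$intron_start, res$intron_end), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- as.integer(skipped)
  res
}

#' Write junction records as BED12
#'
#' Inverse of [read_junctions_bed()]: each junction becomes a two-block
#' record with 20-bp anchors and the read count in the score column, so that
#' re-reading reproduces the intron coordinates exactly.
#'
#' @param junctions Data.frame as returned by [read_junctions_bed()].
#' @param path Output path.
#' @param anchor Anchor (block) width in bp.
#' @export
write_junctions_bed <- function(junctions, path, anchor = 20L) {
  if (nrow(junctions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(junctions$intron_start >= junctions$intron_end))
    stop("intron_start must be < intron_end", call. = FALSE)
  if (any(junctions$intron_start < anchor))
    stop("intron_start < anchor width; cannot place left anchor", call. = FALSE)
  chrom_start <- junctions$intron_start - anchor   # 0-based
  chrom_end <- junctions$intron_end + anchor
  strand <- ifelse(junctions$strand %in% c("+", "-"), junctions$strand, "*")
  blocks <- IRanges::IRangesList(lapply(seq_len(nrow(junctions)), function(i) {
    # relative 1-based block positions within the record
    IRanges::IRanges(start = c(1L, junctions$intron_end[i] - chrom_start[i] + 1L),
                     width = anchor)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = junctions$chrom,
    ranges = IRanges::IRanges(start = chrom_start + 1L, end = chrom_end),
    strand = strand,
    name = sprintf("J%06d", seq_len(nrow(junctions))),
    score = junctions$count,
    blocks = blocks
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
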