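junction_key <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Detect reciprocal splice-junction events
#'
#' Pools the unique junctions across samples and finds reciprocal
#' structures: for every candidate exclusion junction E, the inclusion
#' candidates are junctions sharing exactly one boundary with E whose other
#' boundary lies strictly inside E's span. A left-anchored inclusion `l`
#' (same start) and right-anchored inclusion `r` (same end) with
#' `l_end < r_start` delimit an implied cassette exon and form one cassette
#' event with two inclusion junctions; inclusion candidates participating in
#' no cassette for that exclusion form single-inclusion events (alternative
#' 5'/3' splice sites). Strand is ignored: detection is coordinate-based.
#'
#' @param junctions Data.frame of junction records (any number of samples),
#'   columns `chrom`, `intron_start`, `intron_end`.
#' @param gene_map Optional data.frame mapping junctions to genes, columns
#'   `chrom`, `intron_start`, `intron_end`, `gene_id`; an event inherits the
#'   gene of its exclusion junction.
#' @return Data.frame with one row per event: `event_id`, `chrom`, `type`
#'   (`"cassette"` or `"alt_site"`), inclusion junction coordinates
#'   (`incl1_start`, `incl1_end`, `incl2_start`, `incl2_end`; the second pair
#'   is NA for alt_site events), `excl_start`, `excl_end`, `gene_id`.
#' @export
detect_reciprocal_events <- function(junctions, gene_map = NULL) {
  u <- unique(junctions[, c("chrom", "intron_start", "intron_end")])
  u <- u[order(u$chrom, u$intron_start, u$intron_end), , drop = FALSE]
  rows <- list()
  for (chrom in unique(u$chrom)) {
    jx <- u[u$chrom == chrom, , drop = FALSE]
    by_start <- split(seq_len(nrow(jx)), jx$intron_start)
    by_end <- split(seq_len(nrow(jx)), jx$intron_end)
    for (e in seq_len(nrow(jx))) {
      es <- jx$intron_start[e]; ee <- jx$intron_end[e]
      L <- setdiff(by_start[[as.character(es)]], e)
      L <- L[jx$intron_end[L] < ee]
      R <- setdiff(by_end[[as.character(ee)]], e)
      R <- R[jx$intron_start[R] > es]
      used_l <- logical(length(L)); used_r <- logical(length(R))
      for (li in seq_along(L)) for (ri in seq_along(R)) {
        l <- L[li]; r <- R[ri]
        if (jx$intron_end[l] < jx$intron_start[r]) {
          used_l[li] <- TRUE; used_r[ri] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, type = "cassette",
            incl1_start = jx$intron_start[l], incl1_end = jx$intron_end[l],
            incl2_start = jx$intron_start[r], incl2_end = jx$intron_end[r],
            excl_start = es, excl_end = ee, stringsAsFactors = FALSE)
        }
      }
      for (l in L[!used_l])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, type = "alt_site",
          incl1_start = jx$intron_start[l], incl1_end = jx$intron_end[l],
          incl2_start = NA_integer_, incl2_end = NA_integer_,
          excl_start = es, excl_end = ee, stringsAsFactors = FALSE)
      for (r in R[!used_r])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, type = "alt_site",
          incl1_start = jx$intron_start[r], incl1_end = jx$intron_end[r],
          incl2_start = NA_integer_, incl2_end = NA_integer_,
          excl_start = es, excl_end = ee, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(event_id = character(0), chrom = character(0),
                      type = character(0), incl1_start = integer(0),
                      incl1_end = integer(0), incl2_start = integer(0),
                      incl2_end = integer(0), excl_start = integer(0),
                      excl_end = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$chrom, ev$excl_start, ev$excl_end, ev$incl1_start,
                 ev$incl1_end, ev$incl2_start, ev$incl2_end, method = "radix",
                 na.last = TRUE), , drop = FALSE]
  ev$event_id <- ifelse(
    ev$type == "cassette",
    sprintf("%s:%d-%d<%d-%d|%d-%d", ev$chrom, ev$excl_start, ev$excl_end,
            ev$incl1_start, ev$incl1_end, ev$incl2_start, ev$incl2_end),
    sprintf("%s:%d-%d<%d-%d", ev$chrom, ev$excl_start, ev$excl_end,
            ev$incl1_start, ev$incl1_end))
  ev$gene_id <- NA_character_
  if (!is.null(gene_map)) {
    key_ev <- junction_key(ev$chrom, ev$excl_start, ev$excl_end)
    key_map <- junction_key(gene_map$chrom, gene_map$intron_start,
                            gene_map$intron_end)
    ev$gene_id <- gene_map$gene_id[match(key_ev, key_map)]
  }
  rownames(ev) <- NULL
  ev[, c("event_id", "chrom", "type", "incl1_start", "incl1_end",
         "incl2_start", "incl2_end", "excl_start", "excl_end", "gene_id")]
}

#' Percent-spliced-in (PSI) per event and sample
#'
#' For each event and sample, inclusion support is the mean of the inclusion
#' junction read counts (averaging keeps cassette PSI in \[0, 1\]) and
#' `PSI = inclusion / (inclusion + exclusion)`. PSI is missing (NA) when
#' `inclusion + exclusion` is below `min_total_reads`. A junction absent from
#' a sample's table counts as zero reads.
#'
#' @param events Data.frame from [detect_reciprocal_events()].
#' @param junctions Long junction table over samples (columns `chrom`,
#'   `intron_start`, `intron_end`, `count`, `sample_id`).
#' @param min_total_reads Minimum combined read support.
#' @return Numeric matrix, events (rownames = event_id) by samples, PSI in
#'   \[0, 1\] or NA.
#' @export
compute_psi <- function(events, junctions, min_total_reads = 10) {
  samples <- sort(unique(junctions$sample_id))
  psi <- matrix(NA_real_, nrow(events), length(samples),
                dimnames = list(events$event_id, samples))
  if (!nrow(events) || !length(samples)) return(psi)
  key <- junction_key(junctions$chrom, junctions$intron_start,
                      junctions$intron_end)
  for (s in samples) {
    sel <- junctions$sample_id == s
    counts <- stats::setNames(junctions$count[sel], key[sel])
    get <- function(k) {
      v <- counts[k]
      v[is.na(v)] <- 0
      unname(v)
    }
    inc1 <- get(junction_key(events$chrom, events$incl1_start, events$incl1_end))
    inc2 <- ifelse(is.na(events$incl2_start), NA,
                   get(junction_key(events$chrom, events$incl2_start,
                                    events$incl2_end)))
    excl <- get(junction_key(events$chrom, events$excl_start, events$excl_end))
    inc <- ifelse(is.na(inc2), inc1, (inc1 + inc2) / 2)
    total <- inc + excl
    p <- ifelse(total >= min_total_reads, inc / total, NA_real_)
    psi[, s] <- p
  }
  psi
}

#' Compare PSI between two sample groups
#'
#' Per event, retains samples with non-missing PSI, requires at least
#' `min_samples` per group, and computes `delta_psi` (group B minus group A
#' mean) and a two-sided Wilcoxon rank-sum p-value. An event is regulated
#' when `|delta_psi| >= delta_min` and `p <= alpha` (unadjusted — cohorts are
#' tiny).
#'
#' @param psi PSI matrix from [compute_psi()].
#' @param group_a,group_b Character vectors of sample ids.
#' @param events Optional events data.frame (to attach `gene_id`).
#' @param delta_min Minimum absolute PSI difference.
#' @param alpha P-value threshold.
#' @param min_samples Minimum non-missing samples per group.
#' @return Data.frame with `event_id`, `n_a`, `n_b`, `mean_psi_a`,
#'   `mean_psi_b`, `delta_psi`, `p`, `is_regulated`, `gene_id`; events
#'   failing the coverage requirement are omitted.
#' @export
compare_psi_groups <- function(psi, group_a, group_b, events = NULL,
                               delta_min = 0.1, alpha = 0.05,
                               min_samples = 2) {
  miss <- setdiff(c(group_a, group_b), colnames(psi))
  if (length(miss))
    stop("sample(s) absent from PSI table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(rownames(psi), function(ev) {
    a <- psi[ev, group_a]; b <- psi[ev, group_b]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < min_samples || length(b) < min_samples) return(NULL)
    delta <- mean(b) - mean(a)
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(b, a, exact = NULL)$p.value)
    data.frame(event_id = ev, n_a = length(a), n_b = length(b),
               mean_psi_a = mean(a), mean_psi_b = mean(b), delta_psi = delta,
               p = p, is_regulated = abs(delta) >= delta_min & p <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(event_id = character(0), n_a = integer(0),
                      n_b = integer(0), mean_psi_a = numeric(0),
                      mean_psi_b = numeric(0), delta_psi = numeric(0),
                      p = numeric(0), is_regulated = logical(0),
                      stringsAsFactors = FALSE)
  out$gene_id <- if (!is.null(events))
    events$gene_id[match(out$event_id, events$event_id)] else NA_character_
  rownames(out) <- NULL
  out
}

#' Overlap between two id sets
#'
#' @param list_a,list_b Character vectors (gene or event ids).
#' @return Named integer vector `c(only_a, only_b, shared)`.
#' @export
overlap_events <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  c(only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
    shared = length(intersect(a, b)))
}

#' Filter events against a reference junction panel
#'
#' An event is "found" in the panel when its exclusion junction and at least
#' one inclusion junction appear in the panel with exactly matching
#' coordinates; events absent from a deeply sequenced adult/placental panel
#' are candidate fetal-specific events.
#'
#' @param events Events data.frame from [detect_reciprocal_events()].
#' @param panel Junction table (e.g. from [read_junctions_bed()]).
#' @return `events` with an added logical column `found_in_panel`.
#' @export
filter_against_panel <- function(events, panel) {
  pk <- unique(junction_key(panel$chrom, panel$intron_start, panel$intron_end))
  excl_in <- junction_key(events$chrom, events$excl_start, events$excl_end) %in% pk
  inc1_in <- junction_key(events$chrom, events$incl1_start, events$incl1_end) %in% pk
  inc2_in <- !is.na(events$incl2_start) &
    junction_key(events$chrom, events$incl2_start, events$incl2_end) %in% pk
  events$found_in_panel <- excl_in & (inc1_in | inc2_in)
  events
}
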