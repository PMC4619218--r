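#' Configuration for the synthetic amniotic-fluid study generator
#'
#' Returns a validated list of simulation parameters mirroring the structure
#' of a three-stage amniotic-fluid cell-free RNA study: a small prenatal
#' group and two larger late-preterm and term groups, stage-monotone genes,
#' tissue-specific atlas markers with stage-dependent activity, fetal-sex
#' marker genes, and cassette-exon splicing events with a planted PSI shift
#' between the late-preterm and term groups.
#'
#' @param n_genes Number of genes in the expression matrix (sex-marker genes
#'   are added on top).
#' @param n_tissues Number of atlas tissues.
#' @param markers_per_tissue Planted specific markers per tissue.
#' @param n_active_tissues Number of tissues whose markers are detectable in
#'   amniotic fluid at all (nonzero per-stage activity).
#' @param group_sizes Integer triple: samples in PN, PT, FT.
#' @param stage_effect_log2 log2 expression step per stage for planted
#'   monotone genes.
#' @param marker_expression_fold Atlas fold elevation of a marker in its own
#'   tissue over the mean of the others.
#' @param noise_sd_log2 SD of the log2-normal expression noise.
#' @param n_monotone_genes Planted stage-monotone genes (half induced, half
#'   suppressed).
#' @param n_splicing_events Planted cassette-exon events.
#' @param base_psi True exon-inclusion level around which groups are shifted.
#' @param psi_shift Difference in true PSI between PT and FT groups.
#' @param base_junction_depth Mean per-event junction read depth per sample.
#' @param panel_event_fraction Fraction of events whose junctions are written
#'   to the synthetic reference junction panel.
#' @param seed Integer RNG seed; identical seeds give identical bundles.
#' @return A list of class `af_sim_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_tissues = 66L,
                              markers_per_tissue = 10L,
                              n_active_tissues = 10L,
                              group_sizes = c(PN = 4L, PT = 6L, FT = 6L),
                              stage_effect_log2 = 1.5,
                              marker_expression_fold = 8,
                              noise_sd_log2 = 0.4,
                              n_monotone_genes = 200L,
                              n_splicing_events = 50L,
                              base_psi = 0.5,
                              psi_shift = 0.3,
                              base_junction_depth = 60L,
                              panel_event_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
              markers_per_tissue = as.integer(markers_per_tissue),
              n_active_tissues = as.integer(n_active_tissues),
              group_sizes = stats::setNames(as.integer(group_sizes), STAGES),
              stage_effect_log2 = stage_effect_log2,
              marker_expression_fold = marker_expression_fold,
              noise_sd_log2 = noise_sd_log2,
              n_monotone_genes = as.integer(n_monotone_genes),
              n_splicing_events = as.integer(n_splicing_events),
              base_psi = base_psi, psi_shift = psi_shift,
              base_junction_depth = as.integer(base_junction_depth),
              panel_event_fraction = panel_event_fraction,
              seed = as.integer(seed))
  class(cfg) <- "af_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_genes", "n_tissues", "markers_per_tissue", "base_junction_depth")
  for (f in pos)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] <= 0)
      stop("simulation config: '", f, "' must be a positive integer", call. = FALSE)
  if (length(cfg$group_sizes) != 3 || any(cfg$group_sizes <= 0))
    stop("simulation config: group_sizes must be three positive counts",
         call. = FALSE)
  if (cfg$n_tissues < 3)
    stop("simulation config: need at least 3 tissues", call. = FALSE)
  if (cfg$n_active_tissues < 1 || cfg$n_active_tissues > cfg$n_tissues)
    stop("simulation config: n_active_tissues out of range", call. = FALSE)
  if (cfg$n_monotone_genes < 0 || cfg$n_splicing_events < 0)
    stop("simulation config: counts must be non-negative", call. = FALSE)
  if (cfg$noise_sd_log2 < 0)
    stop("simulation config: noise_sd_log2 must be >= 0", call. = FALSE)
  if (cfg$psi_shift < 0 || cfg$psi_shift >= 1)
    stop("simulation config: psi_shift must lie in [0, 1) so group PSI means stay in [0,1]",
         call. = FALSE)
  if (cfg$base_psi < 0 || cfg$base_psi > 1 ||
      cfg$base_psi - cfg$psi_shift / 2 < 0 || cfg$base_psi + cfg$psi_shift / 2 > 1)
    stop("simulation config: base_psi +/- psi_shift/2 must stay inside [0, 1]",
         call. = FALSE)
  if (cfg$panel_event_fraction < 0 || cfg$panel_event_fraction > 1)
    stop("simulation config: panel_event_fraction must lie in [0, 1]", call. = FALSE)
  need <- cfg$n_monotone_genes + cfg$n_active_tissues * cfg$markers_per_tissue
  if (need > cfg$n_genes)
    stop("simulation config: n_genes too small for the planted monotone genes ",
         "and active-tissue markers (need >= ", need, ")", call. = FALSE)
  invisible(cfg)
}

SEX_GENES <- c("XIST", "RPS4Y1", "DDX3Y", "EIF1AY")
CHRY_GENES <- c("RPS4Y1", "DDX3Y", "EIF1AY")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a three-stage amniotic-fluid cfRNA study with planted truth
#'
#' Generates an RPKM-scale expression matrix, sample metadata, a
#' gene-by-tissue atlas, a marker database, per-sample junction tables and a
#' ground-truth record. Planted structure: `n_monotone_genes` genes whose
#' stage means move by `stage_effect_log2` log2 units per step PN -> PT -> FT
#' (half induced, half suppressed); `markers_per_tissue` atlas markers per
#' tissue, elevated `marker_expression_fold`-fold in their own tissue, of
#' which the markers of `n_active_tissues` tissues are expressed in amniotic
#' fluid in a stage-dependent fraction (the activity table); XIST and
#' Y-chromosome marker genes consistent with each sample's fetal sex; and
#' cassette-exon events whose true PSI differs by `psi_shift` between the PT
#' and FT groups. Expression values are `2^(mu + N(0, noise_sd_log2))`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, all bundle files (matrix,
#'   metadata, atlas, markers GMT, per-sample junction BEDs, panel BED,
#'   ground_truth.json) are written there.
#' @return A list with elements `expression`, `metadata`, `atlas`, `markers`,
#'   `junctions` (all samples pooled, long format), `panel` (junction table of
#'   the synthetic reference panel), and `truth`.
#' @export
simulate_study <- function(config = simulation_config(), out_dir = NULL) {
  validate_sim_config(config)
  with_seed(config$seed, {
    res <- simulate_expression_bundle(config)
    jx <- simulate_junctions(config, res$truth, res$metadata)
    res$junctions <- jx$junctions
    res$panel <- jx$panel
    res$truth$splicing <- jx$truth_splicing
    res$truth$panel_event_ids <- jx$panel_event_ids
    res
  }) -> bundle
  if (!is.null(out_dir)) write_study_bundle(bundle, out_dir)
  bundle
}

simulate_expression_bundle <- function(cfg) {
  stages <- rep(STAGES, times = cfg$group_sizes)
  sample_ids <- sprintf("%s_%02d", stages, unlist(lapply(cfg$group_sizes, seq_len)))
  n_s <- length(sample_ids)
  sexes <- rep_len(c("male", "female"), n_s)

  ## morbidity flags among the PT group: 2 respiratory-only, 2 gavage-only,
  ## 1 both (3 respiratory, 3 gavage in total), extras unflagged
  morb <- rep("", n_s)
  pt_idx <- which(stages == "PT")
  if (length(pt_idx) >= 5) {
    morb[pt_idx[1:2]] <- "respiratory_support"
    morb[pt_idx[3:4]] <- "gavage_feeding"
    morb[pt_idx[5]] <- "respiratory_support;gavage_feeding"
  }
  weeks_rng <- do.call(rbind, STAGE_WEEK_RANGES[stages])
  weeks <- round(stats::runif(n_s, weeks_rng[, 1], weeks_rng[, 2]), 1)
  metadata <- data.frame(sample_id = sample_ids, stage = stages, weeks = weeks,
                         sex = sexes, morbidities = morb,
                         stringsAsFactors = FALSE)

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))

  n_half <- cfg$n_monotone_genes %/% 2
  induced <- genes[seq_len(n_half)]
  suppressed <- genes[n_half + seq_len(cfg$n_monotone_genes - n_half)]
  marker_pool <- genes[cfg$n_monotone_genes +
                         seq_len(cfg$n_tissues * cfg$markers_per_tissue)]
  tissue_markers <- split(marker_pool,
                          rep(tissues, each = cfg$markers_per_tissue))
  tissue_markers <- tissue_markers[tissues]

  active_tissues <- tissues[seq_len(cfg$n_active_tissues)]
  ## per-tissue per-stage fraction of markers expressed in AF, on a 0.2 grid
  activity <- matrix(0, nrow = cfg$n_tissues, ncol = 3,
                     dimnames = list(tissues, STAGES))
  for (t in active_tissues)
    activity[t, ] <- sample(seq(0.2, 1, by = 0.2), 3, replace = TRUE)

  all_genes <- c(genes, SEX_GENES)
  base_log2 <- stats::setNames(stats::rnorm(length(all_genes), 3, 1.5), all_genes)
  base_log2[base_log2 < 0] <- 0
  ## stage-monotone genes must be well expressed at their high end to be
  ## observable at all (a suppressed gene starts high and declines)
  monotone <- c(induced, suppressed)
  base_log2[monotone] <- stats::runif(length(monotone), 3, 6)

  ## per-gene per-sample log2 mean
  mu <- matrix(rep(base_log2, n_s), nrow = length(all_genes),
               dimnames = list(all_genes, sample_ids))
  step <- cfg$stage_effect_log2 * (match(stages, STAGES) - 1)
  mu[induced, ] <- mu[induced, , drop = FALSE] +
    matrix(step, nrow = length(induced), ncol = n_s, byrow = TRUE)
  mu[suppressed, ] <- mu[suppressed, , drop = FALSE] -
    matrix(step, nrow = length(suppressed), ncol = n_s, byrow = TRUE)

  ## markers: inactive ones barely expressed, active ones highly expressed
  active_high <- 10; inactive_low <- 0.5
  for (t in tissues) {
    mk <- tissue_markers[[t]]
    for (s in STAGES) {
      cols <- sample_ids[stages == s]
      n_act <- round(activity[t, s] * length(mk))
      mu[mk, cols] <- inactive_low
      if (n_act > 0) mu[mk[seq_len(n_act)], cols] <- active_high
    }
  }

  ## fetal sex markers
  male <- sample_ids[sexes == "male"]
  female <- sample_ids[sexes == "female"]
  mu["XIST", male] <- -5;  mu["XIST", female] <- 6
  mu[CHRY_GENES, male] <- 6; mu[CHRY_GENES, female] <- -5

  noise <- matrix(stats::rnorm(length(mu), 0, cfg$noise_sd_log2), nrow = nrow(mu))
  expr <- 2^(mu + noise)
  dimnames(expr) <- dimnames(mu)
  attr(expr, "scale") <- "rpkm"

  ## atlas: markers elevated in their own tissue; other genes flat across
  ## tissues up to log2-normal noise; sex genes flat
  atlas_base <- 2^(base_log2)
  atlas <- matrix(rep(atlas_base, cfg$n_tissues), nrow = length(all_genes),
                  dimnames = list(all_genes, tissues))
  for (t in tissues)
    atlas[tissue_markers[[t]], t] <- atlas[tissue_markers[[t]], t] *
      cfg$marker_expression_fold
  atlas <- atlas * 2^matrix(stats::rnorm(length(atlas), 0, cfg$noise_sd_log2),
                            nrow = nrow(atlas))
  dimnames(atlas) <- list(all_genes, tissues)

  ## recorded activity = realized fraction (integer marker counts)
  realized <- activity
  for (t in tissues)
    realized[t, ] <- round(activity[t, ] * cfg$markers_per_tissue) /
      cfg$markers_per_tissue

  truth <- list(
    induced_gene_ids = induced,
    suppressed_gene_ids = suppressed,
    tissue_marker_map = tissue_markers,
    active_tissues = active_tissues,
    marker_activity = realized,
    fetal_sex = stats::setNames(sexes, sample_ids),
    null_gene_ids = setdiff(genes, c(induced, suppressed, marker_pool))
  )
  list(expression = expr, metadata = metadata, atlas = atlas,
       markers = tissue_markers[active_tissues], truth = truth)
}

#' Simulate junction read counts for planted cassette-exon events
#'
#' Each planted event contributes two inclusion junctions flanking an implied
#' cassette exon and one exclusion junction sharing both outer boundaries, as
#' required for reciprocal-pair detection. Per sample, total event depth is
#' Poisson around `base_junction_depth` and inclusion reads are binomial with
#' the sample group's true PSI; the exclusion junction receives the
#' remainder. Junctions with zero reads in a sample are omitted from that
#' sample's table, as spliced aligners omit unobserved junctions.
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth list from the expression step (used for event
#'   bookkeeping; may be an empty list).
#' @param metadata Sample metadata data.frame.
#' @return A list with `junctions` (long data.frame over all samples),
#'   `panel` (junction table of the reference panel), `truth_splicing`
#'   (per-event true group PSI), `panel_event_ids`.
#' @export
simulate_junctions <- function(config, truth, metadata) {
  cfg <- config
  n_ev <- cfg$n_splicing_events
  if (n_ev == 0) {
    empty <- data.frame(chrom = character(0), intron_start = integer(0),
                        intron_end = integer(0), strand = character(0),
                        count = integer(0), sample_id = character(0))
    return(list(junctions = empty, panel = empty,
                truth_splicing = data.frame(), panel_event_ids = character(0)))
  }
  ev_start <- 10000L * seq_len(n_ev)            # 0-based intron starts
  exon_a <- ev_start + 300L; exon_b <- ev_start + 600L
  ev_end <- ev_start + 900L
  gene_ids <- sprintf("SPL%04d", seq_len(n_ev))

  base_psi <- cfg$base_psi
  shift_sign <- rep_len(c(1, -1), n_ev)
  psi <- data.frame(
    event = seq_len(n_ev), gene_id = gene_ids, chrom = "chrS",
    intron_start = ev_start, intron_end = ev_end,
    psi_PN = base_psi,
    psi_PT = base_psi - shift_sign * cfg$psi_shift / 2,
    psi_FT = base_psi + shift_sign * cfg$psi_shift / 2
  )

  rows <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    p_true <- psi[[paste0("psi_", metadata$stage[i])]]
    depth <- pmax(1L, stats::rpois(n_ev, cfg$base_junction_depth))
    incl <- stats::rbinom(n_ev, depth, p_true)
    excl <- depth - incl
    rows[[i]] <- data.frame(
      chrom = "chrS",
      intron_start = c(ev_start, exon_b, ev_start),
      intron_end = c(exon_a, ev_end, ev_end),
      strand = ".",
      count = c(incl, incl, excl),
      sample_id = sid,
      stringsAsFactors = FALSE
    )
  }
  jx <- do.call(rbind, rows)
  jx <- jx[jx$count > 0, , drop = FALSE]
  jx <- jx[order(jx$sample_id, jx$chrom, jx$intron_start, jx$intron_end), ,
           drop = FALSE]
  rownames(jx) <- NULL

  n_panel <- round(cfg$panel_event_fraction * n_ev)
  panel_ev <- sort(sample(seq_len(n_ev), n_panel))
  panel <- data.frame(
    chrom = "chrS",
    intron_start = c(ev_start[panel_ev], exon_b[panel_ev], ev_start[panel_ev]),
    intron_end = c(exon_a[panel_ev], ev_end[panel_ev], ev_end[panel_ev]),
    strand = ".", count = 50L, sample_id = "panel",
    stringsAsFactors = FALSE
  )
  panel <- panel[order(panel$chrom, panel$intron_start, panel$intron_end), ,
                 drop = FALSE]
  rownames(panel) <- NULL
  list(junctions = jx, panel = panel, truth_splicing = psi,
       panel_event_ids = gene_ids[panel_ev])
}

write_study_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(bundle$expression, file.path(out_dir, "expression.tsv"))
  write_sample_metadata(bundle$metadata, file.path(out_dir, "metadata.tsv"))
  write_tissue_atlas(bundle$atlas, file.path(out_dir, "atlas.tsv"))
  write_marker_database(bundle$markers, file.path(out_dir, "markers.gmt"))
  jdir <- file.path(out_dir, "junctions")
  dir.create(jdir, showWarnings = FALSE)
  for (sid in unique(bundle$metadata$sample_id)) {
    j <- bundle$junctions[bundle$junctions$sample_id == sid, , drop = FALSE]
    write_junctions_bed(j, file.path(jdir, paste0(sid, ".bed")))
  }
  write_junctions_bed(bundle$panel, file.path(out_dir, "panel.bed"))
  truth <- bundle$truth
  truth$marker_activity <- as.data.frame(truth$marker_activity)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}
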