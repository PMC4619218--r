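#' Configuration for a full pipeline run
#'
#' Collects thresholds, contrast definitions and the seed for [run_all()].
#' Validation happens before any computation.
#'
#' @param alpha FDR threshold for stage differential expression.
#' @param fold_min Stage fold-change threshold.
#' @param moderated_fold_min Fold threshold for morbidity contrasts.
#' @param quantile Abundance quantile for tissue profiling.
#' @param delta_min Minimum |delta PSI| for a regulated splicing event.
#' @param min_total_reads Junction coverage threshold for PSI.
#' @param trend_method `"sign"` or `"som"` temporal classification.
#' @param seed Integer seed governing the simulation and the SOM.
#' @param simulate A [simulation_config()] used when no input bundle is
#'   supplied (its seed is overridden by `seed`).
#' @return List of class `af_run_config`.
#' @export
run_config <- function(alpha = 0.05, fold_min = 1.5, moderated_fold_min = 2.0,
                       quantile = 0.90, delta_min = 0.1, min_total_reads = 10,
                       trend_method = c("sign", "som"), seed = 1L,
                       simulate = simulation_config()) {
  trend_method <- match.arg(trend_method)
  cfg <- list(alpha = alpha, fold_min = fold_min,
              moderated_fold_min = moderated_fold_min, quantile = quantile,
              delta_min = delta_min, min_total_reads = min_total_reads,
              trend_method = trend_method, seed = as.integer(seed),
              simulate = simulate)
  class(cfg) <- "af_run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  in01 <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x < 1
  if (!in01(cfg$alpha)) stop("run config: alpha must lie in (0, 1)", call. = FALSE)
  if (!in01(cfg$quantile)) stop("run config: quantile must lie in (0, 1)", call. = FALSE)
  if (!is.finite(cfg$fold_min) || cfg$fold_min < 1)
    stop("run config: fold_min must be >= 1", call. = FALSE)
  if (!is.finite(cfg$moderated_fold_min) || cfg$moderated_fold_min < 1)
    stop("run config: moderated_fold_min must be >= 1", call. = FALSE)
  if (!is.finite(cfg$delta_min) || cfg$delta_min < 0 || cfg$delta_min > 1)
    stop("run config: delta_min must lie in [0, 1]", call. = FALSE)
  if (!is.finite(cfg$min_total_reads) || cfg$min_total_reads < 0)
    stop("run config: min_total_reads must be >= 0", call. = FALSE)
  validate_sim_config(cfg$simulate)
  invisible(cfg)
}

log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full amniotic-fluid transcriptome pipeline
#'
#' Simulates (or accepts) a study bundle, then executes normalization and
#' filtering, stage differential expression with temporal classification,
#' morbidity-contrast moderated t-tests, tissue profiling (specific markers,
#' stage profile, marker-set enrichment of differential genes), the fetal
#' origin check, and the splicing analysis (event detection, PSI, PT-vs-FT
#' comparison, panel filtering). All stage outputs are written to `out_dir`
#' as TSVs together with a machine-readable `summary.json`; identical seed
#' and inputs give an identical summary.
#'
#' @param config A [run_config()].
#' @param bundle Optional study bundle (as from [simulate_study()]); when
#'   NULL one is simulated with `config$seed`.
#' @param out_dir Optional output directory.
#' @return A list: the bundle, all stage results, and `summary` (the content
#'   of summary.json).
#' @export
run_all <- function(config = run_config(), bundle = NULL, out_dir = NULL) {
  validate_run_config(config)
  logcon <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logcon <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]

  if (is.null(bundle)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    log_stage(logcon, "simulate", sprintf("seed=%d genes=%d", sim_cfg$seed,
                                          sim_cfg$n_genes))
    bundle <- simulate_study(sim_cfg)
  }
  m <- bundle$expression; meta <- bundle$metadata

  log_stage(logcon, "normalize", "TMM factors + RPKM>1 filter")
  norm <- tmm_normalize(m)
  mf <- filter_expressed(norm$matrix, rpkm_min = 1.0)

  log_stage(logcon, "de", sprintf("ANOVA across stages on %d genes", nrow(mf)))
  de <- anova_stage_test(mf, meta, alpha = config$alpha,
                         fold_min = config$fold_min)
  de <- classify_temporal_patterns(de, mf, meta, method = config$trend_method,
                                   seed = config$seed)

  log_stage(logcon, "morbidity", "moderated t per morbidity flag vs term")
  ft <- stage_samples(meta, "FT")
  morbidity <- lapply(stats::setNames(MORBIDITIES, MORBIDITIES), function(fl) {
    ids <- morbidity_samples(meta, fl)
    if (length(ids) < 2 || length(ft) < 2) return(NULL)
    moderated_t_test(mf, group_a = ft, group_b = ids,
                     fold_min = config$moderated_fold_min, alpha = config$alpha)
  })

  log_stage(logcon, "tissue", "atlas specificity, stage profile, enrichment")
  calls <- score_tissue_specificity(rownames(bundle$atlas), bundle$atlas)
  profile <- stage_marker_profile(mf, meta, bundle$atlas,
                                  quantile = config$quantile)
  de_genes <- de$gene_id[de$is_differential]
  enrichment <- if (length(de_genes) && length(bundle$markers))
    marker_enrichment(de_genes, de$gene_id, bundle$markers,
                      alpha = config$alpha) else NULL
  origin <- check_fetal_origin(mf, meta)

  log_stage(logcon, "splicing", "reciprocal events, PSI, PT vs FT")
  gene_map <- NULL
  if (!is.null(bundle$truth$splicing) && nrow(bundle$truth$splicing))
    gene_map <- bundle$truth$splicing[, c("chrom", "intron_start",
                                          "intron_end", "gene_id")]
  events <- detect_reciprocal_events(bundle$junctions, gene_map = gene_map)
  psi <- compute_psi(events, bundle$junctions,
                     min_total_reads = config$min_total_reads)
  psi_cmp <- compare_psi_groups(psi, stage_samples(meta, "PT"),
                                stage_samples(meta, "FT"), events = events,
                                delta_min = config$delta_min,
                                alpha = config$alpha)
  if (!is.null(bundle$panel) && nrow(bundle$panel))
    events <- filter_against_panel(events, bundle$panel)

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_samples = nrow(meta),
    n_genes_filtered = nrow(mf),
    n_differential = sum(de$is_differential),
    n_induced = sum(de$trend == "induced"),
    n_suppressed = sum(de$trend == "suppressed"),
    n_regulated_morbidity = lapply(morbidity, function(x)
      if (is.null(x)) NA_integer_ else sum(x$is_regulated)),
    n_specific_markers = sum(calls$is_specific),
    stage_profile_tissues = nrow(profile),
    n_enriched_marker_sets = if (is.null(enrichment)) 0L else
      sum(enrichment$is_enriched),
    sex_concordant = sum(origin$concordant, na.rm = TRUE),
    sex_checked = sum(!is.na(origin$concordant)),
    n_events = nrow(events),
    n_regulated_events = sum(psi_cmp$is_regulated),
    n_events_in_panel = if ("found_in_panel" %in% names(events))
      sum(events$found_in_panel) else NA_integer_
  )
  log_stage(logcon, "summary",
            sprintf("elapsed %.2fs", proc.time()[["elapsed"]] - t0))

  if (!is.null(out_dir)) {
    write.table(de, file.path(out_dir, "differential.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (fl in names(morbidity)) if (!is.null(morbidity[[fl]]))
      write.table(morbidity[[fl]],
                  file.path(out_dir, paste0("moderated_", fl, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(out_dir, "tissue_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(profile, file.path(out_dir, "stage_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment))
      write.table(enrichment, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write.table(origin, file.path(out_dir, "fetal_origin.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(event_id = rownames(psi), psi, check.names = FALSE),
                file.path(out_dir, "psi.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(psi_cmp, file.path(out_dir, "psi_regulated.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage(logcon, "done", sprintf("outputs in %s", out_dir))
  }

  list(bundle = bundle, normalization = norm, filtered = mf, differential = de,
       morbidity = morbidity, tissue_calls = calls, stage_profile = profile,
       enrichment = enrichment, fetal_origin = origin, events = events,
       psi = psi, psi_comparison = psi_cmp, summary = summary)
}
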