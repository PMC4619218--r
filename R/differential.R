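STAGE_CONTRASTS <- list(PN_FT = c("PN", "FT"), PN_PT = c("PN", "PT"),
                        PT_FT = c("PT", "FT"))

match_samples <- function(m, ids, what = "sample") {
  miss <- setdiff(ids, colnames(m))
  if (length(miss))
    stop(what, "(s) not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  match(ids, colnames(m))
}

## fold >= 1 with direction, pseudocount acting as a floor on linear group
## means so folds stay bounded when a group is unexpressed
fold_and_direction <- function(mean_first, mean_second, pseudocount) {
  r <- pmax(mean_second, pseudocount) / pmax(mean_first, pseudocount)
  list(fold = pmax(r, 1 / r), direction = ifelse(r >= 1, "up", "down"))
}

## pooled two-sample t on precomputed means/vars; returns two-sided p
pooled_t_p <- function(ma, mb, va, vb, na, nb) {
  d <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / d
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df = d)
  zero <- se == 0
  p[zero & ma == mb] <- 1
  p[zero & ma != mb] <- 0
  p
}

#' Stage-wise differential expression by one-way ANOVA with paired comparisons
#'
#' Per gene, a one-way F-test across the three gestational stages on
#' `log2(value + pseudocount)`, Benjamini-Hochberg adjustment of the ANOVA p,
#' and the three pairwise stage comparisons (classical pooled two-sample t on
#' the log scale; fold change as ratio of linear group means). A gene is
#' called differential when the adjusted ANOVA p is at or below `alpha` and
#' at least one pairwise fold change reaches `fold_min`. Genes with zero
#' between- and within-group variance get p = 1.
#'
#' @param m RPKM-scale expression matrix (already filtered).
#' @param metadata Sample metadata; every matrix column must appear.
#' @param alpha FDR threshold on the adjusted ANOVA p.
#' @param fold_min Minimum linear fold change in at least one comparison.
#' @param pseudocount Added before the log2 transform, and used as a floor on
#'   linear group means when computing fold changes.
#' @return Data.frame with one row per gene: `anova_f`, `anova_p`,
#'   `anova_p_adjusted`, per-contrast `fold_*`, `dir_*`, `p_*` columns
#'   (contrasts PN_FT, PN_PT, PT_FT; direction "up" means the later stage is
#'   higher), `max_fold`, `is_differential`, and a `trend` column
#'   (initialised to "none"; see [classify_temporal_patterns()]).
#' @export
anova_stage_test <- function(m, metadata, alpha = 0.05, fold_min = 1.5,
                             pseudocount = 1.0) {
  validate_expression_matrix(m)
  idx <- match(colnames(m), metadata$sample_id)
  if (anyNA(idx))
    stop("matrix sample(s) missing from metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  stage <- metadata$stage[idx]
  sizes <- table(factor(stage, levels = STAGES))
  if (any(sizes < 2))
    stop("each stage needs >= 2 samples; got ",
         paste(sprintf("%s=%d", STAGES, sizes), collapse = ", "), call. = FALSE)

  x <- log2(m + pseudocount)
  n <- ncol(x)
  ind <- stats::model.matrix(~ 0 + factor(stage, levels = STAGES))
  colnames(ind) <- STAGES
  ns <- colSums(ind)
  gm_log <- (x %*% ind) / rep(ns, each = nrow(x))        # log-scale stage means
  gv_log <- ((x^2) %*% ind - rep(ns, each = nrow(x)) * gm_log^2) /
    rep(ns - 1, each = nrow(x))                          # stage variances
  gv_log[gv_log < 0] <- 0                                # numerical guard
  grand <- rowMeans(x)
  ssb <- rowSums(rep(ns, each = nrow(x)) * (gm_log - grand)^2)
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  k <- length(STAGES)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  f[ssw == 0 & ssb == 0] <- 0
  p_adj <- benjamini_hochberg(p)

  gm_lin <- (m %*% ind) / rep(ns, each = nrow(m))        # linear stage means
  res <- data.frame(gene_id = rownames(m), anova_f = f, anova_p = p,
                    anova_p_adjusted = p_adj, stringsAsFactors = FALSE)
  folds <- matrix(NA_real_, nrow(m), length(STAGE_CONTRASTS))
  for (j in seq_along(STAGE_CONTRASTS)) {
    cn <- names(STAGE_CONTRASTS)[j]
    a <- STAGE_CONTRASTS[[j]][1]; b <- STAGE_CONTRASTS[[j]][2]
    fd <- fold_and_direction(gm_lin[, a], gm_lin[, b], pseudocount)
    pp <- pooled_t_p(gm_log[, a], gm_log[, b], gv_log[, a], gv_log[, b],
                     ns[a], ns[b])
    res[[paste0("fold_", cn)]] <- fd$fold
    res[[paste0("dir_", cn)]] <- fd$direction
    res[[paste0("p_", cn)]] <- pp
    folds[, j] <- fd$fold
  }
  res$max_fold <- apply(folds, 1, max)
  res$is_differential <- res$anova_p_adjusted <= alpha & res$max_fold >= fold_min
  res$trend <- "none"
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validates that all inputs lie in \[0, 1\] and returns the step-up adjusted
#' p-values (monotone, clipped at 1, in the original order).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

trigamma_inverse <- function(y) {
  ## Newton iteration on x -> trigamma(x), decreasing convex
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

estimate_variance_prior <- function(s2, d) {
  ## moment matching on log sample variances against a scaled F distribution
  ok <- s2 > 0
  if (sum(ok) < 2)
    stop("too few genes with positive variance to estimate the prior",
         call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e)
  resid <- evar - trigamma(d / 2)
  if (resid <= 0) {
    d0 <- Inf
    s0 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(resid)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, var_prior = s0)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Pooled per-gene variances are shrunk toward a prior variance `s0^2` with
#' `d0` prior degrees of freedom, `(d0*s0^2 + d*s^2)/(d0 + d)`, where
#' `(d0, s0^2)` are estimated across genes by moment matching of the log
#' sample variances (closed form via the trigamma inverse). The moderated t
#' statistic uses `d + d0` degrees of freedom. Designed for very small
#' morbidity subgroups where per-gene variances are unstable. A gene is
#' called regulated when the BH-adjusted p is at or below `alpha` and the
#' linear fold change exceeds `fold_min`.
#'
#' @param m RPKM-scale expression matrix.
#' @param group_a,group_b Character vectors of sample ids (see
#'   [stage_samples()] / [morbidity_samples()]); each needs >= 2 samples.
#' @param fold_min Linear fold-change threshold (strict).
#' @param alpha Threshold on the BH-adjusted p.
#' @param pseudocount As in [anova_stage_test()].
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom; `0` gives the ordinary pooled two-sample t-test.
#' @return Data.frame with `gene_id`, `log_fold_change` (log2, group_b minus
#'   group_a), `fold_change` (linear, >= 1), `t_moderated`, `p`,
#'   `p_adjusted`, `df_prior`, `var_prior`, `is_regulated`.
#' @export
moderated_t_test <- function(m, group_a, group_b, fold_min = 2.0, alpha = 0.05,
                             pseudocount = 1.0, prior_df = NULL) {
  validate_expression_matrix(m)
  if (nrow(m) == 0) stop("no genes in matrix", call. = FALSE)
  ia <- match_samples(m, group_a); ib <- match_samples(m, group_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  x <- log2(m + pseudocount)
  ma <- rowMeans(x[, ia, drop = FALSE]); mb <- rowMeans(x[, ib, drop = FALSE])
  va <- apply(x[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(x[, ib, drop = FALSE], 1, stats::var)
  d <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d

  if (is.null(prior_df)) {
    pr <- estimate_variance_prior(s2, d)
  } else if (prior_df == 0) {
    pr <- list(df_prior = 0, var_prior = NA_real_)
  } else {
    pr <- list(df_prior = prior_df,
               var_prior = estimate_variance_prior(s2, d)$var_prior)
  }
  d0 <- pr$df_prior; s0 <- pr$var_prior
  s2_post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  delta <- mb - ma
  t <- delta / se
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  zero <- se == 0
  p[zero & delta == 0] <- 1; t[zero & delta == 0] <- 0
  p[zero & delta != 0] <- 0

  fd <- fold_and_direction(rowMeans(m[, ia, drop = FALSE]),
                           rowMeans(m[, ib, drop = FALSE]), pseudocount)
  p_adj <- benjamini_hochberg(p)
  data.frame(gene_id = rownames(m), log_fold_change = delta,
             fold_change = fd$fold, direction = fd$direction,
             t_moderated = t, p = p, p_adjusted = p_adj,
             df_prior = d0, var_prior = s0,
             is_regulated = p_adj <= alpha & fd$fold > fold_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

## online 1-D self-organizing map: rectangular grid, Gaussian neighbourhood,
## linearly decaying learning rate and radius
som_1d <- function(X, k = 2, epochs = 500, lr0 = 0.5, lr1 = 0.01, seed = 1) {
  with_seed(seed, {
    n <- nrow(X)
    cb <- X[sample(n, k, replace = n < k), , drop = FALSE]
    grid <- seq_len(k)
    sigma0 <- max(k / 2, 0.5); sigma1 <- 0.3
    total <- epochs * n; it <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (i in ord) {
        it <- it + 1
        frac <- it / total
        lr <- lr0 + (lr1 - lr0) * frac
        sigma <- sigma0 + (sigma1 - sigma0) * frac
        x <- X[i, ]
        bmu <- which.min(rowSums(sweep(cb, 2, x)^2))
        h <- exp(-((grid - bmu)^2) / (2 * sigma^2))
        cb <- cb + lr * h * sweep(-cb, 2, x, "+")
      }
    }
    list(codebook = cb,
         bmu = apply(X, 1, function(x)
           which.min(rowSums(sweep(cb, 2, x)^2))))
  })
}

#' Classify temporal expression patterns of differential genes
#'
#' Labels each differential gene as `induced` (expression rising with
#' gestational age PN -> PT -> FT), `suppressed`, or `none`. Method `"sign"`
#' requires log-scale stage means to move monotonically, allowing one flat
#' step. Method `"som"` trains a one-dimensional self-organizing map on
#' z-scored stage-mean triples and labels each node by the slope of its
#' codebook vector.
#'
#' @param results Data.frame from [anova_stage_test()].
#' @param m The expression matrix the results came from.
#' @param metadata Sample metadata.
#' @param method `"sign"` or `"som"`.
#' @param k Number of SOM nodes.
#' @param seed RNG seed for the SOM.
#' @param pseudocount As in [anova_stage_test()].
#' @return `results` with the `trend` column filled in for differential genes.
#' @export
classify_temporal_patterns <- function(results, m, metadata,
                                       method = c("sign", "som"), k = 2,
                                       seed = 1, pseudocount = 1.0) {
  method <- match.arg(method)
  genes <- results$gene_id[results$is_differential]
  if (!length(genes)) return(results)
  idx <- match(colnames(m), metadata$sample_id)
  stage <- metadata$stage[idx]
  x <- log2(m[genes, , drop = FALSE] + pseudocount)
  sm <- vapply(STAGES, function(s)
    rowMeans(x[, stage == s, drop = FALSE]), numeric(length(genes)))
  if (length(genes) == 1) sm <- matrix(sm, nrow = 1, dimnames = list(genes, STAGES))

  tol <- 1e-8
  trend <- rep("none", length(genes))
  if (method == "sign") {
    d1 <- sm[, "PT"] - sm[, "PN"]; d2 <- sm[, "FT"] - sm[, "PT"]
    up <- d1 >= -tol & d2 >= -tol & (d1 > tol | d2 > tol)
    dn <- d1 <= tol & d2 <= tol & (d1 < -tol | d2 < -tol)
    trend[up] <- "induced"; trend[dn] <- "suppressed"
  } else {
    sds <- apply(sm, 1, stats::sd)
    ok <- sds > tol
    if (any(ok)) {
      z <- (sm[ok, , drop = FALSE] - rowMeans(sm[ok, , drop = FALSE])) /
        sds[ok]
      fit <- som_1d(z, k = k, seed = seed)
      slope <- fit$codebook[, 3] - fit$codebook[, 1]
      lab <- ifelse(slope > tol, "induced",
                    ifelse(slope < -tol, "suppressed", "none"))
      trend[ok] <- lab[fit$bmu]
    }
  }
  results$trend[match(genes, results$gene_id)] <- trend
  results
}
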