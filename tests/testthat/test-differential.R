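test_that("stage ANOVA handles degenerate genes and recovers strong separations", {
  set.seed(2)
  pn <- c(flat = 4, strong = 1)
  pt <- c(flat = 4, strong = 8)
  ft <- c(flat = 4, strong = 8)
  m <- make_stage_matrix(pn, pt, ft)
  # tiny jitter on the separated gene so within-group variance is nonzero
  m["strong", ] <- m["strong", ] * 2^rnorm(ncol(m), 0, 1e-3)
  meta <- make_stage_metadata(m)
  res <- anova_stage_test(m, meta)

  flat <- res[res$gene_id == "flat", ]
  expect_equal(flat$anova_f, 0)
  expect_equal(flat$anova_p, 1)
  expect_false(flat$is_differential)

  strong <- res[res$gene_id == "strong", ]
  expect_lt(strong$anova_p, 1e-6)
  expect_equal(strong$fold_PN_FT, 8, tolerance = 1e-2)
  expect_identical(strong$dir_PN_FT, "up")
  expect_true(strong$is_differential)
})

test_that("stage ANOVA p-values match the classical aov fit", {
  set.seed(3)
  m <- matrix(2^rnorm(20 * 16, 4, 1), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  colnames(m) <- sprintf("%s_%02d", rep(c("PN", "PT", "FT"), c(4, 6, 6)),
                         c(1:4, 1:6, 1:6))
  meta <- make_stage_metadata(m)
  res <- anova_stage_test(m, meta)
  stage <- factor(meta$stage, levels = c("PN", "PT", "FT"))
  for (g in rownames(m)) {
    y <- log2(m[g, ] + 1)
    fit <- summary(aov(y ~ stage))[[1]]
    expect_equal(res$anova_p[res$gene_id == g], fit[["Pr(>F)"]][1],
                 tolerance = 1e-10)
    expect_equal(res$anova_f[res$gene_id == g], fit[["F value"]][1],
                 tolerance = 1e-10)
  }
})

test_that("stage ANOVA is invariant to column order and stable under rescaling", {
  set.seed(4)
  m <- matrix(2^rnorm(50 * 16, 5, 1), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  colnames(m) <- sprintf("%s_%02d", rep(c("PN", "PT", "FT"), c(4, 6, 6)),
                         c(1:4, 1:6, 1:6))
  m[1:10, 13:16] <- m[1:10, 13:16] * 8
  meta <- make_stage_metadata(m)
  res <- anova_stage_test(m, meta)

  perm <- sample(ncol(m))
  res_perm <- anova_stage_test(m[, perm], meta)
  expect_equal(res_perm$anova_p, res$anova_p)
  expect_equal(res_perm$is_differential, res$is_differential)

  res_scaled <- anova_stage_test(2 * m, meta)
  expect_identical(res_scaled$is_differential, res$is_differential)
  expect_equal(res_scaled$anova_p, res$anova_p, tolerance = 0.05)
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    # monotone in the raw p ordering
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("moderated t reduces to the ordinary t without a prior", {
  set.seed(6)
  m <- matrix(2^rnorm(30 * 6, 4, 1), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30),
                              c(paste0("a", 1:3), paste0("b", 1:3))))
  res <- moderated_t_test(m, paste0("a", 1:3), paste0("b", 1:3), prior_df = 0)
  for (g in sample(rownames(m), 5)) {
    y <- log2(m[g, ] + 1)
    tt <- t.test(y[4:6], y[1:3], var.equal = TRUE)
    expect_equal(res$t_moderated[res$gene_id == g], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(res$p[res$gene_id == g], tt$p.value, tolerance = 1e-10)
  }

  # identical group means -> t = 0, p = 1
  m2 <- matrix(5, nrow = 2, ncol = 4,
               dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  res2 <- moderated_t_test(m2, c("a1", "a2"), c("b1", "b2"), prior_df = 0)
  expect_equal(res2$t_moderated, c(0, 0))
  expect_equal(res2$p, c(1, 1))
})

test_that("variance shrinkage agrees with limma's empirical-Bayes prior", {
  skip_if_not_installed("limma")
  set.seed(7)
  na <- 4; nb <- 4; d <- na + nb - 2
  # heteroscedastic genes so the prior degrees of freedom are finite
  sds <- sqrt(1 / rgamma(500, shape = 2, rate = 2))
  m <- matrix(2^(rnorm(500 * (na + nb), 4, 1) * rep(sds, na + nb)), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500),
                              c(paste0("a", 1:na), paste0("b", 1:nb))))
  res <- moderated_t_test(m, paste0("a", 1:na), paste0("b", 1:nb))
  x <- log2(m + 1)
  va <- apply(x[, 1:na], 1, var); vb <- apply(x[, na + 1:nb], 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d
  sq <- limma::squeezeVar(s2, df = d)
  expect_true(is.finite(sq$df.prior))
  expect_equal(res$df_prior[1], sq$df.prior, tolerance = 1e-6)
  expect_equal(res$var_prior[1], sq$var.prior, tolerance = 1e-6)
  post <- (sq$df.prior * sq$var.prior + d * s2) / (sq$df.prior + d)
  se <- sqrt(post * (1 / na + 1 / nb))
  tmod <- (rowMeans(x[, na + 1:nb]) - rowMeans(x[, 1:na])) / se
  expect_equal(res$t_moderated, unname(tmod), tolerance = 1e-6)
})

test_that("moderated t has more power than the ordinary t at tiny n", {
  set.seed(8)
  reps <- 60
  hits_mod <- hits_ord <- 0; total <- 0
  for (r in seq_len(reps)) {
    n_null <- 400; n_alt <- 40
    m <- matrix(2^rnorm((n_null + n_alt) * 6, 5, 0.7), ncol = 6)
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
    alt <- seq_len(n_alt)
    m[alt, 4:6] <- m[alt, 4:6] * 4  # true log2 shift of 2
    mod <- moderated_t_test(m, paste0("a", 1:3), paste0("b", 1:3))
    ord <- moderated_t_test(m, paste0("a", 1:3), paste0("b", 1:3), prior_df = 0)
    hits_mod <- hits_mod + sum(mod$p[alt] <= 0.05)
    hits_ord <- hits_ord + sum(ord$p[alt] <= 0.05)
    total <- total + n_alt
  }
  expect_gt(hits_mod / total, hits_ord / total)
})

test_that("temporal patterns are classified by sign and by SOM", {
  m <- make_stage_matrix(c(up = 1, down = 4, bump = 1),
                         c(up = 2, down = 2, bump = 6),
                         c(up = 4, down = 1, bump = 1))
  meta <- make_stage_metadata(m)
  res <- data.frame(gene_id = rownames(m), is_differential = TRUE,
                    trend = "none", stringsAsFactors = FALSE)
  sign <- classify_temporal_patterns(res, m, meta, method = "sign")
  expect_identical(sign$trend, c("induced", "suppressed", "none"))

  # SOM on noiseless planted data reproduces the sign labels for all
  # planted monotone genes
  cfg <- simulation_config(n_genes = 300, n_monotone_genes = 40,
                           n_tissues = 10, n_active_tissues = 4,
                           noise_sd_log2 = 0, n_splicing_events = 0, seed = 21)
  b <- simulate_study(cfg)
  mf <- filter_expressed(b$expression)
  de <- anova_stage_test(mf, b$metadata)
  de_sign <- classify_temporal_patterns(de, mf, b$metadata, method = "sign")
  de_som <- classify_temporal_patterns(de, mf, b$metadata, method = "som",
                                       seed = 21)
  planted <- c(b$truth$induced_gene_ids, b$truth$suppressed_gene_ids)
  i <- match(planted, de$gene_id)
  expect_identical(de_som$trend[i], de_sign$trend[i])
})
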