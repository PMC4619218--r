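test_that("abundant genes use a strict linear-interpolation quantile cut", {
  m <- matrix(rep(1:10, 3), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  colnames(m) <- c("FT_01", "FT_02", "FT_03")
  meta <- data.frame(sample_id = colnames(m), stage = "FT", weeks = 39,
                     sex = "unknown", morbidities = "", stringsAsFactors = FALSE)
  # type-7 quantile of 1..10 at 0.9 is 9.1; only the gene with mean 10 exceeds
  expect_identical(abundant_genes(m, meta, "FT", 0.90), "g10")
  expect_identical(abundant_genes(m, meta, "FT", 0.001),
                   sprintf("g%02d", 2:10))
  mc <- m; mc[] <- 7
  expect_length(abundant_genes(mc, meta, "FT", 0.90), 0)
})

test_that("tissue specificity applies the 3x mean and 1.5x max rules", {
  atlas <- matrix(50, nrow = 4, ncol = 66,
                  dimnames = list(c("spec", "enr", "flat", "zero"),
                                  sprintf("t%02d", 1:66)))
  atlas["spec", 1] <- 300; atlas["spec", 2] <- 150
  atlas["enr", 1] <- 300; atlas["enr", 2] <- 250
  atlas["zero", ] <- 0
  expect_warning(calls <- score_tissue_specificity(rownames(atlas), atlas),
                 "all-zero")
  spec <- calls[calls$gene_id == "spec", ]
  expect_identical(spec$tissue, "t01")
  expect_true(spec$is_enriched && spec$is_specific)
  expect_equal(spec$fold_vs_max_other, 2)

  enr <- calls[calls$gene_id == "enr", ]
  expect_true(enr$is_enriched)       # 300 vs mean of others >= 3x
  expect_false(enr$is_specific)      # 300/250 = 1.2 < 1.5
  flat <- calls[calls$gene_id == "flat", ]
  expect_equal(flat$fold_vs_mean_others, 1)
  expect_false(flat$is_enriched)
  expect_false("zero" %in% calls$gene_id)

  # specific implies enriched; calls invariant to uniform atlas rescaling
  expect_true(all(!calls$is_specific | calls$is_enriched))
  calls2 <- suppressWarnings(score_tissue_specificity(rownames(atlas),
                                                      atlas * 7.3))
  expect_identical(calls2$is_specific, calls$is_specific)
  expect_identical(calls2$is_enriched, calls$is_enriched)
})

test_that("stage marker profile is the fraction of specific markers abundant per stage", {
  # 2 tissues x 2 markers; in FT both markers of tissue A are abundant, in PN
  # none are
  genes <- c("a1", "a2", "b1", "b2", sprintf("bg%02d", 1:36))
  atlas <- matrix(10, nrow = length(genes), ncol = 5,
                  dimnames = list(genes, sprintf("t%d", 1:5)))
  atlas[c("a1", "a2"), 1] <- 100
  atlas[c("b1", "b2"), 2] <- 100
  mexp <- matrix(1, nrow = length(genes), ncol = 8,
                 dimnames = list(genes, sprintf("%s_%02d", rep(c("PN", "FT"),
                                                               each = 4), 1:4)))
  mexp[c("a1", "a2"), 5:8] <- 50
  mexp["b1", 5:8] <- 50
  meta <- data.frame(sample_id = colnames(mexp),
                     stage = rep(c("PN", "FT"), each = 4),
                     weeks = rep(c(20, 39), each = 4), sex = "unknown",
                     morbidities = "", stringsAsFactors = FALSE)
  meta <- rbind(meta, data.frame(sample_id = "PT_01", stage = "PT", weeks = 35,
                                 sex = "unknown", morbidities = ""))
  mexp <- cbind(mexp, PT_01 = 1)
  prof <- stage_marker_profile(mexp, meta, atlas, quantile = 0.90)
  expect_setequal(prof$tissue, c("t1", "t2"))
  expect_equal(prof$FT[prof$tissue == "t1"], 1.0)
  expect_equal(prof$FT[prof$tissue == "t2"], 0.5)
  expect_equal(prof$PN, c(0, 0))
})

test_that("marker enrichment matches exhaustive hypergeometric enumeration", {
  universe <- sprintf("u%03d", 1:100)
  set_genes <- universe[1:10]
  query <- c(universe[1:5], universe[90:94])  # overlap r = 5
  res <- marker_enrichment(query, universe, list(hit = set_genes,
                                                 void = c("x1", "x2")))
  expect_identical(nrow(res), 1L)  # the disjoint set is skipped
  expect_equal(res$overlap, 5)
  expect_equal(res$z_score, 4 / sqrt(10 * 0.1 * 0.9 * (1 - 9 / 99)),
               tolerance = 1e-12)
  expect_equal(res$fisher_p, hyper_tail_oracle(100, 10, 10, 5),
               tolerance = 1e-12)
  expect_lt(res$fisher_p, 0.01)
  expect_true(res$is_enriched)

  # overlap at expectation (r = nR/N = 10*10/100 = 1) -> z = 0
  res0 <- marker_enrichment(c(universe[10], universe[51:59]), universe,
                            list(s = set_genes))
  expect_equal(res0$overlap, 1)
  expect_equal(res0$z_score, 0)

  expect_error(marker_enrichment(c("u001", "nope"), universe, list(s = set_genes)),
               "NOPE")
})

test_that("fetal origin check compares chrY markers with XIST", {
  m <- matrix(0, nrow = 4, ncol = 2,
              dimnames = list(c("XIST", "RPS4Y1", "DDX3Y", "EIF1AY"),
                              c("boy", "girl")))
  m["XIST", ] <- c(2, 40)
  m[c("RPS4Y1", "DDX3Y", "EIF1AY"), "boy"] <- 50
  meta <- data.frame(sample_id = c("boy", "girl"), stage = c("PN", "PN"),
                     weeks = 20, sex = c("male", "female"), morbidities = "",
                     stringsAsFactors = FALSE)
  rep <- check_fetal_origin(m, meta)
  expect_identical(rep$predicted_sex, c("male", "female"))
  expect_true(all(rep$concordant))

  # missing markers degrade to unknown
  m2 <- m[c("RPS4Y1", "DDX3Y"), , drop = FALSE]
  expect_warning(rep2 <- check_fetal_origin(m2, meta), "absent")
  expect_identical(unique(rep2$predicted_sex), "unknown")
  expect_true(all(is.na(rep2$concordant)))
})
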