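test_that("reciprocal event detection finds cassette and alt-site structures", {
  # cassette: two inclusions flanking the 200-300 exon inside the exclusion
  jx <- make_junctions(list(c(100, 200), c(300, 500), c(100, 500)))
  ev <- detect_reciprocal_events(jx)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "cassette")
  expect_equal(c(ev$incl1_start, ev$incl1_end), c(100, 200))
  expect_equal(c(ev$incl2_start, ev$incl2_end), c(300, 500))
  expect_equal(c(ev$excl_start, ev$excl_end), c(100, 500))

  # shared start only: a single-inclusion alternative splice-site event
  jx2 <- make_junctions(list(c(100, 200), c(100, 500)))
  ev2 <- detect_reciprocal_events(jx2)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$type, "alt_site")
  expect_true(is.na(ev2$incl2_start))

  # no shared boundary, no containment: nothing
  jx3 <- make_junctions(list(c(100, 200), c(250, 400)))
  expect_identical(nrow(detect_reciprocal_events(jx3)), 0L)
})

test_that("event detection equals the brute-force enumeration oracle", {
  set.seed(31)
  for (i in 1:60) {
    jx <- random_junction_instance(sample(3:50, 1))
    ev <- detect_reciprocal_events(jx)
    expect_identical(sort(ev$event_id), detect_events_oracle(jx))
  }
})

test_that("PSI follows inclusion/(inclusion+exclusion) with a coverage floor", {
  jx <- make_junctions(list(c(100, 200), c(100, 500)), count = c(30, 10))
  ev <- detect_reciprocal_events(jx)
  psi <- compute_psi(ev, jx)
  expect_equal(unname(psi[1, "s1"]), 0.75)

  # cassette averaging: inclusions 20 and 40, exclusion 10 -> 30/(30+10)
  jxc <- make_junctions(list(c(100, 200), c(300, 500), c(100, 500)),
                        count = c(20, 40, 10))
  evc <- detect_reciprocal_events(jxc)
  psic <- compute_psi(evc, jxc)
  expect_equal(unname(psic[evc$event_id[evc$type == "cassette"], "s1"]), 0.75)

  # below the coverage threshold the value is missing
  jlow <- make_junctions(list(c(100, 200), c(100, 500)), count = c(3, 2))
  expect_true(is.na(compute_psi(detect_reciprocal_events(jlow), jlow)[1, "s1"]))

  # scaling all counts by a constant leaves PSI unchanged, and PSI is in [0,1]
  jbig <- jxc; jbig$count <- jbig$count * 13
  expect_equal(compute_psi(evc, jbig), psic)
  set.seed(32)
  jr <- random_junction_instance(30)
  evr <- detect_reciprocal_events(jr)
  pr <- compute_psi(evr, jr, min_total_reads = 1)
  expect_true(all(pr >= 0 & pr <= 1, na.rm = TRUE))
})

test_that("group PSI comparison flags planted shifts and not identical groups", {
  cfg <- simulation_config(n_splicing_events = 12, psi_shift = 0.3,
                           base_junction_depth = 200, seed = 41)
  b <- simulate_study(cfg)
  ev <- detect_reciprocal_events(b$junctions,
                                 gene_map = b$truth$splicing[, c("chrom",
                                   "intron_start", "intron_end", "gene_id")])
  psi <- compute_psi(ev, b$junctions)
  pt <- b$metadata$sample_id[b$metadata$stage == "PT"]
  ft <- b$metadata$sample_id[b$metadata$stage == "FT"]
  cmp <- compare_psi_groups(psi, pt, ft, events = ev)
  cass <- cmp[grepl("\\|", cmp$event_id), ]
  expect_gte(mean(cass$is_regulated), 0.8)
  expect_true(all(!is.na(cass$gene_id)))

  # identical tables give delta 0 everywhere
  cmp0 <- compare_psi_groups(psi, pt, pt)
  expect_equal(cmp0$delta_psi, rep(0, nrow(cmp0)))
  expect_error(compare_psi_groups(psi, pt, c("nope")), "nope")
})

test_that("set overlap partitions exactly", {
  expect_equal(overlap_events(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
               c(only_a = 1L, only_b = 1L, shared = 2L))
  expect_equal(overlap_events(letters[1:5], letters[10:16]),
               c(only_a = 5L, only_b = 7L, shared = 0L))
  expect_equal(overlap_events(letters[1:4], letters[1:4]),
               c(only_a = 0L, only_b = 0L, shared = 4L))
})

test_that("panel filtering requires the exclusion and one inclusion junction", {
  jx <- make_junctions(list(c(100, 200), c(300, 500), c(100, 500)))
  ev <- detect_reciprocal_events(jx)
  full_panel <- jx
  expect_true(filter_against_panel(ev, full_panel)$found_in_panel)
  no_excl <- make_junctions(list(c(100, 200), c(300, 500)))
  expect_false(filter_against_panel(ev, no_excl)$found_in_panel)
  empty <- make_junctions(list())
  expect_false(filter_against_panel(ev, empty)$found_in_panel)
})
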