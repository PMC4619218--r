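# Independent oracles used across the suite. Deliberately naive: literal
# definitions, nested loops, no shared code with the package internals.

# Benjamini-Hochberg step-up, from the definition: adj_(i) over the sorted
# p-values is min_{j >= i} ( m * p_(j) / j ), clipped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact upper hypergeometric tail P(X >= r) by term-wise enumeration.
hyper_tail_oracle <- function(N, R, n, r) {
  ks <- r:min(n, R)
  ks <- ks[ks >= max(0, n - (N - R))]
  if (!length(ks)) return(0)
  sum(choose(R, ks) * choose(N - R, n - ks)) / choose(N, n)
}

# Finite-population z-score for the overlap, from the closed form.
hyper_z_oracle <- function(N, R, n, r) {
  mu <- n * R / N
  sigma <- sqrt(n * (R / N) * (1 - R / N) * (1 - (n - 1) / (N - 1)))
  if (sigma == 0) 0 else (r - mu) / sigma
}

# Brute-force reciprocal-event detection: literal nested loops over all
# (exclusion, left, right) combinations of the pooled unique junctions.
detect_events_oracle <- function(junctions) {
  u <- unique(junctions[, c("chrom", "intron_start", "intron_end")])
  out <- list()
  for (e in seq_len(nrow(u))) {
    es <- u$intron_start[e]; ee <- u$intron_end[e]; ec <- u$chrom[e]
    left <- integer(0); right <- integer(0)
    for (i in seq_len(nrow(u))) {
      if (i == e || u$chrom[i] != ec) next
      if (u$intron_start[i] == es && u$intron_end[i] < ee)
        left <- c(left, i)
      if (u$intron_end[i] == ee && u$intron_start[i] > es)
        right <- c(right, i)
    }
    lp <- rep(FALSE, length(left)); rp <- rep(FALSE, length(right))
    for (a in seq_along(left)) for (b in seq_along(right)) {
      l <- left[a]; r <- right[b]
      if (u$intron_end[l] < u$intron_start[r]) {
        lp[a] <- TRUE; rp[b] <- TRUE
        out[[length(out) + 1]] <- sprintf(
          "%s:%d-%d<%d-%d|%d-%d", ec, es, ee,
          u$intron_start[l], u$intron_end[l],
          u$intron_start[r], u$intron_end[r])
      }
    }
    for (l in left[!lp])
      out[[length(out) + 1]] <- sprintf("%s:%d-%d<%d-%d", ec, es, ee,
                                        u$intron_start[l], u$intron_end[l])
    for (r in right[!rp])
      out[[length(out) + 1]] <- sprintf("%s:%d-%d<%d-%d", ec, es, ee,
                                        u$intron_start[r], u$intron_end[r])
  }
  sort(as.character(unlist(out)))
}

# Random junction instance on a small coordinate lattice so boundary sharing
# is common.
random_junction_instance <- function(n_junctions, n_positions = 12,
                                     chroms = c("chr1", "chr2")) {
  pos <- sort(sample(seq(100, 10000, by = 100), n_positions))
  rows <- list()
  while (length(rows) < n_junctions) {
    p <- sort(sample(pos, 2))
    if (p[1] == p[2]) next
    rows[[length(rows) + 1]] <- data.frame(
      chrom = sample(chroms, 1), intron_start = p[1], intron_end = p[2],
      strand = ".", count = sample(1:50, 1), sample_id = "s1",
      stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, rows))
}

make_junctions <- function(coords, chrom = "chr1", count = 10, sample_id = "s1") {
  if (!length(coords))
    return(data.frame(chrom = character(0), intron_start = numeric(0),
                      intron_end = numeric(0), strand = character(0),
                      count = numeric(0), sample_id = character(0),
                      stringsAsFactors = FALSE))
  data.frame(chrom = chrom, intron_start = vapply(coords, `[`, numeric(1), 1),
             intron_end = vapply(coords, `[`, numeric(1), 2), strand = ".",
             count = count, sample_id = sample_id, stringsAsFactors = FALSE)
}

# Tiny three-stage expression fixture: values per stage supplied as a list of
# per-gene matrices is overkill; instead build from per-stage gene means.
make_stage_matrix <- function(means_pn, means_pt, means_ft,
                              n = c(PN = 4, PT = 6, FT = 6), jitter = 0) {
  g <- length(means_pn)
  cols <- c(replicate(n[["PN"]], means_pn), replicate(n[["PT"]], means_pt),
            replicate(n[["FT"]], means_ft))
  m <- matrix(cols, nrow = g)
  if (jitter > 0) m <- m * 2^matrix(rnorm(length(m), 0, jitter), nrow = g)
  rownames(m) <- if (!is.null(names(means_pn))) names(means_pn) else
    sprintf("g%03d", seq_len(g))
  colnames(m) <- sprintf("%s_%02d", rep(c("PN", "PT", "FT"), times = n),
                         unlist(lapply(n, seq_len)))
  m
}

make_stage_metadata <- function(m) {
  ids <- colnames(m)
  stage <- sub("_.*", "", ids)
  wk <- c(PN = 20, PT = 35, FT = 39)[stage]
  data.frame(sample_id = ids, stage = stage, weeks = unname(wk),
             sex = "unknown", morbidities = "", stringsAsFactors = FALSE)
}
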