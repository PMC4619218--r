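#' Trimmed-mean (TMM) between-sample normalization
#'
#' Computes one scaling factor per sample as `2^` the weighted trimmed mean
#' of per-gene log2 ratios against a reference sample. Ratios are taken on
#' the raw values, so the factor absorbs both sequencing depth and
#' composition; genes with a zero in either sample are excluded. The upper
#' and lower `trim_m` fraction of genes by log-ratio (M) and `trim_a`
#' fraction by average log abundance (A) are trimmed; remaining ratios are
#' weighted by inverse approximate binomial variances. Factors are rescaled
#' to geometric mean one and divided out of the matrix.
#'
#' The reference sample is the one whose upper-quartile expression is closest
#' to the mean upper quartile across samples.
#'
#' @param m Numeric matrix, genes in rows, samples in columns (count scale;
#'   the arithmetic is scale-agnostic).
#' @param trim_m Fraction trimmed from each tail by log-ratio.
#' @param trim_a Fraction trimmed from each tail by average abundance.
#' @return List with `matrix` (normalized values) and `factors` (named
#'   per-sample scaling factors with geometric mean 1).
#' @export
tmm_normalize <- function(m, trim_m = 0.3, trim_a = 0.05) {
  validate_expression_matrix(m)
  if (ncol(m) < 2)
    stop("TMM normalization needs at least 2 samples", call. = FALSE)
  tot <- colSums(m)
  zero <- names(tot)[tot == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  uq <- apply(m, 2, function(x) stats::quantile(x[x > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  xr <- m[, ref]; nr <- tot[ref]
  f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref) return(1)
    xk <- m[, k]; nk <- tot[k]
    keep <- xk > 0 & xr > 0
    xk <- xk[keep]; xrk <- xr[keep]
    if (!length(xk))
      stop("no genes shared between sample '", colnames(m)[k],
           "' and the reference", call. = FALSE)
    M <- log2(xk) - log2(xrk)
    A <- (log2(xk) + log2(xrk)) / 2
    w <- 1 / ((nk - xk) / (nk * xk) + (nr - xrk) / (nr * xrk))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) keep2 <- rep(TRUE, n)  # heavy trim on tiny input
    2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  out <- sweep(m, 2, f, "/")
  attr(out, "scale") <- attr(m, "scale")
  list(matrix = out, factors = f)
}

#' Filter genes by minimum RPKM in at least one sample
#'
#' Keeps exactly the genes whose maximum value across samples strictly
#' exceeds `rpkm_min`.
#'
#' @param m RPKM-scale expression matrix.
#' @param rpkm_min Expression threshold.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(m, rpkm_min = 1.0) {
  validate_expression_matrix(m)
  keep <- apply(m, 1, max) > rpkm_min
  out <- m[keep, , drop = FALSE]
  attr(out, "scale") <- attr(m, "scale")
  out
}
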