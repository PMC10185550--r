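# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Generators must be pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Row z-scores of a numeric matrix; zero-variance rows become NA rows.
row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- sweep(sweep(m, 1L, mu, "-"), 1L, sd, "/")
  z[sd == 0 | !is.finite(sd), ] <- NA_real_
  z
}

# Vectorised Welch two-sample t-test on the rows of two matrices.
# Returns data.frame(diff, t, df, p).
row_welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # constant rows in both groups: no evidence of difference
  degen <- se2 == 0 | !is.finite(se2)
  tt[degen] <- 0; p[degen] <- 1; df[degen] <- NA_real_
  data.frame(diff = ma - mb, t = tt, df = df, p = p,
             row.names = rownames(a), stringsAsFactors = FALSE)
}

# Spearman correlation with two-sided p.
# Exact null (equivalent to exhaustive rank-permutation enumeration) for
# n <= 9 with untied data; t-approximation otherwise. Average ranks for ties.
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = TRUE))
    return(list(rho = unname(ct$estimate), p = ct$p.value, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE), n = n)
}

# Rank-based single-sample enrichment (ssGSEA-style running sum).
# For one sample: genes ordered by decreasing expression (ties broken by
# feature id for determinism); in-set steps weighted by normalized-rank^tau,
# out-of-set steps uniform; the score is the integrated difference of the two
# running CDFs. Shared engine for enrichment_scores() and gsva_scores().
ssgsea_sample <- function(expr, ids, set, tau = 0.25) {
  ord <- order(-expr, ids)
  inset <- ids[ord] %in% set
  G <- length(ids); m <- sum(inset)
  if (m == 0L) return(NA_real_)
  w <- ((G - seq_len(G) + 1) / G)^tau
  pin <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  pout <- cumsum(!inset) / (G - m)
  sum(pin - pout)
}

#' @importFrom stats p.adjust
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
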