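# In-code fixtures shared across test files.

toy_expr <- function(values, layer = "transcript", units = "TPM",
                     features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% rownames(m) %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  expression_matrix(m, layer = layer, units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive permutation two-sided Spearman p: independent oracle.
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  r0 <- abs(stats::cor(x, y, method = "spearman"))
  rs <- vapply(perms(seq_len(n)),
               function(p) abs(stats::cor(x, y[p], method = "spearman")),
               numeric(1L))
  mean(rs >= r0 - 1e-12)
}

# Brute-force ssGSEA running sum for one sample, written step by step.
ssgsea_oracle <- function(expr, ids, set, tau = 0.25) {
  ord <- order(-expr, ids)
  G <- length(ids)
  hits <- ids[ord] %in% set
  w <- numeric(G)
  for (i in seq_len(G)) w[i] <- ((G - i + 1) / G)^tau
  denom_in <- sum(w[hits])
  denom_out <- G - sum(hits)
  pin <- pout <- 0
  total <- 0
  for (i in seq_len(G)) {
    if (hits[i]) pin <- pin + w[i] / denom_in else pout <- pout + 1 / denom_out
    total <- total + (pin - pout)
  }
  total
}

# Exponential proportional-hazards cohort with a planted hazard ratio.
with_planted_survival <- function(hr, n, seed, median_low = 45.63) {
  set.seed(seed)
  high <- rep(c(TRUE, FALSE), length.out = n)
  lam <- log(2) / median_low * ifelse(high, hr, 1)
  te <- stats::rexp(n, lam)
  tc <- stats::runif(n, 0, 1.5 * median_low)
  data.frame(sample_id = sprintf("P%05d", seq_len(n)),
             time = pmin(te, tc), event = as.integer(te <= tc),
             group = ifelse(high, "high", "low"), stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric upper tail by direct combinatorial summation.
hyper_tail_oracle <- function(q, m, n, k) {
  tot <- 0
  for (i in q:min(m, k))
    tot <- tot + choose(m, i) * choose(n, k - i)
  tot / choose(m + n, k)
}
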