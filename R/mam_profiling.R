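#' Differential expression between HD and LD matrix-educated macrophages
#'
#' Per-gene Welch t-test on log2 expression with BH adjustment. The
#' significant set applies the three-part filter: adjusted p < `alpha`,
#' |log2 fold change| > `lfc`, and protein-coding biotype. With a donor
#' factor supplied, profiles are donor-mean centered first (paired design
#' across blood donors). Without a biotype table the coding filter is
#' skipped with a loud warning.
#'
#' @param expr `expr_matrix` of log2TPM values.
#' @param groups Named character vector (sample -> "HD"/"LD") or factor.
#' @param coding Optional named logical vector: gene -> protein-coding.
#' @param donor Optional named factor: sample -> donor (for centering).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2-fold-change threshold (default 1).
#' @return List with `table` (gene, logfc (HD - LD), p, adj_p, direction,
#'   protein_coding, significant) and `up` / `down` significant id vectors.
#' @export
differential_expression <- function(expr, groups, coding = NULL, donor = NULL,
                                    alpha = 0.05, lfc = 1) {
  m <- unclass(expr)
  g <- groups[colnames(m)]
  if (anyNA(g)) stop("group labels missing for some samples", call. = FALSE)
  if (min(table(g)) < 2L) stop("each group needs >= 2 samples", call. = FALSE)
  if (!is.null(donor)) {
    d <- factor(donor[colnames(m)])
    for (lev in levels(d)) {
      idx <- which(d == lev)
      m[, idx] <- m[, idx] - rowMeans(m[, idx, drop = FALSE])
    }
  }
  tt <- row_welch_t(m[, g == "HD", drop = FALSE], m[, g == "LD", drop = FALSE])
  res <- data.frame(gene = rownames(tt), logfc = tt$diff, p = tt$p,
                    adj_p = bh_adjust(tt$p),
                    direction = ifelse(tt$diff > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(coding)) {
    warning("no protein-coding biotype table supplied: coding filter SKIPPED",
            call. = FALSE)
    res$protein_coding <- NA
    codes <- TRUE
  } else {
    res$protein_coding <- unname(coding[res$gene])
    res$protein_coding[is.na(res$protein_coding)] <- FALSE
    codes <- res$protein_coding
  }
  res$significant <- res$adj_p < alpha & abs(res$logfc) > lfc & codes
  list(table = res,
       up = res$gene[res$significant & res$logfc > 0],
       down = res$gene[res$significant & res$logfc < 0])
}

#' Macrophage subtype scores of MAM profiles
#'
#' Deconvolves each profile against a three-column M0/M1/M2 macrophage
#' reference via [fit_fractions()]. Log2 input is linearized first
#' (2^x - 1).
#'
#' @param profiles `expr_matrix` (log2TPM or TPM).
#' @param macrophage_ref `cell_type_signature` restricted to M0/M1/M2.
#' @return `immune_abundance` matrix of per-sample subtype shares.
#' @export
subtype_scores <- function(profiles, macrophage_ref) {
  m <- unclass(profiles)
  if (units_of(profiles) == "log2TPM") m <- pmax(2^m - 1, 0)
  lin <- expression_matrix(m, layer = "transcript", units = "TPM")
  fit_fractions(lin, macrophage_ref)
}

# Scale-free topology fit R^2 for an adjacency's connectivity distribution.
scale_free_fit <- function(adj) {
  k <- colSums(adj) - diag(adj)
  k <- k[k > 0]
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = 11L)))
  if (length(br) < 3L) return(0)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0
  if (sum(ok) < 3L) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (stats::coef(fit)[2L] >= 0) 0 else r2
}

#' Detect co-expression modules (WGCNA-style)
#'
#' Unsigned weighted co-expression network: adjacency `|cor|^beta` with the
#' soft power chosen as the smallest beta in 1..12 achieving scale-free
#' topology fit R^2 >= 0.8 (default 6 if none), topological-overlap
#' dissimilarity, average-linkage dendrogram, fixed-height cut at
#' `cut_frac` of the maximum merge height, and modules below
#' `min_module_size` dissolved to unassigned (module 0). Module eigengenes
#' are the first principal components of the member genes' z-scored
#' profiles (unit-normalized, oriented to correlate positively with the
#' mean member profile).
#'
#' @param expr `expr_matrix` (genes x samples, >= 8 samples).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_frac Dendrogram cut height as a fraction of the maximum merge
#'   height (default 0.9; unrelated genes sit near TOM dissimilarity 1, so
#'   the cut must lie between the intra-module merges and that background
#'   plateau).
#' @param beta Optional fixed soft power (skips selection).
#' @param donor Optional named factor (sample -> donor); profiles are
#'   donor-mean centered before network construction so batch offsets do
#'   not masquerade as co-expression.
#' @return A `coexpression_modules` list: `membership` (named integer, 0 =
#'   unassigned), `eigengenes` (modules x samples), `beta`, `fit_r2`.
#' @export
detect_modules <- function(expr, min_module_size = 30L, cut_frac = 0.9,
                           beta = NULL, donor = NULL) {
  m <- unclass(expr)
  if (!is.null(donor)) {
    d <- factor(donor[colnames(m)])
    for (lev in levels(d)) {
      idx <- which(d == lev)
      m[, idx] <- m[, idx] - rowMeans(m[, idx, drop = FALSE])
    }
  }
  if (ncol(m) < 8L) stop("need >= 8 samples for co-expression modules", call. = FALSE)
  if (nrow(m) < 2L * min_module_size)
    stop("need >= 2 * min_module_size genes", call. = FALSE)
  keep <- apply(m, 1L, stats::sd) > 0
  m <- m[keep, , drop = FALSE]
  cc <- abs(stats::cor(t(m)))
  fit_r2 <- NA_real_
  if (is.null(beta)) {
    for (b in 1:12) {
      r2 <- scale_free_fit(cc^b)
      if (r2 >= 0.8) { beta <- b; fit_r2 <- r2; break }
    }
    if (is.null(beta)) { beta <- 6L; fit_r2 <- scale_free_fit(cc^6) }
  } else fit_r2 <- scale_free_fit(cc^beta)
  adj <- cc^beta
  diag(adj) <- 0
  # topological overlap
  L <- adj %*% adj
  k <- colSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dtom <- stats::as.dist(1 - tom)
  hc <- stats::hclust(dtom, method = "average")
  labels <- stats::cutree(hc, h = cut_frac * max(hc$height))
  sizes <- table(labels)
  keep_mods <- names(sizes)[sizes >= min_module_size]
  membership <- integer(length(labels))
  names(membership) <- names(labels)
  keep_mods <- keep_mods[order(-sizes[keep_mods])]
  for (i in seq_along(keep_mods))
    membership[labels == as.integer(keep_mods[i])] <- i

  eigengene <- function(rows) {
    z <- row_zscore(m[rows, , drop = FALSE])
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)$x[, 1L]
    pc <- pc / sqrt(sum(pc^2))
    if (stats::cor(pc, colMeans(z)) < 0) pc <- -pc
    pc
  }
  # merge modules whose eigengenes are near-collinear (|r| > merge_r),
  # then relabel by decreasing size
  merge_r <- 0.75
  repeat {
    k_mod <- max(membership)
    if (k_mod < 2L) break
    eg <- sapply(seq_len(k_mod), function(i)
      eigengene(names(membership)[membership == i]))
    ec <- abs(stats::cor(eg))
    diag(ec) <- 0
    if (max(ec) <= merge_r) break
    ij <- which(ec == max(ec), arr.ind = TRUE)[1L, ]
    membership[membership == max(ij)] <- min(ij)
    membership[membership > max(ij)] <- membership[membership > max(ij)] - 1L
  }
  if (max(membership) > 0L) {
    ord <- order(-table(factor(membership[membership > 0],
                               levels = seq_len(max(membership)))))
    membership[membership > 0] <- match(membership[membership > 0], ord)
  }
  eig <- NULL
  if (max(membership) > 0L) {
    eig <- t(vapply(seq_len(max(membership)), function(i)
      eigengene(names(membership)[membership == i]), numeric(ncol(m))))
    rownames(eig) <- paste0("ME", seq_len(max(membership)))
    colnames(eig) <- colnames(m)
  }
  structure(list(membership = membership, eigengenes = eig, beta = beta,
                 fit_r2 = fit_r2, min_module_size = min_module_size),
            class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  k <- max(x$membership)
  cat(sprintf("<coexpression_modules> %d modules (beta = %d, scale-free R2 = %.2f)\n",
              k, x$beta, x$fit_r2))
  print(table(module = x$membership))
  invisible(x)
}

#' Per-sample gene-list scores (GSVA-style)
#'
#' Rank-based single-sample enrichment of arbitrary gene lists — the same
#' running-sum engine as [enrichment_scores()]. Scores depend only on
#' within-sample ranks.
#'
#' @param expr `expr_matrix`.
#' @param lists A `gene_set_collection`.
#' @param tau Weight exponent (default 0.25).
#' @return Numeric matrix, samples x lists (`NA` for empty overlap, with a
#'   warning).
#' @export
gsva_scores <- function(expr, lists, tau = 0.25) {
  unclass(enrichment_scores(expr, lists, tau = tau))
}

#' Module eigengene vs trait-score correlations
#'
#' Pearson r with two-sided p for every (module eigengene, trait score)
#' pair over shared samples, plus a masked r matrix (entries at p >= alpha
#' set to NA) for heatmap display.
#'
#' @param modules A `coexpression_modules`.
#' @param traits Samples x traits score matrix (e.g. from [gsva_scores()]).
#' @param alpha Masking level (default 0.05).
#' @return List with `table` (module, trait, r, p, n) and `masked_r`.
#' @export
module_trait_correlation <- function(modules, traits, alpha = 0.05) {
  eig <- modules$eigengenes
  if (is.null(eig)) stop("no modules detected", call. = FALSE)
  samples <- intersect(colnames(eig), rownames(traits))
  if (length(samples) < 4L) stop("fewer than 4 shared samples", call. = FALSE)
  rows <- list()
  for (me in rownames(eig)) for (tr in colnames(traits)) {
    x <- eig[me, samples]; y <- traits[samples, tr]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok])
    rows[[paste(me, tr)]] <- data.frame(module = me, trait = tr,
                                        r = unname(ct$estimate), p = ct$p.value,
                                        n = sum(ok), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  mr <- matrix(NA_real_, nrow(eig), ncol(traits),
               dimnames = list(rownames(eig), colnames(traits)))
  sig <- tab$p < alpha
  mr[cbind(match(tab$module[sig], rownames(mr)),
           match(tab$trait[sig], colnames(mr)))] <- tab$r[sig]
  list(table = tab, masked_r = mr)
}

#' Enrichment of DE genes in macrophage stimulation modules
#'
#' Hypergeometric over-representation of an upregulated DE gene set in each
#' externally published co-expression module (spectrum model of macrophage
#' activation), BH-adjusted across modules.
#'
#' @param de_genes Character vector of upregulated genes for one group.
#' @param stimulus_modules `gene_set_collection` of module gene lists.
#' @param universe Character vector of all testable genes.
#' @param group Label recorded in the output (e.g. "HD").
#' @return `data.frame`: module, group, overlap, module_size, de_size, p,
#'   adj_p.
#' @export
spectrum_association <- function(de_genes, stimulus_modules, universe,
                                 group = "HD") {
  de_genes <- intersect(unique(de_genes), universe)
  N <- length(universe)
  if (N < length(de_genes)) stop("universe smaller than DE set", call. = FALSE)
  rows <- lapply(names(stimulus_modules), function(nm) {
    mod <- intersect(stimulus_modules[[nm]], universe)
    if (N < length(mod)) stop("universe smaller than module '", nm, "'", call. = FALSE)
    q <- length(intersect(de_genes, mod))
    p <- stats::phyper(q - 1L, length(mod), N - length(mod), length(de_genes),
                       lower.tail = FALSE)
    data.frame(module = nm, group = group, overlap = q,
               module_size = length(mod), de_size = length(de_genes), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out
}
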