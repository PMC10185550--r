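#' Normalize a proteomics abundance matrix
#'
#' Label-free MS convention: missing values imputed as zero abundance
#' (logged), per-sample total normalization (each column scaled to a fixed
#' total of 1e4, making samples comparable and the result invariant to
#' per-sample scaling), then log2(x + 1). A per-protein row z-score variant of the
#' log matrix is returned alongside for clustering and heatmaps.
#'
#' @param raw Protein `expr_matrix` of non-negative abundances (`NA`
#'   permitted).
#' @return List with `log` (normalized log2 `expr_matrix`) and `z`
#'   (row z-scores of `log`; zero-variance rows are dropped).
#' @export
normalize_proteomics <- function(raw) {
  m <- unclass(raw)
  if (anyNA(m)) {
    message(sum(is.na(m)), " missing protein values imputed as zero abundance")
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("protein abundances must be non-negative", call. = FALSE)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "),
         call. = FALSE)
  m <- sweep(m, 2L, tot / 1e4, "/")
  lg <- log2(m + 1)
  z <- row_zscore(lg)
  z <- z[stats::complete.cases(z), , drop = FALSE]
  list(log = expression_matrix(lg, layer = "protein", units = "protein-abundance-AU"),
       z = z)
}

#' Cluster samples into ECM composition groups
#'
#' Agglomerative hierarchical clustering (Ward's method, `ward.D2`
#' convention) of samples on Euclidean distance over per-protein z-scores of
#' log abundances, cut into `k` groups. When sample metadata with disease
#' scores is supplied, group labels are ordered by increasing group-mean
#' disease score, so low-disease groups receive small indices; otherwise
#' labels follow decreasing group size (ties by first sample id).
#'
#' @param x Either the `z` matrix from [normalize_proteomics()] or a protein
#'   `expr_matrix` (normalized internally).
#' @param k Number of groups (>= 2, <= number of samples).
#' @param metadata Optional [sample_metadata()] with `disease_score`.
#' @param prevalence Minimum fraction of samples in which a protein must be
#'   detected (non-zero) to enter clustering (default 0.25).
#' @return An `ecg_assignment`: list with `groups` (named integer vector),
#'   `k`, `hclust` (the linkage object) and `silhouette` (mean silhouette
#'   width per candidate k in 2..min(8, n-1), to justify the choice of k).
#' @export
cluster_ecgs <- function(x, k = 5L, metadata = NULL, prevalence = 0.25) {
  if (inherits(x, "expr_matrix")) {
    raw <- unclass(x)
    detected <- rowMeans(raw > 0 & !is.na(raw)) >= prevalence
    x <- normalize_proteomics(expression_matrix(raw[detected, , drop = FALSE],
                                                layer = "protein",
                                                units = units_of(x)))$z
  }
  n <- ncol(x)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  d <- stats::dist(t(x))
  hc <- stats::hclust(d, method = "ward.D2")
  raw_labels <- stats::cutree(hc, k = k)

  # deterministic relabelling
  if (!is.null(metadata) && any(!is.na(metadata$disease_score))) {
    ds <- metadata$disease_score[match(names(raw_labels), metadata$sample_id)]
    ord <- order(tapply(ds, raw_labels, mean, na.rm = TRUE))
  } else {
    sz <- table(raw_labels)
    first <- tapply(names(raw_labels), raw_labels, min)
    ord <- order(-as.integer(sz), first)
  }
  relab <- match(raw_labels, ord)
  names(relab) <- names(raw_labels)

  ks <- 2:min(8L, n - 1L)
  sil <- vapply(ks, function(kk)
    mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"]),
    numeric(1L))
  structure(list(groups = relab, k = k, hclust = hc,
                 silhouette = stats::setNames(sil, ks)),
            class = "ecg_assignment")
}

#' @export
print.ecg_assignment <- function(x, ...) {
  cat(sprintf("<ecg_assignment> %d samples in %d ECM composition groups\n",
              length(x$groups), x$k))
  print(table(ECG = x$groups))
  invisible(x)
}

#' Matrisome category composition
#'
#' Share of summed linear protein abundance falling in each of the six
#' matrisome categories, per sample and cohort-wide. Unannotated proteins
#' are excluded from the denominator with a warning. Shares sum to 1.
#'
#' @param abundances Protein `expr_matrix` on linear scale.
#' @param annotation Matrisome annotation (see [matrisome_annotation()]).
#' @return List with `per_sample` (samples x categories matrix) and
#'   `cohort` (named numeric vector over [MATRISOME_CATEGORIES]).
#' @export
category_composition <- function(abundances, annotation) {
  m <- unclass(abundances)
  m[is.na(m)] <- 0
  unk <- setdiff(rownames(m), annotation$molecule)
  if (length(unk)) {
    warning(length(unk), " unannotated protein(s) excluded from composition",
            call. = FALSE)
    m <- m[setdiff(rownames(m), unk), , drop = FALSE]
  }
  cat_of <- annotation$category[match(rownames(m), annotation$molecule)]
  cat_sums <- rowsum(m, factor(cat_of, levels = MATRISOME_CATEGORIES))
  cat_sums[is.na(cat_sums)] <- 0
  tot <- colSums(cat_sums)
  if (any(tot == 0))
    stop("zero total annotated abundance in sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  per_sample <- t(sweep(cat_sums, 2L, tot, "/"))
  cohort <- rowSums(cat_sums) / sum(cat_sums)
  list(per_sample = per_sample, cohort = cohort)
}

#' Per-group differential matrisome proteins
#'
#' One-vs-rest Welch t-test on log abundances for every protein and ECM
#' composition group, BH-adjusted across proteins within each group.
#' `up` = adjusted p < alpha with higher mean in the group; `down`
#' symmetric. Groups of fewer than 2 samples are skipped with a warning.
#'
#' @param lg Log-scale protein `expr_matrix` (e.g. `$log` from
#'   [normalize_proteomics()]).
#' @param assignment An `ecg_assignment`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Named list per group: `data.frame` with protein, diff, p, adj_p,
#'   direction; plus `up` / `down` id vectors.
#' @export
ecg_differential_proteins <- function(lg, assignment, alpha = 0.05) {
  m <- unclass(lg)
  g <- assignment$groups[colnames(m)]
  if (anyNA(g)) stop("assignment missing for some samples", call. = FALSE)
  out <- list()
  for (grp in sort(unique(g))) {
    ing <- m[, g == grp, drop = FALSE]
    outg <- m[, g != grp, drop = FALSE]
    if (ncol(ing) < 2L) {
      warning("group ", grp, " has <2 samples; skipped", call. = FALSE)
      next
    }
    tt <- row_welch_t(ing, outg)
    tt$adj_p <- bh_adjust(tt$p)
    tt$direction <- ifelse(tt$diff > 0, "up", "down")
    sig <- tt$adj_p < alpha
    out[[as.character(grp)]] <- list(
      table = data.frame(protein = rownames(tt), tt, row.names = NULL),
      up = rownames(tt)[sig & tt$diff > 0],
      down = rownames(tt)[sig & tt$diff < 0])
  }
  out
}

#' ECG association with immune counts and disease score
#'
#' Per IHC marker: group means, row z-scores of the group means, and a
#' one-way ANOVA of counts across groups; the disease score is compared
#' across groups likewise.
#'
#' @param assignment An `ecg_assignment`.
#' @param counts IHC counts matrix, samples x markers (cells per mm^2).
#' @param metadata Optional [sample_metadata()] with disease scores.
#' @return List with `group_means` (markers x groups), `z` (row z-scores of
#'   group means), `anova_p` (named per marker) and `disease` (group means
#'   + ANOVA p), the latter `NULL` without metadata.
#' @export
ecg_immune_association <- function(assignment, counts, metadata = NULL) {
  samples <- intersect(names(assignment$groups), rownames(counts))
  if (length(samples) == 0L) stop("counts cover no assigned samples", call. = FALSE)
  g <- factor(assignment$groups[samples])
  cm <- counts[samples, , drop = FALSE]
  gm <- t(apply(cm, 2L, function(v) tapply(v, g, mean, na.rm = TRUE)))
  anova_p <- apply(cm, 2L, function(v) {
    ok <- !is.na(v)
    if (length(unique(g[ok])) < 2L) return(NA_real_)
    if (stats::sd(v[ok]) == 0) return(NA_real_)  # constant marker: no signal
    summary(stats::aov(v[ok] ~ g[ok]))[[1L]][["Pr(>F)"]][1L]
  })
  disease <- NULL
  if (!is.null(metadata)) {
    ds <- metadata$disease_score[match(samples, metadata$sample_id)]
    ok <- !is.na(ds)
    disease <- list(
      group_means = tapply(ds[ok], g[ok], mean),
      anova_p = if (length(unique(g[ok])) > 1L)
        summary(stats::aov(ds[ok] ~ g[ok]))[[1L]][["Pr(>F)"]][1L] else NA_real_)
  }
  list(group_means = gm, z = row_zscore(gm), anova_p = anova_p,
       disease = disease)
}
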