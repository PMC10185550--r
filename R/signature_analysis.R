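#' Score samples on a molecule signature
#'
#' Per-molecule z-score across samples, averaged over the signature members
#' present in the matrix. Zero-variance molecules are excluded with a
#' warning; missing molecules are logged. The cohort-wide mean score is 0 by
#' construction.
#'
#' @param signature A `signature_set` or character vector of molecule ids.
#' @param molecules An `expr_matrix`.
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(signature, molecules) {
  ids <- if (inherits(signature, "signature_set")) signature$molecules else signature
  present <- intersect(ids, rownames(molecules))
  if (length(present) == 0L)
    stop("no signature molecules present in the matrix", call. = FALSE)
  if (length(present) < length(ids))
    message("signature molecules absent from matrix: ",
            paste(setdiff(ids, present), collapse = ", "))
  m <- unclass(molecules)[present, , drop = FALSE]
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance molecules excluded: ",
            paste(present[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) == 0L) stop("all signature molecules have zero variance", call. = FALSE)
  }
  colMeans(row_zscore(m))
}

#' Median stratification into high / low groups
#'
#' Samples scoring above the cohort median are `high`, below are `low`.
#' Samples tied exactly at the median are allocated (lexicographically by
#' sample id, low first) so the two groups are as balanced as possible. With
#' an even number of all-distinct scores the split is exactly equal-sized.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @return `data.frame` with columns `sample_id`, `score`, `group`
#'   (factor, levels low/high).
#' @export
stratify_median <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(scores)) == 1L)
    stop("all scores identical: no stratification possible", call. = FALSE)
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high", ifelse(scores < med, "low", NA))
  tied <- which(is.na(grp))
  if (length(tied)) {
    tied <- tied[order(names(scores)[tied])]
    n_low <- sum(grp == "low", na.rm = TRUE)
    n_high <- sum(grp == "high", na.rm = TRUE)
    # allocate ties to minimize imbalance, preferring low
    to_low <- min(length(tied), max(0L, ceiling((n_high + length(tied) - n_low) / 2)))
    grp[tied[seq_len(to_low)]] <- "low"
    grp[tied[-seq_len(to_low)]] <- "high"
    grp[is.na(grp)] <- "low"
  }
  out <- data.frame(sample_id = names(scores), score = unname(scores),
                    group = factor(grp, levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id), ]
}

#' Cancer-immunity-cycle step scores
#'
#' Activity score for each of the seven step-wise events of anti-tumor
#' immunity, per sample: the mean z-score (across samples) of the step's
#' signature genes, with optional negative-direction genes subtracted.
#' Scores are invariant to sample ordering and to duplication of genes
#' within a set.
#'
#' @param bulk An `expr_matrix`.
#' @param step_sets A `gene_set_collection` with exactly 7 sets (steps
#'   1..7). Each element may be a character vector (all positive-direction)
#'   or a list with `positive` and `negative` members.
#' @return Numeric matrix, samples x 7 steps.
#' @export
immunity_cycle_scores <- function(bulk, step_sets) {
  if (length(step_sets) != 7L)
    stop("expected exactly 7 immunity-cycle step sets, got ", length(step_sets),
         call. = FALSE)
  z <- row_zscore(unclass(bulk))
  score_one <- function(genes) {
    pos <- if (is.list(genes)) unique(genes$positive) else unique(genes)
    neg <- if (is.list(genes)) unique(genes$negative %||% character()) else character()
    pos <- intersect(pos, rownames(z)); neg <- intersect(neg, rownames(z))
    if (length(pos) + length(neg) == 0L) return(NULL)
    s <- if (length(pos)) colMeans(z[pos, , drop = FALSE]) else 0
    if (length(neg)) s <- s - colMeans(z[neg, , drop = FALSE])
    s
  }
  scores <- lapply(step_sets, score_one)
  empty <- names(step_sets)[vapply(scores, is.null, logical(1L))]
  if (length(empty))
    stop("step(s) with zero genes present in bulk: ",
         paste(empty, collapse = ", "), call. = FALSE)
  do.call(cbind, stats::setNames(scores, names(step_sets)))
}

#' Compare immunity-cycle step scores between groups
#'
#' Two-way (group x step) ANOVA over the long-format step-score table, plus
#' per-step Welch t contrasts of high vs low.
#'
#' @param steps Samples x steps score matrix from [immunity_cycle_scores()].
#' @param strat Stratification `data.frame` from [stratify_median()].
#' @return List with `anova` (the group x step ANOVA table) and `contrasts`
#'   (per-step `data.frame`: step, diff (high - low), t, p).
#' @export
compare_steps <- function(steps, strat) {
  g <- strat$group[match(rownames(steps), strat$sample_id)]
  if (anyNA(g)) stop("stratification missing for some samples", call. = FALSE)
  if (min(table(g)) < 2L) stop("each group needs at least 2 samples", call. = FALSE)
  long <- data.frame(
    score = as.vector(steps),
    step = factor(rep(colnames(steps), each = nrow(steps)),
                  levels = colnames(steps)),
    group = rep(g, times = ncol(steps)))
  fit <- stats::aov(score ~ group * step, data = long)
  contrasts <- do.call(rbind, lapply(colnames(steps), function(st) {
    hi <- steps[g == "high", st]; lo <- steps[g == "low", st]
    tt <- tryCatch(stats::t.test(hi, lo), error = function(e) NULL)
    data.frame(step = st, diff = mean(hi) - mean(lo),
               t = if (is.null(tt)) 0 else unname(tt$statistic),
               p = if (is.null(tt)) 1 else tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(anova = summary(fit), contrasts = contrasts)
}

#' Survival stratification analysis
#'
#' Kaplan-Meier median survival per group, two-sided unweighted
#' (Mantel-Haenszel) log-rank test, and Cox proportional-hazards hazard
#' ratio for high vs low (Efron tie handling) with a 95% Wald interval.
#'
#' @param surv `data.frame` with columns `sample_id`, `time` (months, > 0),
#'   `event` (0/1) and `group` (low/high).
#' @return List with `median_survival` (named; `NA` = not reached),
#'   `logrank_p`, `hr`, `hr_ci` (length-2), and the fitted `coxph` object.
#' @export
survival_analysis <- function(surv) {
  if (any(surv$time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  surv$group <- factor(as.character(surv$group), levels = c("low", "high"))
  ev <- tapply(surv$event, surv$group, sum)
  if (any(is.na(ev)) || any(ev < 2))
    stop("need at least 2 events per group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = surv)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = surv)
  lr_p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  cox <- survival::coxph(survival::Surv(time, event) ~ group, data = surv,
                         ties = "efron")
  hr <- unname(exp(stats::coef(cox)))
  ci <- unname(exp(stats::confint(cox)))
  list(median_survival = med, logrank_p = lr_p, hr = hr,
       hr_ci = as.numeric(ci), cox = cox)
}
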