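#' Construct a cell-type signature
#'
#' Reference for deconvolution: a signature matrix (signature genes x cell
#' types, linear-scale expression) for the fractions backend, and/or
#' per-cell-type marker gene sets for the enrichment backend.
#'
#' @param matrix Numeric matrix, signature genes x cell types, non-negative,
#'   with unique gene rownames (optional if `sets` given).
#' @param sets Optional `gene_set_collection` keyed by cell type.
#' @return A `cell_type_signature` list.
#' @export
cell_type_signature <- function(matrix = NULL, sets = NULL) {
  if (is.null(matrix) && is.null(sets))
    stop("supply a signature matrix, marker sets, or both", call. = FALSE)
  if (!is.null(matrix)) {
    if (anyDuplicated(rownames(matrix)))
      stop("signature genes must be unique", call. = FALSE)
    if (any(matrix < 0)) stop("signature entries must be non-negative", call. = FALSE)
    if (any(colSums(matrix > 0) == 0L))
      stop("every cell type needs at least one signature gene", call. = FALSE)
  }
  structure(list(matrix = matrix, sets = sets), class = "cell_type_signature")
}

#' Construct an immune abundance table
#'
#' @param values Numeric matrix, samples x cell types.
#' @param method Backend tag, `"fractions"` or `"enrichment"`.
#' @param units `"fraction"` (rows sum to 1, non-negative) or
#'   `"enrichment-score"`.
#' @return An `immune_abundance` matrix.
#' @export
immune_abundance <- function(values, method = c("fractions", "enrichment"),
                             units = c("fraction", "enrichment-score")) {
  method <- match.arg(method); units <- match.arg(units)
  if (units == "fraction") {
    if (any(values < -1e-12)) stop("fractions must be non-negative", call. = FALSE)
    if (any(abs(rowSums(values) - 1) > 1e-6))
      stop("fraction rows must sum to 1", call. = FALSE)
  } else if (any(!is.finite(values) & !is.na(values))) {
    stop("enrichment scores must be finite or NA", call. = FALSE)
  }
  structure(values, method = method, units = units,
            class = c("immune_abundance", "matrix"))
}

#' Estimate cell-type fractions by non-negative least squares
#'
#' Deconvolves each bulk transcript profile into reference cell-type
#' fractions: over the genes shared with the signature matrix, solves
#' `min ||S f - b||^2, f >= 0` and normalizes the coefficients to sum to 1.
#' Exact on noiseless mixtures of signature columns and invariant to
#' per-sample scaling.
#'
#' @param bulk Transcript `expr_matrix` on linear scale (TPM).
#' @param ref A `cell_type_signature` carrying a signature matrix.
#' @param min_gene_overlap Minimum fraction of signature genes that must be
#'   present in `bulk` (default 0.5).
#' @return An `immune_abundance` matrix of fractions (samples x cell types).
#' @export
fit_fractions <- function(bulk, ref, min_gene_overlap = 0.5) {
  S <- ref$matrix
  if (is.null(S)) stop("reference carries no signature matrix", call. = FALSE)
  if (max(bulk, na.rm = TRUE) <= 50)
    stop("bulk maximum <= 50: input looks log-transformed; supply linear-scale TPM",
         call. = FALSE)
  shared <- intersect(rownames(S), rownames(bulk))
  if (length(shared) < min_gene_overlap * nrow(S))
    stop("only ", length(shared), "/", nrow(S),
         " signature genes present in bulk; missing: ",
         paste(utils::head(setdiff(rownames(S), rownames(bulk)), 10L), collapse = ", "),
         call. = FALSE)
  S <- S[shared, , drop = FALSE]
  B <- unclass(bulk)[shared, , drop = FALSE]
  out <- matrix(0, ncol(B), ncol(S), dimnames = list(colnames(B), colnames(S)))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    if (all(b == 0)) stop("sample '", colnames(B)[j], "' is all zero", call. = FALSE)
    f <- pracma::lsqnonneg(S, b)$x
    if (sum(f) == 0) stop("degenerate NNLS fit for sample '", colnames(B)[j], "'",
                          call. = FALSE)
    out[j, ] <- f / sum(f)
  }
  immune_abundance(out, method = "fractions", units = "fraction")
}

#' Rank-based single-sample enrichment scores
#'
#' ssGSEA-style scoring of per-cell-type marker sets: within each sample,
#' genes are ordered by decreasing expression (ties broken by gene id);
#' in-set steps are weighted by normalized rank raised to `tau`, out-of-set
#' steps are uniform, and the score is the integrated difference of the two
#' running sums, finally normalized by the (max - min) score over the whole
#' cohort. Scores depend only on within-sample ranks, so they are invariant
#' to any strictly monotone per-sample transform.
#'
#' @param bulk An `expr_matrix`.
#' @param sets A `gene_set_collection` keyed by cell type.
#' @param tau Weight exponent on normalized ranks (default 0.25).
#' @return An `immune_abundance` matrix of enrichment scores
#'   (samples x sets). Sets with no genes in `bulk` give `NA` with a
#'   warning.
#' @export
enrichment_scores <- function(bulk, sets, tau = 0.25) {
  ids <- rownames(bulk)
  miss <- names(sets)[vapply(sets, function(s) !any(s %in% ids), logical(1L))]
  if (length(miss))
    warning("sets with zero overlap scored NA: ", paste(miss, collapse = ", "),
            call. = FALSE)
  raw <- sapply(names(sets), function(nm)
    apply(unclass(bulk), 2L, function(col) ssgsea_sample(col, ids, sets[[nm]], tau)))
  raw <- matrix(raw, nrow = ncol(bulk),
                dimnames = list(colnames(bulk), names(sets)))
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) > 0) raw <- raw / diff(rng)
  immune_abundance(raw, method = "enrichment", units = "enrichment-score")
}

#' Validate estimated abundances against IHC counts
#'
#' Spearman correlation (two-sided) between each estimated cell-type
#' abundance and its paired IHC marker count across shared samples.
#'
#' @param abundances An `immune_abundance` matrix (samples x cell types).
#' @param counts Numeric matrix of IHC counts per mm^2, samples x markers.
#' @param pairs Named character vector mapping cell type -> marker column.
#' @param min_pairs Minimum complete pairs per marker (default 4); pairs
#'   with fewer are skipped with a warning.
#' @return `data.frame` with columns cell_type, marker, rho, p, n.
#' @export
validate_against_counts <- function(abundances, counts, pairs, min_pairs = 4L) {
  samples <- intersect(rownames(abundances), rownames(counts))
  res <- lapply(names(pairs), function(ct) {
    mk <- pairs[[ct]]
    if (!ct %in% colnames(abundances) || !mk %in% colnames(counts)) {
      warning("pair (", ct, ", ", mk, ") missing from inputs; skipped", call. = FALSE)
      return(NULL)
    }
    st <- spearman_test(abundances[samples, ct], counts[samples, mk])
    if (st$n < min_pairs || is.na(st$rho)) {
      warning("pair (", ct, ", ", mk, ") has <", min_pairs,
              " usable pairs; skipped", call. = FALSE)
      return(NULL)
    }
    data.frame(cell_type = ct, marker = mk, rho = st$rho, p = st$p, n = st$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cell_type = character(), marker = character(),
                      rho = numeric(), p = numeric(), n = integer())
  out
}
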