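#' Correlate immune abundances with matrisome molecules in one layer
#'
#' The core integration step: for every (matrisome molecule, cell type)
#' pair, Spearman correlation between the molecule's abundance row and the
#' cell type's estimated abundance across shared samples, with a two-sided
#' p-value (exact null for n <= 9 untied pairs, t-approximation otherwise).
#' Missing protein values are handled pairwise-complete. Molecules with
#' fewer than 4 complete pairs, or constant values, are skipped with a
#' warning.
#'
#' @param abundances An `immune_abundance` matrix (samples x cell types).
#' @param molecules An `expr_matrix` restricted to matrisome molecules (the
#'   restriction is applied here when `annotation` is supplied).
#' @param annotation Optional matrisome annotation `data.frame`
#'   (see [matrisome_annotation()]); molecules absent from it are dropped.
#' @return `data.frame` of correlation records: molecule, cell_type, layer,
#'   method, rho, p, n.
#' @export
correlate_layer <- function(abundances, molecules, annotation = NULL) {
  if (!is.null(annotation))
    molecules <- molecules[rownames(molecules) %in% annotation$molecule, ,
                           drop = FALSE]
  samples <- intersect(rownames(abundances), colnames(molecules))
  if (length(samples) < 4L)
    stop("fewer than 4 shared samples between abundances and molecules",
         call. = FALSE)
  layer <- layer_of(molecules)
  method <- attr(abundances, "method") %||% "fractions"
  skipped <- character()
  rows <- vector("list", nrow(molecules) * ncol(abundances)); k <- 0L
  for (mol in rownames(molecules)) {
    mv <- unclass(molecules)[mol, samples]
    for (ct in colnames(abundances)) {
      st <- spearman_test(mv, abundances[samples, ct])
      if (st$n < 4L || is.na(st$rho)) { skipped <- c(skipped, mol); next }
      k <- k + 1L
      rows[[k]] <- data.frame(molecule = mol, cell_type = ct, layer = layer,
                              method = method, rho = st$rho, p = st$p,
                              n = st$n, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped (constant values or <4 complete pairs): ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out))
    out <- data.frame(molecule = character(), cell_type = character(),
                      layer = character(), method = character(),
                      rho = numeric(), p = numeric(), n = integer())
  rownames(out) <- NULL
  out
}

#' Correlate a per-sample scalar with immune abundances
#'
#' As [correlate_layer()] with a single scalar (disease score or matrix
#' index) in place of the molecule rows.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param abundances An `immune_abundance` matrix.
#' @param label Name recorded in the `molecule` column (default
#'   `"disease_score"`).
#' @return `data.frame` of correlation records.
#' @export
correlate_with_index <- function(values, abundances, label = "disease_score") {
  samples <- intersect(names(values), rownames(abundances))
  if (length(samples) < 4L)
    stop("fewer than 4 shared samples between index and abundances",
         call. = FALSE)
  method <- attr(abundances, "method") %||% "fractions"
  rows <- lapply(colnames(abundances), function(ct) {
    st <- spearman_test(values[samples], abundances[samples, ct])
    if (st$n < 4L || is.na(st$rho)) return(NULL)
    data.frame(molecule = label, cell_type = ct, layer = "index",
               method = method, rho = st$rho, p = st$p, n = st$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("index is constant or has too few pairs", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-method, cross-layer consensus signature
#'
#' Intersects significant positive associations for a target cell type
#' across the four (method x layer) cells: a molecule enters the consensus
#' only if `rho > 0` and `p < alpha` for the target cell type in every
#' required cell. Also returns the broader "both-layers" set: molecules
#' significantly positively associated with at least one cell type in every
#' cell (any cell type, both layers, both methods).
#'
#' @param records Correlation records pooled from both methods and both
#'   layers (rbind of [correlate_layer()] outputs).
#' @param target_cell_type Cell type whose consensus signature is sought.
#' @param alpha Per-test significance level (default 0.05, uncorrected,
#'   matching the analysis this mirrors; set `adjust = "BH"` for a
#'   corrected variant).
#' @param adjust `"none"` (default) or `"BH"`; applied within each
#'   (method, layer) cell across all records in it.
#' @return A `signature_set`: list with `molecules` (lexicographic),
#'   `provenance` (per-molecule records in the passing cells), `target`,
#'   `both_layers` (any-cell-type set) and `cells` (the required
#'   method x layer combinations).
#' @export
consensus_signature <- function(records, target_cell_type, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(records) || nrow(records) == 0L)
    stop("empty record input", call. = FALSE)
  records$cell <- paste(records$method, records$layer, sep = ":")
  cells <- sort(unique(records$cell))
  if (adjust == "BH")
    records$p <- stats::ave(records$p, records$cell, FUN = bh_adjust)
  records$pass <- records$rho > 0 & records$p < alpha

  pass_all_cells <- function(df) {
    # molecules passing in every required cell
    tab <- unique(df[df$pass, c("molecule", "cell")])
    counts <- table(tab$molecule)
    sort(names(counts)[counts == length(cells)])
  }

  tgt <- records[records$cell_type == target_cell_type, , drop = FALSE]
  if (nrow(tgt) == 0L)
    stop("no records for target cell type '", target_cell_type, "'", call. = FALSE)
  members <- pass_all_cells(tgt)

  # broader set: any cell type significant in every cell
  both_layers <- pass_all_cells(records)

  structure(list(
    molecules = members,
    target = target_cell_type,
    alpha = alpha,
    cells = cells,
    provenance = tgt[tgt$molecule %in% members & tgt$pass,
                     c("molecule", "cell_type", "layer", "method", "rho", "p", "n")],
    both_layers = both_layers
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> target: %s | %d consensus molecules across %d cells\n",
              x$target, length(x$molecules), length(x$cells)))
  if (length(x$molecules)) cat("  ", paste(x$molecules, collapse = ", "), "\n")
  cat(sprintf("  both-layers (any cell type): %d molecules\n",
              length(x$both_layers)))
  invisible(x)
}

#' Wide rho matrix with significance masking
#'
#' Heatmap-ready view of one (method, layer) cell: molecules x cell types
#' matrix of Spearman rho with entries at `p >= alpha` masked to `NA`.
#'
#' @param records Correlation records from a single cell.
#' @param alpha Mask level (default 0.05).
#' @return Numeric matrix, molecules x cell types.
#' @export
rho_matrix <- function(records, alpha = 0.05) {
  mols <- sort(unique(records$molecule))
  cts <- sort(unique(records$cell_type))
  m <- matrix(NA_real_, length(mols), length(cts), dimnames = list(mols, cts))
  keep <- records$p < alpha
  m[cbind(match(records$molecule[keep], mols),
          match(records$cell_type[keep], cts))] <- records$rho[keep]
  m
}
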