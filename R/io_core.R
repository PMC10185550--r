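#' Construct an expression matrix
#'
#' The quantitative substrate of every pipeline stage: a dense molecules x
#' samples table of transcript or protein abundances with declared units.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   row and column names (HGNC-style symbols and sample identifiers).
#' @param layer `"transcript"` or `"protein"`.
#' @param units One of `"TPM"`, `"log2TPM"`, `"protein-abundance-AU"`.
#'
#' @details Duplicate feature or sample identifiers are rejected. Transcript
#' TPM values must be finite and non-negative; protein matrices may carry
#' `NA` (missing quantification), which downstream stages impute or drop
#' explicitly. Identifiers are case-sensitive; no symbol aliasing is
#' attempted.
#'
#' @return An object of class `expr_matrix` (a numeric matrix with `layer`
#'   and `units` attributes).
#' @export
expression_matrix <- function(values,
                              layer = c("transcript", "protein"),
                              units = c("TPM", "log2TPM", "protein-abundance-AU")) {
  layer <- match.arg(layer)
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (layer == "transcript") {
    if (anyNA(values) || any(!is.finite(values)))
      stop("transcript matrices must be finite with no missing values", call. = FALSE)
    if (units == "TPM" && any(values < 0))
      stop("TPM values must be non-negative", call. = FALSE)
  } else {
    if (any(!is.finite(values) & !is.na(values)))
      stop("protein values must be finite or NA", call. = FALSE)
  }
  structure(values, layer = layer, units = units, class = c("expr_matrix", "matrix"))
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, layer = attr(x, "layer"), units = attr(x, "units"),
                     class = class(x))
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "layer"), attr(x, "units")))
  invisible(x)
}

layer_of <- function(x) attr(x, "layer") %||% "transcript"
units_of <- function(x) attr(x, "units") %||% "TPM"

#' Read an expression matrix from TSV
#'
#' @param path TSV file; first column holds identifiers, header row holds the
#'   other dimension's identifiers.
#' @param layer,units Passed to [expression_matrix()].
#' @param orientation `"features-in-rows"` (default) or `"samples-in-rows"`;
#'   the latter is transposed so the result is always features x samples.
#' @return An `expr_matrix`.
#' @export
read_matrix <- function(path, layer = "transcript", units = "TPM",
                        orientation = c("features-in-rows", "samples-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col) &
                     col != "NA")
      if (length(bad))
        stop(sprintf("malformed numeric cell at row %d, column '%s' in %s",
                     bad[1L], names(body)[j], path), call. = FALSE)
      body[[j]] <- as.numeric(col)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples-in-rows") m <- t(m)
  expression_matrix(m, layer = layer, units = units)
}

#' Write an expression matrix to TSV
#'
#' Features in rows, header row of sample ids, floats at 6 significant
#' digits. [read_matrix()] of the result reproduces values to 1e-9.
#'
#' @param x An `expr_matrix` (or named numeric matrix).
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(feature = rownames(x),
                   signif(unclass(x), 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a set are
#' deduplicated; empty member lists are rejected.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: named list of character vectors, with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- descs <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT parse error at line %d: set '%s' has no members", i, f[1L]),
           call. = FALSE)
    nms[i] <- f[1L]; descs[i] <- f[2L]; sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(sets) <- nms
  gene_set_collection(sets, descriptions = stats::setNames(descs, nms))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique, non-empty).
#' @param descriptions Optional named character vector of per-set tags
#'   (cell type, immunity-cycle step, stimulation module, ...).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets))) stop("set names must be unique", call. = FALSE)
  if (any(lengths(sets) == 0L)) stop("sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, unique)
  structure(sets, descriptions = descriptions,
            class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Pair transcript and protein layers on shared molecules and samples
#'
#' Restricts both matrices to the intersection of feature ids and of sample
#' ids (lexicographic order) — the paired-layer view on which cross-layer
#' correlation analysis operates.
#'
#' @param transcript,protein `expr_matrix` objects sharing an identifier
#'   namespace.
#' @return List with elements `transcript`, `protein`, `n_shared_features`,
#'   `n_shared_samples`.
#' @export
merge_layers <- function(transcript, protein) {
  feats <- sort(intersect(rownames(transcript), rownames(protein)))
  samps <- sort(intersect(colnames(transcript), colnames(protein)))
  if (length(feats) == 0L)
    stop("zero shared molecules between layers", call. = FALSE)
  if (length(samps) == 0L)
    stop("zero shared samples between layers", call. = FALSE)
  list(transcript = expression_matrix(unclass(transcript)[feats, samps, drop = FALSE],
                                      layer = "transcript", units = units_of(transcript)),
       protein = expression_matrix(unclass(protein)[feats, samps, drop = FALSE],
                                   layer = "protein", units = units_of(protein)),
       n_shared_features = length(feats),
       n_shared_samples = length(samps))
}

#' Construct sample metadata
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param disease_score Percent of tissue area occupied by malignant cells
#'   plus stroma, in `[0, 100]` (optional, NA allowed).
#' @param matrix_index Optional real scalar per sample (published tumor-ECM
#'   signature score).
#' @param group Optional free-form group labels.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, disease_score = NA_real_,
                            matrix_index = NA_real_, group = NA_character_) {
  if (anyDuplicated(sample_id)) stop("sample ids must be unique", call. = FALSE)
  ds <- disease_score[!is.na(disease_score)]
  if (any(ds < 0 | ds > 100))
    stop("disease_score must lie in [0, 100]", call. = FALSE)
  structure(data.frame(sample_id = sample_id, disease_score = disease_score,
                       matrix_index = matrix_index, group = group,
                       stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}

#' Read a matrisome category annotation table
#'
#' TSV with columns `molecule`, `division` (core matrisome /
#' matrisome-associated) and `category` (one of the six matrisome
#' categories).
#'
#' @param path TSV file.
#' @return A validated annotation `data.frame`.
#' @export
read_matrisome_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  matrisome_annotation(df$molecule, df$division, df$category)
}

#' The six matrisome categories
#' @export
MATRISOME_CATEGORIES <- c("collagens", "ECM glycoproteins", "proteoglycans",
                          "ECM regulators", "ECM-affiliated proteins",
                          "secreted factors")

#' Construct a matrisome annotation
#'
#' @param molecule Molecule identifiers (unique).
#' @param division `"core matrisome"` or `"matrisome-associated"`.
#' @param category One of [MATRISOME_CATEGORIES] per molecule.
#' @return `data.frame` with one row per molecule.
#' @export
matrisome_annotation <- function(molecule, division, category) {
  if (anyDuplicated(molecule))
    stop("duplicate molecules in annotation", call. = FALSE)
  if (!all(category %in% MATRISOME_CATEGORIES))
    stop("unknown matrisome category: ",
         paste(setdiff(category, MATRISOME_CATEGORIES), collapse = ", "),
         call. = FALSE)
  if (!all(division %in% c("core matrisome", "matrisome-associated")))
    stop("division must be 'core matrisome' or 'matrisome-associated'",
         call. = FALSE)
  data.frame(molecule = molecule, division = division, category = category,
             stringsAsFactors = FALSE)
}
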