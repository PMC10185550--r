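#' IHC staining score
#'
#' Intensity-weighted stained-area score used to compare ECM marker staining
#' across tissues of different sizes. Stained areas (um^2) are binned by the
#' image-analysis software into low / medium / high intensity; bins are
#' weighted 1 / 2 / 3, summed, divided by total tissue area and scaled by
#' 100:
#'
#' \deqn{score = 100 (S_{low} + 2 S_{med} + 3 S_{high}) / A_{tissue}}
#'
#' The score lives in \[0, 300\] (300 = the whole tissue stained at high
#' intensity) and is invariant to joint rescaling of all areas.
#'
#' @param sum_low,sum_medium,sum_high Stained area (um^2) in each intensity
#'   bin; vectors recycle together.
#' @param tissue_area Total tissue area (um^2), positive.
#' @return Numeric staining score (AU).
#' @export
staining_score <- function(sum_low, sum_medium, sum_high, tissue_area) {
  if (any(tissue_area <= 0)) stop("tissue_area must be positive", call. = FALSE)
  if (any(c(sum_low, sum_medium, sum_high) < 0))
    stop("stained areas must be non-negative", call. = FALSE)
  if (any(sum_low + sum_medium + sum_high > tissue_area * (1 + 1e-12)))
    stop("stained area exceeds tissue area", call. = FALSE)
  100 * (sum_low * 1 + sum_medium * 2 + sum_high * 3) / tissue_area
}

#' Read a staining-area table
#'
#' CSV with columns `tissue, SumLow, SumMedium, SumHigh, tissue_area`
#' (areas in um^2).
#' @param path CSV file.
#' @return `data.frame` with an added `staining_score` column.
#' @export
read_staining_areas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "SumLow", "SumMedium", "SumHigh", "tissue_area")
  if (!all(need %in% names(df)))
    stop("staining table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$staining_score <- staining_score(df$SumLow, df$SumMedium, df$SumHigh,
                                      df$tissue_area)
  df
}

#' Fiber alignment index
#'
#' Circular-statistics order parameter of fiber orientations within a field
#' of view. Orientations are axial (period pi): each angle is doubled, the
#' mean orientation \eqn{\theta_{avg}} is half the argument of the mean
#' doubled-angle unit vector, and
#'
#' \deqn{AI = \frac{1}{N} \sum_j \cos\big(2(\theta_j - \theta_{avg})\big)}
#'
#' which equals the mean resultant length of the doubled angles. AI = 1 for
#' perfectly aligned fibers and tends to 0 for random orientations as N
#' grows; it is invariant to global rotation, to adding pi to any subset of
#' angles, and to permutation of the angle list.
#'
#' @param angles Fiber orientation angles; radians by default.
#' @param unit `"radians"` or `"degrees"`.
#' @return List with `ai` (in \[0, 1\]), `theta_avg` (radians, in
#'   \[-pi/2, pi/2\)), and `n`.
#' @export
alignment_index <- function(angles, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  if (length(angles) == 0L) stop("empty angle list", call. = FALSE)
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  if (unit == "degrees") angles <- angles * pi / 180
  cc <- mean(cos(2 * angles)); ss <- mean(sin(2 * angles))
  r <- sqrt(cc^2 + ss^2)
  list(ai = min(r, 1), theta_avg = atan2(ss, cc) / 2, n = length(angles))
}

#' Per-field and per-tissue fiber summaries
#'
#' Computes the alignment index and diameter summaries per field of view and
#' aggregates to tissue level by the median across fields. Fields with fewer
#' than `min_fibers` quantified fibers are flagged (`qc_pass = FALSE`) and
#' excluded from the tissue aggregate by default.
#'
#' @param fibers Long-format `data.frame` with columns `tissue`, `field`,
#'   `angle` (radians) and optionally `diameter` (nm).
#' @param min_fibers QC threshold on fibers per field (default 30).
#' @param unit Angle unit, see [alignment_index()].
#' @return List with `fields` (per-field table) and `tissues` (per-tissue
#'   medians over QC-passing fields).
#' @export
fiber_summary <- function(fibers, min_fibers = 30L, unit = "radians") {
  need <- c("tissue", "field", "angle")
  if (!all(need %in% names(fibers)))
    stop("fiber table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  key <- interaction(fibers$tissue, fibers$field, drop = TRUE)
  per_field <- do.call(rbind, lapply(split(fibers, key), function(d) {
    ai <- alignment_index(d$angle, unit = unit)
    data.frame(tissue = d$tissue[1L], field = d$field[1L], n_fibers = nrow(d),
               ai = ai$ai, theta_avg = ai$theta_avg,
               mean_diameter = if ("diameter" %in% names(d)) mean(d$diameter) else NA_real_,
               median_diameter = if ("diameter" %in% names(d)) stats::median(d$diameter) else NA_real_,
               qc_pass = nrow(d) >= min_fibers,
               stringsAsFactors = FALSE)
  }))
  rownames(per_field) <- NULL
  ok <- per_field[per_field$qc_pass, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("all fields fall below the ", min_fibers, "-fiber QC threshold",
         call. = FALSE)
  tissues <- do.call(rbind, lapply(split(ok, ok$tissue), function(d)
    data.frame(tissue = d$tissue[1L], n_fields = nrow(d),
               ai = stats::median(d$ai),
               median_diameter = stats::median(d$median_diameter),
               stringsAsFactors = FALSE)))
  rownames(tissues) <- NULL
  list(fields = per_field, tissues = tissues)
}

#' Disease score
#'
#' Digital-histopathology measure of disease extent: the percentage of
#' tissue area occupied by malignant (PAX8-positive) cells plus stroma.
#'
#' @param tumor_pct,stroma_pct Component percentages in \[0, 100\]; their sum
#'   must not exceed 100.
#' @return Numeric disease score in \[0, 100\].
#' @export
disease_score <- function(tumor_pct, stroma_pct) {
  if (any(tumor_pct < 0 | tumor_pct > 100) || any(stroma_pct < 0 | stroma_pct > 100))
    stop("component percentages must lie in [0, 100]", call. = FALSE)
  s <- tumor_pct + stroma_pct
  if (any(s > 100 + 1e-12))
    stop("tumor + stroma percentage exceeds 100", call. = FALSE)
  s
}
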