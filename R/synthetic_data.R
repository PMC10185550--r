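#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the study conditions this pipeline mirrors: a 32-sample
#' metastatic ovarian-cancer cohort with 8 immune cell types, a 5-molecule
#' matrisome signature rank-correlated (~0.7) with the target cell type at
#' both transcript and protein layers, immune counts proportional to
#' fractions, an exponential survival model with a 1.56 hazard ratio for
#' high- vs low-signature samples around a 45.63-month baseline median, five
#' planted ECM composition groups, and a matrisome category composition of
#' collagens 35% / glycoproteins 25% / proteoglycans 25% / regulators 8% /
#' affiliated 5% / secreted factors 1%.
#'
#' @param n_samples Cohort size (default 32).
#' @param n_cell_types Number of immune cell types (default 8).
#' @param n_genes Total transcript features (default 400).
#' @param n_matrisome Matrisome molecules present at both layers (default 80).
#' @param planted_signature_size Planted consensus molecules (default 5).
#' @param planted_rho Target Spearman correlation between planted molecules
#'   and the target cell type's fraction (default 0.7).
#' @param noise_sd Multiplicative log-normal noise SD on bulk expression
#'   (default 0.1).
#' @param dirichlet_alpha Dirichlet concentration per cell type (default 2).
#' @param disease_rho Rank correlation coupling disease score to the target
#'   cell type's fraction (default 0.6).
#' @param hr_true Proportional-hazards ratio, high vs low signature
#'   (default 1.56).
#' @param baseline_median_os Baseline (low-group) median survival in months
#'   (default 45.63).
#' @param kappa von Mises concentration for fiber fields (default 4).
#' @param ecg_k Planted ECM composition groups (default 5).
#' @param ecg_delta Group-marker offset in protein-SD units (default 3).
#' @param ecg_markers_per_group Marker proteins per ECG (default 10).
#' @param protein_noise_sd Log-scale protein noise SD (default 0.5;
#'   cohort CV ~50%, typical of label-free quantification).
#' @param markers_per_type Signature genes per cell type (default 10).
#' @param ihc_scale Expected IHC count (cells/mm^2) at fraction 1
#'   (default 500).
#' @param n_de_genes,de_logfc,de_sd Planted differentially expressed genes,
#'   their log2 fold change and the per-gene noise SD for the MAM
#'   experiment (defaults 50, 2, 0.2).
#' @param n_modules,module_size,intra_module_rho Planted co-expression
#'   modules for the MAM experiment (defaults 5, 40, 0.8).
#' @param n_mam_genes Genes in the MAM experiment (default 1000).
#' @param seed Mandatory RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 32L, n_cell_types = 8L,
                             n_genes = 400L, n_matrisome = 80L,
                             planted_signature_size = 5L, planted_rho = 0.7,
                             noise_sd = 0.1, dirichlet_alpha = 2,
                             disease_rho = 0.6, hr_true = 1.56,
                             baseline_median_os = 45.63, kappa = 4,
                             ecg_k = 5L, ecg_delta = 3,
                             ecg_markers_per_group = 10L,
                             protein_noise_sd = 0.5, markers_per_type = 10L,
                             ihc_scale = 500,
                             n_de_genes = 50L, de_logfc = 2, de_sd = 0.2,
                             n_modules = 5L, module_size = 40L,
                             intra_module_rho = 0.8, n_mam_genes = 1000L,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg <- list(n_samples = n_samples, n_cell_types = n_cell_types,
              n_genes = n_genes, n_matrisome = n_matrisome,
              planted_signature_size = planted_signature_size,
              planted_rho = planted_rho, noise_sd = noise_sd,
              dirichlet_alpha = rep_len(dirichlet_alpha, n_cell_types),
              disease_rho = disease_rho, hr_true = hr_true,
              baseline_median_os = baseline_median_os, kappa = kappa,
              ecg_k = ecg_k, ecg_delta = ecg_delta,
              ecg_markers_per_group = ecg_markers_per_group,
              protein_noise_sd = protein_noise_sd,
              markers_per_type = markers_per_type, ihc_scale = ihc_scale,
              n_de_genes = n_de_genes, de_logfc = de_logfc, de_sd = de_sd,
              n_modules = n_modules, module_size = module_size,
              intra_module_rho = intra_module_rho, n_mam_genes = n_mam_genes,
              seed = as.integer(seed))
  counts <- c(cfg$n_samples, cfg$n_cell_types, cfg$n_genes, cfg$n_matrisome,
              cfg$planted_signature_size, cfg$ecg_k, cfg$n_de_genes,
              cfg$n_modules, cfg$module_size, cfg$n_mam_genes)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (abs(cfg$planted_rho) >= 1) stop("planted_rho must lie in (-1, 1)", call. = FALSE)
  if (cfg$hr_true <= 0) stop("hr_true must be positive", call. = FALSE)
  if (cfg$kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  if (cfg$planted_signature_size > cfg$n_matrisome)
    stop("planted_signature_size exceeds n_matrisome", call. = FALSE)
  if (cfg$module_size * cfg$n_modules > cfg$n_mam_genes)
    stop("modules exceed gene count", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

# Generate a vector rank-correlated ~rho_s with `anchor` via a Gaussian
# copula on the latent-normal scale: z = rho_lat * z_anchor + sqrt(1 -
# rho_lat^2) * eps, with rho_lat = 2 sin(pi rho_s / 6) so the *Spearman*
# correlation targets rho_s. rho_s = 1 reproduces the anchor's ranks
# exactly.
copula_couple <- function(anchor, rho_s, meanlog = 0, sdlog = 1) {
  n <- length(anchor)
  z_anchor <- stats::qnorm((rank(anchor, ties.method = "average") - 0.5) / n)
  rho_lat <- 2 * sin(pi * rho_s / 6)
  z <- rho_lat * z_anchor + sqrt(1 - rho_lat^2) * stats::rnorm(n)
  exp(meanlog + sdlog * z)
}

# Cohort-wide matrisome category layout: molecule counts and total
# abundance weights matching the planted composition.
matrisome_layout <- function(n_matrisome) {
  wt <- c("collagens" = 35, "ECM glycoproteins" = 25, "proteoglycans" = 25,
          "ECM regulators" = 8, "ECM-affiliated proteins" = 5,
          "secreted factors" = 1)
  cnt <- pmax(1L, round(n_matrisome * c(0.18, 0.22, 0.12, 0.22, 0.14, 0.12)))
  cnt[1L] <- n_matrisome - sum(cnt[-1L])
  names(cnt) <- names(wt)
  list(weights = wt, counts = cnt)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Bulk transcript expression is a signature-matrix mixture of Dirichlet
#' cell-type fractions with multiplicative log-normal noise; the planted
#' matrisome molecules are rank-correlated with the target cell type's
#' fraction at BOTH layers via a Gaussian-copula construction; non-planted
#' molecules are independent; IHC counts are Poisson-noised scaled
#' fractions; the disease score is rank-coupled to the target fraction;
#' survival times are exponential with the hazard multiplied by `hr_true`
#' for samples above the median planted-signature score; five ECM
#' composition groups are planted in the protein layer. Bit-reproducible
#' given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with `transcript`, `protein` (`expr_matrix`), `reference`
#'   (a [cell_type_signature()] with matrix and marker sets), `ihc_counts`,
#'   `ihc_pairs`, `metadata`, `survival`, `annotation`, `step_sets`, and
#'   `truth` (fractions, planted molecule ids, target cell type, ECG
#'   labels, hr_true, ...).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ct <- c("Macrophage.M0", "Macrophage.M1", "Macrophage.M2", "T.CD8",
            "T.CD4", "B.cell", "NK", "Dendritic")
    ct <- if (config$n_cell_types <= length(ct)) ct[seq_len(config$n_cell_types)]
          else c(ct, paste0("CellType", seq_len(config$n_cell_types - length(ct))))
    target <- ct[1L]
    samples <- sprintf("S%02d", seq_len(n))

    # Dirichlet fractions
    g <- matrix(stats::rgamma(n * length(ct), shape = config$dirichlet_alpha,
                              rate = 1),
                n, length(ct), byrow = TRUE,
                dimnames = list(samples, ct))
    fractions <- g / rowSums(g)

    # reference signature matrix: markers high in their own type
    mk_genes <- unlist(lapply(seq_along(ct), function(i)
      sprintf("MK_%s_%02d", gsub("[^A-Za-z0-9]", "", ct[i]),
              seq_len(config$markers_per_type))))
    S <- matrix(stats::runif(length(mk_genes) * length(ct), 1, 10),
                length(mk_genes), length(ct),
                dimnames = list(mk_genes, ct))
    for (i in seq_along(ct)) {
      idx <- (i - 1L) * config$markers_per_type + seq_len(config$markers_per_type)
      S[idx, i] <- stats::runif(config$markers_per_type, 300, 700)
    }
    marker_sets <- gene_set_collection(stats::setNames(
      lapply(seq_along(ct), function(i)
        mk_genes[(i - 1L) * config$markers_per_type + seq_len(config$markers_per_type)]),
      ct))

    # filler genes expressed independently of composition
    n_filler <- max(0L, config$n_genes - length(mk_genes) - config$n_matrisome)
    filler <- sprintf("FIL%03d", seq_len(n_filler))

    # matrisome molecules; the planted five carry the field's canonical names
    planted <- c("FN1", "VCAN", "MXRA5", "COL11A1", "SFRP2")
    if (config$planted_signature_size != 5L)
      planted <- c(planted, sprintf("PLT%02d", seq_len(max(0L, config$planted_signature_size - 5L))))
    planted <- planted[seq_len(config$planted_signature_size)]
    mat_other <- sprintf("MAT%03d", seq_len(config$n_matrisome - length(planted)))
    mat_ids <- c(planted, mat_other)

    lay <- matrisome_layout(config$n_matrisome)
    planted_cat <- c("ECM glycoproteins", "proteoglycans", "ECM glycoproteins",
                     "collagens", "secreted factors")[seq_along(planted)]
    remaining <- rep(names(lay$counts), lay$counts)
    for (pc in planted_cat) remaining <- remaining[-match(pc, remaining)]
    categories <- c(planted_cat, remaining)
    division <- ifelse(categories %in% c("collagens", "ECM glycoproteins",
                                         "proteoglycans"),
                       "core matrisome", "matrisome-associated")
    annotation <- matrisome_annotation(mat_ids, division, categories)
    # per-molecule abundance scale: category weight split over its members
    mol_scale <- (lay$weights / lay$counts)[categories] * 10
    names(mol_scale) <- mat_ids

    # transcript layer -------------------------------------------------
    bulk_sig <- S %*% t(fractions)
    base_fil <- stats::runif(n_filler, 5, 50)
    bulk_fil <- matrix(rep(base_fil, n), n_filler, n,
                       dimnames = list(filler, samples))
    tf <- fractions[, target]
    mat_tx <- t(vapply(seq_along(mat_ids), function(i) {
      rho <- if (mat_ids[i] %in% planted) config$planted_rho else 0
      copula_couple(tf, rho, meanlog = log(mol_scale[i]), sdlog = 1)
    }, numeric(n)))
    dimnames(mat_tx) <- list(mat_ids, samples)
    # step-7 immunity-cycle genes anti-correlated with the target fraction
    step7 <- sprintf("STP7_%02d", 1:8)
    stp <- t(vapply(step7, function(id)
      copula_couple(tf, -0.5, meanlog = log(20), sdlog = 1), numeric(n)))
    dimnames(stp) <- list(step7, samples)
    bulk <- rbind(bulk_sig, bulk_fil, mat_tx, stp)
    noise <- matrix(exp(stats::rnorm(length(bulk), 0, config$noise_sd)),
                    nrow(bulk), ncol(bulk))
    bulk <- bulk * noise
    transcript <- expression_matrix(bulk, layer = "transcript", units = "TPM")

    # immunity-cycle step sets (steps 1-6 random filler genes, step 7 planted)
    step_pool <- sample(filler, 48L)
    step_sets <- gene_set_collection(stats::setNames(
      c(lapply(0:5, function(i) step_pool[i * 8L + 1:8]), list(step7)),
      paste0("step", 1:7)))

    # protein layer ----------------------------------------------------
    ecg_groups <- sample(rep_len(seq_len(config$ecg_k), n))
    names(ecg_groups) <- samples
    # ECG marker proteins drawn proportionally from every category so the
    # group shifts leave the cohort-wide composition unchanged
    pool <- setdiff(mat_ids, planted)
    pool_cat <- categories[match(pool, mat_ids)]
    n_mk <- min(config$ecg_k * config$ecg_markers_per_group, length(pool))
    quota <- table(pool_cat) * n_mk / length(pool)
    take <- floor(quota)
    extra <- order(quota - take, decreasing = TRUE)
    take[extra[seq_len(n_mk - sum(take))]] <- take[extra[seq_len(n_mk - sum(take))]] + 1L
    marker_pool <- unlist(lapply(names(take), function(cc)
      utils::head(pool[pool_cat == cc], take[[cc]])), use.names = FALSE)
    ecg_markers <- split(marker_pool, rep_len(seq_len(config$ecg_k), n_mk))
    prot <- t(vapply(seq_along(mat_ids), function(i) {
      rho <- if (mat_ids[i] %in% planted) config$planted_rho else 0
      copula_couple(tf, rho, meanlog = log(mol_scale[i]),
                    sdlog = config$protein_noise_sd)
    }, numeric(n)))
    dimnames(prot) <- list(mat_ids, samples)
    for (grp in seq_len(config$ecg_k)) {
      mk <- ecg_markers[[grp]]
      shift <- config$ecg_delta * config$protein_noise_sd *
        ((ecg_groups == grp) - 1 / config$ecg_k)
      prot[mk, ] <- prot[mk, ] * matrix(2^shift, length(mk), n, byrow = TRUE)
    }
    protein <- expression_matrix(prot, layer = "protein",
                                 units = "protein-abundance-AU")

    # IHC counts proportional to fractions with Poisson noise
    ihc_pairs <- c("Macrophage.M0" = "CD68", "T.CD8" = "CD8", "T.CD4" = "CD4",
                   "B.cell" = "CD20", "NK" = "CD56", "Dendritic" = "CD11c")
    ihc_pairs <- ihc_pairs[names(ihc_pairs) %in% ct]
    ihc <- sapply(names(ihc_pairs), function(tt)
      stats::rpois(n, config$ihc_scale * fractions[, tt]))
    dimnames(ihc) <- list(samples, unname(ihc_pairs))

    # metadata: disease score rank-coupled to the target fraction
    ds_raw <- copula_couple(tf, config$disease_rho)
    dscore <- round(100 * stats::pnorm(log(ds_raw), sd = 1), 1)
    mindex <- log(copula_couple(tf, 0.5))
    metadata <- sample_metadata(samples, disease_score = dscore,
                                matrix_index = mindex)

    # survival tied to the planted-signature protein score
    sig_score <- colMeans(row_zscore(prot[planted, , drop = FALSE]))
    high <- sig_score > stats::median(sig_score)
    lam0 <- log(2) / config$baseline_median_os
    haz <- lam0 * ifelse(high, config$hr_true, 1)
    t_event <- stats::rexp(n, haz)
    t_cens <- stats::runif(n, 0, 1.5 * config$baseline_median_os)
    surv <- data.frame(sample_id = samples,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       group = ifelse(high, "high", "low"),
                       stringsAsFactors = FALSE)

    list(transcript = transcript, protein = protein,
         reference = cell_type_signature(matrix = S, sets = marker_sets),
         ihc_counts = ihc, ihc_pairs = ihc_pairs, metadata = metadata,
         survival = surv, annotation = annotation, step_sets = step_sets,
         truth = list(fractions = fractions, planted_molecules = sort(planted),
                      target_cell_type = target, ecg_groups = ecg_groups,
                      hr_true = config$hr_true, signature_score = sig_score,
                      step7_genes = step7, ecg_markers = ecg_markers))
  })
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 gives
# the circular uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    c <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c * (2 - c) - u2 > 0 || log(c / u2) + 1 - c >= 0) {
      i <- i + 1L
      out[i] <- (sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu) %% (2 * pi)
    }
  }
  out
}

#' Simulate fiber orientation fields
#'
#' Orientations (axial, period pi) drawn from a von Mises distribution on
#' the doubled-angle circle with concentration `kappa`; `kappa = 0` gives
#' uniformly random orientations, large `kappa` perfectly aligned fields.
#'
#' @param kappa von Mises concentration (>= 0); scalar or one per field.
#' @param n_fibers Fibers per field (>= 1).
#' @param n_fields Number of fields.
#' @param seed RNG seed.
#' @param mu Mean orientation angle (radians, default pi/4).
#' @return Long-format `data.frame` with columns `tissue`, `field`, `angle`
#'   (radians in \[0, pi\)) and `kappa`.
#' @export
simulate_fiber_fields <- function(kappa, n_fibers, n_fields = 1L, seed,
                                  mu = pi / 4) {
  if (any(kappa < 0)) stop("kappa must be non-negative", call. = FALSE)
  if (n_fibers < 1L) stop("n_fibers must be >= 1", call. = FALSE)
  kappa <- rep_len(kappa, n_fields)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_fields), function(f) {
      phi <- rvonmises(n_fibers, mu = (2 * mu) %% (2 * pi), kappa = kappa[f])
      data.frame(tissue = "synthetic", field = f, angle = (phi / 2) %% pi,
                 kappa = kappa[f], stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate the matrix-educated-macrophage experiment
#'
#' Two groups of monocyte-derived macrophage profiles (HD = educated on
#' high-disease ECM, LD = low-disease), 4 blood donors with an additive
#' per-donor batch offset, planted differentially expressed genes at
#' `de_logfc` (alternating directions), and planted co-expression modules
#' via a latent-factor model with intra-module correlation
#' ~`intra_module_rho`.
#'
#' @param config A [generator_config()].
#' @param n_hd,n_ld Group sizes (defaults 16, 15).
#' @return List with `expr` (log2TPM `expr_matrix`), `groups`, `donor`,
#'   `coding` (all-TRUE biotype stub) and `truth` (DE gene ids/directions,
#'   module membership).
#' @export
simulate_mam_experiment <- function(config, n_hd = 16L, n_ld = 15L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_de_genes > config$n_mam_genes)
    stop("n_de_genes exceeds n_mam_genes", call. = FALSE)
  with_seed(config$seed + 1L, {
    n <- n_hd + n_ld
    samples <- c(sprintf("HD%02d", seq_len(n_hd)), sprintf("LD%02d", seq_len(n_ld)))
    groups <- stats::setNames(rep(c("HD", "LD"), c(n_hd, n_ld)), samples)
    donor <- stats::setNames(factor(rep_len(paste0("D", 1:4), n)), samples)

    de_ids <- sprintf("DEG%03d", seq_len(config$n_de_genes))
    mod_ids <- sprintf("MOD%d_%03d",
                       rep(seq_len(config$n_modules), each = config$module_size),
                       rep(seq_len(config$module_size), config$n_modules))
    n_null <- config$n_mam_genes - length(de_ids) - length(mod_ids)
    if (n_null < 0L) stop("module and DE genes exceed n_mam_genes", call. = FALSE)
    null_ids <- sprintf("NUL%03d", seq_len(n_null))
    ids <- c(de_ids, mod_ids, null_ids)

    base <- stats::runif(length(ids), 3, 9)
    m <- matrix(stats::rnorm(length(ids) * n, 0, config$de_sd),
                length(ids), n, dimnames = list(ids, samples))
    m <- m + base
    # donor batch effect
    doff <- stats::setNames(stats::rnorm(4L, 0, 0.3), paste0("D", 1:4))
    m <- m + matrix(doff[as.character(donor)], length(ids), n, byrow = TRUE)
    # planted DE, alternating directions, applied to the HD group
    dir <- rep_len(c(1, -1), length(de_ids))
    m[de_ids, groups == "HD"] <- m[de_ids, groups == "HD"] +
      dir * config$de_logfc
    # planted modules: latent factor per module, marginal SD 0.5
    sdm <- 0.5
    for (k in seq_len(config$n_modules)) {
      fac <- stats::rnorm(n)
      rows <- mod_ids[(k - 1L) * config$module_size + seq_len(config$module_size)]
      eps <- matrix(stats::rnorm(length(rows) * n), length(rows), n)
      m[rows, ] <- base[match(rows, ids)] +
        sdm * (sqrt(config$intra_module_rho) * matrix(fac, length(rows), n, byrow = TRUE) +
               sqrt(1 - config$intra_module_rho) * eps) +
        matrix(doff[as.character(donor)], length(rows), n, byrow = TRUE)
    }
    expr <- expression_matrix(m, layer = "transcript", units = "log2TPM")
    truth_mod <- stats::setNames(integer(length(ids)), ids)
    truth_mod[mod_ids] <- rep(seq_len(config$n_modules),
                              each = config$module_size)
    list(expr = expr, groups = groups, donor = donor,
         coding = stats::setNames(rep(TRUE, length(ids)), ids),
         truth = list(de_genes = de_ids,
                      de_direction = stats::setNames(ifelse(dir > 0, "up", "down"), de_ids),
                      modules = truth_mod))
  })
}
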