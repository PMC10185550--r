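test_that("proteomics normalization is scale-invariant with unit z-rows", {
  set.seed(2)
  vals <- matrix(stats::rexp(12, 0.1), 4, 3)
  raw <- toy_expr(vals, layer = "protein", units = "protein-abundance-AU")
  norm <- normalize_proteomics(raw)
  scaled <- toy_expr(vals %*% diag(c(10, 1, 1)), layer = "protein",
                     units = "protein-abundance-AU")
  norm2 <- normalize_proteomics(scaled)
  expect_equal(unclass(norm$log), unclass(norm2$log), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(rowMeans(norm$z)), rep(0, nrow(norm$z)),
               tolerance = 1e-9)
  expect_equal(unname(apply(norm$z, 1, stats::sd)), rep(1, nrow(norm$z)),
               tolerance = 1e-9)
  # spreadsheet oracle on a 3x3 table
  v <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  n3 <- normalize_proteomics(toy_expr(v, layer = "protein",
                                      units = "protein-abundance-AU"))
  tot <- colSums(v); want <- log2(sweep(v, 2, tot / 1e4, "/") + 1)
  expect_equal(unclass(n3$log), want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(
    normalize_proteomics(toy_expr(matrix(0, 2, 2), layer = "protein",
                                  units = "protein-abundance-AU")),
    "all-zero")
})

test_that("well-separated blobs are clustered perfectly and deterministically", {
  set.seed(14)
  a <- matrix(stats::rnorm(20 * 6, 0), 20, 6)
  b <- matrix(stats::rnorm(20 * 6, 8), 20, 6)
  z <- cbind(a, b)
  dimnames(z) <- list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:12))
  ec <- cluster_ecgs(z, k = 2)
  expect_identical(unname(ec$groups[1:6]), rep(ec$groups[[1]], 6))
  expect_identical(unname(ec$groups[7:12]), rep(ec$groups[[7]], 6))
  expect_false(ec$groups[[1]] == ec$groups[[7]])
  # permuting sample order yields the same partition
  perm <- sample(12)
  ec2 <- cluster_ecgs(z[, perm], k = 2)
  expect_identical(ec2$groups[names(ec$groups)], ec$groups)
  expect_error(cluster_ecgs(z, k = 13), "exceeds")
  # k = n gives singletons
  ecn <- cluster_ecgs(z, k = 12)
  expect_identical(length(unique(ecn$groups)), 12L)
})

test_that("planted composition groups are recovered from proteomics", {
  aris <- sapply(1:10, function(s) {
    coh <- simulate_cohort(generator_config(seed = s))
    ec <- cluster_ecgs(coh$protein, k = 5, metadata = coh$metadata)
    mclust::adjustedRandIndex(ec$groups, coh$truth$ecg_groups)
  })
  expect_gte(median(aris), 0.9)
})

test_that("group labels order by increasing mean disease score", {
  coh <- simulate_cohort(generator_config(seed = 7))
  ec <- cluster_ecgs(coh$protein, k = 5, metadata = coh$metadata)
  ds <- coh$metadata$disease_score[match(names(ec$groups),
                                         coh$metadata$sample_id)]
  gm <- tapply(ds, ec$groups, mean)
  expect_identical(order(gm), seq_len(5L))
})

test_that("category composition matches a hand-summed oracle", {
  ann <- matrisome_annotation(
    c("C1", "G1", "P1", "R1", "A1", "S1"),
    c(rep("core matrisome", 3), rep("matrisome-associated", 3)),
    MATRISOME_CATEGORIES)
  vals <- matrix(c(35, 25, 25, 8, 5, 1, 70, 50, 50, 16, 10, 2), 6, 2)
  m <- toy_expr(vals, layer = "protein", units = "protein-abundance-AU",
                features = c("C1", "G1", "P1", "R1", "A1", "S1"))
  comp <- category_composition(m, ann)
  expect_equal(unname(comp$cohort), c(35, 25, 25, 8, 5, 1) / 99,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(comp$per_sample)), c(1, 1), tolerance = 1e-9)
  # unannotated protein excluded from the denominator
  m2 <- toy_expr(rbind(vals, UNK = c(100, 100)), layer = "protein",
                 units = "protein-abundance-AU",
                 features = c("C1", "G1", "P1", "R1", "A1", "S1", "UNK"))
  expect_warning(comp2 <- category_composition(m2, ann), "unannotated")
  expect_equal(comp2$cohort, comp$cohort, tolerance = 1e-12)
  # degenerate: all abundance on collagens
  m3 <- toy_expr(matrix(c(5, 0, 0, 0, 0, 0), 6, 1), layer = "protein",
                 units = "protein-abundance-AU",
                 features = c("C1", "G1", "P1", "R1", "A1", "S1"))
  expect_equal(unname(category_composition(m3, ann)$cohort["collagens"]), 1)
})

test_that("group-specific proteins are detected as up in their group only", {
  found <- sapply(1:10, function(s) {
    coh <- simulate_cohort(generator_config(seed = s))
    norm <- normalize_proteomics(coh$protein)
    ec <- cluster_ecgs(coh$protein, k = 5, metadata = coh$metadata)
    de <- ecg_differential_proteins(norm$log, ec)
    # a marker of the truth group that best matches each found group
    ok <- TRUE
    for (g in names(de)) {
      samples <- names(ec$groups)[ec$groups == as.integer(g)]
      tg <- as.integer(names(which.max(table(coh$truth$ecg_groups[samples]))))
      mk <- coh$truth$ecg_markers[[tg]]
      ok <- ok && any(mk %in% de[[g]]$up)
    }
    ok
  })
  expect_gte(mean(found), 0.9)
  # constant protein lands in no list
  coh <- simulate_cohort(generator_config(seed = 3))
  m <- unclass(normalize_proteomics(coh$protein)$log)
  m["MAT050", ] <- 1
  lg <- expression_matrix(m, layer = "protein",
                          units = "protein-abundance-AU")
  ec <- cluster_ecgs(coh$protein, k = 5, metadata = coh$metadata)
  de <- ecg_differential_proteins(lg, ec)
  expect_false(any(vapply(de, function(g)
    "MAT050" %in% c(g$up, g$down), logical(1L))))
})

test_that("label permutation keeps the false-positive rate nominal", {
  coh <- simulate_cohort(generator_config(seed = 5))
  norm <- normalize_proteomics(coh$protein)
  set.seed(77)
  rates <- sapply(1:5, function(i) {
    perm <- sample(names(coh$truth$ecg_groups))
    fake <- structure(list(groups = stats::setNames(coh$truth$ecg_groups, perm),
                           k = 5L), class = "ecg_assignment")
    de <- ecg_differential_proteins(norm$log, fake)
    sum(vapply(de, function(g) length(c(g$up, g$down)), integer(1L))) /
      (5 * nrow(norm$log))
  })
  expect_lte(mean(rates), 0.05)
})

test_that("immune association z-rows center and detect planted ordering", {
  coh <- simulate_cohort(generator_config(seed = 9))
  ec <- cluster_ecgs(coh$protein, k = 5, metadata = coh$metadata)
  assoc <- ecg_immune_association(ec, coh$ihc_counts, coh$metadata)
  expect_equal(unname(rowMeans(assoc$z, na.rm = TRUE)),
               rep(0, nrow(assoc$z)), tolerance = 1e-9)
  expect_true(all(c("CD68", "CD8") %in% rownames(assoc$group_means)))
  # identical counts in all samples: flat ANOVA
  flat <- matrix(5, 32, 2, dimnames = list(rownames(coh$ihc_counts),
                                           c("CD68", "CD8")))
  a2 <- ecg_immune_association(ec, flat)
  expect_true(all(is.na(a2$anova_p)))
  expect_true(all(is.na(a2$z)))
})
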