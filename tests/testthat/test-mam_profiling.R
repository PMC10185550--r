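test_that("identical groups produce no significant genes", {
  set.seed(3)
  m <- matrix(stats::rnorm(200 * 12, 5), 200, 12,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("S%02d", 1:12)))
  expr <- expression_matrix(m, units = "log2TPM")
  g <- stats::setNames(rep(c("HD", "LD"), 6), colnames(m))
  de <- suppressWarnings(differential_expression(expr, g))
  expect_identical(sum(de$table$significant), 0L)
})

test_that("the logFC filter overrides arbitrarily small p-values", {
  # a gene with tiny within-group variance but |logFC| = 0.5 never passes
  m <- matrix(5, 40, 12, dimnames = list(sprintf("G%02d", 1:40),
                                         sprintf("S%02d", 1:12)))
  g <- stats::setNames(rep(c("HD", "LD"), each = 6), colnames(m))
  set.seed(10)
  m <- m + stats::rnorm(length(m), 0, 0.01)
  m["G01", g == "HD"] <- m["G01", g == "HD"] + 0.5
  expr <- expression_matrix(m, units = "log2TPM")
  de <- suppressWarnings(differential_expression(expr, g))
  tab <- de$table
  expect_lt(tab$adj_p[tab$gene == "G01"], 1e-6)
  expect_false(tab$significant[tab$gene == "G01"])
  # and filter semantics are monotone in the cutoffs
  de2 <- suppressWarnings(differential_expression(expr, g, lfc = 0.25))
  expect_true(all(de$table$gene[de$table$significant] %in%
                    de2$table$gene[de2$table$significant]))
})

test_that("non-coding genes are excluded when a biotype table is supplied", {
  mam <- simulate_mam_experiment(generator_config(seed = 5))
  coding <- mam$coding
  coding[mam$truth$de_genes[1:10]] <- FALSE
  de <- differential_expression(mam$expr, mam$groups, coding = coding,
                                donor = mam$donor)
  expect_false(any(mam$truth$de_genes[1:10] %in%
                     de$table$gene[de$table$significant]))
  expect_warning(differential_expression(mam$expr, mam$groups),
                 "coding filter SKIPPED")
})

test_that("subtype scoring recovers pure and planted profiles", {
  coh <- simulate_cohort(generator_config(seed = 4))
  mac <- c("Macrophage.M0", "Macrophage.M1", "Macrophage.M2")
  ref <- cell_type_signature(matrix = coh$reference$matrix[, mac])
  pure <- expression_matrix(
    log2(coh$reference$matrix[, "Macrophage.M0", drop = FALSE] + 1),
    units = "log2TPM")
  colnames(pure) <- "P1"
  sc <- subtype_scores(pure, ref)
  expect_equal(unname(sc[1, "Macrophage.M0"]), 1, tolerance = 1e-6)
  expect_equal(unname(rowSums(sc)), 1, tolerance = 1e-9)
})

test_that("planted HD enrichment of M0 genes raises HD M0 shares", {
  hits <- sapply(1:10, function(s) {
    coh <- simulate_cohort(generator_config(seed = s))
    mac <- c("Macrophage.M0", "Macrophage.M1", "Macrophage.M2")
    S <- coh$reference$matrix[, mac]
    set.seed(s + 100)
    w_hd <- cbind(stats::runif(8, 0.5, 0.9))
    w_hd <- cbind(w_hd, (1 - w_hd) / 2, (1 - w_hd) / 2)
    w_ld <- cbind(stats::runif(8, 0.1, 0.4))
    w_ld <- cbind(w_ld, (1 - w_ld) / 2, (1 - w_ld) / 2)
    prof <- S %*% t(rbind(w_hd, w_ld)) *
      exp(stats::rnorm(nrow(S) * 16, 0, 0.1))
    colnames(prof) <- c(sprintf("HD%d", 1:8), sprintf("LD%d", 1:8))
    sc <- subtype_scores(expression_matrix(prof, units = "TPM"),
                         cell_type_signature(matrix = S))
    mean(sc[1:8, "Macrophage.M0"]) > mean(sc[9:16, "Macrophage.M0"])
  })
  expect_identical(mean(hits), 1)
})

test_that("perfect blocks give exact modules with unit eigengene correlation", {
  set.seed(12)
  n <- 12
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  m <- rbind(matrix(rep(f1, each = 30), 30, n, byrow = FALSE) * 1,
             matrix(rep(f2, each = 30), 30, n, byrow = FALSE))
  m <- m + 5
  dimnames(m) <- list(sprintf("G%02d", 1:60), sprintf("S%02d", 1:n))
  mod <- detect_modules(expression_matrix(m, units = "log2TPM"),
                        min_module_size = 10)
  expect_identical(max(mod$membership), 2L)
  expect_identical(unname(mod$membership[1:30]), rep(mod$membership[[1]], 30))
  expect_identical(unname(mod$membership[31:60]), rep(mod$membership[[31]], 30))
  # eigengene of identical genes correlates |r| = 1 with each member
  eg <- mod$eigengenes[mod$membership[["G01"]], ]
  expect_equal(abs(stats::cor(eg, m["G01", ])), 1, tolerance = 1e-9)
})

test_that("module detection is invariant to gene-order permutation", {
  mam <- simulate_mam_experiment(generator_config(seed = 2, de_logfc = 0))
  mod <- detect_modules(mam$expr, donor = mam$donor)
  perm <- sample(rownames(mam$expr))
  mod2 <- detect_modules(mam$expr[perm, ], donor = mam$donor)
  g <- names(mod$membership)
  # same partition up to label renaming
  expect_equal(mclust::adjustedRandIndex(mod$membership[g],
                                         mod2$membership[g]), 1)
})

test_that("planted modules are recovered across seeds", {
  aris <- sapply(1:5, function(s) {
    mam <- simulate_mam_experiment(generator_config(seed = s, de_logfc = 0))
    mod <- detect_modules(mam$expr, donor = mam$donor)
    mclust::adjustedRandIndex(mod$membership, mam$truth$modules)
  })
  expect_gte(median(aris), 0.8)
})

test_that("gsva scores share the rank-based engine and its invariances", {
  mam <- simulate_mam_experiment(generator_config(seed = 3))
  lists <- gene_set_collection(list(
    L1 = rownames(mam$expr)[1:25], L2 = rownames(mam$expr)[100:140]))
  sc <- gsva_scores(mam$expr, lists)
  mono <- expression_matrix(unclass(mam$expr)^3, units = "log2TPM")
  expect_equal(gsva_scores(mono, lists), sc, tolerance = 1e-12)
})

test_that("module-trait correlation is exact for self-traits and sign flips", {
  mam <- simulate_mam_experiment(generator_config(seed = 4, de_logfc = 0))
  mod <- detect_modules(mam$expr, donor = mam$donor)
  traits <- cbind(ME1_copy = mod$eigengenes["ME1", ],
                  noise = stats::rnorm(ncol(mod$eigengenes)))
  mt <- module_trait_correlation(mod, traits)
  r_self <- mt$table$r[mt$table$module == "ME1" & mt$table$trait == "ME1_copy"]
  expect_equal(r_self, 1, tolerance = 1e-9)
  flipped <- traits; flipped[, "ME1_copy"] <- -flipped[, "ME1_copy"]
  mt2 <- module_trait_correlation(mod, flipped)
  expect_equal(mt2$table$r[mt2$table$module == "ME1" &
                             mt2$table$trait == "ME1_copy"], -r_self,
               tolerance = 1e-9)
  expect_equal(mt2$table$p, mt$table$p, tolerance = 1e-9)
})

test_that("hypergeometric enrichment equals the exhaustive tail-sum oracle", {
  set.seed(23)
  universe <- sprintf("U%03d", 1:100)
  for (rep in 1:5) {
    mod <- sample(universe, 20)
    de <- sample(universe, 15)
    res <- spectrum_association(de, gene_set_collection(list(m = mod)),
                                universe)
    q <- length(intersect(de, mod))
    want <- hyper_tail_oracle(q, 20, 80, 15)
    expect_equal(res$p, want, tolerance = 1e-9)
  }
  # DE set identical to a module is the top hit; disjoint is ~1
  mods <- gene_set_collection(list(hit = universe[1:15],
                                   other = universe[40:60]))
  res <- spectrum_association(universe[1:15], mods, universe)
  expect_lt(res$p[res$module == "hit"], 1e-12)
  res2 <- spectrum_association(universe[1:15],
                               gene_set_collection(list(x = universe[80:99])),
                               universe)
  expect_gt(res2$p, 0.99)
})
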