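abund_fixture <- function(n = 8, seed = 1) {
  set.seed(seed)
  f1 <- stats::runif(n, 0.05, 0.6)
  immune_abundance(matrix(c(f1, 1 - f1), n, 2,
                          dimnames = list(sprintf("S%02d", seq_len(n)),
                                          c("M0", "CD8T"))),
                   method = "fractions", units = "fraction")
}

test_that("monotone and constant molecules behave as expected", {
  ab <- abund_fixture(10)
  mono <- exp(ab[, "M0"])          # strictly increasing in the abundance
  const <- rep(3, 10)
  m <- toy_expr(rbind(MOL1 = mono, MOL2 = const), samples = rownames(ab))
  recs <- suppressWarnings(correlate_layer(ab, m))
  expect_equal(recs$rho[recs$molecule == "MOL1" & recs$cell_type == "M0"], 1,
               tolerance = 1e-12)
  expect_false("MOL2" %in% recs$molecule)
  expect_warning(correlate_layer(ab, m), "skipped")
})

test_that("small-n p-values equal the exhaustive permutation oracle", {
  set.seed(7)
  for (rep in 1:3) {
    x <- sample(1000, 8); y <- sample(1000, 8)
    ab <- immune_abundance(matrix(y / sum(y), 8, 1,
                                  dimnames = list(sprintf("S%d", 1:8), "M0")),
                           method = "fractions", units = "enrichment-score")
    m <- toy_expr(matrix(x, 1, 8), features = "MOL",
                  samples = sprintf("S%d", 1:8))
    recs <- correlate_layer(ab, m)
    expect_equal(recs$p, spearman_perm_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("scalar-index correlation mirrors molecule-row behavior", {
  ab <- abund_fixture(12)
  idx <- stats::setNames(ab[, "M0"] * 100, rownames(ab))
  recs <- correlate_with_index(idx, ab)
  expect_equal(recs$rho[recs$cell_type == "M0"], 1, tolerance = 1e-12)
  expect_equal(recs$rho[recs$cell_type == "CD8T"], -1, tolerance = 1e-12)
})

make_records <- function(mols, pass_tab) {
  # pass_tab: named list cell -> molecules that pass there
  cells <- expand.grid(method = c("fractions", "enrichment"),
                       layer = c("transcript", "protein"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$method[i], cells$layer[i], sep = ":")
    data.frame(molecule = mols, cell_type = "M0",
               layer = cells$layer[i], method = cells$method[i],
               rho = ifelse(mols %in% pass_tab[[key]], 0.6, 0.1),
               p = ifelse(mols %in% pass_tab[[key]], 0.001, 0.5),
               n = 32, stringsAsFactors = FALSE)
  }))
}

test_that("consensus keeps exactly the molecules passing all four cells", {
  mols <- c("FN1", "VCAN", "MXRA5", "COL11A1", "SFRP2", "LUM", "DCN")
  five <- c("FN1", "VCAN", "MXRA5", "COL11A1", "SFRP2")
  cells <- c("fractions:transcript", "enrichment:transcript",
             "fractions:protein", "enrichment:protein")
  pass <- stats::setNames(list(c(five, "LUM"), five, five, c(five, "DCN")),
                          cells)
  recs <- make_records(mols, pass)
  sig <- consensus_signature(recs, "M0")
  expect_identical(sig$molecules, sort(five))
  # all p = 1 gives the empty set, not an error
  recs$p <- 1
  expect_length(consensus_signature(recs, "M0")$molecules, 0L)
  expect_error(consensus_signature(recs[0, ], "M0"), "empty")
})

test_that("consensus equals a brute-force four-way filter on random tables", {
  set.seed(5)
  for (rep in 1:5) {
    mols <- sprintf("MOL%02d", 1:30)
    cells <- expand.grid(method = c("fractions", "enrichment"),
                         layer = c("transcript", "protein"),
                         stringsAsFactors = FALSE)
    recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      data.frame(molecule = mols, cell_type = "M0",
                 layer = cells$layer[i], method = cells$method[i],
                 rho = stats::runif(30, -1, 1), p = stats::runif(30),
                 n = 32, stringsAsFactors = FALSE)))
    got <- consensus_signature(recs, "M0")$molecules
    # independent naive filter
    want <- Filter(function(mm) {
      sub <- recs[recs$molecule == mm, ]
      all(sub$rho > 0 & sub$p < 0.05)
    }, mols)
    expect_identical(got, sort(want))
  }
})

test_that("consensus is anti-monotone in cells and monotone in alpha", {
  set.seed(9)
  mols <- sprintf("MOL%02d", 1:40)
  cells <- expand.grid(method = c("fractions", "enrichment"),
                       layer = c("transcript", "protein"),
                       stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(molecule = mols, cell_type = "M0", layer = cells$layer[i],
               method = cells$method[i], rho = stats::runif(40, -0.5, 1),
               p = stats::runif(40, 0, 0.2), n = 32,
               stringsAsFactors = FALSE)))
  full <- consensus_signature(recs, "M0")$molecules
  one_cell <- recs[recs$method == "fractions" & recs$layer == "transcript", ]
  single <- consensus_signature(one_cell, "M0")$molecules
  expect_true(all(full %in% single))
  loose <- consensus_signature(recs, "M0", alpha = 0.2)$molecules
  expect_true(all(full %in% loose))
})

test_that("rho matrix masks insignificant entries", {
  recs <- data.frame(molecule = c("A", "B"), cell_type = "M0",
                     layer = "transcript", method = "fractions",
                     rho = c(0.9, 0.8), p = c(0.01, 0.5), n = 10)
  m <- rho_matrix(recs)
  expect_equal(m["A", "M0"], 0.9)
  expect_true(is.na(m["B", "M0"]))
})

test_that("disease score detects the coupled target cell type across seeds", {
  # analytic power at n = 32 and effective rho ~0.59 is about 0.9; the
  # assertion leaves room for binomial noise around it
  hits <- sapply(1:20, function(s) {
    coh <- simulate_cohort(generator_config(seed = s))
    fr <- fit_fractions(coh$transcript, coh$reference)
    di <- correlate_with_index(
      stats::setNames(coh$metadata$disease_score, coh$metadata$sample_id), fr)
    row <- di[di$cell_type == coh$truth$target_cell_type, ]
    row$p < 0.05 && row$rho > 0
  })
  expect_gte(mean(hits), 0.75)
})
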