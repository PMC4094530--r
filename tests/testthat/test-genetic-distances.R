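toy_table <- function() {
  # taxon A: {0,1,2} at L1 (freq 0.5); fixed alt at L2
  # taxon B: all 2 at L1 (freq 1); fixed ref at L2
  genotype_table(rbind(c(0, 2), c(1, 2), c(2, 2),
                       c(2, 0), c(2, 0), c(2, 0)),
                 rep(c("A", "B"), each = 3), c("L1", "L2"))
}

test_that("allele frequencies match a direct counting oracle", {
  tab <- toy_table()
  fr <- allele_frequencies(tab)
  expect_equal(fr$freqs["A", ], c(L1 = 0.5, L2 = 1))
  expect_equal(fr$freqs["B", ], c(L1 = 1, L2 = 0))
  expect_equal(unname(fr$sample_sizes["A", ]), c(6L, 6L))

  set.seed(21)
  g <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6)
  g[1, ] <- 0:2 %% 3  # ensure taxon X has data everywhere
  g[6, ] <- 2
  tab2 <- genotype_table(g, rep(c("X", "Y"), each = 5))
  fr2 <- allele_frequencies(tab2)
  for (tx in c("X", "Y")) {
    for (l in 1:6) {
      col <- g[tab2$taxon == tx, l]
      expect_equal(fr2$freqs[tx, l],
                   sum(col, na.rm = TRUE) / (2 * sum(!is.na(col))))
    }
  }
  g[1:5, 2] <- NA
  expect_error(allele_frequencies(genotype_table(g, tab2$taxon)),
               "all genotypes missing")
})

test_that("Nei standard distance reproduces the hand-evaluated closed form", {
  # single locus, A fixed alt (p = 1), B at p = 0.5:
  # J_A = 1, J_B = 0.5, J_AB = 0.5 -> D = -ln(0.5 / sqrt(0.5)) = 0.346574
  tab <- genotype_table(rbind(2, 2, 2, 0, 1, 2), rep(c("A", "B"), each = 3))
  fr <- allele_frequencies(tab)
  expect_equal(nei_standard_distance(fr, "A", "B"), 0.3465736, tolerance = 1e-6)
  # identical profiles -> 0
  tab0 <- genotype_table(rbind(c(0, 2), c(2, 0), c(0, 2), c(2, 0)),
                         rep(c("A", "B"), each = 2))
  fr0 <- allele_frequencies(tab0)
  expect_equal(nei_standard_distance(fr0, "A", "B"), 0)
  # alternately fixed -> J_AB = 0 -> infinite-distance flag
  tabf <- genotype_table(rbind(2, 2, 0, 0), rep(c("A", "B"), each = 2))
  expect_identical(nei_standard_distance(allele_frequencies(tabf), "A", "B"),
                   Inf)
  # D_A variant bounded in [0, 1]
  expect_equal(nei_standard_distance(allele_frequencies(tabf), "A", "B",
                                     variant = "da"), 1)
})

test_that("chord distance reproduces the alternately fixed hand value and is
           symmetric", {
  tabf <- genotype_table(rbind(2, 2, 0, 0), rep(c("A", "B"), each = 2))
  fr <- allele_frequencies(tabf)
  expect_equal(chord_distance(fr, "A", "B"), (2 / pi) * sqrt(2),
               tolerance = 1e-6)
  expect_equal(chord_distance(fr, "A", "B"), 0.900316, tolerance = 1e-6)
  tab0 <- genotype_table(rbind(c(0, 2), c(2, 0), c(0, 2), c(2, 0)),
                         rep(c("A", "B"), each = 2))
  expect_equal(chord_distance(allele_frequencies(tab0), "A", "B"), 0)
  set.seed(3)
  g <- matrix(sample(0:2, 80, replace = TRUE), 10, 8)
  tabr <- genotype_table(g, rep(c("A", "B"), each = 5))
  frr <- allele_frequencies(tabr)
  expect_equal(chord_distance(frr, "A", "B"), chord_distance(frr, "B", "A"))
})

test_that("Hudson Fst hits its fixed points and agrees with the
           frequency-level formula on pseudo-counts", {
  g <- matrix(sample(0:2, 40, replace = TRUE), 10, 4)
  tab <- genotype_table(rbind(g[1:5, ], g[1:5, ]), rep(c("A", "B"), each = 5))
  expect_equal(fst_pairwise(tab, "A", "B"), 0)  # identical columns, post-clip
  tabx <- genotype_table(rbind(matrix(0, 5, 4), matrix(2, 5, 4)),
                         rep(c("A", "B"), each = 5))
  expect_equal(fst_pairwise(tabx, "A", "B"), 1)
  expect_error(fst_pairwise(
    genotype_table(rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
                   rep(c("A", "B"), each = 2)), "A", "B"),
    "no usable")
  # estimator with huge samples converges to the frequency-level formula
  set.seed(5)
  p1 <- runif(200, 0.05, 0.95); p2 <- runif(200, 0.05, 0.95)
  n <- 3000
  g1 <- sapply(p1, function(p) rbinom(n, 2, p))
  g2 <- sapply(p2, function(p) rbinom(n, 2, p))
  tabl <- genotype_table(rbind(g1, g2), rep(c("A", "B"), each = n))
  expect_equal(fst_pairwise(tabl, "A", "B"),
               shaftshape:::fst_from_freqs(p1, p2), tolerance = 0.02)
})

test_that("Balding-Nichols simulation recovers the target Fst within 0.03", {
  K <- 4
  fst <- matrix(0.2, K, K); diag(fst) <- 0
  sc <- scenario_config(taxa = letters[1:K], fst_matrix = fst,
                        n_loci = 1000, n_geno_per_taxon = 30, seed = 19)
  tab <- make_genotypes(sc)
  fr_true <- attr(tab, "true_freqs")
  pairs <- combn(letters[1:K], 2)
  est <- apply(pairs, 2, function(pr) fst_pairwise(tab, pr[1], pr[2]))
  expected <- apply(pairs, 2, function(pr) {
    shaftshape:::fst_from_freqs(fr_true[pr[1], ], fr_true[pr[2], ])
  })
  expect_lt(max(abs(est - expected)), 0.03)
  expect_lt(abs(mean(est) - 0.2), 0.03)
})

test_that("Patterson PC distances are symmetric, zero-diagonal and collapse
           for identical rows", {
  g <- matrix(rep(c(0, 1, 2, 1), each = 6), 4, 6, byrow = TRUE)
  g <- rbind(g, g)  # duplicate rows but polymorphic columns across taxa
  tab <- genotype_table(g, rep(c("A", "B"), 4))
  d <- patterson_pc_distance(tab, k = 1)
  expect_equal(unname(d$values), matrix(0, 2, 2), tolerance = 1e-9)
  sc <- scenario_config(seed = 23, n_loci = 300, n_geno_per_taxon = 8)
  tab2 <- make_genotypes(sc)
  d2 <- patterson_pc_distance(tab2)
  expect_equal(d2$values, t(d2$values))
  expect_equal(unname(diag(d2$values)), rep(0, 4))
  expect_error(patterson_pc_distance(tab2, k = 100), "k exceeds")
})

test_that("Patterson PC distances rank-match the generator targets in most
           replicates", {
  hits <- vapply(1:20, function(r) {
    sc <- scenario_config(seed = 4000 + r, n_loci = 800,
                          n_geno_per_taxon = 15)
    d <- patterson_pc_distance(make_genotypes(sc))
    identical(order(d$values[upper.tri(d$values)]),
              order(sc$fst_matrix[upper.tri(sc$fst_matrix)]))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("all four F matrices are produced, deterministic and mutually
           concordant on a well-separated drift scenario", {
  sc <- scenario_config(seed = 29, n_loci = 800, n_geno_per_taxon = 20)
  tab <- make_genotypes(sc)
  Fm <- build_F_matrices(tab)
  expect_named(Fm, c("F_nei", "F_chord", "F_fst", "F_ppc"))
  for (m in Fm) {
    expect_equal(m$values, t(m$values))
    expect_true(all(m$values >= 0))
  }
  # mutual Mantel concordance (pairwise r over the 6 distances)
  for (a in names(Fm)) {
    for (b in names(Fm)) {
      if (a < b) {
        expect_gt(mantel_test(Fm[[a]], Fm[[b]])$r, 0.9)
      }
    }
  }
  Fm2 <- build_F_matrices(make_genotypes(sc))
  expect_identical(Fm$F_fst$values, Fm2$F_fst$values)
  # 2-taxon table gives 2x2 matrices
  sub <- tab$taxon %in% sc$taxa[1:2]
  tab2 <- genotype_table(tab$genotypes[sub, ], tab$taxon[sub])
  expect_equal(dim(build_F_matrices(tab2)$F_nei$values), c(2, 2))
})

test_that("distance matrix CSV round trip preserves values and metadata", {
  sc <- scenario_config(seed = 31, n_loci = 100, n_geno_per_taxon = 5)
  d <- patterson_pc_distance(make_genotypes(sc))
  f <- file.path(withr::local_tempdir(), "d.csv")
  write_distance_csv(d, f)
  d2 <- read_distance_csv(f)
  expect_equal(d2$values, d$values, tolerance = 1e-12)
  expect_identical(d2$kind, "F_ppc")
})
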