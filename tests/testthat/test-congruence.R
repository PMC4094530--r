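test_that("PCO embeds a 3-4-5 triangle exactly and satisfies the Gower
           identity", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3
  D[1, 3] <- D[3, 1] <- 4
  D[2, 3] <- D[3, 2] <- 5
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  con <- pco(D, k = 2)
  emb <- as.matrix(dist(con$coordinates))
  expect_equal(unname(emb), unname(D), tolerance = 1e-8)
  expect_equal(colMeans(con$coordinates), c(0, 0), tolerance = 1e-10)
  # Gower: sum of positive eigenvalues = sum of squared distances / n
  expect_equal(sum(con$eigenvalues[con$eigenvalues > 0]),
               sum(D[upper.tri(D)]^2) / 3, tolerance = 1e-8)
  # agreement with classical scaling in stats
  cs <- cmdscale(D, k = 2, eig = TRUE)
  expect_equal(abs(con$coordinates), abs(cs$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate all-zero distances
  expect_error(pco(matrix(0, 3, 3)), "eigenvalues")
})

test_that("PCO reports negative eigenvalues of non-Euclidean input", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 3  # violates the triangle inequality
  rownames(D) <- colnames(D) <- letters[1:4]
  con <- pco(D, k = 3)
  expect_true(length(con$negative_eigenvalues) > 0)
  expect_lt(ncol(con$coordinates), 4)
})

test_that("Procrustes superimposition recovers similarity transforms and is
           symmetric in its arguments", {
  set.seed(17)
  X <- matrix(rnorm(8), 4, 2)
  rownames(X) <- letters[1:4]
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Y <- 2.4 * X %*% R + rep(c(3, -1), each = 4)
  rownames(Y) <- letters[1:4]
  pr <- procrustes_superimpose(X, Y)
  expect_lt(pr$procrustes_d, 1e-10)
  # symmetric residual
  Y2 <- X + matrix(rnorm(8, sd = 0.3), 4, 2)
  rownames(Y2) <- letters[1:4]
  expect_equal(procrustes_superimpose(X, Y2)$procrustes_d,
               procrustes_superimpose(Y2, X)$procrustes_d,
               tolerance = 1e-10)
  expect_error(procrustes_superimpose(X, Y2[c(2, 1, 3, 4), ][1:3, ]),
               "labels")
})

test_that("Procrustes residual matches a rotation-grid + scale-scan oracle", {
  set.seed(19)
  for (rep in 1:3) {
    X <- matrix(rnorm(8), 4, 2); rownames(X) <- letters[1:4]
    Y <- matrix(rnorm(8), 4, 2); rownames(Y) <- letters[1:4]
    pr <- procrustes_superimpose(X, Y)
    # oracle on the symmetric normalized configurations
    norm_cfg <- function(M) {
      M <- sweep(M, 2, colMeans(M))
      M / sqrt(sum(M^2))
    }
    Xn <- norm_cfg(X); Yn <- norm_cfg(Y)
    best <- Inf
    for (ang in seq(0, 2 * pi, length.out = 7200)) {
      R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
      for (Rr in list(R, R %*% diag(c(1, -1)))) {
        Yr <- Yn %*% Rr
        s <- sum(Xn * Yr)  # optimal scale in closed form given rotation
        best <- min(best, sum((Xn - s * Yr)^2))
      }
    }
    expect_equal(pr$procrustes_d, best, tolerance = 1e-4)
  }
})

test_that("Mantel statistic is exact under affine maps and its exhaustive p
           matches an independent enumeration", {
  set.seed(23)
  D1 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  rownames(D1) <- colnames(D1) <- letters[1:4]
  expect_equal(mantel_test(D1, D1)$r, 1)
  D2 <- 3 * D1 + (1 - diag(4))  # affine map of the off-diagonals
  dimnames(D2) <- dimnames(D1)
  expect_equal(mantel_test(D1, D2)$r, 1)
  D3 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(D3) <- dimnames(D1)
  res <- mantel_test(D1, D3)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 24)
  v1 <- D1[upper.tri(D1)]
  rr <- vapply(perms_oracle(1:4), function(pm) {
    M <- D3[pm, pm]
    cor(v1, M[upper.tri(M)])
  }, 0)
  expect_equal(res$p, mean(rr >= res$r - 1e-12))
  # sampling path agrees with vegan on a larger problem
  set.seed(29)
  E1 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  E2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  ours <- mantel_test(E1, E2, n_perm = 999, seed = 5, method = "sample")
  veg <- vegan::mantel(E1, E2, permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - veg$signif), 0.08)
  expect_error(mantel_test(1 - diag(4), 1 - diag(4)), "constant")
})

test_that("element-wise permutation scheme is available and flagged", {
  set.seed(31)
  D1 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  res <- mantel_test(D1, D2, scheme = "element", n_perm = 199, seed = 2)
  expect_identical(res$scheme, "element")
  expect_false(res$exhaustive)
  expect_gt(res$p, 0)
})

test_that("allele-sharing distance counts shared alleles", {
  tab <- genotype_table(rbind(c(0, 0), c(2, 0), c(1, 2)),
                        c("A", "B", "B"))
  D <- allele_sharing_dist(tab)
  expect_equal(D[1, 2], 0.5)   # loci diffs |0-2| and |0-0| -> (1 + 0)/2
  expect_equal(D[1, 3], 0.75)  # |0-1|/2 + |0-2|/2 -> (0.5 + 1)/2
  expect_equal(D[2, 3], 0.75)
  expect_equal(D, t(D))
})

test_that("resampling correlation is exact for proportional block
           distances and normalizes by the medians", {
  # within-taxon degenerate clouds at 0, 0.5, 1.5 -> pheno pair distances
  # (A,B) 0.5, (A,C) 1.5, (B,C) 1.0; genotypes built so allele-sharing
  # distances are 1/6, 3/6, 2/6: exactly proportional
  scores <- matrix(rep(c(0, 0.5, 1.5), each = 3), 9, 1)
  space <- fake_space(scores, rep(c("A", "B", "C"), each = 3), "m2")
  g <- rbind(matrix(rep(c(0, 0, 0, 0, 0, 0), 2), 2, 6, byrow = TRUE),
             matrix(rep(c(2, 0, 0, 0, 0, 0), 2), 2, 6, byrow = TRUE),
             matrix(rep(c(2, 0, 2, 2, 0, 0), 2), 2, 6, byrow = TRUE))
  geno <- genotype_table(g, rep(c("A", "B", "C"), each = 2))
  rs <- resampling_correlation(space, "m2", geno, n_draws = 300, seed = 3,
                               n_perm = 99, n_components = 1)
  expect_equal(rs$R2, 1, tolerance = 1e-12)
  expect_equal(median(rs$pheno_dist), 1)
  expect_equal(median(rs$geno_dist), 1)
  # invariance to rescaling either distance set
  space2 <- fake_space(scores * 7, rep(c("A", "B", "C"), each = 3), "m2")
  rs2 <- resampling_correlation(space2, "m2", geno, n_draws = 300, seed = 3,
                                n_perm = 99, n_components = 1)
  expect_equal(rs2$pheno_dist, rs$pheno_dist, tolerance = 1e-12)
  expect_equal(rs2$R2, rs$R2)
})

test_that("resampling p-values are roughly uniform when taxon labels carry
           no structure", {
  set.seed(41)
  ps <- vapply(1:40, function(r) {
    scores <- matrix(rnorm(30), 30, 1)
    space <- fake_space(scores, sample(rep(c("A", "B", "C"), 10)), "m2")
    g <- matrix(rbinom(30 * 40, 2, 0.4), 30, 40)
    geno <- genotype_table(g, sample(rep(c("A", "B", "C"), 10)))
    resampling_correlation(space, "m2", geno, n_draws = 200, seed = r,
                           n_perm = 99, n_components = 1)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_gt(mean(ps), 0.25)
})

test_that("stage-wise report carries complete fields and reproducible
           seeds", {
  sc <- scenario_preset("neutral_congruent", n_pheno_per_cell = 3,
                        mesh_n_z = 20, mesh_n_theta = 36,
                        n_geno_per_taxon = 8, n_loci = 300, seed = 43)
  space <- quick_space(make_phenotype_sample(sc), n_levels = 16,
                       n_angles = 36)
  geno <- make_genotypes(sc)
  Fd <- patterson_pc_distance(geno)
  reps <- stagewise_report(Fd, space, geno, n_perm = 99, n_draws = 200,
                           seed = 11)
  expect_named(reps, sc$stages)
  for (rp in reps) {
    expect_s3_class(rp, "congruence_report")
    expect_true(all(c("mantel_r", "mantel_p", "mantel_q_r", "mantel_q_p",
                      "resample_R2", "resample_p", "procrustes_d",
                      "n_perm", "n_draws", "seeds") %in% names(rp)))
    expect_true(rp$mantel_r >= -1 && rp$mantel_r <= 1)
    expect_true(rp$mantel_p > 0 && rp$mantel_p <= 1)
    expect_gte(rp$procrustes_d, 0)
    expect_s3_class(rp$M, "distance_matrix")
    expect_s3_class(rp$Q, "distance_matrix")
  }
  reps2 <- stagewise_report(Fd, space, geno, n_perm = 99, n_draws = 200,
                            seed = 11)
  expect_identical(congruence_table(reps), congruence_table(reps2))
})

test_that("neutral-congruent scenarios give significantly positive F-M
           Mantel correlation in most replicates", {
  ps <- vapply(1:50, function(r) {
    sc <- scenario_preset("neutral_congruent", n_pheno_per_cell = 6,
                          mesh_n_z = 32, mesh_n_theta = 48,
                          seed = 1300 + r)
    space <- quick_space(make_phenotype_sample(sc, stages = "m2"),
                         n_levels = 24, n_angles = 48)
    geno <- make_genotypes(sc)
    mantel_test(patterson_pc_distance(geno),
                pheno_distance_matrix(space, "m2"))$p
  }, 0)
  expect_gte(mean(ps < 0.05), 0.9)
})
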