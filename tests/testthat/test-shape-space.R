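# Build a small morphospace from hand-made maps with a known single
# deformation mode.
map_from_values <- function(v, taxon = "A", stage = "m2", id = "x") {
  structure(list(values = v / median(v), n_levels = nrow(v),
                 n_angles = ncol(v), normalized = TRUE,
                 diaphyseal_length = 100, median_radius = median(v),
                 window = 5, n_clamped = 0L, taxon = taxon, stage = stage,
                 specimen_id = id),
            class = "morphometric_map")
}

test_that("PCA satisfies its reconstruction and variance identities", {
  set.seed(42)
  base <- matrix(10, 8, 12)
  mode <- matrix(sin(seq_len(96)), 8, 12)
  amps <- rnorm(6)
  maps <- lapply(seq_along(amps), function(i) {
    map_from_values(base + amps[i] * mode, id = paste0("s", i))
  })
  space <- fit_shape_pca(maps)
  # single deformation mode: PC1 carries all variance
  expect_equal(space$explained_variance_ratio[1], 1, tolerance = 1e-9)
  # orthonormal components, centered scores
  G <- space$components %*% t(space$components)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-8)
  expect_equal(colMeans(space$scores), rep(0, ncol(space$scores)),
               tolerance = 1e-10)

  # reconstruction identity on noisy maps
  maps2 <- lapply(1:7, function(i) {
    map_from_values(base + matrix(rnorm(96, sd = 0.3), 8, 12),
                    id = paste0("n", i))
  })
  sp2 <- fit_shape_pca(maps2)
  X <- t(sapply(maps2, function(m) as.vector(m$values)))
  Xhat <- sweep(sp2$scores %*% sp2$components, 2, sp2$grand_mean, `+`)
  expect_lt(max(abs(X - Xhat)), 1e-8)
  # total variance preserved (independent direct computation)
  total <- sum(apply(X, 2, function(col) sum((col - mean(col))^2)))
  expect_equal(sum(sp2$scores^2), total, tolerance = 1e-8)
  expect_error(fit_shape_pca(maps2[1:2]), "at least 3")
})

test_that("map_from_scores inverts the PCA mapping", {
  set.seed(1)
  maps <- lapply(1:6, function(i) {
    map_from_values(matrix(10 + rnorm(96, sd = 0.5), 8, 12),
                    id = paste0("s", i))
  })
  space <- fit_shape_pca(maps)
  rec <- map_from_scores(space, space$scores[3, ])
  expect_equal(rec$values, maps[[3]]$values, tolerance = 1e-8)
})

test_that("stage and taxon means are cell averages, order invariant, and
           complain about empty cells", {
  sc <- matrix(c(0, 0, 2, 2, 4, 6), 6, 2)
  lab <- data.frame(taxon = c("A", "A", "A", "B", "B", "B"),
                    stage = c("m2", "m2", "M1", "m2", "m2", "M1"))
  space <- fake_space(sc, lab$taxon, lab$stage)
  sm <- stage_taxon_means(space)
  expect_equal(sm$means["A|m2", ], colMeans(sc[1:2, ]))
  expect_equal(sm$means["B|M1", ], sc[6, ])
  perm <- sample(6)
  sm2 <- stage_taxon_means(fake_space(sc[perm, ], lab$taxon[perm],
                                      lab$stage[perm]))
  expect_equal(sm2$means[rownames(sm$means), ], sm$means)
  bad <- fake_space(sc[-6, ], lab$taxon[-6], lab$stage[-6])
  expect_error(stage_taxon_means(bad), "B\\|M1")
})

test_that("mean-shape permutation test matches exhaustive enumeration and
           detects separation", {
  set.seed(7)
  xa <- matrix(rnorm(6, sd = 0.1), 3, 2)
  xb <- matrix(rnorm(6, sd = 0.1), 3, 2) + 5
  space <- fake_space(rbind(xa, xb), rep(c("A", "B"), each = 3), "m2")
  res <- mean_shape_permutation_test(space, "m2", "A", "B", seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_perm, 20)
  # independent exhaustive oracle over all 20 splits
  S <- rbind(xa, xb)
  obs <- sqrt(sum((colMeans(xa) - colMeans(xb))^2))
  splits <- combn(6, 3)
  stats <- apply(splits, 2, function(ix) {
    sqrt(sum((colMeans(S[ix, , drop = FALSE]) -
                colMeans(S[-ix, , drop = FALSE]))^2))
  })
  expect_equal(res$p, mean(stats >= obs - 1e-12))
  # clear separation: only the two labelings recovering the split win
  expect_equal(res$p, 2 / 20)
  # identical point clouds: observed distance 0, every split at least ties
  sp0 <- fake_space(rbind(xa, xa), rep(c("A", "B"), each = 3), "m2")
  expect_equal(mean_shape_permutation_test(sp0, "m2", "A", "B")$p, 1)
})

test_that("trajectories accumulate segment lengths with unit direction", {
  tr <- build_trajectory(cbind(0:3, 0))
  expect_equal(tr$length, 3)
  expect_equal(tr$direction, c(1, 0))
  tr2 <- build_trajectory(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(tr2$length, 2)
  expect_equal(tr2$direction, c(1, 1) / sqrt(2))
  # triangle inequality on random trajectories
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rnorm(12), 4, 3)
    tr <- build_trajectory(m)
    expect_gte(tr$length, sqrt(sum((m[4, ] - m[1, ])^2)) - 1e-12)
  }
})

test_that("trajectory comparison separates rate differences from direction
           differences", {
  # same direction, taxon B progresses twice as fast; noise small
  stages <- c("m2", "M1", "M2", "M3")
  n <- 8
  mk <- function(rate, taxon, seed) {
    set.seed(seed)
    do.call(rbind, lapply(0:3, function(i) {
      cbind(rate * i + rnorm(n, sd = 0.15), rnorm(n, sd = 0.15),
            rnorm(n, sd = 0.15))
    }))
  }
  scores <- rbind(mk(1, "A", 1), mk(2, "B", 2))
  space <- fake_space(scores, rep(c("A", "B"), each = 4 * n),
                      rep(rep(stages, each = n), 2))
  res <- trajectory_comparison_test(space, "A", "B", n_perm = 299, seed = 3,
                                    n_components = 3)
  expect_gt(res$angle_p, 0.05)   # shared direction
  expect_lt(res$length_p, 0.05)  # rate doubled
  expect_equal(res$lengthB / res$lengthA, 2, tolerance = 0.2)
})

test_that("squared-change parsimony solves the star tree and matches the
           brute-force optimizer on random trees", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  root <- squared_change_parsimony(star, c(a = 1, b = 2, c = 3))
  expect_equal(unname(root[1, 1]), 2)
  # all tips equal -> all internal nodes equal
  tree4 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.7,d:2.2):0.8);")
  anc <- squared_change_parsimony(tree4, c(a = 5, b = 5, c = 5, d = 5))
  expect_equal(unname(anc[, 1]), rep(5, 3))

  set.seed(11)
  for (i in 1:20) {
    tr <- ape::rtree(4)
    tips <- stats::setNames(rnorm(4), tr$tip.label)
    fit <- squared_change_parsimony(tr, tips)
    obj <- function(v) {
      states <- c(tips[tr$tip.label], v)
      sum((states[tr$edge[, 1]] - states[tr$edge[, 2]])^2 / tr$edge.length)
    }
    opt <- optim(rep(mean(tips), tr$Nnode), obj, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_lt(max(abs(fit[, 1] - opt$par)), 1e-6)
  }
  bad <- tree4
  bad$edge.length[2] <- 0
  expect_error(squared_change_parsimony(bad, c(a = 1, b = 2, c = 3, d = 4)),
               "positive")
})

test_that("LCA reconstruction respects symmetry and identical-trajectory
           degeneracy", {
  stages <- c("m2", "M1")
  taxa <- c("a", "b", "c", "d")
  mk_means <- function(offsets) {
    means <- do.call(rbind, lapply(seq_along(taxa), function(i) {
      rbind(c(offsets[i], 0), c(offsets[i], 1))
    }))
    rownames(means) <- as.vector(t(outer(taxa, stages, paste, sep = "|")))
    structure(list(taxa = taxa, stages = stages, means = means,
                   n = rep(1, 8)), class = "stage_means")
  }
  # identical taxa: LCA trajectory identical to the shared one
  sm <- mk_means(rep(2, 4))
  star4 <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  lca <- lca_trajectory(star4, sm)
  expect_equal(unname(lca$stage_scores),
               matrix(c(2, 2, 0, 1), 2), tolerance = 1e-10)
  expect_equal(lca$trajectory$length, 1)
  # star tree, equal branches: LCA stage mean = arithmetic mean of taxa
  sm2 <- mk_means(c(0, 1, 2, 9))
  lca2 <- lca_trajectory(star4, sm2)
  expect_equal(unname(lca2$stage_scores[, 1]), rep(3, 2), tolerance = 1e-10)
})

test_that("LCA trajectory length falls within the tip range under the
           neutral preset", {
  ok <- vapply(1:10, function(r) {
    sc <- scenario_preset("neutral_congruent", n_pheno_per_cell = 3,
                          mesh_n_z = 24, mesh_n_theta = 40, seed = 8000 + r)
    space <- quick_space(make_phenotype_sample(sc), n_levels = 20,
                         n_angles = 40)
    sm <- stage_taxon_means(space)
    lca <- lca_trajectory(default_pan_tree(sm$taxa), sm)
    lens <- vapply(sm$taxa, function(tx) build_trajectory(sm, tx)$length, 0)
    lca$trajectory$length >= min(lens) && lca$trajectory$length <= max(lens)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
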