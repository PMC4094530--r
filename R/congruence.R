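#' Principal coordinates (classical scaling) of a distance matrix
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for the top `k` positive eigenvalues
#' (the "taxon constellation"). Negative eigenvalues (non-Euclidean input)
#' are reported in the metadata and their axes dropped. Axis signs follow
#' the same convention as the shape PCA (largest-magnitude coordinate
#' positive).
#'
#' @param dm a `distance_matrix` (or plain symmetric matrix).
#' @param k number of coordinate axes (at most taxa - 1).
#' @return Object of class `taxon_constellation`: `labels`, `coordinates`
#'   (taxa x k, column means 0), `eigenvalues` (all, non-increasing),
#'   `negative_eigenvalues`, `source_kind`.
#' @export
pco <- function(dm, k = NULL) {
  D <- if (inherits(dm, "distance_matrix")) dm$values else as.matrix(dm)
  kind <- if (inherits(dm, "distance_matrix")) dm$kind else NA_character_
  n <- nrow(D)
  k <- k %||% (n - 1L)
  if (k > n - 1) stop("k must be <= taxa - 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  if (!any(pos)) stop("all PCO eigenvalues are <= 0")
  kk <- min(k, sum(pos))
  coords <- eg$vectors[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(kk)]), kk, kk)
  for (i in seq_len(kk)) {
    j <- which.max(abs(coords[, i]))
    if (coords[j, i] < 0) coords[, i] <- -coords[, i]
  }
  rownames(coords) <- rownames(D)
  out <- list(labels = rownames(D), coordinates = coords,
              eigenvalues = eg$values,
              negative_eigenvalues = eg$values[eg$values < 0],
              source_kind = kind)
  class(out) <- "taxon_constellation"
  out
}

#' Procrustes superimposition of two taxon constellations
#'
#' Least-squares superimposition (translation, rotation/reflection and, by
#' default, scaling) of two label-matched constellations, in the symmetric
#' normalized form: both configurations are centered and scaled to unit
#' centroid size, so the residual does not depend on which constellation is
#' the reference. Delegates to [vegan::procrustes()].
#'
#' @param X,Y `taxon_constellation`s (or plain coordinate matrices with
#'   rownames) over the same labels; the narrower is padded with zero
#'   columns.
#' @param allow_scaling optimize a scale factor (default TRUE).
#' @return List: `X`, `Yrot` (aligned coordinates), `procrustes_d`
#'   (symmetric normalized residual sum of squares), `rotation`, `scale`.
#' @export
procrustes_superimpose <- function(X, Y, allow_scaling = TRUE) {
  cx <- if (inherits(X, "taxon_constellation")) X$coordinates else as.matrix(X)
  cy <- if (inherits(Y, "taxon_constellation")) Y$coordinates else as.matrix(Y)
  if (is.null(rownames(cx)) || is.null(rownames(cy)) ||
      !setequal(rownames(cx), rownames(cy))) {
    stop("constellations must carry matching labels")
  }
  cy <- cy[rownames(cx), , drop = FALSE]
  k <- max(ncol(cx), ncol(cy))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  cx <- pad(cx); cy <- pad(cy)
  pr <- vegan::procrustes(cx, cy, scale = allow_scaling, symmetric = TRUE)
  list(X = pr$X, Yrot = pr$Yrot, procrustes_d = pr$ss,
       rotation = pr$rotation, scale = pr$scale)
}

#' Mantel test between two labeled distance matrices
#'
#' Statistic: Pearson correlation of the corresponding upper-triangle
#' entries. Null: simultaneous row/column relabeling of the second matrix;
#' with few taxa (factorial at most `max_exact`) all relabelings are
#' enumerated and the p-value is the exact proportion of relabelings
#' (identity included) with `r` at least the observed; otherwise `n_perm`
#' random relabelings give `p = (b + 1) / (n_perm + 1)`. One-sided
#' (positive association), matching the directional hypothesis of
#' genotype-phenotype congruence. `scheme = "element"` permutes the
#' off-diagonal elements independently instead (not a valid matrix
#' permutation test under label exchangeability; provided for comparison
#' and flagged in the output).
#'
#' @param d1,d2 `distance_matrix` objects (or symmetric matrices) over the
#'   same labels.
#' @param n_perm random permutations when sampling (>= 99).
#' @param seed RNG seed.
#' @param scheme `"label"` (default) or `"element"`.
#' @param method `"auto"` (exhaustive when possible), `"exhaustive"`, or
#'   `"sample"`.
#' @param max_exact largest factorial enumerated under `"auto"`.
#' @return List: `r`, `p`, `scheme`, `exhaustive`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        scheme = c("label", "element"),
                        method = c("auto", "exhaustive", "sample"),
                        max_exact = 5040) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  m1 <- if (inherits(d1, "distance_matrix")) d1$values else as.matrix(d1)
  m2 <- if (inherits(d2, "distance_matrix")) d2$values else as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) stop("label mismatch")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  v1 <- upper_entries(m1)
  if (stats::sd(v1) == 0 || stats::sd(upper_entries(m2)) == 0) {
    stop("constant off-diagonal entries: Mantel r undefined")
  }
  r_obs <- stats::cor(v1, upper_entries(m2))
  if (scheme == "element") {
    v2 <- upper_entries(m2)
    perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stats::cor(v1, sample(v2))
    }, 0))
    p <- (sum(perm_r >= r_obs - 1e-12) + 1) / (n_perm + 1)
    return(list(r = r_obs, p = p, scheme = scheme, exhaustive = FALSE,
                n_perm = n_perm))
  }
  exhaustive <- method == "exhaustive" ||
    (method == "auto" && factorial(n) <= max_exact)
  if (exhaustive) {
    perms <- all_permutations(n)
    perm_r <- apply(perms, 1, function(pm) {
      stats::cor(v1, upper_entries(m2[pm, pm]))
    })
    p <- mean(perm_r >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, scheme = scheme, exhaustive = TRUE,
                n_perm = nrow(perms)))
  }
  if (n_perm < 99) stop("n_perm must be >= 99")
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(n)
    stats::cor(v1, upper_entries(m2[pm, pm]))
  }, 0))
  p <- (sum(perm_r >= r_obs - 1e-12) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, scheme = scheme, exhaustive = FALSE, n_perm = n_perm)
}

#' Allele-sharing distance between individuals
#'
#' `1 - mean(shared allele proportion)` over non-missing loci; for
#' genotypes `a, b` in 0/1/2 the shared-allele proportion at a locus is
#' `1 - |a - b| / 2`.
#'
#' @param table a `genotype_table`.
#' @return Symmetric individuals x individuals distance matrix.
#' @export
allele_sharing_dist <- function(table) {
  G <- table$genotypes
  n <- nrow(G)
  D <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(n - 1)) {
    gi <- G[i, ]
    d <- abs(sweep(G[(i + 1):n, , drop = FALSE], 2, gi)) / 2
    D[i, (i + 1):n] <- D[(i + 1):n, i] <- rowMeans(d, na.rm = TRUE)
  }
  D
}

#' Individual-level resampling correlation of phenotypic and genotypic
#' distances
#'
#' Each draw picks an unordered cross-taxon pair, one phenotyped individual
#' from each taxon (Euclidean distance of morphospace scores at the given
#' stage) and, independently, one genotyped individual from each taxon
#' (allele-sharing distance). Both distance samples are divided by their
#' respective medians; `R2` is the squared Pearson correlation over draws.
#' The p-value permutes the genotype-side taxon labels and repeats the
#' procedure with the same pair sequence.
#'
#' @param space a `shape_space`.
#' @param stage stage label.
#' @param geno a `genotype_table` sharing >= 2 taxa with the phenotypes.
#' @param n_draws resampled distance pairs (default 1000).
#' @param seed RNG seed.
#' @param n_perm label permutations for the p-value (default 999).
#' @param n_components morphospace components (default: 90\% variance set).
#' @return List: `R2`, `r`, `p`, `n_draws`, `n_perm`, `seed`, plus the
#'   normalized distance samples (`pheno_dist`, `geno_dist`).
#' @export
resampling_correlation <- function(space, stage, geno, n_draws = 1000,
                                   seed = 1, n_perm = 999,
                                   n_components = NULL) {
  k <- n_components %||% default_components(space)
  lab <- space$labels
  taxa <- intersect(unique(lab$taxon), unique(geno$taxon))
  if (length(taxa) < 2) stop("need >= 2 taxa shared between datasets")
  sel <- lab$stage == stage & lab$taxon %in% taxa
  if (!any(sel)) stop("no specimens at stage ", stage)
  S <- space$scores[sel, seq_len(k), drop = FALSE]
  ptax <- lab$taxon[sel]
  gD <- allele_sharing_dist(geno)
  gtax <- geno$taxon
  pairs <- utils::combn(taxa, 2)
  with_seed(seed, {
    pair_idx <- sample.int(ncol(pairs), n_draws, replace = TRUE)
    pa <- pairs[1, pair_idx]; pb <- pairs[2, pair_idx]
    pick <- function(tlab, pool) {
      # one individual index per draw, sampled per-taxon for speed
      out <- integer(length(tlab))
      for (tx in names(pool)) {
        w <- which(tlab == tx)
        if (length(w)) {
          out[w] <- pool[[tx]][sample.int(length(pool[[tx]]), length(w),
                                          replace = TRUE)]
        }
      }
      out
    }
    ppool <- lapply(stats::setNames(taxa, taxa), function(tx)
      which(ptax == tx))
    pi1 <- pick(pa, ppool); pi2 <- pick(pb, ppool)
    pd <- sqrt(rowSums((S[pi1, , drop = FALSE] -
                          S[pi2, , drop = FALSE])^2))
    gpool <- lapply(stats::setNames(taxa, taxa), function(tx)
      which(gtax == tx))
    gi1 <- pick(pa, gpool); gi2 <- pick(pb, gpool)
    gd <- gD[cbind(gi1, gi2)]
    med_p <- stats::median(pd); med_g <- stats::median(gd)
    if (med_p <= 0 || med_g <= 0) stop("degenerate distance sample")
    pdn <- pd / med_p; gdn <- gd / med_g
    r_obs <- stats::cor(pdn, gdn)
    if (n_perm == 0) {
      return(list(R2 = r_obs^2, r = r_obs, p = NA_real_, n_draws = n_draws,
                  n_perm = 0, seed = seed, pheno_dist = pdn,
                  geno_dist = gdn))
    }
    perm_r <- vapply(seq_len(n_perm), function(i) {
      gt_perm <- sample(gtax)
      pool <- lapply(stats::setNames(taxa, taxa), function(tx)
        which(gt_perm == tx))
      g1 <- pick(pa, pool); g2 <- pick(pb, pool)
      gdp <- gD[cbind(g1, g2)]
      mg <- stats::median(gdp)
      if (mg <= 0) return(0)
      stats::cor(pdn, gdp / mg)
    }, 0)
    p <- (sum(perm_r >= r_obs - 1e-12) + 1) / (n_perm + 1)
    list(R2 = r_obs^2, r = r_obs, p = p, n_draws = n_draws, n_perm = n_perm,
         seed = seed, pheno_dist = pdn, geno_dist = gdn)
  })
}

#' Stage-wise congruence reports
#'
#' For every stage: the Mantel test of the genotypic matrix `F` against the
#' stage's phenotypic matrix `M` and against its quantitative-genetic
#' matrix `Q`, the individual-level resampling correlation, and the
#' Procrustes distance between the PCO constellations of `F` and `M`.
#'
#' @param F_dm genotypic `distance_matrix` (e.g. the `F_ppc` entry of
#'   [build_F_matrices()]).
#' @param space a `shape_space`.
#' @param geno a `genotype_table`.
#' @param qst a [qst_config()].
#' @param n_perm Mantel/resampling permutations (default 999; the Mantel
#'   null is enumerated exhaustively for few taxa).
#' @param n_draws resampling draws (default 1000).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_components morphospace components for `M` and the resampling
#'   distances (default: 90\% variance set).
#' @param stages stages to analyze (default all, in encounter order).
#' @return List of `congruence_report` objects, one per stage; fields:
#'   `stage`, `mantel_r`, `mantel_p`, `mantel_q_r`, `mantel_q_p`,
#'   `resample_R2`, `resample_p`, `procrustes_d`, `n_perm`, `n_draws`,
#'   `seeds`.
#' @export
stagewise_report <- function(F_dm, space, geno, qst = qst_config(),
                             n_perm = 999, n_draws = 1000, seed = 1,
                             n_components = NULL, stages = NULL) {
  stages <- stages %||% unique(space$labels$stage)
  k <- n_components %||% default_components(space)
  reports <- lapply(seq_along(stages), function(si) {
    s <- stages[si]
    seeds <- c(mantel = child_seed(seed, 100 + si),
               resample = child_seed(seed, 200 + si))
    M <- pheno_distance_matrix(space, s, n_components = k)
    Q <- qst_matrix(space, s, qst)
    mt <- mantel_test(F_dm, M, n_perm = n_perm, seed = seeds[["mantel"]])
    mq <- mantel_test(F_dm, Q, n_perm = n_perm, seed = seeds[["mantel"]])
    rs <- resampling_correlation(space, s, geno, n_draws = n_draws,
                                 seed = seeds[["resample"]], n_perm = n_perm,
                                 n_components = k)
    pr <- procrustes_superimpose(pco(F_dm), pco(M))
    rep <- list(stage = s, mantel_r = mt$r, mantel_p = mt$p,
                mantel_q_r = mq$r, mantel_q_p = mq$p,
                resample_R2 = rs$R2, resample_r = rs$r, resample_p = rs$p,
                procrustes_d = pr$procrustes_d,
                M = M, Q = Q,
                resample_sample = list(pheno = rs$pheno_dist,
                                       geno = rs$geno_dist),
                n_perm = mt$n_perm, n_draws = n_draws, seeds = seeds)
    class(rep) <- "congruence_report"
    rep
  })
  names(reports) <- stages
  reports
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("stage %-4s  F-M Mantel r = %6.3f (p = %.4f)  F-Q r = %6.3f (p = %.4f)  resampling R2 = %.3f (p = %.4f)  Procrustes d = %.4f\n",
              x$stage, x$mantel_r, x$mantel_p, x$mantel_q_r, x$mantel_q_p,
              x$resample_R2, x$resample_p, x$procrustes_d))
  invisible(x)
}

#' Flatten congruence reports to a data.frame (Table-1-style)
#'
#' @param reports list of `congruence_report` ([stagewise_report()]).
#' @return data.frame with one row per stage.
#' @export
congruence_table <- function(reports) {
  do.call(rbind, lapply(reports, function(x) {
    data.frame(stage = x$stage, mantel_r = x$mantel_r, mantel_p = x$mantel_p,
               mantel_q_r = x$mantel_q_r, mantel_q_p = x$mantel_q_p,
               resample_R2 = x$resample_R2, resample_p = x$resample_p,
               procrustes_d = x$procrustes_d, row.names = NULL)
  }))
}
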