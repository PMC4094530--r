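#' Morphospace: PCA over vectorized morphometric maps
#'
#' Centers the vectorized normalized maps by the grand mean and decomposes
#' the variation by singular value decomposition. Component signs follow a
#' deterministic convention (the largest-magnitude loading of each
#' component is positive). At most `min(n - 1, grid size)` components are
#' retained.
#'
#' @param maps list of normalized `morphometric_map`s on identical grids.
#' @param labels data.frame with columns `taxon` and `stage` (and optionally
#'   `specimen_id`), one row per map. Defaults to the labels carried by the
#'   maps themselves.
#' @return An object of class `shape_space`: `grand_mean` (vector),
#'   `components` (k x p orthonormal rows), `explained_variance_ratio`,
#'   `scores` (n x k, zero column means), `labels`, `grid` (c(levels,
#'   angles)), `sdev`.
#' @export
fit_shape_pca <- function(maps, labels = NULL) {
  if (length(maps) < 3) stop("need at least 3 specimens")
  dims <- vapply(maps, function(m) c(m$n_levels, m$n_angles), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("maps have inconsistent grids")
  }
  if (!all(vapply(maps, function(m) isTRUE(m$normalized), logical(1)))) {
    stop("all maps must be normalized (see normalize_map)")
  }
  if (is.null(labels)) {
    labels <- data.frame(
      taxon = vapply(maps, function(m) m$taxon %||% NA_character_, ""),
      stage = vapply(maps, function(m) m$stage %||% NA_character_, ""),
      specimen_id = vapply(maps, function(m) m$specimen_id %||% NA_character_,
                           ""))
  }
  X <- t(vapply(maps, function(m) as.vector(m$values),
                numeric(prod(dims[, 1]))))
  grand_mean <- colMeans(X)
  Xc <- sweep(X, 2, grand_mean)
  k <- min(nrow(X) - 1L, ncol(X))
  sv <- svd(Xc, nu = k, nv = k)
  comp <- t(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  # deterministic sign: largest-magnitude loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) {
      comp[i, ] <- -comp[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  ev <- sv$d^2
  out <- list(grand_mean = grand_mean, components = comp,
              explained_variance_ratio = ev[seq_len(k)] / sum(ev),
              scores = scores, labels = labels,
              grid = c(levels = dims[1, 1], angles = dims[2, 1]),
              sdev = sv$d[seq_len(k)] / sqrt(nrow(X) - 1))
  class(out) <- "shape_space"
  out
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape_space: %d specimens, %d components (grid %d x %d)\n",
              nrow(x$scores), ncol(x$scores), x$grid[1], x$grid[2]))
  cat(sprintf("  PC1+PC2 variance share: %.1f%%\n",
              100 * sum(x$explained_variance_ratio[1:min(2, ncol(x$scores))])))
  invisible(x)
}

#' Number of leading components jointly explaining a variance share
#'
#' @param space a `shape_space`.
#' @param threshold cumulative explained-variance target (default 0.9).
#' @return Integer count of components.
#' @export
default_components <- function(space, threshold = 0.9) {
  max(1L, which(cumsum(space$explained_variance_ratio) >= threshold)[1])
}

#' Mean morphospace position per taxon-by-stage cell
#'
#' @param space a `shape_space`.
#' @return Object of class `stage_means`: `taxa`, `stages` (ordered as first
#'   encountered), `means` (cells x components matrix with rownames
#'   `"taxon|stage"`), `n` (cell sizes).
#' @export
stage_taxon_means <- function(space) {
  lab <- space$labels
  taxa <- unique(lab$taxon)
  stages <- unique(lab$stage)
  cells <- expand.grid(stage = stages, taxon = taxa,
                       stringsAsFactors = FALSE)[, c("taxon", "stage")]
  key <- paste(lab$taxon, lab$stage, sep = "|")
  ckey <- paste(cells$taxon, cells$stage, sep = "|")
  empty <- setdiff(ckey, key)
  if (length(empty)) {
    stop("empty taxon x stage cells: ", paste(empty, collapse = ", "))
  }
  means <- t(vapply(ckey, function(k) {
    colMeans(space$scores[key == k, , drop = FALSE])
  }, numeric(ncol(space$scores))))
  out <- list(taxa = taxa, stages = stages, means = means,
              n = as.integer(table(key)[ckey]))
  class(out) <- "stage_means"
  out
}

# Extract the mean-score matrix (stages x components) for one taxon,
# ordered along `stages`.
taxon_stage_matrix <- function(sm, taxon, stages = sm$stages) {
  rows <- paste(taxon, stages, sep = "|")
  missing <- setdiff(rows, rownames(sm$means))
  if (length(missing)) stop("missing stage means: ",
                            paste(missing, collapse = ", "))
  sm$means[rows, , drop = FALSE]
}

#' Permutation test for a between-taxon mean-shape difference at one stage
#'
#' Statistic: Euclidean distance between the two cell means in morphospace.
#' The null distribution relabels specimens within the stage. When the
#' number of distinct splits is small (`<= max_exact`), all splits are
#' enumerated and the p-value is the exact proportion of splits with a
#' statistic at least as large as observed; otherwise `n_perm` random
#' relabelings are drawn and `p = (b + 1) / (n_perm + 1)`.
#'
#' @param space a `shape_space`.
#' @param stage stage label.
#' @param taxonA,taxonB taxon labels.
#' @param n_perm random permutations (default 999).
#' @param seed RNG seed.
#' @param n_components components used (default all).
#' @param max_exact enumerate exhaustively when `choose(nA + nB, nA)` is at
#'   most this (default 10000).
#' @return List: `statistic`, `p`, `exact` (logical), `n_perm`.
#' @export
mean_shape_permutation_test <- function(space, stage, taxonA, taxonB,
                                        n_perm = 999, seed = 1,
                                        n_components = NULL,
                                        max_exact = 10000) {
  lab <- space$labels
  k <- n_components %||% ncol(space$scores)
  a <- which(lab$stage == stage & lab$taxon == taxonA)
  b <- which(lab$stage == stage & lab$taxon == taxonB)
  if (length(a) < 3 || length(b) < 3) stop("both cells need >= 3 specimens")
  S <- space$scores[c(a, b), seq_len(k), drop = FALSE]
  nA <- length(a)
  n <- nrow(S)
  stat <- function(idxA) {
    vnorm(colMeans(S[idxA, , drop = FALSE]) -
            colMeans(S[-idxA, , drop = FALSE]))
  }
  obs <- stat(seq_len(nA))
  if (choose(n, nA) <= max_exact) {
    splits <- utils::combn(n, nA)
    stats <- apply(splits, 2, stat)
    p <- mean(stats >= obs - 1e-12)
    return(list(statistic = obs, p = p, exact = TRUE,
                n_perm = ncol(splits)))
  }
  perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat(sample.int(n, nA))
  }, 0))
  p <- (sum(perm_stats >= obs - 1e-12) + 1) / (n_perm + 1)
  list(statistic = obs, p = p, exact = FALSE, n_perm = n_perm)
}

#' Ontogenetic trajectory of one taxon through morphospace
#'
#' The trajectory is the ordered sequence of stage-mean positions (youngest
#' to oldest). Its `length` is the sum of consecutive segment norms and its
#' `direction` the unit vector from the first to the last stage mean.
#'
#' @param means stage-by-component matrix of mean scores, rows ordered
#'   youngest to oldest (see [taxon_stage_matrix()] / [stage_taxon_means()]),
#'   or a `stage_means` object together with `taxon`.
#' @param taxon taxon label when `means` is a `stage_means`.
#' @return Object of class `trajectory`: `taxon`, `stage_means`, `length`,
#'   `direction`.
#' @export
build_trajectory <- function(means, taxon = NULL) {
  if (inherits(means, "stage_means")) {
    if (is.null(taxon)) stop("give the taxon when passing stage_means")
    means <- taxon_stage_matrix(means, taxon)
  }
  if (nrow(means) < 2) stop("need at least two stage means")
  segs <- diff(means)
  len <- sum(sqrt(rowSums(segs^2)))
  chord <- means[nrow(means), ] - means[1, ]
  if (vnorm(chord) == 0) {
    direction <- rep(NA_real_, ncol(means))
  } else {
    direction <- chord / vnorm(chord)
  }
  out <- list(taxon = taxon, stage_means = means, length = len,
              direction = direction)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory%s: %d stages, length %.4g\n",
              if (!is.null(x$taxon)) sprintf(" of %s", x$taxon) else "",
              nrow(x$stage_means), x$length))
  invisible(x)
}

#' Compare two taxa's ontogenetic trajectories
#'
#' Observed statistics: the angle (degrees) between the two trajectory
#' directions and the absolute difference in trajectory length. The null
#' relabels specimens between the two taxa within each stage (stage
#' structure preserved) and rebuilds both trajectories. The angle p-value is
#' one-sided (observed angle at least as large as under relabeling); the
#' length p-value is two-sided on the absolute difference.
#'
#' @param space a `shape_space`.
#' @param taxonA,taxonB taxon labels with complete stage coverage.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param n_components components used (default: smallest set explaining
#'   90\% of variance, see [default_components()]).
#' @return List: `angle_deg`, `angle_p`, `length_diff`, `length_p`,
#'   `lengthA`, `lengthB`, `n_perm`.
#' @export
trajectory_comparison_test <- function(space, taxonA, taxonB, n_perm = 999,
                                       seed = 1, n_components = NULL) {
  k <- n_components %||% default_components(space)
  lab <- space$labels
  stages <- unique(lab$stage)
  sel <- lab$taxon %in% c(taxonA, taxonB)
  S <- space$scores[sel, seq_len(k), drop = FALSE]
  lab <- lab[sel, , drop = FALSE]
  traj_stats <- function(taxon_lab) {
    mA <- t(vapply(stages, function(s) {
      colMeans(S[taxon_lab == taxonA & lab$stage == s, , drop = FALSE])
    }, numeric(k)))
    mB <- t(vapply(stages, function(s) {
      colMeans(S[taxon_lab == taxonB & lab$stage == s, , drop = FALSE])
    }, numeric(k)))
    tA <- build_trajectory(mA)
    tB <- build_trajectory(mB)
    if (tA$length == 0 || tB$length == 0 ||
        any(is.na(tA$direction)) || any(is.na(tB$direction))) {
      stop("zero-length trajectory: direction undefined")
    }
    ang <- acos(pmin(pmax(sum(tA$direction * tB$direction), -1), 1)) * 180 / pi
    c(angle = ang, ldiff = abs(tA$length - tB$length),
      lA = tA$length, lB = tB$length)
  }
  obs <- traj_stats(lab$taxon)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      tl <- lab$taxon
      for (s in stages) {
        idx <- which(lab$stage == s)
        tl[idx] <- sample(tl[idx])
      }
      traj_stats(tl)[c("angle", "ldiff")]
    }, numeric(2))
  })
  list(angle_deg = unname(obs["angle"]),
       angle_p = (sum(perms["angle", ] >= obs["angle"] - 1e-12) + 1) /
         (n_perm + 1),
       length_diff = unname(obs["ldiff"]),
       length_p = (sum(perms["ldiff", ] >= obs["ldiff"] - 1e-12) + 1) /
         (n_perm + 1),
       lengthA = unname(obs["lA"]), lengthB = unname(obs["lB"]),
       n_perm = n_perm)
}

#' Map a morphospace position back to a morphometric map
#'
#' Inverse PCA mapping: `grand_mean + scores %*% components`, reshaped onto
#' the map grid. Used to visualize reconstructed (e.g. ancestral) shapes.
#'
#' @param space a `shape_space`.
#' @param scores coordinate vector (length <= number of components; missing
#'   trailing components are taken as 0).
#' @param specimen_id,taxon,stage optional labels for the returned map.
#' @return A normalized `morphometric_map`.
#' @export
map_from_scores <- function(space, scores, specimen_id = NULL,
                            taxon = NULL, stage = NULL) {
  k <- length(scores)
  if (k > nrow(space$components)) stop("more scores than components")
  v <- space$grand_mean +
    as.vector(t(space$components[seq_len(k), , drop = FALSE]) %*% scores)
  out <- list(values = matrix(v, space$grid[1], space$grid[2]),
              n_levels = unname(space$grid[1]),
              n_angles = unname(space$grid[2]),
              normalized = TRUE, diaphyseal_length = NA_real_,
              median_radius = NA_real_, window = NA_integer_,
              n_clamped = NA_integer_, taxon = taxon, stage = stage,
              specimen_id = specimen_id)
  class(out) <- "morphometric_map"
  out
}
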