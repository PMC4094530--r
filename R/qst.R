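#' Configuration of the Pst/Qst computation
#'
#' @param h2 assumed narrow-sense heritability of the shape traits in
#'   `(0, 1]` (default 0.55). Qst values are computed from phenotypic
#'   variance components as `V_B / (V_B + 2 * h2 * V_W)`, i.e. Pst under
#'   the assumption that the within-taxon additive variance is `h2 * V_W`.
#' @param n_components leading shape components entering the variance
#'   decomposition (default 3).
#' @param aggregate `"summed"` (default; Qst from summed variance
#'   components, preserving the variance-ratio interpretation) or `"mean"`
#'   (mean of per-component Qst values).
#' @return Object of class `qst_config`.
#' @export
qst_config <- function(h2 = 0.55, n_components = 3,
                       aggregate = c("summed", "mean")) {
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  stopifnot_scalar_count(n_components, "n_components", 1)
  out <- list(h2 = h2, n_components = as.integer(n_components),
              aggregate = match.arg(aggregate))
  class(out) <- "qst_config"
  out
}

#' Stage-wise phenotypic distance matrix M
#'
#' Euclidean distances between taxon stage-mean positions in morphospace,
#' restricted to the leading `n_components` shape components.
#'
#' @param space a `shape_space`.
#' @param stage stage label.
#' @param n_components components used (default: smallest set explaining
#'   90\% of variance).
#' @return A `distance_matrix` of kind `M_pheno`.
#' @export
pheno_distance_matrix <- function(space, stage, n_components = NULL) {
  k <- n_components %||% default_components(space)
  lab <- space$labels
  taxa <- unique(lab$taxon)
  sel <- lab$stage == stage
  if (!any(sel)) stop("no specimens at stage ", stage)
  cent <- t(vapply(taxa, function(tx) {
    rows <- sel & lab$taxon == tx
    if (!any(rows)) stop("empty cell: ", tx, " | ", stage)
    colMeans(space$scores[rows, seq_len(k), drop = FALSE])
  }, numeric(k)))
  distance_matrix(as.matrix(stats::dist(cent)), kind = "M_pheno",
                  labels = taxa, stage = stage,
                  meta = list(n_components = k))
}

# Per-component two-group variance decomposition: pooled within variance
# and the small-sample-corrected between-group variance
# (m1 - m2)^2 / 2 - V_W * (1/n1 + 1/n2) / 2, clipped at 0.
two_group_components <- function(xA, xB) {
  nA <- nrow(xA); nB <- nrow(xB)
  vw <- (colSums(sweep(xA, 2, colMeans(xA))^2) +
           colSums(sweep(xB, 2, colMeans(xB))^2)) / (nA + nB - 2)
  dm <- colMeans(xA) - colMeans(xB)
  vb <- pmax(dm^2 / 2 - vw * (1 / nA + 1 / nB) / 2, 0)
  list(vb = vb, vw = vw)
}

#' Pairwise Qst between two taxa at one stage
#'
#' Phenotypic variance components are computed per shape component from the
#' morphospace scores: pooled within-taxon variance `V_W` and the
#' small-sample-corrected between-taxon variance of the two cell means
#' `V_B`. The aggregate Qst is
#' `sum(V_B) / (sum(V_B) + 2 * h2 * sum(V_W))` (or the mean of
#' per-component ratios with `aggregate = "mean"`), clipped to `[0, 1]`.
#' When both `V_B` and `V_W` vanish the value is undefined; 0 is returned
#' with attribute `"undefined" = TRUE`.
#'
#' @param space a `shape_space`.
#' @param stage stage label.
#' @param A,B taxon labels (cells need >= 3 specimens).
#' @param config a [qst_config()].
#' @return Qst in `[0, 1]`.
#' @export
qst_pairwise <- function(space, stage, A, B, config = qst_config()) {
  lab <- space$labels
  k <- min(config$n_components, ncol(space$scores))
  xA <- space$scores[lab$stage == stage & lab$taxon == A, seq_len(k),
                     drop = FALSE]
  xB <- space$scores[lab$stage == stage & lab$taxon == B, seq_len(k),
                     drop = FALSE]
  if (nrow(xA) < 3 || nrow(xB) < 3) stop("both cells need >= 3 specimens")
  vc <- two_group_components(xA, xB)
  if (config$aggregate == "summed") {
    den <- sum(vc$vb) + 2 * config$h2 * sum(vc$vw)
    if (den == 0) {
      warning("zero between- and within-variance: Qst undefined, returning 0")
      return(structure(0, undefined = TRUE))
    }
    q <- sum(vc$vb) / den
  } else {
    den <- vc$vb + 2 * config$h2 * vc$vw
    ok <- den > 0
    if (!any(ok)) {
      warning("zero between- and within-variance: Qst undefined, returning 0")
      return(structure(0, undefined = TRUE))
    }
    q <- mean(vc$vb[ok] / den[ok])
  }
  min(max(q, 0), 1)
}

#' Stage-wise quantitative-genetic distance matrix Q
#'
#' All pairwise [qst_pairwise()] values at one stage; `h2`, the component
#' count and the aggregation rule are recorded in the metadata.
#'
#' @inheritParams qst_pairwise
#' @return A `distance_matrix` of kind `Q_qst`.
#' @export
qst_matrix <- function(space, stage, config = qst_config()) {
  taxa <- unique(space$labels$taxon)
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)[-length(taxa)]) {
    for (j in (i + 1):length(taxa)) {
      m[i, j] <- m[j, i] <- qst_pairwise(space, stage, taxa[i], taxa[j],
                                         config)
    }
  }
  distance_matrix(m, kind = "Q_qst", labels = taxa, stage = stage,
                  meta = list(h2 = config$h2,
                              n_components = config$n_components,
                              aggregate = config$aggregate))
}

#' Sensitivity of the Q matrix to the assumed heritability
#'
#' Computes the Q matrix over a grid of `h2` values and, for each, the
#' Mantel correlation against a reference matrix (default: the Q matrix at
#' the first grid value). Because `h2` enters all pairs as a common scale
#' factor of the within-variance, the correlation structure is expected to
#' be nearly invariant; this quantifies that invariance.
#'
#' @param space a `shape_space`.
#' @param stage stage label.
#' @param h2_grid heritability values in `(0, 1]`.
#' @param reference optional `distance_matrix` to correlate against.
#' @param config base [qst_config()] (its `h2` is overridden).
#' @return data.frame (`h2`, `mantel_r`) with attribute `"matrices"`
#'   (named list of `distance_matrix`).
#' @export
h2_sensitivity <- function(space, stage, h2_grid, reference = NULL,
                           config = qst_config()) {
  if (any(h2_grid <= 0 | h2_grid > 1)) stop("h2 grid must be in (0, 1]")
  mats <- lapply(h2_grid, function(h) {
    cfg <- config; cfg$h2 <- h
    qst_matrix(space, stage, cfg)
  })
  names(mats) <- paste0("h2_", h2_grid)
  ref <- reference %||% mats[[1]]
  r <- vapply(mats, function(m) {
    suppressWarnings(stats::cor(upper_entries(m$values),
                                upper_entries(ref$values)))
  }, 0)
  out <- data.frame(h2 = h2_grid, mantel_r = unname(r))
  attr(out, "matrices") <- mats
  out
}

#' Simulate morphospace scores under the neutral drift model
#'
#' Score-level generating model for Qst calibration: for each of
#' `n_components` trait dimensions, taxon means are drawn with
#' between-taxon variance `2 F / (1 - F) * h2 * v_w` (the drift-consistent
#' scaling at differentiation level `F`) and individuals around their taxon
#' mean with within-taxon variance `v_w`. Under this model the expected
#' Qst of [qst_pairwise()] equals `F`.
#'
#' @param F differentiation level in `[0, 1)`.
#' @param n_per_taxon individuals per taxon.
#' @param taxa taxon labels (default two taxa).
#' @param h2 heritability used in the scaling (default 0.55).
#' @param v_w within-taxon variance per component (default 1).
#' @param n_components trait dimensions (default 3).
#' @param seed RNG seed.
#' @param stage stage label attached to the scores (default `"m2"`).
#' @return A minimal `shape_space`-compatible list with `scores` and
#'   `labels`, usable by [qst_pairwise()] and [qst_matrix()].
#' @export
simulate_drift_scores <- function(F, n_per_taxon, taxa = c("A", "B"),
                                  h2 = 0.55, v_w = 1, n_components = 3,
                                  seed = 1, stage = "m2") {
  stopifnot(F >= 0, F < 1)
  K <- length(taxa)
  with_seed(seed, {
    sigma_b <- sqrt(2 * F / (1 - F) * h2 * v_w)
    mu <- matrix(stats::rnorm(K * n_components, 0, sigma_b), K)
    scores <- do.call(rbind, lapply(seq_len(K), function(k) {
      sweep(matrix(stats::rnorm(n_per_taxon * n_components, 0, sqrt(v_w)),
                   n_per_taxon), 2, mu[k, ], `+`)
    }))
    out <- list(scores = scores,
                explained_variance_ratio = rep(1 / n_components,
                                               n_components),
                labels = data.frame(taxon = rep(taxa, each = n_per_taxon),
                                    stage = stage))
    class(out) <- "shape_space"
    out
  })
}
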