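#' Labeled between-taxon distance matrix
#'
#' Common container for genotypic (`F_*`), phenotypic (`M_pheno`) and
#' quantitative-genetic (`Q_qst`) between-taxon distances.
#'
#' @param values symmetric numeric matrix, zero diagonal, non-negative.
#' @param kind one of `"F_nei"`, `"F_chord"`, `"F_fst"`, `"F_ppc"`,
#'   `"M_pheno"`, `"Q_qst"`.
#' @param labels taxon labels (default from dimnames).
#' @param stage optional stage label (phenotypic / quantitative kinds).
#' @param meta list of provenance metadata.
#' @return Object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, kind, labels = NULL, stage = NULL,
                            meta = list()) {
  values <- as.matrix(values)
  labels <- labels %||% rownames(values) %||%
    paste0("taxon", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  if (any(values < -1e-12)) stop("distances must be non-negative")
  kinds <- c("F_nei", "F_chord", "F_fst", "F_ppc", "M_pheno", "Q_qst")
  if (!kind %in% kinds) stop("unknown kind: ", kind)
  out <- list(labels = labels, values = values, kind = kind, stage = stage,
              meta = meta)
  class(out) <- "distance_matrix"
  out
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s%s), %d taxa\n", x$kind,
              if (!is.null(x$stage)) paste0(", stage ", x$stage) else "",
              length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' Export / import a labeled distance matrix as CSV
#'
#' Kind, stage and metadata go to a `<path>.json` sidecar.
#'
#' @param dm a `distance_matrix`.
#' @param path CSV path.
#' @return `read_distance_csv()` returns a `distance_matrix`.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(dm$values, path)
  jsonlite::write_json(list(kind = dm$kind, stage = dm$stage, meta = dm$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  v <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  distance_matrix(v, kind = meta$kind, stage = meta$stage,
                  meta = as.list(meta$meta))
}

#' Population allele frequencies from a genotype table
#'
#' Alternate-allele frequency per taxon and locus: alternate allele count
#' over twice the number of non-missing individuals.
#'
#' @param table a `genotype_table`.
#' @return Object of class `allele_frequencies`: `freqs` (taxa x loci),
#'   `sample_sizes` (taxa x loci allele counts).
#' @export
allele_frequencies <- function(table) {
  taxa <- unique(table$taxon)
  G <- table$genotypes
  freqs <- matrix(NA_real_, length(taxa), ncol(G),
                  dimnames = list(taxa, colnames(G)))
  sizes <- matrix(0L, length(taxa), ncol(G), dimnames = dimnames(freqs))
  for (k in seq_along(taxa)) {
    g <- G[table$taxon == taxa[k], , drop = FALSE]
    nn <- colSums(!is.na(g))
    if (any(nn == 0)) {
      stop(sprintf("all genotypes missing for taxon %s at locus %s",
                   taxa[k], colnames(G)[which(nn == 0)[1]]))
    }
    sizes[k, ] <- 2L * nn
    freqs[k, ] <- colSums(g, na.rm = TRUE) / sizes[k, ]
  }
  out <- list(freqs = freqs, sample_sizes = sizes)
  class(out) <- "allele_frequencies"
  out
}

#' Nei's standard genetic distance between two taxa
#'
#' Biallelic form of the standard distance:
#' `D = -ln(J_AB / sqrt(J_A * J_B))` with `J_A = mean_l(p_A^2 + q_A^2)`,
#' `J_AB = mean_l(p_A p_B + q_A q_B)`. Returns `Inf` when `J_AB = 0`
#' (taxa alternately fixed at every locus). The `"da"` variant gives
#' Nei et al.'s D_A distance `1 - mean_l(sqrt(p_A p_B) + sqrt(q_A q_B))`.
#'
#' @param freqs an `allele_frequencies`.
#' @param A,B taxon labels.
#' @param variant `"standard"` (default) or `"da"`.
#' @param loci optional locus subset (indices or names).
#' @return Non-negative distance (0 iff identical frequency profiles).
#' @export
nei_standard_distance <- function(freqs, A, B, variant = c("standard", "da"),
                                  loci = NULL) {
  variant <- match.arg(variant)
  pA <- freqs$freqs[A, ]; pB <- freqs$freqs[B, ]
  if (!is.null(loci)) { pA <- pA[loci]; pB <- pB[loci] }
  keep <- !is.na(pA) & !is.na(pB)
  pA <- pA[keep]; pB <- pB[keep]
  if (!length(pA)) stop("no loci shared by ", A, " and ", B)
  qA <- 1 - pA; qB <- 1 - pB
  if (variant == "da") {
    return(1 - mean(sqrt(pA * pB) + sqrt(qA * qB)))
  }
  jA <- mean(pA^2 + qA^2)
  jB <- mean(pB^2 + qB^2)
  jAB <- mean(pA * pB + qA * qB)
  if (jAB == 0) return(Inf)
  max(-log(jAB / sqrt(jA * jB)), 0)
}

#' Cavalli-Sforza and Edwards chord distance between two taxa
#'
#' Per-locus chord `(2/pi) * sqrt(2 * (1 - sum_alleles sqrt(p_A p_B)))`,
#' averaged over loci (this constant-factor variant is recorded in the
#' matrix metadata by [build_F_matrices()], since published chord formulas
#' differ by constants).
#'
#' @inheritParams nei_standard_distance
#' @return Distance in `[0, (2/pi) * sqrt(2)]`; 0 iff identical profiles.
#' @export
chord_distance <- function(freqs, A, B, loci = NULL) {
  pA <- freqs$freqs[A, ]; pB <- freqs$freqs[B, ]
  if (!is.null(loci)) { pA <- pA[loci]; pB <- pB[loci] }
  keep <- !is.na(pA) & !is.na(pB)
  pA <- pA[keep]; pB <- pB[keep]
  if (!length(pA)) stop("no loci shared by ", A, " and ", B)
  cosang <- pmin(sqrt(pA * pB) + sqrt((1 - pA) * (1 - pB)), 1)
  mean((2 / pi) * sqrt(2 * (1 - cosang)))
}

# Hudson Fst at the frequency level (exact population frequencies):
# ratio of averages of (p1 - p2)^2 over p1(1-p2) + p2(1-p1).
fst_from_freqs <- function(p1, p2) {
  keep <- !is.na(p1) & !is.na(p2) & !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  p1 <- p1[keep]; p2 <- p2[keep]
  if (!length(p1)) stop("no polymorphic loci")
  num <- sum((p1 - p2)^2)
  den <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  min(max(num / den, 0), 1)
}

#' Pairwise Hudson Fst between two taxa
#'
#' Ratio-of-averages Hudson estimator with the standard small-sample
#' correction of the numerator: per locus
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)` with `n` the allele counts; numerator and
#' denominator are summed over loci before the ratio. Loci monomorphic in
#' both taxa are skipped; the result is clipped to `[0, 1]`.
#'
#' @param table a `genotype_table`.
#' @param A,B taxon labels.
#' @return Fst estimate in `[0, 1]`.
#' @export
fst_pairwise <- function(table, A, B) {
  fr <- allele_frequencies(table)
  p1 <- fr$freqs[A, ]; p2 <- fr$freqs[B, ]
  n1 <- fr$sample_sizes[A, ]; n2 <- fr$sample_sizes[B, ]
  if (any(n1 < 4) || any(n2 < 4)) stop(">= 2 individuals per taxon required")
  keep <- !is.na(p1) & !is.na(p2) &
    !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  if (!any(keep)) stop("no usable polymorphic loci for ", A, " vs ", B)
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- sum((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
               p2 * (1 - p2) / (n2 - 1))
  den <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  min(max(num / den, 0), 1)
}

#' Between-taxon Euclidean distances in Patterson's PC space
#'
#' Genotype columns are standardized as in Patterson's eigenanalysis
#' (subtract the column mean, divide by `sqrt(p(1-p))` with `p` = column
#' mean / 2); monomorphic columns are dropped and missing genotypes imputed
#' at the column mean. Individuals are decomposed by SVD and taxon
#' centroids compared in the top-`k` PC space.
#'
#' @param table a `genotype_table`.
#' @param k number of PCs (default number of taxa - 1).
#' @return A `distance_matrix` of kind `F_ppc` (metadata: `k`, eigenvalue
#'   shares).
#' @export
patterson_pc_distance <- function(table, k = NULL) {
  taxa <- unique(table$taxon)
  k <- k %||% (length(taxa) - 1L)
  G <- table$genotypes
  mu <- colMeans(G, na.rm = TRUE)
  p <- mu / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci")
  G <- G[, poly, drop = FALSE]
  mu <- mu[poly]; p <- p[poly]
  X <- sweep(G, 2, mu)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  if (k > min(dim(X)) - 1) stop("k exceeds available components")
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  cent <- do.call(rbind, lapply(taxa, function(tx) {
    colMeans(scores[table$taxon == tx, , drop = FALSE])
  }))
  rownames(cent) <- taxa
  d <- as.matrix(stats::dist(cent))
  distance_matrix(d, kind = "F_ppc", labels = taxa,
                  meta = list(k = k,
                              eig_share = (sv$d^2 / sum(sv$d^2))[seq_len(k)]))
}

#' All four genotypic distance matrices
#'
#' Nei standard, Cavalli-Sforza-Edwards chord, Hudson Fst, and Patterson
#' PC-space distances between all taxon pairs of a genotype table.
#'
#' @param table a `genotype_table`.
#' @param k PCs for the Patterson distance (default taxa - 1).
#' @param nei_variant passed to [nei_standard_distance()].
#' @return Named list of `distance_matrix` objects
#'   (`F_nei`, `F_chord`, `F_fst`, `F_ppc`).
#' @export
build_F_matrices <- function(table, k = NULL, nei_variant = "standard") {
  taxa <- unique(table$taxon)
  fr <- allele_frequencies(table)
  pairmat <- function(f) {
    m <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
    for (i in seq_along(taxa)[-length(taxa)]) {
      for (j in (i + 1):length(taxa)) {
        m[i, j] <- m[j, i] <- f(taxa[i], taxa[j])
      }
    }
    m
  }
  list(
    F_nei = distance_matrix(
      pairmat(function(a, b) nei_standard_distance(fr, a, b, nei_variant)),
      kind = "F_nei", meta = list(variant = nei_variant)),
    F_chord = distance_matrix(
      pairmat(function(a, b) chord_distance(fr, a, b)),
      kind = "F_chord", meta = list(variant = "(2/pi)*sqrt(2*(1-cos))")),
    F_fst = distance_matrix(
      pairmat(function(a, b) fst_pairwise(table, a, b)),
      kind = "F_fst", meta = list(estimator = "Hudson ratio-of-averages")),
    F_ppc = patterson_pc_distance(table, k))
}
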