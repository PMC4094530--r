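#' Default four-taxon phylogeny
#'
#' A rooted tree for the four *Pan* taxa with the western chimpanzee as
#' sister to the central/eastern clade and the bonobo as outgroup, unit
#' branch lengths: `(((troglodytes, schweinfurthii), verus), paniscus)`.
#' Relative divergence times can be supplied via a Newick string with
#' branch lengths ([ape::read.tree()]).
#'
#' @param taxa taxon labels in the order central, eastern, western, bonobo.
#' @return An [ape::phylo] tree.
#' @export
default_pan_tree <- function(taxa = c("P.t.troglodytes", "P.t.schweinfurthii",
                                      "P.t.verus", "P.paniscus")) {
  txt <- sprintf("(((%s:1,%s:1):1,%s:1):1,%s:1);",
                 taxa[1], taxa[2], taxa[3], taxa[4])
  ape::read.tree(text = txt)
}

#' Ancestral states by squared-change parsimony
#'
#' Internal-node values minimizing the sum over edges of
#' `(delta value)^2 / branch length` (weighted; `weighted = FALSE` uses unit
#' lengths), the reconstruction that is also the maximum-likelihood ancestral
#' state under Brownian motion. Solved exactly from the stationarity
#' conditions: each internal node is the branch-length-weighted harmonic
#' average of its neighbors, a sparse linear system. Columns of `tip_values`
#' are reconstructed independently.
#'
#' @param tree an [ape::phylo] rooted tree; tip labels must match the rows
#'   of `tip_values`.
#' @param tip_values numeric matrix (tips x traits) with rownames = tip
#'   labels, or a vector for a single trait.
#' @param weighted divide squared changes by branch lengths (default TRUE).
#' @return Matrix (internal nodes x traits); rownames are ape node numbers,
#'   the root first.
#' @export
squared_change_parsimony <- function(tree, tip_values, weighted = TRUE) {
  if (is.vector(tip_values)) {
    tip_values <- matrix(tip_values, ncol = 1,
                         dimnames = list(names(tip_values), NULL))
  }
  if (is.null(rownames(tip_values))) stop("tip_values needs rownames")
  miss <- setdiff(tree$tip.label, rownames(tip_values))
  if (length(miss)) stop("tip values missing for: ",
                         paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  bl <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  if (is.null(bl)) bl <- rep(1, nrow(tree$edge))
  if (any(bl <= 0)) stop("branch lengths must be positive")
  w <- 1 / bl
  X <- tip_values[tree$tip.label, , drop = FALSE]
  internal <- ntip + seq_len(nnode)
  A <- matrix(0, nnode, nnode)
  B <- matrix(0, nnode, ncol(X))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    pi <- p - ntip
    A[pi, pi] <- A[pi, pi] + w[e]
    if (c_ <= ntip) {
      B[pi, ] <- B[pi, ] + w[e] * X[c_, ]
    } else {
      ci <- c_ - ntip
      A[ci, ci] <- A[ci, ci] + w[e]
      A[pi, ci] <- A[pi, ci] - w[e]
      A[ci, pi] <- A[ci, pi] - w[e]
    }
  }
  out <- solve(A, B)
  rownames(out) <- as.character(internal)
  colnames(out) <- colnames(tip_values)
  out
}

#' Reconstruct the last common ancestor's ontogenetic trajectory
#'
#' Applies [squared_change_parsimony()] to the taxon stage means
#' independently at every stage, assembles the root (LCA) values into a
#' [build_trajectory()] and reconstructs the LCA's morphometric map at each
#' stage by inverse PCA mapping.
#'
#' @param tree an [ape::phylo] tree whose tips are the taxa.
#' @param stage_means a `stage_means` object ([stage_taxon_means()]).
#' @param space optional `shape_space`; when given, LCA maps are
#'   reconstructed via [map_from_scores()].
#' @param weighted branch-length weighting flag.
#' @return List: `trajectory` (class `trajectory`, taxon `"LCA"`),
#'   `stage_scores` (stages x components), `maps` (list of
#'   `morphometric_map`s or NULL), `ancestral` (per-stage full internal-node
#'   reconstructions).
#' @export
lca_trajectory <- function(tree, stage_means, space = NULL, weighted = TRUE) {
  if (!setequal(tree$tip.label, stage_means$taxa)) {
    stop("tree tips must match the taxa in stage_means")
  }
  ntip <- length(tree$tip.label)
  root_id <- as.character(ntip + 1L)
  anc <- lapply(stage_means$stages, function(s) {
    tips <- t(vapply(stage_means$taxa, function(tx) {
      stage_means$means[paste(tx, s, sep = "|"), ]
    }, numeric(ncol(stage_means$means))))
    squared_change_parsimony(tree, tips, weighted)
  })
  names(anc) <- stage_means$stages
  root <- t(vapply(anc, function(a) a[root_id, ],
                   numeric(ncol(stage_means$means))))
  rownames(root) <- stage_means$stages
  traj <- build_trajectory(root)
  traj$taxon <- "LCA"
  maps <- NULL
  if (!is.null(space)) {
    maps <- lapply(stage_means$stages, function(s) {
      map_from_scores(space, root[s, ], specimen_id = paste0("LCA_", s),
                      taxon = "LCA", stage = s)
    })
    names(maps) <- stage_means$stages
  }
  list(trajectory = traj, stage_scores = root, maps = maps, ancestral = anc)
}
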