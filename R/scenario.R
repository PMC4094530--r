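#' Scenario configuration for the synthetic-data generator
#'
#' A scenario fixes everything the generator needs to produce a study-like
#' dataset: the taxa and ontogenetic stages sampled, per-cell sample sizes,
#' the drift level of the genotypes (pairwise Fst targets), the amplitudes of
#' taxon-specific surface deformations, per-taxon heterochrony rates, and the
#' within-taxon surface noise level.
#'
#' The default taxa and stages mirror a four-taxon *Pan* design sampled at
#' four dental stages (deciduous m2 through permanent M3). `noise_sd` plays
#' the role of environmental variance on the surface (mm of smooth radial
#' offset), `pheno_effect` the role of genetic divergence in taxon-specific
#' shape, and `fst_matrix` the neutral drift level.
#'
#' @param taxa character vector of taxon labels (>= 2).
#' @param stages ordered character vector of stage labels, youngest first.
#' @param n_pheno_per_cell meshes generated per taxon-by-stage cell (>= 2).
#' @param n_geno_per_taxon genotyped individuals per taxon (>= 2).
#' @param n_loci number of biallelic loci (>= 2; >= 50 recommended for
#'   stable Fst estimates).
#' @param fst_matrix symmetric pairwise target differentiation in `[0, 1)`,
#'   zero diagonal, dimnames = taxa. The default encodes a star model with
#'   well-separated per-taxon drift levels 0.03, 0.13, 0.24 and 0.40
#'   (bonobos most diverged); separation keeps the four taxa statistically
#'   distinguishable under the coarse 24-permutation Mantel null.
#' @param pheno_effect taxa-by-stages matrix of divergent deformation
#'   amplitudes (mm of radial surface offset along a taxon-specific
#'   deformation field). Zero means purely drift-proportional divergence.
#' @param heterochrony_rates named per-taxon multipliers (> 0) of
#'   developmental age: effective age = stage index (0-based) times the rate.
#' @param noise_sd standard deviation (mm, surface RMS) of the smooth
#'   within-taxon surface noise field.
#' @param pheno_base_amp amplitude (mm) of the drift-proportional component
#'   of taxon shape: each taxon's baseline deformation field is scaled by
#'   `pheno_base_amp * sqrt(F_k)` with `F_k` its star-model drift level.
#' @param mesh_n_z,mesh_n_theta mesh grid resolution (axial x angular).
#' @param seed integer master seed for the scenario.
#' @return An object of class `scenario_config`.
#' @seealso [scenario_preset()] for the two named presets.
#' @export
scenario_config <- function(taxa = c("P.t.troglodytes", "P.t.schweinfurthii",
                                     "P.t.verus", "P.paniscus"),
                            stages = c("m2", "M1", "M2", "M3"),
                            n_pheno_per_cell = 10,
                            n_geno_per_taxon = 18,
                            n_loci = 2000,
                            fst_matrix = NULL,
                            pheno_effect = NULL,
                            heterochrony_rates = NULL,
                            noise_sd = 0.25,
                            pheno_base_amp = 1.5,
                            mesh_n_z = 48,
                            mesh_n_theta = 60,
                            seed = 1L) {
  taxa <- as.character(taxa)
  stages <- as.character(stages)
  if (length(taxa) < 2 || anyDuplicated(taxa)) stop("need >= 2 distinct taxa")
  if (length(stages) < 1 || anyDuplicated(stages)) stop("stages must be distinct")
  stopifnot_scalar_count(n_pheno_per_cell, "n_pheno_per_cell", 2)
  stopifnot_scalar_count(n_geno_per_taxon, "n_geno_per_taxon", 2)
  stopifnot_scalar_count(n_loci, "n_loci", 2)
  stopifnot_scalar_count(mesh_n_z, "mesh_n_z", 8)
  stopifnot_scalar_count(mesh_n_theta, "mesh_n_theta", 12)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")

  K <- length(taxa)
  if (is.null(fst_matrix)) {
    fk <- c(0.03, 0.13, 0.24, 0.40)[seq_len(min(K, 4))]
    if (K > 4) fk <- c(fk, rep(0.15, K - 4))
    fst_matrix <- (outer(fk, fk, `+`) / 2) * (1 - diag(K))
    dimnames(fst_matrix) <- list(taxa, taxa)
  }
  fst_matrix <- as.matrix(fst_matrix)
  if (!isTRUE(all.equal(fst_matrix, t(fst_matrix), tolerance = 1e-10)) ||
      any(diag(fst_matrix) != 0) ||
      any(fst_matrix < 0) || any(fst_matrix >= 1)) {
    stop("fst_matrix must be symmetric, zero-diagonal, entries in [0, 1)")
  }
  if (is.null(dimnames(fst_matrix))) dimnames(fst_matrix) <- list(taxa, taxa)

  if (is.null(pheno_effect)) {
    pheno_effect <- matrix(0, K, length(stages), dimnames = list(taxa, stages))
  }
  pheno_effect <- as.matrix(pheno_effect)
  if (!all(dim(pheno_effect) == c(K, length(stages)))) {
    stop("pheno_effect must be a taxa x stages matrix")
  }
  dimnames(pheno_effect) <- list(taxa, stages)

  if (is.null(heterochrony_rates)) {
    heterochrony_rates <- stats::setNames(rep(1, K), taxa)
  }
  heterochrony_rates <- heterochrony_rates[taxa]
  if (any(is.na(heterochrony_rates)) || any(heterochrony_rates <= 0)) {
    stop("heterochrony_rates must be positive and named for every taxon")
  }

  out <- list(taxa = taxa, stages = stages,
              n_pheno_per_cell = as.integer(n_pheno_per_cell),
              n_geno_per_taxon = as.integer(n_geno_per_taxon),
              n_loci = as.integer(n_loci),
              fst_matrix = fst_matrix,
              pheno_effect = pheno_effect,
              heterochrony_rates = heterochrony_rates,
              noise_sd = noise_sd,
              pheno_base_amp = pheno_base_amp,
              mesh_n_z = as.integer(mesh_n_z),
              mesh_n_theta = as.integer(mesh_n_theta),
              seed = as.integer(seed))
  class(out) <- "scenario_config"
  # fail early if the drift targets are not star-representable
  out$f_k <- star_model_fk(fst_matrix)
  out
}

#' Per-taxon drift levels from a pairwise Fst target matrix
#'
#' Under a star-shaped population history in which taxon `k` drifts
#' independently from a common ancestral frequency with inbreeding level
#' `F_k` (Balding-Nichols), the frequency-level Hudson Fst between taxa `i`
#' and `j` is `(F_i + F_j) / 2`. This solves the least-squares inversion of
#' that additive relation (the additivity underlying Reynolds' distance) and
#' records the residual fit error.
#'
#' @param fst_matrix symmetric pairwise Fst targets in `[0, 1)`.
#' @return Named vector of `F_k` with attribute `"rmse"` (root-mean-square
#'   residual of the additive fit).
#' @export
star_model_fk <- function(fst_matrix) {
  taxa <- rownames(fst_matrix) %||% paste0("taxon", seq_len(nrow(fst_matrix)))
  K <- nrow(fst_matrix)
  pairs <- which(upper.tri(fst_matrix), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), K)
  for (r in seq_len(nrow(pairs))) A[r, pairs[r, ]] <- 0.5
  y <- fst_matrix[upper.tri(fst_matrix)]
  fk <- if (K == 2) {
    # underdetermined: split the single target evenly
    rep(y, 2)
  } else {
    as.vector(qr.solve(A, y))
  }
  if (any(fk < -1e-8) || any(fk >= 1)) {
    stop("fst_matrix is not representable by non-negative per-taxon F_k ",
         "under the star model")
  }
  fk <- pmax(fk, 0)
  rmse <- sqrt(mean((A %*% fk - y)^2))
  names(fk) <- taxa
  attr(fk, "rmse") <- rmse
  fk
}

#' Named generator presets
#'
#' Two study conditions are shipped:
#' \describe{
#'   \item{`neutral_congruent`}{taxon shape divergence is purely
#'     drift-proportional (each taxon's deformation amplitude scales with the
#'     square root of its star-model drift level) and constant across stages;
#'     heterochrony rates are equal. Phenotypic distance structure should
#'     track neutral genotypic distance structure at every stage.}
#'   \item{`heterochronic_divergence`}{on top of the drift-proportional
#'     baseline, taxa diverge along taxon-specific directions with
#'     amplitudes growing superlinearly with stage, and heterochrony rates
#'     differ between taxa. Congruence with neutral structure is high in
#'     infancy and erodes toward adulthood, with late-stage quantitative
#'     differentiation exceeding the neutral drift level.}
#' }
#'
#' @param name one of `"neutral_congruent"`, `"heterochronic_divergence"`.
#' @param ... overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name = c("neutral_congruent",
                                     "heterochronic_divergence"), ...) {
  name <- match.arg(name)
  args <- list(...)
  base <- do.call(scenario_config, args)
  K <- length(base$taxa)
  S <- length(base$stages)
  if (name == "neutral_congruent") {
    base$pheno_effect[] <- 0
    base$heterochrony_rates[] <- 1
  } else {
    # divergent amplitude grows superlinearly with stage index (0-based)
    growth <- (seq_len(S) - 1)^1.5
    amp <- c(0.32, 0.10, 0.28, 0.14)[seq_len(min(K, 4))]
    if (K > 4) amp <- c(amp, rep(0.2, K - 4))
    base$pheno_effect <- outer(amp, growth)
    dimnames(base$pheno_effect) <- list(base$taxa, base$stages)
    rates <- c(1.0, 0.7, 1.2, 1.4)[seq_len(min(K, 4))]
    if (K > 4) rates <- c(rates, rep(1, K - 4))
    base$heterochrony_rates[] <- rates
  }
  base$preset <- name
  base
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario", if (!is.null(x$preset)) sprintf("(%s)", x$preset),
      "\n")
  cat("  taxa:  ", paste(x$taxa, collapse = ", "), "\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf("  n per pheno cell: %d; genotypes per taxon: %d; loci: %d\n",
              x$n_pheno_per_cell, x$n_geno_per_taxon, x$n_loci))
  cat(sprintf("  star-model F_k: %s (fit rmse %.2g)\n",
              paste(sprintf("%.3f", x$f_k), collapse = ", "),
              attr(x$f_k, "rmse")))
  cat(sprintf("  noise_sd: %.3g mm; base amp: %.3g mm; seed: %d\n",
              x$noise_sd, x$pheno_base_amp, x$seed))
  invisible(x)
}

# Serialize a scenario to a plain list suitable for YAML/JSON.
scenario_to_list <- function(scenario) {
  s <- unclass(scenario)
  s$fst_matrix <- as.data.frame(s$fst_matrix)
  s$pheno_effect <- as.data.frame(s$pheno_effect)
  s$f_k <- NULL
  s
}

#' Read or write a scenario configuration as YAML
#'
#' @param scenario a `scenario_config`.
#' @param path file path.
#' @return `read_scenario()` returns a `scenario_config`.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(scenario_to_list(scenario), path, precision = 12)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  s <- yaml::read_yaml(path)
  fst <- as.matrix(as.data.frame(s$fst_matrix))
  dimnames(fst) <- list(s$taxa, s$taxa)
  pe <- as.matrix(as.data.frame(s$pheno_effect))
  dimnames(pe) <- list(s$taxa, s$stages)
  cfg <- scenario_config(
    taxa = s$taxa, stages = s$stages,
    n_pheno_per_cell = s$n_pheno_per_cell,
    n_geno_per_taxon = s$n_geno_per_taxon,
    n_loci = s$n_loci, fst_matrix = fst, pheno_effect = pe,
    heterochrony_rates = stats::setNames(unlist(s$heterochrony_rates), s$taxa),
    noise_sd = s$noise_sd, pheno_base_amp = s$pheno_base_amp,
    mesh_n_z = s$mesh_n_z, mesh_n_theta = s$mesh_n_theta, seed = s$seed)
  cfg$preset <- s$preset
  cfg
}
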