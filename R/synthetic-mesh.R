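#' Geometry parameters of the synthetic diaphysis
#'
#' The synthetic femoral shaft is a tube `r(theta, z)` around a straight
#' axis, `z` running 0 (distal) to 1 (proximal). The base profile is a
#' circular section with a mild quadratic flare toward both epiphyses, plus
#' an angularly localized posterior ridge emulating a linea-aspera-like
#' crest whose amplitude grows with effective developmental age
#' (stage index x heterochrony rate).
#'
#' @param r_base base radius (mm) at mid-shaft.
#' @param flare relative radius increase at the ends (`r0(z) = r_base *
#'   (1 + flare * (2z - 1)^2)`).
#' @param length_base diaphyseal length (mm) at effective age 0.
#' @param length_growth relative length increase per unit effective age.
#' @param ridge_base ridge amplitude (mm) at effective age 0.
#' @param ridge_gain ridge amplitude growth (mm per unit effective age).
#' @param ridge_sigma_deg angular half-width (degrees) of the ridge.
#' @param ridge_axial_sigma axial Gaussian half-width (fraction of length).
#' @return A list of class `mesh_geometry`.
#' @export
mesh_geometry <- function(r_base = 10, flare = 0.12,
                          length_base = 90, length_growth = 0.25,
                          ridge_base = 0.6, ridge_gain = 0.5,
                          ridge_sigma_deg = 25, ridge_axial_sigma = 0.22) {
  out <- list(r_base = r_base, flare = flare, length_base = length_base,
              length_growth = length_growth, ridge_base = ridge_base,
              ridge_gain = ridge_gain, ridge_sigma_deg = ridge_sigma_deg,
              ridge_axial_sigma = ridge_axial_sigma)
  class(out) <- "mesh_geometry"
  out
}

# Trigonometric basis on (theta, z): trig(m*theta) * cos(l*pi*z),
# m = m_min..m_max (cos and sin), l = 0..l_max. Spatial mean squares are
# known analytically, so coefficient vectors can be scaled to an exact
# surface RMS.
field_modes <- function(m_max = 3, l_max = 2, m_min = 1) {
  g <- expand.grid(m = m_min:m_max, l = 0:l_max,
                   trig = c("cos", "sin"), stringsAsFactors = FALSE)
  g$msq <- 0.5 * ifelse(g$l > 0, 0.5, 1)
  g
}

# Evaluate a coefficient vector on the (theta, z) grid; returns a
# length(z) x length(theta) matrix.
eval_field <- function(coefs, modes, theta, z) {
  out <- matrix(0, length(z), length(theta))
  for (j in seq_len(nrow(modes))) {
    if (coefs[j] == 0) next
    ang <- if (modes$trig[j] == "cos") cos(modes$m[j] * theta) else
      sin(modes$m[j] * theta)
    out <- out + coefs[j] * outer(cos(modes$l[j] * pi * z), ang)
  }
  out
}

# Scale a coefficient vector so the field's spatial RMS equals `rms`.
scale_to_rms <- function(coefs, modes, rms) {
  s <- sqrt(sum(coefs^2 * modes$msq))
  if (s == 0) return(coefs)
  coefs * rms / s
}

# Deterministic per-taxon deformation directions: a drift direction (used
# scaled by sqrt(F_k)) and an independent divergence direction, both
# functions of the scenario seed only. The raw coefficients are shaped by
# the inverse of the curvature gain of each angular order (a radial
# perturbation of order m changes section curvature roughly in proportion
# to m^2 - 1) and normalized in the gain-weighted norm, so each taxon's
# displacement reaches the curvature map with unit magnitude, spread
# nearly isotropically over many modes; order-1 modes (section
# translations, invisible to centroid-referenced curvature) are excluded.
taxon_field_coefs <- function(scenario, taxon) {
  ti <- match(taxon, scenario$taxa)
  modes <- field_modes(m_max = 10, l_max = 10, m_min = 2)
  # curvature gain of order m relative to order 2; normalizing the
  # gain-weighted norm makes the field's curvature-image magnitude (not its
  # surface RMS) equal to 1, so taxon displacements in map space scale
  # deterministically with the configured amplitudes
  gain <- (modes$m^2 - 1) / 3
  shape <- function(z) {
    c0 <- z / gain
    c0 / sqrt(sum((c0 * gain)^2 * modes$msq))
  }
  with_seed(child_seed(scenario$seed, 1000L + ti), {
    drift <- shape(stats::rnorm(nrow(modes)))
    divergent <- shape(stats::rnorm(nrow(modes)))
    list(drift = drift, divergent = divergent, modes = modes)
  })
}

#' Ridge amplitude of the synthetic posterior crest
#'
#' Amplitude (mm) of the linea-aspera-like ridge for a taxon at a stage:
#' `ridge_base + ridge_gain * age`, with effective developmental age
#' `age = stage_index * heterochrony_rate(taxon)` and stage index 0-based
#' from the youngest stage.
#'
#' @param scenario a [scenario_config()].
#' @param taxon,stage labels present in the scenario.
#' @param geometry a [mesh_geometry()].
#' @return Amplitude in mm.
#' @export
ridge_amplitude <- function(scenario, taxon, stage, geometry = mesh_geometry()) {
  si <- match(stage, scenario$stages)
  if (is.na(si)) stop("unknown stage label: ", stage)
  rate <- scenario$heterochrony_rates[[taxon]]
  if (is.null(rate)) stop("unknown taxon label: ", taxon)
  age <- (si - 1) * rate
  geometry$ridge_base + geometry$ridge_gain * age
}

#' Generate one synthetic diaphysis mesh
#'
#' Builds a closed-tube triangulated surface `r(theta, z)` around a straight
#' axis: base profile + drift-proportional taxon deformation + divergent
#' taxon-by-stage deformation (`pheno_effect`) + posterior ridge + smooth
#' correlated noise. Anatomical frame: anterior at 0 degrees, medial 90,
#' posterior 180 (ridge), lateral 270; distal end at the axis origin.
#'
#' Deterministic given `scenario$seed` (taxon-level deformation directions)
#' and `individual_seed` (noise field).
#'
#' @param scenario a [scenario_config()].
#' @param taxon,stage labels present in the scenario.
#' @param individual_seed integer seed for the individual noise field.
#' @param specimen_id identifier string recorded in the mesh.
#' @param geometry a [mesh_geometry()].
#' @return An object of class `diaphysis_mesh`: `vertices` (n x 3, mm),
#'   `faces` (m x 3 vertex indices), `proximal_end`, `distal_end`,
#'   `anterior` (unit vector), `taxon`, `stage`, `specimen_id`.
#' @export
make_diaphysis <- function(scenario, taxon, stage, individual_seed,
                           specimen_id = NULL, geometry = mesh_geometry()) {
  ti <- match(taxon, scenario$taxa)
  si <- match(stage, scenario$stages)
  if (is.na(ti)) stop("unknown taxon label: ", taxon)
  if (is.na(si)) stop("unknown stage label: ", stage)
  n_z <- scenario$mesh_n_z
  n_th <- scenario$mesh_n_theta
  theta <- 2 * pi * (seq_len(n_th) - 1) / n_th
  z <- seq(0, 1, length.out = n_z)

  age <- (si - 1) * scenario$heterochrony_rates[[taxon]]
  L <- geometry$length_base * (1 + geometry$length_growth * age)

  r0 <- geometry$r_base * (1 + geometry$flare * (2 * z - 1)^2)
  r <- matrix(rep(r0, n_th), n_z, n_th)

  # posterior ridge (theta = 180 deg), amplitude grows with effective age
  amp <- ridge_amplitude(scenario, taxon, stage, geometry)
  if (amp != 0) {
    sig <- geometry$ridge_sigma_deg * pi / 180
    dtheta <- atan2(sin(theta - pi), cos(theta - pi))
    prof_th <- exp(-0.5 * (dtheta / sig)^2)
    prof_z <- exp(-0.5 * ((z - 0.5) / geometry$ridge_axial_sigma)^2)
    r <- r + amp * outer(prof_z, prof_th)
  }

  tf <- taxon_field_coefs(scenario, taxon)
  base_amp <- scenario$pheno_base_amp * sqrt(scenario$f_k[[ti]])
  if (base_amp != 0) {
    r <- r + base_amp * eval_field(tf$drift, tf$modes, theta, z)
  }
  div_amp <- scenario$pheno_effect[ti, si]
  if (div_amp != 0) {
    r <- r + div_amp * eval_field(tf$divergent, tf$modes, theta, z)
  }

  if (scenario$noise_sd > 0) {
    # smooth, low-order noise: white vertex jitter would dominate the
    # curvature signal
    nm <- field_modes(m_max = 2, l_max = 3)
    coefs <- with_seed(as.integer(individual_seed), stats::rnorm(nrow(nm)))
    r <- r + eval_field(scale_to_rms(coefs, nm, scenario$noise_sd), nm,
                        theta, z)
  }

  floor_r <- 0.05 * geometry$r_base
  if (any(r < floor_r)) {
    warning("surface radius clamped at ", floor_r, " mm")
    r <- pmax(r, floor_r)
  }

  # vertex grid: index (i, j) -> (i - 1) * n_th + j (axial-major)
  ct <- matrix(cos(theta), n_z, n_th, byrow = TRUE)
  st <- matrix(sin(theta), n_z, n_th, byrow = TRUE)
  zz <- matrix(z * L, n_z, n_th)
  vertices <- cbind(as.vector(t(r * ct)), as.vector(t(r * st)),
                    as.vector(t(zz)))

  idx <- function(i, j) (i - 1L) * n_th + ((j - 1L) %% n_th) + 1L
  i <- rep(seq_len(n_z - 1L), each = n_th)
  j <- rep(seq_len(n_th), times = n_z - 1L)
  f1 <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
  f2 <- cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
  faces <- rbind(f1, f2)

  out <- list(vertices = vertices, faces = faces,
              proximal_end = c(0, 0, L), distal_end = c(0, 0, 0),
              anterior = c(1, 0, 0),
              taxon = taxon, stage = stage,
              specimen_id = specimen_id %||%
                sprintf("%s_%s_s%d", taxon, stage, as.integer(individual_seed)))
  class(out) <- "diaphysis_mesh"
  out
}

#' @export
print.diaphysis_mesh <- function(x, ...) {
  cat(sprintf("diaphysis_mesh '%s' (%s, %s): %d vertices, %d faces, length %.1f mm\n",
              x$specimen_id, x$taxon, x$stage, nrow(x$vertices), nrow(x$faces),
              vnorm(x$proximal_end - x$distal_end)))
  invisible(x)
}

#' Generate the full phenotypic sample of a scenario
#'
#' `n_pheno_per_cell` meshes for every taxon-by-stage cell, with individual
#' seeds derived deterministically from the scenario seed so that any subset
#' of stages reproduces the same specimens.
#'
#' @param scenario a [scenario_config()].
#' @param stages stages to generate (default all in the scenario).
#' @param geometry a [mesh_geometry()].
#' @return A list of `diaphysis_mesh` objects with attribute `"manifest"`
#'   (data.frame: specimen_id, taxon, stage, seed).
#' @export
make_phenotype_sample <- function(scenario, stages = scenario$stages,
                                  geometry = mesh_geometry()) {
  stopifnot(all(stages %in% scenario$stages))
  S <- length(scenario$stages)
  N <- scenario$n_pheno_per_cell
  meshes <- list()
  man <- list()
  for (taxon in scenario$taxa) {
    ti <- match(taxon, scenario$taxa)
    for (stage in stages) {
      si <- match(stage, scenario$stages)
      for (ind in seq_len(N)) {
        counter <- ((ti - 1L) * S + (si - 1L)) * N + ind
        seed_i <- child_seed(scenario$seed, 20000L + counter)
        id <- sprintf("%s_%s_%02d", taxon, stage, ind)
        m <- make_diaphysis(scenario, taxon, stage, seed_i,
                            specimen_id = id, geometry = geometry)
        meshes[[id]] <- m
        man[[id]] <- data.frame(specimen_id = id, taxon = taxon,
                                stage = stage, seed = seed_i)
      }
    }
  }
  attr(meshes, "manifest") <- do.call(rbind, c(man, make.row.names = FALSE))
  meshes
}
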