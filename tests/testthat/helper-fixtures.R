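# Fixtures and independent oracles, built in code.

# Analytic tube mesh: radius_fun(theta, z) -> radius (z in [0, 1]).
# Independent of the package's synthetic generator.
tube_mesh <- function(radius_fun, n_z = 40, n_th = 72, L = 100) {
  theta <- 2 * pi * (seq_len(n_th) - 1) / n_th
  z <- seq(0, 1, length.out = n_z)
  r <- outer(z, theta, Vectorize(function(zz, th) radius_fun(th, zz)))
  ct <- matrix(cos(theta), n_z, n_th, byrow = TRUE)
  st <- matrix(sin(theta), n_z, n_th, byrow = TRUE)
  zz <- matrix(z * L, n_z, n_th)
  vertices <- cbind(as.vector(t(r * ct)), as.vector(t(r * st)),
                    as.vector(t(zz)))
  idx <- function(i, j) (i - 1L) * n_th + ((j - 1L) %% n_th) + 1L
  i <- rep(seq_len(n_z - 1L), each = n_th)
  j <- rep(seq_len(n_th), times = n_z - 1L)
  faces <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
                 cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  structure(list(vertices = vertices, faces = faces,
                 proximal_end = c(0, 0, L), distal_end = c(0, 0, 0),
                 anterior = c(1, 0, 0), taxon = "T", stage = "s",
                 specimen_id = "tube"),
            class = "diaphysis_mesh")
}

cylinder_mesh <- function(radius = 10, ...) {
  tube_mesh(function(th, z) radius, ...)
}

# Ellipse cross-section tube, semi-axes a (at 0 deg) and b (at 90 deg).
ellipse_mesh <- function(a = 15, b = 10, ...) {
  tube_mesh(function(th, z) {
    a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  }, ...)
}

# Analytic radius of curvature of the ellipse at polar angle theta.
ellipse_roc <- function(a, b, theta) {
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  x <- r * cos(theta); y <- r * sin(theta)
  a^2 * b^2 * (x^2 / a^4 + y^2 / b^4)^1.5
}

# Rigid motion of a mesh.
transform_mesh <- function(mesh, R = diag(3), tr = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, tr, `+`)
  mesh$proximal_end <- as.vector(R %*% mesh$proximal_end + tr)
  mesh$distal_end <- as.vector(R %*% mesh$distal_end + tr)
  mesh$anterior <- as.vector(R %*% mesh$anterior)
  mesh
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Independent 3-point circumcircle radius (Heron form on sorted sides,
# Kahan's numerically stable triangle area).
circum3 <- function(p1, p2, p3) {
  s <- sort(c(sqrt(sum((p2 - p3)^2)), sqrt(sum((p1 - p3)^2)),
              sqrt(sum((p1 - p2)^2))))
  a <- s[3]; b <- s[2]; c <- s[1]
  t <- (a + (b + c)) * (c - (a - b)) * (c + (a - b)) * (a + (b - c))
  if (t <= 0) return(Inf)
  area <- 0.25 * sqrt(t)
  a * b * c / (4 * area)
}

# Independent recursive permutation enumeration (oracle for the package's
# exhaustive Mantel null).
perms_oracle <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_oracle(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Small map-building wrapper used throughout the simulation tests: modest
# grid, topology checking off (generator meshes are closed tubes by
# construction; topology checking is exercised in its own tests).
quick_map <- function(mesh, n_levels = 32, n_angles = 60, window = 5) {
  suppressWarnings(normalize_map(build_map(mesh, n_levels, n_angles, window,
                                           check_topology = FALSE)))
}

quick_space <- function(meshes, ...) {
  fit_shape_pca(lapply(meshes, quick_map, ...))
}

# Minimal hand-built shape_space (scores + labels only).
fake_space <- function(scores, taxon, stage) {
  structure(list(scores = as.matrix(scores),
                 explained_variance_ratio = rep(1 / ncol(as.matrix(scores)),
                                                ncol(as.matrix(scores))),
                 labels = data.frame(taxon = taxon, stage = stage)),
            class = "shape_space")
}
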