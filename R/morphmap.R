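#' Morphometric mapping of a diaphysis surface
#'
#' A diaphysis mesh is converted into a 2D "morphometric map": a fixed grid
#' of transverse radii of curvature sampled on evenly spaced cross sections
#' (axial levels, distal = 0 to proximal = 1) and evenly spaced anatomical
#' angles (anterior = 0, medial = 90, posterior = 180, lateral = 270
#' degrees). Sharp structures such as a linea-aspera crest appear as bands
#' of small radius. Size is removed by the level parameterization (length)
#' and by dividing the radii by their median ([normalize_map()]).
#'
#' @name morphmap
NULL

# Unique mesh edges plus the per-face edge index triples.
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2])
  b <- pmax(e[, 1], e[, 2])
  key <- a * (max(b) + 1) + b
  first <- !duplicated(key)
  eid <- match(key, key[first])
  list(edges = cbind(a[first], b[first]),
       face_edges = matrix(eid, ncol = 3))
}

# Number of closed curves formed by a plane section, given the 2-edge sets
# of the crossing faces. Returns NA if the curve is open (boundary reached).
# Each crossing edge must be shared by exactly 2 crossing faces; the curves
# are the connected components of the face graph (union-find).
count_section_loops <- function(face_edges2) {
  nf <- nrow(face_edges2)
  if (nf == 0) return(0L)
  ev <- as.vector(face_edges2)
  fc <- rep(seq_len(nf), 2)
  ord <- order(ev)
  ev <- ev[ord]; fc <- fc[ord]
  if (length(ev) %% 2 != 0) return(NA_integer_)
  odd <- seq(1, length(ev), by = 2)
  if (any(ev[odd] != ev[odd + 1])) return(NA_integer_)
  fa <- fc[odd]; fb <- fc[odd + 1]
  parent <- seq_len(nf)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(fa)) {
    ra <- find_root(fa[e]); rb <- find_root(fb[e])
    if (ra != rb) parent[ra] <- rb
  }
  sum(parent == seq_len(nf))
}

#' Extract evenly spaced cross sections of a diaphysis mesh
#'
#' Slices the shaft at `n_levels` planes at levels `(i - 0.5) / n_levels`
#' of the axial span between `distal_end` and `proximal_end`. The cutting
#' planes are orthogonal to the shaft axis; the axis is the end-to-end line,
#' refined once (by default) by fitting a straight line through the section
#' centroids. Each outline is resampled to `n_angles` points at equal
#' angular spacing about its centroid, angles following the anatomical
#' convention (anterior 0, medial 90, posterior 180, lateral 270 degrees)
#' referenced to the mesh's `anterior` vector.
#'
#' @param mesh a `diaphysis_mesh` with endpoints and anterior direction set.
#' @param n_levels number of section planes (>= 10).
#' @param n_angles points per outline.
#' @param refine centroid-axis refinement passes (default 1).
#' @param check_topology verify each plane cuts the surface in exactly one
#'   closed curve (error naming the level otherwise).
#' @return List of `cross_section` objects: `level`, `angles` (degrees),
#'   `radius` (distance to centroid at each angle), `outline`
#'   (n_angles x 2 in-plane coordinates), `centroid`.
#' @export
fit_axis_and_sections <- function(mesh, n_levels = 100, n_angles = 180,
                                  refine = 1, check_topology = TRUE) {
  stopifnot_scalar_count(n_levels, "n_levels", 10)
  stopifnot_scalar_count(n_angles, "n_angles", 8)
  if (is.null(mesh$proximal_end) || is.null(mesh$distal_end) ||
      is.null(mesh$anterior)) {
    stop("mesh needs proximal_end, distal_end and anterior set")
  }
  axis_len <- vnorm(mesh$proximal_end - mesh$distal_end)
  if (axis_len <= 0) stop("diaphyseal length must be > 0")

  me <- mesh_edges(mesh$faces)
  V <- mesh$vertices
  origin <- mesh$distal_end
  w <- unit(mesh$proximal_end - mesh$distal_end)
  levels <- (seq_len(n_levels) - 0.5) / n_levels

  slice_all <- function(origin, w) {
    u <- mesh$anterior - sum(mesh$anterior * w) * w
    if (vnorm(u) < 1e-8) stop("anterior direction is parallel to the axis")
    u <- unit(u)
    v <- cross3(w, u)
    rel <- sweep(V, 2, origin)
    tv <- (rel %*% w) / axis_len
    pu <- rel %*% u
    pv <- rel %*% v
    ta <- tv[me$edges[, 1]]
    tb <- tv[me$edges[, 2]]
    sections <- vector("list", n_levels)
    for (i in seq_len(n_levels)) {
      t0 <- levels[i]
      if (any(ta == t0) || any(tb == t0)) t0 <- t0 + 1e-9
      crossing <- (ta - t0) * (tb - t0) < 0
      if (!any(crossing)) {
        stop(sprintf("section plane at level %.4f (index %d) misses the surface",
                     levels[i], i))
      }
      if (check_topology) {
        cross_per_face <- matrix(crossing[me$face_edges], ncol = 3)
        cf <- which(rowSums(cross_per_face) == 2L)
        fe <- me$face_edges[cf, , drop = FALSE]
        cm <- cross_per_face[cf, , drop = FALSE] * 1
        rows <- seq_along(cf)
        fe2 <- cbind(fe[cbind(rows, max.col(cm, "first"))],
                     fe[cbind(rows, max.col(cm, "last"))])
        loops <- count_section_loops(fe2)
        if (is.na(loops)) {
          stop(sprintf("open section curve at level %.4f (index %d): surface has a hole",
                       levels[i], i))
        }
        if (loops != 1L) {
          stop(sprintf("section plane at level %.4f (index %d) yields %d closed curves",
                       levels[i], i, loops))
        }
      }
      s <- (t0 - ta[crossing]) / (tb[crossing] - ta[crossing])
      ia <- me$edges[crossing, 1]
      ib <- me$edges[crossing, 2]
      px <- pu[ia] + s * (pu[ib] - pu[ia])
      py <- pv[ia] + s * (pv[ib] - pv[ia])
      cx <- mean(px); cy <- mean(py)
      phi <- atan2(py - cy, px - cx) %% (2 * pi)
      rho <- sqrt((px - cx)^2 + (py - cy)^2)
      ord <- order(phi)
      phi <- phi[ord]; rho <- rho[ord]
      # circular linear interpolation onto the regular angle grid
      phi_ext <- c(phi[length(phi)] - 2 * pi, phi, phi[1] + 2 * pi)
      rho_ext <- c(rho[length(rho)], rho, rho[1])
      target <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
      r_t <- stats::approx(phi_ext, rho_ext, xout = target,
                           ties = mean)$y
      outline <- cbind(cx + r_t * cos(target), cy + r_t * sin(target))
      sec <- list(level = levels[i], angles = target * 180 / pi,
                  radius = r_t, outline = outline, centroid = c(cx, cy))
      class(sec) <- "cross_section"
      sections[[i]] <- sec
    }
    sections
  }

  sections <- slice_all(origin, w)
  for (pass in seq_len(refine)) {
    u <- unit(mesh$anterior - sum(mesh$anterior * w) * w)
    v <- cross3(w, u)
    cent3 <- t(vapply(seq_len(n_levels), function(i) {
      s <- sections[[i]]
      origin + levels[i] * axis_len * w + s$centroid[1] * u + s$centroid[2] * v
    }, numeric(3)))
    m0 <- colMeans(cent3)
    d <- svd(sweep(cent3, 2, m0))$v[, 1]
    if (sum(d * w) < 0) d <- -d
    w <- unit(d)
    # re-anchor the axis on the projections of the original endpoints
    origin <- m0 + sum((mesh$distal_end - m0) * w) * w
    prox <- m0 + sum((mesh$proximal_end - m0) * w) * w
    axis_len <- vnorm(prox - origin)
    sections <- slice_all(origin, w)
  }
  attr(sections, "diaphyseal_length") <- axis_len
  sections
}

#' Transverse radius of curvature along a cross-section outline
#'
#' For each outline point, a circle is least-squares fitted (algebraic
#' Kasa fit) to the `window` neighboring points (periodic wrap at the
#' angular seam); the circle radius is returned. With `window = 3` the fit
#' interpolates the three points exactly, i.e. equals the circumcircle.
#' Near-collinear windows (flat surface, radius diverging) are clamped at
#' 10 times the section's mean centroid distance; a floor of 1e-6 is
#' imposed. The number of clamped points is recorded in attribute
#' `"n_clamped"`.
#'
#' @param section a `cross_section`.
#' @param window odd window size, `>= 3` and less than the outline length.
#' @return Numeric vector of radii, one per outline point.
#' @export
transverse_radius_of_curvature <- function(section, window = 5) {
  n <- nrow(section$outline)
  if (window %% 2 != 1 || window < 3 || window >= n) {
    stop("window must be odd, >= 3 and < outline length")
  }
  x <- section$outline[, 1]
  y <- section$outline[, 2]
  h <- (window - 1) / 2
  roll <- function(q) {
    out <- numeric(n)
    for (o in -h:h) out <- out + q[((seq_len(n) - 1 + o) %% n) + 1]
    out
  }
  if (window == 3) {
    # the 3-point least-squares circle is the interpolating circumcircle;
    # the direct centered form is numerically stabler than normal equations
    jm <- ((seq_len(n) - 2) %% n) + 1
    jp <- (seq_len(n) %% n) + 1
    ax <- x[jm] - x; ay <- y[jm] - y
    bx <- x[jp] - x; by <- y[jp] - y
    cross <- ax * by - ay * bx
    la <- sqrt(ax^2 + ay^2)
    lb <- sqrt(bx^2 + by^2)
    lc <- sqrt((x[jp] - x[jm])^2 + (y[jp] - y[jm])^2)
    r <- ifelse(abs(cross) > 1e-14 * la * lb,
                la * lb * lc / (2 * abs(cross)), NA_real_)
    rmax <- 10 * mean(section$radius)
    raw <- r
    r[is.na(r)] <- rmax
    r <- pmin(pmax(r, 1e-6), rmax)
    attr(r, "n_clamped") <- sum(is.na(raw) | raw > rmax | raw < 1e-6)
    return(r)
  }
  w <- window
  Sx <- roll(x); Sy <- roll(y)
  Sxx <- roll(x^2); Syy <- roll(y^2); Sxy <- roll(x * y)
  Sxxx <- roll(x^3); Syyy <- roll(y^3)
  Sxxy <- roll(x^2 * y); Sxyy <- roll(x * y^2)
  xb <- Sx / w; yb <- Sy / w
  # Kasa fit on window-centered coordinates u = x - xb, v = y - yb:
  # [Suu Suv; Suv Svv] (uc, vc)' = 0.5 (Suuu + Suvv, Svvv + Suuv)'
  Suu <- Sxx - Sx^2 / w
  Svv <- Syy - Sy^2 / w
  Suv <- Sxy - Sx * Sy / w
  Suuu <- Sxxx - 3 * xb * Sxx + 2 * w * xb^3
  Svvv <- Syyy - 3 * yb * Syy + 2 * w * yb^3
  Suuv <- Sxxy - 2 * xb * Sxy - yb * Sxx + 2 * w * xb^2 * yb
  Suvv <- Sxyy - 2 * yb * Sxy - xb * Syy + 2 * w * xb * yb^2
  b1 <- 0.5 * (Suuu + Suvv)
  b2 <- 0.5 * (Svvv + Suuv)
  det2 <- Suu * Svv - Suv^2
  scale2 <- mean(section$radius)^2
  ok <- abs(det2) > 1e-14 * scale2^2 * w^2
  r <- rep(NA_real_, n)
  if (any(ok)) {
    uc <- (b1[ok] * Svv[ok] - b2[ok] * Suv[ok]) / det2[ok]
    vc <- (b2[ok] * Suu[ok] - b1[ok] * Suv[ok]) / det2[ok]
    r[ok] <- sqrt(pmax(uc^2 + vc^2 + (Suu[ok] + Svv[ok]) / w, 0))
  }
  rmax <- 10 * mean(section$radius)
  raw <- r
  r[is.na(r)] <- rmax
  r <- pmin(pmax(r, 1e-6), rmax)
  attr(r, "n_clamped") <- sum(is.na(raw) | raw > rmax | raw < 1e-6)
  r
}

#' Build the morphometric map of a mesh
#'
#' Assembles the `n_levels` x `n_angles` grid of transverse radii of
#' curvature (rows: distal to proximal; columns: anatomical angle 0-360).
#'
#' @inheritParams fit_axis_and_sections
#' @param window curvature window, see [transverse_radius_of_curvature()].
#' @param flip_angles mirror the angle axis (left/right side convention).
#' @return An object of class `morphometric_map`: `values`, `n_levels`,
#'   `n_angles`, `normalized` (FALSE), `diaphyseal_length` (mm),
#'   `median_radius` (mm), `window`, `n_clamped`, `taxon`, `stage`,
#'   `specimen_id`.
#' @export
build_map <- function(mesh, n_levels = 100, n_angles = 180, window = 5,
                      refine = 1, check_topology = TRUE,
                      flip_angles = FALSE) {
  sections <- fit_axis_and_sections(mesh, n_levels, n_angles, refine,
                                    check_topology)
  vals <- matrix(0, n_levels, n_angles)
  n_clamped <- 0L
  for (i in seq_len(n_levels)) {
    r <- transverse_radius_of_curvature(sections[[i]], window)
    n_clamped <- n_clamped + attr(r, "n_clamped")
    vals[i, ] <- r
  }
  if (flip_angles) vals <- vals[, c(1, rev(seq_len(n_angles)[-1]))]
  out <- list(values = vals, n_levels = n_levels, n_angles = n_angles,
              normalized = FALSE,
              diaphyseal_length = attr(sections, "diaphyseal_length"),
              median_radius = stats::median(vals), window = window,
              n_clamped = n_clamped,
              taxon = mesh$taxon, stage = mesh$stage,
              specimen_id = mesh$specimen_id)
  class(out) <- "morphometric_map"
  out
}

#' Normalize a morphometric map for size
#'
#' Divides the radius values by their median so the normalized map has
#' median 1 (the level grid is already length-normalized by construction).
#' Idempotent: a normalized map is returned unchanged.
#'
#' @param map a `morphometric_map`.
#' @return The normalized `morphometric_map`.
#' @export
normalize_map <- function(map) {
  if (isTRUE(map$normalized)) return(map)
  med <- stats::median(map$values)
  if (!is.finite(med) || med <= 0) stop("non-finite or non-positive median")
  map$values <- map$values / med
  map$median_radius <- med
  map$normalized <- TRUE
  map
}

#' @export
print.morphometric_map <- function(x, ...) {
  cat(sprintf("morphometric_map%s: %d levels x %d angles, %s, length %.1f mm, median radius %.3g mm\n",
              if (!is.null(x$specimen_id)) sprintf(" '%s'", x$specimen_id) else "",
              x$n_levels, x$n_angles,
              if (x$normalized) "normalized" else "raw",
              x$diaphyseal_length, x$median_radius))
  invisible(x)
}

#' Render a morphometric map as a false-color PNG
#'
#' x axis: anatomical angle 0-360 degrees; y axis: level (distal at the
#' bottom). Small radii (ridges) map to the warm end of the palette.
#'
#' @param map a normalized `morphometric_map`.
#' @param path output PNG path.
#' @param scale integer pixel magnification per grid cell.
#' @param zlim value range mapped onto the palette (default data range).
#' @return Invisibly, the path.
#' @export
render_map <- function(map, path, scale = 3, zlim = NULL) {
  if (!isTRUE(map$normalized)) stop("render_map expects a normalized map")
  v <- map$values
  zlim <- zlim %||% range(v)
  if (diff(zlim) <= 1e-12 * max(abs(zlim), 1)) {
    zlim <- mean(zlim) + c(-0.5, 0.5)  # numerically constant map
  }
  pal <- grDevices::hcl.colors(256, "Spectral")  # warm = small radius
  idx <- pmin(pmax(1L + floor(255 * (v - zlim[1]) / diff(zlim)), 1L), 256L)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, c(map$n_levels, map$n_angles, 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(rgb[ch, ], map$n_levels, map$n_angles)
  }
  img <- img[rev(seq_len(map$n_levels)), , , drop = FALSE]  # proximal on top
  if (scale > 1) {
    img <- img[rep(seq_len(nrow(img)), each = scale),
               rep(seq_len(ncol(img)), each = scale), , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read and write morphometric maps as CSV with a JSON metadata sidecar
#'
#' The CSV holds the grid values (rows = levels, distal first); metadata
#' (dimensions, normalization flag, diaphyseal length, median radius,
#' window, clamp count, labels) go to `<path>.json`.
#'
#' @param map a `morphometric_map`.
#' @param path CSV path.
#' @return `read_map_csv()` returns a `morphometric_map`.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- map[setdiff(names(map), "values")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- c(list(values = vals), meta)
  class(out) <- "morphometric_map"
  out
}
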