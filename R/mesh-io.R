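#' Read and write diaphysis meshes as ASCII PLY or OBJ
#'
#' The PLY writer stores the axis endpoints, anterior direction and the
#' taxon/stage/specimen labels in `comment` lines so a round trip preserves
#' the full `diaphysis_mesh`. The OBJ writer does the same with `#` comment
#' lines. Only ASCII triangle meshes are supported.
#'
#' @param mesh a `diaphysis_mesh`.
#' @param path file path (`.ply` or `.obj`).
#' @return `read_ply()`/`read_obj()` return a `diaphysis_mesh`; labels and
#'   endpoints missing from the file are left `NULL` (set them before
#'   mapping, e.g. from a manifest).
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    sprintf("comment shaftshape distal_end %.9g %.9g %.9g", mesh$distal_end[1],
            mesh$distal_end[2], mesh$distal_end[3]),
    sprintf("comment shaftshape proximal_end %.9g %.9g %.9g",
            mesh$proximal_end[1], mesh$proximal_end[2], mesh$proximal_end[3]),
    sprintf("comment shaftshape anterior %.9g %.9g %.9g", mesh$anterior[1],
            mesh$anterior[2], mesh$anterior[3]),
    sprintf("comment shaftshape taxon %s", mesh$taxon %||% "NA"),
    sprintf("comment shaftshape stage %s", mesh$stage %||% "NA"),
    sprintf("comment shaftshape specimen_id %s", mesh$specimen_id %||% "NA"))
  writeLines(c("ply", "format ascii 1.0", meta,
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

parse_meta_line <- function(lines, key) {
  hit <- grep(paste0("shaftshape ", key, " "), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(paste0(".*shaftshape ", key, " "), "", hit[1])
}

meta_vec <- function(lines, key) {
  s <- parse_meta_line(lines, key)
  if (is.null(s)) NULL else as.numeric(strsplit(s, " ")[[1]])
}

meta_str <- function(lines, key) {
  s <- parse_meta_line(lines, key)
  if (is.null(s) || s == "NA") NULL else s
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", lines)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)))
  vl <- lines[hdr_end + seq_len(nv)]
  fl <- lines[hdr_end + nv + seq_len(nf)]
  vertices <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fvals <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fvals[, 1] != 3)) stop("only triangle meshes are supported")
  out <- list(vertices = vertices, faces = matrix(as.integer(fvals[, 2:4] + 1),
                                                  ncol = 3),
              proximal_end = meta_vec(hdr, "proximal_end"),
              distal_end = meta_vec(hdr, "distal_end"),
              anterior = meta_vec(hdr, "anterior"),
              taxon = meta_str(hdr, "taxon"), stage = meta_str(hdr, "stage"),
              specimen_id = meta_str(hdr, "specimen_id"))
  class(out) <- "diaphysis_mesh"
  out
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# shaftshape distal_end %.9g %.9g %.9g",
                       mesh$distal_end[1], mesh$distal_end[2],
                       mesh$distal_end[3]),
               sprintf("# shaftshape proximal_end %.9g %.9g %.9g",
                       mesh$proximal_end[1], mesh$proximal_end[2],
                       mesh$proximal_end[3]),
               sprintf("# shaftshape anterior %.9g %.9g %.9g",
                       mesh$anterior[1], mesh$anterior[2], mesh$anterior[3]),
               sprintf("# shaftshape taxon %s", mesh$taxon %||% "NA"),
               sprintf("# shaftshape stage %s", mesh$stage %||% "NA"),
               sprintf("# shaftshape specimen_id %s",
                       mesh$specimen_id %||% "NA")), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  vertices <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
                     ncol = 3, byrow = TRUE)
  faces <- matrix(as.integer(scan(text = sub("^f ", "", fl), quiet = TRUE)),
                  ncol = 3, byrow = TRUE)
  out <- list(vertices = vertices, faces = faces,
              proximal_end = meta_vec(lines, "proximal_end"),
              distal_end = meta_vec(lines, "distal_end"),
              anterior = meta_vec(lines, "anterior"),
              taxon = meta_str(lines, "taxon"),
              stage = meta_str(lines, "stage"),
              specimen_id = meta_str(lines, "specimen_id"))
  class(out) <- "diaphysis_mesh"
  out
}

#' Write a phenotype sample to disk with a manifest
#'
#' One PLY file per specimen plus `manifest.csv` (specimen_id, taxon, stage,
#' file).
#'
#' @param meshes list of `diaphysis_mesh` (e.g. [make_phenotype_sample()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_mesh_sample <- function(meshes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(meshes, function(m) {
    file <- paste0(m$specimen_id, ".ply")
    write_ply(m, file.path(dir, file))
    data.frame(specimen_id = m$specimen_id, taxon = m$taxon %||% NA,
               stage = m$stage %||% NA, file = file)
  })
  manifest <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
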