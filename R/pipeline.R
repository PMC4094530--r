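#' End-to-end run configuration
#'
#' Bundles everything a full analysis run needs. In `"synthetic"` mode the
#' phenotypes and genotypes come from the generator under `scenario`; in
#' `"user-data"` mode `mesh_dir` must contain PLY meshes plus a
#' `manifest.csv` (specimen_id, taxon, stage, file) and `genotype_file` a
#' genotype CSV ([read_genotypes_csv()]) or VCF ([read_genotypes_vcf()]).
#'
#' @param mode `"synthetic"` or `"user-data"`.
#' @param scenario a [scenario_config()] (synthetic mode).
#' @param mesh_dir,genotype_file inputs (user-data mode).
#' @param n_levels,n_angles,window morphometric-map parameters.
#' @param n_components morphospace components for distances and the
#'   resampling test; `NULL` = smallest set explaining 90\% variance.
#' @param qst a [qst_config()].
#' @param n_perm,n_draws congruence-test sizes.
#' @param tree an [ape::phylo], a Newick file path, or `NULL` for
#'   [default_pan_tree()] over the observed taxa.
#' @param output_dir run directory (created).
#' @param master_seed integer; every stochastic stage derives its seed from
#'   it.
#' @param check_topology verify section topology while mapping.
#' @param write_maps write one CSV per specimen map (default TRUE).
#' @param make_plots write PNG figures (default TRUE; numeric outputs are
#'   written regardless).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "user-data"),
                       scenario = scenario_preset("neutral_congruent"),
                       mesh_dir = NULL, genotype_file = NULL,
                       n_levels = 100, n_angles = 180, window = 5,
                       n_components = NULL, qst = qst_config(),
                       n_perm = 999, n_draws = 1000, tree = NULL,
                       output_dir = "shaftshape_run", master_seed = 1,
                       check_topology = TRUE, write_maps = TRUE,
                       make_plots = TRUE) {
  mode <- match.arg(mode)
  if (mode == "user-data") {
    if (is.null(mesh_dir) || !dir.exists(mesh_dir)) {
      stop("user-data mode needs an existing mesh_dir")
    }
    if (is.null(genotype_file) || !file.exists(genotype_file)) {
      stop("user-data mode needs an existing genotype_file")
    }
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  out <- list(mode = mode, scenario = scenario, mesh_dir = mesh_dir,
              genotype_file = genotype_file, n_levels = n_levels,
              n_angles = n_angles, window = window,
              n_components = n_components, qst = qst, n_perm = n_perm,
              n_draws = n_draws, tree = tree, output_dir = output_dir,
              master_seed = as.integer(master_seed),
              check_topology = check_topology, write_maps = write_maps,
              make_plots = make_plots)
  class(out) <- "run_config"
  out
}

load_inputs <- function(config) {
  if (config$mode == "synthetic") {
    scenario <- config$scenario
    scenario$seed <- child_seed(config$master_seed, 1L)
    meshes <- make_phenotype_sample(scenario)
    geno <- make_genotypes(scenario)
    list(meshes = meshes, geno = geno, scenario = scenario)
  } else {
    man <- utils::read.csv(file.path(config$mesh_dir, "manifest.csv"))
    meshes <- lapply(seq_len(nrow(man)), function(i) {
      m <- read_ply(file.path(config$mesh_dir, man$file[i]))
      m$taxon <- man$taxon[i]; m$stage <- man$stage[i]
      m$specimen_id <- man$specimen_id[i]
      m
    })
    names(meshes) <- man$specimen_id
    geno <- if (grepl("\\.vcf$", config$genotype_file)) {
      read_genotypes_vcf(config$genotype_file)
    } else {
      read_genotypes_csv(config$genotype_file)
    }
    list(meshes = meshes, geno = geno, scenario = NULL)
  }
}

#' Validate pipeline inputs
#'
#' Checks mesh topology (closed tube: every non-boundary edge shared by
#' exactly two faces, boundary edges forming exactly two end rings), taxon
#' by stage label completeness, and genotype-table sanity. Problems are
#' split into fatal errors and non-fatal warnings; nothing is thrown.
#'
#' @param config a [run_config()].
#' @return List with character vectors `fatal` and `warnings`, and logical
#'   `ok` (`TRUE` when no fatal problems).
#' @export
validate_inputs <- function(config) {
  fatal <- character()
  warn <- character()
  inputs <- tryCatch(load_inputs(config), error = function(e) {
    fatal <<- c(fatal, conditionMessage(e))
    NULL
  })
  if (is.null(inputs)) {
    return(list(ok = FALSE, fatal = fatal, warnings = warn))
  }
  for (m in inputs$meshes) {
    msg <- mesh_topology_problem(m)
    if (!is.null(msg)) {
      fatal <- c(fatal, sprintf("mesh %s: %s", m$specimen_id, msg))
    }
  }
  taxa <- unique(vapply(inputs$meshes, function(m) m$taxon, ""))
  stages <- unique(vapply(inputs$meshes, function(m) m$stage, ""))
  key <- vapply(inputs$meshes, function(m) paste(m$taxon, m$stage, sep = "|"),
                "")
  want <- as.vector(outer(taxa, stages, paste, sep = "|"))
  missing <- setdiff(want, key)
  if (length(missing)) {
    fatal <- c(fatal, paste("empty taxon x stage cells:",
                            paste(missing, collapse = ", ")))
  }
  small <- names(which(table(key) < 3))
  if (length(small)) {
    warn <- c(warn, paste("cells with < 3 specimens (Qst/permutation tests",
                          "will fail):", paste(small, collapse = ", ")))
  }
  g <- inputs$geno
  if (length(intersect(unique(g$taxon), taxa)) < 2) {
    fatal <- c(fatal, "fewer than 2 taxa shared between meshes and genotypes")
  }
  mono <- sum(apply(g$genotypes, 2, function(x) {
    length(unique(x[!is.na(x)])) < 2
  }))
  if (mono > 0.5 * ncol(g$genotypes)) {
    warn <- c(warn, sprintf("%d of %d loci are monomorphic", mono,
                            ncol(g$genotypes)))
  }
  list(ok = length(fatal) == 0, fatal = fatal, warnings = warn)
}

# NULL if the mesh is a closed tube between its two open ends, otherwise a
# short description of the defect.
mesh_topology_problem <- function(mesh) {
  me <- mesh_edges(mesh$faces)
  cnt <- tabulate(as.vector(me$face_edges), nbins = nrow(me$edges))
  if (any(cnt > 2)) return("non-manifold edge (> 2 incident faces)")
  boundary <- which(cnt == 1)
  if (!length(boundary)) return("no boundary rings (expected two open ends)")
  # boundary edges must form closed vertex loops; count them
  be <- me$edges[boundary, , drop = FALSE]
  deg <- table(as.vector(be))
  if (any(deg != 2)) return("surface has a hole (open boundary curve)")
  verts <- as.integer(names(deg))
  vid <- match(as.vector(be), verts)
  adj <- matrix(vid, ncol = 2)
  nxt <- integer(length(verts))
  parent <- seq_along(verts)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(adj))) {
    ra <- find_root(adj[e, 1]); rb <- find_root(adj[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  loops <- sum(parent == seq_along(verts))
  if (loops != 2) {
    return(sprintf("boundary forms %d rings (expected the 2 epiphyseal ends)",
                   loops))
  }
  NULL
}

#' Run the full analysis pipeline
#'
#' Synthetic or user data in; morphometric maps, morphospace, genotypic /
#' phenotypic / quantitative-genetic distance matrices, stage-wise
#' congruence reports, ontogenetic trajectories and the reconstructed LCA
#' trajectory out, all written under `config$output_dir` with a manifest.
#' Fully deterministic under a fixed `master_seed`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`space`,
#'   `F_matrices`, `reports`, `trajectories`, `lca`, `manifest`).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add_file <- function(path) files <<- c(files, path)

  stage_name <- "input loading"
  result <- tryCatch({
    inputs <- load_inputs(config)
    meshes <- inputs$meshes
    geno <- inputs$geno

    stage_name <- "morphometric mapping"
    maps <- lapply(meshes, function(m) {
      normalize_map(build_map(m, config$n_levels, config$n_angles,
                              config$window,
                              check_topology = config$check_topology))
    })
    if (config$write_maps) {
      dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
      for (mp in maps) {
        f <- file.path(out_dir, "maps", paste0(mp$specimen_id, ".csv"))
        write_map_csv(mp, f)
        add_file(f); add_file(paste0(f, ".json"))
      }
    }

    stage_name <- "shape PCA"
    space <- fit_shape_pca(maps)
    k <- config$n_components %||% default_components(space)
    scores_df <- data.frame(space$labels,
                            stats::setNames(as.data.frame(space$scores),
                                            paste0("PC",
                                                   seq_len(ncol(space$scores)))))
    f <- file.path(out_dir, "morphospace_scores.csv")
    utils::write.csv(scores_df, f, row.names = FALSE); add_file(f)
    f <- file.path(out_dir, "explained_variance.csv")
    utils::write.csv(data.frame(component = seq_along(space$explained_variance_ratio),
                                variance_ratio = space$explained_variance_ratio),
                     f, row.names = FALSE); add_file(f)

    stage_name <- "genotypic distances"
    Fm <- build_F_matrices(geno)
    for (nm in names(Fm)) {
      f <- file.path(out_dir, paste0("dist_", nm, ".csv"))
      write_distance_csv(Fm[[nm]], f); add_file(f); add_file(paste0(f, ".json"))
    }

    stage_name <- "congruence testing"
    reports <- stagewise_report(Fm$F_ppc, space, geno, qst = config$qst,
                                n_perm = config$n_perm,
                                n_draws = config$n_draws,
                                seed = child_seed(config$master_seed, 2L),
                                n_components = k)
    tab <- congruence_table(reports)
    f <- file.path(out_dir, "congruence_table.csv")
    utils::write.csv(tab, f, row.names = FALSE); add_file(f)
    f <- file.path(out_dir, "congruence_table.json")
    jsonlite::write_json(tab, f, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA); add_file(f)
    for (s in names(reports)) {
      for (side in c("M", "Q")) {
        f <- file.path(out_dir, sprintf("dist_%s_%s.csv", side, s))
        write_distance_csv(reports[[s]][[side]], f)
        add_file(f); add_file(paste0(f, ".json"))
      }
    }

    stage_name <- "trajectories and LCA"
    sm <- stage_taxon_means(space)
    trajectories <- lapply(sm$taxa, function(tx) {
      tr <- build_trajectory(sm, tx)
      tr$stage_means <- tr$stage_means[, seq_len(k), drop = FALSE]
      build_trajectory(tr$stage_means, taxon = tx)
    })
    names(trajectories) <- sm$taxa
    tree <- config$tree %||% default_pan_tree(sm$taxa)
    if (!setequal(tree$tip.label, sm$taxa)) {
      stop("tree tips do not match the observed taxa")
    }
    lca <- lca_trajectory(tree, sm, space)
    traj_df <- do.call(rbind, lapply(c(trajectories,
                                       list(LCA = lca$trajectory)),
                                     function(tr) {
      data.frame(taxon = tr$taxon, stage = rownames(tr$stage_means) %||%
                   sm$stages,
                 tr$stage_means[, seq_len(min(3, ncol(tr$stage_means))),
                                drop = FALSE],
                 length = tr$length, row.names = NULL)
    }))
    f <- file.path(out_dir, "trajectories.csv")
    utils::write.csv(traj_df, f, row.names = FALSE); add_file(f)

    stage_name <- "figures"
    if (config$make_plots) {
      for (f in write_figures(out_dir, space, sm, trajectories, lca, Fm,
                              reports, k)) {
        add_file(f)
      }
    }

    stage_name <- "manifest"
    cfg_json <- jsonlite::toJSON(config_summary(config), auto_unbox = TRUE,
                                 digits = NA)
    cfg_file <- file.path(out_dir, "config.json")
    writeLines(cfg_json, cfg_file); add_file(cfg_file)
    manifest <- list(
      package = "shaftshape",
      version = as.character(utils::packageVersion("shaftshape")),
      master_seed = config$master_seed,
      config_hash = unname(tools::md5sum(cfg_file)),
      n_specimens = length(meshes),
      files = sort(unique(c(basename_rel(files, out_dir),
                            "manifest.json"))))
    f <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)

    invisible(list(space = space, F_matrices = Fm, reports = reports,
                   trajectories = trajectories, lca = lca,
                   stage_means = sm, manifest = manifest,
                   output_dir = out_dir))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage_name,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

basename_rel <- function(files, root) {
  sub(paste0("^", root, "/?"), "", files)
}

config_summary <- function(config) {
  list(mode = config$mode,
       scenario = if (!is.null(config$scenario))
         scenario_to_list(config$scenario) else NULL,
       mesh_dir = config$mesh_dir, genotype_file = config$genotype_file,
       n_levels = config$n_levels, n_angles = config$n_angles,
       window = config$window, n_components = config$n_components,
       qst = unclass(config$qst), n_perm = config$n_perm,
       n_draws = config$n_draws,
       tree = if (!is.null(config$tree)) ape::write.tree(config$tree)
       else NULL,
       master_seed = config$master_seed)
}
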