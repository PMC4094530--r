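# Figure outputs of run_pipeline. Every figure has a machine-readable twin
# (CSV/JSON) written by the pipeline itself; failures to open a graphics
# device degrade to a warning so headless runs still produce all numbers.

taxon_palette <- function(taxa) {
  stats::setNames(grDevices::hcl.colors(max(3, length(taxa)), "Dark 3")[
    seq_along(taxa)], taxa)
}

with_png <- function(path, width, height, expr) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height, res = 96)
    TRUE
  }, error = function(e) {
    warning("could not open PNG device for ", path, ": ",
            conditionMessage(e))
    FALSE
  })
  if (!ok) return(NULL)
  on.exit(grDevices::dev.off())
  force(expr)
  path
}

# Morphospace scatter (PC1-PC2) with stage means, per-taxon ontogenetic
# trajectories and the reconstructed LCA trajectory.
plot_trajectories <- function(space, sm, trajectories, lca, path) {
  with_png(path, 720, 640, {
    cols <- taxon_palette(sm$taxa)
    xy <- space$scores[, 1:2, drop = FALSE]
    evr <- 100 * space$explained_variance_ratio[1:2]
    graphics::plot(xy, col = grDevices::adjustcolor(cols[space$labels$taxon], 0.45),
         pch = 16, cex = 0.8,
         xlab = sprintf("PC1 (%.1f%%)", evr[1]),
         ylab = sprintf("PC2 (%.1f%%)", evr[2]),
         main = "Morphospace and ontogenetic trajectories")
    for (tx in sm$taxa) {
      m <- taxon_stage_matrix(sm, tx)[, 1:2, drop = FALSE]
      graphics::lines(m, col = cols[tx], lwd = 2)
      graphics::points(m, col = cols[tx], pch = 21, bg = "white", cex = 1.3)
    }
    lm2 <- lca$stage_scores[, 1:2, drop = FALSE]
    graphics::lines(lm2, col = "grey25", lwd = 2, lty = 2)
    graphics::points(lm2, col = "grey25", pch = 23, bg = "grey80", cex = 1.3)
    graphics::legend("topleft", legend = c(sm$taxa, "LCA"),
                     col = c(cols, "grey25"), lwd = 2,
                     lty = c(rep(1, length(sm$taxa)), 2), bty = "n",
                     cex = 0.8)
  })
}

# Grid of mean morphometric maps (taxa x stages), plus the LCA row.
plot_map_grid <- function(space, sm, lca, dir) {
  files <- character()
  rng <- NULL
  mean_maps <- list()
  for (tx in sm$taxa) {
    for (s in sm$stages) {
      mp <- map_from_scores(space, sm$means[paste(tx, s, sep = "|"), ],
                            taxon = tx, stage = s,
                            specimen_id = sprintf("mean_%s_%s", tx, s))
      mean_maps[[mp$specimen_id]] <- mp
      rng <- range(c(rng, mp$values))
    }
  }
  if (!is.null(lca$maps)) {
    for (s in names(lca$maps)) {
      mp <- lca$maps[[s]]
      mean_maps[[mp$specimen_id]] <- mp
      rng <- range(c(rng, mp$values))
    }
  }
  for (mp in mean_maps) {
    f <- file.path(dir, paste0("map_", mp$specimen_id, ".png"))
    render_map(mp, f, scale = 3, zlim = rng)
    files <- c(files, f)
  }
  files
}

# Procrustes-aligned PCO constellations of F (genotypic) vs M (phenotypic)
# per stage.
plot_overlays <- function(Fm, reports, dir) {
  files <- character()
  cf <- pco(Fm$F_ppc)
  for (s in names(reports)) {
    cm <- pco(reports[[s]]$M)
    pr <- procrustes_superimpose(cf, cm)
    f <- file.path(dir, sprintf("overlay_%s.png", s))
    res <- with_png(f, 560, 560, {
      lim <- range(c(pr$X[, 1:2], pr$Yrot[, 1:2]))
      graphics::plot(pr$X[, 1:2], pch = 16, col = "steelblue", xlim = lim, ylim = lim,
           xlab = "PCO 1", ylab = "PCO 2",
           main = sprintf("Stage %s: genotypic (blue) vs phenotypic (black)",
                          s))
      graphics::points(pr$Yrot[, 1:2], pch = 17, col = "black")
      graphics::segments(pr$X[, 1], pr$X[, 2], pr$Yrot[, 1], pr$Yrot[, 2],
                         col = "grey60")
      graphics::text(pr$X[, 1:2], labels = rownames(pr$X), pos = 3,
                     cex = 0.7)
    })
    if (!is.null(res)) files <- c(files, f)
  }
  files
}

# Resampled phenotypic vs genotypic distance scatter per stage, from the
# samples already drawn by stagewise_report.
plot_resampling <- function(reports, dir) {
  files <- character()
  for (s in names(reports)) {
    rep <- reports[[s]]
    smp <- rep$resample_sample
    if (is.null(smp)) next
    f <- file.path(dir, sprintf("resampling_%s.png", s))
    res <- with_png(f, 560, 560, {
      graphics::plot(smp$geno, smp$pheno, pch = 16,
           col = grDevices::adjustcolor("grey20", 0.3),
           xlab = "genotypic distance (median-normalized)",
           ylab = "phenotypic distance (median-normalized)",
           main = sprintf("Stage %s: R2 = %.2f", s, rep$resample_R2))
      graphics::abline(stats::lm(smp$pheno ~ smp$geno), col = "firebrick")
    })
    if (!is.null(res)) files <- c(files, f)
  }
  files
}

write_figures <- function(out_dir, space, sm, trajectories, lca, Fm,
                          reports, k) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  files <- character()
  f <- plot_trajectories(space, sm, trajectories, lca,
                         file.path(fig_dir, "trajectories.png"))
  if (!is.null(f)) files <- c(files, f)
  files <- c(files, plot_map_grid(space, sm, lca, fig_dir))
  files <- c(files, plot_overlays(Fm, reports, fig_dir))
  files <- c(files, plot_resampling(reports, fig_dir))
  files
}
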