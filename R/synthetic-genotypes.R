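#' Genotype table container
#'
#' Individuals-by-loci counts of the alternate allele (0/1/2, `NA` allowed)
#' with a per-individual taxon label.
#'
#' @param genotypes integer matrix (individuals x loci) with values in
#'   `{0, 1, 2, NA}`.
#' @param taxon character vector of taxon labels, one per row.
#' @param locus_ids optional locus identifiers (default `L1..Lp`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(genotypes, taxon, locus_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1, 2, NA))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  if (length(taxon) != nrow(genotypes)) stop("one taxon label per individual")
  if (length(unique(taxon)) < 2) stop("need >= 2 taxa")
  if (ncol(genotypes) < 1) stop("need >= 1 locus")
  locus_ids <- locus_ids %||% paste0("L", seq_len(ncol(genotypes)))
  colnames(genotypes) <- locus_ids
  out <- list(genotypes = genotypes, taxon = as.character(taxon),
              locus_ids = locus_ids)
  class(out) <- "genotype_table"
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci, taxa: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(names(table(x$taxon)), table(x$taxon), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Simulate genotypes under a star-shaped drift model
#'
#' Balding-Nichols sampling: each locus draws an ancestral frequency
#' `p0 ~ Uniform(0.05, 0.95)`; each taxon `k` draws its frequency from a
#' Beta with mean `p0` and variance `F_k * p0 * (1 - p0)`, where the
#' per-taxon drift levels `F_k` are recovered from the scenario's pairwise
#' Fst targets by [star_model_fk()]; individual genotypes are
#' `Binomial(2, p_k)`. With `F_k = 0` the taxon frequency equals `p0`.
#'
#' @param scenario a [scenario_config()].
#' @return A `genotype_table` with attribute `"true_freqs"` (the simulated
#'   taxa x loci frequencies, synthetic ground truth for calibration tests)
#'   and `"p0"` (ancestral frequencies).
#' @export
make_genotypes <- function(scenario) {
  fk <- scenario$f_k
  K <- length(scenario$taxa)
  L <- scenario$n_loci
  n <- scenario$n_geno_per_taxon
  with_seed(child_seed(scenario$seed, 7L), {
    p0 <- stats::runif(L, 0.05, 0.95)
    freqs <- matrix(0, K, L, dimnames = list(scenario$taxa, NULL))
    for (k in seq_len(K)) {
      if (fk[k] <= 0) {
        freqs[k, ] <- p0
      } else {
        lambda <- (1 - fk[k]) / fk[k]
        freqs[k, ] <- stats::rbeta(L, p0 * lambda, (1 - p0) * lambda)
      }
    }
    geno <- matrix(NA_integer_, K * n, L)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * n + seq_len(n)
      geno[rows, ] <- matrix(stats::rbinom(n * L, 2,
                                           rep(freqs[k, ], each = n)), n, L)
    }
    tab <- genotype_table(geno, rep(scenario$taxa, each = n))
    rownames(tab$genotypes) <- paste(rep(scenario$taxa, each = n),
                                     rep(seq_len(n), K), sep = "__")
    attr(tab, "true_freqs") <- freqs
    attr(tab, "p0") <- p0
    tab
  })
}

#' Read and write genotype tables as CSV or minimal VCF
#'
#' CSV layout: `individual`, `taxon`, then one 0/1/2 column per locus
#' (empty = missing). The VCF writer emits minimal biallelic SNP records
#' with a GT field only, sample names `taxon__individual`; the reader
#' accepts that convention or an explicit `taxon` vector.
#'
#' @param table a `genotype_table`.
#' @param path file path.
#' @param taxon optional explicit taxon labels for `read_genotypes_vcf()`.
#' @return Readers return a `genotype_table`.
#' @export
write_genotypes_csv <- function(table, path) {
  df <- data.frame(individual = rownames(table$genotypes) %||%
                     paste0("ind", seq_len(nrow(table$genotypes))),
                   taxon = table$taxon, table$genotypes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  geno <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- df$individual
  genotype_table(geno, df$taxon, colnames(geno))
}

#' @rdname write_genotypes_csv
#' @export
write_genotypes_vcf <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- rownames(table$genotypes) %||%
    paste(table$taxon, seq_len(nrow(table$genotypes)), sep = "__")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=shaftshape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (l in seq_len(ncol(table$genotypes))) {
    g <- table$genotypes[, l]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c("1", l, table$locus_ids[l], "A", "G", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_vcf <- function(path, taxon = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(lines[1], "\t")[[1]]
  if (hdr[1] != "#CHROM") stop("malformed VCF header")
  ids <- hdr[-(1:9)]
  body <- strsplit(lines[-1], "\t")
  locus_ids <- vapply(body, `[`, "", 3)
  gt <- vapply(body, function(f) {
    g <- sub(":.*", "", f[-(1:9)])
    a <- suppressWarnings(as.integer(substr(g, 1, 1)) +
                            as.integer(substr(g, 3, 3)))
    a
  }, integer(length(ids)))
  geno <- matrix(gt, nrow = length(ids))
  rownames(geno) <- ids
  if (is.null(taxon)) {
    if (!all(grepl("__", ids))) {
      stop("sample names are not 'taxon__individual'; pass `taxon` explicitly")
    }
    taxon <- sub("__.*", "", ids)
  }
  genotype_table(geno, taxon, locus_ids)
}
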