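valid_alleles <- c("A", "C", "G", "T")

check_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
}

#' Read / write GWAS summary statistics
#'
#' Tab-delimited with header SNP, CHR, POS, A1, A2, Z (extra columns such as
#' N are preserved). Z is the association Z-score of allele A1. Malformed
#' content (duplicated ids, allele codes outside A/C/G/T, non-numeric or
#' non-finite Z) fails with the offending lines named.
#'
#' @param path file path.
#' @return \code{read_gwas_summary}: a \code{gwas_summary} data.frame.
#' @export
read_gwas_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_cols(df, c("SNP", "CHR", "POS", "A1", "A2", "Z"), path)
  df$CHR <- as.character(df$CHR)
  if (anyDuplicated(df$SNP))
    stopf("%s: duplicated SNP id(s) at line(s) %s", path,
          paste(which(duplicated(df$SNP)) + 1L, collapse = ", "))
  bad <- which(!(df$A1 %in% valid_alleles) | !(df$A2 %in% valid_alleles))
  if (length(bad))
    stopf("%s: invalid allele code at line(s) %s", path,
          paste(bad + 1L, collapse = ", "))
  if (!is.numeric(df$Z) || any(!is.finite(df$Z)))
    stopf("%s: non-numeric or non-finite Z at line(s) %s", path,
          paste(which(!is.finite(suppressWarnings(as.numeric(df$Z)))) + 1L,
                collapse = ", "))
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' @rdname read_gwas_summary
#' @param x a \code{gwas_summary} data.frame.
#' @export
write_gwas_summary <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference panel
#'
#' Two tab-delimited files: a dosage matrix (individuals x SNPs, header =
#' SNP ids) and SNP metadata (snp_id, chrom, pos, a1, a2, maf). The stored
#' maf is recomputed from the dosages on read and must agree with the file.
#'
#' @param genotype_path,snp_path file paths.
#' @return \code{read_panel}: a \code{\link{reference_panel}}.
#' @export
read_panel <- function(genotype_path, snp_path) {
  G <- as.matrix(utils::read.delim(genotype_path, check.names = FALSE))
  meta <- utils::read.delim(snp_path, stringsAsFactors = FALSE)
  check_cols(meta, c("snp_id", "chrom", "pos", "a1", "a2", "maf"), snp_path)
  if (!identical(colnames(G), meta$snp_id))
    stopf("genotype columns and SNP metadata disagree")
  panel <- reference_panel(G, meta$snp_id, meta$chrom, meta$pos, meta$a1,
                           meta$a2)
  if (max(abs(panel$snps$maf - meta$maf)) > 1e-6)
    stopf("%s: stored maf disagrees with dosage matrix", snp_path)
  panel
}

#' @rdname read_panel
#' @param panel a \code{\link{reference_panel}}.
#' @export
write_panel <- function(panel, genotype_path, snp_path) {
  utils::write.table(panel$genotypes, genotype_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$snps, snp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotype_path, snp_path))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: set_id TAB description TAB member genes. Duplicate
#' members within a set or duplicate set ids are parse failures naming the
#' set.
#'
#' @param path GMT file path.
#' @param universe optional scorable universe; defaults to the union of all
#'   members.
#' @return \code{read_gmt}: a \code{\link{gene_set_collection}}.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("%s: empty GMT file", path)
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("%s line %d: fewer than 3 tab-separated fields", path, i)
    id <- f[1]
    genes <- f[-(1:2)]
    if (id %in% names(sets)) stopf("%s: duplicated set id %s", path, id)
    if (anyDuplicated(genes))
      stopf("%s: set %s has duplicated member(s): %s", path, id,
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    sets[[id]] <- genes
    desc[id] <- f[2]
  }
  gene_set_collection(sets, universe %||% unique(unlist(sets)), desc)
}

#' @rdname read_gmt
#' @param collection a \code{\link{gene_set_collection}}.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]] %||% "",
            collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a weight panel
#'
#' One TSV per panel with columns gene_id, snp_id, chrom, pos, a1, a2, maf,
#' weight, model_tag, cv_r2, h2_est, h2_p (one row per gene-SNP pair).
#' Unknown model tags are parse failures.
#'
#' @param path file path.
#' @return \code{read_weight_panel}: named list of \code{gene_weights}.
#' @export
read_weight_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_cols(df, c("gene_id", "snp_id", "chrom", "pos", "a1", "a2", "maf",
                   "weight", "model_tag", "cv_r2", "h2_est", "h2_p"), path)
  df$chrom <- as.character(df$chrom)
  bad <- setdiff(unique(df$model_tag), names(weight_fitters))
  if (length(bad))
    stopf("%s: unknown model_tag(s): %s", path, paste(bad, collapse = ", "))
  if (!all(c(df$a1, df$a2) %in% valid_alleles))
    stopf("%s: invalid allele code", path)
  lapply(split(df, df$gene_id), function(g) {
    if (anyDuplicated(g$snp_id))
      stopf("%s: gene %s has duplicated SNPs", path, g$gene_id[1])
    structure(list(
      gene_id = g$gene_id[1],
      snps = data.frame(snp_id = g$snp_id, chrom = g$chrom, pos = g$pos,
                        a1 = g$a1, a2 = g$a2, maf = g$maf,
                        weight = g$weight, stringsAsFactors = FALSE),
      model_tag = g$model_tag[1],
      cv_r2 = g$cv_r2[1],
      h2_est = g$h2_est[1],
      h2_p = g$h2_p[1],
      nonpredictive = g$cv_r2[1] <= 0
    ), class = "gene_weights")
  })
}

#' @rdname read_weight_panel
#' @param weight_panel named list of \code{gene_weights}.
#' @export
write_weight_panel <- function(weight_panel, path) {
  rows <- lapply(weight_panel, function(g) {
    data.frame(gene_id = g$gene_id, g$snps, model_tag = g$model_tag,
               cv_r2 = g$cv_r2, h2_est = g$h2_est, h2_p = g$h2_p,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration
#'
#' YAML serialization of a \code{\link{pipeline_config}}; the round trip is
#' lossless.
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_config
#' @param config a \code{pipeline_config} list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
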