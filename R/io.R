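# Plain-text readers and writers for the pipeline's interchange formats.

#' Write / read GWAS summary statistics as TSV
#'
#' The sumstats dialect is `chrom, pos, ref, alt, z, n_cases, n_controls`
#' plus any extra columns present (`id`, `imputed`, `impute_r2`, ...).
#'
#' @param gwas A `gwas_summary` tibble.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `gwas_summary` tibble (reader).
#' @export
write_sumstats_tsv <- function(gwas, path) {
  readr::write_tsv(tibble::as_tibble(gwas), path)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = readr::col_character()))
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Write an expression matrix (and covariates) as TSV
#'
#' @param expr An `expression_set`.
#' @param path Output file for the continuous expression matrix
#'   (genes x samples, first column `gene_id`).
#' @param what Which matrix to write: `"expression"`, `"counts"` or `"tpm"`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, what = c("expression", "counts", "tpm")) {
  what <- match.arg(what)
  m <- expr[[what]]
  d <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
write_covariates_tsv <- function(expr, path) {
  d <- tibble::as_tibble(expr$covariates)
  d <- dplyr::bind_cols(tibble::tibble(sample_id = expr$samples$id), d)
  readr::write_tsv(d, path)
  invisible(path)
}

#' Write per-population expression weights as TSV
#'
#' One row per gene x variant: dense and sparse weights, credible-set
#' membership, within-set inclusion probability, and PIP — the weight-
#' database format consumed by [run_twas()] after selecting a column.
#'
#' @param models Named list of `sushie_fit` objects.
#' @param population Population label.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(models, population, path) {
  d <- purrr::imap_dfr(models, function(m, g) {
    td <- dplyr::filter(tidy(m), .data$population == !!population)
    dplyr::bind_cols(tibble::tibble(gene_id = g), td)
  })
  readr::write_tsv(d, path)
  invisible(path)
}

#' Write a genotype panel as an uncompressed VCF
#'
#' Minimal VCFv4.2 with unphased GT genotypes derived from the dosages
#' (missing dosages become `./.`).
#'
#' @param panel A `genotype_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(panel, path) {
  v <- panel$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(panel$dosages)  # variants x samples
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(panel$dosages)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF into a genotype panel
#'
#' GT fields are converted to alternate-allele dosages. Requires the vcfR
#' package.
#'
#' @param path VCF file.
#' @param population Population label to attach.
#' @return A `genotype_panel` (without sample phenotype columns).
#' @export
read_genotypes_vcf <- function(path, population = "unknown") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  variants <- tibble::tibble(id = fix[, "ID"], chrom = fix[, "CHROM"],
                             pos = as.integer(fix[, "POS"]),
                             ref = fix[, "REF"], alt = fix[, "ALT"])
  samples <- tibble::tibble(id = colnames(gt), population = population,
                            status = NA_integer_, age = NA_real_,
                            apoe = NA_character_)
  structure(list(dosages = t(dos), variants = variants, samples = samples,
                 blocks = NULL, population = population),
            class = "genotype_panel")
}

#' Write LD-block definitions as BED
#'
#' @param panel A `genotype_panel` with a `blocks` table.
#' @param path Output file (0-based half-open BED intervals).
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(panel, path) {
  b <- panel$blocks
  stop_if_not(!is.null(b), "panel has no block definitions")
  readr::write_tsv(tibble::tibble(chrom = b$chrom, start = b$bp_start - 1L,
                                  end = b$bp_end, name = paste0("block", b$block)),
                   path, col_names = FALSE)
  invisible(path)
}
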