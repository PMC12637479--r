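# Summary-based TWAS association statistics.

#' TWAS z-score from weights, GWAS z-scores and LD
#'
#' The association statistic for genetically predicted expression is
#' `Z = W'z / sqrt(W' S W)` where `W` are the expression weights, `z` the
#' GWAS z-scores, and `S` the LD (correlation) matrix of the weight
#' variants; the denominator normalizes by the variance the weighted LD
#' induces. The LD matrix is floored to positive semi-definite before use.
#'
#' @param weights,z Aligned numeric vectors.
#' @param ld Aligned LD (correlation) matrix.
#' @param eps Variance threshold below which the statistic is undefined
#'   (default 1e-8).
#' @return The z-score, or `NA` when `W' S W <= eps` (degenerate variance).
#' @export
twas_zscore <- function(weights, z, ld, eps = 1e-8) {
  p <- length(weights)
  stop_if_not(length(z) == p && all(dim(ld) == p), "weights, z, ld must align")
  ld <- make_psd(as.matrix(ld), floor = 0)
  denom <- drop(crossprod(weights, ld %*% weights))
  if (denom <= eps) return(NA_real_)
  drop(crossprod(weights, z)) / sqrt(denom)
}

#' Is a position inside the MHC mask?
#'
#' The major histocompatibility complex (chr6 ~24-34 Mb) is conventionally
#' excluded from expression-weight analyses because of its complex LD.
#' @param chrom,pos Vectors of chromosome labels and base-pair positions.
#' @return Logical vector.
#' @export
in_mhc <- function(chrom, pos) {
  chrom %in% c("6", "chr6") & pos >= 24e6 & pos <= 34e6
}

#' Run a TWAS over a weight database
#'
#' Per gene: intersect the weight variants with the GWAS variants carrying a
#' (typed or imputed) z-score, compute the LD of the intersected variants
#' from the panel (with a 1e-6 diagonal ridge), and form the TWAS z-score.
#' Genes with no overlapping variants, all-zero weights, or degenerate
#' weighted variance are reported with a `skipped_reason` instead of a
#' statistic. Genes overlapping the MHC mask are excluded up front.
#'
#' @param weightdb Tibble with columns `gene_id, id, weight` (one row per
#'   gene x variant; zero-weight rows allowed), or a named list of named
#'   weight vectors.
#' @param gwas Harmonized (optionally imputation-completed) summary
#'   statistics with `id`, `z`.
#' @param panel `genotype_panel` used as the LD reference.
#' @param mode Label recorded in the output (`"dense"` or `"sparse"`).
#' @param gene_info Optional tibble `gene_id, chrom, start, end` used for
#'   the MHC exclusion.
#' @return A `twas_table` tibble: `gene_id, population, mode, z, p, q,
#'   n_weights_nonzero, skipped_reason`.
#' @export
run_twas <- function(weightdb, gwas, panel, mode = c("dense", "sparse"),
                     gene_info = NULL) {
  mode <- match.arg(mode)
  if (is.list(weightdb) && !is.data.frame(weightdb)) {
    weightdb <- purrr::imap_dfr(weightdb, function(w, g) {
      tibble::tibble(gene_id = g, id = names(w), weight = unname(w))
    })
  }
  stop_if_not(nrow(weightdb) > 0, "empty weight database")
  genes <- unique(weightdb$gene_id)
  if (!is.null(gene_info)) {
    masked <- gene_info$gene_id[in_mhc(gene_info$chrom, gene_info$start) |
                                  in_mhc(gene_info$chrom, gene_info$end)]
    genes <- setdiff(genes, masked)
  }
  zmap <- setNames(gwas$z, gwas$id)
  Xs <- standardize_columns(panel$dosages)
  rows <- purrr::map_dfr(genes, function(g) {
    wtab <- weightdb[weightdb$gene_id == g, ]
    w <- setNames(wtab$weight, wtab$id)
    avail <- names(w)[names(w) %in% names(zmap) & !is.na(zmap[names(w)])]
    base <- tibble::tibble(gene_id = g, population = panel$population,
                           mode = mode, z = NA_real_, p = NA_real_,
                           n_weights_nonzero = sum(w != 0),
                           skipped_reason = NA_character_)
    if (all(w == 0)) {
      base$skipped_reason <- "all_zero_weights"
      return(base)
    }
    keep <- avail[w[avail] != 0]
    if (length(keep) == 0) {
      base$skipped_reason <- "no_overlapping_variants"
      return(base)
    }
    ld <- crossprod(Xs[, keep, drop = FALSE]) / (nrow(Xs) - 1)
    diag(ld) <- diag(ld) + 1e-6
    zt <- twas_zscore(w[keep], zmap[keep], ld)
    if (is.na(zt)) {
      base$skipped_reason <- "degenerate_variance"
      return(base)
    }
    base$z <- zt
    base$p <- 2 * pnorm(-abs(zt))
    base
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(gene_id = character(), population = character(),
                           mode = character(), z = numeric(), p = numeric(),
                           n_weights_nonzero = integer(),
                           skipped_reason = character())
  }
  rows$q <- NA_real_
  ok <- !is.na(rows$p)
  if (any(ok)) rows$q[ok] <- bh_qvalues(rows$p[ok])$q
  class(rows) <- c("twas_table", class(rows))
  rows
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(z^2) / 0.454936` — the median of the squared
#' statistics divided by the chi-square(1 df) median (0.454936, via
#' `qchisq(0.5, 1)`). Values near 1 indicate calibrated tests.
#'
#' @param z_values Numeric vector of at least 20 finite z-scores.
#' @return The inflation factor.
#' @export
genomic_lambda <- function(z_values) {
  z <- z_values[is.finite(z_values)]
  stop_if_not(length(z) >= 20, "need at least 20 finite z-values")
  median(z^2) / qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values and the significant set
#'
#' Step-up BH adjustment (monotone by construction) with a significance call
#' at `q < q_threshold`.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param q_threshold Significance threshold (default 0.05).
#' @return List with `q` (adjusted values) and `significant` (logical).
#' @export
bh_qvalues <- function(p_values, q_threshold = 0.05) {
  stop_if_not(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = !is.na(q) & q < q_threshold)
}

#' Fraction of dense weight mass inside retained credible sets
#'
#' Diagnostic for dense-vs-sparse TWAS divergence: when most absolute dense
#' weight lies inside the retained credible sets, the two statistics should
#' agree; divergences flag signal carried by out-of-set variants.
#'
#' @param model A `sushie_fit`.
#' @param population Population label.
#' @return Fraction in \[0, 1\] (NA when dense mass is zero).
#' @export
weight_mass_containment <- function(model, population) {
  wd <- abs(extract_weights(model, population, "dense"))
  if (sum(wd) == 0) return(NA_real_)
  keep <- unique(unlist(lapply(retained_sets(model), `[[`, "variant_idx")))
  sum(wd[keep]) / sum(wd)
}

#' Pair dense and sparse TWAS tables for comparison
#'
#' Joins the two tables per gene and population, reports the absolute
#' z difference, and (when the fitted models are supplied) the dense
#' weight-mass containment explaining divergences.
#'
#' @param table_dense,table_sparse `twas_table` tibbles over the same genes.
#' @param models Optional named list of `sushie_fit` objects (by gene id).
#' @return Tibble `gene_id, population, z_dense, z_sparse, abs_diff,
#'   containment`.
#' @export
compare_dense_sparse <- function(table_dense, table_sparse, models = NULL) {
  d <- dplyr::select(tibble::as_tibble(table_dense), "gene_id", "population",
                     z_dense = "z")
  s <- dplyr::select(tibble::as_tibble(table_sparse), "gene_id", "population",
                     z_sparse = "z")
  out <- dplyr::full_join(d, s, by = c("gene_id", "population"))
  out$abs_diff <- abs(out$z_dense - out$z_sparse)
  out$containment <- NA_real_
  if (!is.null(models)) {
    for (i in seq_len(nrow(out))) {
      m <- models[[out$gene_id[i]]]
      if (!is.null(m)) {
        out$containment[i] <- weight_mass_containment(m, out$population[i])
      }
    }
  }
  out
}
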