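# End-to-end glue: fit every gene at a locus, build weight databases, and
# run the population-stratified TWAS.

#' Fit the fine-mapping model for every gene at a simulated locus
#'
#' For each gene, residualizes expression on an intercept plus the measured
#' covariates (and, optionally, hidden factors detected by
#' [mp_hidden_factors()] from the expression matrix) within each
#' population, then fits [fit_sushie()] across populations.
#'
#' @param locus Output of [simulate_locus()].
#' @param L Maximum number of effects (default 5 — compact loci need fewer
#'   than genome-scale runs).
#' @param use_covariates Residualize on the measured covariates (default
#'   TRUE).
#' @param detect_hidden Also residualize on Marchenko-Pastur-retained
#'   hidden factors (default FALSE; only informative with many genes).
#' @param compute_h2 Attach per-population cis-heritability estimates
#'   (default FALSE).
#' @param ... Passed to [fit_sushie()].
#' @return Named list of `sushie_fit` objects (by gene id).
#' @export
fit_locus <- function(locus, L = 5, use_covariates = TRUE,
                      detect_hidden = FALSE, compute_h2 = FALSE, ...) {
  pops <- names(locus$panels)
  gene_ids <- locus$genes$gene_id
  hidden <- lapply(pops, function(popn) {
    if (!detect_hidden) return(NULL)
    mp_hidden_factors(locus$expr[[popn]]$expression)$scores
  })
  names(hidden) <- pops
  fits <- lapply(seq_along(gene_ids), function(g) {
    X_by_pop <- lapply(locus$panels, `[[`, "dosages")
    y_by_pop <- lapply(pops, function(popn) {
      es <- locus$expr[[popn]]
      covs <- cbind(intercept = 1,
                    if (use_covariates) es$covariates,
                    hidden[[popn]])
      residualize(es$expression[g, ], covs)
    })
    names(y_by_pop) <- pops
    fit <- fit_sushie(X_by_pop, y_by_pop, L = L, gene_id = gene_ids[g], ...)
    if (compute_h2) {
      fit$cis_h2 <- lapply(setNames(pops, pops), function(popn) {
        cis_heritability(locus$panels[[popn]]$dosages, y_by_pop[[popn]])
      })
    }
    fit
  })
  setNames(fits, gene_ids)
}

#' Build a weight database from fitted models
#'
#' @param models Named list of `sushie_fit` objects.
#' @param population Population label.
#' @param mode `"dense"` or `"sparse"`.
#' @return Tibble `gene_id, id, weight` consumed by [run_twas()].
#' @export
build_weight_db <- function(models, population, mode = c("dense", "sparse")) {
  mode <- match.arg(mode)
  purrr::imap_dfr(models, function(m, g) {
    w <- extract_weights(m, population, mode)
    tibble::tibble(gene_id = g, id = names(w), weight = unname(w))
  })
}

#' Population-stratified TWAS for a set of fitted genes
#'
#' Convenience wrapper: builds the weight database for each population,
#' harmonizes (and optionally imputes) the GWAS, and runs the TWAS,
#' returning the stacked long table.
#'
#' @param models Named list of `sushie_fit` objects.
#' @param gwas_by_pop Named list of raw `gwas_summary` tibbles.
#' @param panels Named list of `genotype_panel` LD references.
#' @param mode `"dense"` or `"sparse"`.
#' @param impute Run [impute_zscores()] after harmonization (default TRUE).
#' @param ridge Imputation ridge (default 0.1).
#' @param min_impute_r2 Drop imputed variants below this predicted quality
#'   (default 0.8, mirroring the genotype-imputation convention). Poorly
#'   imputed z-scores are shrunk toward zero while the LD denominator still
#'   assigns them full variance, which deflates the test statistic; the
#'   quality filter keeps the null calibrated.
#' @return A `twas_table` over all populations.
#' @export
locus_twas <- function(models, gwas_by_pop, panels, mode = c("dense", "sparse"),
                       impute = TRUE, ridge = 0.1, min_impute_r2 = 0.8) {
  mode <- match.arg(mode)
  pops <- names(panels)
  out <- purrr::map_dfr(pops, function(popn) {
    g <- match_alleles(gwas_by_pop[[popn]], panels[[popn]]$variants)
    if (impute) g <- impute_zscores(g, panels[[popn]], ridge = ridge,
                                    min_impute_r2 = min_impute_r2)
    run_twas(build_weight_db(models, popn, mode), g, panels[[popn]], mode)
  })
  class(out) <- c("twas_table", setdiff(class(out), "twas_table"))
  out
}
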