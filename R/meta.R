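# Sample-size-weighted meta-analysis of population-stratified TWAS z-scores.

#' Effective sample size of a case-control study
#'
#' `N_eff = 4 / (1/n_cases + 1/n_controls)`: equals the total sample size
#' for a balanced design and down-weights unbalanced studies toward the
#' information they actually carry.
#'
#' @param n_cases,n_controls Positive counts.
#' @return Effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  stop_if_not(all(n_cases > 0) && all(n_controls > 0),
              "case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Sample-size-weighted z-score meta-analysis
#'
#' `z_meta = sum_i sqrt(n_i) z_i / sqrt(sum_i n_i)` over the populations
#' with an available z-score (missing populations are simply excluded); the
#' p-value is two-sided normal. Used because summary-based TWAS supplies no
#' effect sizes or standard errors for inverse-variance weighting.
#'
#' @param z_by_pop Named numeric vector (or list) of per-population
#'   z-scores; NAs allowed.
#' @param n_by_pop Matching per-population (effective) sample sizes.
#' @return List with `z_meta`, `p_meta`, `populations_used`.
#' @export
ssw_meta <- function(z_by_pop, n_by_pop) {
  z <- unlist(z_by_pop)
  n <- unlist(n_by_pop)[names(z) %||% seq_along(z)]
  ok <- !is.na(z) & !is.na(n)
  if (!any(ok)) rlang::abort("all population z-scores missing")
  zm <- sum(sqrt(n[ok]) * z[ok]) / sqrt(sum(n[ok]))
  list(z_meta = zm, p_meta = 2 * pnorm(-abs(zm)),
       populations_used = names(z)[ok] %||% which(ok))
}

#' Meta-analyze a long table of population-stratified TWAS results
#'
#' Combines per-gene z-scores across populations with [ssw_meta()] using
#' case/control effective sample sizes (or total N with
#' `weights = "total"`), and adds BH q-values over the meta p-values.
#'
#' @param twas Long tibble with `gene_id, population, z` (NAs/skips allowed).
#' @param n_cases,n_controls Named vectors (by population label).
#' @param weights `"effective"` (default) or `"total"`.
#' @return Tibble: `gene_id`, `z_<pop>` columns, `z_meta, p_meta, q_meta`.
#' @export
meta_analyze <- function(twas, n_cases, n_controls,
                         weights = c("effective", "total")) {
  weights <- match.arg(weights)
  pops <- unique(twas$population)
  stop_if_not(all(pops %in% names(n_cases)) && all(pops %in% names(n_controls)),
              "n_cases/n_controls must be named by population")
  n_w <- if (weights == "effective") {
    effective_n(n_cases[pops], n_controls[pops])
  } else {
    n_cases[pops] + n_controls[pops]
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(twas), "gene_id", "population", "z"),
    names_from = "population", values_from = "z")
  res <- purrr::pmap_dfr(wide, function(gene_id, ...) {
    z <- unlist(list(...))
    if (all(is.na(z))) {
      return(tibble::tibble(gene_id = gene_id, z_meta = NA_real_, p_meta = NA_real_))
    }
    m <- ssw_meta(z, n_w[names(z)])
    tibble::tibble(gene_id = gene_id, z_meta = m$z_meta, p_meta = m$p_meta)
  })
  out <- dplyr::left_join(
    dplyr::rename_with(wide, ~ paste0("z_", .x), -"gene_id"),
    res, by = "gene_id")
  out$q_meta <- NA_real_
  ok <- !is.na(out$p_meta)
  if (any(ok)) out$q_meta[ok] <- bh_qvalues(out$p_meta[ok])$q
  out
}

#' Sign concordance of TWAS z-scores against an anchor population
#'
#' Over all genes and non-anchor populations, the percentage of
#' (gene, population) pairs whose z-score sign matches the anchor
#' population's sign for that gene. A zero z-score counts as discordant.
#'
#' @param z_table Matrix or data frame of z-scores with one column per
#'   population (a `gene_id` column is allowed and ignored in the
#'   computation).
#' @param anchor Anchor population column name.
#' @return Percentage in \[0, 100\].
#' @export
sign_concordance <- function(z_table, anchor) {
  zt <- as.data.frame(z_table)
  num <- vapply(zt, is.numeric, TRUE)
  zt <- zt[, num, drop = FALSE]
  stop_if_not(anchor %in% colnames(zt), "anchor population not found")
  stop_if_not(nrow(zt) >= 1 && ncol(zt) >= 2, "need >= 1 gene and >= 2 populations")
  za <- zt[[anchor]]
  others <- setdiff(colnames(zt), anchor)
  conc <- vapply(others, function(p) {
    sign(zt[[p]]) == sign(za) & sign(zt[[p]]) != 0
  }, logical(nrow(zt)))
  100 * mean(conc)
}

#' Published multi-ancestry AD TWAS meta-analysis genes
#'
#' The nine genes reaching meta-analysis significance with gene-level
#' fine-mapping support (PIP > 0.8) in a published three-population
#' (NHW/AA/HISP) whole-blood TWAS of Alzheimer's disease, with their
#' population-stratified and meta-analysis z-scores. Bundled as the input
#' for the sign-concordance worked example.
#'
#' @return Tibble: `chrom, start, end, gene, z_meta, p_meta, z_AA, z_NHW,
#'   z_HISP`.
#' @export
ad_twas_meta_genes <- function() {
  path <- system.file("extdata", "ad_twas_meta_genes.tsv", package = "matwas",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
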