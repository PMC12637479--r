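# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multi-population eQTL fine-mapping fit
#'
#' One row per variant per population: PIP, retained-credible-set
#' membership, the member's inclusion probability within its set's effect,
#' and the dense/sparse expression weights.
#'
#' @param x A `sushie_fit`.
#' @param ... Unused.
#' @return A tibble `variant, population, pip, cs, alpha, weight_dense,
#'   weight_sparse`.
#' @export
tidy.sushie_fit <- function(x, ...) {
  p <- length(x$variant_ids)
  ret <- retained_sets(x)
  cs_idx <- rep(NA_integer_, p)
  alpha_cs <- rep(NA_real_, p)
  for (i in seq_along(ret)) {
    cs_idx[ret[[i]]$variant_idx] <- i
    alpha_cs[ret[[i]]$variant_idx] <- x$alpha[ret[[i]]$effect_index,
                                              ret[[i]]$variant_idx]
  }
  purrr::map_dfr(x$populations, function(popn) {
    tibble::tibble(variant = x$variant_ids, population = popn,
                   pip = unname(x$pip), cs = cs_idx, alpha = alpha_cs,
                   weight_dense = unname(extract_weights(x, popn, "dense")),
                   weight_sparse = unname(extract_weights(x, popn, "sparse")))
  })
}

#' One-row summary of a fine-mapping fit
#'
#' @param x A `sushie_fit`.
#' @param ... Unused.
#' @return A tibble with the gene id, dimensions, retained-set count,
#'   convergence state and final ELBO (plus cis-h2 columns when attached).
#' @export
glance.sushie_fit <- function(x, ...) {
  out <- tibble::tibble(
    gene_id = x$gene_id, n_variants = length(x$variant_ids),
    n_populations = length(x$populations),
    n_cs_retained = length(retained_sets(x)),
    n_iter = x$niter, converged = x$converged,
    elbo = x$elbo[x$niter])
  if (!is.null(x$cis_h2)) {
    for (popn in names(x$cis_h2)) {
      out[[paste0("h2_", popn)]] <- x$cis_h2[[popn]]$h2
      out[[paste0("h2_p_", popn)]] <- x$cis_h2[[popn]]$p
    }
  }
  out
}

#' Tidy a gene-level fine-mapping fit
#'
#' @param x A `focus_fit`.
#' @param rho Credible-set coverage used for the membership flag (0.8).
#' @param ... Unused.
#' @return A tibble `gene_id, pip, in_credible_set`.
#' @export
tidy.focus_fit <- function(x, rho = 0.8, ...) {
  cs <- credible_gene_set(x$pip, rho = rho)
  tibble::tibble(gene_id = names(x$pip), pip = unname(x$pip),
                 in_credible_set = names(x$pip) %in% cs)
}

#' One-row summary of a gene-level fine-mapping fit
#' @param x A `focus_fit`.
#' @param ... Unused.
#' @return A tibble with posterior mass accounting and the priors used.
#' @export
glance.focus_fit <- function(x, ...) {
  tibble::tibble(n_genes = length(x$pip), n_configs = nrow(x$configs),
                 null_model_prob = x$null_model_prob,
                 top_pip = max(x$pip), prior_causal = x$prior_causal,
                 prior_variance = x$prior_variance, max_causal = x$max_causal)
}
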