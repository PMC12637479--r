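# Gene-level fine-mapping of TWAS results within LD blocks: Bayesian model
# selection over causal-gene configurations, per population and combined
# across populations.

#' Correlation of genetically predicted expression between genes
#'
#' Entry (g, h) is `W_g' S W_h / sqrt(W_g' S W_g * W_h' S W_h)` — the
#' correlation the prediction weights and LD induce between the two genes'
#' predicted expression. Genes with degenerate predicted variance are
#' excluded (listed in the `"excluded"` attribute).
#'
#' @param weights_by_gene Named list of weight vectors on a shared variant
#'   index (equal lengths), or a variants x genes matrix.
#' @param ld Shared-variant LD matrix (floored to PSD).
#' @param eps Variance threshold for exclusion (default 1e-10).
#' @return Gene x gene correlation matrix (unit diagonal), attribute
#'   `"excluded"` naming dropped genes.
#' @export
grex_correlation <- function(weights_by_gene, ld, eps = 1e-10) {
  W <- if (is.matrix(weights_by_gene)) weights_by_gene else
    do.call(cbind, weights_by_gene)
  ld <- make_psd(as.matrix(ld), floor = 0)
  stop_if_not(nrow(W) == nrow(ld), "weights and ld must share the variant index")
  covm <- crossprod(W, ld %*% W)
  v <- diag(covm)
  bad <- v <= eps
  excluded <- colnames(W)[bad]
  covm <- covm[!bad, !bad, drop = FALSE]
  corr <- stats::cov2cor(covm)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  attr(corr, "excluded") <- excluded
  corr
}

config_key <- function(idx) paste(sort(idx), collapse = ",")

enumerate_configs <- function(m, max_causal) {
  configs <- list(integer(0))
  for (s in seq_len(min(max_causal, m))) {
    configs <- c(configs, combn(m, s, simplify = FALSE))
  }
  configs
}

# log Bayes factor of configuration c against the no-causal-gene model:
# z ~ N(0, V + pv * V[, c] %*% V[c, ]) vs z ~ N(0, V), V = grex correlation.
config_logbf <- function(z, V, cfg, prior_variance) {
  if (length(cfg) == 0) return(0)
  Sc <- V + prior_variance * V[, cfg, drop = FALSE] %*% V[cfg, , drop = FALSE]
  dmvnorm0_log(z, Sc) - dmvnorm0_log(z, V)
}

#' Gene-level fine-mapping posterior inclusion probabilities
#'
#' Enumerates causal-gene configurations up to `max_causal` genes (plus the
#' empty configuration), scores each by the marginal likelihood of the TWAS
#' z-vector under `z ~ N(0, V + prior_variance * V[, c] V[c, ])` with `V`
#' the predicted-expression correlation, applies independent-Bernoulli
#' configuration priors `prior_causal^|c| (1 - prior_causal)^(m - |c|)`, and
#' marginalizes to per-gene PIPs.
#'
#' @param z Named vector of per-gene TWAS z-scores for one LD block.
#' @param grex_corr Matching predicted-expression correlation matrix.
#' @param prior_causal Per-gene prior causal probability; default
#'   `1/max(m, 2)` so the null model keeps prior mass even in single-gene
#'   blocks.
#' @param prior_variance Prior variance of the non-centrality per causal
#'   gene (default 40, an `n * sigma^2`-scale quantity).
#' @param max_causal Maximum configuration size (default 3).
#' @param max_configs Guard on the enumeration size (default 1e5).
#' @return A `focus_fit`: `pip` (named), `null_model_prob`, `configs` tibble
#'   (`config, size, logbf, posterior`).
#' @export
focus_pips <- function(z, grex_corr, prior_causal = NULL, prior_variance = 40,
                       max_causal = 3, max_configs = 1e5) {
  m <- length(z)
  stop_if_not(max_causal >= 1, "max_causal must be >= 1")
  stop_if_not(all(dim(grex_corr) == m), "z and grex_corr must align")
  prior_causal <- prior_causal %||% (1 / max(m, 2))
  n_configs <- sum(choose(m, 0:min(max_causal, m)))
  if (n_configs > max_configs) {
    rlang::abort(sprintf(
      "block of %d genes yields %.0f configurations; shrink max_causal or split the block",
      m, n_configs))
  }
  V <- make_psd(as.matrix(grex_corr), floor = 1e-8)
  diag(V) <- 1
  configs <- enumerate_configs(m, max_causal)
  logbf <- vapply(configs, config_logbf, 0, z = z, V = V,
                  prior_variance = prior_variance)
  sizes <- lengths(configs)
  logprior <- sizes * log(prior_causal) + (m - sizes) * log1p(-prior_causal)
  logpost <- logbf + logprior
  post <- softmax_log(logpost)
  gene_ids <- names(z) %||% paste0("gene", seq_len(m))
  pip <- vapply(seq_len(m), function(g) {
    sum(post[vapply(configs, function(cfg) g %in% cfg, TRUE)])
  }, 0)
  structure(list(
    pip = setNames(pip, gene_ids),
    null_model_prob = post[sizes == 0],
    configs = tibble::tibble(
      config = vapply(configs, config_key, ""),
      size = sizes, logbf = logbf, posterior = post),
    prior_causal = prior_causal, prior_variance = prior_variance,
    max_causal = max_causal, gene_ids = gene_ids), class = "focus_fit")
}

#' @export
print.focus_fit <- function(x, ...) {
  cat(sprintf("<focus_fit> %d genes, %d configurations; null-model posterior %.3f\n",
              length(x$pip), nrow(x$configs), x$null_model_prob))
  invisible(x)
}

#' Multi-population gene-level fine-mapping
#'
#' Combines evidence across populations by multiplying each configuration's
#' Bayes factor over populations (independence of the ancestries given the
#' configuration), normalizing to posteriors, and marginalizing to combined
#' PIPs. Populations missing a gene contribute the Bayes factor of the
#' configuration restricted to their available genes, so missing genes are
#' uninformative rather than penalized.
#'
#' @param per_pop_inputs List (one element per population) of lists with
#'   `z` (named gene z-scores) and `grex_corr`.
#' @param prior_causal,prior_variance,max_causal As in [focus_pips()],
#'   applied on the union gene universe.
#' @return A `focus_fit` with combined `pip` (PIP_ME), `null_model_prob`,
#'   `configs`.
#' @export
ma_focus_pips <- function(per_pop_inputs, prior_causal = NULL,
                          prior_variance = 40, max_causal = 3) {
  stop_if_not(length(per_pop_inputs) >= 1, "empty input")
  universe <- unique(unlist(lapply(per_pop_inputs, function(x) names(x$z))))
  m <- length(universe)
  prior_causal <- prior_causal %||% (1 / max(m, 2))
  configs <- enumerate_configs(m, max_causal)
  sizes <- lengths(configs)
  logbf <- rep(0, length(configs))
  for (pp in per_pop_inputs) {
    gk <- names(pp$z)
    Vk <- make_psd(as.matrix(pp$grex_corr), floor = 1e-8)
    diag(Vk) <- 1
    for (i in seq_along(configs)) {
      cfg_genes <- universe[configs[[i]]]
      local_idx <- match(intersect(cfg_genes, gk), gk)
      logbf[i] <- logbf[i] + config_logbf(pp$z, Vk, local_idx, prior_variance)
    }
  }
  logprior <- sizes * log(prior_causal) + (m - sizes) * log1p(-prior_causal)
  post <- softmax_log(logbf + logprior)
  pip <- vapply(seq_len(m), function(g) {
    sum(post[vapply(configs, function(cfg) g %in% cfg, TRUE)])
  }, 0)
  structure(list(
    pip = setNames(pip, universe), null_model_prob = post[sizes == 0],
    configs = tibble::tibble(
      config = vapply(configs, config_key, ""),
      size = sizes, logbf = logbf, posterior = post),
    prior_causal = prior_causal, prior_variance = prior_variance,
    max_causal = max_causal, gene_ids = universe), class = "focus_fit")
}

#' Credible gene set at a coverage level
#'
#' Ranks genes by normalized posterior mass descending (ties broken by gene
#' id) and returns the smallest prefix reaching cumulative mass `rho`.
#'
#' @param pips_or_posteriors Named non-negative vector (normalized
#'   internally).
#' @param rho Coverage target (default 0.8).
#' @return Character vector of gene ids in the credible set.
#' @export
credible_gene_set <- function(pips_or_posteriors, rho = 0.8) {
  v <- pips_or_posteriors
  ids <- names(v) %||% paste0("gene", seq_along(v))
  stop_if_not(all(v >= 0) && sum(v) > 0, "posteriors must be non-negative, not all zero")
  v <- v / sum(v)
  o <- order(-v, ids)
  cum <- cumsum(v[o])
  sz <- which(cum >= rho - 1e-12)[1]
  ids[o[seq_len(sz)]]
}

#' Flag high-confidence causal genes
#'
#' A gene is flagged when it is TWAS-significant (`q < q_threshold`) and
#' reaches a population-specific PIP above `pip_threshold` in its own
#' population, or a combined multi-population PIP above the threshold.
#'
#' @param twas_q Named per-gene q-values.
#' @param pip_pop Named per-gene population-specific PIPs (NAs allowed).
#' @param pip_me Named per-gene combined PIPs (NAs allowed).
#' @param q_threshold,pip_threshold Defaults 0.05 and 0.8.
#' @return Tibble `gene_id, q, pip_pop, pip_me, high_confidence`.
#' @export
classify_high_confidence <- function(twas_q, pip_pop, pip_me,
                                     q_threshold = 0.05, pip_threshold = 0.8) {
  ids <- names(twas_q) %||% paste0("gene", seq_along(twas_q))
  pp <- pip_pop[ids]; pm <- pip_me[ids]
  pp[is.na(pp)] <- -Inf; pm[is.na(pm)] <- -Inf
  tibble::tibble(
    gene_id = ids, q = unname(twas_q),
    pip_pop = ifelse(is.finite(pp), unname(pp), NA_real_),
    pip_me = ifelse(is.finite(pm), unname(pm), NA_real_),
    high_confidence = !is.na(twas_q) & twas_q < q_threshold &
      (pp > pip_threshold | pm > pip_threshold))
}
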