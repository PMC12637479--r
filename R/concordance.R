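# Cross-population concordance analytics: first-credible-set effect
# correlations, anticorrelation overlaps, credible-set precision metrics,
# and locus-view data extraction.

cs1_of <- function(model) {
  ret <- retained_sets(model)
  if (length(ret) == 0) return(NULL)
  ret[[which.min(vapply(ret, `[[`, 0L, "effect_index"))]]
}

#' Cross-population effect correlation over the first credible set
#'
#' Pearson correlation between two populations' alpha-weighted posterior
#' mean effects over the members of the first retained credible set (the
#' retained set with the lowest effect index — the strongest shared
#' signal). For singleton sets the correlation is undefined; the sign
#' product of the two effects is returned instead, with attribute
#' `"singleton" = TRUE`. Genes with no retained set return NA.
#'
#' @param model A `sushie_fit`.
#' @param pop_a,pop_b Population labels.
#' @return Correlation in \[-1, 1\] (or a sign product for singletons);
#'   `NA` when no credible set was retained.
#' @export
cs1_effect_correlation <- function(model, pop_a, pop_b) {
  cs <- cs1_of(model)
  if (is.null(cs)) return(NA_real_)
  ka <- match(pop_a, model$populations)
  kb <- match(pop_b, model$populations)
  stop_if_not(!is.na(ka) && !is.na(kb), "unknown population label")
  l <- cs$effect_index
  idx <- cs$variant_idx
  ea <- model$alpha[l, idx] * model$post_mean[l, idx, ka]
  eb <- model$alpha[l, idx] * model$post_mean[l, idx, kb]
  if (length(idx) == 1) {
    out <- sign(ea * eb)
    attr(out, "singleton") <- TRUE
    return(out)
  }
  if (sd(ea) == 0 || sd(eb) == 0) return(NA_real_)
  cor(ea, eb)
}

#' Overlap counts of anticorrelated-gene flags across population pairs
#'
#' Venn-style counts for genes flagged (e.g. at r < -0.5) per population
#' pair: per-pair totals, all pairwise intersections, and the intersection
#' across every pair.
#'
#' @param flags_by_pair Named list of logical vectors over the same gene
#'   universe (same length and order).
#' @return List with `per_pair` (named counts), `pairwise` (tibble
#'   `pair_a, pair_b, overlap`), `all_pairs` (count flagged everywhere).
#' @export
anticorrelation_overlap <- function(flags_by_pair) {
  lens <- lengths(flags_by_pair)
  stop_if_not(length(unique(lens)) == 1, "flag vectors must share the gene universe")
  nm <- names(flags_by_pair) %||% paste0("pair", seq_along(flags_by_pair))
  per_pair <- vapply(flags_by_pair, function(f) sum(f, na.rm = TRUE), 0L)
  names(per_pair) <- nm
  combos <- if (length(nm) >= 2) combn(nm, 2, simplify = FALSE) else list()
  pairwise <- purrr::map_dfr(combos, function(cc) {
    tibble::tibble(pair_a = cc[1], pair_b = cc[2],
                   overlap = sum(flags_by_pair[[cc[1]]] & flags_by_pair[[cc[2]]],
                                 na.rm = TRUE))
  })
  all_pairs <- sum(Reduce(`&`, lapply(flags_by_pair, function(f) f %in% TRUE)))
  list(per_pair = per_pair, pairwise = pairwise, all_pairs = all_pairs)
}

#' Credible-set precision metrics over a collection of fits
#'
#' The compactness summaries used to compare fine-mapping designs: median
#' member count over all retained credible sets, mean retained-set count per
#' gene (genes with none count as zero), and the fraction of cis variants
#' with PIP above `pip_threshold`.
#'
#' @param models List of `sushie_fit` objects.
#' @param pip_threshold Default 0.9.
#' @return One-row tibble: `median_cs_size, mean_cs_per_gene,
#'   frac_pip_high, n_genes, n_sets`.
#' @export
cs_precision_metrics <- function(models, pip_threshold = 0.9) {
  sizes <- integer(0)
  n_sets_per_gene <- integer(0)
  pip_all <- numeric(0)
  for (m in models) {
    ret <- retained_sets(m)
    sizes <- c(sizes, vapply(ret, function(s) length(s$variant_idx), 0L))
    n_sets_per_gene <- c(n_sets_per_gene, length(ret))
    pip_all <- c(pip_all, m$pip)
  }
  tibble::tibble(
    median_cs_size = if (length(sizes)) median(sizes) else NA_real_,
    mean_cs_per_gene = mean(n_sets_per_gene),
    frac_pip_high = mean(pip_all > pip_threshold),
    n_genes = length(models), n_sets = length(sizes))
}

#' Long-format locus view of credible-set variants
#'
#' One row per credible-set member variant per population, carrying the
#' fine-mapping quantities (credible set index, alpha, PIP, dense weight)
#' and the harmonized GWAS z-score, ready for plotting with
#' [plot_locus_view()].
#'
#' @param model A `sushie_fit`.
#' @param gwas_by_pop Named list of harmonized `gwas_summary` tibbles.
#' @param variants Optional variant table (`id, pos`) for positions;
#'   positions are otherwise taken from the GWAS rows when available.
#' @param include_background Also emit non-credible-set variants with
#'   `cs = NA` (default FALSE).
#' @return Tibble `variant, population, cs, alpha, pip, weight, gwas_z,
#'   pos`.
#' @export
locus_view_extract <- function(model, gwas_by_pop, variants = NULL,
                               include_background = FALSE) {
  ret <- retained_sets(model)
  p <- length(model$variant_ids)
  cs_idx <- rep(NA_integer_, p)
  alpha_cs <- rep(NA_real_, p)
  for (i in seq_along(ret)) {
    cs_idx[ret[[i]]$variant_idx] <- i
    alpha_cs[ret[[i]]$variant_idx] <- model$alpha[ret[[i]]$effect_index,
                                                  ret[[i]]$variant_idx]
  }
  keep <- if (include_background) seq_len(p) else which(!is.na(cs_idx))
  pos_map <- NULL
  if (!is.null(variants)) pos_map <- setNames(variants$pos, variants$id)
  purrr::map_dfr(names(gwas_by_pop) %||% seq_along(gwas_by_pop), function(popn) {
    g <- gwas_by_pop[[popn]]
    zmap <- setNames(g$z, g$id)
    w <- extract_weights(model, popn, "dense")
    ids <- model$variant_ids[keep]
    pos <- if (!is.null(pos_map)) unname(pos_map[ids]) else {
      pm <- setNames(g$pos, g$id); unname(pm[ids])
    }
    tibble::tibble(variant = ids, population = popn, cs = cs_idx[keep],
                   alpha = alpha_cs[keep], pip = unname(model$pip[keep]),
                   weight = unname(w[keep]), gwas_z = unname(zmap[ids]),
                   pos = pos)
  })
}

#' Full concordance report across a collection of fitted genes
#'
#' Computes, for every gene and population pair, the first-credible-set
#' effect correlation, the anticorrelation flag (r < `anticorr_r`), and the
#' overlap counts, plus the credible-set precision metrics.
#'
#' @param models Named list of `sushie_fit` objects.
#' @param anticorr_r Anticorrelation threshold (default -0.5).
#' @param count_singletons Whether singleton sign products enter the
#'   anticorrelation flags (a sign product of -1 flags the gene when
#'   `TRUE`, the default).
#' @return List with `correlations` (tibble `gene_id, pair, r, singleton`),
#'   `overlap` (from [anticorrelation_overlap()]), `cs_stats`.
#' @export
concordance_report <- function(models, anticorr_r = -0.5,
                               count_singletons = TRUE) {
  pops <- models[[1]]$populations
  pairs <- combn(pops, 2, simplify = FALSE)
  gene_ids <- names(models) %||% vapply(models, `[[`, "", "gene_id")
  correlations <- purrr::map_dfr(seq_along(models), function(i) {
    purrr::map_dfr(pairs, function(pp) {
      r <- cs1_effect_correlation(models[[i]], pp[1], pp[2])
      tibble::tibble(gene_id = gene_ids[i], pair = paste(pp, collapse = "-"),
                     r = as.numeric(r),
                     singleton = isTRUE(attr(r, "singleton")))
    })
  })
  flags <- lapply(split(correlations, correlations$pair), function(d) {
    f <- !is.na(d$r) & d$r < anticorr_r
    if (!count_singletons) f[d$singleton] <- FALSE
    f
  })
  list(correlations = correlations,
       overlap = anticorrelation_overlap(flags),
       cs_stats = cs_precision_metrics(models))
}
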