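# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline facet_grid
#'   facet_wrap labs theme_minimal scale_colour_brewer
#' @export
ggplot2::autoplot

#' PIP plot of a fine-mapping fit
#'
#' Per-variant posterior inclusion probabilities along the locus, coloured
#' by retained credible set.
#'
#' @param object A `sushie_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sushie_fit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$population == object$populations[1])
  d$index <- seq_len(nrow(d))
  d$credible_set <- ifelse(is.na(d$cs), "none", paste0("CS", d$cs))
  ggplot(d, aes(x = .data$index, y = .data$pip, colour = .data$credible_set)) +
    geom_point(size = 1.6) +
    labs(x = "cis variant", y = "PIP",
         title = sprintf("Fine-mapping of %s", object$gene_id),
         colour = "credible set") +
    theme_minimal()
}

#' Association plot of a TWAS table
#'
#' Signed z-scores per gene, faceted by population, with the nominal
#' |z| = 1.96 guides.
#'
#' @param object A `twas_table` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twas_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$z), ]
  d$index <- as.integer(factor(d$gene_id))
  ggplot(d, aes(x = .data$index, y = .data$z)) +
    geom_point(size = 1.2, alpha = 0.8) +
    geom_hline(yintercept = c(-1.96, 1.96), linetype = 2, colour = "grey50") +
    facet_wrap(~ .data$population) +
    labs(x = "gene", y = "TWAS z") +
    theme_minimal()
}

#' Locus view: expression weights and GWAS signal per credible-set variant
#'
#' Renders the long table from [locus_view_extract()] as the usual
#' two-panel locus figure: per-variant eQTL weights (top) and GWAS z-scores
#' (bottom), points coloured by credible set and shaped by population.
#'
#' @param locus_view Tibble from [locus_view_extract()].
#' @return A ggplot object.
#' @export
plot_locus_view <- function(locus_view) {
  d <- tidyr::pivot_longer(locus_view, c("weight", "gwas_z"),
                           names_to = "panel", values_to = "value")
  d$panel <- factor(d$panel, c("weight", "gwas_z"),
                    c("eQTL weight", "GWAS z"))
  d$credible_set <- ifelse(is.na(d$cs), "none", paste0("CS", d$cs))
  ggplot(d, aes(x = .data$pos, y = .data$value,
                colour = .data$credible_set, shape = .data$population,
                size = .data$pip)) +
    geom_point(alpha = 0.85) +
    facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_size_continuous(range = c(1, 4), limits = c(0, 1)) +
    labs(x = "position (bp)", y = NULL, colour = "credible set") +
    theme_minimal()
}
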