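# Harmonization of GWAS summary statistics to a genotype reference panel,
# and conditional-MVN imputation of missing z-scores from panel LD.

complement_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

is_palindromic <- function(ref, alt) {
  ref == complement_allele(alt)
}

#' Swap the allele representation of summary-statistic rows
#'
#' Exchanges ref/alt and negates the z-score for the selected rows; applying
#' it twice restores the original table. Useful for constructing
#' harmonization fixtures.
#'
#' @param gwas Summary-statistics tibble with `ref`, `alt`, `z`.
#' @param idx Row indices to swap (default all).
#' @return The tibble with the representation swapped.
#' @export
swap_allele_representation <- function(gwas, idx = seq_len(nrow(gwas))) {
  r <- gwas$ref[idx]
  gwas$ref[idx] <- gwas$alt[idx]
  gwas$alt[idx] <- r
  gwas$z[idx] <- -gwas$z[idx]
  gwas
}

#' Harmonize GWAS alleles to a reference panel
#'
#' Variants are matched to the panel by chromosome and position. An exact
#' ref/alt match keeps the z-score; a swapped match negates it (so the sign
#' follows the panel's alternate allele); strand-complement matches are
#' resolved by complementing and re-matching. Palindromic (A/T, C/G) SNPs
#' are removed because their strand cannot be resolved from alleles alone;
#' indels, irreconcilable alleles, unmatched positions, and duplicated
#' positions with conflicting alleles are dropped and counted in the
#' attached report.
#'
#' @param gwas Summary-statistics tibble (`chrom, pos, ref, alt, z,
#'   n_cases, n_controls`).
#' @param panel_variants Panel variant table (`id, chrom, pos, ref, alt`).
#' @return Harmonized tibble in the panel's allele convention, with panel
#'   `id`; attribute `"harmonization_report"` tabulates the outcome of every
#'   input row.
#' @export
match_alleles <- function(gwas, panel_variants) {
  pv <- panel_variants
  key <- function(ch, po) paste(ch, po, sep = ":")
  pk <- key(pv$chrom, pv$pos)
  stop_if_not(!anyDuplicated(pk), "panel has duplicated positions")
  gk <- key(gwas$chrom, gwas$pos)
  dup <- gk %in% gk[duplicated(gk)]
  snp <- gwas$ref %in% c("A", "C", "G", "T") & gwas$alt %in% c("A", "C", "G", "T")
  pal <- rep(FALSE, nrow(gwas))
  pal[snp] <- is_palindromic(gwas$ref[snp], gwas$alt[snp])
  j <- match(gk, pk)
  outcome <- rep("unmatched", nrow(gwas))
  outcome[!snp] <- "indel"
  outcome[snp & pal] <- "ambiguous_palindromic"
  outcome[dup] <- "duplicate_position"
  z <- gwas$z
  ref <- gwas$ref; alt <- gwas$alt
  usable <- which(!dup & snp & !pal & !is.na(j))
  for (i in usable) {
    pr <- pv$ref[j[i]]; pa <- pv$alt[j[i]]
    if (ref[i] == pr && alt[i] == pa) {
      outcome[i] <- "exact"
    } else if (ref[i] == pa && alt[i] == pr) {
      outcome[i] <- "swapped"; z[i] <- -z[i]
    } else {
      cr <- unname(complement_allele(ref[i])); ca <- unname(complement_allele(alt[i]))
      if (cr == pr && ca == pa) {
        outcome[i] <- "strand"
      } else if (cr == pa && ca == pr) {
        outcome[i] <- "strand_swapped"; z[i] <- -z[i]
      } else {
        outcome[i] <- "irreconcilable"
      }
    }
  }
  keep <- outcome %in% c("exact", "swapped", "strand", "strand_swapped")
  out <- gwas[keep, , drop = FALSE]
  out$z <- z[keep]
  out$ref <- pv$ref[j[keep]]
  out$alt <- pv$alt[j[keep]]
  out$id <- pv$id[j[keep]]
  report <- dplyr::count(tibble::tibble(outcome = outcome), .data$outcome,
                         name = "n")
  attr(out, "harmonization_report") <- report
  attr(out, "population") <- attr(gwas, "population")
  class(out) <- c("gwas_summary", setdiff(class(out), "gwas_summary"))
  out
}

#' Impute missing GWAS z-scores from panel LD
#'
#' For each panel variant absent from the (harmonized) GWAS, the z-score is
#' imputed by the conditional multivariate-normal rule
#' `z_u = S_uT (S_TT + ridge I)^{-1} z_T` over typed variants T within the
#' window, with predicted quality `r2_u = S_uT (S_TT + ridge I)^{-1} S_Tu`,
#' where S is the panel dosage correlation matrix. Typed rows pass through
#' with `imputed = FALSE`.
#'
#' @param gwas Harmonized summary statistics (panel `id` column present).
#' @param panel The `genotype_panel` providing LD.
#' @param window_bp Half-width of the imputation window around each untyped
#'   variant; `NULL` (default) uses all panel variants, appropriate for
#'   per-gene cis windows.
#' @param ridge Ridge added to the typed-typed correlation block (default
#'   0.1, on the correlation scale).
#' @param min_impute_r2 Optional quality filter: imputed rows below this
#'   predicted r2 are dropped. Off (`NULL`) by default.
#' @param standardize Rescale each imputed z by its predicted standard
#'   deviation so imputed statistics have unit variance like typed ones
#'   (default TRUE). Without this, imputed z-scores carry variance r2 < 1
#'   while downstream LD-based tests assume unit variance, deflating them.
#' @return A `gwas_summary` tibble over all panel variants with columns
#'   `imputed` and `impute_r2` (NA for typed rows; untyped variants with no
#'   typed variant in the window keep `z = NA`).
#' @export
impute_zscores <- function(gwas, panel, window_bp = NULL, ridge = 0.1,
                           min_impute_r2 = NULL, standardize = TRUE) {
  pv <- panel$variants
  typed_idx <- match(gwas$id, pv$id)
  stop_if_not(!any(is.na(typed_idx)),
              "gwas must be harmonized to the panel (unknown variant ids)")
  m <- nrow(pv)
  Xs <- standardize_columns(panel$dosages)
  z_full <- rep(NA_real_, m)
  z_full[typed_idx] <- gwas$z
  imputed <- rep(FALSE, m)
  r2 <- rep(NA_real_, m)
  untyped <- setdiff(seq_len(m), typed_idx)
  typed <- typed_idx[!is.na(gwas$z)]
  if (length(untyped) > 0 && length(typed) > 0) {
    if (is.null(window_bp)) {
      Sig <- crossprod(Xs) / (nrow(Xs) - 1)
      A <- Sig[typed, typed, drop = FALSE] + ridge * diag(length(typed))
      Ainv_z <- solve(A, z_full[typed])
      Ainv_S <- solve(A, Sig[typed, untyped, drop = FALSE])
      z_hat <- drop(crossprod(Sig[typed, untyped, drop = FALSE], Ainv_z))
      r2[untyped] <- pmin(1, pmax(0, colSums(Sig[typed, untyped, drop = FALSE] * Ainv_S)))
      if (standardize) {
        pvar <- colSums(Ainv_S * (Sig[typed, typed, drop = FALSE] %*% Ainv_S))
        z_hat <- ifelse(pvar > 1e-12, z_hat / sqrt(pvar), 0)
      }
      z_full[untyped] <- z_hat
      imputed[untyped] <- TRUE
    } else {
      for (u in untyped) {
        tw <- typed[abs(pv$pos[typed] - pv$pos[u]) <= window_bp &
                      pv$chrom[typed] == pv$chrom[u]]
        if (length(tw) == 0) next
        su <- drop(crossprod(Xs[, u], Xs[, tw, drop = FALSE])) / (nrow(Xs) - 1)
        Stt <- crossprod(Xs[, tw, drop = FALSE]) / (nrow(Xs) - 1)
        A <- Stt + ridge * diag(length(tw))
        w <- solve(A, su)
        z_hat <- sum(w * z_full[tw])
        if (standardize) {
          pvar <- drop(crossprod(w, Stt %*% w))
          z_hat <- if (pvar > 1e-12) z_hat / sqrt(pvar) else 0
        }
        z_full[u] <- z_hat
        r2[u] <- min(1, max(0, sum(w * su)))
        imputed[u] <- TRUE
      }
    }
  }
  out <- tibble::tibble(id = pv$id, chrom = pv$chrom, pos = pv$pos,
                        ref = pv$ref, alt = pv$alt, z = z_full,
                        n_cases = gwas$n_cases[1], n_controls = gwas$n_controls[1],
                        imputed = imputed, impute_r2 = r2)
  if (!is.null(min_impute_r2)) {
    out <- out[!(out$imputed & (is.na(out$impute_r2) | out$impute_r2 < min_impute_r2)), ]
  }
  attr(out, "population") <- attr(gwas, "population")
  class(out) <- c("gwas_summary", class(out))
  out
}
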