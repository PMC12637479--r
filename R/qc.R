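# Genotype and expression quality control.

#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count (no mid-p
#' correction). Computed by the standard recurrence on the hypergeometric-
#' type HWE distribution.
#'
#' @param n_het Number of heterozygotes.
#' @param n_hom1,n_hom2 Homozygote counts (either order).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n_rare_hom <- min(n_hom1, n_hom2)
  n <- n_het + n_hom1 + n_hom2
  rare <- n_het + 2 * n_rare_hom
  if (n == 0 || rare == 0) return(1)
  # heterozygote count has the same parity as the rare allele count
  het_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- numeric(length(het_vals))
  for (i in seq_along(het_vals)) {
    h <- het_vals[i]
    ra <- (rare - h) / 2
    ca <- n - h - ra
    logp[i] <- lfactorial(n) - lfactorial(h) - lfactorial(ra) - lfactorial(ca) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }
  p <- exp(logp - log_sum_exp(logp))
  obs <- which(het_vals == n_het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Filter a genotype panel on missingness, MAC and HWE
#'
#' Sample-level missingness is applied first (so a badly genotyped sample
#' does not drag variants down), then variant-level filters: missingness,
#' minor allele count (on non-missing genotypes; `MAC < mac_min` removed),
#' and the exact HWE test. A per-filter removal report is attached as the
#' `"qc_report"` attribute.
#'
#' @param panel A `genotype_panel`.
#' @param mac_min Minimum minor allele count to retain (default 10).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-8).
#' @param var_miss_max Maximum variant missingness fraction (default 0.1).
#' @param sample_miss_max Maximum sample missingness fraction (default 0.1).
#' @return Filtered `genotype_panel` with attribute `"qc_report"` (a tibble
#'   of removal counts per filter).
#' @export
filter_variants <- function(panel, mac_min = 10, hwe_p_min = 1e-8,
                            var_miss_max = 0.1, sample_miss_max = 0.1) {
  dos <- panel$dosages
  stop_if_not(nrow(dos) > 0 && ncol(dos) > 0, "panel is empty")
  smiss <- rowMeans(is.na(dos))
  keep_s <- smiss <= sample_miss_max
  if (!any(keep_s)) {
    rlang::abort("all samples removed by the sample-missingness filter")
  }
  dos <- dos[keep_s, , drop = FALSE]
  vmiss <- colMeans(is.na(dos))
  alt_count <- colSums(dos, na.rm = TRUE)
  n_obs <- colSums(!is.na(dos))
  mac <- pmin(alt_count, 2 * n_obs - alt_count)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    hwe_exact_p(sum(g == 1, na.rm = TRUE), sum(g == 0, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, 0)
  fail_miss <- vmiss > var_miss_max
  fail_mac <- mac < mac_min
  fail_hwe <- hwe_p < hwe_p_min
  keep_v <- !(fail_miss | fail_mac | fail_hwe)
  report <- tibble::tibble(
    filter = c("sample_missingness", "variant_missingness", "mac", "hwe"),
    removed = c(sum(!keep_s), sum(fail_miss), sum(fail_mac), sum(fail_hwe)))
  out <- panel
  out$dosages <- dos[, keep_v, drop = FALSE]
  out$variants <- panel$variants[keep_v, , drop = FALSE]
  out$samples <- panel$samples[keep_s, , drop = FALSE]
  hap <- attr(panel, "haplotypes")
  if (!is.null(hap)) {
    attr(out, "haplotypes") <- list(h1 = hap$h1[keep_s, keep_v, drop = FALSE],
                                    h2 = hap$h2[keep_s, keep_v, drop = FALSE])
  }
  out$blocks <- NULL  # block indexing is invalidated by variant removal
  attr(out, "qc_report") <- report
  out
}

#' KING-robust pairwise kinship estimates
#'
#' For each sample pair (i, j), with counts over variants non-missing in
#' both: `phi_hat = (N_Aa,Aa - 2 * N_opposite_homozygote) /
#' (N_Aa(i) + N_Aa(j))`, the KING-robust between-family estimator, which is
#' ~0.5 for duplicates/MZ twins, ~0.25 for full sibs, and ~0 for unrelated
#' pairs, without requiring allele-frequency estimates.
#'
#' @param panel A `genotype_panel`.
#' @return Tibble with one row per unordered pair: `id1, id2, n_snps,
#'   kinship` (NA with a warning if a pair has no informative variants).
#' @export
king_kinship <- function(panel) {
  dos <- panel$dosages
  n <- nrow(dos)
  stop_if_not(n >= 2, "need at least 2 samples")
  M <- !is.na(dos)
  A <- (dos == 1) & M; A[!M] <- FALSE
  B0 <- (dos == 0) & M; B0[!M] <- FALSE
  B2 <- (dos == 2) & M; B2[!M] <- FALSE
  Am <- matrix(as.numeric(A), n); B0m <- matrix(as.numeric(B0), n)
  B2m <- matrix(as.numeric(B2), n); Mm <- matrix(as.numeric(M), n)
  n_hh <- Am %*% t(Am)
  n_opp <- B0m %*% t(B2m) + B2m %*% t(B0m)
  het_pair <- Am %*% t(Mm)            # het in i over variants observed in j
  denom <- het_pair + t(het_pair)
  n_both <- Mm %*% t(Mm)
  phi <- (n_hh - 2 * n_opp) / denom
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  out <- tibble::tibble(
    id1 = rownames(dos)[idx[, 1]], id2 = rownames(dos)[idx[, 2]],
    n_snps = as.integer(n_both[idx]), kinship = phi[idx])
  bad <- denom[idx] == 0
  if (any(bad)) {
    out$kinship[bad] <- NA_real_
    rlang::warn(sprintf("%d pair(s) had no informative variants; kinship set NA", sum(bad)))
  }
  out
}

#' Prune related samples with clinically informed retention priority
#'
#' Greedily removes samples until no retained pair has kinship at or above
#' the threshold. Within a related cluster the retention priority (highest
#' kept first) is: cognitively normal individuals of advanced age
#' (`status == 0`, `age >= advanced_age`, ordered by descending age), then
#' diagnosed cases (`status == 1`), then controls carrying an e3/e4 or e4/e4
#' APOE genotype, then everyone else; ties broken by sample id (smaller id
#' kept).
#'
#' @param kinship Pair table from [king_kinship()].
#' @param samples Sample table with columns `id, status, age, apoe`.
#' @param threshold Kinship threshold (default 0.0625, third-degree
#'   relatives).
#' @param advanced_age Age (years) at which a cognitively normal sample
#'   enters the top retention tier (default 80).
#' @return Character vector of retained sample ids.
#' @export
prune_related <- function(kinship, samples, threshold = 0.0625,
                          advanced_age = 80) {
  rel <- kinship[!is.na(kinship$kinship) & kinship$kinship >= threshold, ]
  retained <- samples$id
  if (nrow(rel) == 0) return(retained)
  tier <- ifelse(samples$status == 0 & samples$age >= advanced_age, 1L,
          ifelse(samples$status == 1, 2L,
          ifelse(samples$apoe %in% c("e3/e4", "e4/e4"), 3L, 4L)))
  # removal order: worst tier first, youngest first within tier, largest id first
  prio <- order(tier, -samples$age, samples$id)
  rank <- setNames(seq_along(prio)[order(prio)], samples$id)
  repeat {
    live <- rel[rel$id1 %in% retained & rel$id2 %in% retained, ]
    if (nrow(live) == 0) break
    involved <- unique(c(live$id1, live$id2))
    drop <- involved[which.max(rank[involved])]
    retained <- setdiff(retained, drop)
  }
  retained
}

#' Filter lowly expressed genes on TPM and count support
#'
#' A gene is removed if its TPM is at or below `tpm_level` in more than
#' `tpm_frac` of samples, or if it has counts of at least `count_min` in
#' fewer than `count_frac` of samples. Both fractions and thresholds are
#' exposed because published low-expression rules vary in wording; the
#' defaults require a fifth of samples to support expression.
#'
#' @param expr An `expression_set`.
#' @param tpm_level TPM level at/below which a sample is called unexpressed.
#' @param tpm_frac Maximum tolerated fraction of unexpressed samples (0.20).
#' @param count_min Minimum supporting read count (6).
#' @param count_frac Minimum fraction of samples with supporting counts (0.20).
#' @return Filtered `expression_set` with attribute `"gene_filter_report"`.
#' @export
filter_genes <- function(expr, tpm_level = 0.1, tpm_frac = 0.20,
                         count_min = 6, count_frac = 0.20) {
  stop_if_not(all(dim(expr$tpm) == dim(expr$counts)), "tpm and counts must align")
  fail_tpm <- rowMeans(expr$tpm <= tpm_level) > tpm_frac
  fail_count <- rowMeans(expr$counts >= count_min) < count_frac
  keep <- !(fail_tpm | fail_count)
  out <- expr
  for (f in c("expression", "counts", "tpm")) {
    out[[f]] <- expr[[f]][keep, , drop = FALSE]
  }
  out$genes <- expr$genes[keep, , drop = FALSE]
  attr(out, "truth") <- attr(expr, "truth")
  attr(out, "gene_filter_report") <- tibble::tibble(
    filter = c("low_tpm", "low_counts"),
    removed = c(sum(fail_tpm), sum(fail_count)),
    retained = sum(keep))
  out
}

#' TMM normalization factors and normalized expression
#'
#' Computes trimmed-mean-of-M-values scaling factors (reference sample
#' chosen by upper-quartile proximity to the mean upper quartile; M-values
#' doubly trimmed by log-ratio and absolute intensity; precision-weighted
#' mean; factors rescaled to geometric mean 1) via edgeR's standard
#' implementation, and returns the matrix scaled by the effective library
#' sizes (counts per million on the TMM-effective scale).
#'
#' @param counts Non-negative gene x sample count matrix.
#' @param trim_m Log-ratio trim fraction (default 0.30).
#' @param trim_a Absolute-intensity trim fraction (default 0.05).
#' @return List with `factors` (per-sample scaling factors, geometric mean
#'   1; NA for all-zero samples) and `normalized` (gene x sample matrix).
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero)) rlang::warn("all-zero sample(s): TMM factor undefined, set NA")
  f <- rep(NA_real_, ncol(counts))
  ok <- which(!zero)
  f[ok] <- edgeR::calcNormFactors(counts[, ok, drop = FALSE], method = "TMM",
                                  logratioTrim = trim_m, sumTrim = trim_a)
  eff <- libsize * f
  normalized <- counts
  normalized[, ok] <- sweep(counts[, ok, drop = FALSE], 2, eff[ok], "/") * 1e6
  normalized[, zero] <- NA_real_
  list(factors = f, normalized = normalized)
}

#' Hidden expression factors by Marchenko-Pastur thresholding
#'
#' Standardizes the matrix per gene, computes the eigenvalues of
#' `t(X) %*% X / n_samples` (an n x n matrix whose null eigenvalue bulk
#' follows the Marchenko-Pastur law with aspect ratio
#' `gamma = n_genes / n_samples`), and retains components with eigenvalue
#' above the bulk edge `sigma2 * (1 + sqrt(gamma))^2` (`sigma2 = 1` on
#' standardized data). Retained components are returned as sample scores for
#' use as hidden-factor covariates.
#'
#' @param expr_matrix Gene x sample numeric matrix.
#' @param sigma2 Noise variance for the bulk edge (default 1).
#' @return List with `scores` (sample x retained-component matrix, possibly
#'   0 columns), `eigenvalues`, `threshold`, `n_retained`.
#' @export
mp_hidden_factors <- function(expr_matrix, sigma2 = 1) {
  X <- as.matrix(expr_matrix)
  stop_if_not(ncol(X) >= 3, "need at least 3 samples")
  X <- scale_rows(X)
  G <- nrow(X); n <- ncol(X)
  S <- crossprod(X) / n
  ee <- eigen(S, symmetric = TRUE)
  gamma <- G / n
  thr <- sigma2 * (1 + sqrt(gamma))^2
  k <- sum(ee$values > thr)
  scores <- if (k > 0) {
    sweep(ee$vectors[, seq_len(k), drop = FALSE], 2,
          sqrt(ee$values[seq_len(k)]), "*")
  } else {
    matrix(0, n, 0)
  }
  rownames(scores) <- colnames(expr_matrix)
  list(scores = scores, eigenvalues = ee$values, threshold = thr, n_retained = k)
}
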