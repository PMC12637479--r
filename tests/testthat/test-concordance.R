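test_that("CS1 effect correlation handles identical, negated and singleton effects", {
  alpha <- matrix(0, 1, 5)
  alpha[1, 1:3] <- c(0.5, 0.3, 0.2)
  pm <- array(0, c(1, 5, 2))
  pm[1, 1:3, 1] <- c(1, 2, 3)
  pm[1, 1:3, 2] <- c(1, 2, 3)
  m_same <- mock_sushie_fit(alpha, pm, list(1:3))
  expect_equal(cs1_effect_correlation(m_same, "A", "B"), 1, tolerance = 1e-12)

  pm_neg <- pm
  pm_neg[1, 1:3, 2] <- -pm[1, 1:3, 1]
  m_neg <- mock_sushie_fit(alpha, pm_neg, list(1:3))
  expect_equal(cs1_effect_correlation(m_neg, "A", "B"), -1, tolerance = 1e-12)
  expect_equal(cs1_effect_correlation(m_neg, "B", "A"),
               cs1_effect_correlation(m_neg, "A", "B"), tolerance = 1e-12)

  a1 <- matrix(0, 1, 5); a1[1, 2] <- 1
  pm1 <- array(0, c(1, 5, 2)); pm1[1, 2, ] <- c(0.5, -0.7)
  m_single <- mock_sushie_fit(a1, pm1, list(2))
  r <- cs1_effect_correlation(m_single, "A", "B")
  expect_equal(as.numeric(r), -1)
  expect_true(attr(r, "singleton"))

  m_none <- mock_sushie_fit(alpha, pm, list())
  expect_true(is.na(cs1_effect_correlation(m_none, "A", "B")))
})

test_that("simulated genes at high cross-population correlation recover it", {
  specs <- lapply(quick_specs(), function(s) {
    s$n_panel <- 300L; s$ld_decay <- 0.02; s  # tight LD: multi-member sets
  })
  rs <- vapply(1:10, function(i) {
    loc <- simulate_locus(specs, n_genes = 1, n_variants = 40,
                          block_sizes = c(20, 20), n_causal = 1,
                          cross_pop_corr = 0.9, cis_h2 = 0.5, seed = 150 + i,
                          covariate_effects = matrix(0, 2, 1))
    f <- fit_locus(loc, L = 3)[[1]]
    as.numeric(cs1_effect_correlation(f, "NHW", "AA"))
  }, 0)
  expect_gt(mean(rs, na.rm = TRUE), 0.8)
  expect_lte(mean(rs, na.rm = TRUE), 1)
})

test_that("anticorrelation flags are directional in the generating correlation", {
  specs <- lapply(quick_specs(180), function(s) { s$ld_decay <- 0.02; s })
  frac_flagged <- function(rho, seeds) {
    flags <- vapply(seeds, function(i) {
      loc <- simulate_locus(specs, n_genes = 1, n_variants = 30,
                            block_sizes = c(15, 15), cross_pop_corr = rho,
                            cis_h2 = 0.5, seed = i,
                            covariate_effects = matrix(0, 2, 1))
      f <- fit_locus(loc, L = 2)[[1]]
      r <- cs1_effect_correlation(f, "NHW", "AA")
      !is.na(r) && as.numeric(r) < -0.5
    }, TRUE)
    mean(flags)
  }
  expect_lt(frac_flagged(0.9, 160 + 1:12), 0.1)
  expect_gt(frac_flagged(-0.9, 180 + 1:12), 0.8)
})

test_that("anticorrelation overlap counting matches set arithmetic", {
  none <- anticorrelation_overlap(list(p1 = rep(FALSE, 10), p2 = rep(FALSE, 10),
                                       p3 = rep(FALSE, 10)))
  expect_true(all(none$per_pair == 0))
  expect_true(all(none$pairwise$overlap == 0))
  expect_equal(none$all_pairs, 0)

  one <- rep(FALSE, 10); one[4] <- TRUE
  allp <- anticorrelation_overlap(list(p1 = one, p2 = one, p3 = one))
  expect_equal(allp$all_pairs, 1)
  expect_true(all(allp$pairwise$overlap == 1))

  set.seed(151)
  n <- 4000
  fl <- list(p1 = runif(n) < 0.3, p2 = runif(n) < 0.3, p3 = runif(n) < 0.3)
  ov <- anticorrelation_overlap(fl)
  bounds <- qbinom(c(0.005, 0.995), n, 0.09)
  expect_true(all(ov$pairwise$overlap >= bounds[1] &
                    ov$pairwise$overlap <= bounds[2]))
})

test_that("credible-set precision metrics match hand enumeration", {
  a <- matrix(0, 1, 10); a[1, 1:4] <- 0.25
  pm <- array(0.1, c(1, 10, 2))
  one_set <- mock_sushie_fit(a, pm, list(1:4))
  m1 <- cs_precision_metrics(list(one_set))
  expect_equal(m1$median_cs_size, 4)
  expect_equal(m1$mean_cs_per_gene, 1)

  a2 <- matrix(0, 2, 10); a2[1, 1:2] <- 0.5; a2[2, 3:8] <- 1 / 6
  two_sets <- mock_sushie_fit(a2, array(0.1, c(2, 10, 2)), list(1:2, 3:8))
  no_sets <- mock_sushie_fit(a, pm, list())
  m2 <- cs_precision_metrics(list(two_sets, no_sets))
  expect_equal(m2$median_cs_size, 4)     # sizes 2 and 6
  expect_equal(m2$mean_cs_per_gene, 1)   # (2 + 0) / 2
  # gene ordering does not matter
  m2r <- cs_precision_metrics(list(no_sets, two_sets))
  expect_equal(m2, m2r[, names(m2)])
})

test_that("locus view extraction produces one row per member per population", {
  specs <- quick_specs(100)
  loc <- simulate_locus(specs, n_genes = 1, n_variants = 30, cis_h2 = 0.5,
                        seed = 152, covariate_effects = matrix(0, 2, 1))
  for (p in names(loc$panels)) {  # no palindromic SNPs: keep every variant
    loc$panels[[p]]$variants$ref <- "A"
    loc$panels[[p]]$variants$alt <- "G"
  }
  f <- fit_locus(loc, L = 2)[[1]]
  gwas <- lapply(names(loc$panels), function(p) {
    g <- simulate_gwas(loc$panels[[p]], loc$arch, specs[[p]], seed = 153,
                       mask_frac = 0, flip_frac = 0)
    match_alleles(g, loc$panels[[p]]$variants)
  })
  names(gwas) <- names(loc$panels)
  lv <- locus_view_extract(f, gwas, variants = loc$panels$NHW$variants)
  n_members <- sum(vapply(Filter(function(s) s$retained, f$sets),
                          function(s) length(s$variant_idx), 0L))
  expect_equal(nrow(lv), 3 * n_members)
  expect_true(all(c("variant", "population", "cs", "alpha", "pip", "weight",
                    "gwas_z", "pos") %in% names(lv)))
  # a variant absent from the GWAS keeps its row with missing z
  gwas2 <- gwas
  drop_id <- lv$variant[1]
  gwas2$NHW <- gwas2$NHW[gwas2$NHW$id != drop_id, ]
  lv2 <- locus_view_extract(f, gwas2, variants = loc$panels$NHW$variants)
  expect_equal(nrow(lv2), nrow(lv))
  expect_true(is.na(lv2$gwas_z[lv2$variant == drop_id &
                                 lv2$population == "NHW"]))
  # round-trip through TSV preserves the table
  tmp <- tempfile(fileext = ".tsv")
  readr::write_tsv(lv, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(lv), tolerance = 1e-12)
})

test_that("the concordance report assembles correlations, overlaps and stats", {
  specs <- quick_specs(120)
  models <- lapply(1:3, function(i) {
    loc <- simulate_locus(specs, n_genes = 1, n_variants = 25, cis_h2 = 0.5,
                          seed = 170 + i, covariate_effects = matrix(0, 2, 1))
    fit_locus(loc, L = 2)[[1]]
  })
  names(models) <- paste0("gene", 1:3)
  rep_out <- concordance_report(models)
  expect_equal(nrow(rep_out$correlations), 9)  # 3 genes x 3 pairs
  expect_true(all(rep_out$correlations$r >= -1 & rep_out$correlations$r <= 1,
                  na.rm = TRUE))
  expect_s3_class(rep_out$cs_stats, "tbl_df")
})
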