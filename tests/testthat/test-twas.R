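random_psd_corr <- function(p) {
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.1
  stats::cov2cor(S)
}

test_that("twas_zscore matches closed forms and brute-force arithmetic", {
  ld <- random_psd_corr(5)
  z <- rnorm(5)
  w <- c(0, 0, 1, 0, 0)
  expect_equal(twas_zscore(w, z, ld), z[3], tolerance = 1e-12)

  expect_equal(twas_zscore(c(1, 1), c(1, 1), diag(2)), sqrt(2),
               tolerance = 1e-12)

  set.seed(110)
  for (i in 1:10) {
    p <- sample(5:50, 1)
    w <- rnorm(p); z <- rnorm(p); ld <- random_psd_corr(p)
    brute <- sum(w * z) / sqrt(drop(t(w) %*% ld %*% w))
    expect_equal(twas_zscore(w, z, ld), brute, tolerance = 1e-10)
  }
})

test_that("twas_zscore is permutation- and scale-invariant", {
  set.seed(111)
  p <- 20
  w <- rnorm(p); z <- rnorm(p); ld <- random_psd_corr(p)
  z0 <- twas_zscore(w, z, ld)
  perm <- sample(p)
  expect_equal(twas_zscore(w[perm], z[perm], ld[perm, perm]), z0,
               tolerance = 1e-10)
  expect_equal(twas_zscore(3.7 * w, z, ld), z0, tolerance = 1e-10)
  expect_equal(twas_zscore(-2 * w, z, ld), -z0, tolerance = 1e-10)
  expect_true(is.na(twas_zscore(rep(0, p), z, ld)))
})

test_that("run_twas records skip reasons and BH q-values", {
  spec <- population_spec("NHW", 150, 500, 500)
  panel <- simulate_genotypes(spec, 30, rep(30, 1), seed = 112)
  g <- simulate_gwas(panel, list(), spec, seed = 113, mask_frac = 0, flip_frac = 0)
  h <- match_alleles(g, panel$variants)
  db <- dplyr::bind_rows(
    tibble::tibble(gene_id = "ok", id = panel$variants$id[1:5],
                   weight = c(1, 0.5, 0, 0, -0.2)),
    tibble::tibble(gene_id = "zero", id = panel$variants$id[6:8], weight = 0),
    tibble::tibble(gene_id = "nooverlap", id = "var_nowhere", weight = 1))
  out <- run_twas(db, h, panel, "sparse")
  expect_equal(out$skipped_reason[out$gene_id == "zero"], "all_zero_weights")
  expect_equal(out$skipped_reason[out$gene_id == "nooverlap"],
               "no_overlapping_variants")
  ok_row <- out[out$gene_id == "ok", ]
  expect_false(is.na(ok_row$z))
  expect_equal(ok_row$p, 2 * pnorm(-abs(ok_row$z)), tolerance = 1e-12)
  expect_equal(ok_row$n_weights_nonzero, 3L)
  expect_false(is.na(ok_row$q))
})

test_that("genes in the MHC are excluded from testing", {
  spec <- population_spec("NHW", 100, 500, 500)
  panel <- simulate_genotypes(spec, 10, rep(10, 1), seed = 114, chrom = "6",
                              start_bp = 25e6)
  g <- simulate_gwas(panel, list(), spec, seed = 115, mask_frac = 0, flip_frac = 0)
  h <- match_alleles(g, panel$variants)
  db <- tibble::tibble(gene_id = "mhc_gene", id = panel$variants$id[1:3],
                       weight = 1)
  gi <- tibble::tibble(gene_id = "mhc_gene", chrom = "6",
                       start = 25.2e6, end = 25.3e6)
  out <- run_twas(db, h, panel, "dense", gene_info = gi)
  expect_equal(nrow(out), 0)
})

test_that("genomic lambda follows its definition and null calibration", {
  z_cal <- sqrt(qchisq(0.5, 1)) * c(rep(0.9, 10), rep(1, 11), rep(1.1, 10))
  z_cal[11:21] <- sqrt(qchisq(0.5, 1))
  expect_equal(genomic_lambda(z_cal), 1, tolerance = 1e-10)
  expect_equal(genomic_lambda(sqrt(2) * z_cal), 2, tolerance = 1e-10)
  set.seed(116)
  lam <- genomic_lambda(rnorm(10000))
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
  expect_error(genomic_lambda(rnorm(10)), "at least 20")
})

test_that("BH q-values follow the step-up hand calculation", {
  out <- bh_qvalues(c(0.01, 0.02, 0.03))
  expect_equal(out$q, c(0.03, 0.03, 0.03), tolerance = 1e-12)
  one <- bh_qvalues(0.04)
  expect_equal(one$q, 0.04)
  expect_true(one$significant)
  expect_false(any(bh_qvalues(rep(1, 5))$significant))
})

test_that("dense-sparse comparison surfaces containment and tagging divergence", {
  spec <- population_spec("NHW", 200, 2000, 2000, ld_decay = 0.05)
  panel <- simulate_genotypes(spec, 40, rep(20, 2), seed = 117)
  panel$variants$ref <- "A"; panel$variants$alt <- "G"  # no palindromic drops
  # strong GWAS signal at variant 30 (block 2), none at the eQTL (variant 5)
  n_eff <- effective_n(2000, 2000)
  lambda <- rep(0, 40); lambda[30] <- 8 / sqrt(n_eff)
  g <- simulate_gwas(panel, list(), spec, seed = 122, mask_frac = 0,
                     flip_frac = 0, lambda = lambda)
  h <- match_alleles(g, panel$variants)
  ids <- panel$variants$id
  # dense model: real weight at the credible-set eQTL plus a small tagging
  # weight on the GWAS variant outside the set; sparse zeroes the tag
  dense_db <- tibble::tibble(gene_id = "g1", id = ids,
                             weight = replace(rep(0, 40), c(5, 30), c(1, 0.4)))
  sparse_db <- tibble::tibble(gene_id = "g1", id = ids,
                              weight = replace(rep(0, 40), 5, 1))
  td <- run_twas(dense_db, h, panel, "dense")
  ts <- run_twas(sparse_db, h, panel, "sparse")
  cmp <- compare_dense_sparse(td, ts)
  expect_gt(abs(cmp$z_dense), 2)
  expect_lt(abs(cmp$z_sparse), 1.5)
  expect_gt(cmp$abs_diff, 1)

  # no-retained-set gene: sparse z missing, dense present
  db0 <- tibble::tibble(gene_id = "g0", id = ids[1:3], weight = c(1, 1, 0))
  db0s <- tibble::tibble(gene_id = "g0", id = ids[1:3], weight = 0)
  cmp0 <- compare_dense_sparse(run_twas(db0, h, panel, "dense"),
                               run_twas(db0s, h, panel, "sparse"))
  expect_false(is.na(cmp0$z_dense))
  expect_true(is.na(cmp0$z_sparse))
})

test_that("weights independent of a null GWAS give calibrated type-I error", {
  spec <- population_spec("NHW", 150, 1000, 1000)
  panel <- simulate_genotypes(spec, 40, rep(20, 2), seed = 119)
  set.seed(120)
  hits <- 0; total <- 0
  for (r in 1:40) {
    g <- simulate_gwas(panel, list(), spec, seed = 1200 + r, mask_frac = 0,
                       flip_frac = 0)
    h <- match_alleles(g, panel$variants)
    db <- purrr::map_dfr(1:50, function(j) {
      w <- rep(0, 40); w[sample(40, 3)] <- rnorm(3)
      tibble::tibble(gene_id = paste0("g", j), id = panel$variants$id,
                     weight = w)
    })
    out <- run_twas(db, h, panel, "dense")
    hits <- hits + sum(abs(out$z) > 1.96, na.rm = TRUE)
    total <- total + sum(!is.na(out$z))
  }
  rate <- hits / total
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})
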