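test_that("residualize centers, standardizes and orthogonalizes", {
  set.seed(50)
  y <- rnorm(200, 5, 2)
  r0 <- residualize(y, matrix(1, 200, 1))
  expect_equal(mean(r0), 0, tolerance = 1e-12)
  expect_equal(sd(r0), 1, tolerance = 1e-12)
  expect_equal(cor(r0, y), 1, tolerance = 1e-12)

  X <- cbind(1, matrix(rnorm(200 * 5), 200, 5))
  r <- residualize(rnorm(200), X)
  expect_lt(max(abs(crossprod(X, r))), 1e-8)

  y_lin <- drop(X %*% c(1, 2, -1, 0.5, 3, -2))
  r_deg <- residualize(y_lin, X)
  expect_true(attr(r_deg, "degenerate"))
  expect_equal(unclass(r_deg), rep(0, 200), ignore_attr = TRUE)

  expect_warning(residualize(rnorm(200), cbind(1, X[, 2], X[, 2])),
                 "collinear")
  expect_error(residualize(rnorm(10), matrix(rnorm(20), 10, 2)), "intercept")
})

test_that("credible sets are the smallest coverage-reaching prefixes", {
  one_hot <- matrix(c(0, 0, 1, 0), 1)
  s1 <- make_credible_sets(one_hot)
  expect_equal(s1[[1]]$variant_idx, 3)

  unif <- matrix(rep(0.1, 10), 1)
  expect_length(make_credible_sets(unif, coverage = 0.9)[[1]]$variant_idx, 9)

  a <- matrix(c(0.5, 0.3, 0.15, 0.05), 1)
  s3 <- make_credible_sets(a, coverage = 0.9)
  expect_equal(sort(s3[[1]]$variant_idx), 1:3)
  expect_equal(s3[[1]]$coverage_attained, 0.95, tolerance = 1e-12)
})

test_that("purity is the sample-size-weighted minimum absolute correlation", {
  # exact correlations by construction: x2 = r*x1 + sqrt(1-r^2)*z, z orth x1
  n <- 8
  x1 <- scale(rep(c(1, -1), 4))[, 1]
  z <- scale(rep(c(1, 1, -1, -1), 2))[, 1]
  make_X <- function(r) cbind(x1, r * x1 + sqrt(1 - r^2) * z)
  sets <- list(list(effect_index = 1L, variant_idx = 1:2,
                    variant_ids = c("a", "b"), coverage_attained = 0.95))
  out <- purity_filter(sets, list(A = make_X(0.8), B = make_X(0.2)),
                       n_by_pop = c(300, 100))
  expect_equal(out[[1]]$purity, (300 * 0.8 + 100 * 0.2) / 400, tolerance = 1e-10)
  expect_true(out[[1]]$retained)

  low <- purity_filter(sets, list(A = make_X(0.3), B = make_X(0.3)),
                       n_by_pop = c(100, 100))
  expect_equal(low[[1]]$purity, 0.3, tolerance = 1e-10)
  expect_false(low[[1]]$retained)

  singleton <- list(list(effect_index = 1L, variant_idx = 2,
                         variant_ids = "b", coverage_attained = 1))
  s_out <- purity_filter(singleton, list(A = make_X(0)), n_by_pop = 100)
  expect_equal(s_out[[1]]$purity, 1)
})

test_that("the ELBO is monotone and alpha/pip identities hold", {
  loc <- simulate_locus(quick_specs(120), n_genes = 1, n_variants = 50,
                        cis_h2 = 0.4, seed = 51,
                        covariate_effects = matrix(0, 2, 1))
  f <- fit_locus(loc, L = 5)[[1]]
  expect_true(all(diff(f$elbo) > -1e-6))
  expect_equal(rowSums(f$alpha), rep(1, 5), tolerance = 1e-8)
  kept <- which(f$effect_lbf > 3 * 4 / 2)
  pip_re <- 1 - apply(1 - f$alpha[kept, , drop = FALSE], 2, prod)
  expect_equal(unname(f$pip), pip_re, tolerance = 1e-10)
  for (C in f$prior_corr) {
    expect_equal(C, t(C), tolerance = 1e-8)
    expect_equal(unname(diag(C)), rep(1, 3), tolerance = 1e-8)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("permuting variant order permutes alpha, PIPs and weights identically", {
  loc <- simulate_locus(quick_specs(100), n_genes = 1, n_variants = 40,
                        cis_h2 = 0.4, seed = 52,
                        covariate_effects = matrix(0, 2, 1))
  X <- lapply(loc$panels, `[[`, "dosages")
  y <- lapply(names(X), function(p) {
    residualize(loc$expr[[p]]$expression[1, ],
                cbind(1, loc$expr[[p]]$covariates))
  })
  names(y) <- names(X)
  f1 <- fit_sushie(X, y, L = 3)
  set.seed(53)
  perm <- sample(40)
  Xp <- lapply(X, function(m) m[, perm])
  f2 <- fit_sushie(Xp, y, L = 3)
  expect_equal(f2$alpha, f1$alpha[, perm], tolerance = 1e-6)
  expect_equal(unname(f2$pip), unname(f1$pip[perm]), tolerance = 1e-6)
  expect_equal(unname(extract_weights(f2, "NHW", "dense")),
               unname(extract_weights(f1, "NHW", "dense")[perm]),
               tolerance = 1e-6)
})

test_that("with one population the fit matches an independent univariate oracle", {
  specs <- quick_specs(250)["NHW"]
  diffs <- vapply(1:20, function(i) {
    loc <- simulate_locus(specs, n_genes = 1, n_variants = 60,
                          cis_h2 = 0.35, seed = 60 + i,
                          covariate_effects = matrix(0, 2, 1))
    y <- residualize(loc$expr$NHW$expression[1, ],
                     cbind(1, loc$expr$NHW$covariates))
    f <- fit_sushie(list(NHW = loc$panels$NHW$dosages), list(NHW = y), L = 10)
    ref <- susie_ref_pip(loc$panels$NHW$dosages, y, L = 10)
    max(abs(f$pip - ref))
  }, 0)
  expect_lt(max(diffs), 0.02)
})

test_that("the estimated prior correlation recovers the generating value", {
  specs <- lapply(quick_specs(), function(s) { s$n_panel <- 400L; s })
  r_hat <- vapply(1:12, function(i) {
    loc <- simulate_locus(specs, n_genes = 1, n_variants = 50,
                          cis_h2 = 0.5, cross_pop_corr = 0.9, seed = 70 + i,
                          covariate_effects = matrix(0, 2, 1))
    f <- fit_locus(loc, L = 3)[[1]]
    ret <- Filter(function(s) s$retained, f$sets)
    if (length(ret) == 0) return(NA_real_)
    C <- f$prior_corr[[ret[[1]]$effect_index]]
    mean(C[upper.tri(C)])
  }, 0)
  expect_lt(abs(mean(r_hat, na.rm = TRUE) - 0.9), 0.1)
})

test_that("cis-heritability REML is calibrated and recovers the truth", {
  # null: median LRT p near 0.5 (boundary mixture)
  pvals <- vapply(1:200, function(i) {
    set.seed(80 + i)
    X <- matrix(rbinom(100 * 30, 2, 0.3), 100, 30)
    cis_heritability(X, rnorm(100))$p
  }, 0)
  expect_gt(median(pvals), 0.3)
  expect_lt(median(pvals), 0.7)

  # recovery at h2 = 0.5
  h2s <- vapply(1:50, function(i) {
    set.seed(300 + i)
    n <- 500; p <- 100
    X <- scale(matrix(rbinom(n * p, 2, 0.3), n, p))
    b <- rnorm(p, 0, sqrt(0.5 / p))
    g <- drop(X %*% b)
    y <- g + rnorm(n, 0, sqrt(var(g)))
    cis_heritability(X, y)$h2
  }, 0)
  expect_gt(mean(h2s), 0.4)
  expect_lt(mean(h2s), 0.6)

  # noiseless limit
  set.seed(90)
  Xn <- matrix(rbinom(200 * 20, 2, 0.4), 200, 20)
  fit <- cis_heritability(Xn, 2 * scale(Xn[, 3])[, 1])
  expect_gt(fit$h2, 0.95)
})

test_that("weight extraction follows alpha and credible-set membership", {
  alpha <- matrix(0, 1, 4); alpha[1, 2] <- 1
  pm <- array(0, c(1, 4, 2)); pm[1, 2, ] <- c(0.7, -0.3)
  m <- mock_sushie_fit(alpha, pm, list(2))
  expect_equal(unname(extract_weights(m, "A", "dense")), c(0, 0.7, 0, 0))
  expect_equal(unname(extract_weights(m, "B", "dense")), c(0, -0.3, 0, 0))
  expect_equal(extract_weights(m, "A", "sparse"),
               extract_weights(m, "A", "dense"))
  expect_error(extract_weights(m, "Z", "dense"), "unknown population")

  # no retained sets: sparse weights all zero
  m2 <- mock_sushie_fit(alpha, pm, list())
  expect_equal(unname(extract_weights(m2, "A", "sparse")), rep(0, 4))
  expect_false(all(extract_weights(m2, "A", "dense") == 0))
})

test_that("dense and sparse weights agree when alpha mass sits in retained sets", {
  loc <- simulate_locus(quick_specs(200), n_genes = 1, n_variants = 40,
                        cis_h2 = 0.5, seed = 95,
                        covariate_effects = matrix(0, 2, 1))
  f <- fit_locus(loc, L = 3)[[1]]
  ret <- Filter(function(s) s$retained, f$sets)
  mass <- sum(f$alpha[ret[[1]]$effect_index, ret[[1]]$variant_idx])
  expect_gt(mass, 1 - 1e-4)
  # out-of-set weight comes only from parked (floored) effects and is
  # numerically negligible relative to the in-set weights
  expect_lt(max(abs(extract_weights(f, "NHW", "dense") -
                      extract_weights(f, "NHW", "sparse"))),
            1e-4 * max(abs(extract_weights(f, "NHW", "dense"))))
  expect_gt(weight_mass_containment(f, "NHW"), 0.9)
})
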