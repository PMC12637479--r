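# Direct-enumeration oracle for the exact HWE test: probability of every
# heterozygote count conditional on the allele counts, two-sided sum.
hwe_oracle <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  rare <- n_het + 2 * min(n_hom1, n_hom2)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  pr <- vapply(hets, function(h) {
    ra <- (rare - h) / 2
    exp(lfactorial(n) - lfactorial(h) - lfactorial(ra) -
          lfactorial(n - h - ra) + h * log(2) +
          lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n))
  }, 0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == n_het] * (1 + 1e-12)])
}

test_that("exact HWE p-values match direct enumeration", {
  cases <- list(c(50, 25, 25), c(0, 50, 50), c(10, 80, 10), c(3, 90, 7),
                c(40, 40, 20))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  expect_equal(hwe_exact_p(50, 25, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_p(0, 50, 50), 1e-8)
})

make_panel_with_genotypes <- function(geno_cols) {
  panel_from_dosages(do.call(cbind, geno_cols))
}

test_that("variant filters remove low-MAC and HWE-violating variants", {
  n <- 100
  low_mac <- c(rep(1, 5), rep(0, 95))            # MAC 5
  equil <- c(rep(0, 25), rep(1, 50), rep(2, 25)) # exactly in HWE
  no_het <- c(rep(0, 50), rep(2, 50))            # extreme HWE violation
  common <- rep_len(c(0, 1, 1, 2), n)            # well-behaved
  panel <- make_panel_with_genotypes(list(low_mac, equil, no_het, common))
  out <- filter_variants(panel)
  kept <- colnames(out$dosages)
  expect_false(colnames(panel$dosages)[1] %in% kept)  # MAC below 10
  expect_true(colnames(panel$dosages)[2] %in% kept)   # HWE p = 1
  expect_false(colnames(panel$dosages)[3] %in% kept)  # HWE p < 1e-8
  rep_tab <- attr(out, "qc_report")
  expect_equal(rep_tab$removed[rep_tab$filter == "mac"], 1)
  expect_gte(rep_tab$removed[rep_tab$filter == "hwe"], 1)
})

test_that("sample-missingness is applied before variant filters and the filter is idempotent", {
  set.seed(21)
  dos <- matrix(rbinom(60 * 40, 2, 0.3), 60, 40)
  dos[1, 1:30] <- NA  # sample 1: 75% missing
  panel <- make_panel_with_genotypes(lapply(seq_len(40), function(j) dos[, j]))
  out <- filter_variants(panel)
  expect_false("s001" %in% rownames(out$dosages))
  twice <- filter_variants(out)
  expect_equal(out$dosages, twice$dosages)
  expect_equal(out$variants, twice$variants)
})

test_that("all samples removed raises an explicit error", {
  dos <- matrix(NA_integer_, 4, 3)
  dos[, 1] <- 1L
  panel <- make_panel_with_genotypes(lapply(1:3, function(j) dos[, j]))
  expect_error(filter_variants(panel), "all samples removed")
})

test_that("KING kinship is near zero for unrelated samples and symmetric", {
  spec <- population_spec("NHW", 30, 100, 100, ld_decay = 3)
  panel <- simulate_genotypes(spec, 5000, rep(100, 50), seed = 22)
  kin <- king_kinship(panel)
  first_pair <- kin$kinship[kin$id1 == "NHW_0001" & kin$id2 == "NHW_0002"]
  expect_lt(abs(first_pair), 0.03)
  expect_lt(abs(mean(kin$kinship)), 0.03)
  expect_gt(mean(abs(kin$kinship) < 0.03), 0.9)
  # symmetry: reversing the sample order leaves pair estimates unchanged
  panel_rev <- panel
  panel_rev$dosages <- panel$dosages[rev(seq_len(nrow(panel$dosages))), ]
  kin_rev <- king_kinship(panel_rev)
  key <- function(k) paste(pmin(k$id1, k$id2), pmax(k$id1, k$id2))
  m <- match(key(kin), key(kin_rev))
  expect_equal(kin$kinship, kin_rev$kinship[m], tolerance = 1e-12)
})

test_that("relatedness pruning honors the clinical retention priority", {
  kin_none <- tibble::tibble(id1 = "a", id2 = "b", n_snps = 100L, kinship = 0.01)
  samples <- tibble::tibble(id = c("a", "b"), status = c(1L, 0L),
                            age = c(70, 70), apoe = c("e3/e3", "e3/e3"))
  expect_setequal(prune_related(kin_none, samples), c("a", "b"))

  # duplicate pair: AD case outranks a young e3/e3 control
  kin_dup <- tibble::tibble(id1 = "case", id2 = "ctrl", n_snps = 100L,
                            kinship = 0.5)
  samples2 <- tibble::tibble(id = c("case", "ctrl"), status = c(1L, 0L),
                             age = c(72, 70), apoe = c("e3/e3", "e3/e3"))
  expect_identical(prune_related(kin_dup, samples2), "case")

  # an aged cognitively normal sample outranks the case
  samples3 <- tibble::tibble(id = c("case", "ctrl"), status = c(1L, 0L),
                             age = c(72, 85), apoe = c("e3/e3", "e3/e3"))
  expect_identical(prune_related(kin_dup, samples3), "ctrl")

  # an e4-carrying control outranks an e3/e3 control
  kin_cc <- tibble::tibble(id1 = "c1", id2 = "c2", n_snps = 100L, kinship = 0.3)
  samples4 <- tibble::tibble(id = c("c1", "c2"), status = c(0L, 0L),
                             age = c(70, 71), apoe = c("e3/e4", "e3/e3"))
  expect_identical(prune_related(kin_cc, samples4), "c1")
})

test_that("a triangle of mutually related samples keeps exactly one, under any removal order", {
  ids <- c("a", "b", "c")
  kin <- tibble::tibble(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                        n_snps = 100L, kinship = 0.3)
  samples <- tibble::tibble(id = ids, status = c(1L, 0L, 0L),
                            age = c(70, 65, 75), apoe = "e3/e3")
  kept <- prune_related(kin, samples)
  expect_length(kept, 1)
  # oracle: greedy removal from any starting order always ends with one sample
  for (perm in list(ids, rev(ids), c("b", "a", "c"))) {
    left <- perm
    repeat {
      live <- kin[kin$id1 %in% left & kin$id2 %in% left, ]
      if (nrow(live) == 0) break
      left <- setdiff(left, left[max(match(unique(c(live$id1, live$id2)), left))])
    }
    expect_length(left, 1)
  }
  # the retained pairings never violate the threshold
  live <- kin[kin$id1 %in% kept & kin$id2 %in% kept, ]
  expect_true(all(live$kinship < 0.0625))
})

test_that("gene filters match hand enumeration on a toy matrix", {
  # 5 genes x 10 samples; thresholds: tpm_level 1, fractions 0.2, counts >= 6
  counts <- rbind(
    g1 = rep(10, 10),                 # passes both
    g2 = rep(0, 10),                  # fails both
    g3 = c(rep(10, 9), 0),           # counts >= 6 in 90% -> passes counts
    g4 = c(rep(10, 1), rep(0, 9)),   # counts >= 6 in 10% < 20% -> fails
    g5 = rep(10, 10))
  tpm <- rbind(
    g1 = rep(5, 10),
    g2 = rep(0, 10),
    g3 = rep(5, 10),
    g4 = rep(5, 10),
    g5 = c(rep(0.5, 3), rep(5, 7)))  # tpm <= 1 in 30% > 20% -> fails
  es <- structure(list(counts = counts, tpm = tpm, expression = counts,
                       covariates = matrix(0, 10, 1),
                       genes = tibble::tibble(gene_id = rownames(counts)),
                       samples = tibble::tibble(id = paste0("s", 1:10)),
                       population = "X"), class = "expression_set")
  out <- filter_genes(es, tpm_level = 1)
  expect_setequal(out$genes$gene_id, c("g1", "g3"))
})

test_that("TMM factors behave as the M-value construction requires", {
  set.seed(30)
  base <- matrix(rpois(200 * 4, 50), 200, 4)
  same <- tmm_normalize(cbind(base[, 1], base[, 1]))
  expect_equal(same$factors, c(1, 1), tolerance = 1e-12)
  depth <- tmm_normalize(cbind(base[, 1], 2 * base[, 1]))
  expect_equal(depth$factors, c(1, 1), tolerance = 1e-12)
  rand <- tmm_normalize(base)
  expect_equal(exp(mean(log(rand$factors))), 1, tolerance = 1e-12)
  scaled <- tmm_normalize(3 * base)
  expect_equal(rand$factors, scaled$factors, tolerance = 1e-10)
})

test_that("all-zero samples get NA TMM factors with a warning", {
  counts <- cbind(c(5, 10, 0), c(0, 0, 0))
  expect_warning(out <- tmm_normalize(counts), "all-zero")
  expect_true(is.na(out$factors[2]))
})

test_that("Marchenko-Pastur thresholding separates noise from structure", {
  retained_iid <- vapply(1:20, function(i) {
    set.seed(40 + i)
    mp_hidden_factors(matrix(rnorm(600 * 80), 600, 80))$n_retained
  }, 0L)
  expect_gte(mean(retained_iid <= 1), 0.95)

  set.seed(41)
  X <- matrix(rnorm(600 * 80), 600, 80)
  base_k <- mp_hidden_factors(X)$n_retained
  gamma <- 600 / 80
  edge <- (1 + sqrt(gamma))^2
  u <- rnorm(80); u <- u / sqrt(sum(u^2))
  spike_strength <- sqrt(10 * edge * 80)
  ks <- vapply(c(0.5, 1, 2), function(sc) {
    Xs <- X + sc * spike_strength * outer(rnorm(600) / sqrt(600), u)
    mp_hidden_factors(Xs)$n_retained
  }, 0L)
  expect_equal(ks[3], base_k + 1L)       # strong spike adds one component
  expect_true(all(diff(ks) >= 0))        # monotone in spike strength
  expect_error(mp_hidden_factors(matrix(rnorm(10), 5, 2)), "3 samples")
})
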