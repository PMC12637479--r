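# Shared fixtures and oracles, built in code.

# Small three-population design for fast tests: same structure as the
# default study design, panel sizes shrunk.
quick_specs <- function(n = 150) {
  specs <- default_population_specs()
  lapply(specs, function(s) { s$n_panel <- as.integer(n); s })
}

# Construct a genotype_panel directly from a dosage matrix (deterministic
# fixtures for harmonization/LD tests).
panel_from_dosages <- function(dos, chrom = "1", start_bp = 1000L,
                               spacing = 1000L, population = "POP",
                               ref = NULL, alt = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  ids <- sprintf("s%03d", seq_len(n))
  pos <- as.integer(start_bp + (seq_len(m) - 1L) * spacing)
  vid <- sprintf("var_%s_%d", chrom, pos)
  dimnames(dos) <- list(ids, vid)
  variants <- tibble::tibble(id = vid, chrom = chrom, pos = pos,
                             ref = ref %||% rep("A", m),
                             alt = alt %||% rep("G", m),
                             af = colMeans(dos) / 2)
  samples <- tibble::tibble(id = ids, population = population,
                            status = rep_len(c(0L, 1L), n),
                            age = seq(60, 90, length.out = n),
                            apoe = rep("e3/e3", n))
  blocks <- tibble::tibble(block = 1L, chrom = chrom, idx_start = 1L,
                           idx_end = m, bp_start = pos[1], bp_end = pos[m])
  structure(list(dosages = dos, variants = variants, samples = samples,
                 blocks = blocks, population = population),
            class = "genotype_panel")
}

# Independently coded single-population sum-of-single-effects fine-mapper
# (scalar prior variance, univariate SER formulas): the oracle for the
# K = 1 degeneration of the multi-population model.
susie_ref_pip <- function(X, y, L = 10, maxit = 500, floor = 1e-6) {
  X <- scale(X); y <- y - mean(y)
  n <- nrow(X); p <- ncol(X); d <- colSums(X^2)
  s2 <- var(y); V <- rep(1e-3, L)
  alpha <- matrix(1 / p, L, p); mu <- matrix(0, L, p)
  eta <- matrix(0, n, L); fitted <- rep(0, n)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  lbf_keep <- rep(0, L)
  for (it in seq_len(maxit)) {
    for (l in seq_len(L)) {
      r <- y - fitted + eta[, l]
      z <- drop(crossprod(X, r)) / s2; s <- d / s2
      Vl <- V[l]
      for (inner in 1:50) {
        pv <- 1 / (1 / Vl + s); m1 <- pv * z
        lbf <- 0.5 * (log(pv) - log(Vl) + pv * z^2)
        a <- exp(lbf - max(lbf)); a <- a / sum(a)
        Vn <- max(sum(a * (m1^2 + pv)), floor)
        if (abs(Vn - Vl) / Vn < 1e-3) { Vl <- Vn; break }
        Vl <- Vn
      }
      pv <- 1 / (1 / Vl + s)
      lbf <- 0.5 * (log(pv) - log(Vl) + pv * z^2)
      pvn <- 1 / (1 / floor + s)
      lbfn <- 0.5 * (log(pvn) - log(floor) + pvn * z^2)
      gain <- (lse(lbf) - lse(lbfn))
      if (gain <= 0) { Vl <- floor; pv <- pvn; lbf <- lbfn }
      lbf_keep[l] <- gain
      a <- exp(lbf - max(lbf)); a <- a / sum(a)
      m1 <- pv * z
      V[l] <- Vl; alpha[l, ] <- a; mu[l, ] <- m1
      newe <- drop(X %*% (a * m1))
      fitted <- fitted - eta[, l] + newe; eta[, l] <- newe
    }
    erss <- sum((y - fitted)^2)
    for (l in seq_len(L)) {
      pv <- 1 / (1 / V[l] + d / s2)
      erss <- erss + sum(d * alpha[l, ] * (mu[l, ]^2 + pv)) - sum(eta[, l]^2)
    }
    s2n <- erss / n
    if (abs(s2n - s2) < 1e-8 && it > 3) { s2 <- s2n; break }
    s2 <- s2n
  }
  kept <- which(lbf_keep > 1)  # same complexity rule as the fit (K = 1)
  if (length(kept) == 0) return(rep(0, p))
  1 - apply(1 - alpha[kept, , drop = FALSE], 2, prod)
}

# Mock fitted object with specified alpha rows, posterior means and
# retained sets, for exercising the downstream analytics in isolation.
mock_sushie_fit <- function(alpha, post_mean, retained_idx_list,
                            populations = c("A", "B"),
                            gene_id = "mock_gene") {
  L <- nrow(alpha); p <- ncol(alpha); K <- length(populations)
  sets <- lapply(seq_along(retained_idx_list), function(i) {
    idx <- retained_idx_list[[i]]
    list(effect_index = i, variant_idx = idx,
         variant_ids = paste0("v", idx), coverage_attained = 1,
         purity = 1, retained = TRUE)
  })
  structure(list(
    gene_id = gene_id, populations = populations,
    variant_ids = paste0("v", seq_len(p)),
    alpha = alpha, post_mean = post_mean,
    pip = setNames(1 - apply(1 - alpha, 2, prod), paste0("v", seq_len(p))),
    effect_lbf = rep(10, L), sets = sets, coverage = 0.9, min_purity = 0.5,
    sigma2 = setNames(rep(1, K), populations),
    n_by_pop = setNames(rep(100, K), populations),
    elbo = c(-10, -9), niter = 2, converged = TRUE, L = L, cis_h2 = NULL),
    class = "sushie_fit")
}
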