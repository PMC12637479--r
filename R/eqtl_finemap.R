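# Multi-population sum-of-single-effects cis-eQTL fine-mapping.
#
# Model, per population k = 1..K and effect l = 1..L:
#   y_k = X_k %*% sum_l b_{l,k} + e_k,   e_k ~ N(0, sigma2_k I)
#   effect l picks one variant gamma_l ~ Uniform(1..p) shared across
#   populations; its K-vector of population effects is MVN(0, C_l), with the
#   K x K prior covariance C_l re-estimated each iteration by EM.
# Inference is coordinate-ascent variational: each effect is a single-effect
# regression (SER) whose posterior is available in closed form given the
# residual of the other effects; the ELBO is monotone non-decreasing.

#' Residualize a phenotype on covariates and standardize
#'
#' Least-squares residuals of `y` on the covariate matrix (which must
#' include an intercept column), then standardized to zero mean and unit
#' variance. Collinear covariate columns are dropped with a warning. If the
#' residual is numerically zero (y exactly linear in covariates) the result
#' is flagged degenerate and returned as zeros.
#'
#' @param y Numeric vector.
#' @param covariates Numeric matrix with an intercept column.
#' @return Standardized residual vector; attribute `"degenerate"` is TRUE
#'   when y is exactly explained by the covariates.
#' @export
residualize <- function(y, covariates) {
  X <- as.matrix(covariates)
  stop_if_not(nrow(X) == length(y), "dimension mismatch")
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
    rlang::abort("covariates must include an intercept column")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    rlang::warn(sprintf("dropping %d collinear covariate column(s)",
                        ncol(X) - qrX$rank))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  r <- resid(lm.fit(X, y))
  if (sd(r) < 1e-12) {
    r <- rep(0, length(y))
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  r <- drop(scale(r))
  attr(r, "degenerate") <- FALSE
  r
}

#' Fit the multi-population sum-of-single-effects eQTL model
#'
#' Coordinate-ascent variational inference over `L` single-effect
#' regressions with a shared causal-indicator distribution across
#' populations and population-specific effect sizes under an EM-updated
#' multivariate-normal prior. Residual variances are re-estimated per
#' population each iteration. Convergence is declared when the evidence
#' lower bound (ELBO) changes by less than `tol`.
#'
#' @param X_by_pop Named list of genotype matrices (samples x variants; the
#'   same variants, in the same order, in every population). Columns are
#'   standardized within population before fitting.
#' @param y_by_pop Named list of residualized expression vectors.
#' @param L Maximum number of effects (default 10).
#' @param max_iter,tol Convergence controls (500 iterations, ELBO tolerance
#'   1e-4).
#' @param prior_var_init Initial per-population prior effect variance
#'   (default 1e-3); the full K x K prior covariance is EM-updated from
#'   there.
#' @param var_floor Floor applied to the prior variances to avoid collapse
#'   (default 1e-6).
#' @param coverage Credible-set coverage target (default 0.9).
#' @param min_purity Minimum sample-size-weighted purity for a credible set
#'   to be retained (default 0.5).
#' @param gene_id Optional gene identifier stored on the fit.
#' @param variant_ids Optional variant ids (defaults to the column names of
#'   the first population's matrix).
#' @return A `sushie_fit`: `alpha` (L x p inclusion probabilities, rows sum
#'   to 1), `post_mean` (L x p x K posterior mean effects, alpha-weighted
#'   summaries available via [extract_weights()]), `prior_covariance` and
#'   `prior_corr` (per effect), `pip`, `sets` (all credible sets, with
#'   purity and retained flags), `elbo` trace, `sigma2`, convergence info.
#' @export
fit_sushie <- function(X_by_pop, y_by_pop, L = 10, max_iter = 500, tol = 1e-4,
                       prior_var_init = 1e-3, var_floor = 1e-6,
                       coverage = 0.9, min_purity = 0.5, lbf_min = NULL,
                       gene_id = NA_character_, variant_ids = NULL) {
  stop_if_not(L >= 1, "L must be >= 1")
  stop_if_not(length(X_by_pop) == length(y_by_pop) && length(X_by_pop) >= 1,
              "X_by_pop and y_by_pop must be non-empty lists of equal length")
  K <- length(X_by_pop)
  pops <- names(X_by_pop) %||% paste0("pop", seq_len(K))
  p <- ncol(X_by_pop[[1]])
  stop_if_not(all(vapply(X_by_pop, ncol, 0L) == p),
              "all populations must share the same variant set")
  variant_ids <- variant_ids %||% colnames(X_by_pop[[1]]) %||% paste0("v", seq_len(p))
  Xs <- lapply(X_by_pop, standardize_columns)
  ys <- lapply(y_by_pop, function(y) y - mean(y))
  for (k in seq_len(K)) {
    stop_if_not(all(is.finite(Xs[[k]])) && all(is.finite(ys[[k]])),
                "non-finite values in input")
    stop_if_not(nrow(Xs[[k]]) == length(ys[[k]]), "dimension mismatch")
  }
  n_k <- vapply(Xs, nrow, 0L)
  d <- lapply(Xs, function(X) pmax(colSums(X^2), 1e-12))
  sigma2 <- vapply(ys, var, 0)
  sigma2[sigma2 <= 0] <- 1

  alpha <- matrix(1 / p, L, p)
  mu <- array(0, dim = c(L, p, K))
  Vv <- array(0, dim = c(L, p, K, K))
  Cl <- replicate(L, diag(prior_var_init, K), simplify = FALSE)
  effect_lbf <- rep(0, L)
  lbf_min <- lbf_min %||% (K * (K + 1) / 2)
  eta <- lapply(seq_len(K), function(k) matrix(0, n_k[k], L))
  fitted <- lapply(seq_len(K), function(k) rep(0, n_k[k]))
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE

  safe_inv <- function(M) {
    tryCatch(chol2inv(chol(M)),
             error = function(e) chol2inv(chol(M + 1e-8 * mean(diag(M)) * diag(nrow(M)) +
                                                  1e-12 * diag(nrow(M)))))
  }

  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      Z <- matrix(0, p, K); S <- matrix(0, p, K)
      for (k in seq_len(K)) {
        r <- ys[[k]] - fitted[[k]] + eta[[k]][, l]
        Z[, k] <- crossprod(Xs[[k]], r) / sigma2[k]
        S[, k] <- d[[k]] / sigma2[k]
      }
      # Inner EM on (q_l, C_l): the data summaries (Z, S) are fixed while
      # effect l is updated, so the prior-covariance EM can be iterated to
      # convergence cheaply. Every inner step is an exact coordinate ascent
      # on the ELBO.
      ser <- function(C) {
        Cinv <- safe_inv(C)
        post <- batched_posterior(Cinv, S, Z)
        logbf <- 0.5 * (post$logdetV + determinant_spd(Cinv) + post$quad)
        list(post = post, logbf = logbf, a = softmax_log(logbf),
             evidence = log_sum_exp(logbf) - log(p))
      }
      Ccur <- Cl[[l]]
      fit_l <- ser(Ccur)
      for (inner in seq_len(50)) {
        a <- fit_l$a; post <- fit_l$post
        Cnew <- matrix(0, K, K)
        for (k1 in seq_len(K)) for (k2 in k1:K) {
          v <- sum(a * (post$mu[, k1] * post$mu[, k2] + post$V[, k1, k2]))
          Cnew[k1, k2] <- Cnew[k2, k1] <- v
        }
        diag(Cnew) <- pmax(diag(Cnew), var_floor)
        delta <- max(abs(Cnew - Ccur)) / max(diag(Cnew))
        Ccur <- Cnew
        fit_l <- ser(Ccur)
        if (delta < 1e-3) break
      }
      # Null check (threshold 0, so every step remains an exact ascent): if
      # the floored (effectively null) prior explains the data at least as
      # well, park the effect there and let its inclusion probabilities
      # stay diffuse. The evidence gain is kept as the effect's log Bayes
      # factor for the credible-set filter.
      Cnull <- diag(var_floor, K)
      fit_null <- ser(Cnull)
      lbf_l <- fit_l$evidence - fit_null$evidence
      if (lbf_l <= 0) {
        Ccur <- Cnull
        fit_l <- fit_null
      }
      effect_lbf[l] <- lbf_l
      Cl[[l]] <- Ccur
      a <- fit_l$a; post <- fit_l$post
      alpha[l, ] <- a
      mu[l, , ] <- post$mu
      Vv[l, , , ] <- post$V
      for (k in seq_len(K)) {
        new_eta <- drop(Xs[[k]] %*% (a * post$mu[, k]))
        fitted[[k]] <- fitted[[k]] - eta[[k]][, l] + new_eta
        eta[[k]][, l] <- new_eta
      }
    }
    # residual variance updates and ELBO
    erss <- numeric(K)
    for (k in seq_len(K)) {
      res2 <- sum((ys[[k]] - fitted[[k]])^2)
      extra <- 0
      for (l in seq_len(L)) {
        second <- alpha[l, ] * (mu[l, , k]^2 + Vv[l, , k, k])
        extra <- extra + sum(d[[k]] * second) - sum(eta[[k]][, l]^2)
      }
      erss[k] <- res2 + extra
      sigma2[k] <- max(erss[k] / n_k[k], 1e-12)
    }
    eloglik <- sum(-n_k / 2 * log(2 * pi * sigma2) - erss / (2 * sigma2))
    kl <- 0
    for (l in seq_len(L)) {
      Cinv <- safe_inv(Cl[[l]])
      logdetC <- -determinant_spd(Cinv)
      a <- alpha[l, ]
      nz <- a > 0
      kl_gamma <- sum(a[nz] * (log(a[nz]) + log(p)))
      trCV <- rep(0, p); muCmu <- rep(0, p); logdetV <- rep(0, p)
      for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
        trCV <- trCV + Cinv[k1, k2] * Vv[l, , k2, k1]
        muCmu <- muCmu + Cinv[k1, k2] * mu[l, , k1] * mu[l, , k2]
      }
      logdetV <- batched_logdet(Vv[l, , , , drop = FALSE], K, p)
      kl_b <- 0.5 * sum(a * (trCV + muCmu - K - logdetV + logdetC))
      kl <- kl + kl_gamma + kl_b
    }
    elbo <- eloglik - kl
    elbo_trace <- c(elbo_trace, elbo)
    if (elbo < elbo_prev - 1e-6) {
      rlang::abort(sprintf(
        "ELBO decreased at iteration %d (%.8f -> %.8f); aborting with diagnostics",
        it, elbo_prev, elbo))
    }
    if (it > 1 && abs(elbo - elbo_prev) < tol) {
      converged <- TRUE
      elbo_prev <- elbo
      break
    }
    elbo_prev <- elbo
  }

  # Effects whose evidence gain over the null prior does not clear the
  # complexity of the K x K prior (K(K+1)/2 free parameters) are treated as
  # empty: they contribute neither credible sets nor PIP mass.
  kept <- which(effect_lbf > lbf_min)
  pip <- if (length(kept) > 0) {
    1 - apply(1 - alpha[kept, , drop = FALSE], 2, prod)
  } else {
    rep(0, p)
  }
  sets_all <- if (length(kept) > 0) {
    ss <- make_credible_sets(alpha[kept, , drop = FALSE], coverage = coverage,
                             variant_ids = variant_ids)
    for (i in seq_along(ss)) ss[[i]]$effect_index <- kept[ss[[i]]$effect_index]
    ss
  } else {
    list()
  }
  sets <- purity_filter(sets_all, Xs, n_by_pop = n_k, min_purity = min_purity)
  structure(list(
    gene_id = gene_id, populations = pops, variant_ids = variant_ids,
    alpha = alpha, post_mean = mu, post_var = Vv,
    prior_covariance = Cl,
    prior_corr = lapply(Cl, function(C) stats::cov2cor(C)),
    pip = setNames(pip, variant_ids), effect_lbf = effect_lbf,
    sets = sets, coverage = coverage, min_purity = min_purity,
    sigma2 = setNames(sigma2, pops), n_by_pop = setNames(n_k, pops),
    elbo = elbo_trace, niter = length(elbo_trace), converged = converged,
    L = L, cis_h2 = NULL), class = "sushie_fit")
}

determinant_spd <- function(M) {
  2 * sum(log(diag(chol(M))))
}

# log-determinants of the p posterior covariance K x K slices
batched_logdet <- function(Vl, K, p) {
  if (K == 1L) return(log(Vl[1, , 1, 1]))
  out <- numeric(p)
  if (K == 2L) {
    out <- log(Vl[1, , 1, 1] * Vl[1, , 2, 2] - Vl[1, , 1, 2]^2)
  } else if (K == 3L) {
    a <- Vl[1, , 1, 1]; b <- Vl[1, , 1, 2]; c3 <- Vl[1, , 1, 3]
    e <- Vl[1, , 2, 2]; f <- Vl[1, , 2, 3]; i <- Vl[1, , 3, 3]
    out <- log(a * (e * i - f^2) - b * (b * i - c3 * f) + c3 * (b * f - c3 * e))
  } else {
    for (j in seq_len(p)) out[j] <- determinant_spd(Vl[1, j, , ])
  }
  out
}

#' @export
print.sushie_fit <- function(x, ...) {
  n_ret <- sum(vapply(x$sets, function(s) isTRUE(s$retained), TRUE))
  cat(sprintf("<sushie_fit> gene %s: %d variants, %d population(s), L=%d\n",
              x$gene_id, length(x$pip), length(x$populations), x$L))
  cat(sprintf("  %d credible set(s) retained (coverage %.2f, purity >= %.2f); ELBO %.3f after %d iterations\n",
              n_ret, x$coverage, x$min_purity, x$elbo[x$niter], x$niter))
  invisible(x)
}

#' Build coverage-level credible sets from inclusion probabilities
#'
#' Per effect, variants are sorted by inclusion probability descending and
#' the smallest prefix with cumulative probability at or above `coverage`
#' forms the set. Exact duplicate sets from later effects are dropped.
#'
#' @param alpha L x p matrix of per-effect inclusion probabilities (rows sum
#'   to 1).
#' @param coverage Target cumulative probability (default 0.9).
#' @param variant_ids Optional variant ids.
#' @return List of credible sets; each has `effect_index`, `variant_idx`,
#'   `variant_ids` (in descending-alpha order), `coverage_attained`.
#' @export
make_credible_sets <- function(alpha, coverage = 0.9, variant_ids = NULL) {
  alpha <- rbind(alpha)
  stop_if_not(all(abs(rowSums(alpha) - 1) < 1e-6), "alpha rows must sum to 1")
  p <- ncol(alpha)
  variant_ids <- variant_ids %||% colnames(alpha) %||% paste0("v", seq_len(p))
  sets <- list()
  seen <- character(0)
  for (l in seq_len(nrow(alpha))) {
    o <- order(alpha[l, ], decreasing = TRUE)
    cum <- cumsum(alpha[l, o])
    sz <- which(cum >= coverage - 1e-12)[1]
    if (is.na(sz)) sz <- p
    idx <- o[seq_len(sz)]
    key <- paste(sort(idx), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sets[[length(sets) + 1]] <- list(
      effect_index = l, variant_idx = idx, variant_ids = variant_ids[idx],
      coverage_attained = cum[sz])
  }
  sets
}

#' Purity-filter credible sets
#'
#' Purity is the minimum over member pairs of the sample-size-weighted
#' average across populations of the absolute genotype correlation;
#' single-member sets have purity 1 by convention. Sets with purity below
#' `min_purity` are flagged `retained = FALSE`.
#'
#' @param sets List of credible sets from [make_credible_sets()].
#' @param X_by_pop List of genotype matrices (same variant order as used to
#'   build the sets).
#' @param n_by_pop Per-population sample sizes used as weights (defaults to
#'   the matrix row counts).
#' @param min_purity Retention threshold (default 0.5).
#' @return The sets, each augmented with `purity` and `retained`.
#' @export
purity_filter <- function(sets, X_by_pop, n_by_pop = NULL, min_purity = 0.5) {
  n_by_pop <- n_by_pop %||% vapply(X_by_pop, nrow, 0L)
  w <- n_by_pop / sum(n_by_pop)
  for (i in seq_along(sets)) {
    idx <- sets[[i]]$variant_idx
    if (length(idx) == 1) {
      purity <- 1
    } else {
      wabs <- matrix(0, length(idx), length(idx))
      for (k in seq_along(X_by_pop)) {
        ck <- suppressWarnings(cor(X_by_pop[[k]][, idx, drop = FALSE]))
        ck[!is.finite(ck)] <- 0
        wabs <- wabs + w[k] * abs(ck)
      }
      purity <- min(wabs[upper.tri(wabs)])
    }
    sets[[i]]$purity <- purity
    sets[[i]]$retained <- purity >= min_purity
  }
  sets
}

retained_sets <- function(fit) {
  Filter(function(s) isTRUE(s$retained), fit$sets)
}

#' Cis-SNP heritability by restricted maximum likelihood
#'
#' Fits `y ~ N(intercept, sigma_g^2 K + sigma_e^2 I)` with the genetic
#' relatedness matrix `K = X X' / p` from standardized genotypes, profiling
#' the REML log-likelihood over `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`
#' after a single eigendecomposition of K. The p-value is a likelihood-ratio
#' test of `sigma_g^2 = 0` against the one-sided boundary null
#' (0.5 chi^2_0 + 0.5 chi^2_1 mixture, reported as
#' `0.5 * P(chi^2_1 > LRT)`, i.e. 0.5 at a zero statistic).
#'
#' @param X Genotype matrix (standardized internally).
#' @param y Phenotype vector.
#' @return List with `h2`, `p`, `loglik`, `loglik_null`, `converged`.
#' @export
cis_heritability <- function(X, y) {
  Xs <- standardize_columns(X)
  n <- nrow(Xs)
  stop_if_not(n == length(y), "dimension mismatch")
  p <- ncol(Xs)
  Kmat <- tcrossprod(Xs) / p
  ee <- eigen(Kmat, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  yt <- drop(crossprod(ee$vectors, y))
  xt <- drop(crossprod(ee$vectors, rep(1, n)))
  reml_ll <- function(h2) {
    v <- h2 * lam + (1 - h2)
    if (any(v <= 0)) return(-Inf)
    xvx <- sum(xt^2 / v)
    quad <- sum(yt^2 / v) - sum(yt * xt / v)^2 / xvx
    st2 <- quad / (n - 1)
    if (st2 <= 0) return(-Inf)
    -0.5 * (sum(log(v)) + log(xvx) + (n - 1) * (log(st2) + 1))
  }
  opt <- optimize(reml_ll, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  ll0 <- reml_ll(0)
  h2 <- opt$maximum
  ll1 <- max(opt$objective, ll0)
  if (ll0 >= opt$objective) h2 <- 0
  stat <- max(0, 2 * (ll1 - ll0))
  pval <- 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  conv <- is.finite(ll1)
  if (!conv) {
    return(list(h2 = NA_real_, p = NA_real_, loglik = NA_real_,
                loglik_null = ll0, converged = FALSE))
  }
  list(h2 = h2, p = pval, loglik = ll1, loglik_null = ll0, converged = TRUE)
}

#' Extract per-variant expression weights from a fit
#'
#' Dense weights sum the alpha-weighted posterior mean effects over all
#' effects for every cis variant; sparse weights zero everything outside the
#' retained credible sets. Weights are on the standardized-genotype,
#' standardized-expression scale.
#'
#' @param model A `sushie_fit`.
#' @param population Population label.
#' @param mode `"dense"` or `"sparse"`.
#' @return Named numeric weight vector (one entry per cis variant).
#' @export
extract_weights <- function(model, population, mode = c("dense", "sparse")) {
  mode <- match.arg(mode)
  k <- match(population, model$populations)
  if (is.na(k)) rlang::abort(sprintf("unknown population '%s'", population))
  p <- length(model$variant_ids)
  w <- rep(0, p)
  for (l in seq_len(model$L)) {
    w <- w + model$alpha[l, ] * model$post_mean[l, , k]
  }
  if (mode == "sparse") {
    keep <- unique(unlist(lapply(retained_sets(model), `[[`, "variant_idx")))
    mask <- rep(FALSE, p)
    mask[keep] <- TRUE
    w[!mask] <- 0
  }
  setNames(w, model$variant_ids)
}
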