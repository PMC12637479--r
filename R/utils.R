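# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm qnorm pnorm pchisq rbinom runif rpois sd var cor
#'   median optimize lm resid dnorm quantile setNames complete.cases
#' @importFrom rlang .data abort warn `%||%`
#' @importFrom utils combn head
NULL

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax_log <- function(x) {
  exp(x - log_sum_exp(x))
}

#' Column-standardize a matrix to zero mean, unit variance
#'
#' Zero-variance columns are centered and left at zero (with attribute
#' `constant` marking them) rather than producing NaN.
#' @param X numeric matrix.
#' @return standardized matrix with the same dimensions.
#' @keywords internal
standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  keep <- s > 0
  Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2, s[keep], "/")
  attr(Xc, "constant") <- !keep
  Xc
}

# Batched inversion of symmetric positive-definite matrices P_j = Cinv + diag(S[j, ])
# across j = 1..p, with K = 1, 2 or 3 handled in closed form (vectorized over p)
# and a chol() loop otherwise. Returns the posterior pieces used by the
# single-effect regression update: V_j = P_j^{-1}, mu_j = V_j z_j,
# log|V_j|, and the quadratic form z_j' V_j z_j.
batched_posterior <- function(Cinv, S, Z) {
  p <- nrow(S)
  K <- ncol(S)
  V <- array(0, dim = c(p, K, K))
  mu <- matrix(0, p, K)
  logdetV <- numeric(p)
  quad <- numeric(p)
  if (K == 1L) {
    pr <- Cinv[1, 1] + S[, 1]
    v <- 1 / pr
    V[, 1, 1] <- v
    mu[, 1] <- v * Z[, 1]
    logdetV <- log(v)
    quad <- v * Z[, 1]^2
  } else if (K == 2L) {
    a <- Cinv[1, 1] + S[, 1]
    d <- Cinv[2, 2] + S[, 2]
    b <- Cinv[1, 2]
    det <- a * d - b^2
    V[, 1, 1] <- d / det
    V[, 2, 2] <- a / det
    V[, 1, 2] <- V[, 2, 1] <- -b / det
    mu[, 1] <- V[, 1, 1] * Z[, 1] + V[, 1, 2] * Z[, 2]
    mu[, 2] <- V[, 2, 1] * Z[, 1] + V[, 2, 2] * Z[, 2]
    logdetV <- -log(det)
    quad <- mu[, 1] * Z[, 1] + mu[, 2] * Z[, 2]
  } else if (K == 3L) {
    a <- Cinv[1, 1] + S[, 1]
    e <- Cinv[2, 2] + S[, 2]
    i <- Cinv[3, 3] + S[, 3]
    b <- Cinv[1, 2]; c3 <- Cinv[1, 3]; f <- Cinv[2, 3]
    A11 <- e * i - f^2
    A12 <- c3 * f - b * i
    A13 <- b * f - c3 * e
    A22 <- a * i - c3^2
    A23 <- b * c3 - a * f
    A33 <- a * e - b^2
    det <- a * A11 + b * A12 + c3 * A13
    V[, 1, 1] <- A11 / det
    V[, 2, 2] <- A22 / det
    V[, 3, 3] <- A33 / det
    V[, 1, 2] <- V[, 2, 1] <- A12 / det
    V[, 1, 3] <- V[, 3, 1] <- A13 / det
    V[, 2, 3] <- V[, 3, 2] <- A23 / det
    for (k in 1:3) {
      mu[, k] <- V[, k, 1] * Z[, 1] + V[, k, 2] * Z[, 2] + V[, k, 3] * Z[, 3]
    }
    logdetV <- -log(det)
    quad <- rowSums(mu * Z)
  } else {
    for (j in seq_len(p)) {
      P <- Cinv + diag(S[j, ], K)
      R <- chol(P)
      Vj <- chol2inv(R)
      V[j, , ] <- Vj
      mu[j, ] <- drop(Vj %*% Z[j, ])
      logdetV[j] <- -2 * sum(log(diag(R)))
      quad[j] <- sum(mu[j, ] * Z[j, ])
    }
  }
  list(V = V, mu = mu, logdetV = logdetV, quad = quad)
}

# log determinant of a symmetric positive-definite matrix via Cholesky
logdet_spd <- function(M) {
  2 * sum(log(diag(chol(M))))
}

# Nearest-PSD projection by flooring eigenvalues at `floor` (default 0).
make_psd <- function(M, floor = 0) {
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  if (min(ee$values) >= floor) return(M)
  v <- pmax(ee$values, floor)
  ee$vectors %*% (v * t(ee$vectors))
}

# Draw n samples from MVN(mean, Sigma) using a pivoted Cholesky-safe route.
rmvnorm_chol <- function(n, mean, Sigma) {
  K <- length(mean)
  R <- tryCatch(chol(Sigma), error = function(e) {
    chol(make_psd(Sigma, floor = 1e-10) + 1e-10 * diag(K))
  })
  Zm <- matrix(rnorm(n * K), n, K) %*% R
  sweep(Zm, 2, mean, "+")
}

# Log-density of z under N(0, Sigma); Sigma regularized if needed.
dmvnorm0_log <- function(z, Sigma) {
  K <- length(z)
  R <- tryCatch(chol(Sigma), error = function(e) {
    chol(make_psd(Sigma, floor = 1e-10) + 1e-8 * diag(K))
  })
  u <- backsolve(R, z, transpose = TRUE)
  -0.5 * K * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(u^2)
}

stop_if_not <- function(cond, msg) {
  if (!cond) rlang::abort(msg)
  invisible(TRUE)
}
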