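# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own code paths: brute-force loops,
# dense-grid quadrature, generic numerical optimization, and the
# QR/SVD-based canonical-correlation machinery in base R.

# Brute-force evidence count: explicit loop, no vectorized comparison.
brute_force_ev_bar <- function(logpost, log_s_star) {
  hits <- 0L
  for (v in logpost) if (v > log_s_star) hits <- hits + 1L
  hits / length(logpost)
}

# Dense-grid quadrature of the unnormalized (psi, sigma) posterior of the
# 3-parameter ADF model (p = 1, constant only) over {logpost > log_s_star}.
# Integrates with respect to (mu, gamma0, sigma).
quadrature_ev <- function(design, log_s_star, ng = 180) {
  stopifnot(design$p == 1L, design$k == 2L)
  X <- design$X
  dY <- design$dY
  Tn <- design$T
  XtX <- crossprod(X)
  psi_hat <- solve(XtX, crossprod(X, dY))
  ssr <- sum((dY - X %*% psi_hat)^2)
  se <- sqrt((ssr / (Tn - 2)) * diag(solve(XtX)))
  sig_hat <- sqrt(ssr / (Tn + 1))
  mu_g <- seq(psi_hat[1] - 10 * se[1], psi_hat[1] + 10 * se[1], length.out = ng)
  g0_g <- seq(psi_hat[2] - 10 * se[2], psi_hat[2] + 10 * se[2], length.out = ng)
  sig_g <- seq(sig_hat * 0.35, sig_hat * 3, length.out = ng)
  Q <- outer(mu_g, g0_g,
             Vectorize(function(m, g) sum((dY - m - g * X[, 2])^2)))
  lp <- array(NA_real_, c(ng, ng, ng))
  for (k in seq_along(sig_g)) {
    lp[, , k] <- -(Tn + 1) * log(sig_g[k]) - Q / (2 * sig_g[k]^2)
  }
  w <- exp(lp - max(lp))
  1 - sum(w[lp > log_s_star]) / sum(w)
}

# Generic numerical maximization of the restricted (Gamma0 = 0) log
# posterior in (psi_r, log sigma).
optim_restricted_ur <- function(design) {
  Xr <- design$X[, -design$gamma0_col, drop = FALSE]
  dY <- design$dY
  Tn <- design$T
  negf <- function(par) {
    kr <- ncol(Xr)
    psi_r <- par[seq_len(kr)]
    s2 <- exp(2 * par[kr + 1L])
    ssr <- sum((dY - Xr %*% psi_r)^2)
    -(-(Tn + 1) / 2 * log(s2) - ssr / (2 * s2))
  }
  start <- c(rep(0, ncol(Xr)), log(stats::sd(dY)))
  o <- stats::optim(start, negf, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 5000))
  -o$value
}

# Generic numerical maximization of the VECM log posterior over
# (eta_1, alpha, beta, chol(Omega)) with Pi = alpha beta' of rank r
# (n = 2, p = 1, constant). Starts from a perturbation of `start_par`.
optim_restricted_vecm <- function(design, r, start_par, perturb_seed = 1) {
  n <- design$n
  stopifnot(n == 2L, design$p == 1L, ncol(design$Z1) == 1L)
  nu <- design$T + n + 1
  negf <- function(par) {
    cc <- par[1:2]
    Pi <- if (r == 0L) {
      matrix(0, 2, 2)
    } else if (r == 1L) {
      par[3:4] %*% t(par[5:6])
    } else {
      matrix(par[3:6], 2, 2)
    }
    ip <- if (r == 0L) 3L else 7L
    L <- matrix(c(exp(par[ip]), par[ip + 1L], 0, exp(par[ip + 2L])), 2, 2)
    Om <- L %*% t(L)
    if (any(!is.finite(Om)) || kappa(Om) > 1e12) return(1e10)
    eta <- rbind(cc, t(Pi))
    A <- crossprod(design$dY - design$Z %*% eta)
    val <- -(nu / 2) * determinant(Om)$modulus[1] - 0.5 * sum(solve(Om) * A)
    if (!is.finite(val)) return(1e10)
    -val
  }
  set.seed(perturb_seed)
  start <- start_par + stats::rnorm(length(start_par), 0, 0.1)
  o <- stats::optim(start, negf, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 5000))
  o2 <- stats::optim(o$par, negf, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 50000))
  -o2$value
}

# Squared canonical correlations between two residual matrices, via the
# QR-based stats::cancor (independent of the package's Cholesky-symmetrized
# eigen route).
cca_squared_correlations <- function(U, V) {
  sort(stats::cancor(U, V, xcenter = FALSE, ycenter = FALSE)$cor^2,
       decreasing = TRUE)
}
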