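#' Define an AR(p) simulation scenario
#'
#' Describes an autoregressive data-generating process
#' `y_t = mu + delta * t + phi_1 y_{t-1} + ... + phi_p y_{t-p} + eps_t`
#' with Gaussian innovations, either through the AR coefficients `phi` or
#' through the ADF-form parameters `(gamma0, gammas)` (converted with
#' [phi_from_gamma()]). `gamma0 = 0` puts a unit root in the process.
#'
#' Series are started at zero and a warm-up stretch is discarded; a
#' stationary-distribution start is impossible in general because unit-root
#' processes have no stationary law, so the zero start plus warm-up is used
#' for every scenario.
#'
#' @param T Effective sample length; the generated series has `T + p`
#'   observations (after the warm-up is dropped).
#' @param phi AR coefficients (length `p`), or `NULL` to use `gamma0`/
#'   `gammas`.
#' @param gamma0,gammas ADF-form parameters, used when `phi` is `NULL`.
#' @param mu,delta Intercept and linear-trend coefficient.
#' @param sigma Innovation standard deviation (> 0 unless the degenerate
#'   noiseless process is wanted; `sigma = 0` is allowed and produces the
#'   deterministic skeleton).
#' @param seed Integer seed controlling all randomness of the scenario.
#' @param warmup Number of initial observations discarded (default 100).
#'
#' @return Object of class `ar_scenario`; includes `rho = sum(phi)` as
#'   metadata.
#' @export
ar_scenario <- function(T, phi = NULL, gamma0 = NULL, gammas = numeric(0),
                        mu = 0, delta = 0, sigma = 1, seed = 1,
                        warmup = 100) {
  if (is.null(phi)) {
    if (is.null(gamma0)) {
      abort("Supply either `phi` or `gamma0` (with optional `gammas`).",
            class = "fbsts_invalid_scenario")
    }
    phi <- phi_from_gamma(gamma0, gammas)
  }
  stopifnot(T >= 1, warmup >= 0, sigma >= 0, length(phi) >= 1)
  structure(
    list(T = as.integer(T), p = length(phi), phi = phi,
         mu = mu, delta = delta, sigma = sigma,
         seed = as.integer(seed), warmup = as.integer(warmup),
         rho = sum(phi)),
    class = "ar_scenario"
  )
}

#' Simulate a series from an AR scenario
#'
#' Runs the AR(p) recursion from zero initial values, discards the warm-up,
#' and returns the remaining `T + p` observations. Identical seeds give
#' identical series.
#'
#' @param scenario An [ar_scenario()].
#' @return Numeric vector of length `T + p`.
#' @examples
#' y <- simulate_ar(ar_scenario(T = 200, gamma0 = 0, seed = 3))  # random walk
#' @export
simulate_ar <- function(scenario) {
  stopifnot(inherits(scenario, "ar_scenario"))
  p <- scenario$p
  n_total <- scenario$warmup + scenario$T + p
  set.seed(scenario$seed)
  eps <- rnorm(n_total, 0, scenario$sigma)
  y <- numeric(n_total)
  for (t in seq_len(n_total)) {
    ar <- 0
    for (j in seq_len(p)) {
      if (t - j >= 1L) ar <- ar + scenario$phi[[j]] * y[t - j]
    }
    y[t] <- scenario$mu + scenario$delta * t + ar + eps[t]
  }
  y[(scenario$warmup + 1L):n_total]
}

#' Define a cointegrated VECM simulation scenario
#'
#' Describes an n-dimensional VAR(p) in error-correction form
#' `dY_t = c + G1 dY_{t-1} + ... + G_{p-1} dY_{t-p+1} + Pi Y_{t-1} + E_t`
#' with `Pi = alpha beta'` of prescribed rank `r` and Gaussian innovations
#' `E_t ~ N(0, Omega)`. At construction the implied VAR companion matrix is
#' checked: it must have exactly `n - r` eigenvalues within `1e-8` of 1
#' (the unit roots) and all remaining eigenvalues strictly inside the unit
#' circle, so that `beta' Y_t` is stationary by construction. A scenario
#' violating this is rejected with the offending eigenvalues listed.
#'
#' @param n Number of series.
#' @param T Effective sample length; the simulated matrix has `T + p` rows.
#' @param r True cointegration rank (0 to `n`).
#' @param alpha,beta `n x r` loading and cointegration matrices (ignored,
#'   and may be `NULL`, when `r = 0`).
#' @param Gamma List of `p - 1` short-run `n x n` matrices (default: none,
#'   i.e. `p = 1`).
#' @param c_const Length-`n` drift vector (default zeros).
#' @param Omega Innovation covariance, symmetric positive definite
#'   (default identity).
#' @param seed Integer seed.
#' @param warmup Discarded initial stretch (default 100).
#'
#' @return Object of class `vecm_scenario`; includes the VAR coefficient
#'   matrices `Phi` and the companion eigenvalues as metadata.
#' @export
vecm_scenario <- function(n, T, r, alpha = NULL, beta = NULL,
                          Gamma = list(), c_const = rep(0, n),
                          Omega = diag(n), seed = 1, warmup = 100) {
  stopifnot(n >= 1, T >= 1, r >= 0, r <= n, warmup >= 0)
  p <- length(Gamma) + 1L
  Omega <- as.matrix(Omega)
  if (!isSymmetric(Omega, tol = 1e-10) ||
      inherits(tryCatch(chol(Omega), error = identity), "error")) {
    abort("`Omega` must be symmetric positive definite.",
          class = "fbsts_invalid_scenario")
  }
  if (r > 0) {
    alpha <- as.matrix(alpha)
    beta <- as.matrix(beta)
    if (!all(dim(alpha) == c(n, r)) || !all(dim(beta) == c(n, r))) {
      abort(sprintf("`alpha` and `beta` must be %d x %d matrices.", n, r),
            class = "fbsts_invalid_scenario")
    }
    Pi <- alpha %*% t(beta)
  } else {
    Pi <- matrix(0, n, n)
  }

  # VAR coefficients from the VECM form:
  # Phi_1 = I + Pi + G_1;  Phi_j = G_j - G_{j-1} (1 < j < p);  Phi_p = -G_{p-1}
  Phi <- vector("list", p)
  if (p == 1L) {
    Phi[[1L]] <- diag(n) + Pi
  } else {
    Phi[[1L]] <- diag(n) + Pi + Gamma[[1L]]
    if (p > 2L) {
      for (j in 2:(p - 1L)) Phi[[j]] <- Gamma[[j]] - Gamma[[j - 1L]]
    }
    Phi[[p]] <- -Gamma[[p - 1L]]
  }

  companion <- matrix(0, n * p, n * p)
  for (j in seq_len(p)) {
    companion[seq_len(n), ((j - 1L) * n + 1L):(j * n)] <- Phi[[j]]
  }
  if (p > 1L) {
    companion[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  }
  ev <- eigen(companion, only.values = TRUE)$values
  n_unit <- sum(abs(Mod(ev) - 1) <= 1e-8 & abs(Im(ev)) <= 1e-6 &
                  abs(Re(ev) - 1) <= 1e-8)
  n_inside <- sum(Mod(ev) < 1 - 1e-8)
  if (n_unit != n - r || n_unit + n_inside != n * p) {
    abort(paste0(
      sprintf("Invalid scenario: expected %d unit eigenvalue(s) and the rest ",
              n - r),
      "inside the unit circle; companion eigenvalue moduli: ",
      paste(sprintf("%.6f", sort(Mod(ev), decreasing = TRUE)), collapse = ", ")),
      class = "fbsts_invalid_scenario")
  }
  structure(
    list(n = n, T = as.integer(T), p = p, r = as.integer(r),
         alpha = alpha, beta = beta, Gamma = Gamma, Pi = Pi,
         c_const = c_const, Omega = Omega, Phi = Phi,
         companion_eigenvalues = ev,
         seed = as.integer(seed), warmup = as.integer(warmup)),
    class = "vecm_scenario"
  )
}

#' Simulate a multivariate series from a VECM scenario
#'
#' Runs the VAR recursion implied by the error-correction parameters from
#' zero initial values, discards the warm-up, and returns a tibble with
#' `T + p` rows and one column per series (`y1`, `y2`, ...), ready to pass
#' to [fbst_coint()].
#'
#' @param scenario A [vecm_scenario()].
#' @return Tibble with `T + p` rows and `n` numeric columns.
#' @examples
#' sc <- vecm_scenario(n = 2, T = 200, r = 1,
#'                     alpha = matrix(c(-0.4, 0.1)),
#'                     beta = matrix(c(1, -1)), seed = 11)
#' Y <- simulate_vecm(sc)
#' @export
simulate_vecm <- function(scenario) {
  stopifnot(inherits(scenario, "vecm_scenario"))
  n <- scenario$n
  p <- scenario$p
  n_total <- scenario$warmup + scenario$T + p
  set.seed(scenario$seed)
  cOm <- chol(scenario$Omega)
  E <- matrix(rnorm(n_total * n), n_total, n) %*% cOm
  Y <- matrix(0, n_total, n)
  for (t in seq_len(n_total)) {
    acc <- scenario$c_const + E[t, ]
    for (j in seq_len(p)) {
      if (t - j >= 1L) acc <- acc + scenario$Phi[[j]] %*% Y[t - j, ]
    }
    Y[t, ] <- acc
  }
  out <- Y[(scenario$warmup + 1L):n_total, , drop = FALSE]
  colnames(out) <- paste0("y", seq_len(n))
  as_tibble(out)
}
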