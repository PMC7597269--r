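#' Build the ADF-form design for an AR(p) unit-root regression
#'
#' Rewrites the AR(p) model
#' `y_t = mu + delta * t + phi_1 y_{t-1} + ... + phi_p y_{t-p} + eps_t`
#' in its augmented Dickey-Fuller form
#' `dy_t = mu + delta * t + G0 * y_{t-1} + G1 * dy_{t-1} + ... + G_{p-1} * dy_{t-p+1} + eps_t`,
#' where `G0 = phi_1 + ... + phi_p - 1`, so that a single unit root in the
#' autoregressive polynomial corresponds to the sharp hypothesis `G0 = 0`.
#' The first `p` observations are conditioned on (never modeled), leaving an
#' effective sample of `T = length(y) - p` rows.
#'
#' Column order of the regressor matrix is (constant, trend, lagged level,
#' lagged differences), matching the coefficient ordering
#' `(mu, delta, G0, G1, ..., G_{p-1})`. The trend column holds the raw date
#' index `p+1, ..., T+p`; it is deliberately not recentred so that results
#' are bit-comparable across lag choices.
#'
#' @param y Numeric vector, the raw series of length `T + p`.
#' @param p AR lag order (>= 1).
#' @param constant Include an intercept? Default `TRUE`.
#' @param trend Include a deterministic linear trend? Default `FALSE`.
#'
#' @return An object of class `ur_design`: a list with the response `dY`
#'   (length `T`), regressor matrix `X` (`T x k`) with labelled columns,
#'   `k`, `p`, `T`, and `gamma0_col`, the index of the lagged-level column.
#' @examples
#' d <- ur_design(cumsum(rnorm(50)), p = 2, trend = TRUE)
#' dim(d$X)  # 48 x 4
#' @export
ur_design <- function(y, p = 1, constant = TRUE, trend = FALSE) {
  y <- as.numeric(y)
  bad <- which(!is.finite(y))
  if (length(bad) > 0L) {
    abort(sprintf("Non-finite value in `y` at index %d.", bad[[1L]]),
          class = "fbsts_invalid_input")
  }
  stopifnot(p >= 1)
  k <- as.integer(constant) + as.integer(trend) + 1L + (p - 1L)
  min_len <- p + k + 2L
  if (length(y) < min_len) {
    abort(sprintf("Series too short: need at least %d observations for p = %d.",
                  min_len, p),
          class = "fbsts_invalid_input")
  }
  n_obs <- length(y)
  T_eff <- n_obs - p
  dy_full <- diff(y)                       # dy_t for t = 2, ..., T + p
  dY <- dy_full[p:(n_obs - 1L)]            # dy_t for t = p + 1, ..., T + p

  cols <- list()
  labels <- character()
  if (constant) {
    cols <- c(cols, list(rep(1, T_eff)))
    labels <- c(labels, "const")
  }
  if (trend) {
    cols <- c(cols, list(as.numeric((p + 1L):n_obs)))
    labels <- c(labels, "trend")
  }
  cols <- c(cols, list(y[p:(n_obs - 1L)]))  # y_{t-1}
  labels <- c(labels, "ylag")
  gamma0_col <- length(cols)
  if (p > 1L) {
    for (j in seq_len(p - 1L)) {
      cols <- c(cols, list(dy_full[(p - j):(n_obs - 1L - j)]))  # dy_{t-j}
      labels <- c(labels, paste0("dlag", j))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  structure(
    list(dY = dY, X = X, k = k, p = p, T = T_eff,
         gamma0_col = gamma0_col, constant = constant, trend = trend,
         column_labels = labels),
    class = "ur_design"
  )
}

check_full_rank <- function(X, what = "design matrix") {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    abort(sprintf("Singular %s: collinear column(s) %s.", what,
                  paste(dropped, collapse = ", ")),
          class = "fbsts_singular_design")
  }
  qrx
}

#' OLS fit of the ADF-form regression
#'
#' @param design An [ur_design()] object.
#' @return A list with `psi_hat` (named coefficient vector), `ssr` (residual
#'   sum of squares), `se` (classical OLS standard errors using
#'   `ssr / (T - k)`), and `XtX`.
#' @export
ur_ols <- function(design) {
  X <- design$X
  qrx <- check_full_rank(X)
  psi_hat <- qr.coef(qrx, design$dY)
  resid <- design$dY - as.vector(X %*% psi_hat)
  ssr <- sum(resid^2)
  XtX <- crossprod(X)
  s2 <- ssr / (design$T - design$k)
  se <- sqrt(s2 * diag(chol2inv(chol(XtX))))
  names(se) <- names(psi_hat) <- design$column_labels
  list(psi_hat = psi_hat, ssr = ssr, se = se, XtX = XtX)
}

#' Restricted posterior mode under the unit-root hypothesis
#'
#' Maximizes the (unnormalized) joint posterior of `(psi, sigma)` under the
#' constraint `G0 = 0`, i.e. with the lagged-level column removed from the
#' regression. Under the flat-times-`1/sigma` improper prior the restricted
#' maximum a posteriori estimate is the restricted OLS coefficient vector
#' together with `sigma_r^2 = SSR_r / (T + 1)` (the value of `sigma^2` that
#' maximizes `sigma^{-(T+1)} exp(-SSR_r / (2 sigma^2))`; setting the
#' derivative of `-(T+1) log(sigma) - SSR_r / (2 sigma^2)` in `sigma` to zero
#' gives exactly this value).
#'
#' The returned `log_s_star` is the restricted maximum of the log posterior
#' on the same unnormalized scale used for the Gibbs draws,
#' `-(T+1) log(sigma_r) - SSR_r / (2 sigma_r^2)`.
#'
#' @param design An [ur_design()] object.
#' @return List with `psi_hat_r` (full-length coefficient vector with the
#'   `G0` entry fixed at 0), `sigma2_hat_r`, `ssr_r` and `log_s_star`.
#' @export
ur_restricted_map <- function(design) {
  Xr <- design$X[, -design$gamma0_col, drop = FALSE]
  Tn <- design$T
  if (ncol(Xr) == 0L) {
    psi_r_part <- numeric(0)
    ssr_r <- sum(design$dY^2)
  } else {
    qrx <- check_full_rank(Xr, "restricted design matrix")
    psi_r_part <- qr.coef(qrx, design$dY)
    ssr_r <- sum((design$dY - as.vector(Xr %*% psi_r_part))^2)
  }
  if (ssr_r <= 0) {
    abort("Degenerate restricted fit: zero residual variance (sigma_r = 0).",
          class = "fbsts_degenerate_variance")
  }
  sigma2_hat_r <- ssr_r / (Tn + 1)
  psi_hat_r <- numeric(design$k)
  psi_hat_r[-design$gamma0_col] <- psi_r_part
  names(psi_hat_r) <- design$column_labels
  log_s_star <- -(Tn + 1) / 2 * log(sigma2_hat_r) - ssr_r / (2 * sigma2_hat_r)
  list(psi_hat_r = psi_hat_r, sigma2_hat_r = sigma2_hat_r,
       ssr_r = ssr_r, log_s_star = log_s_star)
}

# Unnormalized log posterior of (psi, sigma) for the ADF-form model:
# -(T+1) log sigma - SSR(psi) / (2 sigma^2), with
# SSR(psi) = ssr_ols + (psi - psi_hat)' X'X (psi - psi_hat).
# `Psi` may be a vector (one point) or an N x k matrix of draws.
ur_logpost <- function(design, Psi, sigma2, ols = NULL) {
  ols <- ols %||% ur_ols(design)
  R <- chol(ols$XtX)
  if (is.null(dim(Psi))) Psi <- matrix(Psi, nrow = 1L)
  centred <- sweep(Psi, 2L, ols$psi_hat)
  qf <- rowSums((centred %*% t(R))^2)
  -(design$T + 1) / 2 * log(sigma2) - (ols$ssr + qf) / (2 * sigma2)
}

#' Gibbs sampler for the ADF-form Normal-Inverse-Gamma posterior
#'
#' Alternates the two full conditionals of the joint posterior under the
#' improper prior `h(psi, sigma) proportional to 1/sigma`:
#' `psi | sigma^2, y ~ N(psi_hat, sigma^2 (X'X)^{-1})` and
#' `sigma^2 | psi, y ~ Inverse-Gamma((T+1)/2, H)` with
#' `H = 0.5 * [SSR + (psi - psi_hat)' X'X (psi - psi_hat)]`, where the
#' Inverse-Gamma(a, b) density is proportional to `x^{-(a+1)} exp(-b/x)`.
#'
#' The shape `(T+1)/2` treats the posterior as a density in `sigma`; reading
#' it as a density in `sigma^2` (change of variables) would give shape `T/2`.
#' The printed-form shape is the default; set `jacobian_corrected = TRUE`
#' for the change-of-variables shape. The difference is O(1/T).
#'
#' @param design An [ur_design()] object.
#' @param draws Total number of Gibbs iterations (default 51000).
#' @param burn Number of initial iterations discarded (default 1000).
#' @param seed Integer seed; identical seeds give bit-identical chains.
#' @param jacobian_corrected Use Inverse-Gamma shape `T/2` instead of
#'   `(T+1)/2`. Default `FALSE`.
#'
#' @return Object of class `ur_draws`: list with `psi` (`N x k` matrix of
#'   retained draws), `sigma2` (length `N`), `logpost` (length `N`,
#'   unnormalized log posterior at each draw), and the sampler settings.
#' @export
ur_gibbs <- function(design, draws = 51000, burn = 1000, seed = 1,
                     jacobian_corrected = FALSE) {
  stopifnot(draws >= 1, burn >= 0, burn < draws)
  ols <- ur_ols(design)
  Tn <- design$T
  k <- design$k
  R <- chol(ols$XtX)                       # X'X = R'R, R upper triangular
  shape <- if (jacobian_corrected) Tn / 2 else (Tn + 1) / 2

  set.seed(as.integer(seed))
  n_keep <- draws - burn
  psi_out <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, design$column_labels))
  sig_out <- numeric(n_keep)
  sigma2 <- ols$ssr / (Tn + 1)
  for (i in seq_len(draws)) {
    # psi | sigma^2: psi_hat + sigma * R^{-1} z has covariance sigma^2 (X'X)^{-1}
    z <- rnorm(k)
    psi <- ols$psi_hat + sqrt(sigma2) * backsolve(R, z)
    qf <- sum((R %*% (psi - ols$psi_hat))^2)
    H <- 0.5 * (ols$ssr + qf)
    if (!is.finite(H) || H <= 0) {
      abort("Nonpositive Inverse-Gamma scale in the sigma^2 update.",
            class = "fbsts_degenerate_variance")
    }
    sigma2 <- 1 / rgamma(1L, shape = shape, rate = H)
    if (i > burn) {
      psi_out[i - burn, ] <- psi
      sig_out[i - burn] <- sigma2
    }
  }
  logpost <- ur_logpost(design, psi_out, sig_out, ols = ols)
  structure(
    list(psi = psi_out, sigma2 = sig_out, logpost = logpost,
         seed = as.integer(seed), burn_in = burn, n_draws = n_keep,
         jacobian_corrected = jacobian_corrected),
    class = "ur_draws"
  )
}

#' FBST unit-root test for an AR(p) series
#'
#' Tests the sharp hypothesis `G0 = 0` (one unit root) in the ADF form of an
#' AR(p) model, returning the FBST e-value supporting the hypothesis, the
#' posterior probability of non-stationarity `P(G0 >= 0 | y)`, and the
#' classical ADF t-statistic as a frequentist comparator (no p-value is
#' attached to it).
#'
#' The procedure: (1) build the ADF design ([ur_design()]); (2) find the
#' restricted posterior maximum `s*` under `G0 = 0` in closed form
#' ([ur_restricted_map()]); (3) draw from the unrestricted
#' Normal-Inverse-Gamma posterior by Gibbs sampling ([ur_gibbs()]);
#' (4) estimate the evidence against the hypothesis as the proportion of
#' draws whose posterior value exceeds `s*` ([estimate_evidence()]).
#' Large `ev` supports the unit root.
#'
#' @param data A data frame with one column per series, or a numeric vector.
#' @param column Column name holding the series (default: first numeric
#'   column).
#' @param p AR lag order.
#' @param constant,trend Deterministic terms; see [ur_design()].
#' @param draws,burn,seed,jacobian_corrected Sampler settings; see
#'   [ur_gibbs()].
#'
#' @return An object of class `fbst_ur` with [tidy()], [glance()] and
#'   [autoplot()] methods. `glance()` returns a one-row tibble with `ev`,
#'   `ev_bar`, `mc_se`, `prob_nonstationary`, `adf_tstat` and model
#'   dimensions.
#' @examples
#' y <- simulate_ar(ar_scenario(T = 100, phi = 0.6, seed = 42))
#' fit <- fbst_unit_root(y, p = 1, draws = 3000, burn = 500, seed = 7)
#' glance(fit)
#' @export
fbst_unit_root <- function(data, column = NULL, p = 1, constant = TRUE,
                           trend = FALSE, draws = 51000, burn = 1000,
                           seed = 1, jacobian_corrected = FALSE) {
  y <- extract_series(data, column)
  design <- ur_design(y, p = p, constant = constant, trend = trend)
  ols <- ur_ols(design)
  restr <- ur_restricted_map(design)

  # restricted maximum can never exceed the unrestricted one
  sigma2_hat <- ols$ssr / (design$T + 1)
  log_s_unrestricted <- -(design$T + 1) / 2 * log(sigma2_hat) -
    ols$ssr / (2 * sigma2_hat)
  stopifnot(restr$log_s_star <= log_s_unrestricted + 1e-8)

  post <- ur_gibbs(design, draws = draws, burn = burn, seed = seed,
                   jacobian_corrected = jacobian_corrected)
  evidence <- estimate_evidence(post$logpost, restr$log_s_star,
                                hypothesis = "Gamma0 = 0 (unit root)")
  g0 <- design$gamma0_col
  prob_nonstationary <- mean(post$psi[, g0] >= 0)
  adf_tstat <- unname(ols$psi_hat[g0] / ols$se[g0])

  structure(
    list(evidence = evidence,
         prob_nonstationary = prob_nonstationary,
         psi_hat = ols$psi_hat,
         se = ols$se,
         psi_hat_restricted = restr$psi_hat_r,
         sigma2_hat_restricted = restr$sigma2_hat_r,
         adf_tstat = adf_tstat,
         design = design,
         draws = post,
         settings = list(p = p, constant = constant, trend = trend,
                         draws = draws, burn = burn, seed = seed,
                         jacobian_corrected = jacobian_corrected)),
    class = "fbst_ur"
  )
}

extract_series <- function(data, column = NULL) {
  if (is.numeric(data)) return(as.numeric(data))
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame or a numeric vector.",
          class = "fbsts_invalid_input")
  }
  if (is.null(column)) {
    num <- vapply(data, is.numeric, logical(1))
    if (!any(num)) abort("No numeric column found.", class = "fbsts_invalid_input")
    column <- names(data)[which(num)[1L]]
  }
  if (!column %in% names(data)) {
    abort(sprintf("Column '%s' not found; available: %s.", column,
                  paste(names(data), collapse = ", ")),
          class = "fbsts_invalid_input")
  }
  as.numeric(data[[column]])
}

#' Map AR coefficients to their ADF-form parameters and back
#'
#' `gamma_from_phi()` converts AR(p) coefficients `phi` to the ADF-form
#' parameters `G0 = phi_1 + ... + phi_p - 1` and
#' `G_i = -(phi_{i+1} + ... + phi_p)`; `phi_from_gamma()` is the exact
#' inverse of this linear bijection.
#'
#' @param phi Numeric vector of AR coefficients, length `p`.
#' @return For `gamma_from_phi()`: list with `gamma0` (scalar) and `gammas`
#'   (length `p - 1`). For `phi_from_gamma()`: numeric vector `phi`.
#' @examples
#' gamma_from_phi(c(0.5, 0.3))  # gamma0 = -0.2, gammas = -0.3
#' phi_from_gamma(-0.2, -0.3)   # 0.5 0.3
#' @export
gamma_from_phi <- function(phi) {
  p <- length(phi)
  stopifnot(p >= 1)
  gamma0 <- sum(phi) - 1
  gammas <- if (p > 1L) {
    vapply(seq_len(p - 1L), function(i) -sum(phi[(i + 1L):p]), numeric(1))
  } else numeric(0)
  list(gamma0 = gamma0, gammas = gammas)
}

#' @rdname gamma_from_phi
#' @param gamma0 ADF-form coefficient of the lagged level.
#' @param gammas ADF-form coefficients of the lagged differences (length
#'   `p - 1`; may be empty for `p = 1`).
#' @export
phi_from_gamma <- function(gamma0, gammas = numeric(0)) {
  p <- length(gammas) + 1L
  if (p == 1L) return(gamma0 + 1)
  g_ext <- c(gammas, 0)                     # G_p := 0
  phi_tail <- g_ext[2:p] - g_ext[1:(p - 1)] # phi_{i+1} = G_{i+1} - G_i
  phi1 <- gamma0 + 1 + gammas[[1L]]
  c(phi1, phi_tail)
}

#' @export
print.fbst_ur <- function(x, ...) {
  ev <- x$evidence
  cat("FBST unit-root test (H: Gamma0 = 0)\n")
  cat(sprintf("  T = %d, p = %d, constant = %s, trend = %s\n",
              x$design$T, x$design$p, x$settings$constant, x$settings$trend))
  cat(sprintf("  e-value (support for unit root): %.4f  (MC se %.4f, %d draws)\n",
              ev$ev, ev$mc_se, ev$n_draws))
  cat(sprintf("  P(Gamma0 >= 0 | y): %.4f\n", x$prob_nonstationary))
  cat(sprintf("  ADF t-statistic: %.3f\n", x$adf_tstat))
  invisible(x)
}

#' @export
tidy.fbst_ur <- function(x, ...) {
  tibble(
    term = x$design$column_labels,
    estimate = unname(x$psi_hat),
    std.error = unname(x$se),
    estimate_restricted = unname(x$psi_hat_restricted)
  )
}

#' @export
glance.fbst_ur <- function(x, ...) {
  er <- x$evidence
  tibble(
    ev = er$ev, ev_bar = er$ev_bar, mc_se = er$mc_se,
    log_s_star = er$log_s_star,
    prob_nonstationary = x$prob_nonstationary,
    adf_tstat = x$adf_tstat,
    sigma2_hat_restricted = x$sigma2_hat_restricted,
    n_draws = er$n_draws, T = x$design$T, p = x$design$p
  )
}

#' @export
autoplot.fbst_ur <- function(object, ...) {
  g0 <- object$design$gamma0_col
  df <- tibble(gamma0 = object$draws$psi[, g0])
  ggplot(df, aes(x = .data$gamma0)) +
    geom_histogram(bins = 80, fill = "steelblue", colour = NA) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = expression(Gamma[0]),
         y = "posterior draws",
         title = "Posterior of the lagged-level coefficient",
         subtitle = sprintf("P(Gamma0 >= 0 | y) = %.4f, ev = %.4f",
                            object$prob_nonstationary, object$evidence$ev)) +
    theme_minimal()
}
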