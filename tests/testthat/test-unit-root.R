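test_that("ADF design has the documented shape and content", {
  set.seed(1)
  y <- cumsum(rnorm(10))
  d <- ur_design(y, p = 2, trend = TRUE)
  expect_equal(dim(d$X), c(8, 4))
  expect_equal(d$column_labels, c("const", "trend", "ylag", "dlag1"))
  expect_equal(d$X[, "trend"], as.numeric(3:10))  # raw dates p+1 ... T+p

  d1 <- ur_design(cumsum(rnorm(20)), p = 1)
  expect_equal(d1$column_labels, c("const", "ylag"))
  expect_equal(d1$k, 2L)

  # hand computation on a linear ramp
  d2 <- ur_design(c(1, 2, 3, 4, 5), p = 1)
  expect_equal(d2$dY, c(1, 1, 1, 1))
  expect_equal(unname(d2$X[, "ylag"]), c(1, 2, 3, 4))
})

test_that("ADF design rejects short or non-finite series", {
  expect_error(ur_design(c(1, 2, 3), p = 2), "at least",
               class = "fbsts_invalid_input")
  expect_error(ur_design(c(1, 2, NA, 4, 5, 6, 7, 8), p = 1), "index 3",
               class = "fbsts_invalid_input")
})

test_that("OLS fit matches an independent normal-equations solution", {
  set.seed(7)
  y <- cumsum(rnorm(60))
  d <- ur_design(y, p = 3, trend = TRUE)
  fit <- ur_ols(d)
  # oracle: explicit normal equations via solve()
  beta <- solve(crossprod(d$X), crossprod(d$X, d$dY))
  expect_equal(unname(fit$psi_hat), as.numeric(beta), tolerance = 1e-10)
  expect_equal(fit$ssr, sum((d$dY - d$X %*% beta)^2), tolerance = 1e-10)

  # response exactly in the column span: zero residual
  d2 <- d
  d2$dY <- as.numeric(d$X %*% c(0.5, -0.1, 0.2, 0.05, 0.01))
  expect_lt(ur_ols(d2)$ssr, 1e-18)
})

test_that("collinear designs raise a singular-design error naming columns", {
  d <- ur_design(c(1, 2, 3, 4, 5, 6, 7, 8), p = 1)
  # a constant level series makes ylag collinear with the constant
  d$X[, "ylag"] <- 1
  expect_error(ur_ols(d), "ylag", class = "fbsts_singular_design")
})

test_that("restricted MAP maximizes the constrained posterior", {
  set.seed(15)
  y <- simulate_ar(ar_scenario(T = 15, phi = 0.5, mu = 0.2, seed = 15))
  d <- ur_design(y, p = 1)
  restr <- ur_restricted_map(d)
  expect_equal(restr$sigma2_hat_r, restr$ssr_r / (d$T + 1))
  expect_equal(unname(restr$psi_hat_r[d$gamma0_col]), 0)

  # generic constrained-optimizer oracle
  expect_equal(restr$log_s_star, optim_restricted_ur(d), tolerance = 1e-6)

  # restricted maximum never exceeds the unrestricted one
  ols <- ur_ols(d)
  s2 <- ols$ssr / (d$T + 1)
  unrestr <- -(d$T + 1) / 2 * log(s2) - ols$ssr / (2 * s2)
  expect_lte(restr$log_s_star, unrestr + 1e-12)
})

test_that("a perfectly fit restricted model triggers the zero-variance guard", {
  d <- ur_design(c(1, 2, 3, 4, 5, 6, 7), p = 1)
  d$dY <- rep(0, length(d$dY))
  expect_error(ur_restricted_map(d), class = "fbsts_degenerate_variance")
})

test_that("the Gibbs chain is seed-reproducible and recovers the posterior mean", {
  y <- simulate_ar(ar_scenario(T = 200, phi = 0.6, mu = 0.3, seed = 21))
  d <- ur_design(y, p = 1)
  a <- ur_gibbs(d, draws = 2000, burn = 200, seed = 42)
  b <- ur_gibbs(d, draws = 2000, burn = 200, seed = 42)
  expect_identical(a$psi, b$psi)
  expect_identical(a$sigma2, b$sigma2)
  expect_identical(a$logpost, b$logpost)

  # posterior mean of psi equals the OLS estimate (within MC error)
  post <- ur_gibbs(d, draws = 21000, burn = 1000, seed = 5)
  ols <- ur_ols(d)
  n <- nrow(post$psi)
  for (j in seq_len(d$k)) {
    se_naive <- sd(post$psi[, j]) / sqrt(n)
    expect_lt(abs(mean(post$psi[, j]) - ols$psi_hat[j]), 4 * se_naive)
  }

  # self-consistency of the sigma^2 marginal against a long reference chain
  ref <- ur_gibbs(d, draws = 41000, burn = 1000, seed = 777)
  rel <- abs(mean(post$sigma2) - mean(ref$sigma2)) / mean(ref$sigma2)
  expect_lt(rel, 0.01)
})

test_that("unit-root e-values separate stationary series from random walks", {
  y_stat <- simulate_ar(ar_scenario(T = 300, gamma0 = -0.5, seed = 2))
  f_stat <- fbst_unit_root(y_stat, p = 1, draws = 11000, burn = 1000, seed = 3)
  expect_lt(f_stat$evidence$ev, 0.05)
  expect_lt(f_stat$prob_nonstationary, 0.01)

  y_rw <- simulate_ar(ar_scenario(T = 300, gamma0 = 0, seed = 2))
  f_rw <- fbst_unit_root(y_rw, p = 1, draws = 11000, burn = 1000, seed = 3)
  expect_gt(f_rw$evidence$ev, 0.2)

  # counting boundary: every draw strictly negative means probability zero
  expect_equal(mean(f_stat$draws$psi[, f_stat$design$gamma0_col] >= 0),
               f_stat$prob_nonstationary)
})

test_that("tidy, glance and report surfaces expose the fit", {
  y <- simulate_ar(ar_scenario(T = 80, phi = 0.5, seed = 31))
  f <- fbst_unit_root(y, p = 2, draws = 2000, burn = 200, seed = 1)
  td <- tidy(f)
  expect_equal(td$term, c("const", "ylag", "dlag1"))
  expect_equal(td$estimate_restricted[td$term == "ylag"], 0)
  gl <- glance(f)
  expect_equal(gl$ev + gl$ev_bar, 1)
  expect_s3_class(autoplot(f), "ggplot")
  rpt <- as_report(f)
  expect_equal(rpt$evidence$ev, gl$ev)
})

test_that("AR and ADF parametrizations are an exact linear bijection", {
  expect_equal(gamma_from_phi(1)$gamma0, 0)           # AR(1) unit root
  g <- gamma_from_phi(c(0.5, 0.3))
  expect_equal(g$gamma0, -0.2)
  expect_equal(g$gammas, -0.3)
  set.seed(9)
  for (p in 1:5) {
    phi <- rnorm(p)
    g <- gamma_from_phi(phi)
    expect_equal(phi_from_gamma(g$gamma0, g$gammas), phi, tolerance = 1e-12)
  }
})

test_that("the jacobian-corrected sampler matches the quadrature oracle closely", {
  y <- simulate_ar(ar_scenario(T = 29, phi = 0.7, mu = 0.5, seed = 8))
  d <- ur_design(y, p = 1)
  restr <- ur_restricted_map(d)
  ev_quad <- quadrature_ev(d, restr$log_s_star, ng = 140)
  post <- ur_gibbs(d, draws = 31000, burn = 1000, seed = 3,
                   jacobian_corrected = TRUE)
  ev_gibbs <- 1 - mean(post$logpost > restr$log_s_star)
  expect_lt(abs(ev_quad - ev_gibbs), 0.01)
})
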