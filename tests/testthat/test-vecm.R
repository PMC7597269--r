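rank1_scenario <- function(T = 200, seed = 4) {
  vecm_scenario(n = 2, T = T, r = 1,
                alpha = matrix(c(-0.4, 0.1)),
                beta = matrix(c(1, -1)), seed = seed)
}

test_that("VECM design stacks the regressors in the documented order", {
  set.seed(3)
  Y4 <- matrix(cumsum(rnorm(200)), ncol = 4)
  d4 <- vecm_design(Y4, p = 1)                     # constant + lagged levels
  expect_equal(ncol(d4$Z), 5L)
  expect_equal(ncol(d4$Z1), 1L)
  expect_equal(d4$Z[, 2:5], unname(d4$Ylag), ignore_attr = TRUE)

  Y2 <- matrix(cumsum(rnorm(120)), ncol = 2)
  d2 <- vecm_design(Y2, p = 2, constant = FALSE)   # dY lags + levels only
  expect_equal(ncol(d2$Z), 4L)
  expect_equal(ncol(d2$Z1), 2L)

  expect_error(vecm_design(matrix(rnorm(6), 3, 2), p = 2),
               class = "fbsts_invalid_input")
})

test_that("seasonal dummies are 0/1 indicators for the first s-1 seasons", {
  set.seed(3)
  Y <- matrix(cumsum(rnorm(160)), ncol = 2)
  d <- vecm_design(Y, p = 2, seasonal = 4)
  expect_equal(d$n_det, 4L)                        # constant + 3 dummies
  sd_cols <- d$Z1[, c("sd1", "sd2", "sd3")]
  expect_true(all(sd_cols %in% c(0, 1)))
  expect_true(all(rowSums(sd_cols) <= 1))
  dc <- vecm_design(Y, p = 2, seasonal = 4, seasonal_centered = TRUE)
  expect_equal(sort(unique(as.vector(dc$Z1[, "sd1"]))), c(-0.25, 0.75))
})

test_that("reduced-rank eigenvalues are the squared canonical correlations", {
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 50, seed = 17)))
  d <- vecm_design(Y, p = 1)
  j <- johansen_step(d)
  expect_equal(j$eigenvalues, cca_squared_correlations(j$U, j$V),
               tolerance = 1e-8)
  expect_true(all(diff(j$eigenvalues) <= 0))
  expect_true(all(j$eigenvalues >= 0 & j$eigenvalues <= 1))
  # normalization v' Sigma_VV v = 1, largest component positive
  for (k in 1:2) {
    v <- j$eigenvectors[, k]
    expect_equal(as.numeric(t(v) %*% j$Sigma_VV %*% v), 1, tolerance = 1e-10)
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("degenerate and orthogonal inputs hit the eigenvalue boundaries", {
  # lagged levels spanning the differenced response: perfect correlation
  set.seed(23)
  A <- matrix(rnorm(80), 40, 2)
  d <- list(dY = A, Z1 = matrix(numeric(0), 40, 0), Ylag = A,
            Z = A, n = 2L, p = 1L, T = 40L, n_det = 0L)
  class(d) <- "vecm_design"
  j <- johansen_step(d)
  expect_equal(j$eigenvalues, c(1, 1), tolerance = 1e-10)

  # independent white noise: all eigenvalues near zero at large T
  set.seed(29)
  d0 <- list(dY = matrix(rnorm(20000), ncol = 2),
             Z1 = matrix(numeric(0), 10000, 0),
             Ylag = matrix(rnorm(20000), ncol = 2),
             n = 2L, p = 1L, T = 10000L, n_det = 0L)
  d0$Z <- d0$Ylag
  class(d0) <- "vecm_design"
  expect_lt(max(johansen_step(d0)$eigenvalues), 0.01)

  # constant series: singular covariance block is reported as such
  Yc <- cbind(rep(1, 30), cumsum(rnorm(30)))
  expect_error(johansen_step(vecm_design(Yc, p = 1)),
               class = "fbsts_singular_covariance")
})

test_that("eigenvalues are invariant to rescaling the series' units", {
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 120, seed = 19)))
  d1 <- vecm_design(Y, p = 2)
  d2 <- vecm_design(Y %*% diag(c(1000, 0.01)), p = 2)
  expect_equal(johansen_step(d1)$eigenvalues, johansen_step(d2)$eigenvalues,
               tolerance = 1e-8)
})

test_that("the Frisch-Waugh-Lovell identity holds on full-rank designs", {
  for (seed in c(5, 6)) {
    Y <- as.matrix(simulate_vecm(rank1_scenario(T = 80, seed = seed)))
    expect_true(fwl_check(vecm_design(Y, p = 2)))
  }
  # empty Z1 (no deterministics, p = 1): identity is trivial
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 60, seed = 7)))
  expect_true(fwl_check(vecm_design(Y, p = 1, constant = FALSE)))
})

test_that("restricted posterior maxima agree across routes and nest in r", {
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 100, seed = 13)))
  d <- vecm_design(Y, p = 1)
  j <- johansen_step(d)
  ls <- vapply(0:2, function(r) {
    rm_ <- coint_restricted_max(j, d, r, route = "both")
    expect_equal(rm_$log_s_star_closed, rm_$log_s_star_reconstructed,
                 tolerance = 1e-6)
    rm_$log_s_star
  }, numeric(1))
  expect_true(!is.unsorted(ls))

  # r = n reproduces the unrestricted concentrated maximum (OLS eta, S/nu)
  qrz <- qr(d$Z)
  eta_hat <- qr.coef(qrz, d$dY)
  A <- crossprod(d$dY - d$Z %*% eta_hat)
  nu <- d$T + d$n + 1
  Om <- A / nu
  unrestr <- -(nu / 2) * determinant(Om)$modulus[1] - 0.5 * sum(solve(Om) * A)
  expect_equal(ls[3], unrestr, tolerance = 1e-8)

  expect_error(coint_restricted_max(j, d, 3), class = "fbsts_invalid_input")
})

test_that("restricted maxima match a generic constrained optimizer", {
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 20, seed = 13)))
  d <- vecm_design(Y, p = 1)
  j <- johansen_step(d)
  starts <- list(
    `0` = c(0, 0, 0, 0, 0),
    `1` = c(0, 0, -0.3, 0.3, 1, -1, 0, 0, 0),
    `2` = c(0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  for (r in 0:2) {
    rm_ <- coint_restricted_max(j, d, r, route = "both")
    opt <- optim_restricted_vecm(d, r, starts[[as.character(r)]])
    expect_equal(rm_$log_s_star, opt, tolerance = 1e-4)
  }
})

test_that("the VECM Gibbs chain is reproducible with valid covariance draws", {
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 100, seed = 4)))
  d <- vecm_design(Y, p = 1)
  a <- vecm_gibbs(d, draws = 1500, burn = 200, seed = 12)
  b <- vecm_gibbs(d, draws = 1500, burn = 200, seed = 12)
  expect_identical(a$eta, b$eta)
  expect_identical(a$logpost, b$logpost)
  spd <- apply(a$Omega, 1, function(v) {
    M <- matrix(v, d$n, d$n)
    isSymmetric(M, tol = 1e-10) &&
      !inherits(tryCatch(chol(M), error = identity), "error")
  })
  expect_true(all(spd))
})

test_that("VECM posterior draw means recover the OLS coefficients", {
  Y <- as.matrix(simulate_vecm(rank1_scenario(T = 300, seed = 4)))
  d <- vecm_design(Y, p = 1)
  post <- vecm_gibbs(d, draws = 16000, burn = 1000, seed = 6)
  N <- dim(post$eta)[1]
  em <- apply(post$eta, c(2, 3), mean)
  ese <- apply(post$eta, c(2, 3), sd) / sqrt(N)
  expect_true(all(abs(em - post$eta_hat) < 4 * ese))
})

test_that("max-eigenvalue statistic follows its closed form", {
  j <- structure(list(eigenvalues = c(0.3, 0.1), T = 100L, n = 2L),
                 class = "johansen_decomp")
  expect_equal(maxeig_stat(j, 1), -100 * log(0.9), tolerance = 1e-10)
  expect_equal(round(maxeig_stat(j, 1), 4), 10.5361)
  j0 <- structure(list(eigenvalues = c(0.3, 0), T = 100L, n = 2L),
                  class = "johansen_decomp")
  expect_equal(maxeig_stat(j0, 1), 0)
  expect_gt(maxeig_stat(j, 0), maxeig_stat(j, 1))  # monotone in lambda
  expect_error(maxeig_stat(j, 2), class = "fbsts_invalid_input")
})

test_that("rank e-values are nested, end at 1, and recover the true rank", {
  fit <- fbst_coint(simulate_vecm(rank1_scenario(T = 200, seed = 4)),
                    draws = 11000, burn = 1000, seed = 5)
  pr <- tidy(fit)
  expect_true(!is.unsorted(pr$ev))
  expect_identical(pr$ev[pr$rank == 2], 1)
  expect_lt(pr$ev[pr$rank == 0], 0.05)
  expect_gt(pr$ev[pr$rank == 1], 0.9)
  expect_equal(pr$m, c(9, 9, 9))
  expect_equal(pr$h, c(5, 6, 7))
  expect_s3_class(autoplot(fit), "ggplot")
  rpt <- as_report(fit)
  expect_length(rpt$per_rank, 3L)
})

test_that("cointegration direction is recovered across replications", {
  beta_true <- c(1, -1)
  angles <- vapply(1:50, function(s) {
    Y <- as.matrix(simulate_vecm(rank1_scenario(T = 400, seed = 1000 + s)))
    j <- johansen_step(vecm_design(Y, p = 1))
    b <- j$eigenvectors[, 1]
    cosang <- abs(sum(b * beta_true)) /
      (sqrt(sum(b^2)) * sqrt(sum(beta_true^2)))
    acos(pmin(cosang, 1)) * 180 / pi
  }, numeric(1))
  expect_lt(median(angles), 5)
})
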