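# Laplace approximation, evidence and the fit surface.

# tiny model with only intercept (+ optional covariate) on a coarse mesh
toy_model <- function(n_events = 5, beta_precision = 1e-8, covariate = FALSE,
                      seed = 71) {
  mesh <- build_mesh(unit_square, 2, extension_fraction = 0)  # 4 vertices
  set.seed(seed)
  ev <- grid_events(unit_square, n_events, t = 1L)
  pat <- lgcp_pattern(ev$x, ev$y, ev$t, unit_square, T = 1)
  des <- NULL
  if (covariate) {
    Z <- matrix(seq(-1, 1, length.out = nrow(mesh$vertices)),
                dimnames = list(NULL, "z1"))
    des <- covariate_design(Z)
  }
  spec <- lgcp_spec(trend = FALSE, seasonal = FALSE, cycle = FALSE,
                    field = FALSE, beta_precision = beta_precision)
  lgcp_model(pat, mesh, spec, covariates = des)
}

test_that("intercept-only Laplace mode solves the 1-D score equation", {
  mod <- toy_model(n_events = 5)
  ga <- gaussian_approx(mod)
  # score: n_events - |window| e^eta = 0 with a flat prior
  expect_equal(ga$mean[1], log(5), tolerance = 1e-7)
  expect_true(ga$converged)
})

test_that("Gaussian pseudo-likelihood makes one Newton step exact (GLS)", {
  mod <- toy_model()
  # replace rows by three direct Gaussian observations of the intercept
  mod$aug$y <- c(0.4, 1.1, -0.2); mod$aug$a <- c(2, 1, 0.5)
  mod$aug$is_event <- rep(TRUE, 3)
  mod$A <- Matrix::Matrix(matrix(1, 3, 1), sparse = TRUE)
  ga <- gaussian_approx(mod, family = "gaussian", max_iter = 2L)
  w <- c(2, 1, 0.5)
  gls <- sum(w * mod$aug$y) / (sum(w) + 1e-8)
  expect_equal(ga$mean[1], gls, tolerance = 1e-12)
  expect_lte(ga$iterations, 2L)
})

test_that("Laplace evidence is exact for the conjugate Gaussian toy and
           factorises over empty components", {
  mod <- toy_model(beta_precision = 2)
  y <- c(1.2, 0.7, 1.9)
  mod$aug$y <- y; mod$aug$a <- rep(1, 3); mod$aug$is_event <- rep(TRUE, 3)
  mod$A <- Matrix::Matrix(matrix(1, 3, 1), sparse = TRUE)
  th0 <- setNames(numeric(0), character(0))
  val <- as.numeric(log_marginal_hyper(mod, th0, family = "gaussian"))
  S <- diag(3) + tcrossprod(rep(1, 3)) / 2
  exact <- as.numeric(-0.5 * t(y) %*% solve(S, y) -
                        0.5 * determinant(S)$modulus - 1.5 * log(2 * pi))
  expect_equal(val, exact, tolerance = 1e-8)
})

test_that("Laplace latent posterior matches dense 2-D quadrature within 1%", {
  mod <- toy_model(n_events = 150, beta_precision = 0.5, covariate = TRUE)
  ga <- gaussian_approx(mod)
  d <- 2L
  Sig <- as.matrix(Matrix::solve(ga$Q_post, diag(d)))
  lap_mean <- ga$mean; lap_sd <- sqrt(diag(Sig))

  # exact posterior by dense quadrature over (intercept, beta)
  y <- mod$aug$y; a <- mod$aug$a; A <- as.matrix(mod$A)
  logpost <- function(b0, b1) {
    eta <- A %*% c(b0, b1)
    sum(y * eta) - sum(a * exp(eta)) - 0.25 * (b0^2 + b1^2)
  }
  g0 <- seq(lap_mean[1] - 6 * lap_sd[1], lap_mean[1] + 6 * lap_sd[1], length.out = 201)
  g1 <- seq(lap_mean[2] - 6 * lap_sd[2], lap_mean[2] + 6 * lap_sd[2], length.out = 201)
  lp <- outer(g0, g1, Vectorize(logpost))
  wgt <- exp(lp - max(lp)); wgt <- wgt / sum(wgt)
  m0 <- sum(rowSums(wgt) * g0); m1 <- sum(colSums(wgt) * g1)
  s0 <- sqrt(sum(rowSums(wgt) * (g0 - m0)^2))
  s1 <- sqrt(sum(colSums(wgt) * (g1 - m1)^2))

  expect_lt(abs(lap_mean[1] - m0), 0.01 * max(abs(m0), s0))
  expect_lt(abs(lap_mean[2] - m1), 0.01 * max(abs(m1), s1))
  expect_lt(abs(lap_sd[1] - s0) / s0, 0.01)
  expect_lt(abs(lap_sd[2] - s1) / s1, 0.01)
})

test_that("evidence prefers the data-generating field dependence over a
           sign-flipped one", {
  scn <- lgcp_scenario(square10, T = 6,
                       mesh = list(max_edge_inner = 2.5, extension_fraction = 0),
                       intercept = 0.3, trend = NULL, seasonal = NULL,
                       cycle = NULL,
                       field = list(sigma = 1, rho = 3, phi = 0.7), seed = 5)
  sim <- simulate_pattern(scn)
  spec <- lgcp_spec(trend = FALSE, seasonal = FALSE, cycle = FALSE,
                    field = TRUE, sigma0 = 1, rho0 = 3)
  mod <- lgcp_model(sim$pattern, sim$mesh, spec)
  th_true <- mod$layout$theta_init
  th_true["z_phi_group"] <- atanh(0.7)
  th_flip <- th_true
  th_flip["z_phi_group"] <- atanh(-0.7)
  expect_gt(as.numeric(log_marginal_hyper(mod, th_true)),
            as.numeric(log_marginal_hyper(mod, th_flip)))
})

test_that("fits are reproducible bit-for-bit under a fixed seed and expose
           ordered summaries", {
  scn <- lgcp_scenario(square10, T = 8,
                       mesh = list(max_edge_inner = 3, extension_fraction = 0),
                       intercept = 0.5,
                       trend = list(path = c(0.4, 0.25, 0.1, -0.1, -0.25, -0.1, 0.1, 0.3)),
                       seasonal = list(period = 4, phi = 1, path = rep(c(-0.2, 0, 0.2, 0), 2)),
                       cycle = list(p1 = 0.3, p2 = -0.3, sd = 0.05),
                       field = NULL, seed = 9)
  sim <- simulate_pattern(scn)
  spec <- lgcp_spec(field = FALSE)
  mod <- lgcp_model(sim$pattern, sim$mesh, spec)
  f1 <- fit_lgcp(mod, seed = 3)
  f2 <- fit_lgcp(mod, seed = 3)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$hyper, f2$hyper)
  expect_identical(f1$latent, f2$latent)

  # quantiles ordered, trend constrained to sum zero
  expect_true(all(f1$hyper$q0.025 <= f1$hyper$q0.5 + 1e-12))
  expect_true(all(f1$hyper$q0.5 <= f1$hyper$q0.975 + 1e-12))
  expect_lt(abs(sum(f1$components$trend$mean)), 1e-6)

  dec1 <- extract_components(f1)
  dec2 <- extract_components(f2)
  expect_identical(dec1$totals, dec2$totals)
  expect_true(all(dec1$temporal$lwr <= dec1$temporal$mean + 1e-12))
  expect_true(all(dec1$temporal$mean <= dec1$temporal$upr + 1e-12))
})

test_that("the grid strategy mixes over design points and does not shrink
           latent uncertainty below the empirical-Bayes fit", {
  scn <- lgcp_scenario(square10, T = 6,
                       mesh = list(max_edge_inner = 4, extension_fraction = 0),
                       intercept = 0.3,
                       trend = list(path = c(0.3, 0.15, 0, -0.15, 0, 0.2)),
                       seasonal = NULL, cycle = NULL, field = NULL, seed = 13)
  sim <- simulate_pattern(scn)
  spec <- lgcp_spec(seasonal = FALSE, cycle = FALSE, field = FALSE)
  mod <- lgcp_model(sim$pattern, sim$mesh, spec)
  f_eb <- fit_lgcp(mod, strategy = "eb", seed = 1)
  f_gr <- fit_lgcp(mod, strategy = "grid", seed = 1)
  expect_equal(sum(f_gr$grid$weights), 1, tolerance = 1e-12)
  expect_equal(length(f_gr$grid$points), 2 * length(f_gr$theta) + 1)
  expect_equal(f_gr$theta, f_eb$theta)
  # mixing over theta can only add latent spread
  expect_true(all(f_gr$latent$sd >= f_eb$latent$sd - 1e-8))
})
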