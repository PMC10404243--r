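# Laplace-approximation inference for the latent Gaussian LGCP model:
# Newton optimisation of the latent posterior given hyperparameters,
# Laplace approximation of the hyperparameter marginal posterior, and
# empirical-Bayes (or small-grid) exploration of that posterior.

#' Log-likelihood of the augmented Poisson pseudo-observations
#' @noRd
pseudo_loglik <- function(eta, y, a, family = "poisson") {
  if (family == "poisson") {
    sum(y * eta) - sum(a * exp(pmin(eta, 50)))
  } else {  # gaussian pseudo-likelihood: a is the per-row precision
    sum(-0.5 * a * (y - eta)^2 + 0.5 * log(a / (2 * pi)))
  }
}

#' Gaussian (Laplace) approximation of the latent field at fixed
#' hyperparameters
#'
#' Newton optimisation of the latent log-posterior (Poisson pseudo-likelihood
#' plus GMRF prior) with step halving; convergence when the gradient's
#' largest entry falls below `grad_tol` or the relative mode change falls
#' below `step_tol`. Sum-to-zero constraints are imposed afterwards by
#' conditioning by kriging.
#'
#' @param model an `lgcp_model`.
#' @param theta named hyperparameter vector on the transformed scale
#'   (defaults to the layout's initial values).
#' @param x0 optional warm start for the latent mode.
#' @param family `"poisson"` (the LGCP pseudo-likelihood) or `"gaussian"`
#'   (exact conjugate case, used for verification).
#' @param max_iter,grad_tol,step_tol Newton controls.
#' @return list with the constrained mode `mean`, the unconstrained mode,
#'   the posterior precision `Q_post`, its Cholesky factor, log-determinants,
#'   the log-likelihood and prior quadratic form at the mode, and the
#'   constraint bookkeeping (`V = Q_post^-1 A_c'`, `S = A_c Q_post^-1 A_c'`).
#' @export
gaussian_approx <- function(model, theta = model$layout$theta_init, x0 = NULL,
                            family = "poisson",
                            max_iter = 50L, grad_tol = 1e-6, step_tol = 1e-8) {
  layout <- model$layout; A <- model$A
  y <- model$aug$y; a <- model$aug$a
  Qp <- layout$prior_precision(theta)
  d <- layout$dim

  if (is.null(x0)) {
    x0 <- numeric(d)
    if (family == "poisson") {
      tot_a <- sum(a)
      x0[1L] <- log((sum(y) + 0.5) / max(tot_a, 1e-12))
    }
  }
  x <- x0
  obj <- function(x, eta) pseudo_loglik(eta, y, a, family) -
    0.5 * as.numeric(Matrix::crossprod(x, Qp %*% x))

  eta <- as.numeric(A %*% x)
  f <- obj(x, eta)
  converged <- FALSE
  ch <- NULL
  for (it in seq_len(max_iter)) {
    if (family == "poisson") {
      mu <- a * exp(pmin(eta, 50))
      g_lik <- y - mu
      w <- mu
    } else {
      g_lik <- a * (y - eta)
      w <- a
    }
    grad <- as.numeric(Matrix::crossprod(A, g_lik)) - as.numeric(Qp %*% x)
    Qpost <- methods::as(Matrix::forceSymmetric(Qp + Matrix::crossprod(A, A * w)),
                         "CsparseMatrix")
    ch <- suppressWarnings(Matrix::Cholesky(Qpost, LDL = FALSE, perm = TRUE))
    dx <- as.numeric(Matrix::solve(ch, grad))
    step <- 1
    repeat {
      x_new <- x + step * dx
      eta_new <- as.numeric(A %*% x_new)
      f_new <- obj(x_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12 * abs(f)) break
      step <- step / 2
      if (step < 1e-10) break
    }
    rel_change <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x^2)), 1)
    x <- x_new; eta <- eta_new; f <- f_new
    if (max(abs(grad)) < grad_tol || rel_change < step_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(structure(class = c("lgcp_convergence_error", "error", "condition"),
                   list(message = sprintf("Newton did not converge in %d iterations (last |grad| %.3g)",
                                          max_iter, max(abs(grad))),
                        call = NULL, last_iterate = x)))

  # final curvature at the mode
  if (family == "poisson") w <- a * exp(pmin(eta, 50)) else w <- a
  Qpost <- methods::as(Matrix::forceSymmetric(Qp + Matrix::crossprod(A, A * w)), "CsparseMatrix")
  ch <- chol_spd(Qpost)
  logdet_post <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)

  # conditioning by kriging for sum-to-zero constraints
  Ac <- layout$constraints
  V <- NULL; S <- NULL; x_c <- x; logdet_S <- 0
  if (nrow(Ac) > 0L) {
    V <- as.matrix(Matrix::solve(ch, t(Ac)))
    S <- Ac %*% V
    x_c <- x - as.numeric(V %*% solve(S, Ac %*% x))
    logdet_S <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  }
  eta_c <- as.numeric(A %*% x_c)

  list(mean = x_c, mode_unconstrained = x, eta = eta_c,
       Q_prior = Qp, Q_post = Qpost, chol = ch,
       logdet_post = logdet_post, logdet_S = logdet_S, V = V, S = S,
       loglik = pseudo_loglik(eta_c, y, a, family),
       prior_quad = 0.5 * as.numeric(Matrix::crossprod(x_c, Qp %*% x_c)),
       iterations = it, converged = converged, family = family)
}

#' Log prior density of the transformed hyperparameters
#' @noRd
theta_log_prior <- function(layout, theta) {
  pr <- layout$spec$priors
  lp <- 0
  for (nm in layout$theta_names) {
    v <- unname(theta[[nm]])
    if (startsWith(nm, "log_prec")) {
      lp <- lp + pr$prec_shape * v - pr$prec_rate * exp(v)  # log-gamma
    } else if (startsWith(nm, "z_")) {
      lp <- lp + stats::dnorm(v, 0, pr$z_sd, log = TRUE)
    } else if (nm == "log_tau") {
      lp <- lp + stats::dnorm(v, layout$theta_init[["log_tau"]], pr$logtau_sd, log = TRUE)
    } else if (nm == "log_kappa") {
      lp <- lp + stats::dnorm(v, layout$theta_init[["log_kappa"]], pr$logkappa_sd, log = TRUE)
    }
  }
  lp
}

#' Laplace approximation of the hyperparameter log-posterior
#'
#' `log pi(theta | Y)` up to a constant: hyperprior plus the Laplace
#' evidence `loglik(x*) - prior quadratic + 0.5 log|Q_prior| -
#' 0.5 log|Q_post|` (generalised determinant for intrinsic blocks, with the
#' constraint correction when sum-to-zero constraints are active).
#'
#' @param model an `lgcp_model`.
#' @param theta named hyperparameter vector (transformed scale).
#' @param ga optional precomputed [gaussian_approx()] result at `theta`.
#' @param family passed to [gaussian_approx()].
#' @return scalar log-density (unnormalised); attribute `"ga"` carries the
#'   Gaussian approximation.
#' @export
log_marginal_hyper <- function(model, theta, ga = NULL, family = "poisson") {
  if (is.null(ga)) ga <- gaussian_approx(model, theta, family = family)
  layout <- model$layout
  val <- theta_log_prior(layout, theta) +
    0.5 * layout$prior_logdet(theta) -
    ga$prior_quad + ga$loglik -
    0.5 * ga$logdet_post - 0.5 * ga$logdet_S
  attr(val, "ga") <- ga
  val
}

#' Fit the dynamic LGCP model
#'
#' Empirical-Bayes strategy (`"eb"`): BFGS maximisation of
#' [log_marginal_hyper()]; hyperparameter spread from the negative inverse
#' Hessian at the mode, Gaussian on the transformed scale. Grid strategy
#' (`"grid"`): a star design around the mode, with evidence-weighted mixture
#' summaries. Latent summaries come from the Gaussian approximation at the
#' mode (or the weighted mixture).
#'
#' @param model an `lgcp_model`.
#' @param strategy `"eb"` or `"grid"`.
#' @param seed integer seed governing every stochastic step downstream
#'   (posterior draws in [extract_components()]).
#' @param theta_init optional start values; defaults to the layout's.
#' @param control list: `maxit` (BFGS iterations, default 100), `grid_delta`
#'   (star-design step in posterior sds, default 1.1), `reltol`.
#' @return object of class `lgcp_fit`.
#' @export
fit_lgcp <- function(model, strategy = c("eb", "grid"), seed = 1L,
                     theta_init = NULL, control = list()) {
  strategy <- match.arg(strategy)
  ctl <- utils::modifyList(list(maxit = 100L, grid_delta = 1.1, reltol = 1e-8),
                           control)
  layout <- model$layout
  theta0 <- theta_init %||% layout$theta_init
  cache <- new.env(parent = emptyenv())
  cache$x0 <- NULL

  negll <- function(th) {
    names(th) <- layout$theta_names
    val <- tryCatch({
      ga <- gaussian_approx(model, th, x0 = cache$x0)
      cache$x0 <- ga$mode_unconstrained
      as.numeric(log_marginal_hyper(model, th, ga = ga))
    }, error = function(e) -Inf)
    if (!is.finite(val)) return(1e10)
    -val
  }

  if (length(theta0)) {
    opt <- stats::optim(theta0, negll, method = "BFGS",
                        control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    if (!opt$convergence %in% c(0L, 1L))
      stop("fit error: hyperparameter optimisation failed (code ", opt$convergence, ")",
           call. = FALSE)
    theta_hat <- opt$par
    H <- stats::optimHess(theta_hat, negll)
    cov_theta <- tryCatch(solve(H), error = function(e) NULL)
    ok <- !is.null(cov_theta) && all(diag(cov_theta) > 0)
    if (!ok) {
      warning("non-SPD hyperparameter Hessian; falling back to diagonal curvature")
      dH <- pmax(diag(H), 1e-8)
      cov_theta <- diag(1 / dH, nrow = length(dH))
    }
    dimnames(cov_theta) <- list(layout$theta_names, layout$theta_names)
  } else {
    theta_hat <- theta0
    cov_theta <- matrix(0, 0L, 0L)
  }
  names(theta_hat) <- layout$theta_names

  grid_points <- NULL; grid_weights <- NULL
  if (strategy == "grid" && length(theta_hat)) {
    sds <- sqrt(pmax(diag(cov_theta), 0))
    pts <- list(theta_hat)
    for (k in seq_along(theta_hat)) {
      for (sgn in c(-1, 1)) {
        th <- theta_hat; th[k] <- th[k] + sgn * ctl$grid_delta * sds[k]
        pts <- c(pts, list(th))
      }
    }
    lv <- vapply(pts, function(th) -negll(th), numeric(1))
    wts <- exp(lv - max(lv)); wts <- wts / sum(wts)
    grid_points <- pts; grid_weights <- wts
  }

  ga <- gaussian_approx(model, theta_hat, x0 = cache$x0)
  marg <- latent_marginals(model, ga)

  if (strategy == "grid" && length(theta_hat)) {
    mix_mean <- 0; mix_m2 <- 0
    for (g in seq_along(grid_points)) {
      gg <- if (g == 1L) ga else gaussian_approx(model, grid_points[[g]],
                                                 x0 = cache$x0)
      mg <- if (g == 1L) marg else latent_marginals(model, gg)
      mix_mean <- mix_mean + grid_weights[g] * mg$mean
      mix_m2 <- mix_m2 + grid_weights[g] * (mg$sd^2 + mg$mean^2)
    }
    marg <- list(mean = mix_mean, sd = sqrt(pmax(mix_m2 - mix_mean^2, 0)))
  }

  hyper <- hyper_summaries(layout, theta_hat, cov_theta)
  fixed <- block_summaries(marg, layout$ranges$fixed,
                           c("intercept", if (layout$p) model$covariates$names))
  comp <- list()
  for (nm in c("trend", "seasonal", "cycle"))
    if (!is.null(layout$ranges[[nm]]))
      comp[[nm]] <- block_summaries(marg, layout$ranges[[nm]],
                                    paste0(nm, "_", seq_len(layout$T)))

  # fitted log-intensity at mesh vertices (vertex pseudo-rows come first in
  # each period block of the design)
  N <- model$aug$N; T <- layout$T
  vrows <- which(!model$aug$is_event)
  eta_fit <- matrix(ga$eta[vrows], N, T)

  field <- NULL
  if (!is.null(layout$ranges$field)) {
    idx <- layout$ranges$field
    xi_mean <- matrix(marg$mean[idx], N, T)
    xi_sd <- matrix(marg$sd[idx], N, T)
    field <- list(mean = xi_mean, sd = xi_sd,
                  time_avg_mean = rowMeans(xi_mean),
                  time_avg_sd = sqrt(rowMeans(xi_sd^2) / T))
  }

  structure(list(model = model, strategy = strategy, seed = seed,
                 theta = theta_hat, cov_theta = cov_theta,
                 hyper = hyper, fixed = fixed, components = comp,
                 field = field, eta_fit = eta_fit,
                 latent = marg, ga = ga,
                 grid = if (strategy == "grid")
                   list(points = grid_points, weights = grid_weights),
                 convergence = list(newton_iterations = ga$iterations,
                                    converged = ga$converged)),
            class = "lgcp_fit")
}

#' Marginal means and sds of the latent field (constraint-corrected)
#' @noRd
latent_marginals <- function(model, ga) {
  d <- model$layout$dim
  Sigma <- as.matrix(Matrix::solve(ga$Q_post, Matrix::Diagonal(d)))
  if (!is.null(ga$V)) Sigma <- Sigma - ga$V %*% solve(ga$S, t(ga$V))
  list(mean = ga$mean, sd = sqrt(pmax(diag(Sigma), 0)))
}

#' Tables-1/2 style summary rows on the natural scale
#' @noRd
hyper_summaries <- function(layout, theta_hat, cov_theta) {
  if (!length(theta_hat))
    return(data.frame(parameter = character(0), mean = numeric(0), sd = numeric(0),
                      q0.025 = numeric(0), q0.5 = numeric(0), q0.975 = numeric(0),
                      mode = numeric(0)))
  trans <- function(nm) {
    if (startsWith(nm, "log_prec")) list(f = exp, label = sub("log_", "", nm))
    else if (startsWith(nm, "z_")) list(f = tanh, label = sub("z_", "", nm))
    else list(f = identity, label = nm)
  }
  rows <- lapply(seq_along(theta_hat), function(k) {
    nm <- layout$theta_names[k]
    tr <- trans(nm)
    m <- theta_hat[k]; s <- sqrt(max(cov_theta[k, k], 0))
    qs <- tr$f(stats::qnorm(c(0.025, 0.5, 0.975), m, s))
    # delta-method moments on the natural scale
    eps <- 1e-5
    deriv <- (tr$f(m + eps) - tr$f(m - eps)) / (2 * eps)
    data.frame(parameter = tr$label, mean = tr$f(m), sd = abs(deriv) * s,
               q0.025 = min(qs), q0.5 = qs[2L], q0.975 = max(qs), mode = tr$f(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @noRd
block_summaries <- function(marg, idx, labels) {
  m <- marg$mean[idx]; s <- marg$sd[idx]
  data.frame(parameter = labels, mean = m, sd = s,
             q0.025 = m - 1.959964 * s, q0.5 = m, q0.975 = m + 1.959964 * s,
             mode = m)
}

#' @export
print.lgcp_fit <- function(x, ...) {
  cat(sprintf("lgcp_fit (%s): %d hyperparameters, latent dim %d, seed %d\n",
              x$strategy, length(x$theta), x$model$layout$dim, x$seed))
  if (nrow(x$hyper)) {
    cat("hyperparameters (natural scale):\n")
    print(x$hyper, digits = 4)
  }
  cat("fixed effects:\n")
  print(x$fixed, digits = 4)
  invisible(x)
}
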