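# Matern covariance bookkeeping and the SPDE/GMRF precision.
#
# The spatial field is a stationary Matern field with smoothness nu = 1
# (operator order alpha = 2 in two dimensions), represented on the mesh as a
# Gaussian Markov random field whose sparse precision comes from the
# finite-element discretisation of (kappa^2 - Laplacian) x(s) = white noise.

#' Matern correlation function
#'
#' `C(h) = 2^(1-nu)/Gamma(nu) (kappa h)^nu K_nu(kappa h)`, with `C(0) = 1`
#' by continuity.
#'
#' @param h non-negative distance(s).
#' @param kappa spatial scale parameter (`> 0`); `kappa = sqrt(8 nu) / rho`
#'   where `rho` is the distance at which correlation drops to about 0.14.
#' @param nu smoothness (`> 0`), default 1.
#' @return correlation value(s) in `(0, 1]`.
#' @export
matern_correlation <- function(h, kappa, nu = 1) {
  if (any(h < 0)) stop("domain error: h must be non-negative", call. = FALSE)
  if (kappa <= 0 || nu <= 0) stop("domain error: kappa and nu must be positive", call. = FALSE)
  out <- numeric(length(h))
  z <- kappa * h
  pos <- z > 0
  out[!pos] <- 1
  out[pos] <- 2^(1 - nu) / gamma(nu) * z[pos]^nu * besselK(z[pos], nu)
  out
}

#' Convert spatial range to the SPDE scale parameter kappa
#'
#' Uses the standard definition `rho = sqrt(8 nu) / kappa`, the distance at
#' which the Matern correlation is approximately 0.14.
#' @param rho spatial range (`> 0`, km).
#' @param nu smoothness.
#' @export
range_to_kappa <- function(rho, nu = 1) {
  if (any(rho <= 0)) stop("domain error: rho must be positive", call. = FALSE)
  sqrt(8 * nu) / rho
}

#' @rdname range_to_kappa
#' @param kappa scale parameter (`> 0`).
#' @export
kappa_to_range <- function(kappa, nu = 1) {
  if (any(kappa <= 0)) stop("domain error: kappa must be positive", call. = FALSE)
  sqrt(8 * nu) / kappa
}

#' Marginal standard deviation implied by (tau, kappa)
#'
#' `sigma^2 = Gamma(nu) / (4 pi kappa^(2 nu) tau^2 Gamma(nu + d/2))` for a
#' Matern field in dimension `d`.
#' @param tau,kappa SPDE scale parameters (`> 0`).
#' @param nu smoothness; `d` spatial dimension.
#' @export
sigma_from_tau_kappa <- function(tau, kappa, nu = 1, d = 2) {
  if (any(tau <= 0) || any(kappa <= 0))
    stop("domain error: tau and kappa must be positive", call. = FALSE)
  sqrt(gamma(nu) / (4 * pi * kappa^(2 * nu) * tau^2 * gamma(nu + d / 2)))
}

#' Internal (log tau, log kappa) parameters for a target (sigma, rho)
#'
#' Inverts the marginal-variance identity together with
#' `kappa = sqrt(8 nu)/rho`.
#' @param sigma marginal standard deviation (`> 0`).
#' @param rho spatial range (`> 0`).
#' @param nu smoothness; `d` spatial dimension.
#' @return named list with `log_tau`, `log_kappa`.
#' @export
tau_kappa_from_sigma_rho <- function(sigma, rho, nu = 1, d = 2) {
  if (sigma <= 0 || rho <= 0)
    stop("domain error: sigma and rho must be positive", call. = FALSE)
  kappa <- range_to_kappa(rho, nu)
  tau <- sqrt(gamma(nu) / (4 * pi * kappa^(2 * nu) * gamma(nu + d / 2))) / sigma
  list(log_tau = log(tau), log_kappa = log(kappa))
}

#' Matern parameter bundle
#'
#' Carries the natural `(sigma, rho)` and internal `(log tau, log kappa)`
#' parameterisations, kept mutually consistent.
#' @param sigma marginal sd; `rho` range; `nu` smoothness (1 for the
#'   order-2 SPDE in the plane).
#' @export
matern_params <- function(sigma = 1, rho = 1, nu = 1) {
  lk <- tau_kappa_from_sigma_rho(sigma, rho, nu = nu)
  structure(list(sigma = sigma, rho = rho, nu = nu,
                 log_tau = lk$log_tau, log_kappa = lk$log_kappa),
            class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("matern_params: sigma = %.4g, rho = %.4g, nu = %g (log tau = %.4g, log kappa = %.4g)\n",
              x$sigma, x$rho, x$nu, x$log_tau, x$log_kappa))
  invisible(x)
}

#' SPDE precision matrix of the mesh weights
#'
#' `Q = tau^2 (kappa^2 Ct + G)' Ct^{-1} (kappa^2 Ct + G)` with `Ct` the
#' diagonal lumped mass matrix. Lumping in both factors keeps `Q` sparse
#' (the Markov approximation) and `tau^2` scales the field to the marginal
#' variance implied by `sigma_from_tau_kappa()`.
#'
#' @param fem an `lgcp_fem` from [assemble_fem()].
#' @param params a `matern_params` (or list with `log_tau`, `log_kappa`).
#' @return sparse symmetric positive-definite `N x N` [Matrix::Matrix].
#' @export
spde_precision <- function(fem, params) {
  tau <- exp(params$log_tau); kappa <- exp(params$log_kappa)
  cl <- fem$C_lumped
  if (any(cl <= 0))
    stop("assembly error: zero lumped mass (unused mesh vertex?)", call. = FALSE)
  n <- length(cl)
  K <- kappa^2 * Matrix::Diagonal(n, cl) + fem$G
  Q <- tau^2 * Matrix::crossprod(K, Matrix::Diagonal(n, 1 / cl) %*% K)
  Matrix::forceSymmetric(Q)
}

#' Sparse Cholesky that treats CHOLMOD's not-positive-definite warning as
#' an error (a partially factored matrix would silently give a wrong
#' log-determinant)
#' @noRd
chol_spd <- function(M) {
  ok <- TRUE
  ch <- withCallingHandlers(
    Matrix::Cholesky(methods::as(Matrix::forceSymmetric(M), "CsparseMatrix"),
                     LDL = FALSE, perm = TRUE),
    warning = function(w) {
      if (grepl("not positive definite", conditionMessage(w))) ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (!ok)
    stop("not positive definite: matrix is numerically singular", call. = FALSE)
  ch
}

#' Draw zero-mean samples from a GMRF with sparse precision Q
#'
#' Uses the sparse Cholesky factorisation `Q = P' L L' P`: solves
#' `L' u = z`, `x = P' u` for standard-normal `z`. Deterministic under a
#' fixed seed.
#'
#' @param Q sparse symmetric positive-definite precision.
#' @param n_samples number of draws.
#' @param seed optional integer seed.
#' @return `N x n_samples` matrix of samples.
#' @export
sample_gmrf <- function(Q, n_samples = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE),
                 error = function(e) stop("not positive definite: ", conditionMessage(e), call. = FALSE))
  n <- nrow(Q)
  z <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  u <- Matrix::solve(ch, z, system = "Lt")
  x <- Matrix::solve(ch, u, system = "Pt")
  as.matrix(x)
}

#' Export a sparse matrix in Matrix-Market format (debugging aid)
#' @param Q sparse matrix; `path` output file.
#' @export
export_mtx <- function(Q, path) {
  Matrix::writeMM(methods::as(methods::as(Q, "generalMatrix"), "TsparseMatrix"), path)
  invisible(path)
}
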