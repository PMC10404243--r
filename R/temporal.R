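# Sparse precision builders for the structural temporal priors: RW2 trend,
# lag-m seasonal, stationary AR(2) cycle, and the separable AR(1)-in-time
# extension of the spatial field.

#' Second-order random walk (RW2) precision
#'
#' `Q = precision * D'D` with `D` the `(T-2) x T` second-difference operator.
#' Intrinsic: rank `T - 2`, null space spanned by constants and linear trends,
#' so a sum-to-zero constraint is applied at fit time to separate the trend
#' from the global intercept.
#'
#' @param T number of periods (`>= 3`).
#' @param precision innovation precision `1/sigma^2_eta` (`> 0`).
#' @return sparse symmetric `T x T` matrix.
#' @export
rw2_precision <- function(T, precision = 1) {
  if (T < 3) stop("size error: RW2 needs T >= 3", call. = FALSE)
  if (precision <= 0) stop("domain error: precision must be positive", call. = FALSE)
  D <- Matrix::bandSparse(T - 2L, T, k = 0:2,
                          diagonals = list(rep(1, T - 2L), rep(-2, T - 2L), rep(1, T - 2L)))
  Matrix::forceSymmetric(precision * Matrix::crossprod(D))
}

#' Seasonal lag-m autoregressive precision
#'
#' Operator rows `s_t - phi * s_(t-m)` for `t = m+1, ..., T`:
#' `Q = precision * L'L`. With `phi = 1` (seasonal random walk) the null
#' space is every period-m sequence (dimension m).
#'
#' @param T number of periods (`> period`).
#' @param period seasonal period m (4 quarterly, 12 monthly).
#' @param phi lag-m coefficient, `|phi| <= 1`; 1 gives the random-walk form.
#' @param precision innovation precision (`> 0`).
#' @return sparse symmetric `T x T` matrix.
#' @export
seasonal_precision <- function(T, period = 4L, phi = 1, precision = 1) {
  if (T <= period) stop("size error: seasonal component needs T > period", call. = FALSE)
  if (abs(phi) > 1) stop("domain error: |phi| must be <= 1", call. = FALSE)
  if (precision <= 0) stop("domain error: precision must be positive", call. = FALSE)
  r <- T - period
  L <- Matrix::sparseMatrix(i = c(seq_len(r), seq_len(r)),
                            j = c(seq_len(r), seq_len(r) + period),
                            x = c(rep(-phi, r), rep(1, r)),
                            dims = c(r, T))
  Matrix::forceSymmetric(precision * Matrix::crossprod(L))
}

#' AR(2) coefficients from partial autocorrelations
#'
#' Durbin-Levinson map `theta2 = p2`, `theta1 = p1 (1 - p2)`. The open box
#' `|p1| < 1, |p2| < 1` maps exactly onto the stationarity triangle, which is
#' why the cycle hyperparameters are carried as Fisher-z transformed PACFs.
#' The cycle has complex characteristic roots iff `theta1^2 + 4 theta2 < 0`.
#'
#' @param p1,p2 partial autocorrelations, each in `(-1, 1)`.
#' @return named numeric vector `c(theta1, theta2)`.
#' @export
ar2_from_pacf <- function(p1, p2) {
  if (abs(p1) >= 1 || abs(p2) >= 1)
    stop("domain error: partial autocorrelations must lie in (-1, 1)", call. = FALSE)
  c(theta1 = p1 * (1 - p2), theta2 = p2)
}

#' @rdname ar2_from_pacf
#' @param theta1,theta2 stationary AR(2) coefficients.
#' @export
pacf_from_ar2 <- function(theta1, theta2) {
  c(p1 = theta1 / (1 - theta2), p2 = theta2)
}

#' Autocovariance of a stationary AR(2) process
#'
#' Closed-form `gamma(0), gamma(1)` followed by the Yule-Walker recursion.
#' @param theta1,theta2 AR coefficients (stationary region).
#' @param sigma2 innovation variance.
#' @param lag_max largest lag.
#' @return numeric vector `gamma(0), ..., gamma(lag_max)`.
#' @export
ar2_autocovariance <- function(theta1, theta2, sigma2 = 1, lag_max = 10L) {
  check_ar2_stationary(theta1, theta2)
  g0 <- sigma2 * (1 - theta2) / ((1 + theta2) * ((1 - theta2)^2 - theta1^2))
  g1 <- theta1 * g0 / (1 - theta2)
  g <- numeric(lag_max + 1L)
  g[1L] <- g0
  if (lag_max >= 1L) g[2L] <- g1
  if (lag_max >= 2L) for (k in 3:(lag_max + 1L))
    g[k] <- theta1 * g[k - 1L] + theta2 * g[k - 2L]
  g
}

#' @noRd
check_ar2_stationary <- function(theta1, theta2) {
  if (!(abs(theta2) < 1 && theta2 + theta1 < 1 && theta2 - theta1 < 1))
    stop("domain error: AR(2) coefficients outside the stationarity triangle", call. = FALSE)
  invisible(TRUE)
}

#' Exact precision of a stationary AR(2) cycle
#'
#' Banded (bandwidth 2) `T x T` precision whose inverse equals the
#' Yule-Walker autocovariance matrix: the stationary distribution of the
#' first two states provides the initial-condition block and each transition
#' contributes `(c_t - theta1 c_(t-1) - theta2 c_(t-2))^2 / sigma^2`.
#'
#' @param T number of periods (`>= 2`).
#' @param theta AR coefficients `c(theta1, theta2)` (stationary); build from
#'   PACFs with [ar2_from_pacf()].
#' @param precision innovation precision `1/sigma^2`.
#' @return sparse symmetric `T x T` matrix.
#' @export
ar2_precision <- function(T, theta, precision = 1) {
  if (T < 2) stop("size error: AR(2) needs T >= 2", call. = FALSE)
  theta1 <- theta[[1L]]; theta2 <- theta[[2L]]
  check_ar2_stationary(theta1, theta2)
  sigma2 <- 1 / precision
  g <- ar2_autocovariance(theta1, theta2, sigma2, lag_max = 1L)
  Gamma2 <- matrix(c(g[1L], g[2L], g[2L], g[1L]), 2L, 2L)
  Q <- matrix(0, T, T)
  Q[1:2, 1:2] <- solve(Gamma2)
  if (T >= 3L) {
    for (t in 3:T) {
      idx <- c(t - 2L, t - 1L, t)
      r <- c(-theta2, -theta1, 1)
      Q[idx, idx] <- Q[idx, idx] + precision * tcrossprod(r)
    }
  }
  Matrix::forceSymmetric(Matrix::Matrix(Q, sparse = TRUE))
}

#' Exact precision of a stationary AR(1) with unit marginal variance
#'
#' Tridiagonal; innovation variance `1 - phi^2` so that every margin has
#' variance one. For `T = 1` this is the scalar 1.
#'
#' @param T number of periods.
#' @param phi autoregressive coefficient, `|phi| < 1`.
#' @return sparse symmetric `T x T` matrix.
#' @export
ar1_precision <- function(T, phi) {
  if (abs(phi) >= 1) stop("domain error: |phi| must be < 1", call. = FALSE)
  if (T == 1L) return(Matrix::Matrix(1, 1L, 1L, sparse = TRUE))
  s2 <- 1 - phi^2
  d <- c(1, rep(1 + phi^2, T - 2L), 1) / s2
  od <- rep(-phi, T - 1L) / s2
  Matrix::forceSymmetric(Matrix::bandSparse(T, T, k = 0:1, diagonals = list(d, od)))
}

#' Separable space-time precision
#'
#' `Q_st = Q_time(phi) %x% Q_space`: the spatial field evolves as
#' `xi(., t) = phi xi(., t-1) + omega(., t)` with innovations independent
#' across periods, so the per-period marginal covariance is `Q_space^{-1}`
#' for every t. Ordering is node-fastest within period.
#'
#' @param Q_space sparse spatial precision (`N x N`).
#' @param phi temporal dependence, `|phi| < 1`.
#' @param T number of periods.
#' @return sparse symmetric `NT x NT` matrix.
#' @export
spacetime_precision <- function(Q_space, phi, T) {
  if (T < 1) stop("size error: T must be >= 1", call. = FALSE)
  Qt <- ar1_precision(T, phi)
  methods::as(Matrix::forceSymmetric(Qt %x% Q_space), "CsparseMatrix")
}
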