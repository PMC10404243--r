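# Model specification, Poisson augmentation of the LGCP likelihood, and the
# joint latent-Gaussian layout.
#
# The intractable LGCP likelihood over the window is replaced by (n + n_t)T
# independent Poisson pseudo-observations per the dual-mesh quadrature rule:
# one zero-count row per mesh vertex and period with exposure equal to the
# dual-cell weight times the offset, plus one unit-count row with zero
# exposure per observed event.

#' Model specification for the dynamic LGCP
#'
#' Chooses which components of the log-intensity decomposition
#' `lambda(s,t) = intercept + z(s,t) beta + mu_t + s_t + c_t + xi(s,t)`
#' are active, and carries prior settings and hyperparameter initialisation.
#'
#' @param trend logical: include the RW2 long-term trend.
#' @param seasonal `FALSE`, or a list with `period` (4 quarterly, 12 monthly)
#'   and `estimate_phi` (estimate the lag-m coefficient; `FALSE` fixes it at
#'   1, the seasonal random walk, which then receives per-phase sum-to-zero
#'   constraints).
#' @param cycle logical: include the stationary AR(2) cycle.
#' @param field logical: include the AR(1)-in-time Matern spatial field.
#' @param sigma0,rho0 initial marginal sd and range of the field; `rho0 = NULL`
#'   defaults to 20% of the window diameter at build time.
#' @param phi0 initial temporal dependence of the field.
#' @param beta_precision diffuse Gaussian prior precision on intercept and
#'   fixed effects.
#' @param priors list of hyperprior settings: `prec_shape`, `prec_rate`
#'   (gamma prior on innovation precisions), `z_sd` (normal sd on Fisher-z
#'   transformed correlation parameters), `logtau_sd`, `logkappa_sd`
#'   (normal sds on the SPDE internal scales, centred at the `sigma0`/`rho0`
#'   values).
#' @return object of class `lgcp_spec`.
#' @export
lgcp_spec <- function(trend = TRUE,
                      seasonal = list(period = 4L, estimate_phi = TRUE),
                      cycle = TRUE,
                      field = TRUE,
                      sigma0 = 1, rho0 = NULL, phi0 = 0.5,
                      beta_precision = 1e-3,
                      priors = list()) {
  if (isTRUE(seasonal)) seasonal <- list(period = 4L, estimate_phi = TRUE)
  if (is.list(seasonal)) {
    seasonal$period <- as.integer(seasonal$period %||% 4L)
    seasonal$estimate_phi <- isTRUE(seasonal$estimate_phi %||% TRUE)
  }
  pr <- utils::modifyList(list(prec_shape = 1, prec_rate = 5e-5, z_sd = 1,
                               logtau_sd = 1, logkappa_sd = 1), priors)
  structure(list(trend = isTRUE(trend), seasonal = seasonal,
                 cycle = isTRUE(cycle), field = isTRUE(field),
                 sigma0 = sigma0, rho0 = rho0, phi0 = phi0,
                 beta_precision = beta_precision, priors = pr),
            class = "lgcp_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate design for the latent linear predictor
#'
#' @param node numeric `(N*T) x p` matrix of per-vertex-per-period covariate
#'   values, vertex index fastest; continuous covariates should be
#'   standardised, categorical ones one-hot encoded with a dropped reference
#'   level (first category alphabetically unless declared otherwise).
#' @param names column names (coefficient labels).
#' @return object of class `lgcp_covariates`.
#' @export
covariate_design <- function(node, names = colnames(node)) {
  node <- as.matrix(node)
  if (is.null(names)) names <- paste0("beta", seq_len(ncol(node)))
  if (any(colSums(abs(node)) == 0))
    stop("covariate design has an all-zero column", call. = FALSE)
  structure(list(node = node, names = names), class = "lgcp_covariates")
}

#' Augmented Poisson representation of the LGCP likelihood
#'
#' Builds the pseudo-observations: per period, `N` vertex rows with count 0
#' and exposure `alpha_k * e(k,t)`, and `n_t` event rows with count 1 and
#' exposure 0. The log-likelihood `sum(y * eta - a * exp(eta))` over these
#' rows equals the LGCP log-likelihood (up to a constant) for intensities
#' resolved at the dual-cell scale.
#'
#' @param pattern an `lgcp_pattern`.
#' @param mesh the `lgcp_mesh` the model is built on.
#' @param weights dual-cell quadrature weights from [dual_weights()].
#' @param offset per-vertex-per-period exposure multiplier: scalar or
#'   `N x T` matrix (default 1, a pure point process).
#' @return object of class `lgcp_augmented`: vectors `y`, `a`, `t`, `node`
#'   (the row's dual-cell vertex: its own vertex for vertex rows, the
#'   dominant barycentric vertex for event rows), `is_event`, and the sparse
#'   indicator `B` (rows x N) reading the field at that vertex. The whole
#'   linear predictor of a row -- covariates and field alike -- is evaluated
#'   at its dual-cell vertex, making the augmented likelihood exact for
#'   intensities piecewise constant per dual cell and keeping the
#'   pseudo-likelihood bounded.
#' @export
augment_likelihood <- function(pattern, mesh, weights, offset = 1) {
  N <- nrow(mesh$vertices); T <- pattern$T
  if (length(weights) != N) stop("weights do not match the mesh", call. = FALSE)
  E <- if (is.matrix(offset)) offset else matrix(offset, N, T)
  if (any(E[weights > 0, ] <= 0))
    stop("offset must be positive wherever quadrature weight is positive", call. = FALSE)

  ev <- pattern$events
  loc <- if (nrow(ev)) locate_points(mesh, cbind(ev$x, ev$y)) else NULL

  y <- c(); a <- c(); tt <- c(); node <- c(); is_event <- c()
  Bi <- c(); Bj <- c(); Bx <- c()
  row0 <- 0L
  for (t in seq_len(T)) {
    # vertex rows
    y <- c(y, rep(0, N)); a <- c(a, weights * E[, t])
    tt <- c(tt, rep(t, N)); node <- c(node, seq_len(N))
    is_event <- c(is_event, rep(FALSE, N))
    Bi <- c(Bi, row0 + seq_len(N)); Bj <- c(Bj, seq_len(N)); Bx <- c(Bx, rep(1, N))
    row0 <- row0 + N
    # event rows
    idx <- which(ev$t == t)
    n_t <- length(idx)
    if (n_t) {
      y <- c(y, rep(1, n_t)); a <- c(a, rep(0, n_t))
      tt <- c(tt, rep(t, n_t))
      tr <- mesh$triangles[loc$triangle[idx], , drop = FALSE]
      bar <- loc$bary[idx, , drop = FALSE]
      # the whole event-row predictor (field and covariates alike) is read at
      # the event's dual-cell vertex, i.e. the dominant barycentric vertex:
      # evaluating different predictor parts at different locations would
      # leave near-collinear covariate/field directions without exposure
      # penalty and make the pseudo-likelihood mode degenerate
      ev_node <- tr[cbind(seq_len(n_t), max.col(bar, ties.method = "first"))]
      node <- c(node, ev_node)
      is_event <- c(is_event, rep(TRUE, n_t))
      Bi <- c(Bi, row0 + seq_len(n_t))
      Bj <- c(Bj, ev_node); Bx <- c(Bx, rep(1, n_t))
      row0 <- row0 + n_t
    }
  }
  B <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bx, dims = c(row0, N))
  structure(list(y = y, a = a, t = tt, node = node, is_event = is_event,
                 B = B, N = N, T = T, n_t = pattern$n_t),
            class = "lgcp_augmented")
}

#' Latent-field layout: index ranges, prior precision, constraints
#'
#' Assembles the block structure of the joint latent Gaussian vector
#' `[intercept, beta | mu_1..T | s_1..T | c_1..T | xi_1..NT]`, a builder for
#' the block-diagonal prior precision at given hyperparameters, and the
#' sum-to-zero constraint rows (trend always; each seasonal phase when the
#' lag-m coefficient is fixed at 1).
#'
#' @param spec an `lgcp_spec`.
#' @param mesh the mesh (only needed when the spatial field is active).
#' @param T number of periods.
#' @param design an `lgcp_covariates` or `NULL`.
#' @param fem optional precomputed [assemble_fem()] result.
#' @return object of class `lgcp_layout`: `ranges` (named list of index
#'   vectors), `dim`, `theta_names`, `theta_init`, `constraints` (dense
#'   matrix, 0 rows if none), and the functions `prior_precision(theta)` and
#'   `prior_logdet(theta)` (generalised log-determinant, intrinsic blocks
#'   contributing their rank times the log precision).
#' @export
build_layout <- function(spec, mesh, T, design = NULL, fem = NULL) {
  if (spec$trend && T < 3L) stop("spec error: RW2 trend needs T >= 3", call. = FALSE)
  m <- if (is.list(spec$seasonal)) spec$seasonal$period else NULL
  if (is.list(spec$seasonal) && T <= m)
    stop("spec error: seasonal component needs T > period", call. = FALSE)

  p <- if (is.null(design)) 0L else ncol(design$node)
  N <- if (spec$field) nrow(mesh$vertices) else 0L

  ranges <- list(fixed = seq_len(1L + p))
  off <- 1L + p
  if (spec$trend) { ranges$trend <- off + seq_len(T); off <- off + T }
  if (is.list(spec$seasonal)) { ranges$seasonal <- off + seq_len(T); off <- off + T }
  if (spec$cycle) { ranges$cycle <- off + seq_len(T); off <- off + T }
  if (spec$field) { ranges$field <- off + seq_len(N * T); off <- off + N * T }
  dim <- off

  # hyperparameter vector (transformed scale)
  theta_names <- character(0); theta_init <- numeric(0)
  if (spec$trend) { theta_names <- c(theta_names, "log_prec_trend"); theta_init <- c(theta_init, log(10)) }
  if (is.list(spec$seasonal)) {
    theta_names <- c(theta_names, "log_prec_seasonal"); theta_init <- c(theta_init, log(10))
    if (spec$seasonal$estimate_phi) { theta_names <- c(theta_names, "z_phi_seasonal"); theta_init <- c(theta_init, atanh(0.5)) }
  }
  if (spec$cycle) {
    theta_names <- c(theta_names, "log_prec_cycle", "z_p1", "z_p2")
    theta_init <- c(theta_init, log(10), atanh(0.3), atanh(-0.3))
  }
  lt0 <- lk0 <- NULL
  if (spec$field) {
    rho0 <- spec$rho0 %||% (0.2 * polygon_diameter(mesh$boundary))
    tk <- tau_kappa_from_sigma_rho(spec$sigma0, rho0)
    lt0 <- tk$log_tau; lk0 <- tk$log_kappa
    theta_names <- c(theta_names, "log_tau", "log_kappa", "z_phi_group")
    theta_init <- c(theta_init, lt0, lk0, atanh(spec$phi0))
    if (is.null(fem)) fem <- assemble_fem(mesh)
  }
  names(theta_init) <- theta_names

  # constraint rows
  cons <- NULL
  if (spec$trend) {
    r <- numeric(dim); r[ranges$trend] <- 1; cons <- rbind(cons, r)
  }
  if (is.list(spec$seasonal) && !spec$seasonal$estimate_phi) {
    for (ph in seq_len(m)) {
      r <- numeric(dim); r[ranges$seasonal[seq(ph, T, by = m)]] <- 1
      cons <- rbind(cons, r)
    }
  }
  if (is.null(cons)) cons <- matrix(0, 0L, dim)
  rownames(cons) <- NULL

  # cached constant log-determinant pieces of intrinsic structures
  logpdet_struct <- function(M, rank) {
    ev <- sort(eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    sum(log(ev[seq_len(rank)]))
  }
  const_trend <- if (spec$trend) logpdet_struct(rw2_precision(T, 1), T - 2L) else 0

  th <- function(theta, nm) unname(theta[[nm]])

  # intrinsic blocks get a tiny relative diagonal jitter so the joint
  # posterior precision stays factorisable when their null spaces overlap
  # (e.g. the constant shared by trend and a phi = 1 seasonal); the
  # sum-to-zero constraints remove those directions from the summaries
  jitter_intrinsic <- function(Q, prec) Q + Matrix::Diagonal(nrow(Q), 1e-6 * prec)

  prior_precision <- function(theta) {
    blocks <- list(Matrix::Diagonal(1L + p, spec$beta_precision))
    if (spec$trend) {
      pr_t <- exp(th(theta, "log_prec_trend"))
      blocks <- c(blocks, list(jitter_intrinsic(rw2_precision(T, pr_t), pr_t)))
    }
    if (is.list(spec$seasonal)) {
      phi_s <- if (spec$seasonal$estimate_phi) tanh(th(theta, "z_phi_seasonal")) else 1
      pr_s <- exp(th(theta, "log_prec_seasonal"))
      blocks <- c(blocks, list(jitter_intrinsic(
        seasonal_precision(T, m, phi_s, pr_s), pr_s)))
    }
    if (spec$cycle) {
      thet <- ar2_from_pacf(tanh(th(theta, "z_p1")), tanh(th(theta, "z_p2")))
      blocks <- c(blocks, list(ar2_precision(T, thet, exp(th(theta, "log_prec_cycle")))))
    }
    if (spec$field) {
      Qs <- spde_precision(fem, list(log_tau = th(theta, "log_tau"),
                                     log_kappa = th(theta, "log_kappa")))
      blocks <- c(blocks, list(spacetime_precision(Qs, tanh(th(theta, "z_phi_group")), T)))
    }
    methods::as(Matrix::forceSymmetric(Matrix::bdiag(blocks)), "CsparseMatrix")
  }

  prior_logdet <- function(theta) {
    ld <- (1L + p) * log(spec$beta_precision)
    if (spec$trend) ld <- ld + (T - 2L) * th(theta, "log_prec_trend") + const_trend
    if (is.list(spec$seasonal)) {
      phi_s <- if (spec$seasonal$estimate_phi) tanh(th(theta, "z_phi_seasonal")) else 1
      ld <- ld + (T - m) * th(theta, "log_prec_seasonal") +
        logpdet_struct(seasonal_precision(T, m, phi_s, 1), T - m)
    }
    if (spec$cycle) {
      thet <- ar2_from_pacf(tanh(th(theta, "z_p1")), tanh(th(theta, "z_p2")))
      Qc <- ar2_precision(T, thet, exp(th(theta, "log_prec_cycle")))
      ld <- ld + 2 * sum(log(diag(chol(as.matrix(Qc)))))
    }
    if (spec$field) {
      Qs <- spde_precision(fem, list(log_tau = th(theta, "log_tau"),
                                     log_kappa = th(theta, "log_kappa")))
      phi <- tanh(th(theta, "z_phi_group"))
      chS <- chol_spd(Qs)
      ldS <- 2 * Matrix::determinant(chS, sqrt = TRUE)$modulus
      ldT <- if (T > 1L) -(T - 1L) * log(1 - phi^2) else 0
      ld <- ld + N * ldT + T * as.numeric(ldS)
    }
    ld
  }

  structure(list(ranges = ranges, dim = dim, p = p, N = N, T = T,
                 theta_names = theta_names, theta_init = theta_init,
                 constraints = cons, spec = spec, fem = fem,
                 prior_precision = prior_precision, prior_logdet = prior_logdet),
            class = "lgcp_layout")
}

#' Assemble a ready-to-fit model object
#'
#' Glues together the augmented likelihood, the covariate design and the
#' latent layout, producing the sparse design matrix mapping the latent
#' vector to every pseudo-observation's linear predictor.
#'
#' @param pattern an `lgcp_pattern`.
#' @param mesh an `lgcp_mesh` covering the pattern's window.
#' @param spec an `lgcp_spec`.
#' @param covariates an `lgcp_covariates` or `NULL`.
#' @param offset exposure multiplier (scalar or `N x T`).
#' @return object of class `lgcp_model` with the augmented data, layout,
#'   design matrix `A`, window area and bookkeeping.
#' @export
lgcp_model <- function(pattern, mesh, spec = lgcp_spec(), covariates = NULL,
                       offset = 1) {
  fem <- assemble_fem(mesh)
  wts <- dual_weights(mesh, pattern$window)
  aug <- augment_likelihood(pattern, mesh, wts, offset)
  layout <- build_layout(spec, mesh, pattern$T, covariates, fem = fem)
  A <- model_design(layout, aug, covariates)
  structure(list(pattern = pattern, mesh = mesh, spec = spec,
                 covariates = covariates, aug = aug, layout = layout, A = A,
                 weights = wts, area = polygon_area(pattern$window)),
            class = "lgcp_model")
}

#' Sparse design matrix rows -> latent vector
#' @noRd
model_design <- function(layout, aug, covariates = NULL) {
  nr <- length(aug$y); dim <- layout$dim
  ii <- rep(seq_len(nr), 1L)  # intercept
  jj <- rep(1L, nr); xx <- rep(1, nr)
  if (layout$p > 0L) {
    zidx <- (aug$t - 1L) * aug$N + aug$node  # nearest-node covariate lookup
    Z <- covariates$node[zidx, , drop = FALSE]
    for (k in seq_len(layout$p)) {
      ii <- c(ii, seq_len(nr)); jj <- c(jj, rep(1L + k, nr)); xx <- c(xx, Z[, k])
    }
  }
  for (comp in c("trend", "seasonal", "cycle")) {
    if (!is.null(layout$ranges[[comp]])) {
      ii <- c(ii, seq_len(nr))
      jj <- c(jj, layout$ranges[[comp]][aug$t])
      xx <- c(xx, rep(1, nr))
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, dim))
  if (!is.null(layout$ranges$field)) {
    Bt <- methods::as(aug$B, "TsparseMatrix")
    A <- A + Matrix::sparseMatrix(
      i = Bt@i + 1L,
      j = layout$ranges$field[1L] - 1L + (aug$t[Bt@i + 1L] - 1L) * aug$N + Bt@j + 1L,
      x = Bt@x, dims = c(nr, dim))
  }
  A
}

#' @export
print.lgcp_model <- function(x, ...) {
  comps <- names(x$layout$ranges)
  cat(sprintf("lgcp_model: %d pseudo-observations (%d events), latent dim %d\n",
              length(x$aug$y), sum(x$aug$is_event), x$layout$dim))
  cat("  components:", paste(comps, collapse = ", "), "\n")
  cat("  hyperparameters:", paste(x$layout$theta_names, collapse = ", "), "\n")
  invisible(x)
}
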