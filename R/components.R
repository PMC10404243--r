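# Posterior decomposition outputs: component paths, per-period predicted
# totals and the spatial-effect surface.

#' Draws from the latent Gaussian approximation (constraint-corrected)
#' @noRd
latent_draws <- function(fit, n_draws = 200L, seed = fit$seed) {
  set.seed(seed)
  ga <- fit$ga
  d <- length(ga$mean)
  z <- matrix(stats::rnorm(d * n_draws), d, n_draws)
  u <- Matrix::solve(ga$chol, z, system = "Lt")
  e <- as.matrix(Matrix::solve(ga$chol, u, system = "Pt"))
  if (!is.null(ga$V)) {
    Ac <- fit$model$layout$constraints
    e <- e - ga$V %*% solve(ga$S, Ac %*% e)
  }
  sweep(e, 1L, ga$mean, `+`)
}

#' Extract the posterior decomposition from a fitted model
#'
#' Produces per-period summaries of the trend, seasonal and cycle paths,
#' per-period predicted event totals (posterior mean and 95% credibility
#' interval of the integrated intensity, plus a Poisson predictive interval
#' for realised counts) against the observed counts, and the posterior
#' mean/sd of the time-averaged spatial effect per mesh vertex. Interval
#' endpoints for totals come from Monte Carlo draws of the latent Gaussian
#' approximation, reproducible under the fit's seed.
#'
#' @param fit an `lgcp_fit`.
#' @param n_draws Monte Carlo draws for the totals intervals.
#' @return list with data.frames `temporal` (component, period, mean, lwr,
#'   upr), `totals` (period, observed, predicted, lwr, upr, pred_lwr,
#'   pred_upr) and `spatial` (vertex, x, y, mean, sd; `NULL` when the field
#'   is off).
#' @export
extract_components <- function(fit, n_draws = 200L) {
  model <- fit$model; layout <- model$layout
  T <- layout$T

  temporal <- NULL
  for (nm in names(fit$components)) {
    cs <- fit$components[[nm]]
    temporal <- rbind(temporal,
                      data.frame(component = nm, period = seq_len(T),
                                 mean = cs$mean, lwr = cs$q0.025, upr = cs$q0.975))
  }

  # per-period totals: Lambda_t = sum_k alpha_k e_kt exp(eta_kt)
  vrows <- which(!model$aug$is_event)
  a_nodes <- matrix(model$aug$a[vrows], model$aug$N, T)
  A_nodes <- model$A[vrows, , drop = FALSE]
  draws <- latent_draws(fit, n_draws = n_draws)
  eta_d <- as.matrix(A_nodes %*% draws)  # (N*T) x n_draws
  tot_d <- rowsum(as.vector(a_nodes) * exp(pmin(eta_d, 50)),
                  group = rep(seq_len(T), each = model$aug$N))
  lam_mean <- rowMeans(tot_d)
  lam_q <- t(apply(tot_d, 1L, stats::quantile, probs = c(0.025, 0.975)))
  cnt_d <- matrix(stats::rpois(length(tot_d), lambda = pmin(as.vector(tot_d), 1e8)),
                  nrow = T)
  cnt_q <- t(apply(cnt_d, 1L, stats::quantile, probs = c(0.025, 0.975)))
  totals <- data.frame(period = seq_len(T), observed = model$aug$n_t,
                       predicted = lam_mean,
                       lwr = lam_q[, 1L], upr = lam_q[, 2L],
                       pred_lwr = cnt_q[, 1L], pred_upr = cnt_q[, 2L])

  spatial <- NULL
  if (!is.null(fit$field)) {
    spatial <- data.frame(vertex = seq_len(model$aug$N),
                          x = model$mesh$vertices[, 1L],
                          y = model$mesh$vertices[, 2L],
                          mean = fit$field$time_avg_mean,
                          sd = fit$field$time_avg_sd)
  }

  list(temporal = temporal, totals = totals, spatial = spatial)
}
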