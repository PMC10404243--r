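# Simulation of point patterns with the exact generative structure the model
# assumes: RW2 trend, lag-m seasonal, stationary AR(2) cycle, covariate
# effects and an AR(1)-in-time Matern field, with events placed by thinning
# against per-triangle intensity bounds.

#' Simulation scenario
#'
#' Bundles everything the simulator needs. Components may be given either as
#' stochastic specs (innovation sds etc.) or as fixed true paths.
#'
#' @param window polygon (`n x 2`).
#' @param T number of periods.
#' @param frequency `"quarterly"` or `"monthly"` (sets the default seasonal
#'   period, 4 or 12).
#' @param mesh list: `max_edge_inner`, `extension_fraction`.
#' @param intercept global log-intensity level (events per unit area per
#'   period when all components are zero).
#' @param beta named vector of true covariate effects (names must match the
#'   simulated covariate columns).
#' @param trend `NULL`, or list with either `path` (length-T, will be
#'   centred) or `sd` innovation sd and `init` (first two values).
#' @param seasonal `NULL`, or list with `period`, and either `path` or
#'   `phi`, `sd`, `init` (first `period` values).
#' @param cycle `NULL`, or list with either `path` or `p1`, `p2` (PACFs)
#'   and `sd`.
#' @param field `NULL`, or list `sigma`, `rho`, `phi`.
#' @param covariates `NULL`, or list `k` (number of climate-class categories,
#'   `>= 2`), `n_continuous` (default 2: temperature- and rainfall-like
#'   fields) and `polyline` (road stand-in; default a diagonal across the
#'   window) controlling the distance covariate.
#' @param event_cap abort if the expected event count exceeds this.
#' @param seed default seed for the whole scenario.
#' @return object of class `lgcp_scenario`.
#' @export
lgcp_scenario <- function(window, T = 8L, frequency = c("quarterly", "monthly"),
                          mesh = list(max_edge_inner = NULL, extension_fraction = 0.2),
                          intercept = 0, beta = NULL,
                          trend = list(sd = 0.1, init = c(0, 0)),
                          seasonal = list(period = NULL, phi = 1, sd = 0.05),
                          cycle = list(p1 = 0.3, p2 = -0.3, sd = 0.05),
                          field = list(sigma = 1, rho = NULL, phi = 0.8),
                          covariates = NULL,
                          event_cap = 1e6, seed = 1L) {
  frequency <- match.arg(frequency)
  window <- ccw(as_polygon(window))
  m_default <- if (frequency == "quarterly") 4L else 12L
  if (is.list(seasonal) && is.null(seasonal$period)) seasonal$period <- m_default
  diam <- polygon_diameter(window)
  if (is.null(mesh$max_edge_inner)) mesh$max_edge_inner <- diam / 12
  if (is.null(mesh$extension_fraction)) mesh$extension_fraction <- 0.2
  if (is.list(field) && is.null(field$rho)) field$rho <- 0.2 * diam
  structure(list(window = window, T = as.integer(T), frequency = frequency,
                 mesh = mesh, intercept = intercept, beta = beta,
                 trend = trend, seasonal = seasonal, cycle = cycle,
                 field = field, covariates = covariates,
                 event_cap = event_cap, seed = as.integer(seed)),
            class = "lgcp_scenario")
}

#' Simulate the temporal components of the decomposition
#'
#' Trend by the RW2 recursion (then centred to sum zero); seasonal by the
#' lag-m recursion from its initial phases (centred per phase when
#' `phi = 1`); cycle from the stationary AR(2) distribution.
#'
#' @param scenario an `lgcp_scenario`.
#' @param seed seed (`NULL` to use the current RNG state).
#' @return list with numeric length-T vectors `mu`, `s`, `c` (zeros for
#'   inactive components).
#' @export
simulate_components <- function(scenario, seed = scenario$seed) {
  if (!is.null(seed)) set.seed(seed)
  T <- scenario$T
  mu <- s <- cc <- numeric(T)

  tr <- scenario$trend
  if (is.list(tr)) {
    if (!is.null(tr$path)) {
      mu <- tr$path - mean(tr$path)
    } else {
      init <- tr$init %||% c(0, 0)
      mu[1:2] <- init
      if (T >= 3L) for (t in 3:T)
        mu[t] <- 2 * mu[t - 1L] - mu[t - 2L] + stats::rnorm(1L, 0, tr$sd %||% 0.1)
      mu <- mu - mean(mu)
    }
  }

  se <- scenario$seasonal
  if (is.list(se)) {
    m <- se$period
    if (!is.null(se$path)) {
      s <- rep_len(se$path, T)
    } else {
      phi <- se$phi %||% 1
      init <- se$init %||% stats::rnorm(m, 0, 0.3)
      s[seq_len(m)] <- init
      if (T > m) for (t in (m + 1L):T)
        s[t] <- phi * s[t - m] + stats::rnorm(1L, 0, se$sd %||% 0.05)
      if (phi == 1) for (ph in seq_len(m)) {
        idx <- seq(ph, T, by = m)
        s[idx] <- s[idx] - mean(s[idx])
      }
    }
  }

  cy <- scenario$cycle
  if (is.list(cy)) {
    if (!is.null(cy$path)) {
      cc <- rep_len(cy$path, T)
    } else {
      th <- ar2_from_pacf(cy$p1, cy$p2)
      sd <- cy$sd %||% 0.05
      g <- ar2_autocovariance(th[1L], th[2L], sd^2, lag_max = 1L)
      G2 <- matrix(c(g[1L], g[2L], g[2L], g[1L]), 2L, 2L)
      cc[1:2] <- as.numeric(t(chol(G2)) %*% stats::rnorm(2L))
      if (T >= 3L) for (t in 3:T)
        cc[t] <- th[1L] * cc[t - 1L] + th[2L] * cc[t - 2L] + stats::rnorm(1L, 0, sd)
    }
  }
  list(mu = mu, s = s, c = cc)
}

#' Simulate the AR(1)-in-time spatial field on a mesh
#'
#' First period from the stationary distribution, then
#' `xi_t = phi xi_(t-1) + omega_t` with innovation precision
#' `Q_space / (1 - phi^2)`, so every period has marginal precision `Q_space`.
#'
#' @param Q_space sparse spatial precision.
#' @param phi temporal dependence (`|phi| < 1`).
#' @param T periods.
#' @param seed seed (`NULL` to use current RNG state).
#' @return `N x T` matrix.
#' @export
simulate_field <- function(Q_space, phi, T, seed = NULL) {
  if (abs(phi) >= 1) stop("domain error: |phi| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(Q_space)
  xi <- matrix(0, N, T)
  xi[, 1L] <- sample_gmrf(Q_space, 1L)
  if (T > 1L) {
    s2 <- 1 - phi^2
    for (t in 2:T)
      xi[, t] <- phi * xi[, t - 1L] + sqrt(s2) * sample_gmrf(Q_space, 1L)
  }
  xi
}

#' Simulate covariate fields on the mesh
#'
#' A k-category climate-class stand-in by nearest-centroid partition,
#' smooth continuous temperature/rainfall stand-ins (low-order spatial
#' polynomials with seasonal modulation, standardised over vertex-periods)
#' and the distance from each vertex to a road polyline.
#'
#' @param mesh an `lgcp_mesh`.
#' @param T periods.
#' @param k number of classes (`>= 2`).
#' @param period seasonal period of the continuous-field modulation.
#' @param polyline `n x 2` matrix (road stand-in); default the window's
#'   main diagonal.
#' @param seed seed (`NULL` to use current RNG state).
#' @return list: `design` (an `lgcp_covariates` with one-hot classes 2..k,
#'   standardised `temperature`, `rainfall` and `dist_road`), `class`
#'   (integer N), `fields` (raw N x T matrices, incl. raw distance).
#' @export
simulate_covariates <- function(mesh, T, k = 3L, period = 4L, polyline = NULL,
                                seed = NULL) {
  if (k < 2L) stop("spec error: need at least two classes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- mesh$vertices; N <- nrow(v)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])

  cent <- cbind(stats::runif(k, xr[1L], xr[2L]), stats::runif(k, yr[1L], yr[2L]))
  d2 <- outer(v[, 1L], cent[, 1L], "-")^2 + outer(v[, 2L], cent[, 2L], "-")^2
  cls <- max.col(-d2, ties.method = "first")

  xs <- (v[, 1L] - mean(xr)) / (diff(xr) / 2)
  ys <- (v[, 2L] - mean(yr)) / (diff(yr) / 2)
  seas <- sin(2 * pi * (seq_len(T) - 1) / period)
  temp_raw <- outer(xs + 0.5 * ys - 0.3 * xs * ys, rep(1, T)) +
    outer(rep(1, N), 0.6 * seas)
  rain_raw <- outer(ys - 0.4 * xs + 0.2 * xs^2, rep(1, T)) -
    outer(rep(1, N), 0.8 * seas)

  if (is.null(polyline))
    polyline <- rbind(c(xr[1L], yr[1L]), c(xr[2L], yr[2L]))
  dist_raw <- matrix(dist_to_polyline(polyline, v), N, T)

  std <- function(M) (M - mean(M)) / stats::sd(as.vector(M))
  cols <- list(); nms <- character(0)
  for (j in 2:k) {
    cols <- c(cols, list(matrix(as.numeric(cls == j), N, T)))
    nms <- c(nms, paste0("class", j))
  }
  cols <- c(cols, list(std(temp_raw), std(rain_raw), std(dist_raw)))
  nms <- c(nms, "temperature", "rainfall", "dist_road")
  node <- do.call(cbind, lapply(cols, as.vector))
  colnames(node) <- nms
  list(design = covariate_design(node, nms), class = cls,
       fields = list(temperature = temp_raw, rainfall = rain_raw,
                     dist_road = dist_raw),
       centroids = cent, polyline = polyline)
}

#' Simulate a point pattern from a scenario
#'
#' Assembles the log-intensity at the mesh vertices from all active
#' components, then draws events per period and triangle: a homogeneous
#' Poisson number at the triangle's maximum vertex intensity, uniform
#' placement, and thinning by the ratio of the interpolated intensity to the
#' bound (exact for piecewise log-linear intensity), keeping points inside
#' the window.
#'
#' @param scenario an `lgcp_scenario`.
#' @param seed seed for the whole simulation.
#' @return list of class `lgcp_sim`: `pattern` (an `lgcp_pattern`), `mesh`,
#'   `covariates` (or `NULL`), and `truth` (component paths, `xi`, `beta`,
#'   `intercept` and the vertex log-intensity `eta`).
#' @export
simulate_pattern <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  T <- scenario$T
  mesh <- build_mesh(scenario$window, scenario$mesh$max_edge_inner,
                     extension_fraction = scenario$mesh$extension_fraction)
  N <- nrow(mesh$vertices)

  comps <- simulate_components(scenario, seed = NULL)

  xi <- matrix(0, N, T)
  if (is.list(scenario$field)) {
    fem <- assemble_fem(mesh)
    pars <- matern_params(scenario$field$sigma, scenario$field$rho)
    Qs <- spde_precision(fem, pars)
    xi <- simulate_field(Qs, scenario$field$phi, T, seed = NULL)
  }

  cov <- NULL; zbeta <- matrix(0, N, T)
  if (is.list(scenario$covariates)) {
    cov <- simulate_covariates(mesh, T,
                               k = scenario$covariates$k %||% 3L,
                               period = if (is.list(scenario$seasonal))
                                 scenario$seasonal$period else 4L,
                               polyline = scenario$covariates$polyline,
                               seed = NULL)
    beta <- scenario$beta
    if (is.null(beta)) stop("scenario has covariates but no beta", call. = FALSE)
    Z <- cov$design$node[, names(beta), drop = FALSE]
    zbeta <- matrix(Z %*% beta, N, T)
  }

  eta <- scenario$intercept + zbeta + xi +
    matrix(rep(comps$mu + comps$s + comps$c, each = N), N, T)

  # expected-count guard via vertex quadrature over the window
  tr <- mesh$triangles
  a_tri <- tri_signed_areas(mesh$vertices, tr)
  ain <- vapply(seq_len(nrow(tr)), function(m)
    clip_area(scenario$window, mesh$vertices[tr[m, ], , drop = FALSE]),
    numeric(1))
  act <- which(ain > 0)
  exp_eta <- exp(pmin(eta, 50))
  expected <- sum(vapply(act, function(m)
    sum(ain[m] / 3 * colSums(matrix(exp_eta[tr[m, ], ], 3L))), numeric(1)))
  if (expected > scenario$event_cap)
    stop(sprintf("resource error: expected event count %.3g exceeds cap %.3g",
                 expected, scenario$event_cap), call. = FALSE)

  ex <- c(); ey <- c(); et <- c()
  for (t in seq_len(T)) {
    lam_v <- exp_eta[, t]
    for (m in act) {
      vid <- tr[m, ]
      lam_max <- max(lam_v[vid])
      n <- stats::rpois(1L, lam_max * a_tri[m])
      if (n == 0L) next
      # uniform points in the triangle
      u1 <- stats::runif(n); u2 <- stats::runif(n)
      sw <- u1 + u2 > 1
      u1[sw] <- 1 - u1[sw]; u2[sw] <- 1 - u2[sw]
      p1 <- mesh$vertices[vid[1L], ]; p2 <- mesh$vertices[vid[2L], ]
      p3 <- mesh$vertices[vid[3L], ]
      px <- p1[1L] + u1 * (p2[1L] - p1[1L]) + u2 * (p3[1L] - p1[1L])
      py <- p1[2L] + u1 * (p2[2L] - p1[2L]) + u2 * (p3[2L] - p1[2L])
      lam_p <- exp((1 - u1 - u2) * eta[vid[1L], t] + u1 * eta[vid[2L], t] +
                     u2 * eta[vid[3L], t])
      keep <- stats::runif(n) < lam_p / lam_max
      if (any(keep)) {
        keep[keep] <- points_in_polygon(scenario$window,
                                        cbind(px[keep], py[keep]),
                                        tol = mesh$snap)
        ex <- c(ex, px[keep]); ey <- c(ey, py[keep]); et <- c(et, rep(t, sum(keep)))
      }
    }
  }
  pattern <- lgcp_pattern(ex, ey, et, window = scenario$window, T = T)
  structure(list(pattern = pattern, mesh = mesh, covariates = cov,
                 truth = list(mu = comps$mu, s = comps$s, c = comps$c, xi = xi,
                              beta = scenario$beta, intercept = scenario$intercept,
                              eta = eta, expected = expected)),
            class = "lgcp_sim")
}

#' Amazon-like scenario preset
#'
#' An irregular pentagon window of roughly 100 x 70 km-units, eight quarters,
#' a V-shaped trend (decline then rise), dry-season seasonality peaking in
#' the third and fourth quarters, a mild stochastic cycle, three climate
#' classes, and positive-temperature / negative-rainfall / negative
#' distance-to-road effects.
#'
#' @param seed scenario seed.
#' @param intercept baseline log-intensity (events per km^2 per quarter).
#' @export
amazon_scenario <- function(seed = 1L, intercept = -3.3) {
  window <- cbind(c(0, 45, 100, 92, 30), c(10, 0, 12, 58, 70))
  Tq <- 8L
  trend_path <- c(0.5, 0.25, 0.0, -0.3, -0.35, -0.15, 0.15, 0.45)
  seas_path <- c(-0.35, -0.25, 0.3, 0.3)
  lgcp_scenario(window, T = Tq, frequency = "quarterly",
                mesh = list(max_edge_inner = 14, extension_fraction = 0.2),
                intercept = intercept,
                beta = c(class2 = 0.25, class3 = 0.45, temperature = 0.3,
                         rainfall = -0.3, dist_road = -0.4),
                trend = list(path = trend_path),
                seasonal = list(period = 4L, phi = 1, path = rep(seas_path, 2L)),
                cycle = list(p1 = 0.308, p2 = -0.366, sd = 0.05),
                field = list(sigma = 0.7, rho = 20, phi = 0.842),
                covariates = list(k = 3L),
                seed = seed)
}
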