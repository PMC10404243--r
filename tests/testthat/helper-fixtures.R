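# Shared fixtures: small windows, meshes and toy scenarios built in code.

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
square10 <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
pentagon <- cbind(c(0, 4.5, 10, 9.2, 3), c(1, 0, 1.2, 5.8, 7))

# a mesh of exactly two triangles on the unit square
two_triangle_mesh <- function() {
  structure(list(vertices = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                 triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                 boundary = unit_square,
                 interior_mask = rep(TRUE, 4L),
                 spacing = c(1, 1), snap = 1e-9),
            class = "lgcp_mesh")
}

# single right triangle with unit legs
one_triangle_mesh <- function() {
  structure(list(vertices = cbind(c(0, 1, 0), c(0, 0, 1)),
                 triangles = rbind(c(1L, 2L, 3L)),
                 boundary = cbind(c(0, 1, 0), c(0, 0, 1)),
                 interior_mask = rep(TRUE, 3L),
                 spacing = c(1, 1), snap = 1e-9),
            class = "lgcp_mesh")
}

# independent Yule-Walker oracle: solve the YW system for an AR(p)
# autocovariance, then build the T x T covariance by Toeplitz extension
yw_covariance <- function(theta, sigma2, T) {
  p <- length(theta)
  # gamma(0..p) from the linear Yule-Walker equations
  M <- matrix(0, p + 1L, p + 1L)
  b <- c(sigma2, rep(0, p))
  M[1L, 1L] <- 1
  for (j in seq_len(p)) M[1L, j + 1L] <- -theta[j]
  for (i in seq_len(p)) {
    M[i + 1L, i + 1L] <- M[i + 1L, i + 1L] + 1
    for (j in seq_len(p)) {
      k <- abs(i - j)
      M[i + 1L, k + 1L] <- M[i + 1L, k + 1L] - theta[j]
    }
  }
  g <- solve(M, b)
  gam <- numeric(T)
  gam[seq_len(min(p + 1L, T))] <- g[seq_len(min(p + 1L, T))]
  if (T > p + 1L) for (k in (p + 2L):T)
    gam[k] <- sum(theta * gam[k - seq_len(p)])
  toeplitz(gam)
}

# deterministic small event cloud inside a polygon
grid_events <- function(window, n, t = 1L) {
  xr <- range(window[, 1L]); yr <- range(window[, 2L])
  set.seed(4242)
  pts <- NULL
  while (is.null(pts) || nrow(pts) < n) {
    cand <- cbind(runif(4 * n, xr[1L], xr[2L]), runif(4 * n, yr[1L], yr[2L]))
    keep <- mgcv::in.out(rbind(window, window[1L, ]), cand)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  data.frame(x = pts[, 1L], y = pts[, 2L], t = rep_len(t, n))
}
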