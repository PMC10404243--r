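# Finite-element assembly for piecewise-linear (P1) basis functions on a
# triangulation: mass matrix, lumped mass, stiffness, barycentric projection
# and dual-cell quadrature weights.

#' Assemble finite-element matrices for a mesh
#'
#' Computes the P1 mass matrix `C_exact` (entries `<phi_i, phi_j>`), its
#' row-sum lumped diagonal `C_lumped` (the Markov approximation used in the
#' SPDE precision) and the stiffness matrix `G` (entries
#' `<grad phi_i, grad phi_j>`). Per triangle of area A the exact mass block is
#' A/12 with 2 on the diagonal and 1 off it; the lumped contribution is A/3
#' per vertex; the stiffness block follows the edge-gradient formula.
#'
#' @param mesh an `lgcp_mesh`.
#' @param area_tol triangles with area below this are reported as degenerate.
#' @return list of class `lgcp_fem` with `C_exact` (sparse symmetric),
#'   `C_lumped` (numeric N), `G` (sparse symmetric) and `total_area`.
#' @export
assemble_fem <- function(mesh, area_tol = 1e-12) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  a <- tri_signed_areas(v, tr)
  if (any(a <= area_tol))
    stop(sprintf("assembly error: degenerate triangle %d (area %.3g)",
                 which(a <= area_tol)[1L], a[which(a <= area_tol)[1L]]), call. = FALSE)

  x1 <- v[tr[, 1L], 1L]; y1 <- v[tr[, 1L], 2L]
  x2 <- v[tr[, 2L], 1L]; y2 <- v[tr[, 2L], 2L]
  x3 <- v[tr[, 3L], 1L]; y3 <- v[tr[, 3L], 2L]
  # gradient coefficients: grad phi_i = (b_i, c_i) / (2A)
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1

  ii <- c(tr[, 1L], tr[, 1L], tr[, 1L], tr[, 2L], tr[, 2L], tr[, 2L],
          tr[, 3L], tr[, 3L], tr[, 3L])
  jj <- c(tr[, 1L], tr[, 2L], tr[, 3L], tr[, 1L], tr[, 2L], tr[, 3L],
          tr[, 1L], tr[, 2L], tr[, 3L])

  mass <- c(2 * a, a, a, a, 2 * a, a, a, a, 2 * a) / 12
  C_exact <- Matrix::sparseMatrix(i = ii, j = jj, x = mass, dims = c(n, n))

  gg <- function(bi, ci, bj, cj) (bi * bj + ci * cj) / (4 * a)
  stiff <- c(gg(b1, c1, b1, c1), gg(b1, c1, b2, c2), gg(b1, c1, b3, c3),
             gg(b2, c2, b1, c1), gg(b2, c2, b2, c2), gg(b2, c2, b3, c3),
             gg(b3, c3, b1, c1), gg(b3, c3, b2, c2), gg(b3, c3, b3, c3))
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = stiff, dims = c(n, n))

  C_lumped <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(tr), j = rep(1L, 3L * nrow(tr)),
    x = rep(a / 3, 3L), dims = c(n, 1L)))

  structure(list(C_exact = C_exact, C_lumped = C_lumped, G = G,
                 total_area = sum(a)),
            class = "lgcp_fem")
}

#' Barycentric projection matrix from mesh vertices to arbitrary points
#'
#' Each row holds the P1 basis evaluations (barycentric coordinates) of one
#' point in its containing triangle: at most three non-zeros in `[0, 1]`
#' summing to one; a point coinciding with vertex `l` yields the indicator of
#' column `l`. Points on a shared edge are resolved deterministically to the
#' lowest-index containing triangle.
#'
#' @param mesh an `lgcp_mesh`.
#' @param points `P x 2` matrix of planar coordinates.
#' @return sparse `P x N` matrix.
#' @export
projection_matrix <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  loc <- locate_points(mesh, points)
  P <- nrow(points); n <- nrow(mesh$vertices)
  tr <- mesh$triangles[loc$triangle, , drop = FALSE]
  Matrix::sparseMatrix(i = rep(seq_len(P), 3L),
                       j = as.vector(tr),
                       x = as.vector(loc$bary),
                       dims = c(P, n))
}

#' Locate points in mesh triangles (lowest-index tie-break)
#' @return list(triangle = integer P, bary = P x 3)
#' @noRd
locate_points <- function(mesh, points) {
  v <- mesh$vertices; tr <- mesh$triangles
  M <- nrow(tr); P <- nrow(points)
  tol <- max(mesh$snap, 1e-12)
  a2 <- 2 * tri_signed_areas(v, tr)  # positive (CCW)

  # grid bucket index over triangle bounding boxes
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  ng <- max(1L, as.integer(floor(sqrt(M / 2))))
  gx <- function(x) pmin(pmax(1L + as.integer(floor((x - xr[1L]) / (diff(xr) + 1e-300) * ng)), 1L), ng)
  gy <- function(y) pmin(pmax(1L + as.integer(floor((y - yr[1L]) / (diff(yr) + 1e-300) * ng)), 1L), ng)
  tx1 <- pmin(v[tr[, 1L], 1L], v[tr[, 2L], 1L], v[tr[, 3L], 1L])
  tx2 <- pmax(v[tr[, 1L], 1L], v[tr[, 2L], 1L], v[tr[, 3L], 1L])
  ty1 <- pmin(v[tr[, 1L], 2L], v[tr[, 2L], 2L], v[tr[, 3L], 2L])
  ty2 <- pmax(v[tr[, 1L], 2L], v[tr[, 2L], 2L], v[tr[, 3L], 2L])
  buckets <- vector("list", ng * ng)
  for (m in seq_len(M)) {
    for (cxi in gx(tx1[m]):gx(tx2[m])) for (cyi in gy(ty1[m]):gy(ty2[m])) {
      k <- (cyi - 1L) * ng + cxi
      buckets[[k]] <- c(buckets[[k]], m)
    }
  }

  tri_id <- integer(P); bary <- matrix(0, P, 3L)
  for (i in seq_len(P)) {
    px <- points[i, 1L]; py <- points[i, 2L]
    cand <- buckets[[(gy(py) - 1L) * ng + gx(px)]]
    found <- FALSE
    for (m in sort(cand)) {
      j1 <- tr[m, 1L]; j2 <- tr[m, 2L]; j3 <- tr[m, 3L]
      l1 <- ((v[j2, 1L] - px) * (v[j3, 2L] - py) - (v[j3, 1L] - px) * (v[j2, 2L] - py)) / a2[m]
      if (l1 < -tol) next
      l2 <- ((v[j3, 1L] - px) * (v[j1, 2L] - py) - (v[j1, 1L] - px) * (v[j3, 2L] - py)) / a2[m]
      if (l2 < -tol) next
      l3 <- 1 - l1 - l2
      if (l3 < -tol) next
      l <- pmax(c(l1, l2, l3), 0)
      bary[i, ] <- l / sum(l)
      tri_id[i] <- m
      found <- TRUE
      break
    }
    if (!found)
      stop(sprintf("location error: point %d (%.4g, %.4g) is outside the mesh",
                   i, px, py), call. = FALSE)
  }
  list(triangle = tri_id, bary = bary)
}

#' Dual-cell quadrature weights
#'
#' Weight of vertex k is the area of its barycentric dual cell (union over
#' incident triangles of the vertex--edge-midpoints--centroid quadrilateral)
#' intersected with the window. The weights integrate the intensity in the
#' augmented Poisson likelihood; they sum exactly to the window area and the
#' rule is exact for fields constant over the window.
#'
#' @param mesh an `lgcp_mesh`.
#' @param window polygon; defaults to the mesh's own window.
#' @return numeric vector of length N (area units, all `>= 0`).
#' @export
dual_weights <- function(mesh, window = mesh$boundary) {
  window <- ccw(as_polygon(window))
  if (polygon_area(window) <= 0)
    stop("invalid geometry: empty window", call. = FALSE)
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  a <- tri_signed_areas(v, tr)
  wts <- numeric(n)
  for (m in seq_len(nrow(tr))) {
    p1 <- v[tr[m, 1L], ]; p2 <- v[tr[m, 2L], ]; p3 <- v[tr[m, 3L], ]
    tri <- rbind(p1, p2, p3)
    ain <- clip_area(window, tri)
    if (ain <= 0) next
    if (abs(ain - a[m]) <= 1e-12 * a[m]) {
      wts[tr[m, ]] <- wts[tr[m, ]] + a[m] / 3
    } else {
      g <- (p1 + p2 + p3) / 3
      m12 <- (p1 + p2) / 2; m23 <- (p2 + p3) / 2; m31 <- (p3 + p1) / 2
      quads <- list(rbind(p1, m12, g, m31),
                    rbind(p2, m23, g, m12),
                    rbind(p3, m31, g, m23))
      for (k in 1:3) wts[tr[m, k]] <- wts[tr[m, k]] + clip_area(window, quads[[k]])
    }
  }
  wts
}
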