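# Mesh construction and finite-element assembly.

test_that("mesh construction covers the window and refines monotonically", {
  m <- build_mesh(unit_square, max_edge_inner = 0.2, extension_fraction = 0)
  expect_gte(nrow(m$vertices), 25)
  fem <- assemble_fem(m)
  expect_gte(fem$total_area, 1 - 1e-9)
  expect_true(all(m$interior_mask))

  m_fine <- build_mesh(unit_square, max_edge_inner = 0.1, extension_fraction = 0)
  expect_gt(nrow(m_fine$vertices), nrow(m$vertices))

  # all edges at most max_edge_inner
  tr <- m$triangles; v <- m$vertices
  for (k in 1:3) {
    i <- tr[, k]; j <- tr[, if (k == 3) 1 else k + 1]
    expect_lte(max(sqrt(rowSums((v[i, ] - v[j, ])^2))), 0.2 + 1e-12)
  }
})

test_that("extension ring vertices are flagged and capped mesh errors", {
  m <- build_mesh(unit_square, max_edge_inner = 0.3, extension_fraction = 0.2)
  expect_true(any(m$interior_mask))
  expect_true(any(!m$interior_mask))
  # extension vertices lie outside the window
  out <- m$vertices[!m$interior_mask, , drop = FALSE]
  expect_false(any(mgcv::in.out(rbind(unit_square, unit_square[1, ]), out)))
  expect_error(build_mesh(unit_square, 1e-4, max_vertices = 1000),
               "resource error")
  crossed <- cbind(c(0, 4, 4, 3, 0), c(0, 0, 2, -1, 2))
  expect_error(build_mesh(crossed, 0.5), "self-intersecting")
})

test_that("P1 mass and stiffness blocks match hand-computed values", {
  # single right triangle with unit legs, area 1/2
  fem1 <- assemble_fem(one_triangle_mesh())
  expect_equal(fem1$C_lumped, rep(1 / 6, 3), tolerance = 1e-12)
  expect_equal(as.matrix(fem1$C_exact),
               (1 / 24) * (diag(3) + matrix(1, 3, 3)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(max(abs(Matrix::rowSums(fem1$G))), 0, tolerance = 1e-12)

  # two-triangle unit square: hand-computed 4x4 matrices
  fem2 <- assemble_fem(two_triangle_mesh())
  expect_equal(sum(fem2$C_lumped), 1, tolerance = 1e-12)
  # vertices 1 and 3 sit on the shared diagonal: lumped mass 2*(1/6), others 1/6
  expect_equal(fem2$C_lumped, c(1 / 3, 1 / 6, 1 / 3, 1 / 6), tolerance = 1e-12)
  C_hand <- matrix(c(4, 1, 2, 1,
                     1, 2, 1, 0,
                     2, 1, 4, 1,
                     1, 0, 1, 2) / 24, 4, 4)
  expect_equal(as.matrix(fem2$C_exact), C_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
  G_hand <- matrix(c( 1, -0.5,  0, -0.5,
                     -0.5, 1, -0.5, 0,
                      0, -0.5, 1, -0.5,
                     -0.5, 0, -0.5, 1), 4, 4)
  expect_equal(as.matrix(fem2$G), G_hand, tolerance = 1e-12, ignore_attr = TRUE)
  # G is PSD with the constant vector in its null space
  ev <- eigen(as.matrix(fem2$G), symmetric = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_equal(as.numeric(fem2$G %*% rep(1, 4)), rep(0, 4), tolerance = 1e-12)
  expect_error(assemble_fem(structure(list(
    vertices = cbind(c(0, 1, 2), c(0, 0, 0)), triangles = rbind(c(1L, 2L, 3L)),
    boundary = unit_square, interior_mask = rep(TRUE, 3), spacing = c(1, 1),
    snap = 1e-9), class = "lgcp_mesh")), "degenerate triangle")
})

test_that("projection rows are barycentric: indicators, centroids, unity", {
  m <- build_mesh(unit_square, max_edge_inner = 0.3, extension_fraction = 0)
  # point at a vertex -> indicator row
  k <- 7L
  A <- projection_matrix(m, m$vertices[k, , drop = FALSE])
  expect_equal(as.numeric(A[1, k]), 1)
  expect_equal(sum(A), 1)
  # triangle centroid -> 1/3 on its three vertices
  tr <- m$triangles[5L, ]
  cen <- colMeans(m$vertices[tr, ])
  A2 <- projection_matrix(m, rbind(cen))
  expect_equal(sort(as.numeric(A2[1, tr])), rep(1 / 3, 3), tolerance = 1e-9)
  # partition of unity for random interior points
  set.seed(11)
  pts <- cbind(runif(50), runif(50))
  A3 <- projection_matrix(m, pts)
  expect_equal(as.numeric(Matrix::rowSums(A3)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(A3@x >= 0 & A3@x <= 1 + 1e-12))
  expect_error(projection_matrix(m, cbind(5, 5)), "location error")
})

test_that("dual weights conserve area, vanish outside, and are exact for linear fields", {
  m <- build_mesh(unit_square, max_edge_inner = 0.25, extension_fraction = 0.3)
  w <- dual_weights(m, unit_square)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # vertices far outside the window get zero weight
  ring <- rbind(unit_square, unit_square[1, ])
  d_bnd <- vapply(seq_len(nrow(m$vertices)), function(i) {
    p <- m$vertices[i, ]
    min(sqrt((ring[, 1] - p[1])^2 + (ring[, 2] - p[2])^2))
  }, numeric(1))
  far_out <- !m$interior_mask & d_bnd > 0.5
  expect_true(any(far_out) && all(w[far_out] == 0))

  # exact quadrature of a linear field when triangles tile the window exactly
  m0 <- build_mesh(unit_square, max_edge_inner = 0.25, extension_fraction = 0)
  w0 <- dual_weights(m0, unit_square)
  f <- 2 + 3 * m0$vertices[, 1] - m0$vertices[, 2]
  exact <- 2 + 3 * 0.5 - 0.5  # integral of f over the unit square
  expect_equal(sum(w0 * f), exact, tolerance = 1e-8)

  # area conservation under refinement
  w1 <- dual_weights(build_mesh(unit_square, 0.125, extension_fraction = 0), unit_square)
  expect_lt(abs(sum(w1) - sum(w0)), 1e-9)

  # non-convex window through a coarse mesh still conserves area
  ell <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  me <- build_mesh(ell, max_edge_inner = 0.6, extension_fraction = 0.2)
  expect_equal(sum(dual_weights(me, ell)), 3, tolerance = 1e-9)
  expect_error(dual_weights(m0, cbind(c(0, 0, 0), c(0, 1, 2))), "invalid geometry")
})
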