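test_that("coincident endpoints map to their vertex at distance zero", {
  surfs <- tiny_surfaces()
  tr <- tractogram(list(rbind(surfs$left$vertices[2L, ], c(0, 0, 0),
                              surfs$right$vertices[3L, ])))
  a <- assign_endpoints(tr, surfs)
  expect_equal(a$endpoints$vertex, c(2L, 6L))     # global ids: left 1..3, right 4..6
  expect_equal(a$endpoints$distance, c(0, 0))
  expect_equal(a$endpoints$hemisphere, c("left", "right"))
})

test_that("ties break to the lowest vertex id, left hemisphere before right", {
  # vertices 3 and 12 equidistant from the endpoint; 3 must win
  v <- matrix(rep(100, 14 * 3), 14, 3)
  v[3L, ] <- c(1, 0, 0); v[12L, ] <- c(-1, 0, 0)
  left <- cortical_surface(v, cbind(1:12, 2:13, 3:14), "left")
  right <- cortical_surface(v + 200, cbind(1:12, 2:13, 3:14), "right")
  tr <- tractogram(list(rbind(c(0, 0, 0), c(0, 0, 0.001))))
  a <- assign_endpoints(tr, list(left = left, right = right))
  expect_equal(a$endpoints$vertex[1L], 3L)
  # a left and a right vertex at mirrored positions: left wins the exact tie
  vl <- rbind(c(-5, 0, 0), c(-50, 50, 0), c(-50, -50, 0))
  vr <- rbind(c(5, 0, 0), c(50, 50, 0), c(50, -50, 0))
  surfs <- list(left = cortical_surface(vl, rbind(c(1, 2, 3)), "left"),
                right = cortical_surface(vr, rbind(c(1, 2, 3)), "right"))
  tr2 <- tractogram(list(rbind(c(0, 0, 0), c(0, 1, 0))))
  a2 <- assign_endpoints(tr2, surfs)
  expect_equal(a2$endpoints$hemisphere, c("left", "left"))
})

test_that("assignment equals the exhaustive oracle on random endpoints", {
  b <- small_bundle(seed = 31, n_streamlines = 250)
  a <- assign_endpoints(b$tractogram, b$surfaces)
  eps <- streamline_endpoints(b$tractogram)
  verts <- rbind(b$surfaces$left$vertices, b$surfaces$right$vertices)
  o <- oracle_nearest_vertex(eps$points, verts)
  expect_identical(a$endpoints$vertex, o$index)
  expect_equal(a$endpoints$distance, o$distance)
})

test_that("conservation: assigned endpoints = 2 x streamlines; cap creates unassigned", {
  b <- small_bundle(seed = 32, n_streamlines = 400)
  a <- assign_endpoints(b$tractogram, b$surfaces)
  expect_equal(sum(a$endpoints$assigned), 2L * 400L)
  expect_equal(sum(a$vertex_counts), 2L * 400L)
  capped <- assign_endpoints(b$tractogram, b$surfaces, max_distance_mm = 0.1)
  expect_equal(sum(capped$endpoints$assigned), 0L)   # endpoints sit 0.3 mm off-surface
  empty <- assign_endpoints(tractogram(list()), b$surfaces)
  expect_equal(nrow(empty$endpoints), 0L)
  expect_equal(sum(empty$vertex_counts), 0L)
})

test_that("triangle median counts follow the median-of-three rule", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  surf <- cortical_surface(v, rbind(c(1, 2, 3)), "left")
  fake <- structure(list(vertex_counts = c(2L, 5L, 100L), n_left_vertices = 3L,
                         endpoints = data.frame()),
                    class = "endpoint_assignment")
  f <- triangle_counts(fake, surf)
  expect_equal(f$n, 5)
  expect_equal(f$display, log(6))
  fake$vertex_counts <- c(0L, 0L, 0L)
  f0 <- triangle_counts(fake, surf)
  expect_equal(f0$n, 0); expect_equal(f0$display, 0)
  expect_false(f0$any_involved)
  fake$vertex_counts <- c(7L, 7L, 7L)
  expect_equal(triangle_counts(fake, surf)$n, 7)
})

test_that("hemisphere coverage: trivial extremes and area weighting", {
  b <- small_bundle(seed = 33, n_streamlines = 5)
  empty <- assign_endpoints(tractogram(list()), b$surfaces)
  f <- triangle_counts(empty, b$surfaces$left)
  expect_equal(hemisphere_coverage(f, b$surfaces$left), 0)
  full <- empty
  full$vertex_counts <- rep(1L, length(full$vertex_counts))
  f1 <- triangle_counts(full, b$surfaces$left)
  expect_equal(hemisphere_coverage(f1, b$surfaces$left), 1)
  expect_equal(hemisphere_coverage(f1, b$surfaces$left, area_weighted = TRUE), 1)
  # area-weighted and count-based agree on a near-uniform mesh
  a <- assign_endpoints(b$tractogram, b$surfaces)
  fl <- triangle_counts(a, b$surfaces$left)
  expect_lt(abs(hemisphere_coverage(fl, b$surfaces$left) -
                hemisphere_coverage(fl, b$surfaces$left, area_weighted = TRUE)), 0.05)
})

test_that("monotonicity: adding streamlines never decreases counts or coverage", {
  b <- small_bundle(seed = 34, n_streamlines = 600)
  half <- tractogram(b$tractogram$streamlines[1:300])
  a_half <- assign_endpoints(half, b$surfaces)
  a_full <- assign_endpoints(b$tractogram, b$surfaces)
  expect_true(all(a_full$vertex_counts >= a_half$vertex_counts))
  f_half <- triangle_counts(a_half, b$surfaces$left)
  f_full <- triangle_counts(a_full, b$surfaces$left)
  expect_true(all(f_full$n >= f_half$n))
  expect_gte(hemisphere_coverage(f_full, b$surfaces$left),
             hemisphere_coverage(f_half, b$surfaces$left))
})

test_that("translation invariance: rigid shift leaves assignments unchanged", {
  b <- small_bundle(seed = 35, n_streamlines = 150)
  shift <- c(12.3, -4.5, 7.7)
  shift_surf <- function(s) cortical_surface(sweep(s$vertices, 2L, -shift),
                                             s$triangles, s$hemisphere)
  surfs2 <- list(left = shift_surf(b$surfaces$left),
                 right = shift_surf(b$surfaces$right))
  tr2 <- tractogram(lapply(b$tractogram$streamlines,
                           function(s) sweep(s, 2L, -shift)))
  a1 <- assign_endpoints(b$tractogram, b$surfaces)
  a2 <- assign_endpoints(tr2, surfs2)
  expect_identical(a1$endpoints$vertex, a2$endpoints$vertex)
  expect_identical(a1$vertex_counts, a2$vertex_counts)
})

test_that("recovered coverage matches planted ground truth", {
  b <- small_bundle(seed = 36, n_streamlines = 4000)
  a <- assign_endpoints(b$tractogram, b$surfaces)
  for (h in c("left", "right")) {
    f <- triangle_counts(a, b$surfaces[[h]])
    cov <- hemisphere_coverage(f, b$surfaces[[h]])
    planted <- b$ground_truth$coverage[[h]]
    expect_lt(abs(cov - planted), tol3se(planted, nrow(b$surfaces[[h]]$triangles)))
  }
})
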