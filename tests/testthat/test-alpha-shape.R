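test_that("the 2-D in-circumcircle predicate classifies the textbook cases", {
  A <- c(1, 0); B <- c(0, 1); C <- c(-1, 0)
  expect_equal(in_circumcircle_2d(A, B, C, c(0, 0)), "inside")
  expect_equal(in_circumcircle_2d(A, B, C, c(10, 10)), "outside")
  expect_equal(in_circumcircle_2d(A, B, C, c(0, -1)), "on")
  # orientation-independent
  expect_equal(in_circumcircle_2d(C, B, A, c(0, 0)), "inside")
  expect_error(in_circumcircle_2d(c(0, 0), c(1, 1), c(2, 2), c(0, 1)),
               "collinear")
})

test_that("orthogonality classes follow the power-distance convention", {
  p <- function(loc, w) list(location = loc, weight = w)
  expect_equal(orthogonality_class(p(c(0, 0, 0), 1), p(c(sqrt(2), 0, 0), 1)),
               "orthogonal")
  expect_equal(orthogonality_class(p(c(0, 0, 0), 1), p(c(10, 0, 0), 1)),
               "sub_orthogonal")
  expect_equal(orthogonality_class(p(c(0, 0, 0), 1), p(c(0, 0, 0), 1)),
               "super_orthogonal")
  # audit convention: unsquared distance against the weight sum
  expect_equal(orthogonality_class(p(c(0, 0, 0), 1), p(c(2, 0, 0), 1),
                                   convention = "linear"), "orthogonal")
})

test_that("four non-coplanar points give exactly one tetrahedron", {
  wp <- data.frame(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1),
                   weight = 1)
  tri <- build_regular_triangulation(wp)
  expect_equal(nrow(tri$tetrahedra), 1)
  expect_equal(sort(tri$tetrahedra[1, ]), 1:4)
})

test_that("degenerate inputs raise dimension errors", {
  expect_error(build_regular_triangulation(
    data.frame(x = 0:2, y = 0, z = 0, weight = 1)), "at least 4")
  expect_error(build_regular_triangulation(
    data.frame(x = 0:5, y = (0:5)^2, z = 0, weight = 1)), "coplanar")
})

test_that("the triangulation matches brute-force empty-orthosphere enumeration", {
  for (s in 1:15) {
    wp <- random_weighted_points(n = sample(8:20, 1), seed = 1000 + s)
    tri <- build_regular_triangulation(wp, jitter = 0)
    got <- tet_keys(tri$tetrahedra)
    want <- bf_regular_triangulation(as.matrix(wp[, c("x", "y", "z")]),
                                     wp$weight)
    expect_identical(got, want)
  }
})

test_that("cospherical cube corners still triangulate the cube", {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 2
  wp <- data.frame(x = g[, 1], y = g[, 2], z = g[, 3], weight = 1)
  tri <- build_regular_triangulation(wp)
  # tiles the cube: total volume 8
  vol <- 0
  pu <- tri$coords_used
  for (k in seq_len(nrow(tri$tetrahedra))) {
    v <- tri$tetrahedra[k, ]
    vol <- vol + abs(det(pu[v[2:4], ] - matrix(pu[v[1], ], 3, 3, TRUE))) / 6
  }
  # tolerance covers the tie-break jitter moving the hull corners slightly;
  # a missing or doubled tetrahedron would be off by ~1.3
  expect_equal(vol, 8, tolerance = 2e-2)
  # empty-orthosphere property holds on the jittered coordinates
  for (k in seq_len(nrow(tri$tetrahedra))) {
    v <- tri$tetrahedra[k, ]
    others <- setdiff(1:8, v)
    pw <- colSums((t(pu[others, , drop = FALSE]) - tri$orthocenter[k, ])^2) -
      1 - tri$ortho_r2[k]
    expect_gte(min(pw), -1e-6)
  }
})

test_that("fully dominated points are reported as redundant, never dropped silently", {
  wp <- random_weighted_points(10, seed = 5)
  wp <- rbind(wp, data.frame(serial = 11:12, chain = "A",
                             x = c(5, 5.02), y = 5, z = 5,
                             weight = c(100, 1e-3)))
  tri <- build_regular_triangulation(wp, jitter = 0)
  expect_true(12 %in% tri$redundant)
  expect_false(12 %in% unique(as.vector(tri$tetrahedra)))
})

test_that("the alpha filtration is monotone and reaches the full triangulation", {
  wp <- random_weighted_points(25, seed = 42)
  tri <- build_regular_triangulation(wp)
  alphas <- c(-5, -1, 0, 1, 5, 25, Inf)
  prev <- character()
  for (a in alphas) {
    keys <- tet_keys(alpha_complex(tri, a)$tetrahedra)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
  expect_identical(prev, tet_keys(tri$tetrahedra))
})

test_that("no alpha-zero tetrahedron spans two far-apart clusters", {
  wp1 <- random_weighted_points(8, seed = 1, box = 5)
  wp2 <- random_weighted_points(8, seed = 2, box = 5)
  wp2$x <- wp2$x + 100
  wp2$serial <- wp2$serial + 8
  wp <- rbind(wp1, wp2)
  cx <- alpha_complex(build_regular_triangulation(wp), alpha = 0)
  if (nrow(cx$tetrahedra)) {
    spans <- apply(cx$tetrahedra, 1, function(v) any(v <= 8) && any(v > 8))
    expect_false(any(spans))
  } else succeed()
})

test_that("four touching carbon-like atoms form an alpha-zero tetrahedron", {
  # regular tetrahedron, edge 2.0, radius 1.7: circumradius 2*sqrt(3/8),
  # signed squared orthoradius 1.5 - 2.89 < 0
  fr <- regular_tet_frame(edge = 2, radius = 1.7)
  cx <- alpha_complex(build_regular_triangulation(assign_weights(fr)), 0)
  expect_equal(nrow(cx$tetrahedra), 1)
})

test_that("lattice blocks expose exactly the boundary sites as surface", {
  for (m in 3:5) {
    spec <- synthetic_spec("lattice_block", dims = c(m, m, m), jitter = 0)
    fr <- make_lattice_block(spec)
    cx <- alpha_complex(build_regular_triangulation(assign_weights(fr)), 0)
    surf <- surface_atoms(cx)
    expect_length(surf, m^3 - (m - 2)^3)
    expect_setequal(surf, attr(fr, "truth")$expected_surface)
  }
})

test_that("a single-tetrahedron complex has all four atoms on the surface", {
  fr <- regular_tet_frame()
  cx <- alpha_complex(build_regular_triangulation(assign_weights(fr)), 0)
  expect_setequal(surface_atoms(cx), 1:4)
})

test_that("combinatorial output is invariant under rigid motion of generic sets", {
  for (s in 1:5) {
    wp <- random_weighted_points(20, seed = 300 + s)
    tri1 <- build_regular_triangulation(wp)
    rm <- rigid_motion(400 + s)
    xyz <- as.matrix(wp[, c("x", "y", "z")]) %*% t(rm$R)
    wp2 <- wp
    wp2$x <- xyz[, 1] + rm$t[1]; wp2$y <- xyz[, 2] + rm$t[2]
    wp2$z <- xyz[, 3] + rm$t[3]
    tri2 <- build_regular_triangulation(wp2)
    expect_identical(tet_keys(tri1$tetrahedra), tet_keys(tri2$tetrahedra))
    expect_setequal(surface_atoms(alpha_complex(tri1, 0)),
                    surface_atoms(alpha_complex(tri2, 0)))
  }
})
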