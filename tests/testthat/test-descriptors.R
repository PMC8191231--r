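test_that("the apex of a single regular tetrahedron has the closed-form solid angle", {
  fr <- regular_tet_frame(edge = 2, radius = 1.7)
  # generic input: no tie-break jitter needed, so the closed form is hit to
  # floating-point accuracy
  cx <- alpha_complex(build_regular_triangulation(assign_weights(fr),
                                                  jitter = 0), 0)
  # per-tetrahedron solid angle 3*acos(1/3) - pi, rescaled by cos(s/4)
  want <- cos((3 * acos(1 / 3) - pi) / 4)
  for (s in 1:4) {
    expect_equal(solid_angle(s, cx), want, tolerance = 1e-6)
    # cross-check against the Van Oosterom-Strackee closed form
    pts <- cx$coords_used
    rest <- setdiff(1:4, s)
    vos <- cos(vos_solid_angle(pts[s, ], pts[rest[1], ], pts[rest[2], ],
                               pts[rest[3], ]) / 4)
    expect_equal(solid_angle(s, cx), vos, tolerance = 1e-9)
  }
  expect_equal(cos((3 * acos(1 / 3) - pi) / 4), 0.99051, tolerance = 1e-4)
})

test_that("interior lattice atoms are fully buried and flat-face atoms near zero", {
  spec <- synthetic_spec("lattice_block", dims = c(5, 5, 5), jitter = 0)
  fr <- make_lattice_block(spec)
  cx <- alpha_complex(build_regular_triangulation(assign_weights(fr)), 0)
  om <- solid_angle_map(cx)
  at <- fr$atoms
  s <- spec$spacing
  interior <- at$serial[at$x > s / 2 & at$x < 3.5 * s + s / 2 &
                        at$y > s / 2 & at$y < 3.5 * s + s / 2 &
                        at$z > s / 2 & at$z < 3.5 * s + s / 2]
  center <- at$serial[abs(at$x - 2 * s) < s / 2 & abs(at$y - 2 * s) < s / 2 &
                      abs(at$z - 2 * s) < s / 2]
  expect_equal(unname(om[as.character(center)]), -1, tolerance = 1e-6)
  face <- at$serial[at$z < s / 2 & at$x > s / 2 & at$x < 3.5 * s &
                    at$y > s / 2 & at$y < 3.5 * s]
  expect_length(face, 9)
  expect_true(all(abs(om[as.character(face)]) <= 0.1))
  # lattice edge and corner atoms are markedly convex by contrast
  corner <- at$serial[at$x < s / 2 & at$y < s / 2 & at$z < s / 2]
  expect_gt(om[as.character(corner)], 0.5)
})

test_that("the dihedral-angle implementation agrees with the VOS oracle atomwise", {
  kh <- make_knob_hole_dimer(synthetic_spec("knob_hole_dimer", n_knobs = 2))
  wp <- assign_weights(kh)
  cx <- alpha_complex(build_regular_triangulation(
    wp[wp$chain == "B", , drop = FALSE]), 0)
  expect_equal(solid_angle_map(cx), vos_omega_map(cx), tolerance = 1e-9)
})

test_that("every solid angle lies in [-1, 1]", {
  fr <- make_slab_dimer(synthetic_spec("slab_dimer", seed = 9))
  cx <- alpha_complex(build_regular_triangulation(assign_weights(fr)), 0)
  om <- solid_angle_map(cx)
  expect_true(all(om >= -1 & om <= 1))
  expect_error(solid_angle(99999, cx), "unknown vertex")
})

test_that("the match indicator follows the strict product rule", {
  expect_equal(match_indicator(0.5, -0.3), 1L)
  expect_equal(match_indicator(0.5, 0.2), 0L)
  expect_equal(match_indicator(0, -0.9), 0L)
  expect_equal(match_indicator(-0.4, -0.7), 0L)
  expect_equal(match_indicator(c(0.5, 0.5, 0, -0.4), c(-0.3, 0.2, -0.9, -0.7)),
               c(1L, 0L, 0L, 0L))
  expect_error(match_indicator(1.5, 0), "\\[-1, 1\\]")
})

test_that("matching_rate is the matched fraction and is undefined without pairs", {
  om <- c(`1` = 0.5, `2` = 0.4, `3` = -0.2, `4` = 0.6,
          `11` = -0.5, `12` = -0.4, `13` = -0.3, `14` = 0.2)
  pairs <- cbind(1:4, 11:14)
  expect_equal(matching_rate(pairs, om), 0.5)   # pairs 1 and 2 match
  om_all <- om; om_all[5:8] <- -abs(om_all[5:8])
  pairs_all <- cbind(c(1, 2, 4), c(11, 12, 13))
  expect_equal(matching_rate(pairs_all, om), 1.0)
  expect_true(is.na(matching_rate(pairs[0, , drop = FALSE], om)))
})

test_that("centers of mass are mass-weighted means", {
  expect_equal(com_of_particles(c(1, 1), rbind(c(0, 0, 0), c(2, 0, 0))),
               c(1, 0, 0))
  expect_equal(com_of_particles(c(1, 3), rbind(c(0, 0, 0), c(4, 0, 0))),
               c(3, 0, 0))
  expect_equal(com_of_particles(5, c(1, 2, 3)), c(1, 2, 3))
  expect_error(com_of_particles(0, c(0, 0, 0)), "positive")
})

test_that("mean interfacial COM distance averages pair distances", {
  atoms <- data.frame(serial = 1:4, name = "C", element = "C",
                      resname = "LIG", resno = 1:4,
                      chain = c("A", "A", "B", "B"),
                      x = c(0, 0, 3, 2), y = c(0, 0, 4, 0),
                      z = c(0, 10, 0, 10),
                      mass = 12.011, radius = 1.7)
  fr <- structure_frame(atoms)
  expect_equal(mean_interface_com_distance(cbind(1, 3), fr), 5)
  expect_equal(mean_interface_com_distance(cbind(c(1, 2), c(3, 4)), fr),
               (5 + 2) / 2)
  expect_true(is.na(mean_interface_com_distance(matrix(0, 0, 2), fr)))
})

test_that("RMSD is zero to itself, translation-sensitive, and fit-removable", {
  fr <- make_slab_dimer(synthetic_spec("slab_dimer", seed = 6))
  expect_equal(rmsd_to_reference(fr, fr, fit = "none"), 0, tolerance = 1e-9)
  shifted <- fr
  shifted$atoms$x <- fr$atoms$x + 1
  expect_equal(rmsd_to_reference(shifted, fr, fit = "none"), 1,
               tolerance = 1e-9)
  expect_equal(rmsd_to_reference(shifted, fr, fit = "superpose"), 0,
               tolerance = 1e-6)
  bad <- fr; bad$atoms <- fr$atoms[-1, ]
  expect_error(rmsd_to_reference(bad, fr), "mismatch")
})

test_that("the moving average shrinks its window at the edges and skips NA", {
  expect_equal(moving_average(rep(3, 7), 5), rep(3, 7))
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 1), c(1, 2, 3, 4, 5))
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(c(1, NA, 3), 3), c(1, NA, 3))
  expect_error(moving_average(1:5, 4), "odd")
  expect_error(moving_average(1:5, 0), "odd")
})

test_that("identical frames give a constant series with smoothing a no-op", {
  fr <- make_slab_dimer(synthetic_spec("slab_dimer", seed = 10))
  frames <- lapply(0:3, function(i) { f <- fr; f$frame_index <- i; f })
  ds <- trajectory_descriptors(frames, "A", "B", window = 3)
  expect_equal(length(unique(ds$matching_rate)), 1)
  expect_equal(ds$matching_rate_smoothed, ds$matching_rate)
  expect_equal(ds$mean_com_distance_smoothed, ds$mean_com_distance)
  expect_equal(attr(ds, "series_mean")$mean_com_distance,
               ds$mean_com_distance[1])
  expect_equal(ds$rmsd, rep(0, 4), tolerance = 1e-6)
})

test_that("separation trajectories have increasing COM distance, undefined when apart", {
  spec <- synthetic_spec("separation_trajectory",
                         schedule = c(seq(1.2, 2.4, 0.3), 40))
  frames <- make_separation_trajectory(spec)
  ds <- trajectory_descriptors(frames, "A", "B", window = 1, rmsd = FALSE)
  with_pairs <- which(ds$n_pairs > 0)
  expect_gte(length(with_pairs), 3)
  expect_true(all(diff(ds$mean_com_distance[with_pairs]) > 0))
  # far-separated last frame is flagged undefined, not zero
  expect_true(is.na(ds$matching_rate[nrow(ds)]))
  expect_true(is.na(ds$mean_com_distance[nrow(ds)]))
  # window = 1 smoothing is the identity
  expect_equal(ds$matching_rate_smoothed, ds$matching_rate)
})

test_that("matching rate and COM distance are rigid-motion invariant", {
  kh <- make_knob_hole_dimer(synthetic_spec("knob_hole_dimer", n_knobs = 2))
  an1 <- alphadimer:::analyze_dimer_frame(kh, "A", "B")
  rm <- rigid_motion(77)
  an2 <- alphadimer:::analyze_dimer_frame(apply_rigid(kh, rm), "A", "B")
  expect_equal(an2$matching_rate, an1$matching_rate, tolerance = 1e-9)
  expect_equal(an2$mean_com_distance, an1$mean_com_distance,
               tolerance = 1e-9)
  expect_setequal(an2$result$X, an1$result$X)
})
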