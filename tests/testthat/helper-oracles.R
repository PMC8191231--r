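# Independent oracles and small fixture builders shared across tests.

# Brute-force regular triangulation: enumerate all 4-subsets and keep those
# whose orthosphere has non-negative power distance to every other point.
# Vectorized over subsets (adjugate solve for the orthocenters), independent
# of the incremental algorithm under test.
bf_regular_triangulation <- function(pts, w, tol = 1e-7) {
  n <- nrow(pts)
  cmb <- t(utils::combn(n, 4))
  P1 <- pts[cmb[, 1], , drop = FALSE]; P2 <- pts[cmb[, 2], , drop = FALSE]
  P3 <- pts[cmb[, 3], , drop = FALSE]; P4 <- pts[cmb[, 4], , drop = FALSE]
  l <- rowSums(pts^2) - w
  a1 <- 2 * (P2 - P1); a2 <- 2 * (P3 - P1); a3 <- 2 * (P4 - P1)
  b1 <- l[cmb[, 2]] - l[cmb[, 1]]
  b2 <- l[cmb[, 3]] - l[cmb[, 1]]
  b3 <- l[cmb[, 4]] - l[cmb[, 1]]
  cross_rows <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross_rows(a2, a3); c31 <- cross_rows(a3, a1); c12 <- cross_rows(a1, a2)
  det <- rowSums(a1 * c23)
  ok <- abs(det) > 1e-12
  ctr <- (b1 * c23 + b2 * c31 + b3 * c12) / det
  r2 <- rowSums((ctr - P1)^2) - w[cmb[, 1]]
  # power of every point against every subset's orthosphere
  pow <- matrix(0, nrow(cmb), n)
  for (ax in 1:3)
    pow <- pow + (matrix(pts[, ax], nrow(cmb), n, byrow = TRUE) - ctr[, ax])^2
  pow <- pow - matrix(w, nrow(cmb), n, byrow = TRUE) - r2
  for (j in 1:4) pow[cbind(seq_len(nrow(cmb)), cmb[, j])] <- Inf
  keep <- ok & (apply(pow, 1, min) >= -tol)
  kept <- cmb[keep, , drop = FALSE]
  sort(apply(kept, 1, function(r) paste(sort(r), collapse = "-")))
}

tet_keys <- function(tets) {
  if (nrow(tets) == 0) return(character())
  sort(apply(tets, 1, function(r) paste(sort(r), collapse = "-")))
}

# Van Oosterom-Strackee closed form for the solid angle subtended at A by
# triangle BCD; the oracle for the dihedral-angle implementation.
vos_solid_angle <- function(A, B, C, D) {
  a <- B - A; b <- C - A; d <- D - A
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); ld <- sqrt(sum(d^2))
  num <- abs(det(rbind(a, b, d)))
  den <- la * lb * ld + sum(a * b) * ld + sum(a * d) * lb + sum(b * d) * la
  2 * atan2(num, den)
}

# total subtended angle per atom of a complex, via the VOS oracle
vos_omega_map <- function(complex, flat_tol = 0.02) {
  pts <- complex$coords_used
  n <- nrow(pts)
  tot <- numeric(n); seen <- logical(n)
  tt <- complex$tetrahedra
  for (k in seq_len(nrow(tt))) {
    v <- tt[k, ]
    for (j in 1:4) {
      o <- v[j]; r <- v[-j]
      tot[o] <- tot[o] + vos_solid_angle(pts[o, ], pts[r[1], ], pts[r[2], ],
                                         pts[r[3], ])
      seen[o] <- TRUE
    }
  }
  om <- rep(1, n)
  om[seen] <- cos(tot[seen] / 4)
  om[abs(om) < flat_tol] <- 0
  ids <- if (!is.null(complex$points$serial)) complex$points$serial else seq_len(n)
  stats::setNames(om, ids)
}

# random rigid motion (proper rotation + translation)
rigid_motion <- function(seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::runif(3, -20, 20))
}

apply_rigid <- function(frame, rm) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(rm$R)
  xyz <- sweep(xyz, 2, rm$t, "+")
  frame$atoms$x <- xyz[, 1]; frame$atoms$y <- xyz[, 2]; frame$atoms$z <- xyz[, 3]
  frame
}

random_weighted_points <- function(n, seed, box = 10, wmax = 4) {
  set.seed(seed)
  data.frame(serial = seq_len(n), chain = "A",
             x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
             z = stats::runif(n, 0, box), weight = stats::runif(n, 0, wmax))
}

# a frame of four carbon-like atoms at pairwise distance `edge`
regular_tet_frame <- function(edge = 2, radius = 1.7) {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3))) * edge
  atoms <- data.frame(serial = 1:4, name = "C", element = "C",
                      resname = "LIG", resno = 1:4, chain = "A",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      mass = 12.011, radius = radius)
  structure_frame(atoms)
}
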