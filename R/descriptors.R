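# Per-atom solid-angle curvature, convex/concave matching rate of
# cross-chain pairs, interfacial center-of-mass distances, RMSD, and the
# per-frame trajectory pipeline with moving-average smoothing.

# solid angle subtended at vertex A of tetrahedron ABCD: the three interior
# dihedral angles along the edges through A, minus pi (spherical excess);
# vectorized over rows of the coordinate matrices
tet_solid_angles <- function(A, B, C, D) {
  cross3 <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  dihed <- function(e, f1, f2) {
    n1 <- cross3(e, f1); n2 <- cross3(e, f2)
    cosv <- rowSums(n1 * n2) /
      sqrt(pmax(rowSums(n1^2) * rowSums(n2^2), 1e-300))
    acos(pmin(1, pmax(-1, cosv)))
  }
  u <- B - A; v <- C - A; w <- D - A
  dihed(u, v, w) + dihed(v, u, w) + dihed(w, u, v) - pi
}

#' Solid-angle curvature of atoms in an alpha complex
#'
#' For every complex tetrahedron incident to an atom, the solid angle
#' subtended at the atom is the sum of the three dihedral angles along its
#' edges minus pi. The total subtended angle `S` over all incident
#' tetrahedra (0 for a fully exposed atom, `2*pi` on a flat surface, `4*pi`
#' for a fully interior atom) is rescaled to `Omega = cos(S / 4)`, so
#' `Omega` is +1 when exposed, 0 when flat, and -1 when buried; positive
#' values are convex, negative concave. Atoms whose `|Omega|` falls below
#' `flat_tol` are snapped to exactly 0: at that scale the sign only reflects
#' coordinate noise, and the matching indicator treats flat atoms as
#' unmatched by its strict inequality.
#'
#' @param complex an `alpha_complex`.
#' @param serials atom serials to evaluate; default all points.
#' @param flat_tol flatness tolerance on the Omega scale (default 0.02,
#'   i.e. total angles within ~0.08 rad of `2*pi` count as flat).
#' @return named numeric vector, one Omega in `[-1, 1]` per serial.
#' @export
solid_angle_map <- function(complex, serials = NULL, flat_tol = 0.02) {
  if (!inherits(complex, "alpha_complex")) stop("expected an alpha_complex")
  pts <- complex$coords_used
  n <- nrow(pts)
  ids <- if (!is.null(complex$points$serial)) complex$points$serial
         else seq_len(n)
  tot <- numeric(n)
  seen <- logical(n)
  tt <- complex$tetrahedra
  if (nrow(tt)) {
    for (j in 1:4) {
      rest <- setdiff(1:4, j)
      sa <- tet_solid_angles(pts[tt[, j], , drop = FALSE],
                             pts[tt[, rest[1]], , drop = FALSE],
                             pts[tt[, rest[2]], , drop = FALSE],
                             pts[tt[, rest[3]], , drop = FALSE])
      acc <- rowsum(sa, tt[, j])
      at <- as.integer(rownames(acc))
      tot[at] <- tot[at] + acc[, 1]
      seen[at] <- TRUE
    }
  }
  omega <- rep(1, n)             # incident to nothing: fully exposed
  omega[seen] <- cos(tot[seen] / 4)
  omega[abs(omega) < flat_tol] <- 0
  omega <- pmin(1, pmax(-1, omega))
  if (is.null(serials)) return(setNames(omega, ids))
  miss <- setdiff(serials, ids)
  if (length(miss))
    stop("unknown vertex serial(s): ", paste(miss, collapse = ", "))
  setNames(omega[match(serials, ids)], serials)
}

#' Solid angle of a single atom
#'
#' @param vertex atom serial.
#' @inheritParams solid_angle_map
#' @return Omega in `[-1, 1]`.
#' @export
solid_angle <- function(vertex, complex, flat_tol = 0.02) {
  unname(solid_angle_map(complex, serials = vertex, flat_tol = flat_tol))
}

#' Convex-concave match indicator of a pair
#'
#' Returns 1 when the two solid angles have strictly opposite signs (a
#' convex atom facing a concave one), otherwise 0 -- including when either
#' value is exactly 0.
#'
#' @param omega_a,omega_b solid angles in `[-1, 1]` (vectorized).
#' @return integer 0/1 vector.
#' @export
match_indicator <- function(omega_a, omega_b) {
  if (any(abs(omega_a) > 1 + 1e-12) || any(abs(omega_b) > 1 + 1e-12))
    stop("solid angles must lie in [-1, 1]")
  as.integer(omega_a * omega_b < 0)
}

#' Matching rate of cross-chain interfacial pairs
#'
#' The fraction of pairs whose endpoints are convex-concave complementary:
#' `sum(f) / N` over the `N` pairs.
#'
#' @param pairs two-column serial matrix from [cross_chain_pairs()].
#' @param omegas named Omega vector covering every pair endpoint (e.g. the
#'   concatenated [solid_angle_map()]s of the two monomer complexes).
#' @return fraction in `[0, 1]`, or `NA` when there are no pairs (an
#'   undefined rate is flagged, never reported as 0).
#' @export
matching_rate <- function(pairs, omegas) {
  if (is.null(pairs) || nrow(pairs) == 0) return(NA_real_)
  key_a <- as.character(pairs[, 1]); key_b <- as.character(pairs[, 2])
  miss <- setdiff(c(key_a, key_b), names(omegas))
  if (length(miss))
    stop("pair endpoints without a solid angle: ", paste(miss, collapse = ", "))
  mean(match_indicator(omegas[key_a], omegas[key_b]))
}

#' Center of mass of a particle set
#'
#' Mass-weighted mean position, per axis.
#'
#' @param masses positive masses (Da).
#' @param positions matrix with one row per particle (3 columns), or a
#'   3-vector for a single particle.
#' @return 3-vector.
#' @export
com_of_particles <- function(masses, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  if (length(masses) != nrow(positions))
    stop("one mass per particle required")
  total <- sum(masses)
  if (!is.finite(total) || total <= 0) stop("total mass must be positive")
  colSums(positions * masses) / total
}

#' Mean center-of-mass distance over interfacial pairs
#'
#' For each cross-chain pair the Euclidean distance between the two atoms'
#' centers of mass (a single atom's center of mass is its own position),
#' averaged over pairs.
#'
#' @param pairs two-column serial matrix.
#' @param frame the `structure_frame` providing coordinates.
#' @return mean distance in angstrom, or `NA` for an empty pair set.
#' @export
mean_interface_com_distance <- function(pairs, frame) {
  if (is.null(pairs) || nrow(pairs) == 0) return(NA_real_)
  at <- frame$atoms
  ia <- match(pairs[, 1], at$serial)
  ib <- match(pairs[, 2], at$serial)
  if (anyNA(ia) || anyNA(ib)) stop("pair serial not present in frame")
  pa <- as.matrix(at[ia, c("x", "y", "z")])
  pb <- as.matrix(at[ib, c("x", "y", "z")])
  mean(sqrt(rowSums((pa - pb)^2)))
}

#' RMSD of a frame against a reference frame
#'
#' Root-mean-square deviation over the (heavy) atoms, optionally after
#' optimal least-squares rigid-body superposition.
#'
#' @param frame,reference `structure_frame`s with identical atom count and
#'   ordering.
#' @param fit `"superpose"` (default) removes the rigid-body motion first;
#'   `"none"` compares coordinates as given.
#' @return RMSD in angstrom.
#' @export
rmsd_to_reference <- function(frame, reference, fit = c("superpose", "none")) {
  fit <- match.arg(fit)
  a <- frame$atoms; b <- reference$atoms
  if (nrow(a) != nrow(b) || any(a$serial != b$serial))
    stop("atom mismatch between frame and reference")
  xa <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  xb <- as.vector(t(as.matrix(b[, c("x", "y", "z")])))
  as.numeric(bio3d::rmsd(xb, xa, fit = (fit == "superpose")))
}

#' Centered moving average with edge-shrunk windows
#'
#' The window is truncated at the series edges (so the first smoothed value
#' of `(1,2,3,4,5)` with `window = 3` is `mean(1,2) = 1.5`), and undefined
#' (`NA`) entries are excluded from every window. An entry that is itself
#' undefined stays undefined.
#'
#' @param series numeric vector, possibly with `NA` for undefined frames.
#' @param window odd positive integer width.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(series, window) {
  if (length(window) != 1 || is.na(window) || window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer")
  n <- length(series)
  h <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(series[i])) next
    win <- series[max(1, i - h):min(n, i + h)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  out
}

# full single-frame pipeline: complexes, interface, pairs, solid angles,
# matching rate and mean COM distance. Solid angles are evaluated on each
# monomer's own complex: complementarity compares the shapes the two
# monomer surfaces present to each other.
analyze_dimer_frame <- function(frame, chain_a, chain_b, alpha = 0,
                                radius_table = vdw_radii(), flat_tol = 0.02,
                                jitter = 1e-3, jitter_seed = 1L) {
  wp <- assign_weights(frame, radius_table)
  wa <- wp[wp$chain == chain_a, , drop = FALSE]
  wb <- wp[wp$chain == chain_b, , drop = FALSE]
  res <- interface_atoms(frame, chain_a, chain_b, alpha, radius_table,
                         jitter, jitter_seed)
  wd <- wp[wp$chain %in% c(chain_a, chain_b), , drop = FALSE]
  cx_dimer <- build_alpha_complex(wd, alpha, jitter, jitter_seed)
  cx_a <- build_alpha_complex(wa, alpha, jitter, jitter_seed)
  cx_b <- build_alpha_complex(wb, alpha, jitter, jitter_seed)
  res <- cross_chain_pairs(cx_dimer, res)
  omegas <- c(solid_angle_map(cx_a, flat_tol = flat_tol),
              solid_angle_map(cx_b, flat_tol = flat_tol))
  list(result = res,
       complex_dimer = cx_dimer, complex_a = cx_a, complex_b = cx_b,
       omegas = omegas,
       matching_rate = matching_rate(res$pairs, omegas),
       mean_com_distance = mean_interface_com_distance(res$pairs, frame))
}

#' Per-frame interface descriptors of a trajectory
#'
#' Runs the alpha complex, interface extraction, pair enumeration, matching
#' rate and mean center-of-mass distance for every frame, and attaches
#' moving-average-smoothed series and per-series means (the dashed lines of
#' a trajectory plot). Frames with no pairs are reported as `NA` (undefined,
#' never zero). Frames that fail are flagged with `NA` and a warning; the
#' run aborts only if every frame fails.
#'
#' @param frames list of `structure_frame`s with identical atom ordering.
#' @param chain_a,chain_b chain labels.
#' @param alpha alpha value (default 0).
#' @param window odd moving-average window in frames (default 51).
#' @param radius_table named radius vector.
#' @param rmsd compute RMSD against the first frame? Default `TRUE`.
#' @param rmsd_fit `"superpose"` or `"none"`.
#' @param flat_tol flatness tolerance for [solid_angle_map()].
#' @param jitter,jitter_seed tie-break jitter for the triangulations.
#' @return data frame of class `descriptor_series` with columns `frame`,
#'   `n_interface_atoms`, `n_pairs`, `matching_rate`,
#'   `matching_rate_smoothed`, `mean_com_distance`,
#'   `mean_com_distance_smoothed`, `rmsd`, and a `series_mean` attribute.
#' @export
trajectory_descriptors <- function(frames, chain_a, chain_b, alpha = 0,
                                   window = 51, radius_table = vdw_radii(),
                                   rmsd = TRUE,
                                   rmsd_fit = c("superpose", "none"),
                                   flat_tol = 0.02, jitter = 1e-3,
                                   jitter_seed = 1L) {
  rmsd_fit <- match.arg(rmsd_fit)
  if (length(frames) < 1) stop("need at least one frame")
  if (window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer")
  nf <- length(frames)
  n_int <- n_pairs <- rep(NA_integer_, nf)
  rate <- comd <- rms <- rep(NA_real_, nf)
  failed <- logical(nf)
  for (i in seq_len(nf)) {
    an <- tryCatch(
      analyze_dimer_frame(frames[[i]], chain_a, chain_b, alpha, radius_table,
                          flat_tol, jitter, jitter_seed),
      error = function(e) e)
    if (inherits(an, "error")) {
      warning(sprintf("frame %d failed: %s", i - 1L, conditionMessage(an)))
      failed[i] <- TRUE
      next
    }
    n_int[i] <- length(an$result$X)
    n_pairs[i] <- nrow(an$result$pairs)
    rate[i] <- an$matching_rate
    comd[i] <- an$mean_com_distance
    if (rmsd)
      rms[i] <- rmsd_to_reference(frames[[i]], frames[[1]], fit = rmsd_fit)
  }
  if (all(failed)) stop("all frames failed")
  out <- data.frame(frame = vapply(frames, function(f) f$frame_index, 0L),
                    n_interface_atoms = n_int, n_pairs = n_pairs,
                    matching_rate = rate,
                    matching_rate_smoothed = moving_average(rate, window),
                    mean_com_distance = comd,
                    mean_com_distance_smoothed = moving_average(comd, window),
                    rmsd = rms)
  attr(out, "series_mean") <- list(
    matching_rate = mean(rate, na.rm = TRUE),
    mean_com_distance = mean(comd, na.rm = TRUE),
    rmsd = if (rmsd) mean(rms, na.rm = TRUE) else NA_real_)
  attr(out, "window") <- window
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("<descriptor_series>: %d frames (window = %d)\n", nrow(x),
              attr(x, "window")))
  sm <- attr(x, "series_mean")
  cat(sprintf("  mean matching rate: %s\n  mean COM distance:  %s\n",
              format(sm$matching_rate), format(sm$mean_com_distance)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a descriptor series as CSV
#'
#' Fixed column order, suitable for diffing across runs.
#'
#' @param series a `descriptor_series`.
#' @param path output path.
#' @export
write_descriptor_csv <- function(series, path) {
  cols <- c("frame", "n_interface_atoms", "n_pairs", "matching_rate",
            "matching_rate_smoothed", "mean_com_distance",
            "mean_com_distance_smoothed", "rmsd")
  df <- as.data.frame(series)[, cols]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con, sep = "\n")
  if (nrow(df)) {
    fmt <- function(v) {
      s <- vapply(v, function(x)
        if (is.na(x)) "NA" else format(x, digits = 12, scientific = FALSE,
                                       trim = TRUE), character(1))
      s
    }
    body <- do.call(paste, c(lapply(df, fmt), sep = ","))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Write a descriptor series summary as JSON
#'
#' Mirrors the CSV plus the per-series means.
#'
#' @param series a `descriptor_series`.
#' @param path output path.
#' @export
write_descriptor_json <- function(series, path) {
  payload <- list(series = as.data.frame(series),
                  series_mean = attr(series, "series_mean"),
                  window = attr(series, "window"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
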