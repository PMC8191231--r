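# Deterministic synthetic structures with known ground truth: lattice
# blocks (known surface set), slab dimers (known interfacial set),
# knob-hole dimers (designed convex/concave complementarity), and rigid
# separation trajectories (programmed gap schedule). Fixtures are plain
# carbon pseudo-atoms (one atom per "LIG" residue) so they exercise the
# real PDB I/O path.

#' Specification of a synthetic fixture
#'
#' @param kind one of `"lattice_block"`, `"slab_dimer"`, `"knob_hole_dimer"`,
#'   `"separation_trajectory"`.
#' @param dims integer lattice dimensions: 3 for a block (default `c(5,5,5)`),
#'   3 per slab for the dimers (default `c(5,5,2)`).
#' @param spacing lattice spacing in angstrom.
#' @param radius van der Waals radius annotated on every fixture atom and
#'   used in the construction-truth formulas. Fixture atoms are carbon, and
#'   analyses look radii up by element, so the default (1.7, the Bondi
#'   carbon radius) keeps fixture truth and analysis consistent; a
#'   non-default value requires passing a matching custom radius table to
#'   the analysis functions.
#' @param gap inter-slab gap in angstrom (slab dimer).
#' @param schedule strictly increasing gap schedule in angstrom
#'   (separation trajectory), length >= 3.
#' @param n_knobs number of knob/socket units (knob-hole dimer).
#' @param flatten build the flattened control variant of the knob-hole
#'   dimer (knobs removed, flat slab instead).
#' @param jitter coordinate jitter magnitude in angstrom (must stay below
#'   `spacing / 10`); makes fixtures generic without moving any atom far
#'   enough to change the designed combinatorics.
#' @param seed integer seed making the fixture fully deterministic.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("lattice_block", "slab_dimer",
                                    "knob_hole_dimer",
                                    "separation_trajectory"),
                           dims = NULL, spacing = 1.5, radius = 1.7,
                           gap = 2.0, schedule = seq(1.2, 2.4, by = 0.3),
                           n_knobs = 4, flatten = FALSE, jitter = 0.01,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(dims))
    dims <- if (kind == "lattice_block") c(5L, 5L, 5L) else c(5L, 5L, 2L)
  if (spacing <= 0) stop("spacing must be positive")
  if (radius <= 0) stop("radius must be positive")
  if (jitter < 0 || jitter >= spacing / 10)
    stop("jitter must lie in [0, spacing/10)")
  if (kind == "lattice_block" && any(dims < 2))
    stop("lattice dims must be >= 2 per axis")
  if (kind == "separation_trajectory") {
    if (length(schedule) < 3) stop("schedule needs at least 3 frames")
    if (any(diff(schedule) <= 0))
      stop("schedule must be strictly increasing")
  }
  if (kind == "slab_dimer" && gap <= 0) stop("gap must be positive")
  structure(list(kind = kind, dims = as.integer(dims), spacing = spacing,
                 radius = radius, gap = gap, schedule = schedule,
                 n_knobs = as.integer(n_knobs), flatten = isTRUE(flatten),
                 jitter = jitter, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# lattice coordinates dims[1] x dims[2] x dims[3], corner at origin
lattice_xyz <- function(dims, spacing, z0 = 0) {
  g <- expand.grid(x = seq(0, by = spacing, length.out = dims[1]),
                   y = seq(0, by = spacing, length.out = dims[2]),
                   z = seq(z0, by = spacing, length.out = dims[3]))
  as.matrix(g)
}

# deterministic uniform jitter from the spec seed, independent of the
# caller's RNG state
with_spec_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

jitter_xyz <- function(xyz, jitter, seed) {
  if (jitter <= 0) return(xyz)
  with_spec_rng(seed, xyz + matrix(stats::runif(length(xyz), -jitter, jitter),
                                   nrow(xyz)))
}

# assemble a structure_frame of carbon pseudo-atoms
fixture_frame <- function(xyz, chain, radius, frame_index = 0L) {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = "C", element = "C",
                      resname = "LIG", resno = seq_len(n),
                      chain = chain,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      mass = 12.011, radius = radius,
                      stringsAsFactors = FALSE)
  structure_frame(atoms, frame_index = frame_index)
}

#' Lattice block with known surface set
#'
#' `dims[1] x dims[2] x dims[3]` carbon-like atoms on a cubic lattice,
#' single chain A. The expected surface set (all boundary lattice sites) is
#' attached as `attr(frame, "truth")$expected_surface`.
#'
#' @param spec a [synthetic_spec()] of kind `"lattice_block"`.
#' @return a `structure_frame` with a `truth` attribute.
#' @export
make_lattice_block <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "lattice_block")
  xyz0 <- lattice_xyz(spec$dims, spec$spacing)
  xyz <- jitter_xyz(xyz0, spec$jitter, spec$seed)
  fr <- fixture_frame(xyz, "A", spec$radius)
  on_boundary <- function(col, m)
    xyz0[, col] < spec$spacing / 2 |
    xyz0[, col] > (m - 1) * spec$spacing - spec$spacing / 2
  surf <- which(on_boundary(1, spec$dims[1]) | on_boundary(2, spec$dims[2]) |
                on_boundary(3, spec$dims[3]))
  attr(fr, "truth") <- list(kind = spec$kind, dims = spec$dims,
                            expected_surface = as.integer(surf))
  fr
}

# slab-dimer core shared with the separation trajectory: chain A above
# chain B, facing layers separated by `gap`
slab_dimer_xyz <- function(spec, gap) {
  dz <- spec$dims[3]
  a0 <- lattice_xyz(spec$dims, spec$spacing, z0 = 0)
  b0 <- lattice_xyz(spec$dims, spec$spacing,
                    z0 = -(dz - 1) * spec$spacing - gap)
  list(a = a0, b = b0)
}

# construction truth of the slab interface: the facing layers' interior
# atoms (the perimeter of a facing layer lies on the dimer's lateral hull,
# stays on the dimer surface, and is therefore never interfacial). Valid in
# the contact regime: every gap-spanning lattice box must pass the alpha=0
# test, i.e. gap <= sqrt(4 r^2 - 2 s^2) (box half-diagonal <= radius), with
# a safety margin of half a jitter amplitude.
slab_truth <- function(spec, gap) {
  contact_max <- sqrt(max(4 * spec$radius^2 - 2 * spec$spacing^2, 0))
  pair_max <- 2 * spec$radius
  regime <- if (gap <= contact_max - 0.1) "contact"
            else if (gap > pair_max + 0.2) "separated" else "marginal"
  nA <- prod(spec$dims)
  expected <- integer(0)
  if (regime == "contact") {
    m1 <- spec$dims[1]; m2 <- spec$dims[2]
    interior <- function(i, m) i > 1 & i < m
    g <- expand.grid(i = seq_len(m1), j = seq_len(m2))
    int_idx <- which(interior(g$i, m1) & interior(g$j, m2))
    # chain A facing layer is its first z-layer (rows 1..m1*m2),
    # chain B facing layer is its last z-layer
    a_face <- int_idx
    b_face <- (spec$dims[3] - 1) * m1 * m2 + int_idx + nA
    expected <- sort(c(a_face, b_face))
  }
  list(kind = "slab_dimer", gap = gap, regime = regime,
       contact_gap_max = contact_max,
       expected_interface = as.integer(expected))
}

#' Slab dimer with known interfacial set
#'
#' Two lattice slabs face to face at the given gap: chain A above, chain B
#' below. In the contact regime the interfacial set is exactly the interior
#' of the two facing layers, stored in `attr(frame, "truth")`; far-separated
#' slabs have an empty interface.
#'
#' @param spec a [synthetic_spec()] of kind `"slab_dimer"`.
#' @return a `structure_frame` (chains A and B) with a `truth` attribute.
#' @export
make_slab_dimer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "slab_dimer")
  xy <- slab_dimer_xyz(spec, spec$gap)
  nA <- nrow(xy$a)
  xyz <- jitter_xyz(rbind(xy$a, xy$b), spec$jitter, spec$seed)
  fr <- fixture_frame(xyz, rep(c("A", "B"), times = c(nA, nrow(xy$b))),
                      spec$radius)
  attr(fr, "truth") <- slab_truth(spec, spec$gap)
  fr
}

# octahedral knob: a center and its six axial lattice neighbours
oct_sites <- function(spacing)
  rbind(c(0, 0, 0), c(spacing, 0, 0), c(-spacing, 0, 0), c(0, spacing, 0),
        c(0, -spacing, 0), c(0, 0, spacing), c(0, 0, -spacing))

#' Knob-hole dimer with designed convex/concave complementarity
#'
#' Chain A carries `n_knobs` octahedral knobs whose atoms register exactly
#' into matching vacancies ("sockets") carved out of the chain-B lattice
#' block, knob centers in the block's top face. The buried knob atoms are
#' locally convex (positive solid angle) and the socket-wall atoms they pair
#' with are locally concave, so every cross-chain interfacial pair is
#' complementary and the designed matching rate is 1. The flattened control
#' (`flatten = TRUE` in the spec) replaces the knobs by a flat slab at
#' contact distance over the un-carved block; its facing surfaces are flat,
#' giving a designed matching rate of (essentially) 0.
#'
#' @param spec a [synthetic_spec()] of kind `"knob_hole_dimer"`.
#' @return a `structure_frame` (chains A and B) with a `truth` attribute.
#' @export
make_knob_hole_dimer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "knob_hole_dimer")
  s <- spec$spacing
  pitch <- 5 * s           # knob-to-knob pitch: sockets never touch
  centers <- cbind(x = (seq_len(spec$n_knobs) - 1) * pitch, y = 0)
  half <- 3 * s
  xs <- seq(min(centers[, 1]) - half, max(centers[, 1]) + half, by = s)
  ys <- seq(-half, half, by = s)
  zs <- seq(-4 * s, 0, by = s)
  base <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  if (!spec$flatten) {
    drop <- rep(FALSE, nrow(base))
    a_xyz <- NULL
    for (k in seq_len(spec$n_knobs)) {
      sites <- sweep(oct_sites(s), 2, c(centers[k, 1], centers[k, 2], 0), "+")
      for (i in seq_len(nrow(sites)))
        drop <- drop | (abs(base[, 1] - sites[i, 1]) < s / 10 &
                        abs(base[, 2] - sites[i, 2]) < s / 10 &
                        abs(base[, 3] - sites[i, 3]) < s / 10)
      a_xyz <- rbind(a_xyz, sites)
    }
    b_xyz <- base[!drop, , drop = FALSE]
    designed_rate <- 1
  } else {
    b_xyz <- base
    a_xyz <- as.matrix(expand.grid(x = xs, y = ys,
                                   z = c(spec$gap, spec$gap + s)))
    designed_rate <- 0
  }
  nA <- nrow(a_xyz)
  xyz <- jitter_xyz(rbind(a_xyz, b_xyz), spec$jitter, spec$seed)
  fr <- fixture_frame(xyz, rep(c("A", "B"), times = c(nA, nrow(b_xyz))),
                      spec$radius)
  attr(fr, "truth") <- list(kind = spec$kind, n_knobs = spec$n_knobs,
                            flatten = spec$flatten,
                            designed_matching_rate = designed_rate)
  fr
}

#' Rigid-body separation trajectory of a slab dimer
#'
#' The slab dimer translated apart rigidly along z, one frame per entry of
#' the gap schedule. The same jittered monomer coordinates are reused in
#' every frame, so within-chain geometry is frame-invariant and the mean
#' interfacial center-of-mass distance increases with the programmed gap
#' for as long as pairs exist.
#'
#' @param spec a [synthetic_spec()] of kind `"separation_trajectory"`.
#' @return list of `structure_frame`s with a `truth` attribute on the list.
#' @export
make_separation_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            spec$kind == "separation_trajectory")
  xy <- slab_dimer_xyz(spec, gap = 0)     # chain B top layer at z = 0 - gap
  nA <- nrow(xy$a)
  xyz0 <- jitter_xyz(rbind(xy$a, xy$b), spec$jitter, spec$seed)
  frames <- lapply(seq_along(spec$schedule), function(i) {
    g <- spec$schedule[i]
    xyz <- xyz0
    xyz[seq_len(nA), 3] <- xyz[seq_len(nA), 3] + g
    fr <- fixture_frame(xyz, rep(c("A", "B"), times = c(nA, nrow(xy$b))),
                        spec$radius, frame_index = i - 1L)
    fr
  })
  attr(frames, "truth") <- list(kind = spec$kind, schedule = spec$schedule,
                                per_frame = lapply(spec$schedule, function(g)
                                  slab_truth(spec, g)))
  frames
}

#' Materialize a synthetic fixture on disk
#'
#' Writes the fixture as a (multi-model) PDB file plus a JSON file with the
#' ground-truth annotations, both deterministic for a given spec.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param name base file name; defaults to the fixture kind.
#' @return named list with the written `pdb` and `truth` paths.
#' @export
write_fixture <- function(spec, dir, name = spec$kind) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- switch(spec$kind,
                lattice_block = make_lattice_block(spec),
                slab_dimer = make_slab_dimer(spec),
                knob_hole_dimer = make_knob_hole_dimer(spec),
                separation_trajectory = make_separation_trajectory(spec))
  frames <- if (inherits(obj, "structure_frame")) list(obj) else obj
  truth <- attr(if (inherits(obj, "structure_frame")) obj else obj, "truth")
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  write_structure(frames, pdb_path)
  jsonlite::write_json(c(list(spec = unclass(spec)), truth), truth_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(pdb = pdb_path, truth = truth_path)
}
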