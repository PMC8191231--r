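# Weighted alpha-shape machinery: reference predicates, the regular
# (weighted Delaunay) triangulation, the alpha filtration, and surface-atom
# classification.

#' 2-D in-circumcircle reference predicate
#'
#' Classifies point `D` against the circumcircle of triangle `ABC` by the
#' sign of the classical 4x4 lifting determinant (the predicate underlying
#' Delaunay triangulation). The triangle orientation is normalized
#' internally, so `A`, `B`, `C` may be given in either order.
#'
#' @param A,B,C,D numeric 2-vectors.
#' @param tol relative tolerance below which `D` is reported on the circle.
#' @return one of `"inside"`, `"on"`, `"outside"`.
#' @examples
#' in_circumcircle_2d(c(1, 0), c(0, 1), c(-1, 0), c(0, 0))   # "inside"
#' in_circumcircle_2d(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))  # "on"
#' @export
in_circumcircle_2d <- function(A, B, C, D, tol = 1e-9) {
  stopifnot(length(A) == 2, length(B) == 2, length(C) == 2, length(D) == 2)
  orient <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
  scale2 <- max(sum((B - A)^2), sum((C - A)^2), sum((C - B)^2), 1e-300)
  if (abs(orient) <= tol * scale2)
    stop("degenerate triangle: A, B, C are collinear")
  M <- rbind(c(A - D, sum(A^2) - sum(D^2)),
             c(B - D, sum(B^2) - sum(D^2)),
             c(C - D, sum(C^2) - sum(D^2)))
  d <- det(M) * sign(orient)
  if (abs(d) <= tol * scale2^2) "on" else if (d > 0) "inside" else "outside"
}

#' Orthogonality class of two weighted points
#'
#' Under the power-distance convention two weighted points (spheres with
#' squared radii as weights) are orthogonal when the squared distance of
#' their centers equals the sum of their weights, sub-orthogonal when it
#' exceeds it (further apart), and super-orthogonal when it is smaller. The
#' `"linear"` convention compares the unsquared distance against the weight
#' sum instead and is provided for auditing only.
#'
#' @param p1,p2 weighted points: lists with `location` (3-vector) and
#'   `weight` (scalar), or rows of a [assign_weights()] table.
#' @param convention `"power"` (default) or `"linear"`.
#' @param tol relative tolerance for equality.
#' @return one of `"orthogonal"`, `"sub_orthogonal"`, `"super_orthogonal"`.
#' @examples
#' p1 <- list(location = c(0, 0, 0), weight = 1)
#' p2 <- list(location = c(sqrt(2), 0, 0), weight = 1)
#' orthogonality_class(p1, p2)  # "orthogonal": d^2 = 2 = 1 + 1
#' @export
orthogonality_class <- function(p1, p2, convention = c("power", "linear"),
                                tol = 1e-9) {
  convention <- match.arg(convention)
  as_wp <- function(p) {
    if (is.list(p) && !is.null(p$location)) list(loc = p$location, w = p$weight)
    else if (is.data.frame(p)) list(loc = c(p$x, p$y, p$z), w = p$weight)
    else stop("weighted point must have 'location' and 'weight'")
  }
  a <- as_wp(p1); b <- as_wp(p2)
  if (a$w < 0 || b$w < 0) stop("weights must be non-negative")
  d2 <- sum((a$loc - b$loc)^2)
  lhs <- if (convention == "power") d2 else sqrt(d2)
  rhs <- a$w + b$w
  scale <- max(abs(lhs), abs(rhs), 1e-300)
  if (abs(lhs - rhs) <= tol * scale) "orthogonal"
  else if (lhs > rhs) "sub_orthogonal"
  else "super_orthogonal"
}

#' Build the regular (weighted Delaunay) triangulation of a weighted point set
#'
#' Incremental construction with power-distance conflict regions, evaluated
#' through translated in-orthosphere determinants. Exact degeneracies
#' (cospherical lattices, coplanar faces) are broken by a deterministic
#' jitter of magnitude `jitter` applied once to a copy of the coordinates;
#' the jittered coordinates actually triangulated are retained in the result
#' so that independent verification sees the same point set. Points fully
#' dominated under the weighting (redundant) appear in no tetrahedron and
#' are listed in `$redundant`.
#'
#' @param points a `weighted_points` table from [assign_weights()], or any
#'   data frame with columns `x`, `y`, `z`, `weight` (and optionally
#'   `serial`, `chain`).
#' @param jitter deterministic tie-break jitter magnitude in angstrom.
#' @param jitter_seed integer seed of the jitter stream.
#' @return object of class `regular_triangulation` with elements
#'   `tetrahedra` (m x 4 row indices), `orthocenter`, `ortho_r2` (signed
#'   squared orthoradii), `redundant`, `coords_used`, `points`.
#' @export
build_regular_triangulation <- function(points, jitter = 1e-3,
                                        jitter_seed = 1L) {
  pts <- as.data.frame(points)
  if (!all(c("x", "y", "z", "weight") %in% names(pts)))
    stop("points must have columns x, y, z, weight")
  if (nrow(pts) < 4)
    stop("dimension error: need at least 4 points for a 3-D triangulation")
  if (any(pts$weight < 0)) stop("weights must be non-negative")
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  # coplanarity is checked on the raw input: jitter is a tie-break, not a
  # way to conjure volume out of a flat point set
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))$d
  if (sv[3] <= 1e-9 * max(sv[1], 1))
    stop("dimension error: points are (nearly) coplanar")
  out <- .rt_build_cpp(xyz, pts$weight, jitter, as.integer(jitter_seed))
  structure(list(points = pts,
                 tetrahedra = out$tetrahedra,
                 orthocenter = out$orthocenter,
                 ortho_r2 = as.numeric(out$ortho_r2),
                 redundant = as.integer(out$redundant),
                 coords_used = out$coords_used,
                 jitter = jitter, jitter_seed = as.integer(jitter_seed)),
            class = "regular_triangulation")
}

#' @export
print.regular_triangulation <- function(x, ...) {
  cat(sprintf("<regular_triangulation>: %d points, %d tetrahedra, %d redundant\n",
              nrow(x$points), nrow(x$tetrahedra), length(x$redundant)))
  invisible(x)
}

# sorted facet table of a tetrahedron matrix (one row per facet, 4 per tet)
tet_facets <- function(tets) {
  if (nrow(tets) == 0) return(matrix(integer(), 0, 3))
  f <- rbind(tets[, c(1, 2, 3), drop = FALSE], tets[, c(1, 2, 4), drop = FALSE],
             tets[, c(1, 3, 4), drop = FALSE], tets[, c(2, 3, 4), drop = FALSE])
  t(apply(f, 1, sort))
}

#' Filter a regular triangulation to the weighted alpha complex
#'
#' A tetrahedron belongs to the alpha complex when the signed squared radius
#' of its orthosphere is at most `alpha`. With `alpha = 0` and weights equal
#' to squared van der Waals radii this keeps exactly the tetrahedra of
#' mutually overlapping or touching atom spheres, which is the molecular
#' shape model used throughout this package. The filtration is monotone in
#' `alpha`.
#'
#' @param triangulation a `regular_triangulation`.
#' @param alpha filtration value (squared-angstrom scale); default 0.
#' @return object of class `alpha_complex` with elements `tetrahedra`,
#'   `ortho_r2`, `boundary_facets` (facets of exactly one complex
#'   tetrahedron), `edges`, `points`, `alpha`.
#' @export
alpha_complex <- function(triangulation, alpha = 0) {
  if (!inherits(triangulation, "regular_triangulation"))
    stop("first argument must be a regular_triangulation")
  keep <- triangulation$ortho_r2 <= alpha
  tets <- triangulation$tetrahedra[keep, , drop = FALSE]
  fac <- tet_facets(tets)
  bnd <- matrix(integer(), 0, 3)
  edges <- matrix(integer(), 0, 2)
  if (nrow(fac)) {
    key <- paste(fac[, 1], fac[, 2], fac[, 3])
    bnd <- fac[key %in% names(which(table(key) == 1)), , drop = FALSE]
    e <- rbind(tets[, c(1, 2), drop = FALSE], tets[, c(1, 3), drop = FALSE],
               tets[, c(1, 4), drop = FALSE], tets[, c(2, 3), drop = FALSE],
               tets[, c(2, 4), drop = FALSE], tets[, c(3, 4), drop = FALSE])
    e <- t(apply(e, 1, sort))
    edges <- unique(e)
  }
  structure(list(points = triangulation$points,
                 coords_used = triangulation$coords_used,
                 tetrahedra = tets,
                 ortho_r2 = triangulation$ortho_r2[keep],
                 boundary_facets = bnd,
                 edges = edges,
                 redundant = triangulation$redundant,
                 alpha = alpha),
            class = "alpha_complex")
}

#' @export
print.alpha_complex <- function(x, ...) {
  cat(sprintf("<alpha_complex alpha=%g>: %d points, %d tetrahedra, %d boundary facets\n",
              x$alpha, nrow(x$points), nrow(x$tetrahedra), nrow(x$boundary_facets)))
  invisible(x)
}

#' Surface atoms of an alpha complex
#'
#' Surface atoms are the vertices incident to a boundary facet of the
#' complex, together with vertices that belong to no complex tetrahedron at
#' all (singular atoms, including weighted-redundant points). Interior atoms
#' -- those whose entire triangulated neighborhood lies inside the complex --
#' are excluded.
#'
#' @param complex an `alpha_complex`.
#' @return integer vector of atom serials (the `serial` column of the
#'   weighted points; row indices if no serial column was present).
#' @export
surface_atoms <- function(complex) {
  if (!inherits(complex, "alpha_complex")) stop("expected an alpha_complex")
  n <- nrow(complex$points)
  if (n == 0) stop("empty complex: no points")
  on_bnd <- unique(as.vector(complex$boundary_facets))
  in_tet <- unique(as.vector(complex$tetrahedra))
  idx <- sort(union(on_bnd, setdiff(seq_len(n), in_tet)))
  if (!is.null(complex$points$serial)) complex$points$serial[idx] else idx
}

# convenience: weighted points -> alpha complex in one call
build_alpha_complex <- function(points, alpha = 0, jitter = 1e-3,
                                jitter_seed = 1L) {
  alpha_complex(build_regular_triangulation(points, jitter = jitter,
                                            jitter_seed = jitter_seed),
                alpha = alpha)
}
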