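#' Van der Waals radius table
#'
#' Returns a named vector of van der Waals radii in angstroms, keyed by
#' upper-case element symbol. The packaged default is the Bondi (1964)
#' compilation, extended with common metals found in protein structures.
#' Atom weights for the weighted alpha complex are the squares of these
#' radii.
#'
#' @param set name of a packaged table; currently `"bondi"`.
#' @param file path to a custom two-column CSV (`element,radius`) overriding
#'   the packaged table.
#' @return named numeric vector of radii (angstrom).
#' @examples
#' vdw_radii()[["C"]]  # 1.70
#' @export
vdw_radii <- function(set = "bondi", file = NULL) {
  if (is.null(file)) {
    set <- match.arg(set, "bondi")
    file <- system.file("extdata", paste0("vdw_radii_", set, ".csv"),
                        package = "alphadimer", mustWork = TRUE)
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(tab)))
    stop("radius table must have columns 'element' and 'radius'")
  if (any(!is.finite(tab$radius)) || any(tab$radius <= 0))
    stop("radius table contains non-positive or missing radii")
  setNames(tab$radius, toupper(tab$element))
}

#' Standard atomic masses
#'
#' Named vector of standard atomic weights (Da) keyed by upper-case element
#' symbol, used for center-of-mass computations.
#'
#' @param file optional custom two-column CSV (`element,mass`).
#' @return named numeric vector of masses (Da).
#' @export
atomic_masses <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "atomic_masses.csv",
                        package = "alphadimer", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("element", "mass") %in% names(tab)))
    stop("mass table must have columns 'element' and 'mass'")
  setNames(tab$mass, toupper(tab$element))
}
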