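# Multi-model PDB reading/writing and weighted point assignment. Parsing is
# delegated to bio3d; this layer enforces the conventions the downstream
# geometry relies on: heavy atoms only (by default), first altloc conformer,
# serials and residue numbers renumbered from 1 per frame, and identical atom
# ordering across frames.

#' Construct a structure frame
#'
#' A structure frame is one set of atoms (one model of a PDB file, or one
#' trajectory snapshot) with per-atom metadata. Most users obtain frames from
#' [read_structure()] or the synthetic generators rather than building them
#' directly.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`, `mass`, `radius`.
#' @param frame_index non-negative integer index of the frame.
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, frame_index = 0L) {
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z", "mass", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a frame")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$mass <= 0)) stop("non-positive atomic mass")
  if (any(atoms$radius <= 0)) stop("non-positive van der Waals radius")
  structure(list(frame_index = as.integer(frame_index),
                 atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  ch <- chain_labels(x)
  cat(sprintf("<structure_frame %d>: %d atoms, chains %s\n",
              x$frame_index, nrow(x$atoms), paste(ch, collapse = ", ")))
  invisible(x)
}

#' Chain labels present in a frame
#' @param frame a `structure_frame`.
#' @return character vector of chain identifiers.
#' @export
chain_labels <- function(frame) sort(unique(frame$atoms$chain))

# element symbol from a PDB atom name when the element column is absent;
# digits and primes stripped, two-letter elements recognized by prefix
derive_element <- function(name) {
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA", "SE", "CU",
           "NI", "CO", "SI")
  vapply(name, function(nm) {
    s <- toupper(gsub("[0-9' ]", "", nm))
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% two) return(substr(s, 1, 2))
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# basic well-formedness scan so a broken ATOM record is reported with its
# line number instead of surfacing as a cryptic downstream failure
validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM record at line %d: fewer than 54 columns", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed ATOM record at line %d: unparseable coordinates", i))
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB structure as trajectory frames
#'
#' MODEL/ENDMDL blocks are returned as successive frames; a file without
#' MODEL records yields a single frame. Hydrogens are dropped by default
#' (the geometric model is built from heavy atoms), alternate locations are
#' resolved to the first-listed conformer, water/ion HETATM records are
#' excluded by default, and atoms and residues are renumbered sequentially
#' from 1 within each frame.
#'
#' @param path path to a PDB file.
#' @param hydrogen_policy `"drop"` (default) or `"keep"`.
#' @param keep_hetatm keep non-water HETATM records? Default `FALSE`.
#' @param radii named radius vector from [vdw_radii()] used to annotate atoms.
#' @param masses named mass vector from [atomic_masses()].
#' @return list of `structure_frame` objects, in file order.
#' @export
read_structure <- function(path, hydrogen_policy = c("drop", "keep"),
                           keep_hetatm = FALSE, radii = vdw_radii(),
                           masses = atomic_masses()) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nframes <- nrow(pdb$xyz)

  el <- at$elesy
  bad <- is.na(el) | el == ""
  if (any(bad)) el[bad] <- derive_element(at$elety[bad])
  el <- toupper(trimws(el))

  keep <- rep(TRUE, nrow(at))
  if (!keep_hetatm)
    keep <- keep & (at$type == "ATOM" | !(at$resid %in%
             c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN", "SO4",
               "PO4")))
  if (hydrogen_policy == "drop") keep <- keep & !(el %in% c("H", "D"))
  # altloc: first-listed conformer per (chain, resno, insert, atom name)
  altkey <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- keep & !duplicated(altkey)
  if (!any(keep)) stop("empty structure: no atoms left after filtering")

  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  unknown <- setdiff(unique(el), names(masses))
  if (length(unknown))
    stop("element(s) not in mass table: ", paste(unknown, collapse = ", "))
  unknown_r <- setdiff(unique(el), names(radii))
  if (length(unknown_r))
    stop("element(s) not in radius table: ", paste(unknown_r, collapse = ", "))

  # renumber residues from 1 in order of first appearance (insertion codes
  # folded into the sequence), atoms from 1
  reskey <- paste(at$chain, at$resno, at$insert)
  resno_new <- as.integer(factor(reskey, levels = unique(reskey)))
  idx3 <- rep((which(keep) - 1L) * 3L, each = 3L) + seq_len(3L)

  lapply(seq_len(nframes), function(f) {
    xyz <- matrix(pdb$xyz[f, idx3], ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      serial = seq_len(nrow(at)),
      name = trimws(at$elety),
      element = el,
      resname = trimws(at$resid),
      resno = resno_new,
      chain = as.character(at$chain),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      mass = unname(masses[el]),
      radius = unname(radii[el]),
      original_serial = at$eleno,
      stringsAsFactors = FALSE)
    structure_frame(atoms, frame_index = f - 1L)
  })
}

#' Write frames to a (multi-model) PDB file
#'
#' One frame writes a plain PDB; several frames write MODEL/ENDMDL blocks.
#' All frames must share the same atom table (trajectory convention).
#'
#' @param frames a `structure_frame` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  a0 <- frames[[1]]$atoms
  for (f in frames)
    if (nrow(f$atoms) != nrow(a0) || any(f$atoms$serial != a0$serial))
      stop("all frames must share the same atom table")
  xyz <- do.call(rbind, lapply(frames, function(f)
    as.vector(t(as.matrix(f$atoms[, c("x", "y", "z")])))))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a0)),
                   eleno = a0$serial, elety = a0$name, resid = a0$resname,
                   chain = a0$chain, resno = a0$resno, elesy = a0$element)
  invisible(path)
}

#' Assign alpha-shape weights to a frame's atoms
#'
#' Every atom becomes a weighted point whose weight is the square of its van
#' der Waals radius (looked up by element in `radius_table`), the convention
#' under which two atoms are orthogonal exactly when their spheres intersect
#' orthogonally. The chain partition is preserved in the `chain` column.
#'
#' @param frame a `structure_frame`.
#' @param radius_table named radius vector, see [vdw_radii()].
#' @return data frame of class `weighted_points` with columns `serial`,
#'   `chain`, `x`, `y`, `z`, `weight`.
#' @examples
#' \dontrun{assign_weights(frame)$weight[1]  # 1.70^2 = 2.89 for carbon}
#' @export
assign_weights <- function(frame, radius_table = vdw_radii()) {
  at <- frame$atoms
  unknown <- setdiff(unique(at$element), names(radius_table))
  if (length(unknown))
    stop("element(s) not in radius table: ", paste(unknown, collapse = ", "))
  r <- unname(radius_table[at$element])
  wp <- data.frame(serial = at$serial, chain = at$chain,
                   x = at$x, y = at$y, z = at$z, weight = r^2,
                   stringsAsFactors = FALSE)
  class(wp) <- c("weighted_points", "data.frame")
  wp
}
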