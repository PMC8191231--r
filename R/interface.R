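# Interfacial atom extraction by the three-surface construction, and
# cross-chain interacting pairs read off the dimer complex.
#
# With M the surface of the dimer and A, B the surfaces of the monomers
# computed in their dimer-frame coordinates at the same alpha and weights,
# the interfacial set is X = (A u B) - M (monomer-surface atoms buried upon
# dimerization), partitioned as X_A = X n A and X_B = X n B.

#' Extract interfacial atom sets of a dimer frame
#'
#' Computes the dimer surface and both monomer surfaces with the weighted
#' alpha complex at the same `alpha` and weights, and returns the monomer
#' surface atoms that are buried in the dimer.
#'
#' @param frame a `structure_frame` containing both chains.
#' @param chain_a,chain_b chain labels.
#' @param alpha alpha value for all three complexes (default 0).
#' @param radius_table named radius vector, see [vdw_radii()].
#' @param jitter,jitter_seed tie-break jitter passed to the triangulation.
#' @return object of class `interface_result`: `X`, `X_A`, `X_B` (atom
#'   serial vectors), `pairs` (initially `NULL`, see [cross_chain_pairs()]),
#'   `frame_index`, `chain_a`, `chain_b`.
#' @export
interface_atoms <- function(frame, chain_a, chain_b, alpha = 0,
                            radius_table = vdw_radii(), jitter = 1e-3,
                            jitter_seed = 1L) {
  present <- chain_labels(frame)
  for (ch in c(chain_a, chain_b))
    if (!ch %in% present)
      stop("unknown chain '", ch, "'; frame has chains ",
           paste(present, collapse = ", "))
  if (chain_a == chain_b) stop("chain_a and chain_b must differ")
  wp <- assign_weights(frame, radius_table)
  wa <- wp[wp$chain == chain_a, , drop = FALSE]
  wb <- wp[wp$chain == chain_b, , drop = FALSE]
  for (w in list(wa, wb))
    if (nrow(w) < 4)
      stop("dimension error: each chain needs at least 4 atoms")
  wd <- wp[wp$chain %in% c(chain_a, chain_b), , drop = FALSE]
  M <- surface_atoms(build_alpha_complex(wd, alpha, jitter, jitter_seed))
  A <- surface_atoms(build_alpha_complex(wa, alpha, jitter, jitter_seed))
  B <- surface_atoms(build_alpha_complex(wb, alpha, jitter, jitter_seed))
  X <- sort(setdiff(union(A, B), M))
  structure(list(X = X, X_A = sort(intersect(X, A)),
                 X_B = sort(intersect(X, B)), pairs = NULL,
                 frame_index = frame$frame_index,
                 chain_a = chain_a, chain_b = chain_b),
            class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf("<interface_result frame %d>: |X|=%d (|X_%s|=%d, |X_%s|=%d), %s pairs\n",
              x$frame_index, length(x$X), x$chain_a, length(x$X_A),
              x$chain_b, length(x$X_B),
              if (is.null(x$pairs)) "un-enumerated" else nrow(x$pairs)))
  invisible(x)
}

#' Cross-chain interacting atom pairs
#'
#' A pair is an unordered cross-chain edge of the dimer's alpha complex whose
#' endpoints are both interfacial: atom `a` in `X_A` and atom `b` in `X_B`
#' sharing an edge in at least one complex tetrahedron (any tetrahedron
#' containing such an edge necessarily connects the two chains). Interfacial
#' atoms may legitimately have no partner.
#'
#' @param complex the dimer's `alpha_complex` (same frame and alpha as
#'   `result`).
#' @param result an `interface_result` from [interface_atoms()].
#' @return the `interface_result` with `pairs` filled in as a two-column
#'   matrix of serials (`X_A` side first).
#' @export
cross_chain_pairs <- function(complex, result) {
  if (!inherits(complex, "alpha_complex")) stop("expected an alpha_complex")
  if (!inherits(result, "interface_result")) stop("expected an interface_result")
  pts <- complex$points
  if (is.null(pts$serial) || is.null(pts$chain))
    stop("complex points carry no serial/chain information")
  pairs <- matrix(integer(), 0, 2,
                  dimnames = list(NULL, c("serial_a", "serial_b")))
  e <- complex$edges
  if (nrow(e)) {
    s1 <- pts$serial[e[, 1]]; s2 <- pts$serial[e[, 2]]
    c1 <- pts$chain[e[, 1]];  c2 <- pts$chain[e[, 2]]
    keep <- ((c1 == result$chain_a & c2 == result$chain_b) |
             (c1 == result$chain_b & c2 == result$chain_a)) &
            s1 %in% result$X & s2 %in% result$X
    if (any(keep)) {
      a <- ifelse(c1[keep] == result$chain_a, s1[keep], s2[keep])
      b <- ifelse(c1[keep] == result$chain_a, s2[keep], s1[keep])
      pairs <- unique(cbind(serial_a = a, serial_b = b))
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    }
  }
  result$pairs <- pairs
  result
}

#' Write (or build) the interfacial-atom report
#'
#' One row per interfacial atom: chain label, residue number, residue name,
#' atom number, atom type (element), and the comma-joined serials of its
#' interacting partners (possibly empty). Numbering follows the
#' renumbered-from-1 convention of [read_structure()]; the original PDB
#' serials can be added as an extra column.
#'
#' @param result an `interface_result` with `pairs` filled in (see
#'   [cross_chain_pairs()]); a `NULL`-pair result yields empty partner lists.
#' @param frame the `structure_frame` the result was computed from.
#' @param path optional output path; when given, the report is written as
#'   TSV (and returned invisibly).
#' @param original_serial add the `original_serial` column if available.
#' @return data frame with columns `chain_label`, `residue_number`,
#'   `residue_name`, `atom_number`, `atom_type`, `interacting_partners`.
#' @export
write_interface_report <- function(result, frame, path = NULL,
                                   original_serial = FALSE) {
  at <- frame$atoms
  rows <- at[at$serial %in% result$X, , drop = FALSE]
  partner_of <- function(s) {
    p <- result$pairs
    if (is.null(p) || nrow(p) == 0) return("")
    hit <- sort(unique(c(p[p[, 1] == s, 2], p[p[, 2] == s, 1])))
    paste(hit, collapse = ",")
  }
  rep_df <- data.frame(
    chain_label = rows$chain,
    residue_number = rows$resno,
    residue_name = rows$resname,
    atom_number = rows$serial,
    atom_type = rows$element,
    interacting_partners = vapply(rows$serial, partner_of, character(1)),
    stringsAsFactors = FALSE)
  if (original_serial && !is.null(rows$original_serial))
    rep_df$original_serial <- rows$original_serial
  rep_df <- rep_df[order(rep_df$chain_label, rep_df$atom_number), ,
                   drop = FALSE]
  rownames(rep_df) <- NULL
  if (!is.null(path)) {
    write_report_tsv(rep_df, path)
    return(invisible(rep_df))
  }
  rep_df
}

# fixed TSV serialization used for byte-stable round trips
write_report_tsv <- function(rep_df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(rep_df), collapse = "\t"), con, sep = "\n")
  if (nrow(rep_df)) {
    lines <- apply(rep_df, 1, function(r) paste(trimws(unname(r)), collapse = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read an interfacial-atom report written by [write_interface_report()]
#'
#' @param path TSV path.
#' @return data frame in the report schema.
#' @export
read_interface_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chain_label", "residue_number", "residue_name", "atom_number",
            "atom_type", "interacting_partners")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("report is missing columns: ", paste(miss, collapse = ", "))
  df$residue_number <- as.integer(df$residue_number)
  df$atom_number <- as.integer(df$atom_number)
  df$interacting_partners[is.na(df$interacting_partners)] <- ""
  df
}

#' Check partner-list symmetry of an interface report
#'
#' Atom `b` must list `a` whenever `a` lists `b`. Returns `TRUE` invisibly
#' or stops with the offending pair.
#'
#' @param report data frame in the report schema.
#' @export
check_report_symmetry <- function(report) {
  plists <- lapply(strsplit(report$interacting_partners, ","), function(v)
    as.integer(v[nzchar(v)]))
  names(plists) <- as.character(report$atom_number)
  for (i in seq_len(nrow(report))) {
    a <- report$atom_number[i]
    for (b in plists[[i]]) {
      back <- plists[[as.character(b)]]
      if (is.null(back) || !(a %in% back))
        stop(sprintf("asymmetric partner list: %d lists %d but not conversely",
                     a, b))
    }
  }
  invisible(TRUE)
}
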