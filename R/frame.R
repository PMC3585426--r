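#' Atomic coordinate frame
#'
#' A frame holds one set of atomic coordinates together with per-atom
#' metadata (chain identifier, residue number, atom name, residue name) and an
#' optional orthorhombic box. Coordinates are treated as unwrapped: no
#' periodic-image handling is performed by any geometry operation, so
#' trajectory readers must deliver whole molecules.
#'
#' @param coords numeric matrix, N x 3, coordinates in Angstrom.
#' @param atoms data.frame with N rows and columns `chain`, `resno`, `elety`
#'   (atom name) and optionally `resid` (residue name, default "ALA").
#' @param box optional numeric vector of 3 box lengths in Angstrom.
#' @return An object of class `mdframe`.
#' @export
mdframe <- function(coords, atoms, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (nrow(coords) < 1L) stop("a frame needs at least one atom")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (!is.data.frame(atoms) || nrow(atoms) != nrow(coords))
    stop("atom metadata must be a data.frame with one row per atom")
  need <- c("chain", "resno", "elety")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  atoms$resno <- as.integer(atoms$resno)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive lengths")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, atoms = atoms, box = box), class = "mdframe")
}

#' @export
print.mdframe <- function(x, ...) {
  cat(sprintf("<mdframe> %d atoms, %d residues, chains: %s\n",
              nrow(x$coords),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a frame
#' @param frame an [mdframe].
#' @return integer atom count.
#' @export
natoms <- function(frame) nrow(frame$coords)

#' Select atom indices by metadata
#'
#' @param frame an [mdframe].
#' @param chain,resno,elety optional filters; `resno` may be a vector of
#'   residue numbers.
#' @return integer vector of atom indices (1-based) in frame order.
#' @export
select_atoms <- function(frame, chain = NULL, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, natoms(frame))
  a <- frame$atoms
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  which(keep)
}

#' Apply a rigid transform or replace coordinates
#' @param frame an [mdframe].
#' @param coords replacement N x 3 coordinate matrix.
#' @return the frame with new coordinates.
#' @export
set_coords <- function(frame, coords) {
  mdframe(coords, frame$atoms, frame$box)
}
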