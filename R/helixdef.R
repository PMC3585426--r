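#' Helix definition
#'
#' Defines one helix by the atom groups entering the collective variables:
#' four consecutive C-alpha atoms at each end of the helix (head and tail)
#' and a rotational-reference group of C-alpha atoms spaced four residues
#' apart, whose center of mass lies off the helix axis. By convention the
#' head is the group listed first and positive piston shift is displacement
#' along `V = H - T`, i.e. toward the head.
#'
#' @param head integer indices of exactly 4 C-alpha atoms at the head end.
#' @param tail integer indices of exactly 4 C-alpha atoms at the tail end.
#' @param rotref integer indices of the rotational-reference C-alpha atoms.
#' @param label helix label, e.g. "N1", "C1", "N2", "C2".
#' @param all_ca optional indices of every C-alpha in the helix, tail to
#'   head order; required by the Crick-angle analysis.
#' @return object of class `helix_definition`.
#' @export
helix_definition <- function(head, tail, rotref, label = "H", all_ca = NULL) {
  head <- as.integer(head); tail <- as.integer(tail); rotref <- as.integer(rotref)
  if (length(head) != 4L || length(tail) != 4L)
    stop("head and tail must each contain exactly 4 atoms")
  if (length(intersect(head, tail)))
    stop("head and tail groups must be disjoint")
  if (!length(rotref)) stop("rotational reference group is empty")
  structure(list(head = head, tail = tail, rotref = rotref,
                 label = label, all_ca = if (!is.null(all_ca)) as.integer(all_ca)),
            class = "helix_definition")
}

#' Build a helix definition from residue numbers
#'
#' Compiles chain/residue specifications against a loaded structure into
#' atom indices. Head and tail are the four C-alpha atoms at the
#' highest-numbered and lowest-numbered ends of the residue range.
#'
#' @param frame an [mdframe].
#' @param chain chain identifier.
#' @param residues integer vector of the helix residue numbers (contiguous).
#' @param rotref_residues residue numbers of the rotational reference group.
#' @param label helix label.
#' @param elety atom name used (default `"CA"`).
#' @return a [helix_definition].
#' @export
helix_definition_from_residues <- function(frame, chain, residues,
                                           rotref_residues, label = "H",
                                           elety = "CA") {
  residues <- sort(as.integer(residues))
  idx_of <- function(resnos, groupname) {
    idx <- vapply(resnos, function(r) {
      i <- select_atoms(frame, chain = chain, resno = r, elety = elety)
      if (length(i) != 1L)
        stop(sprintf("%s: expected one %s atom for chain %s residue %d, found %d",
                     groupname, elety, chain, r, length(i)))
      i
    }, integer(1))
    idx
  }
  n <- length(residues)
  if (n < 8L) stop("helix must span at least 8 residues")
  helix_definition(head = idx_of(residues[(n - 3):n], "head"),
                   tail = idx_of(residues[1:4], "tail"),
                   rotref = idx_of(rotref_residues, "rotational reference"),
                   label = label,
                   all_ca = idx_of(residues, "helix"))
}

#' Reference model for piston and rotation collective variables
#'
#' Caches the per-helix reference quantities (head/tail centers of mass,
#' axis vector, midpoint, rotational-reference center) evaluated on a
#' reference structure, together with the alignment selection used to
#' superpose the reference onto each analyzed frame.
#'
#' @param ref_frame reference [mdframe] (e.g. the wild-type NMR model).
#' @param helices named list of [helix_definition] objects.
#' @param align_sel atom indices used for superposition; conventionally the
#'   helical C-alpha selection of the bundle.
#' @return object of class `reference_model`.
#' @export
reference_model <- function(ref_frame, helices, align_sel) {
  stopifnot(inherits(ref_frame, "mdframe"))
  if (is.null(names(helices)) || any(!nzchar(names(helices))))
    names(helices) <- vapply(helices, `[[`, "", "label")
  cache <- lapply(helices, function(hd) {
    g <- helix_axis_groups(ref_frame$coords, hd)
    if (vnorm(g$V) < 1e-9)
      stop(sprintf("helix %s: reference axis vector has zero length", hd$label))
    g$R <- colMeans(ref_frame$coords[hd$rotref, , drop = FALSE])
    g
  })
  structure(list(ref_frame = ref_frame, helices = helices,
                 align_sel = as.integer(align_sel), cache = cache),
            class = "reference_model")
}

#' Bundle definition
#'
#' Groups the four helix definitions of a HAMP-like bundle with the atom
#' selections used by trajectory analyses: the helical C-alpha selection for
#' RMSD/alignment and the residue set scanned for i -> i+4 backbone hydrogen
#' bonds.
#'
#' @param helices named list of four [helix_definition]s (N1, C1, N2, C2).
#' @param helical_sel atom indices (C-alpha) of the helical selection.
#' @param hbond_residues data.frame with columns `chain`, `resno`: residues
#'   scanned as hydrogen-bond donors/acceptors.
#' @param crick_register optional named integer vector: for each helix label,
#'   the residue number occupying heptad position `a`.
#' @return object of class `bundle_definition`.
#' @export
bundle_definition <- function(helices, helical_sel, hbond_residues = NULL,
                              crick_register = NULL) {
  labs <- names(helices)
  if (length(labs) != length(unique(labs)))
    stop("helix labels must be unique")
  structure(list(helices = helices, helical_sel = as.integer(helical_sel),
                 hbond_residues = hbond_residues,
                 crick_register = crick_register),
            class = "bundle_definition")
}

#' Pool two helices of one monomer into a tilt group
#'
#' For the inter-monomer tilt angle the head and tail groups comprise all
#' head and tail C-alpha atoms of both helices of the monomer.
#'
#' @param hdN,hdC the monomer's N- and C-helix [helix_definition]s.
#' @param label group label.
#' @return a list with `head`, `tail` and `label`, usable by [tilt_cv()].
#' @export
monomer_group <- function(hdN, hdC, label = "M") {
  structure(list(head = c(hdN$head, hdC$head), tail = c(hdN$tail, hdC$tail),
                 label = label),
            class = "tilt_group")
}
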