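# Synthetic fixtures: ideal alpha-helices and parallel four-helix bundles
# with injectable piston / rotation / tilt motions and Gaussian positional
# noise. The generator exists to provide structures whose CV coordinates are
# known exactly, so that the collective variables and analyses can be
# validated without an external simulation engine.

# Cylindrical offsets of backbone N, C', O relative to the C-alpha helix of
# an ideal alpha-helix (phi = -57, psi = -47, omega = 180, standard bond
# geometry), derived once from an internal-coordinate chain build:
# columns are (radial offset A, phase offset deg, axial offset A).
.backbone_offsets <- rbind(
  N = c(-0.7244, -26.7747, -0.9187),
  C = c(-0.6098,  26.7436,  1.0689),
  O = c(-0.3552,  20.3385,  2.2566))

#' Ideal helix parameters
#'
#' @param n_residues number of residues (>= 8).
#' @param rise axial rise per residue in Angstrom (default 1.5).
#' @param twist rotation per residue in degrees (default 100).
#' @param radius C-alpha helix radius in Angstrom (default 2.3).
#' @param chain chain identifier.
#' @param resno_start first residue number.
#' @param phase azimuthal phase of the first C-alpha in degrees.
#' @return object of class `ideal_helix_params`.
#' @export
ideal_helix_params <- function(n_residues, rise = 1.5, twist = 100,
                               radius = 2.3, chain = "A", resno_start = 1L,
                               phase = 0) {
  stopifnot(n_residues >= 8, rise > 0, radius > 0, twist > 0, twist < 180)
  structure(list(n_residues = as.integer(n_residues), rise = rise,
                 twist = twist, radius = radius, chain = chain,
                 resno_start = as.integer(resno_start), phase = phase),
            class = "ideal_helix_params")
}

#' Build an ideal alpha-helix
#'
#' C-alpha atoms lie exactly on the parametric helix
#' `(radius cos(twist i), radius sin(twist i), rise i)`; backbone N, C and O
#' are placed on companion helices using fixed cylindrical offsets derived
#' from standard internal coordinates, so that at the default geometry every
#' i -> i+4 backbone hydrogen bond satisfies the 3.5 Angstrom / 30 degree
#' criterion. The helix axis is +z with residue numbers increasing along it;
#' the helix is centered axially on the origin.
#'
#' @param p an [ideal_helix_params].
#' @return an [mdframe] with atoms N, CA, C, O per residue.
#' @export
build_ideal_helix <- function(p) {
  stopifnot(inherits(p, "ideal_helix_params"))
  j <- seq_len(p$n_residues) - 1
  z0 <- (p$n_residues - 1) * p$rise / 2
  at_names <- c("N", "CA", "C", "O")
  coords <- matrix(0, 4 * p$n_residues, 3)
  meta <- data.frame(chain = p$chain,
                     resno = rep(p$resno_start + j, each = 4),
                     elety = rep(at_names, p$n_residues),
                     resid = "ALA")
  for (k in seq_along(at_names)) {
    nm <- at_names[k]
    if (nm == "CA") { dr <- 0; dphi <- 0; dz <- 0 }
    else { o <- .backbone_offsets[nm, ]; dr <- o[1]; dphi <- o[2]; dz <- o[3] }
    th <- (p$phase + p$twist * j + dphi) * pi / 180
    r <- p$radius + dr
    rows <- seq(k, by = 4, length.out = p$n_residues)
    coords[rows, ] <- cbind(r * cos(th), r * sin(th), p$rise * j + dz - z0)
  }
  mdframe(coords, meta)
}

#' Bundle layout
#'
#' Geometry of a parallel four-helix HAMP-like bundle: the four helices sit
#' at azimuths 45, 135, 225, 315 degrees on a circle, with their axes tilted
#' inward by a cone half-angle so that they converge toward a tip on the
#' C-terminal (head) side. Monomer 1 comprises N1 and C1 (chain A), monomer
#' 2 comprises N2 and C2 (chain B).
#'
#' @param monomer_tilt target inter-monomer tilt angle in degrees (default
#'   18, the equilibrium value of the wild-type bundle).
#' @param separation distance in Angstrom between adjacent helix axes at the
#'   bundle waist (default 10).
#' @param n_residues residues per helix (default 15).
#' @return object of class `bundle_layout` with fields `cone_half_angle`
#'   (degrees), `rho` (placement radius), `azimuths`, `tip` (tip of the
#'   cone on the bundle axis) and `n_residues`.
#' @export
bundle_layout <- function(monomer_tilt = 18, separation = 10, n_residues = 15) {
  # monomer axis = mean of its two helix axes; with azimuths +-45, +-135 the
  # inter-monomer tilt is 2*atan(sqrt(2)/2 * tan(alpha))
  alpha <- atan(tan(monomer_tilt / 2 * pi / 180) * sqrt(2)) * 180 / pi
  rho <- separation / sqrt(2)
  tip_z <- if (alpha > 1e-9) rho / tan(alpha * pi / 180) else Inf
  structure(list(monomer_tilt = monomer_tilt, cone_half_angle = alpha,
                 rho = rho, azimuths = c(N1 = 45, C1 = 135, N2 = 225, C2 = 315),
                 tip = c(0, 0, tip_z), n_residues = as.integer(n_residues)),
            class = "bundle_layout")
}

#' Build a synthetic four-helix bundle
#'
#' Places four ideal helices in the [bundle_layout()] geometry and compiles
#' the helix definitions, bundle definition and reference model against the
#' generated structure. Residue numbering follows the HAMP convention: N
#' helices span 282-296, C helices 312-326; rotational reference groups are
#' residues 283, 287, 291, 295 (N) and 313, 317, 321, 325 (C). With no
#' injected motion every piston and rotation CV is exactly 0 and the
#' inter-monomer tilt equals the layout's target angle (within the small
#' off-axis wobble of the 4-atom end groups).
#'
#' @param layout a [bundle_layout()].
#' @param helix_params optional [ideal_helix_params()] template; `chain`,
#'   `resno_start` and `n_residues` are overridden per helix.
#' @return list with `frame` (the [mdframe]), `bundle`
#'   (a [bundle_definition]), `ref` (a [reference_model]) and `layout`.
#' @export
build_bundle <- function(layout = bundle_layout(),
                         helix_params = ideal_helix_params(15)) {
  n <- layout$n_residues
  specs <- list(
    N1 = list(chain = "A", start = 282L, rotref = c(283L, 287L, 291L, 295L)),
    C1 = list(chain = "A", start = 312L, rotref = c(313L, 317L, 321L, 325L)),
    N2 = list(chain = "B", start = 282L, rotref = c(283L, 287L, 291L, 295L)),
    C2 = list(chain = "B", start = 312L, rotref = c(313L, 317L, 321L, 325L)))
  alpha <- layout$cone_half_angle
  pieces <- lapply(names(specs), function(lab) {
    sp <- specs[[lab]]
    hp <- helix_params
    hp$chain <- sp$chain; hp$resno_start <- sp$start; hp$n_residues <- n
    h <- build_ideal_helix(hp)
    psi <- layout$azimuths[[lab]]
    X <- h$coords %*% t(rotation_about_axis(c(0, 0, 1), psi))
    e <- c(cos(psi * pi / 180), sin(psi * pi / 180), 0)
    # tilt the axis inward (converging toward +z, the C-terminal head side)
    tilt_axis <- cross3(c(0, 0, 1), -e)
    X <- X %*% t(rotation_about_axis(tilt_axis, alpha))
    X <- sweep(X, 2, layout$rho * e, "+")
    set_coords(h, X)
  })
  names(pieces) <- names(specs)
  coords <- do.call(rbind, lapply(pieces, `[[`, "coords"))
  atoms <- do.call(rbind, lapply(pieces, function(f) f$atoms))
  rownames(atoms) <- NULL
  frame <- mdframe(coords, atoms)
  # steric sanity: no two helices may collapse onto each other
  ca_of <- lapply(names(specs), function(lab)
    select_atoms(frame, chain = specs[[lab]]$chain,
                 resno = specs[[lab]]$start + 0:(n - 1), elety = "CA"))
  for (i in 1:3) for (j in (i + 1):4) {
    d2 <- outer(seq_along(ca_of[[i]]), seq_along(ca_of[[j]]),
                Vectorize(function(a, b)
                  sum((frame$coords[ca_of[[i]][a], ] - frame$coords[ca_of[[j]][b], ])^2)))
    if (min(d2) < 4) stop("steric collapse: inter-helix C-alpha distance < 2 Angstrom")
  }
  helices <- lapply(names(specs), function(lab) {
    sp <- specs[[lab]]
    helix_definition_from_residues(frame, sp$chain, sp$start + 0:(n - 1),
                                   sp$rotref, label = lab)
  })
  names(helices) <- names(specs)
  helical_sel <- unlist(ca_of, use.names = FALSE)
  bundle <- bundle_definition(
    helices, helical_sel,
    hbond_residues = unique(frame$atoms[, c("chain", "resno")]),
    crick_register = c(N1 = 284L, C1 = 314L, N2 = 284L, C2 = 314L))
  ref <- reference_model(frame, helices, helical_sel)
  list(frame = frame, bundle = bundle, ref = ref, layout = layout)
}

#' Inject piston / rotation / tilt motions into a bundle
#'
#' Applies rigid sub-motions to a synthetic bundle frame so that the emitted
#' structure has exactly the requested CV coordinates (relative to the given
#' reference, with identity alignment): a monomer tilt about the waist axis
#' through the cone tip (perpendicular to the inter-monomer plane, tip held
#' fixed), an axial rotation of each helix about its own axis (the line
#' through its head and tail centers of mass) and a translation of each
#' helix along that axis. Because the monomer tilt genuinely displaces helix
#' midpoints axially, small per-helix corrections along/about the axes are
#' applied after the tilt so that the injected piston and rotation values
#' are exact CV coordinates of the result; the corrections leave the tilt
#' untouched (axial rotations and translations change neither the helix
#' axis vectors nor the pooled monomer vectors).
#'
#' @param frame the bundle [mdframe] to perturb.
#' @param bundle the matching [bundle_definition].
#' @param ref the [reference_model] the CVs are measured against.
#' @param piston named numeric vector (helix label -> Angstrom, within
#'   +-3).
#' @param rotation named numeric vector (helix label -> degrees, within
#'   +-45).
#' @param tilt additional inter-monomer tilt in degrees (0-45).
#' @param noise_sd standard deviation of i.i.d. Gaussian positional noise in
#'   Angstrom, added to every coordinate after the rigid motions.
#' @param seed optional integer seed making the noise reproducible.
#' @param layout the [bundle_layout()] (needed when `tilt != 0` for the tip
#'   position).
#' @return the perturbed [mdframe].
#' @export
inject_motion <- function(frame, bundle, ref, piston = NULL, rotation = NULL,
                          tilt = 0, noise_sd = 0, seed = NULL, layout = NULL) {
  if (any(abs(as.numeric(unlist(piston))) > 3) ||
      any(abs(as.numeric(unlist(rotation))) > 45) || tilt < 0 || tilt > 45)
    stop("motions must be within +-3 Angstrom, +-45 degrees, tilt in [0, 45]")
  X <- frame$coords
  labs <- names(bundle$helices)
  helix_rows <- lapply(bundle$helices, function(hd) {
    ch <- frame$atoms$chain[hd$head[1]]
    rr <- range(frame$atoms$resno[c(hd$head, hd$tail)])
    which(frame$atoms$chain == ch & frame$atoms$resno >= rr[1] &
            frame$atoms$resno <= rr[2])
  })
  if (tilt != 0) {
    if (is.null(layout)) stop("layout is required to inject a tilt motion")
    waist_axis <- c(1, 0, 0)
    rot_about_point <- function(X, rows, angle) {
      Rm <- rotation_about_axis(waist_axis, angle)
      Xc <- sweep(X[rows, , drop = FALSE], 2, layout$tip)
      X[rows, ] <- sweep(Xc %*% t(Rm), 2, layout$tip, "+")
      X
    }
    m1 <- unlist(helix_rows[c("N1", "C1")]); m2 <- unlist(helix_rows[c("N2", "C2")])
    X <- rot_about_point(X, m1, +tilt / 2)
    X <- rot_about_point(X, m2, -tilt / 2)
  }
  want_rot <- stats::setNames(rep(0, length(labs)), labs)
  want_pis <- want_rot
  if (!is.null(rotation)) want_rot[names(rotation)] <- rotation
  if (!is.null(piston)) want_pis[names(piston)] <- piston
  idal <- identity_alignment(ref)
  for (lab in labs) {
    hd <- bundle$helices[[lab]]
    rows <- helix_rows[[lab]]
    g <- helix_axis_groups(X, hd)
    u <- unitv(g$V)
    # rotate about the helix's own axis to reach the requested rotation CV
    q0 <- rotation_core(X, hd, R0 = idal[[lab]]$R0)$value
    dq <- want_rot[lab] - q0
    if (abs(dq) > 1e-12) {
      Rm <- rotation_about_axis(u, dq)
      Xc <- sweep(X[rows, , drop = FALSE], 2, g$M)
      X[rows, ] <- sweep(Xc %*% t(Rm), 2, g$M, "+")
    }
    # translate along the axis to reach the requested piston CV
    p0 <- piston_core(X, hd, idal[[lab]]$M0)$value
    dp <- want_pis[lab] - p0
    if (abs(dp) > 1e-12)
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, dp * u, "+")
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X), 3)
  }
  set_coords(frame, X)
}

#' Interpolated synthetic trajectory between two bundle conformations
#'
#' Linear rigid-motion interpolation per helix (rotation interpolated
#' through the axis-angle representation, helix centroid moving on a
#' straight line) plus optional Gaussian noise per frame. With one frame and
#' no noise the start frame is returned unchanged.
#'
#' @param start,end atom-compatible [mdframe]s.
#' @param bundle the [bundle_definition] describing the helices.
#' @param n_frames number of frames (endpoints included).
#' @param noise_sd per-coordinate Gaussian noise in Angstrom.
#' @param seed optional integer seed.
#' @return list of [mdframe]s of length `n_frames`.
#' @export
generate_trajectory <- function(start, end, bundle, n_frames, noise_sd = 0,
                                seed = NULL) {
  if (natoms(start) != natoms(end) ||
      !identical(start$atoms$elety, end$atoms$elety))
    stop("start and end frames have incompatible atom sets")
  if (!is.null(seed)) set.seed(seed)
  helix_rows <- lapply(bundle$helices, function(hd) {
    ch <- start$atoms$chain[hd$head[1]]
    rr <- range(start$atoms$resno[c(hd$head, hd$tail)])
    which(start$atoms$chain == ch & start$atoms$resno >= rr[1] &
            start$atoms$resno <= rr[2])
  })
  # per-helix rigid motion start -> end
  motions <- lapply(helix_rows, function(rows) {
    fit <- kabsch_superpose(start$coords[rows, , drop = FALSE],
                            end$coords[rows, , drop = FALSE])
    R <- fit$transform$rotation
    ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    axis <- if (ang < 1e-9) c(0, 0, 1) else
      c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    c0 <- colMeans(start$coords[rows, , drop = FALSE])
    c1 <- colMeans(end$coords[rows, , drop = FALSE])
    list(rows = rows, angle = ang, axis = axis, c0 = c0, c1 = c1)
  })
  fracs <- if (n_frames == 1) 0 else seq(0, 1, length.out = n_frames)
  lapply(fracs, function(f) {
    X <- start$coords
    for (m in motions) {
      Rm <- rotation_about_axis(m$axis, f * m$angle)
      ct <- m$c0 + f * (m$c1 - m$c0)
      Xc <- sweep(start$coords[m$rows, , drop = FALSE], 2, m$c0)
      X[m$rows, ] <- sweep(Xc %*% t(Rm), 2, ct, "+")
    }
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X), 3)
    set_coords(start, X)
  })
}
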