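# Trajectory-level bundle analyses: helical RMSD, backbone i -> i+4
# hydrogen bonds, Crick-angle deviation from ideal knobs-into-holes
# packing, piston-state classification and negative-log-probability
# surfaces.

#' Helical RMSD against the reference structure
#'
#' C-alpha RMSD over the helical selection (by default residues 282-296 and
#' 312-326 of each chain for HAMP), after superposition over the same
#' selection. Termini and the inter-helix linker are excluded by
#' construction of the selection.
#'
#' @param frame an [mdframe].
#' @param ref a [reference_model].
#' @param bundle a [bundle_definition] supplying `helical_sel`.
#' @return RMSD in Angstrom.
#' @export
helical_rmsd <- function(frame, ref, bundle) {
  sel <- bundle$helical_sel
  if (any(sel > natoms(frame)))
    stop("helical selection indexes unresolved atoms: ",
         paste(sel[sel > natoms(frame)], collapse = ", "))
  rmsd_frames(frame, ref$ref_frame, sel, superpose = TRUE)
}

#' Count backbone i -> i+4 hydrogen bonds
#'
#' A helical hydrogen bond between residues i and i+4 is counted when the
#' distance between the backbone oxygen of residue i and the backbone
#' nitrogen of residue i+4 is below `dist_cutoff` and the angle at the donor
#' nitrogen between the acceptor oxygen and the amide hydrogen is below
#' `angle_cutoff`. When no explicit hydrogen is present it is reconstructed
#' on the bisector of the N-CA and N-C(i+3) directions (1.01 Angstrom from
#' N), the standard amide geometry.
#'
#' @param frame an [mdframe] with backbone N, O (and optionally H) atoms.
#' @param bundle a [bundle_definition]; its `hbond_residues` are scanned.
#' @param dist_cutoff O..N distance cutoff in Angstrom (default 3.5).
#' @param angle_cutoff acceptor-donor-hydrogen angle cutoff in degrees
#'   (default 30).
#' @return integer bond count. Pairs with missing backbone atoms are
#'   skipped with a warning, never silently.
#' @export
count_helical_hbonds <- function(frame, bundle, dist_cutoff = 3.5,
                                 angle_cutoff = 30) {
  res <- bundle$hbond_residues
  if (is.null(res)) res <- unique(frame$atoms[, c("chain", "resno")])
  n <- 0L; skipped <- character(0)
  one <- function(ch, r, ety) {
    i <- select_atoms(frame, chain = ch, resno = r, elety = ety)
    if (length(i) == 1L) frame$coords[i, ] else NULL
  }
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; i <- res$resno[k]
    if (!any(res$chain == ch & res$resno == i + 4L)) next
    O <- one(ch, i, "O"); N <- one(ch, i + 4L, "N")
    if (is.null(O) || is.null(N)) {
      skipped <- c(skipped, sprintf("%s:%d", ch, i)); next
    }
    if (vnorm(O - N) >= dist_cutoff) next
    H <- one(ch, i + 4L, "H")
    if (is.null(H)) {
      CA <- one(ch, i + 4L, "CA"); Cp <- one(ch, i + 3L, "C")
      if (is.null(CA) || is.null(Cp)) {
        skipped <- c(skipped, sprintf("%s:%d", ch, i)); next
      }
      H <- N + 1.01 * unitv(unitv(N - CA) + unitv(N - Cp))
    }
    ang <- acos(max(-1, min(1, sum(unitv(O - N) * unitv(H - N))))) * 180 / pi
    if (ang < angle_cutoff) n <- n + 1L
  }
  if (length(skipped))
    warning("skipped hydrogen-bond pairs with missing backbone atoms: ",
            paste(skipped, collapse = ", "))
  n
}

#' Ideal Crick-angle ladder
#'
#' Canonical knobs-into-holes reference angles by heptad position. The
#' ladder advances by 720/7 degrees per residue (two turns per heptad) from
#' the `a`-position value; the defaults place `a` at 19.5 degrees, the
#' canonical core orientation. Supplied as configuration rather than
#' hard-coded so alternative ladders can be used.
#'
#' @param a_angle Crick angle of heptad position `a` in degrees.
#' @param per_residue advance per residue in degrees (default 720/7).
#' @return named numeric vector of ideal angles for positions a-g, wrapped
#'   to (-180, 180].
#' @export
crick_ladder <- function(a_angle = 19.5, per_residue = 720 / 7) {
  ang <- a_angle + per_residue * (0:6)
  stats::setNames(((ang + 180) %% 360) - 180, letters[1:7])
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Per-residue Crick angle deviation
#'
#' For every residue of every helix: the angle, measured in the plane normal
#' to the helix principal axis, between the direction from the helix axis
#' toward the bundle axis and the direction from the helix axis to the
#' residue's C-alpha atom (sign: right-hand rule about the helix axis,
#' tail-to-head). The deviation is the measured angle minus the ideal
#' knobs-into-holes angle for the residue's heptad position.
#'
#' @param frame an [mdframe].
#' @param bundle a [bundle_definition] whose helices carry `all_ca` indices
#'   and whose `crick_register` names an `a`-position residue per helix.
#' @param ladder ideal ladder from [crick_ladder()].
#' @return data.frame with columns `helix`, `resno`, `heptad`, `crick`
#'   (measured, degrees), `ideal`, `deviation`.
#' @export
crick_deviation_profile <- function(frame, bundle, ladder = crick_ladder()) {
  sel_all <- bundle$helical_sel
  bundle_com <- colMeans(frame$coords[sel_all, , drop = FALSE])
  # bundle axis: first principal component of all helical C-alpha atoms
  pc <- stats::prcomp(frame$coords[sel_all, , drop = FALSE])
  baxis <- pc$rotation[, 1]
  out <- list()
  for (lab in names(bundle$helices)) {
    hd <- bundle$helices[[lab]]
    if (is.null(hd$all_ca))
      stop(sprintf("helix %s lacks all_ca indices needed for the axis fit", lab))
    ca <- frame$coords[hd$all_ca, , drop = FALSE]
    if (nrow(ca) < 7L) stop("helix too short to fit a principal axis (< 7 CA)")
    # fit the axis through sliding-window C-alpha centroids (7 residues =
    # two turns), which lie on the helix axis to a small fraction of the
    # helix radius; raw per-atom PCA tilts with the azimuth-z correlation
    ws <- min(7L, nrow(ca) - 3L)
    wcom <- t(vapply(seq_len(nrow(ca) - ws + 1L),
                     function(i) colMeans(ca[i:(i + ws - 1L), , drop = FALSE]),
                     numeric(3)))
    hpc <- stats::prcomp(wcom)
    if (hpc$sdev[1] < 2 * hpc$sdev[2] + 1e-12)
      stop(sprintf("helix %s: degenerate principal-axis fit", lab))
    haxis <- hpc$rotation[, 1]
    # orient tail -> head (increasing residue order in all_ca)
    if (sum(haxis * (ca[nrow(ca), ] - ca[1, ])) < 0) haxis <- -haxis
    hcent <- colMeans(wcom)
    if (sum(baxis * haxis) < 0) bax <- -baxis else bax <- baxis
    reg <- bundle$crick_register[[lab]]
    if (is.null(reg)) stop(sprintf("no heptad register configured for helix %s", lab))
    resnos <- frame$atoms$resno[hd$all_ca]
    for (k in seq_along(hd$all_ca)) {
      p_ca <- frame$coords[hd$all_ca[k], ]
      # closest point on the helix principal axis
      tproj <- sum((p_ca - hcent) * haxis)
      pax <- hcent + tproj * haxis
      # bundle-axis point closest to the helix-axis point
      bax_pt <- bundle_com + sum((pax - bundle_com) * bax) * bax
      v1 <- p_ca - pax
      v2 <- bax_pt - pax
      v1p <- v1 - sum(v1 * haxis) * haxis
      v2p <- v2 - sum(v2 * haxis) * haxis
      ang <- atan2(sum(haxis * cross3(v2p, v1p)), sum(v1p * v2p)) * 180 / pi
      hpos <- letters[((resnos[k] - reg) %% 7) + 1]
      ideal <- ladder[[hpos]]
      out[[length(out) + 1L]] <- data.frame(
        helix = lab, resno = resnos[k], heptad = hpos, crick = ang,
        ideal = ideal, deviation = wrap180(ang - ideal))
    }
  }
  do.call(rbind, out)
}

#' Classify the piston state of a frame
#'
#' Maps the four piston values (ordered N1, C1, N2, C2) onto the
#' conformational-state taxonomy: `P00` (no shift), `P10` (N1 up, C2 down),
#' `P01` (N2 up, C1 down), `P11` (both diagonal pairs shifted) or `OTHER`.
#' Configurations with any |z| at or beyond `out_of_register` Angstrom are
#' additionally flagged as out-of-register candidates (attribute
#' `out_of_register`), reflecting the exclusion of register-shifted,
#' misfolded bundles from analysis.
#'
#' @param z numeric vector of four piston values in Angstrom, ordered
#'   (N1, C1, N2, C2).
#' @param threshold piston threshold in Angstrom (default 0.5, midway
#'   between the resting-state fluctuation scale and the shifted-state
#'   displacement).
#' @param out_of_register flag threshold in Angstrom (default 3).
#' @return character state label with attribute `out_of_register` (logical).
#' @export
classify_piston_state <- function(z, threshold = 0.5, out_of_register = 3) {
  if (length(z) != 4L || !all(is.finite(z)))
    stop("z must be four finite piston values (N1, C1, N2, C2)")
  zN1 <- z[1]; zC1 <- z[2]; zN2 <- z[3]; zC2 <- z[4]
  oor <- any(abs(z) >= out_of_register)
  within <- abs(z) < threshold
  pair1 <- zN1 > threshold & zC2 < -threshold   # N1 up, C2 down
  pair2 <- zN2 > threshold & zC1 < -threshold   # N2 up, C1 down
  lab <- if (oor) "OTHER"                       # register-shift candidate
    else if (all(within)) "P00"
    else if (pair1 && pair2) "P11"
    else if (pair1 && within[2] && within[3]) "P10"
    else if (pair2 && within[1] && within[4]) "P01"
    else "OTHER"
  structure(lab, out_of_register = oor)
}

#' Negative-log-probability surface of CV samples
#'
#' Histograms 1D or 2D CV samples (optionally weighted, e.g. by
#' metadynamics reweighting factors), normalizes to a probability and
#' returns `-ln(p)` in units of kT with the minimum shifted to zero. Empty
#' bins are masked (NA), never zero-filled.
#'
#' @param samples numeric vector (1D) or 2-column matrix/data.frame (2D).
#' @param bins bins per axis (default 50) or a vector per axis.
#' @param limits optional list of c(min, max) per axis; default observed
#'   range padded by 5 percent.
#' @param weights optional per-sample weights.
#' @return object of class `surface_grid`: list with `axes` (bin edges per
#'   axis), `mids`, `values` (vector or matrix of -ln p, kT), `kind` and
#'   `low_information` flag (all samples in one bin).
#' @export
neg_log_probability_surface <- function(samples, bins = 50, limits = NULL,
                                        weights = NULL) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  d <- ncol(samples)
  if (!d %in% 1:2) stop("surfaces support 1 or 2 CV axes")
  if (nrow(samples) < 1L) stop("at least one sample is required")
  if (is.null(weights)) weights <- rep(1, nrow(samples))
  if (length(bins) == 1L) bins <- rep(bins, d)
  edges <- lapply(seq_len(d), function(k) {
    if (!is.null(limits)) lim <- limits[[k]]
    else {
      lim <- range(samples[, k])
      pad <- 0.05 * max(diff(lim), 1e-12)
      lim <- lim + c(-pad, pad)
    }
    seq(lim[1], lim[2], length.out = bins[k] + 1L)
  })
  bin_of <- function(x, e) {
    i <- findInterval(x, e, rightmost.closed = TRUE)
    i[i < 1L | i > length(e) - 1L] <- NA_integer_
    i
  }
  idx <- lapply(seq_len(d), function(k) bin_of(samples[, k], edges[[k]]))
  keep <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  counts <- array(0, dim = vapply(edges, function(e) length(e) - 1L, 1L))
  if (d == 1L) {
    t1 <- tapply(weights[keep], idx[[1]][keep], sum)
    counts[as.integer(names(t1))] <- t1
  } else {
    key <- (idx[[1]][keep] - 1L) * dim(counts)[2] + idx[[2]][keep]
    t1 <- tapply(weights[keep], key, sum)
    kk <- as.integer(names(t1))
    counts[cbind((kk - 1L) %/% dim(counts)[2] + 1L,
                 (kk - 1L) %% dim(counts)[2] + 1L)] <- t1
  }
  p <- counts / sum(counts)
  vals <- -log(p)
  vals[!is.finite(vals)] <- NA
  vals <- vals - min(vals, na.rm = TRUE)
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(axes = edges, mids = mids,
                 values = if (d == 1L) as.vector(vals) else vals,
                 kind = "kT",
                 low_information = sum(p > 0) <= 1L),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %dD, %s bins, units %s%s\n",
              length(x$axes),
              paste(vapply(x$axes, function(e) length(e) - 1L, 1L), collapse = " x "),
              x$kind,
              if (isTRUE(x$low_information)) " [low information]" else ""))
  invisible(x)
}
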