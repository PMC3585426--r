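# Collective variables for helix bundles: piston shift (Angstrom), axial
# rotation (degrees, signed) and tilt angle (degrees), each with analytic
# gradients with respect to the contributing atom coordinates. Piston and
# rotation are measured against a reference structure that is first
# superposed onto the current frame to remove overall translation and
# rotation; gradients treat the aligned reference as fixed (the optimal
# rotation is not differentiated through), which is the approximation
# validated by the frozen-alignment finite-difference check.

helix_axis_groups <- function(coords, hd) {
  H <- colMeans(coords[hd$head, , drop = FALSE])
  T <- colMeans(coords[hd$tail, , drop = FALSE])
  list(H = H, T = T, V = H - T, M = (H + T) / 2)
}

#' Helix axis vector
#'
#' Head and tail centers of mass, the axis vector `V = H - T` and the
#' midpoint `M = (H + T)/2` of a helix. The centers are unweighted means of
#' four consecutive C-alpha atoms at each end.
#'
#' @param frame an [mdframe].
#' @param hd a [helix_definition].
#' @return list with 3-vectors `H`, `T`, `V`, `M` (Angstrom).
#' @export
helix_axis_vector <- function(frame, hd) {
  for (g in c("head", "tail"))
    if (any(hd[[g]] > natoms(frame)))
      stop(sprintf("helix %s: %s atoms missing from frame", hd$label, g))
  helix_axis_groups(frame$coords, hd)
}

#' Align the reference model onto a frame
#'
#' Superposes the reference structure onto the current frame over the
#' alignment selection and returns the transformed per-helix reference
#' quantities. Used internally by [piston_cv()] and [rotation_cv()]; exposed
#' so that the alignment can be frozen, e.g. for finite-difference gradient
#' checks.
#'
#' @param frame an [mdframe].
#' @param ref a [reference_model].
#' @param align_sel atom indices for the superposition (default: the
#'   reference model's alignment selection). `NULL` with `align = FALSE`
#'   semantics is not allowed here; use [identity_alignment()] instead.
#' @return named list (per helix) of transformed reference quantities
#'   `H0`, `T0`, `V0`, `M0`, `R0`.
#' @export
align_reference <- function(frame, ref, align_sel = NULL) {
  if (is.null(align_sel)) align_sel <- ref$align_sel
  fit <- kabsch_superpose(ref$ref_frame$coords, frame$coords, align_sel)
  lapply(ref$cache, function(g) {
    list(H0 = apply_transform(fit$transform, g$H),
         T0 = apply_transform(fit$transform, g$T),
         V0 = apply_transform(fit$transform, g$V) - fit$transform$translation,
         M0 = apply_transform(fit$transform, g$M),
         R0 = apply_transform(fit$transform, g$R))
  })
}

#' Identity alignment of a reference model
#'
#' Returns the reference quantities untransformed, for frames that are
#' already expressed in the reference coordinate system (e.g. synthetic
#' fixtures derived from the reference itself).
#'
#' @param ref a [reference_model].
#' @return per-helix reference quantities as in [align_reference()].
#' @export
identity_alignment <- function(ref) {
  lapply(ref$cache, function(g)
    list(H0 = g$H, T0 = g$T, V0 = g$V, M0 = g$M, R0 = g$R))
}

cv_result <- function(value, gradient, units) {
  # an atom may belong to several defining groups (e.g. a rotational
  # reference residue inside the tail quadruple); its contributions add
  idx <- as.integer(rownames(gradient))
  if (anyDuplicated(idx)) {
    agg <- rowsum(gradient, idx, reorder = FALSE)
    rownames(agg) <- unique(idx)
    gradient <- agg
  }
  structure(list(value = value, gradient = gradient, units = units),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %.6g %s, gradient over %d atoms\n",
              x$value, x$units, nrow(x$gradient)))
  invisible(x)
}

# ---- cores: value + gradient at fixed (pre-aligned) reference ----------

piston_core <- function(coords, hd, M0) {
  g <- helix_axis_groups(coords, hd)
  nv <- vnorm(g$V)
  if (nv < 1e-9) stop("helix axis vector has zero length")
  u <- g$V / nv
  w <- g$M - M0
  value <- sum(w * u)
  wp <- (w - sum(w * u) * u) / nv        # (I - uu^T) w / |V|
  gh <- matrix(rep(u / 8 + wp / 4, each = 4), 4, 3)
  gt <- matrix(rep(u / 8 - wp / 4, each = 4), 4, 3)
  grad <- rbind(gh, gt)
  rownames(grad) <- c(hd$head, hd$tail)
  cv_result(value, grad, "Angstrom")
}

rotation_core <- function(coords, hd, R0, M0 = NULL) {
  g <- helix_axis_groups(coords, hd)
  nv <- vnorm(g$V)
  if (nv < 1e-9) stop("helix axis vector has zero length")
  u <- g$V / nv
  R <- colMeans(coords[hd$rotref, , drop = FALSE])
  r <- R - g$M
  # reference azimuth vector: against the current midpoint (default) or the
  # aligned reference midpoint; the latter makes r0 a constant, so the
  # frozen-alignment gradient is exactly translation-invariant
  use_current_mid <- is.null(M0)
  r0 <- if (use_current_mid) R0 - g$M else R0 - M0
  a <- r - sum(r * u) * u                 # projections onto plane normal to V
  b <- r0 - sum(r0 * u) * u
  if (vnorm(a) < 1e-6 || vnorm(b) < 1e-6)
    stop("rotational reference lies on the helix axis (degenerate projection)")
  s <- sum(u * cross3(r0, r))             # = u . (b x a)
  cc <- sum(r * r0) - sum(r * u) * sum(r0 * u)  # = a . b
  value <- atan2(s, cc) * 180 / pi
  den <- s^2 + cc^2
  # partials of s and cc w.r.t. r, r0 and u
  ds_dr <- cross3(u, r0);  dc_dr <- b
  ds_dr0 <- -cross3(u, r); dc_dr0 <- a
  ds_du <- cross3(r0, r)
  dc_du <- -sum(u * r0) * r - sum(u * r) * r0
  g_r  <- (cc * ds_dr  - s * dc_dr)  / den
  g_r0 <- if (use_current_mid) (cc * ds_dr0 - s * dc_dr0) / den else c(0, 0, 0)
  g_u  <- (cc * ds_du  - s * dc_du)  / den
  Pg_u <- (g_u - sum(g_u * u) * u) / nv   # chain through u = V/|V|
  nr <- length(hd$rotref)
  grad_rot  <- g_r / nr
  grad_head <- -(g_r + g_r0) / 8 + Pg_u / 4
  grad_tail <- -(g_r + g_r0) / 8 - Pg_u / 4
  grad <- rbind(matrix(rep(grad_head, each = 4), 4, 3),
                matrix(rep(grad_tail, each = 4), 4, 3),
                matrix(rep(grad_rot, each = nr), nr, 3))
  grad <- grad * 180 / pi
  rownames(grad) <- c(hd$head, hd$tail, hd$rotref)
  cv_result(value, grad, "degrees")
}

tilt_core <- function(coords, ga, gb) {
  comg <- function(idx) colMeans(coords[idx, , drop = FALSE])
  V1 <- comg(ga$head) - comg(ga$tail)
  V2 <- comg(gb$head) - comg(gb$tail)
  n1 <- vnorm(V1); n2 <- vnorm(V2)
  if (n1 < 1e-9 || n2 < 1e-9) stop("tilt: zero-length axis vector")
  u1 <- V1 / n1; u2 <- V2 / n2
  x <- sum(u1 * u2)
  xc <- max(-1, min(1, x))
  value <- acos(xc) * 180 / pi
  # d acos(x)/dV1 = -1/sqrt(1-x^2) * (u2 - x u1)/|V1|
  sx <- sqrt(max(1 - xc^2, 1e-24))
  dV1 <- -(u2 - xc * u1) / (sx * n1)
  dV2 <- -(u1 - xc * u2) / (sx * n2)
  n1h <- length(ga$head); n1t <- length(ga$tail)
  n2h <- length(gb$head); n2t <- length(gb$tail)
  grad <- rbind(matrix(rep(dV1 / n1h, each = n1h), n1h, 3),
                matrix(rep(-dV1 / n1t, each = n1t), n1t, 3),
                matrix(rep(dV2 / n2h, each = n2h), n2h, 3),
                matrix(rep(-dV2 / n2t, each = n2t), n2t, 3))
  grad <- grad * 180 / pi
  rownames(grad) <- c(ga$head, ga$tail, gb$head, gb$tail)
  cv_result(value, grad, "degrees")
}

# ---- public CV evaluators ----------------------------------------------

#' Piston-shift collective variable
#'
#' Projection of the displacement of the helix midpoint from its (aligned)
#' reference position onto the current helix axis direction:
#' `Z = (M - M0') . V / |V|`, in Angstrom. Positive values are displacements
#' toward the head group. The reference structure is superposed onto the
#' current frame before evaluation; the gradient treats the aligned
#' reference as fixed.
#'
#' @param frame an [mdframe].
#' @param ref a [reference_model].
#' @param hd a [helix_definition]; must be one of the reference model's
#'   helices (matched by label).
#' @param align_sel atom indices for reference alignment (default: the
#'   model's alignment selection).
#' @param aligned optionally, pre-aligned reference quantities from
#'   [align_reference()] or [identity_alignment()], to freeze the alignment.
#' @return a `cv_result` with value in Angstrom and an n x 3 gradient matrix
#'   (rownames = atom indices, units per Angstrom of displacement).
#' @export
piston_cv <- function(frame, ref, hd, align_sel = NULL, aligned = NULL) {
  if (is.null(aligned)) aligned <- align_reference(frame, ref, align_sel)
  piston_core(frame$coords, hd, aligned[[hd$label]]$M0)
}

#' Helix-rotation collective variable
#'
#' Signed angle (degrees) between the projections, onto the plane normal to
#' the helix axis, of the rotational-reference vector `r = R - M` and its
#' counterpart in the aligned reference structure `r0 = R0' - M`. The sign
#' follows the right-hand rule about the axis direction `V/|V|` (positive =
#' counterclockwise looking from tail to head). Insensitive to translation
#' along the axis.
#'
#' @inheritParams piston_cv
#' @param ref_midpoint which midpoint anchors the reference azimuth vector
#'   `r0 = R0' - M`: `"current"` (the frame's midpoint, the default) or
#'   `"reference"` (the aligned reference midpoint, which makes the
#'   frozen-alignment gradient exactly translation-invariant).
#' @return a `cv_result` in degrees with gradient in deg/Angstrom.
#' @export
rotation_cv <- function(frame, ref, hd, align_sel = NULL, aligned = NULL,
                        ref_midpoint = c("current", "reference")) {
  ref_midpoint <- match.arg(ref_midpoint)
  if (is.null(aligned)) aligned <- align_reference(frame, ref, align_sel)
  rotation_core(frame$coords, hd, R0 = aligned[[hd$label]]$R0,
                M0 = if (ref_midpoint == "reference") aligned[[hd$label]]$M0)
}

#' Tilt-angle collective variable
#'
#' Angle between the axis vectors of two helices (or two monomers),
#' `arccos(V1 . V2 / |V1||V2|)` in [0, 180] degrees. Requires no reference
#' structure and is invariant under any global rigid motion. For the
#' monomer variant pass [monomer_group()] objects pooling the head and tail
#' atoms of both helices of each monomer.
#'
#' @param frame an [mdframe].
#' @param hdA,hdB [helix_definition] or [monomer_group()] objects.
#' @return a `cv_result` in degrees with gradient in deg/Angstrom.
#' @export
tilt_cv <- function(frame, hdA, hdB) {
  tilt_core(frame$coords, hdA, hdB)
}

#' Finite-difference validation of analytic CV gradients
#'
#' Central-difference check of the analytic gradient of a collective
#' variable, with the reference alignment frozen during the differencing
#' (the same approximation under which the analytic gradients are derived).
#'
#' @param cv one of `"piston"`, `"rotation"`, `"tilt"`.
#' @param frame an [mdframe].
#' @param ref a [reference_model] (ignored for tilt).
#' @param hd a [helix_definition] (for tilt: `list(hdA, hdB)` or a pair of
#'   groups).
#' @param step finite-difference step in Angstrom, within [1e-6, 1e-3].
#' @param align_sel alignment selection used to freeze the alignment.
#' @return maximum absolute discrepancy between analytic and numerical
#'   gradient over all contributing atoms and components (CV units per
#'   Angstrom).
#' @export
numeric_gradient_check <- function(cv = c("piston", "rotation", "tilt"),
                                   frame, ref = NULL, hd, step = 1e-5,
                                   align_sel = NULL) {
  cv <- match.arg(cv)
  if (step < 1e-6 || step > 1e-3) stop("step must be within [1e-6, 1e-3] Angstrom")
  if (cv == "tilt") {
    evalf <- function(coords) tilt_core(coords, hd[[1]], hd[[2]])
  } else {
    aligned <- align_reference(frame, ref, align_sel)
    evalf <- switch(cv,
      piston = function(coords) piston_core(coords, hd, aligned[[hd$label]]$M0),
      rotation = function(coords) rotation_core(coords, hd, R0 = aligned[[hd$label]]$R0))
  }
  res <- evalf(frame$coords)
  idx <- as.integer(rownames(res$gradient))
  worst <- 0
  for (k in seq_along(idx)) {
    for (dim in 1:3) {
      cp <- frame$coords; cp[idx[k], dim] <- cp[idx[k], dim] + step
      cm <- frame$coords; cm[idx[k], dim] <- cm[idx[k], dim] - step
      num <- (evalf(cp)$value - evalf(cm)$value) / (2 * step)
      worst <- max(worst, abs(num - res$gradient[k, dim]))
    }
  }
  worst
}

#' Per-frame CV time series for a bundle
#'
#' Evaluates the four piston shifts, four helix rotations and the
#' inter-monomer tilt for every frame of a trajectory, in the column layout
#' of a COLVAR file.
#'
#' @param frames list of [mdframe]s (one trajectory), or a single frame.
#' @param ref a [reference_model] whose helices are labeled N1, C1, N2, C2.
#' @param times optional per-frame times in ps (default 0, 1, 2, ...).
#' @param align_sel alignment selection override.
#' @return data.frame with columns `time`, `z_N1 .. z_C2`, `rot_N1 ..
#'   rot_C2`, `tilt_M1M2`.
#' @export
colvar_series <- function(frames, ref, times = NULL, align_sel = NULL) {
  if (inherits(frames, "mdframe")) frames <- list(frames)
  labs <- names(ref$helices)
  need <- c("N1", "C1", "N2", "C2")
  if (!all(need %in% labs))
    stop("reference model must define helices N1, C1, N2, C2")
  m1 <- monomer_group(ref$helices$N1, ref$helices$C1, "M1")
  m2 <- monomer_group(ref$helices$N2, ref$helices$C2, "M2")
  if (is.null(times)) times <- seq_along(frames) - 1
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    aligned <- align_reference(fr, ref, align_sel)
    z <- vapply(need, function(l)
      piston_core(fr$coords, ref$helices[[l]], aligned[[l]]$M0)$value, 0)
    rot <- vapply(need, function(l)
      rotation_core(fr$coords, ref$helices[[l]], R0 = aligned[[l]]$R0)$value, 0)
    c(time = times[i], stats::setNames(z, paste0("z_", need)),
      stats::setNames(rot, paste0("rot_", need)),
      tilt_M1M2 = tilt_core(fr$coords, m1, m2)$value)
  })
  as.data.frame(do.call(rbind, rows))
}
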