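#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3 x 3, det = +1) plus a
#' translation. Applied to row-vector coordinates as `X %*% t(R) + t`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector (Angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be a proper orthonormal matrix (det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tr a [rigid_transform].
#' @param x N x 3 coordinate matrix, a 3-vector, or an [mdframe].
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(tr, x) {
  if (inherits(x, "mdframe"))
    return(set_coords(x, apply_transform(tr, x$coords)))
  if (is.null(dim(x)))
    return(drop(tr$rotation %*% x) + tr$translation)
  sweep(x %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @param a,b [rigid_transform] objects.
#' @return the composed [rigid_transform].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tr a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), drop(-t(tr$rotation) %*% tr$translation))
}

frame_coords <- function(x) if (inherits(x, "mdframe")) x$coords else as.matrix(x)

#' Kabsch superposition
#'
#' Finds the proper rigid transform that minimizes the RMSD of `mobile` onto
#' `target` over a selection of corresponding atoms. Reflections are excluded
#' by sign-correcting the smallest singular value, so the result is always a
#' physical rigid motion. The fit is unweighted over the selection.
#'
#' @param mobile,target [mdframe] objects or N x 3 coordinate matrices.
#' @param selection integer atom indices used for the fit; must index
#'   corresponding atoms in both inputs. Defaults to all atoms.
#' @return list with `transform` (a [rigid_transform] mapping mobile onto
#'   target) and `rmsd` (Angstrom, over the selection after the fit).
#' @export
kabsch_superpose <- function(mobile, target, selection = NULL) {
  P <- frame_coords(mobile); Q <- frame_coords(target)
  if (is.null(selection)) {
    if (nrow(P) != nrow(Q)) stop("mobile and target have different atom counts")
    selection <- seq_len(nrow(P))
  }
  selection <- as.integer(selection)
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selected atoms")
  if (max(selection) > nrow(P) || max(selection) > nrow(Q))
    stop("selection indexes atoms beyond the frame")
  Ps <- P[selection, , drop = FALSE]; Qs <- Q[selection, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  Pc <- sweep(Ps, 2, cp); Qc <- sweep(Qs, 2, cq)
  sv <- svd(crossprod(Pc, Qc))        # H = t(Pc) %*% Qc
  # degenerate (collinear or coincident) selections leave the rotation
  # undetermined about an axis
  sq <- svd(Qc, nu = 0, nv = 0)$d
  if (sq[2] < 1e-8 * max(sq[1], 1))
    stop("degenerate selection: selected atoms are collinear or coincident")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, cq - drop(R %*% cp))
  fitted <- apply_transform(tr, Ps)
  list(transform = tr, rmsd = sqrt(mean(rowSums((fitted - Qs)^2))))
}

#' Root-mean-square deviation between two frames
#'
#' @param a,b [mdframe] objects or coordinate matrices with corresponding
#'   atoms.
#' @param selection integer atom indices to compare (default: all).
#' @param superpose if `TRUE`, `a` is optimally superposed onto `b` over the
#'   selection first (Kabsch, no reflection).
#' @return RMSD in Angstrom.
#' @export
rmsd_frames <- function(a, b, selection = NULL, superpose = FALSE) {
  A <- frame_coords(a); B <- frame_coords(b)
  if (is.null(selection)) {
    if (nrow(A) != nrow(B)) stop("frames have different atom counts")
    selection <- seq_len(nrow(A))
  }
  if (length(selection) == 0L) stop("empty selection")
  if (superpose) {
    fit <- kabsch_superpose(A, B, selection)
    return(fit$rmsd)
  }
  As <- A[selection, , drop = FALSE]; Bs <- B[selection, , drop = FALSE]
  if (nrow(As) != nrow(Bs)) stop("selection lengths differ between frames")
  sqrt(mean(rowSums((As - Bs)^2)))
}

# small vector helpers used throughout
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be unit length).
#' @param angle rotation angle in degrees, right-hand rule about `axis`.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unitv(axis); th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
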