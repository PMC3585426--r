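# Shared fixtures, built in code at test time.

HELIX_LABELS <- c("N1", "C1", "N2", "C2")

unitv <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

make_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_bundle()
    cache
  }
})

# knobs-into-holes fixture: heptad-periodic twist (720/7 deg/residue) and
# azimuthal phase calibrated so the register residue (284, heptad a) faces
# the bundle core at the ideal a angle; straight parallel helices
make_kih_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      phase <- 19.5 + 180 - 2 * 720 / 7
      hp <- ideal_helix_params(14, twist = 720 / 7, phase = phase)
      cache <<- build_bundle(bundle_layout(monomer_tilt = 0, n_residues = 14),
                             helix_params = hp)
    }
    cache
  }
})

monomer_groups <- function(b) {
  list(M1 = monomer_group(b$ref$helices$N1, b$ref$helices$C1, "M1"),
       M2 = monomer_group(b$ref$helices$N2, b$ref$helices$C2, "M2"))
}

helix_atom_rows <- function(frame, hd) {
  ch <- frame$atoms$chain[hd$head[1]]
  rr <- range(frame$atoms$resno[c(hd$head, hd$tail)])
  which(frame$atoms$chain == ch & frame$atoms$resno >= rr[1] &
          frame$atoms$resno <= rr[2])
}

all_pistons <- function(frame, b, aligned = NULL, align_sel = NULL) {
  vapply(HELIX_LABELS, function(l)
    piston_cv(frame, b$ref, b$bundle$helices[[l]], align_sel = align_sel,
              aligned = aligned)$value, 0)
}

all_rotations <- function(frame, b, aligned = NULL, align_sel = NULL) {
  vapply(HELIX_LABELS, function(l)
    rotation_cv(frame, b$ref, b$bundle$helices[[l]], align_sel = align_sel,
                aligned = aligned)$value, 0)
}

# helical C-alpha alignment selection excluding one helix (used when a
# single helix is moved: the three static helices anchor the alignment)
align_sel_excluding <- function(b, label) {
  drop_ca <- b$bundle$helices[[label]]$all_ca
  setdiff(b$bundle$helical_sel, drop_ca)
}

random_rigid_motion <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, -180, 180)),
                  stats::rnorm(3, sd = 5))
}

# minimal single-frame CHARMM-format DCD writer (float32 coordinates with
# Fortran record markers), used only to cross-check the DCD reading path
write_dcd_frames <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  nf <- length(frames); na <- natoms(frames[[1]])
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "helixcv test trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4), 4)
  for (fr in frames)
    for (k in 1:3)
      rec(function() writeBin(as.numeric(fr$coords[, k]), con, size = 4),
          4 * na)
  invisible(path)
}

# per-bin proportion and moving-block standard error of an indicator series
binned_proportions <- function(x, breaks, weights = NULL, n_blocks = 25) {
  if (is.null(weights)) weights <- rep(1, length(x))
  nb <- length(breaks) - 1
  block <- cut(seq_along(x), n_blocks, labels = FALSE)
  p_blocks <- matrix(0, n_blocks, nb)
  for (bk in seq_len(n_blocks)) {
    sel <- block == bk
    wt <- weights[sel]
    h <- tapply(wt, cut(x[sel], breaks), sum)
    h[is.na(h)] <- 0
    p_blocks[bk, ] <- h / sum(wt)
  }
  list(p = colMeans(p_blocks),
       se = apply(p_blocks, 2, stats::sd) / sqrt(n_blocks))
}
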