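set.seed(101)

test_that("helix axis vector has the expected geometry", {
  h <- build_ideal_helix(ideal_helix_params(15))
  ca <- select_atoms(h, elety = "CA")
  hd <- helix_definition(head = ca[12:15], tail = ca[1:4],
                         rotref = ca[c(2, 6, 10, 14)], label = "H",
                         all_ca = ca)
  ax <- helix_axis_vector(h, hd)
  expect_equal(ax$V, ax$H - ax$T)
  expect_equal(ax$M, (ax$H + ax$T) / 2)
  ang <- acos(sum(unitv(ax$V) * c(0, 0, 1))) * 180 / pi
  expect_lt(ang, 0.5)  # COM of 4 helical CA lies near the axis
  # translation moves H, T, M but not V
  t0 <- c(3, -2, 7)
  h2 <- set_coords(h, sweep(h$coords, 2, t0, "+"))
  ax2 <- helix_axis_vector(h2, hd)
  expect_equal(ax2$H, ax$H + t0)
  expect_equal(ax2$M, ax$M + t0)
  expect_equal(ax2$V, ax$V)
})

test_that("piston responds only to axial displacement", {
  b <- make_bundle()
  expect_equal(all_pistons(b$frame, b), c(N1 = 0, C1 = 0, N2 = 0, C2 = 0),
               tolerance = 1e-10)
  hd <- b$bundle$helices$N1
  rows <- helix_atom_rows(b$frame, hd)
  u <- unitv(helix_axis_vector(b$frame, hd)$V)
  sel <- align_sel_excluding(b, "N1")
  # +1 A along the axis
  X <- b$frame$coords; X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, u, "+")
  z <- piston_cv(set_coords(b$frame, X), b$ref, hd, align_sel = sel)$value
  expect_equal(z, 1, tolerance = 1e-6)
  # 2 A perpendicular to the axis
  perp <- unitv(cross3(u, c(1, 0, 0)))
  Xp <- b$frame$coords
  Xp[rows, ] <- sweep(Xp[rows, , drop = FALSE], 2, 2 * perp, "+")
  zp <- piston_cv(set_coords(b$frame, Xp), b$ref, hd, align_sel = sel)$value
  expect_equal(zp, 0, tolerance = 1e-6)
})

test_that("rotation measures axial spin and ignores axial translation", {
  b <- make_bundle()
  expect_equal(all_rotations(b$frame, b), c(N1 = 0, C1 = 0, N2 = 0, C2 = 0),
               tolerance = 1e-10)
  hd <- b$bundle$helices$C1
  rows <- helix_atom_rows(b$frame, hd)
  ax <- helix_axis_vector(b$frame, hd)
  u <- unitv(ax$V)
  sel <- align_sel_excluding(b, "C1")
  spin <- function(angle, slide = 0) {
    R <- rotation_about_axis(u, angle)
    X <- b$frame$coords
    Xc <- sweep(X[rows, , drop = FALSE], 2, ax$M)
    X[rows, ] <- sweep(Xc %*% t(R), 2, ax$M + slide * u, "+")
    rotation_cv(set_coords(b$frame, X), b$ref, hd, align_sel = sel)$value
  }
  expect_equal(spin(10), 10, tolerance = 0.1)
  expect_equal(spin(-25, slide = 0.5), -25, tolerance = 0.1)
})

test_that("tilt matches closed-form angles", {
  # two synthetic 8-atom 'helices' with prescribed axis directions
  stick <- function(dir, origin) {
    dir <- unitv(dir)
    side <- unitv(cross3(dir, c(1, 0.2, 0)))
    t(sapply(0:7, function(i) origin + i * 2 * dir + 0.5 * side * (i %% 2)))
  }
  frame_for <- function(d1, d2) {
    coords <- rbind(stick(d1, c(0, 0, 0)), stick(d2, c(8, 0, 0)))
    mdframe(coords, data.frame(chain = rep(c("A", "B"), each = 8),
                               resno = rep(1:8, 2), elety = "CA"))
  }
  g1 <- list(head = 5:8, tail = 1:4)
  g2 <- list(head = 13:16, tail = 9:12)
  expect_equal(tilt_cv(frame_for(c(0, 0, 1), c(0, 0, 1)), g1, g2)$value, 0,
               tolerance = 1e-8)
  expect_equal(tilt_cv(frame_for(c(0, 0, 1), c(0, 1, 1)), g1, g2)$value, 45,
               tolerance = 1e-8)
  expect_equal(tilt_cv(frame_for(c(0, 0, 1), c(0, 0, -1)), g1, g2)$value, 180,
               tolerance = 1e-8)
})

test_that("all CVs are invariant under global rigid motion", {
  b <- make_bundle()
  mg <- monomer_groups(b)
  fr <- inject_motion(b$frame, b$bundle, b$ref,
                      piston = c(N1 = 1, C2 = -1.5), rotation = c(C1 = 15))
  z0 <- all_pistons(fr, b); r0 <- all_rotations(fr, b)
  t0 <- tilt_cv(fr, mg$M1, mg$M2)$value
  for (k in 1:3) {
    moved <- apply_transform(random_rigid_motion(), fr)
    expect_equal(all_pistons(moved, b), z0, tolerance = 1e-6)
    expect_equal(all_rotations(moved, b), r0, tolerance = 1e-6)
    expect_equal(tilt_cv(moved, mg$M1, mg$M2)$value, t0, tolerance = 1e-6)
  }
})

test_that("analytic gradients match frozen-alignment finite differences", {
  b <- make_bundle()
  mg <- monomer_groups(b)
  fr <- inject_motion(b$frame, b$bundle, b$ref,
                      piston = c(N1 = 0.7, C2 = -1.1),
                      rotation = c(N1 = 12, C1 = -20),
                      noise_sd = 0.15, seed = 7)
  expect_lt(numeric_gradient_check("piston", fr, b$ref, b$bundle$helices$N1), 1e-5)
  expect_lt(numeric_gradient_check("rotation", fr, b$ref, b$bundle$helices$N1), 1e-4)
  expect_lt(numeric_gradient_check("tilt", fr, hd = list(mg$M1, mg$M2)), 1e-4)
  # rotation at a configuration with near-orthogonal projections
  f90 <- inject_motion(b$frame, b$bundle, b$ref, rotation = c(N2 = 45))
  expect_lt(numeric_gradient_check("rotation", f90, b$ref, b$bundle$helices$N2), 1e-4)
  expect_error(numeric_gradient_check("piston", fr, b$ref, b$bundle$helices$N1,
                                      step = 1e-2), "step")
})

test_that("gradients respect translation invariance", {
  b <- make_bundle()
  mg <- monomer_groups(b)
  fr <- inject_motion(b$frame, b$bundle, b$ref, piston = c(N1 = 1),
                      rotation = c(N1 = 10), noise_sd = 0.1, seed = 3)
  al <- identity_alignment(b$ref)
  hd <- b$bundle$helices$N1
  # tilt: gradient rows sum to the zero vector
  gt <- tilt_cv(fr, mg$M1, mg$M2)$gradient
  expect_equal(colSums(gt), c(0, 0, 0), tolerance = 1e-9)
  # rotation: translation-invariant under the reference-midpoint anchoring
  # (the current-midpoint default couples r0 to the frame midpoint, so its
  # frozen-alignment gradient keeps a small net translation response)
  gr <- rotation_cv(fr, b$ref, hd, aligned = al,
                    ref_midpoint = "reference")$gradient
  expect_equal(colSums(gr), c(0, 0, 0), tolerance = 1e-9)
  # piston: gradient sum is the axis direction, so components perpendicular
  # to V vanish
  gp <- piston_cv(fr, b$ref, hd, aligned = al)
  u <- unitv(helix_axis_vector(fr, hd)$V)
  s <- colSums(gp$gradient)
  expect_equal(unname(s - sum(s * u) * u), c(0, 0, 0), tolerance = 1e-9)
})

test_that("injected single motions are recovered within tolerance", {
  b <- make_bundle()
  mg <- monomer_groups(b)
  base_tilt <- tilt_cv(b$frame, mg$M1, mg$M2)$value
  for (delta in c(-2, -1, -0.5, 0.5, 1, 2)) {
    fr <- inject_motion(b$frame, b$bundle, b$ref, piston = c(C2 = delta))
    z <- piston_cv(fr, b$ref, b$bundle$helices$C2,
                   align_sel = align_sel_excluding(b, "C2"))$value
    expect_lt(abs(z - delta), max(0.02 * abs(delta), 1e-3))
  }
  for (phi in c(-30, -10, 10, 30)) {
    fr <- inject_motion(b$frame, b$bundle, b$ref, rotation = c(N2 = phi))
    r <- rotation_cv(fr, b$ref, b$bundle$helices$N2,
                     align_sel = align_sel_excluding(b, "N2"))$value
    expect_lt(abs(r - phi), max(0.02 * abs(phi), 0.2))
  }
  for (dth in c(5, 10, 20)) {
    fr <- inject_motion(b$frame, b$bundle, b$ref, tilt = dth, layout = b$layout)
    incr <- tilt_cv(fr, mg$M1, mg$M2)$value - base_tilt
    expect_lt(abs(incr - dth), max(0.02 * dth, 0.2))
  }
})

test_that("degenerate helix definitions are rejected", {
  b <- make_bundle()
  expect_error(helix_definition(head = 1:4, tail = 3:6, rotref = 10),
               "disjoint")
  expect_error(helix_definition(head = 1:3, tail = 5:8, rotref = 10),
               "exactly 4")
  # rotref collapsed onto the axis -> degenerate projection; the probe
  # rotref atom (middle residue) is outside the head/tail groups, so moving
  # it does not move the axis itself
  hd0 <- b$bundle$helices$N1
  probe <- select_atoms(b$frame, chain = "A", resno = 289, elety = "CA")
  hd <- helix_definition(hd0$head, hd0$tail, rotref = probe, label = "N1")
  ax <- helix_axis_vector(b$frame, hd)
  X <- b$frame$coords
  X[probe, ] <- ax$M
  bad <- set_coords(b$frame, X)
  ref2 <- reference_model(b$ref$ref_frame, list(N1 = hd), b$ref$align_sel)
  expect_error(rotation_cv(bad, ref2, hd, aligned = identity_alignment(ref2)),
               "axis|degenerate")
})

test_that("colvar series lays out the standard columns", {
  b <- make_bundle()
  fr <- inject_motion(b$frame, b$bundle, b$ref, piston = c(N1 = 1, C2 = -1.5))
  cs <- colvar_series(list(b$frame, fr), b$ref, times = c(0, 2))
  expect_named(cs, c("time", "z_N1", "z_C1", "z_N2", "z_C2",
                     "rot_N1", "rot_C1", "rot_N2", "rot_C2", "tilt_M1M2"))
  expect_equal(cs$time, c(0, 2))
  expect_equal(unlist(cs[1, 2:9]), rep(0, 8), ignore_attr = TRUE,
               tolerance = 1e-8)
})
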