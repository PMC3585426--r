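set.seed(202)

test_that("helical RMSD behaves under construction and superposition", {
  b <- make_bundle()
  expect_equal(helical_rmsd(b$frame, b$ref, b$bundle), 0, tolerance = 1e-10)
  # every helical C-alpha displaced radially (from its own helix axis) by
  # 0.5 A: superposition cannot reduce the symmetric displacement
  X <- b$frame$coords
  for (hd in b$bundle$helices) {
    ax <- helix_axis_vector(b$frame, hd)
    u <- unitv(ax$V)
    for (i in hd$all_ca) {
      w <- X[i, ] - ax$M
      radial <- w - sum(w * u) * u
      X[i, ] <- X[i, ] + 0.5 * unitv(radial)
    }
  }
  moved <- set_coords(b$frame, X)
  expect_equal(rmsd_frames(moved, b$frame, b$bundle$helical_sel), 0.5,
               tolerance = 1e-10)
  expect_equal(helical_rmsd(moved, b$ref, b$bundle), 0.5, tolerance = 2e-3)
  # fitted RMSD never exceeds the unfitted one
  noisy <- set_coords(b$frame, b$frame$coords +
                        matrix(stats::rnorm(length(b$frame$coords), sd = 0.4),
                               ncol = 3))
  expect_lte(helical_rmsd(noisy, b$ref, b$bundle),
             rmsd_frames(noisy, b$frame, b$bundle$helical_sel))
})

test_that("ideal helix hydrogen-bond counts match construction", {
  for (n in c(12L, 15L, 20L)) {
    h <- build_ideal_helix(ideal_helix_params(n))
    bb <- bundle_definition(helices = list(), helical_sel = 1L,
                            hbond_residues = unique(h$atoms[, c("chain", "resno")]))
    expect_identical(count_helical_hbonds(h, bb), n - 4L)
    # axial stretch x1.3 breaks every i -> i+4 bond
    stretched <- set_coords(h, cbind(h$coords[, 1:2], h$coords[, 3] * 1.3))
    expect_identical(count_helical_hbonds(stretched, bb), 0L)
    # invariant under global rigid motion
    moved <- apply_transform(random_rigid_motion(), h)
    expect_identical(count_helical_hbonds(moved, bb), n - 4L)
  }
})

test_that("missing backbone atoms are skipped loudly", {
  h <- build_ideal_helix(ideal_helix_params(12))
  keep <- !(h$atoms$resno == 5 & h$atoms$elety == "N")
  pruned <- mdframe(h$coords[keep, ], h$atoms[keep, ])
  bb <- bundle_definition(helices = list(), helical_sel = 1L,
                          hbond_residues = unique(pruned$atoms[, c("chain", "resno")]))
  expect_warning(n <- count_helical_hbonds(pruned, bb), "skipped")
  expect_identical(n, 7L)
})

test_that("Crick deviation is zero for the canonical fixture and shifts with rotation", {
  b <- make_kih_bundle()
  prof <- crick_deviation_profile(b$frame, b$bundle)
  expect_lt(max(abs(prof$deviation)), 1e-6)
  expect_setequal(unique(prof$heptad), letters[1:7])
  # +26 degree axial rotation of one helix shifts only its profile, by the
  # applied angle
  f2 <- inject_motion(b$frame, b$bundle, b$ref, rotation = c(N1 = 26))
  p2 <- crick_deviation_profile(f2, b$bundle)
  shift <- p2$deviation - prof$deviation
  expect_true(all(abs(shift[p2$helix == "N1"] - 26) < 3))
  expect_lt(max(abs(shift[p2$helix != "N1"])), 3)
  # invariant under a global rotation of the bundle
  moved <- apply_transform(random_rigid_motion(), b$frame)
  pm <- crick_deviation_profile(moved, b$bundle)
  expect_equal(pm$deviation, prof$deviation, tolerance = 1e-6)
})

test_that("piston states classify per the four-state taxonomy", {
  expect_identical(as.character(classify_piston_state(c(0, 0, 0, 0))), "P00")
  expect_identical(as.character(classify_piston_state(c(1.0, 0, 0, -1.5))), "P10")
  expect_identical(as.character(classify_piston_state(c(0, -1.5, 1.0, 0))), "P01")
  expect_identical(as.character(classify_piston_state(c(1.0, -1.2, 1.0, -1.5))), "P11")
  oor <- classify_piston_state(c(4.5, 0, 0, -4.5))
  expect_identical(as.character(oor), "OTHER")
  expect_true(attr(oor, "out_of_register"))
  expect_false(attr(classify_piston_state(c(1.0, 0, 0, -1.5)), "out_of_register"))
  expect_error(classify_piston_state(c(1, NA, 0, 0)), "finite")
  expect_error(classify_piston_state(c(1, 2, 3)), "four")
})

test_that("classification is symmetric under monomer swap", {
  swap <- c(P00 = "P00", P10 = "P01", P01 = "P10", P11 = "P11",
            OTHER = "OTHER")
  set.seed(11)
  for (k in 1:1000) {
    z <- stats::runif(4, -4, 4)
    a <- as.character(classify_piston_state(z))
    bsw <- as.character(classify_piston_state(z[c(3, 4, 1, 2)]))
    expect_identical(bsw, swap[[a]])
  }
})

test_that("negative-log-probability surfaces have the expected shapes", {
  # all samples in one bin: constant-zero surface, flagged low-information
  s <- neg_log_probability_surface(rep(0.5, 100),
                                   limits = list(c(0, 1)), bins = 10)
  expect_true(s$low_information)
  expect_equal(s$values[!is.na(s$values)], 0)
  expect_true(all(is.na(s$values[-6])))

  # standard normal: quadratic profile with curvature 1/2
  set.seed(5)
  x <- stats::rnorm(1e5)
  s1 <- neg_log_probability_surface(x, bins = 40, limits = list(c(-2.5, 2.5)))
  mids <- s1$mids[[1]]
  fit <- stats::lm(s1$values ~ poly(mids, 2, raw = TRUE),
                   weights = exp(-s1$values))
  expect_equal(unname(stats::coef(fit)[3]), 0.5, tolerance = 0.05)

  # two-cluster series: two minima at the cluster centers
  y <- c(stats::rnorm(5e4, -1.2, 0.15), stats::rnorm(5e4, 0.9, 0.15))
  s2 <- neg_log_probability_surface(y, bins = 50)
  m <- s2$mids[[1]]
  v <- s2$values
  locmin <- which(diff(sign(diff(v))) == 2) + 1
  locmin <- locmin[order(v[locmin])][1:2]
  binw <- diff(m[1:2])
  expect_true(any(abs(m[locmin] + 1.2) < binw))
  expect_true(any(abs(m[locmin] - 0.9) < binw))

  # 2D surface integrates the weights
  xy <- cbind(stats::rnorm(2e4), stats::rnorm(2e4))
  s3 <- neg_log_probability_surface(xy, bins = c(20, 25))
  expect_equal(dim(s3$values), c(20L, 25L))
  expect_equal(min(s3$values, na.rm = TRUE), 0)
})
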