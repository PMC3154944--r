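test_that("orientation vectors come from window C-alpha midpoints", {
  # single-atom windows: vector is the plain coordinate difference
  xyz <- rbind(c(0, 0, 0), c(1, 2, 2), c(5, 5, 5), c(6, 5, 8))
  m <- model_from_xyz(xyz, resid = c(10, 20, 30, 40))
  cfg <- orientation_config(v1_windows = list(c(10, 10), c(20, 20)),
                            v2_windows = list(c(30, 30), c(40, 40)))
  v <- compute_vectors(m, cfg)
  expect_equal(v$v1, c(1, 2, 2), ignore_attr = TRUE)
  expect_equal(v$v2, c(1, 0, 3), ignore_attr = TRUE)
  # multi-atom windows equal an independent mean-of-points oracle
  pr <- build_toy_anchored_protein()
  vv <- compute_vectors(pr)
  a <- pr$atoms
  mid <- function(r1, r2) colMeans(as.matrix(
    a[a$residue_seq >= r1 & a$residue_seq <= r2 & a$atom_name == "CA",
      c("x", "y", "z")]))
  expect_equal(vv$v1, mid(312, 316) - mid(285, 289), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a missing window C-alpha is reported with the residue number
  cfg_bad <- orientation_config(v1_windows = list(c(10, 11), c(20, 20)),
                                v2_windows = list(c(30, 30), c(40, 40)))
  expect_error(compute_vectors(m, cfg_bad), "11")
})

test_that("orientation angles match closed forms and the acos oracle", {
  expect_equal(orientation_angles(c(0, 0, 1), c(1, 0, 0)),
               c(alpha = 0, beta = 90))
  expect_equal(orientation_angles(c(1, 0, 0), c(0, 0, -1)),
               c(alpha = 90, beta = 180))
  expect_equal(orientation_angles(c(1, 0, 1), c(0, 1, 1))[["alpha"]], 45,
               tolerance = 1e-9)
  set.seed(5)
  for (i in 1:20) {
    v1 <- rnorm(3); v2 <- rnorm(3)
    ang <- orientation_angles(v1, v2)
    expect_equal(ang[["alpha"]],
                 acos(v1[3] / sqrt(sum(v1^2))) * 180 / pi,
                 tolerance = 1e-9)
    expect_equal(ang[["beta"]],
                 acos(v2[3] / sqrt(sum(v2^2))) * 180 / pi,
                 tolerance = 1e-9)
  }
  expect_error(orientation_angles(c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("signed COM z-projection is mass-weighted", {
  # point protein at z = 40 over a membrane centered at z = 0
  prot <- data.frame(atom_id = 1, atom_name = "CA", element = "C",
                     residue_seq = 1, residue_name = "ALA", chain = "A",
                     x = 0, y = 0, z = 40)
  lip <- data.frame(atom_id = 2:3, atom_name = "T1", element = "C",
                    residue_seq = 2:3, residue_name = "PLP", chain = "L",
                    x = 0, y = 0, z = c(-5, 5))
  m <- structure_model(rbind(prot, lip))
  expect_equal(com_distance_z(m), 40)
  # heterogeneous masses: equals the hand-computed weighted mean
  lip2 <- lip
  lip2$element <- c("P", "C")  # 30.974 vs 12.011
  m2 <- structure_model(rbind(prot, lip2))
  wm <- sum(c(30.974, 12.011) * c(-5, 5)) / (30.974 + 12.011)
  expect_equal(com_distance_z(m2), 40 - wm, tolerance = 1e-6)
  expect_gt(com_distance_z(m2, euclidean = TRUE), 0)
  expect_error(com_distance_z(m, protein = "resname XXX"), "empty")
})

test_that("helix tilt is exact on ideal helices and equivariant", {
  pr <- build_toy_anchored_protein()
  expect_lt(helix_tilt(pr, c(1, 22)), 1e-6)
  # rotating the helix 30 degrees about x gives exactly 30
  rot30 <- rbind(c(1, 0, 0),
                 c(0, cos(pi / 6), -sin(pi / 6)),
                 c(0, sin(pi / 6), cos(pi / 6)))
  pr30 <- set_coords(pr, coords(pr) %*% t(rot30))
  expect_equal(helix_tilt(pr30, c(1, 22)), 30, tolerance = 1e-6)
  # collinear C-alpha: the line itself is the axis
  line <- model_from_xyz(cbind(0, 0, seq(0, 30, by = 2)))
  expect_lt(helix_tilt(line, c(1, 16)), 1e-9)
  expect_error(helix_tilt(line, c(1, 3)), ">= 4")
})

test_that("pca helix axis matches a total-least-squares oracle", {
  set.seed(17)
  pr <- build_toy_anchored_protein()
  noisy <- set_coords(pr, coords(pr) + rnorm(3 * nrow(pr$atoms), 0, 0.2))
  t_pca <- helix_tilt(noisy, c(1, 22), method = "pca")
  # oracle: smallest-residual line through the C-alpha cloud via SVD
  rows <- which(noisy$atoms$residue_seq <= 22 &
                  noisy$atoms$atom_name == "CA")
  xyz <- coords(noisy)[rows, ]
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))
  axis <- sv$v[, 1]
  t_oracle <- acos(abs(axis[3])) * 180 / pi
  expect_equal(t_pca, t_oracle, tolerance = 1e-9)
  # the default estimator stays near the truth (0) under coordinate
  # noise; its second differences amplify noise, so the band is wider
  expect_lt(helix_tilt(noisy, c(1, 22)), 3)
})

test_that("heme tilt is the plane-plane dihedral folded into [0, 90]", {
  pr <- build_toy_anchored_protein()
  expect_equal(heme_tilt(pr), 0, tolerance = 1e-9)
  rot90 <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  expect_equal(heme_tilt(set_coords(pr, coords(pr) %*% t(rot90))), 90,
               tolerance = 1e-6)
  # arbitrary pose: equals the cross-product normal oracle
  set.seed(23)
  R <- random_rotation()
  prR <- set_coords(pr, coords(pr) %*% t(R))
  a <- prR$atoms
  hx <- function(nm) unlist(a[a$role == "heme" & a$atom_name == nm,
                              c("x", "y", "z")])
  nrm <- c((hx("NC") - hx("NA"))[2] * (hx("ND") - hx("NB"))[3] -
             (hx("NC") - hx("NA"))[3] * (hx("ND") - hx("NB"))[2],
           (hx("NC") - hx("NA"))[3] * (hx("ND") - hx("NB"))[1] -
             (hx("NC") - hx("NA"))[1] * (hx("ND") - hx("NB"))[3],
           (hx("NC") - hx("NA"))[1] * (hx("ND") - hx("NB"))[2] -
             (hx("NC") - hx("NA"))[2] * (hx("ND") - hx("NB"))[1])
  expected <- acos(abs(nrm[3]) / sqrt(sum(nrm^2))) * 180 / pi
  expected <- unname(ifelse(expected > 90, 180 - expected, expected))
  expect_equal(heme_tilt(prR), expected, tolerance = 1e-6)
})

test_that("height above membrane uses max-z minus head-group mean", {
  sys <- toy_system(nx = 3, ny = 3)
  a <- sys$atoms
  top <- max(a$z[a$role %in% "protein"])
  heads <- a$z[a$role == "lipid" & a$atom_name %in% c("H1", "H2") &
                 a$z > 0]
  expect_equal(height_above_membrane(sys), top - mean(heads),
               tolerance = 1e-9)
  # protein fully below the plane: negative, no error
  low <- sys
  pr_rows <- low$atoms$role == "protein"
  low$atoms$z[pr_rows] <- low$atoms$z[pr_rows] - 200
  expect_lt(height_above_membrane(low), 0)
})

test_that("histogram peaks recover generating modes and select frames", {
  # constant records: frame 1, peaks equal the constants
  rec <- data.frame(frame = 1:20, d = 39.5, alpha = 100, beta = 123)
  sel <- histogram_peak_select(rec)
  expect_equal(sel$frame, 1)
  expect_equal(unname(sel$peaks), c(39.5, 100, 123), tolerance = 1e-9)
  # noisy records around known modes: peaks within one bin
  set.seed(3)
  rec2 <- data.frame(frame = 1:5000, d = rnorm(5000, 39.5, 2.5),
                     alpha = rnorm(5000, 100, 9),
                     beta = rnorm(5000, 123, 8))
  sel2 <- histogram_peak_select(rec2)
  expect_lt(abs(sel2$peaks[["alpha"]] - 100), 1)
  expect_lt(abs(sel2$peaks[["beta"]] - 123), 1)
  expect_lt(abs(sel2$peaks[["d"]] - 39.5), 0.5)
  # the selected frame honours the 1% multiplicative window
  row <- rec2[rec2$frame == sel2$frame, ]
  expect_true(all(abs(c(row$d, row$alpha, row$beta) - sel2$peaks) <=
                    0.01 * abs(sel2$peaks)))
  # zero window on continuous data: no qualifying frame is an error
  expect_error(histogram_peak_select(rec2, window_frac = 0), "no frame")
  # last-frame variant picks a later frame than the first-frame variant
  sel_last <- histogram_peak_select(rec2, which = "last")
  expect_gte(sel_last$frame, sel2$frame)
})

test_that("angles are invariant under translation and z-rotation", {
  sys <- toy_system(nx = 2, ny = 2)
  rb <- generate_rigid_body_trajectory(sys, nframes = 1, seed = 4)
  fm <- frame_model(rb$trajectory, 1)
  v0 <- compute_vectors(fm)
  a0 <- orientation_angles(v0$v1, v0$v2)
  shifted <- set_coords(fm, sweep(coords(fm), 2, c(7, -4, 13), "+"))
  vs <- compute_vectors(shifted)
  expect_equal(orientation_angles(vs$v1, vs$v2), a0, tolerance = 1e-9)
  th <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotz <- set_coords(fm, coords(fm) %*% t(Rz))
  vr <- compute_vectors(rotz)
  expect_equal(orientation_angles(vr$v1, vr$v2), a0, tolerance = 1e-9)
  # tilts are invariant under in-plane translation of the membrane
  lip <- fm$atoms$role == "lipid"
  fm2 <- fm
  fm2$atoms$x[lip] <- fm2$atoms$x[lip] + 25
  expect_equal(heme_tilt(fm2), heme_tilt(fm), tolerance = 1e-12)
  expect_equal(helix_tilt(fm2, c(1, 22)), helix_tilt(fm, c(1, 22)),
               tolerance = 1e-12)
})

test_that("internal-dynamics control shows near-zero angle variance", {
  sys <- toy_system(nx = 2, ny = 2)
  # rigid-body-only motion: after superposition all deviations vanish
  rb <- generate_rigid_body_trajectory(
    sys, schedule = list(d = 39.5, alpha = 100, beta = 123,
                         sigma_d = 0.5, sigma_alpha = 1.5,
                         sigma_beta = 1.5),
    nframes = 60, seed = 6)
  avc <- angle_variance_control(rb$trajectory, window_frac = 0.03)
  expect_lt(max(abs(avc$dalpha)), 1e-6)
  expect_lt(max(abs(avc$dbeta)), 1e-6)
  expect_true(attr(avc, "reference_frame") %in% 1:60)
})
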