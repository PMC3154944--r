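test_that("cg_map places beads at heavy-atom centroids", {
  # 4 heavy atoms at tetrahedron corners -> one bead at the centroid
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- model_from_xyz(tet, resname = "GLY", atom_name = c("N", "CA", "C", "O"),
                      resid = 1, element = c("N", "C", "C", "O"))
  cg <- cg_map(m, list(GLY = list(BB = c("N", "CA", "C", "O"))))
  expect_equal(unlist(cg[1, c("x", "y", "z")]), colMeans(tet),
               tolerance = 1e-12, ignore_attr = TRUE)
  # hydrogens do not move the bead
  mh <- model_from_xyz(rbind(tet, c(9, 9, 9)), resname = "GLY",
                       atom_name = c("N", "CA", "C", "O", "H"),
                       resid = 1, element = c("N", "C", "C", "O", "H"))
  cgh <- cg_map(mh, list(GLY = list(BB = c("N", "CA", "C", "O", "H"))))
  expect_equal(unlist(cgh[1, c("x", "y", "z")]), colMeans(tet),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(cg_map(m, list(ALA = list(BB = "CA"))), "GLY")
})

test_that("cg_map equals an independent per-atom accumulation oracle", {
  pr <- build_toy_anchored_protein()
  cg <- cg_map(pr, protein_cg_mapping(), roles = "protein")
  a <- pr$atoms[pr$atoms$role == "protein" & pr$atoms$element != "H", ]
  for (i in sample(nrow(cg), 25)) {
    res <- a[a$residue_seq == cg$residue_seq[i], ]
    members <- if (cg$bead_name[i] == "BB")
      res[res$atom_name %in% c("N", "CA", "C", "O"), ]
    else res[!(res$atom_name %in% c("N", "CA", "C", "O")), ]
    expect_equal(unlist(cg[i, c("x", "y", "z")]),
                 colMeans(as.matrix(members[, c("x", "y", "z")])),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("elastic network uses a strict 7 A cutoff", {
  two <- function(dist) {
    m <- model_from_xyz(rbind(c(0, 0, 0), c(dist, 0, 0)), resname = "ALA",
                        atom_name = "CA", resid = 1:2)
    cg_map(m, list(ALA = list(BB = "CA")))
  }
  expect_equal(nrow(build_elastic_network(two(6.9))), 1)
  expect_equal(nrow(build_elastic_network(two(7.1))), 0)
  expect_equal(nrow(build_elastic_network(two(7.0))), 0)  # ties excluded
  expect_equal(build_elastic_network(two(6.9))$rest_length, 6.9,
               tolerance = 1e-9)
})

test_that("linker residues are decoupled from the elastic network", {
  pr <- build_toy_anchored_protein()
  cg <- cg_map(pr, protein_cg_mapping(), roles = "protein")
  net <- build_elastic_network(cg, excluded = c(23, 37))
  expect_gt(nrow(net), 0)
  expect_equal(sum(net$residue_i %in% 23:37 | net$residue_j %in% 23:37), 0)
  # without exclusion, the linker does receive springs
  net0 <- build_elastic_network(cg)
  expect_gt(sum(net0$residue_i %in% 23:37 | net0$residue_j %in% 23:37), 0)
  expect_equal(attr(net, "k"), 10.75)
})

test_that("elastic network equals the O(n^2) pairwise-distance oracle", {
  set.seed(41)
  xyz <- matrix(rnorm(50 * 3, sd = 4), ncol = 3)
  m <- model_from_xyz(xyz, resname = "ALA", atom_name = "CA")
  cg <- cg_map(m, list(ALA = list(BB = "CA")))
  net <- build_elastic_network(cg)
  oracle <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (dij < 7) {
      oracle <- oracle + 1
      row <- net[net$residue_i == i & net$residue_j == j, ]
      expect_equal(nrow(row), 1)
      expect_equal(row$rest_length, dij, tolerance = 1e-9)
    }
  }
  expect_equal(nrow(net), oracle)
})

test_that("randomize_linker preserves rigid-body internal geometry", {
  sys <- toy_system(nx = 4, ny = 4)
  confs <- randomize_linker(sys, n_conformers = 3, seed = 7)
  a <- sys$atoms
  body <- which(a$role %in% c("protein", "heme") & a$residue_seq > 37)
  anchor <- which(a$role == "protein" & a$residue_seq < 23)
  d0 <- stats::dist(coords(sys)[body, ])
  for (cf in confs) {
    # body internal distances exact (pure rigid motion)
    expect_equal(as.vector(stats::dist(coords(cf)[body, ])),
                 as.vector(d0), tolerance = 1e-9)
    # anchor and membrane untouched
    expect_equal(coords(cf)[anchor, ], coords(sys)[anchor, ],
                 ignore_attr = TRUE)
    expect_equal(coords(cf)[a$role == "lipid", ],
                 coords(sys)[a$role == "lipid", ], ignore_attr = TRUE)
    # clash-free against anchor + membrane
    dmin <- min(as.matrix(stats::dist(rbind(
      coords(cf)[body, ],
      coords(cf)[c(anchor, which(a$role == "lipid")), ])))[
        seq_along(body), -seq_along(body)])
    expect_gte(dmin, 3.0)
  }
})

test_that("12 linker conformers span a wide range of orientations", {
  sys <- toy_system(nx = 4, ny = 4)
  confs <- randomize_linker(sys, n_conformers = 12, seed = 5)
  alphas <- vapply(confs, function(cf) {
    v <- compute_vectors(cf)
    orientation_angles(v$v1, v$v2)[["alpha"]]
  }, numeric(1))
  expect_gte(diff(range(alphas)), 60)
})

test_that("backmapping recovers library conformers exactly", {
  lib <- build_lipid_template_library(60, seed = 3)
  k <- 7
  cg <- cg_map(lib$conformers[[k]], lipid_cg_mapping(), roles = "lipid",
               backbone_beads = character(0))
  bm <- backmap_lipid(cg, lib)
  expect_equal(attr(bm, "conformer"), k)
  expect_lt(attr(bm, "rmsd"), 1e-9)
  expect_lt(conversion_rmsd(cg, bm), 1e-9)
  # rigid invariance: arbitrary rotation + translation, still RMSD 0
  set.seed(21)
  R <- random_rotation()
  cg2 <- cg
  cg2[, c("x", "y", "z")] <- as.matrix(cg[, c("x", "y", "z")]) %*% t(R) +
    matrix(c(5, -3, 11), nrow(cg), 3, byrow = TRUE)
  bm2 <- backmap_lipid(cg2, lib)
  expect_lt(attr(bm2, "rmsd"), 1e-9)
})

test_that("backmapping equals the exhaustive-search oracle on noisy beads", {
  lib <- build_lipid_template_library(50, seed = 4)
  set.seed(31)
  cg <- cg_map(lib$conformers[[12]], lipid_cg_mapping(), roles = "lipid",
               backbone_beads = character(0))
  cg[, c("x", "y", "z")] <- as.matrix(cg[, c("x", "y", "z")]) +
    rnorm(3 * nrow(cg), 0, 0.3)
  bm <- backmap_lipid(cg, lib)
  target <- as.matrix(cg[, c("x", "y", "z")])
  oracle <- vapply(lib$bead_centroids, oracle_fit_rmsd, numeric(1),
                   B = target)
  expect_equal(attr(bm, "rmsd"), min(oracle), tolerance = 1e-9)
  expect_error(backmap_lipid(cg[-1, ], lib), "topology")
})

test_that("conversion RMSD has its closed forms and oracle", {
  lib <- build_lipid_template_library(5, seed = 6)
  m <- lib$conformers[[2]]
  cg <- cg_map(m, lipid_cg_mapping(), roles = "lipid",
               backbone_beads = character(0))
  expect_equal(conversion_rmsd(cg, m), 0, tolerance = 1e-12)
  # uniform 1 A x-offset of the molecule -> RMSD exactly 1
  m2 <- m
  m2$atoms$x <- m2$atoms$x + 1
  expect_equal(conversion_rmsd(cg, m2), 1.0, tolerance = 1e-9)
  # random case: equals an independent per-bead accumulation
  set.seed(8)
  m3 <- set_coords(m, coords(m) + rnorm(3 * nrow(m$atoms), 0, 0.4))
  map <- lipid_cg_mapping()$TPL
  a3 <- m3$atoms
  dev2 <- vapply(names(map), function(bn) {
    rows <- a3$atom_name %in% map[[bn]]
    b <- colMeans(as.matrix(a3[rows, c("x", "y", "z")]))
    sum((unlist(cg[cg$bead_name == bn, c("x", "y", "z")]) - b)^2)
  }, numeric(1))
  expect_equal(conversion_rmsd(cg, m3), sqrt(mean(dev2)),
               tolerance = 1e-9)
  # per-part breakdown covers head/middle/tail
  pp <- conversion_rmsd(cg, m3, by_part = TRUE)
  expect_named(pp, c("all", "head", "middle", "tail"))
})

test_that("map -> perturb -> backmap round trip stays under 1.5 A", {
  lib <- build_lipid_template_library(50, seed = 9)
  set.seed(10)
  worst <- 0
  for (k in seq(1, 50, by = 2)) {
    cg <- cg_map(lib$conformers[[k]], lipid_cg_mapping(), roles = "lipid",
                 backbone_beads = character(0))
    cg[, c("x", "y", "z")] <- as.matrix(cg[, c("x", "y", "z")]) +
      rnorm(3 * nrow(cg), 0, 0.5)
    bm <- backmap_lipid(cg, lib)
    worst <- max(worst, conversion_rmsd(cg, bm))
  }
  expect_lt(worst, 1.5)
})
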