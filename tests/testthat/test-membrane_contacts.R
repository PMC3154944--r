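# helper: protein residues at prescribed z positions over a toy bilayer
peptide_at_z <- function(zs, resname = "LEU") {
  bl <- build_toy_bilayer(4, 4, 8, seed = 2)
  prot <- data.frame(
    atom_id = seq_along(zs), atom_name = "CA", element = "C",
    residue_seq = seq_along(zs), residue_name = rep_len(resname, length(zs)),
    chain = "A", x = 100, y = 100, z = zs, stringsAsFactors = FALSE)
  combine_systems(structure_model(prot), bl)
}

test_that("frame geometry splits leaflets and regions consistently", {
  sys <- toy_system(nx = 4, ny = 4)
  g <- frame_geometry(sys)
  expect_lt(abs(g$midplane), 0.5)
  expect_gt(g$upper_head_z, 14)
  expect_lt(g$lower_head_z, -14)
  expect_equal(sort(unique(g$leaflet)), c("lower", "upper"))
  expect_equal(sum(g$leaflet == "upper"), 16)
  # translating the bilayer translates the regions equally
  sh <- sys
  sh$atoms$z <- sh$atoms$z + 11
  g2 <- frame_geometry(sh)
  expect_equal(g2$upper_head_z, g$upper_head_z + 11, tolerance = 1e-9)
  expect_equal(g2$midplane, g$midplane + 11, tolerance = 1e-9)
  # a single leaflet is a geometry error
  up <- sys
  up$atoms <- up$atoms[up$atoms$role != "lipid" | up$atoms$z > 0, ]
  expect_error(frame_geometry(up), "leaflet")
})

test_that("residue regions and location strings follow the z-slabs", {
  m <- peptide_at_z(c(0, 5, 16, 40))
  g <- frame_geometry(m)
  expect_equal(residue_region(m, 1, g), "M")
  expect_equal(residue_region(m, 3, g), "HG")
  expect_equal(residue_region(m, 4, g), "C")
  # N-terminus in the membrane, C-terminus in the cytosol
  mhgc <- peptide_at_z(c(0, 2, 16, 17, 40, 45))
  gg <- frame_geometry(mhgc)
  expect_equal(peptide_location_string(mhgc, c(1, 6), gg), "M-HG-C")
  # revisits are kept in order
  mhgm <- peptide_at_z(c(0, 16, 2))
  expect_equal(peptide_location_string(mhgm, c(1, 3), frame_geometry(mhgm)),
               "M-HG-M")
  allc <- peptide_at_z(c(40, 41, 44))
  expect_equal(peptide_location_string(allc, c(1, 3), frame_geometry(allc)),
               "C")
  # every residue falls in exactly one of M / HG / C
  sys <- toy_system(nx = 4, ny = 4)
  g3 <- frame_geometry(sys)
  regs <- vapply(unique(sys$atoms$residue_seq[sys$atoms$role == "protein"]),
                 function(r) residue_region(sys, r, g3), character(1))
  expect_true(all(regs %in% c("M", "HG", "C")))
})

test_that("contacts use the strict 4 A heavy-atom rule", {
  bl <- build_toy_bilayer(2, 2, 8, seed = 3)
  head_atom <- bl$atoms[bl$atoms$atom_name == "H1" & bl$atoms$z > 0, ][1, ]
  place_leu <- function(gap) {
    prot <- data.frame(atom_id = 1, atom_name = "CD1", element = "C",
                       residue_seq = 1, residue_name = "LEU", chain = "A",
                       x = head_atom$x, y = head_atom$y,
                       z = head_atom$z + gap, stringsAsFactors = FALSE)
    combine_systems(structure_model(prot), bl)
  }
  ct39 <- count_contacts(place_leu(3.9))
  expect_equal(unname(ct39$counts["hydrophobic", "head"]), 1)
  expect_equal(sum(ct39$counts), 1)
  expect_equal(sum(count_contacts(place_leu(4.1))$counts), 0)
  expect_equal(sum(count_contacts(place_leu(4.0))$counts), 0)
})

test_that("contact tables equal a brute-force double-loop oracle", {
  set.seed(12)
  # random 500-atom frame: 60 protein residues + lipids
  nres <- 60
  resnames <- sample(c("LEU", "PHE", "SER", "ASP", "GLY", "PRO", "ALA",
                       "HIS"), nres, replace = TRUE)
  prot <- data.frame(
    atom_id = seq_len(nres * 3),
    atom_name = rep(c("CA", "CB", "CG"), nres), element = "C",
    residue_seq = rep(seq_len(nres), each = 3),
    residue_name = rep(resnames, each = 3), chain = "A",
    x = runif(nres * 3, 0, 30), y = runif(nres * 3, 0, 30),
    z = runif(nres * 3, -25, 25), stringsAsFactors = FALSE)
  bl <- build_toy_bilayer(4, 4, 8, seed = 5)
  m <- combine_systems(structure_model(prot), bl)
  ct <- count_contacts(m)
  parts <- lipid_part_config("toy")
  a <- m$atoms
  cat31 <- c(L = "hydrophobic", I = "hydrophobic", V = "hydrophobic",
             F = "aromatic", Y = "aromatic", W = "aromatic",
             S = "hydrophilic", T = "hydrophilic", N = "hydrophilic",
             Q = "hydrophilic", D = "charged", E = "charged",
             R = "charged", K = "charged", G = "glycine", P = "proline")
  aa1 <- c(LEU = "L", PHE = "F", SER = "S", ASP = "D", GLY = "G",
           PRO = "P", ALA = "A", HIS = "H")
  oracle <- matrix(0L, 6, 3,
                   dimnames = list(c("hydrophobic", "aromatic",
                                     "hydrophilic", "charged", "glycine",
                                     "proline"),
                                   c("head", "middle", "tail")))
  for (r in seq_len(nres)) {
    aa <- aa1[[resnames[r]]]
    if (aa %in% c("A", "H")) next
    pxyz <- as.matrix(a[a$residue_seq == r & a$role == "protein",
                        c("x", "y", "z")])
    for (p in names(parts)) {
      lxyz <- as.matrix(a[a$role == "lipid" &
                            a$atom_name %in% parts[[p]],
                          c("x", "y", "z")])
      hit <- FALSE
      for (i in seq_len(nrow(pxyz))) for (j in seq_len(nrow(lxyz))) {
        if (sqrt(sum((pxyz[i, ] - lxyz[j, ])^2)) < 4) hit <- TRUE
      }
      if (hit) oracle[cat31[[aa]], p] <- oracle[cat31[[aa]], p] + 1L
    }
  }
  expect_equal(ct$counts, oracle)
  # monotone in cutoff: 3.5 A contacts are a subset of 4 A contacts
  ct35 <- count_contacts(m, cutoff = 3.5)
  expect_true(all(ct35$counts <= ct$counts))
})

test_that("percent of domain in contact matches hand counts", {
  # protein far above the membrane: 0%
  far <- peptide_at_z(seq(60, 75, length.out = 6))
  tr1 <- trajectory(far, array(coords(far), c(nrow(far$atoms), 3, 1)))
  expect_equal(percent_domain_in_contact(tr1, c(1, 6))$mean, 0)
  # half the residues touching the head groups
  g <- frame_geometry(far)
  half <- peptide_at_z(c(0, 2, 4, 60, 62, 64))
  # place the first three right on lipid atoms to guarantee contact
  lip1 <- half$atoms[half$atoms$role == "lipid", ][1:3, ]
  pr <- which(half$atoms$role == "protein")[1:3]
  half$atoms$x[pr] <- lip1$x + 1
  half$atoms$y[pr] <- lip1$y
  half$atoms$z[pr] <- lip1$z
  tr2 <- trajectory(half, array(coords(half), c(nrow(half$atoms), 3, 1)))
  expect_equal(percent_domain_in_contact(tr2, c(1, 6))$mean, 50)
})

test_that("area per lipid is the box area over the leaflet count", {
  bl <- build_toy_bilayer(8, 8, 8, seed = 1)
  expect_equal(area_per_lipid(bl, "upper"), 64.00)
  expect_equal(area_per_lipid(bl, "lower"), 64.00)
  # halving the spacing quarters the area per lipid
  bl2 <- build_toy_bilayer(8, 8, 4, seed = 1)
  expect_equal(area_per_lipid(bl2, "upper"), 16.00)
  nobox <- bl
  nobox$box <- NULL
  expect_error(area_per_lipid(nobox), "box")
})

test_that("gate ring to head-group z-distance is signed", {
  sys <- toy_system(nx = 4, ny = 4)
  g <- frame_geometry(sys)
  gd <- gate_membrane_distance(sys)
  expect_named(gd, c("F100", "F114", "F476"))
  ring_z <- ring_center(sys, 100)[3]
  expect_equal(unname(gd["F100"]), ring_z - g$upper_head_z,
               tolerance = 1e-9)
  # a ring 5 A below the reference plane reads -5
  low <- sys
  ring_rows <- low$atoms$residue_seq == 100 & low$atoms$role == "protein"
  low$atoms$z[ring_rows] <- low$atoms$z[ring_rows] -
    (ring_z - g$upper_head_z) - 5
  expect_equal(unname(gate_membrane_distance(low)["F100"]), -5,
               tolerance = 1e-9)
})
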