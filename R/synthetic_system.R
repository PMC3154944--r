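# Synthetic study systems: toy bilayer, anchored protein with annotated
# features, rigid-body orientation trajectories with exact ground truth,
# Gaussian-fluctuation trajectories, tilted-helix pose sets and cavity
# fixtures with known tunnel bottlenecks.
#
# Every generator is a pure function of its parameters and seed.

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# ideal alpha-helix backbone (N, CA, C per residue), axis along +z,
# CA radius 2.3 A, 100 deg twist, 1.5 A rise per residue, centered on z=0
.ideal_helix <- function(n_res, first_resid = 1, resname = "LEU",
                         chain = "A") {
  twist <- 100 * pi / 180
  rise <- 1.5
  geom <- list(N = c(r = 1.60, dphi = -28 * pi / 180, dz = -0.60),
               CA = c(r = 2.30, dphi = 0, dz = 0),
               C = c(r = 1.70, dphi = 26 * pi / 180, dz = 0.45))
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- (i - 1) * twist
    z <- (i - 1) * rise
    for (an in names(geom)) {
      g <- geom[[an]]
      rows[[length(rows) + 1]] <- data.frame(
        atom_name = an, element = substr(an, 1, 1),
        residue_seq = first_resid + i - 1, residue_name = resname,
        chain = chain,
        x = g["r"] * cos(th + g["dphi"]),
        y = g["r"] * sin(th + g["dphi"]),
        z = z + g["dz"], stringsAsFactors = FALSE)
    }
  }
  a <- do.call(rbind, rows)
  a$z <- a$z - mean(range(a$z))
  rownames(a) <- NULL
  a
}

#' Build a toy lipid bilayer
#'
#' Two leaflets of pseudo-lipids on a jittered square grid. Each lipid has
#' six atoms in three z-bands tagged by atom-name prefix: head (H1, H2),
#' middle (M1) and tail (T1-T3), which is all the structure the contact
#' and membrane-geometry analyses require. The bilayer midplane is z = 0;
#' upper-leaflet head groups sit near `z = +head_z`.
#'
#' @param nx,ny lipids per leaflet along x and y (>= 2).
#' @param spacing grid spacing (A); the in-plane box is
#'   `nx*spacing x ny*spacing`, so the constructed area per lipid is
#'   `spacing^2`.
#' @param seed RNG seed (generator is bit-reproducible given the seed).
#' @param head_z unsigned head-group z position (A).
#' @param jitter s.d. of in-plane Gaussian jitter (A).
#' @return `structure_model` with `2*nx*ny` lipids and a recorded box.
#' @export
build_toy_bilayer <- function(nx = 8, ny = 8, spacing = 8, seed = 1,
                              head_z = 17, jitter = 0.4) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  set.seed(seed)
  atom_z <- c(H1 = 17, H2 = 15.5, M1 = 11, T1 = 7.5, T2 = 4.5, T3 = 1.5)
  atom_z <- atom_z * (head_z / 17)
  el <- c(H1 = "N", H2 = "P", M1 = "O", T1 = "C", T2 = "C", T3 = "C")
  grid <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  res <- list()
  rid <- 0
  for (leaf in c(1, -1)) {
    for (g in seq_len(nrow(grid))) {
      rid <- rid + 1
      cx <- grid$ix[g] * spacing + rnorm(1, 0, jitter)
      cy <- grid$iy[g] * spacing + rnorm(1, 0, jitter)
      res[[rid]] <- data.frame(
        atom_name = names(atom_z), element = unname(el),
        residue_seq = rid, residue_name = "PLP", chain = "L",
        x = cx + rnorm(6, 0, jitter / 2),
        y = cy + rnorm(6, 0, jitter / 2),
        z = leaf * atom_z + rnorm(6, 0, jitter / 2),
        stringsAsFactors = FALSE)
    }
  }
  a <- do.call(rbind, res)
  a$atom_id <- seq_len(nrow(a))
  structure_model(a, box = c(nx * spacing, ny * spacing, 6 * head_z))
}

.hex_ring <- function(center, normal = c(0, 0, 1), radius = 1.39) {
  n <- .unit(normal)
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(pracma_cross(ref, n))
  e2 <- pracma_cross(n, e1)
  th <- (0:5) * pi / 3
  t(vapply(th, function(a)
    center + radius * (cos(a) * e1 + sin(a) * e2), numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default feature annotation for the toy anchored protein
#'
#' Residue windows and feature residues follow the numbering used
#' throughout the analyses: orientation vector v1 from residue windows
#' 285-289 to 312-316 (helix I), v2 from 127-131 to 197-201, a
#' transmembrane helix at residues 1-22, a linker at 23-37, the aromatic
#' gate at residues 100/114/476 and a heme proxy.
#'
#' @return named list of feature parameters.
#' @export
toy_protein_params <- function() {
  list(v1_windows = list(c(285, 289), c(312, 316)),
       v2_windows = list(c(127, 131), c(197, 201)),
       tm_helix = c(1, 22), linker = c(23, 37),
       gate = c(100, 114, 476), heme_resid = 999,
       domain = c(38, 499), domain_center = c(0, 0, 40),
       domain_radius = 12, gate_d1 = 5, gate_d2 = 6.5)
}

#' Build a toy membrane-anchored protein with annotated features
#'
#' A rigid assembly designed so every orientation descriptor has an exact,
#' analytically known value: an ideal transmembrane alpha-helix spanning
#' z ~ [-16, 16], an extended linker, and a globular shell
#' (center `domain_center`, radius `domain_radius`) containing
#' (i) the four C-alpha windows defining v1 and v2, placed so that v1 is
#' exactly +z and v2 exactly +x (orthogonal), (ii) three phenylalanine
#' gate residues with planar hexagonal rings, (iii) a planar 4-atom heme
#' proxy (atoms NA/NB/NC/ND, plane parallel to the membrane), and (iv)
#' filler residues cycling through all residue categories used by the
#' contact analysis.
#'
#' @param params feature annotation, see [toy_protein_params()].
#' @return `structure_model` with a `features` attribute recording the
#'   parameters.
#' @export
build_toy_anchored_protein <- function(params = toy_protein_params()) {
  p <- params
  ctr <- p$domain_center
  blocks <- list()
  # transmembrane helix + linker
  tm <- .ideal_helix(p$tm_helix[2] - p$tm_helix[1] + 1,
                     first_resid = p$tm_helix[1])
  blocks$tm <- tm
  # helical linker: its torsion axes are oblique to the chain direction,
  # so dihedral randomization reorients the downstream body effectively
  nl <- p$linker[2] - p$linker[1] + 1
  lk <- .ideal_helix(nl, first_resid = p$linker[1], resname = "GLY")
  lk$z <- lk$z - min(lk$z) + max(tm$z) + 1.5
  blocks$linker <- lk
  # orientation windows: CA atoms with symmetric offsets so window
  # midpoints are exact
  win <- function(range, center, resname = "ALA") {
    k <- range[2] - range[1] + 1
    off <- seq(-1, 1, length.out = k)
    data.frame(atom_name = "CA", element = "C",
               residue_seq = range[1]:range[2], residue_name = resname,
               chain = "A", x = center[1] + off, y = center[2],
               z = center[3], stringsAsFactors = FALSE)
  }
  blocks$w1a <- win(p$v1_windows[[1]], ctr + c(0, 0, -6), "ALA")
  blocks$w1b <- win(p$v1_windows[[2]], ctr + c(0, 0, 6), "ALA")
  blocks$w2a <- win(p$v2_windows[[1]], ctr + c(-6, 0, 0), "SER")
  blocks$w2b <- win(p$v2_windows[[2]], ctr + c(6, 0, 0), "SER")
  # gate phenylalanines: CA + planar hexagonal phenyl ring
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  gate_centers <- list(ctr + c(0, 6, -2),
                       ctr + c(p$gate_d1, 6, -2),
                       ctr + c(-p$gate_d2, 6, -2))
  for (i in 1:3) {
    ring <- .hex_ring(gate_centers[[i]], normal = c(0, 1, 0))
    blocks[[paste0("gate", i)]] <- data.frame(
      atom_name = c("CA", ring_names), element = "C",
      residue_seq = p$gate[i], residue_name = "PHE", chain = "A",
      x = c(gate_centers[[i]][1], ring[, 1]),
      y = c(gate_centers[[i]][2] + 2, ring[, 2]),
      z = c(gate_centers[[i]][3], ring[, 3]), stringsAsFactors = FALSE)
  }
  # heme proxy: NA/NB/NC/ND square (radius 2 A) parallel to the membrane
  hx <- rbind(c(-2, 0, 0), c(0, -2, 0), c(2, 0, 0), c(0, 2, 0))
  hc <- ctr + c(0, -3, -2)
  blocks$heme <- data.frame(
    atom_name = c("NA", "NB", "NC", "ND"), element = "N",
    residue_seq = p$heme_resid, residue_name = "HEM", chain = "A",
    x = hc[1] + hx[, 1], y = hc[2] + hx[, 2], z = hc[3] + hx[, 3],
    stringsAsFactors = FALSE)
  # filler shell residues cycling through the contact categories
  used <- unique(unlist(lapply(blocks, function(b) b$residue_seq)))
  fill_ids <- setdiff(p$domain[1]:p$domain[2], used)
  cyc <- c("LEU", "ILE", "VAL", "PHE", "TYR", "TRP", "SER", "THR", "ASN",
           "GLN", "ASP", "GLU", "ARG", "LYS", "GLY", "PRO")
  sph <- .fibonacci_sphere(length(fill_ids)) * p$domain_radius
  blocks$fill <- data.frame(
    atom_name = "CA", element = "C", residue_seq = fill_ids,
    residue_name = rep(cyc, length.out = length(fill_ids)), chain = "A",
    x = ctr[1] + sph[, 1], y = ctr[2] + sph[, 2], z = ctr[3] + sph[, 3],
    stringsAsFactors = FALSE)
  a <- do.call(rbind, blocks)
  a <- a[order(a$residue_seq, match(a$atom_name,
                                    c("N", "CA", "C", "O", ring_names,
                                      "NA", "NB", "NC", "ND"))), ]
  rownames(a) <- NULL
  a$atom_id <- seq_len(nrow(a))
  # overlapping feature placements are a construction error
  key <- c("w1a", "w1b", "w2a", "w2b", "gate1", "gate2", "gate3", "heme")
  for (i in seq_along(key)) for (j in seq_along(key)) {
    if (i >= j) next
    bi <- as.matrix(blocks[[key[i]]][, c("x", "y", "z")])
    bj <- as.matrix(blocks[[key[j]]][, c("x", "y", "z")])
    d2 <- outer(rowSums(bi^2), rowSums(bj^2), "+") - 2 * bi %*% t(bj)
    if (min(d2) < 0.25)
      stop("construction error: features '", key[i], "' and '", key[j],
           "' overlap")
  }
  m <- structure_model(a)
  attr(m, "features") <- p
  m
}

#' Combine a protein and a bilayer into one system
#'
#' @param protein,bilayer structure models; atom ids are renumbered to
#'   stay unique.
#' @return combined `structure_model` (bilayer box retained).
#' @export
combine_systems <- function(protein, bilayer) {
  a <- rbind(protein$atoms, bilayer$atoms)
  a$atom_id <- seq_len(nrow(a))
  m <- structure_model(a, box = bilayer$box)
  attr(m, "features") <- attr(protein, "features")
  m
}

# orthonormal body frame from v1 (exact) and v2 (Gram-Schmidt)
.body_frame <- function(v1, v2) {
  e1 <- .unit(v1)
  u2 <- v2 - sum(v2 * e1) * e1
  e2 <- .unit(u2)
  cbind(e1, e2, pracma_cross(e1, e2))
}

# target frame with angle(v1,z)=alpha, angle(v2,z)=beta (degrees)
.target_frame <- function(alpha, beta) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  if (sin(a) < abs(cos(b)) - 1e-12) return(NULL)  # infeasible pair
  v1 <- c(sin(a), 0, cos(a))
  ca <- -cos(b) / max(sin(a), 1e-12)
  cb <- sqrt(max(0, 1 - ca^2))
  v2 <- ca * c(cos(a), 0, -sin(a)) + cb * c(0, 1, 0)
  cbind(v1, v2, pracma_cross(v1, v2))
}

.rotz <- function(phi) {
  rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
}

#' Generate a rigid-body orientation trajectory with exact ground truth
#'
#' The protein is posed rigidly each frame so that its orientation
#' descriptors are exactly the scheduled targets plus independent
#' Gaussian noise: the angle of v1 to z equals `alpha`, the angle of v2
#' to z equals `beta` (the toy protein's v1 and v2 are orthogonal by
#' construction, making both exact), and the z-projection of the
#' protein-membrane center-of-mass separation equals `d`. A uniform
#' random spin about z is added each frame (it leaves all three
#' descriptors unchanged). The membrane is static.
#'
#' @param system combined protein+bilayer `structure_model`
#'   (see [combine_systems()]).
#' @param schedule named list with targets `d` (A), `alpha`, `beta`
#'   (degrees) and noise s.d.s `sigma_d`, `sigma_alpha`, `sigma_beta`
#'   (0 for a noise-free trajectory).
#' @param nframes number of frames.
#' @param seed RNG seed.
#' @param config orientation configuration ([orientation_config()]) naming
#'   the residue windows.
#' @param frame_interval frame spacing (ps).
#' @return list with `trajectory` and `truth` (data.frame frame, d,
#'   alpha, beta, clash flag). Frames where the sampled pose would sink
#'   the protein into the membrane tail region are flagged, not altered.
#' @export
generate_rigid_body_trajectory <- function(system,
                                           schedule = list(
                                             d = 39.5, alpha = 100,
                                             beta = 123, sigma_d = 2.5,
                                             sigma_alpha = 9,
                                             sigma_beta = 8),
                                           nframes = 100, seed = 1,
                                           config = orientation_config(),
                                           frame_interval = 150) {
  set.seed(seed)
  atoms <- system$atoms
  prot <- which(atoms$role %in% c("protein", "heme"))
  sel <- .sel_rows(system, config$protein)  # COM selection used by the
  selin <- match(sel, prot)                 # d estimator
  memb <- .sel_rows(system, config$membrane)
  if (!length(prot) || !length(memb) || anyNA(selin))
    stop("system must contain protein and membrane atoms")
  xyz0 <- coords(system)
  mass <- element_mass(atoms$element)
  wsel <- mass[sel] / sum(mass[sel])
  com_m <- colSums(xyz0[memb, , drop = FALSE] *
                     (mass[memb] / sum(mass[memb])))
  v <- compute_vectors(system, config)
  Bref <- .body_frame(v$v1, v$v2)
  com_p0 <- colSums(xyz0[sel, , drop = FALSE] * wsel)
  centered <- sweep(xyz0[prot, , drop = FALSE], 2, com_p0)
  memb_top <- max(xyz0[memb, 3])
  nat <- nrow(xyz0)
  arr <- array(rep(xyz0, nframes), dim = c(nat, 3, nframes))
  truth <- data.frame(frame = seq_len(nframes), d = NA_real_,
                      alpha = NA_real_, beta = NA_real_, clash = FALSE)
  for (f in seq_len(nframes)) {
    repeat {
      al <- schedule$alpha + rnorm(1, 0, schedule$sigma_alpha)
      be <- schedule$beta + rnorm(1, 0, schedule$sigma_beta)
      Btgt <- .target_frame(al, be)
      if (!is.null(Btgt)) break
    }
    dd <- schedule$d + rnorm(1, 0, schedule$sigma_d)
    R <- .rotz(runif(1, 0, 2 * pi)) %*% Btgt %*% t(Bref)
    pr <- centered %*% t(R)
    com_sel <- colSums(pr[selin, , drop = FALSE] * wsel)
    shift <- c(com_p0[1] - com_sel[1], com_p0[2] - com_sel[2],
               com_m[3] + dd - com_sel[3])
    pr <- sweep(pr, 2, shift, "+")
    arr[prot, , f] <- pr
    truth$d[f] <- dd
    truth$alpha[f] <- al
    truth$beta[f] <- be
    truth$clash[f] <- min(pr[, 3]) < memb_top - 2
  }
  tr <- trajectory(system, arr, frame_interval)
  attr(truth, "schedule") <- schedule
  attr(truth, "seed") <- seed
  list(trajectory = tr, truth = truth)
}

#' Generate an isotropic Gaussian fluctuation trajectory
#'
#' Each atom is displaced i.i.d. N(0, sigma^2) per axis about its
#' reference position in every frame, giving per-atom mean squared
#' displacement 3 sigma^2 - the closed-form input for B-factor checks.
#'
#' @param model reference structure_model.
#' @param sigma per-axis displacement s.d. (A), >= 0.
#' @param nframes number of frames.
#' @param seed RNG seed.
#' @param frame_interval frame spacing (ps).
#' @return a `trajectory`.
#' @export
generate_gaussian_fluctuation_trajectory <- function(model, sigma = 0.5,
                                                     nframes = 100,
                                                     seed = 1,
                                                     frame_interval = 150) {
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  xyz0 <- coords(model)
  nat <- nrow(xyz0)
  arr <- array(rep(xyz0, nframes), dim = c(nat, 3, nframes)) +
    array(rnorm(nat * 3 * nframes, 0, sigma), dim = c(nat, 3, nframes))
  trajectory(model, arr, frame_interval)
}

#' Generate rigidly tilted ideal-helix poses with known true inclination
#'
#' Draws true tilt values from N(`tilt_mean`, `tilt_sd`), folds them into
#' [0, 90] degrees, and rigidly rotates an ideal transmembrane helix to
#' that inclination (random azimuth and spin per frame), giving a pose
#' set with exact per-frame ground truth for the tilt estimator.
#'
#' @param n_res helix length in residues.
#' @param tilt_mean,tilt_sd tilt distribution parameters (degrees).
#' @param nframes number of poses.
#' @param seed RNG seed.
#' @return list with `trajectory` and `truth` (data.frame frame, tilt).
#' @export
generate_tilted_helix_trajectory <- function(n_res = 22, tilt_mean = 12,
                                             tilt_sd = 6, nframes = 100,
                                             seed = 1) {
  set.seed(seed)
  a <- .ideal_helix(n_res)
  a$atom_id <- seq_len(nrow(a))
  model <- structure_model(a)
  xyz0 <- coords(model)
  fold <- function(t) {
    t <- abs(t) %% 180
    ifelse(t > 90, 180 - t, t)
  }
  tilt <- fold(rnorm(nframes, tilt_mean, tilt_sd))
  arr <- array(NA_real_, dim = c(nrow(xyz0), 3, nframes))
  for (f in seq_len(nframes)) {
    th <- tilt[f] * pi / 180
    Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
    R <- .rotz(runif(1, 0, 2 * pi)) %*% Ry %*% .rotz(runif(1, 0, 2 * pi))
    arr[, , f] <- xyz0 %*% t(R)
  }
  list(trajectory = trajectory(model, arr, 150),
       truth = data.frame(frame = seq_len(nframes), tilt = tilt))
}

#' Build a hollow cavity fixture with channels of known bottleneck radius
#'
#' Atoms (carbon, vdW 1.7 A) form a closed spherical shell around an
#' internal chamber, pierced by a cylindrical channel along +x whose
#' clearance radius is exactly `bottleneck_radius`; an optional second,
#' narrower channel runs along -x. `blocked = TRUE` plugs the channel(s)
#' with an axial file of atoms (residual leak clearance < 0.5 A). The
#' shell is dense enough to be watertight for any positive probe radius.
#'
#' @param bottleneck_radius channel clearance radius (A), > 0.
#' @param blocked plug the channel(s).
#' @param second_radius optional radius of a second channel along -x.
#' @param shell_radius shell radius (A).
#' @return list (`cavity_fixture`) with `model`, `start_point` (chamber
#'   center) and `tunnels` (data.frame label, entrance x/y/z, radius;
#'   empty when blocked).
#' @export
build_cavity_fixture <- function(bottleneck_radius = 2.0, blocked = FALSE,
                                 second_radius = NULL, shell_radius = 12) {
  rvdw <- 1.7
  if (bottleneck_radius <= 0) stop("bottleneck_radius must be positive")
  if (bottleneck_radius + rvdw > shell_radius / 2)
    stop("construction error: channel radius too large for the shell")
  R <- shell_radius
  n_shell <- round(4 * pi * R^2 / 2.0^2)
  pts <- .fibonacci_sphere(n_shell) * R
  chans <- data.frame(label = "T1", dir = 1, radius = bottleneck_radius,
                      stringsAsFactors = FALSE)
  if (!is.null(second_radius))
    chans <- rbind(chans, data.frame(label = "T2", dir = -1,
                                     radius = second_radius))
  keep <- rep(TRUE, nrow(pts))
  walls <- list()
  plugs <- list()
  for (ci in seq_len(nrow(chans))) {
    a <- chans$radius[ci] + rvdw
    dir <- chans$dir[ci]
    # open a hole in the shell around the channel axis
    ax <- dir * pts[, 1]
    rad <- sqrt(pts[, 2]^2 + pts[, 3]^2)
    keep <- keep & !(ax > 0 & rad < a + 0.9)
    # cylindrical wall rings from inside the shell to beyond it
    x_from <- sqrt(max(R^2 - (a + 0.9)^2, 1)) - 1.0
    xs <- seq(x_from, R + 3.5, by = 1.2)
    nang <- max(12, ceiling(2 * pi * a / 1.2))
    th <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
    wall <- do.call(rbind, lapply(xs, function(x)
      cbind(dir * x, a * cos(th), a * sin(th))))
    walls[[ci]] <- wall
    if (blocked)
      plugs[[ci]] <- cbind(dir * seq(x_from + 0.5, R + 1.5, by = 1.0), 0, 0)
  }
  xyz <- rbind(pts[keep, , drop = FALSE], do.call(rbind, walls),
               if (blocked) do.call(rbind, plugs))
  a <- data.frame(atom_id = seq_len(nrow(xyz)),
                  atom_name = "C", element = "C",
                  residue_seq = 1, residue_name = "CAV", chain = "X",
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  stringsAsFactors = FALSE)
  tunnels <- if (blocked) {
    data.frame(label = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), radius = numeric(0))
  } else {
    data.frame(label = chans$label, x = chans$dir * (R + 3),
               y = 0, z = 0, radius = chans$radius,
               stringsAsFactors = FALSE)
  }
  structure(list(model = structure_model(a), start_point = c(0, 0, 0),
                 tunnels = tunnels), class = "cavity_fixture")
}

#' Write / read a ground-truth sidecar table
#'
#' Ground truth is stored beside a generated trajectory as TSV; analysis
#' functions never read it - it exists only for validation.
#'
#' @param truth data.frame as returned by the generators.
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
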