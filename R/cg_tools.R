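# Coarse-grain machinery: heavy-atom-centroid bead mapping, elastic
# network with linker decoupling, randomized linker-dihedral conformer
# generation, and template-library lipid backmapping with the RMSD
# acceptance check.

#' Default coarse-grain mapping for protein residues
#'
#' One backbone bead (`BB`: N, CA, C, O) and one side-chain bead (`SC`:
#' all remaining heavy atoms, written as `"*"`) per residue, applied to
#' any protein residue name.
#'
#' @return mapping list usable with [cg_map()].
#' @export
protein_cg_mapping <- function() {
  m <- lapply(.AA3, function(x) list(BB = c("N", "CA", "C", "O"),
                                     SC = "*"))
  names(m) <- .AA3
  m
}

#' Coarse-grain mapping for the idealized template lipid
#'
#' Seven beads: two head-group beads (NC3, PO4), one glycerol bead (GL)
#' and four tail beads (T1A/T1B, T2A/T2B), each placed at the centroid of
#' its member heavy atoms.
#'
#' @return mapping list usable with [cg_map()].
#' @export
lipid_cg_mapping <- function() {
  list(TPL = list(NC3 = c("N1", "C1", "C2", "C3"),
                  PO4 = c("P1", "O1", "O2"),
                  GL = c("G1", "G2", "G3"),
                  T1A = paste0("A", 1:4), T1B = paste0("A", 5:8),
                  T2A = paste0("B", 1:4), T2B = paste0("B", 5:8)))
}

.BEAD_PART <- c(NC3 = "head", PO4 = "head", GL = "middle",
                T1A = "tail", T1B = "tail", T2A = "tail", T2B = "tail")

#' Map a structure to coarse-grain beads at heavy-atom centroids
#'
#' Each bead is placed at the unweighted average position of its member
#' non-hydrogen atoms. A `"*"` member list collects every heavy atom of
#' the residue not claimed by another bead; beads with no member atoms
#' present are dropped.
#'
#' @param model structure_model.
#' @param mapping named list: residue name -> named list of bead ->
#'   member atom names.
#' @param roles atom roles to map (default protein, lipid and heme).
#' @param backbone_beads bead names flagged as backbone.
#' @return `cg_model`: data.frame with `bead_id`, `bead_name`,
#'   `residue_seq`, `residue_name`, `x`, `y`, `z`, `backbone`.
#' @export
cg_map <- function(model, mapping, roles = c("protein", "lipid", "heme"),
                   backbone_beads = "BB") {
  a <- model$atoms[model$atoms$role %in% roles, ]
  if (!nrow(a)) stop("mapping error: no atoms with roles ",
                     paste(roles, collapse = "/"))
  keys <- unique(a[, c("residue_seq", "residue_name", "chain")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    rs <- keys$residue_seq[i]
    rn <- keys$residue_name[i]
    entry <- mapping[[toupper(rn)]]
    if (is.null(entry))
      stop("mapping error: residue ", rn, " ", rs, " has no mapping entry")
    res <- a[a$residue_seq == rs & a$residue_name == rn &
               a$chain == keys$chain[i] & a$element != "H", ]
    claimed <- toupper(unlist(entry[vapply(entry, function(x)
      !identical(x, "*"), logical(1))]))
    for (bn in names(entry)) {
      members <- if (identical(entry[[bn]], "*"))
        res[!(toupper(res$atom_name) %in% claimed), , drop = FALSE]
      else res[toupper(res$atom_name) %in% toupper(entry[[bn]]), ,
               drop = FALSE]
      if (!nrow(members)) next
      out[[length(out) + 1]] <- data.frame(
        bead_name = bn, residue_seq = rs, residue_name = rn,
        x = mean(members$x), y = mean(members$y), z = mean(members$z),
        backbone = bn %in% backbone_beads, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("mapping error: no beads produced")
  cg <- do.call(rbind, out)
  cg <- cbind(bead_id = seq_len(nrow(cg)), cg)
  class(cg) <- c("cg_model", "data.frame")
  cg
}

.cg_xyz <- function(cg) as.matrix(cg[, c("x", "y", "z")])

#' Build an elastic network over backbone beads
#'
#' A harmonic spring connects every pair of backbone beads strictly
#' closer than `cutoff` (ties at exactly the cutoff are excluded); rest
#' lengths are the distances at construction. Beads of residues in
#' `excluded` (e.g. a flexible linker that must stay decoupled so the
#' anchor can reorient) receive no springs.
#'
#' @param cg `cg_model` with backbone beads.
#' @param cutoff spring distance cutoff (A), strict.
#' @param k spring constant (kcal mol^-1 A^-2), recorded as metadata.
#' @param excluded residue range `c(first, last)` decoupled from the
#'   network, or NULL.
#' @return `elastic_network`: data.frame `i`, `j` (bead ids, i < j),
#'   `residue_i`, `residue_j`, `rest_length`; attributes `k`, `cutoff`,
#'   `excluded`.
#' @export
build_elastic_network <- function(cg, cutoff = 7, k = 10.75,
                                  excluded = NULL) {
  bb <- cg[cg$backbone, , drop = FALSE]
  if (!nrow(bb)) stop("cg model has no backbone beads")
  if (!is.null(excluded))
    bb <- bb[bb$residue_seq < excluded[1] | bb$residue_seq > excluded[2], ,
             drop = FALSE]
  xyz <- .cg_xyz(bb)
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  net <- data.frame(i = bb$bead_id[pairs[, 1]], j = bb$bead_id[pairs[, 2]],
                    residue_i = bb$residue_seq[pairs[, 1]],
                    residue_j = bb$residue_seq[pairs[, 2]],
                    rest_length = d[pairs])
  swap <- net$i > net$j
  if (any(swap)) {
    tmp <- net$i[swap]; net$i[swap] <- net$j[swap]; net$j[swap] <- tmp
    tmp <- net$residue_i[swap]
    net$residue_i[swap] <- net$residue_j[swap]
    net$residue_j[swap] <- tmp
  }
  net <- net[order(net$i, net$j), ]
  rownames(net) <- NULL
  attr(net, "k") <- k
  attr(net, "cutoff") <- cutoff
  attr(net, "excluded") <- excluded
  class(net) <- c("elastic_network", "data.frame")
  net
}

# Rodrigues rotation of points about an axis through p0
.rotate_about_axis <- function(xyz, p0, axis, angle) {
  u <- .unit(axis)
  p <- sweep(xyz, 2, p0)
  cosa <- cos(angle); sina <- sin(angle)
  dotu <- as.vector(p %*% u)
  crossu <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                  u[3] * p[, 1] - u[1] * p[, 3],
                  u[1] * p[, 2] - u[2] * p[, 1])
  rot <- p * cosa + crossu * sina + outer(dotu * (1 - cosa), u)
  sweep(rot, 2, p0, "+")
}

#' Generate conformers by randomizing linker backbone dihedrals
#'
#' Each conformer differs from the input only by rigid rotations about
#' the linker residues' backbone torsion axes (N-CA and CA-C); bond
#' lengths and angles are unchanged and everything downstream of each
#' axis (including the whole globular body) moves as one rigid unit.
#' Dihedral draws are uniform on (-180, 180] degrees. Conformers placing
#' any heavy atom of the rotated body closer than `clash_cutoff` to the
#' anchor or membrane are rejected and redrawn.
#'
#' @param model structure_model (protein with optional membrane).
#' @param linker linker residue range `c(first, last)`.
#' @param n_conformers number of clash-free conformers to produce.
#' @param seed RNG seed.
#' @param clash_cutoff heavy-atom clash distance (A).
#' @param max_attempts attempts allowed per conformer before giving up.
#' @return list of `structure_model` conformers, with the drawn dihedral
#'   angles (degrees) attached as attribute `dihedrals` on each.
#' @export
randomize_linker <- function(model, linker = c(23, 37), n_conformers = 12,
                             seed = 1, clash_cutoff = 3.0,
                             max_attempts = 200) {
  set.seed(seed)
  a <- model$atoms
  mobile_roles <- a$role %in% c("protein", "heme")
  lrows <- which(mobile_roles & a$residue_seq >= linker[1] &
                   a$residue_seq <= linker[2])
  if (!length(lrows)) stop("no linker residues found")
  # torsion axes: for each linker residue, N->CA and CA->C
  axes <- list()
  for (r in linker[1]:linker[2]) {
    rr <- which(mobile_roles & a$residue_seq == r)
    nm <- toupper(a$atom_name[rr])
    if (!all(c("N", "CA", "C") %in% nm)) next
    iN <- rr[nm == "N"][1]; iCA <- rr[nm == "CA"][1]; iC <- rr[nm == "C"][1]
    axes[[length(axes) + 1]] <- c(from = iN, to = iCA)
    axes[[length(axes) + 1]] <- c(from = iCA, to = iC)
  }
  if (!length(axes))
    stop("linker residues have no identifiable backbone atoms")
  body <- which(mobile_roles & a$residue_seq > linker[2] & a$element != "H")
  static <- which((a$role == "lipid" |
                     (mobile_roles & a$residue_seq < linker[1])) &
                    a$element != "H")
  xyz0 <- coords(model)
  out <- vector("list", n_conformers)
  for (k in seq_len(n_conformers)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      draws <- runif(length(axes), -pi, pi)
      xyz <- xyz0
      for (ai in seq_along(axes)) {
        ax <- axes[[ai]]
        pivot <- xyz[ax["to"], ]
        dir <- xyz[ax["to"], ] - xyz[ax["from"], ]
        moving <- which(mobile_roles &
                          (seq_len(nrow(a)) > ax["to"]) &
                          a$residue_seq >= a$residue_seq[ax["to"]])
        if (!length(moving)) next
        xyz[moving, ] <- .rotate_about_axis(xyz[moving, , drop = FALSE],
                                            pivot, dir, draws[ai])
      }
      if (length(body) && length(static)) {
        bm <- xyz[body, , drop = FALSE]
        sm <- xyz[static, , drop = FALSE]
        d2 <- outer(rowSums(bm^2), rowSums(sm^2), "+") - 2 * bm %*% t(sm)
        if (min(d2) < clash_cutoff^2) next
      }
      conf <- set_coords(model, xyz)
      attr(conf, "dihedrals") <- draws * 180 / pi
      out[[k]] <- conf
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not generate clash-free conformer ", k, " in ",
           max_attempts, " attempts")
  }
  out
}

# NeRF internal-coordinate placement: position of the next chain atom
# given the three previous atoms, bond length, bond angle and dihedral
.nerf <- function(p1, p2, p3, bond, angle, dihedral) {
  bc <- .unit(p3 - p2)
  n <- .unit(pracma_cross(p2 - p1, bc))
  m <- pracma_cross(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  p3 + cbind(bc, m, n) %*% d
}

# build the idealized lipid: fixed covalent geometry, given dihedrals
# (radians) for the main chain (G1..A8) and the sn-2 tail (B1..B8)
.build_template_lipid <- function(dih_main, dih_b) {
  bond <- 1.53
  ang <- 111 * pi / 180
  main_names <- c("N1", "C1", "C2", "C3", "P1", "O1", "G1", "G2", "G3",
                  paste0("A", 1:8))
  xyz <- matrix(NA_real_, 17 + 1 + 8, 3,
                dimnames = list(c(main_names, "O2", paste0("B", 1:8)),
                                NULL))
  xyz["N1", ] <- c(0, 0, 0)
  xyz["C1", ] <- c(bond, 0, 0)
  xyz["C2", ] <- .nerf(c(-1, 1, 0), xyz["N1", ], xyz["C1", ], bond, ang, pi)
  # main chain beyond the first three atoms: first 4 torsions frozen
  # trans (rigid head), the rest supplied
  tors <- c(rep(pi, 4), dih_main)
  for (i in 4:length(main_names)) {
    xyz[main_names[i], ] <- .nerf(xyz[main_names[i - 3], ],
                                  xyz[main_names[i - 2], ],
                                  xyz[main_names[i - 1], ],
                                  bond, ang, tors[i - 3])
  }
  xyz["O2", ] <- .nerf(xyz["C3", ], xyz["P1", ], xyz["O1", ], 1.48,
                       109 * pi / 180, 70 * pi / 180)
  # sn-2 tail branches from G2
  prev <- list(xyz["G1", ], xyz["G2", ], xyz["G3", ])
  for (i in 1:8) {
    nm <- paste0("B", i)
    xyz[nm, ] <- .nerf(prev[[1]], prev[[2]], prev[[3]], bond, ang,
                       dih_b[i])
    prev <- list(prev[[2]], prev[[3]], xyz[nm, ])
  }
  el <- c(N1 = "N", C1 = "C", C2 = "C", C3 = "C", P1 = "P", O1 = "O",
          G1 = "C", G2 = "C", G3 = "C",
          setNames(rep("C", 16), c(paste0("A", 1:8), paste0("B", 1:8))),
          O2 = "O")
  a <- data.frame(atom_id = seq_len(nrow(xyz)),
                  atom_name = rownames(xyz),
                  element = unname(el[rownames(xyz)]),
                  residue_seq = 1, residue_name = "TPL", chain = "L",
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  row.names = NULL, stringsAsFactors = FALSE)
  structure_model(a)
}

#' Build a template library of idealized lipid conformers
#'
#' Conformers of one idealized lipid (shared atom naming, 26 atoms)
#' generated by uniform sampling of the rotatable glycerol/tail
#' dihedrals; self-clashing draws (any non-bonded pair < 2 A) are
#' rejected. Bead centroids under [lipid_cg_mapping()] are precomputed
#' per conformer.
#'
#' @param n_conformers library size.
#' @param seed RNG seed.
#' @return `lipid_template_library`: list with `mapping`, `bead_names`,
#'   `conformers` (structure models) and `bead_centroids` (matrices).
#' @export
build_lipid_template_library <- function(n_conformers = 200, seed = 1) {
  set.seed(seed)
  mapping <- lipid_cg_mapping()
  bead_names <- names(mapping$TPL)
  conformers <- vector("list", n_conformers)
  centroids <- vector("list", n_conformers)
  # covalent-neighbour exclusion for the self-clash check: pairs closer
  # than 2.6 A in the all-trans reference are bonded or 1-3
  ref <- coords(.build_template_lipid(rep(pi, 11), rep(pi, 8)))
  excl <- as.matrix(stats::dist(ref)) < 2.6
  made <- 0
  while (made < n_conformers) {
    m <- .build_template_lipid(runif(11, -pi, pi), runif(8, -pi, pi))
    xyz <- coords(m)
    d <- as.matrix(stats::dist(xyz))
    if (min(d[!excl]) < 2.0) next
    made <- made + 1
    cg <- cg_map(m, mapping, roles = "lipid", backbone_beads = character(0))
    cg <- cg[match(bead_names, cg$bead_name), ]
    conformers[[made]] <- m
    centroids[[made]] <- .cg_xyz(cg)
  }
  structure(list(mapping = mapping, bead_names = bead_names,
                 conformers = conformers, bead_centroids = centroids),
            class = "lipid_template_library")
}

#' @export
print.lipid_template_library <- function(x, ...) {
  cat("lipid_template_library:", length(x$conformers), "conformers,",
      length(x$bead_names), "beads\n")
  invisible(x)
}

.check_bead_topology <- function(cg_lipid, bead_names) {
  if (!setequal(cg_lipid$bead_name, bead_names) ||
      nrow(cg_lipid) != length(bead_names))
    stop("mapping error: bead topology mismatch (expected beads ",
         paste(bead_names, collapse = ", "), ")")
  cg_lipid[match(bead_names, cg_lipid$bead_name), ]
}

#' Backmap a coarse-grain lipid to atomic resolution
#'
#' Exhaustive template fit: every library conformer is rigid-body
#' superposed (optimal rotation + translation on bead-centroid pairs)
#' onto the CG beads and the conformer minimizing the bead-to-centroid
#' RMSD is returned at the fitted pose. No force-field relaxation is
#' applied; the RMSD is assessed on the as-fitted coordinates.
#'
#' @param cg_lipid `cg_model` of one lipid (bead topology must match the
#'   library's).
#' @param library [build_lipid_template_library()] result.
#' @return fitted `structure_model` with attributes `rmsd` (A, bead fit)
#'   and `conformer` (library index).
#' @export
backmap_lipid <- function(cg_lipid, library) {
  cg <- .check_bead_topology(cg_lipid, library$bead_names)
  target <- .cg_xyz(cg)
  best <- list(rmsd = Inf, k = NA_integer_, fit = NULL)
  for (k in seq_along(library$conformers)) {
    fit <- superpose(library$bead_centroids[[k]], target)
    if (fit$rmsd < best$rmsd) best <- list(rmsd = fit$rmsd, k = k,
                                           fit = fit)
  }
  conf <- library$conformers[[best$k]]
  out <- set_coords(conf, apply_superposition(coords(conf), best$fit))
  attr(out, "rmsd") <- best$rmsd
  attr(out, "conformer") <- best$k
  out
}

#' Conversion RMSD between a CG lipid and an atomistic reconstruction
#'
#' RMSD between the CG bead positions and the beads recomputed from the
#' atomistic molecule (direct positional RMSD, no re-fitting). With
#' `by_part = TRUE` the same quantity is additionally reported per lipid
#' part (head, middle, tail).
#'
#' @param cg_lipid `cg_model` of one lipid.
#' @param atomistic `structure_model` of the reconstructed lipid.
#' @param mapping CG mapping (default [lipid_cg_mapping()]).
#' @param by_part also return per-part RMSDs.
#' @return RMSD in A (scalar), or a named vector `c(all, head, middle,
#'   tail)` when `by_part`.
#' @export
conversion_rmsd <- function(cg_lipid, atomistic,
                            mapping = lipid_cg_mapping(),
                            by_part = FALSE) {
  remapped <- cg_map(atomistic, mapping, roles = "lipid",
                     backbone_beads = character(0))
  cg <- .check_bead_topology(cg_lipid, remapped$bead_name)
  dif <- .cg_xyz(cg) - .cg_xyz(remapped)
  total <- sqrt(mean(rowSums(dif^2)))
  if (!by_part) return(total)
  part <- .BEAD_PART[remapped$bead_name]
  per <- vapply(c("head", "middle", "tail"), function(p)
    sqrt(mean(rowSums(dif[part == p, , drop = FALSE]^2))), numeric(1))
  c(all = total, per)
}
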