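# Structure / trajectory containers and I/O.
#
# A `structure_model` is a list with:
#   $atoms : data.frame(atom_id, atom_name, element, residue_seq,
#            residue_name, chain, x, y, z, role)
#   $box   : optional c(x, y, z) box lengths (Angstrom)
# A `trajectory` is a list with:
#   $topology       : structure_model
#   $coords         : array [natoms x 3 x nframes] (Angstrom)
#   $frame_interval : frame spacing (ps)

#' Construct a structure model
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `residue_seq`, `residue_name`, `chain`, `x`, `y`, `z` and optionally
#'   `role`; roles are assigned from residue names when absent.
#' @param box optional numeric length-3 box dimensions (Angstrom).
#' @param lipid_names residue names to tag as lipids.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, box = NULL,
                            lipid_names = lipid_residue_names()) {
  need <- c("atom_id", "atom_name", "element", "residue_seq",
            "residue_name", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_id))
    stop("atom_ids must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("all coordinates must be finite")
  if (is.null(atoms$role))
    atoms$role <- assign_roles(atoms, lipid_names)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, box = box), class = "structure_model")
}

#' Assign protein/lipid/heme/solvent/other roles from residue names
#'
#' @param atoms data.frame with a `residue_name` column.
#' @param lipid_names residue names treated as lipids.
#' @return character vector of roles, one per atom.
#' @export
assign_roles <- function(atoms, lipid_names = lipid_residue_names()) {
  rn <- toupper(atoms$residue_name)
  role <- rep("other", nrow(atoms))
  role[rn %in% .AA3] <- "protein"
  role[rn %in% lipid_names] <- "lipid"
  role[rn %in% .HEME_NAMES] <- "heme"
  role[rn %in% .SOLVENT_NAMES] <- "solvent"
  role
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$residue_seq))), "residues\n")
  cat("  roles:", paste(names(table(a$role)), table(a$role),
                        sep = "=", collapse = ", "), "\n")
  if (!is.null(x$box))
    cat("  box:", paste(sprintf("%.2f", x$box), collapse = " x "), "A\n")
  invisible(x)
}

#' Coordinates of a structure model as an n x 3 matrix
#'
#' @param model structure_model.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure model
#'
#' @param model structure_model.
#' @param xyz n x 3 matrix.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

#' Read a structure file (PDB or GRO)
#'
#' PDB files are parsed with bio3d; GRO files with a fixed-column reader
#' (GRO stores nm, converted to Angstrom on read). Heme groups are detected
#' by residue name (HEM and variants), lipids by a configurable residue
#' name list.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param lipid_names residue names to tag as lipids.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           lipid_names = lipid_residue_names()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .read_pdb_model(path, lipid_names)
  else .read_gro_model(path, lipid_names)
}

.read_pdb_model <- function(path, lipid_names) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el) || all(is.na(el) | el == ""))
    el <- .guess_element(a$elety)
  el[is.na(el) | el == ""] <- .guess_element(a$elety[is.na(el) | el == ""])
  atoms <- data.frame(atom_id = a$eleno, atom_name = a$elety,
                      element = toupper(el), residue_seq = a$resno,
                      residue_name = a$resid, chain = ifelse(
                        is.na(a$chain) | a$chain == "", "A", a$chain),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, n = 30), value = TRUE)
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                       substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33))))
    if (!anyNA(v) && all(v > 1)) box <- v
  }
  structure_model(atoms, box = box, lipid_names = lipid_names)
}

.read_gro_model <- function(path, lipid_names) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file at line 2: atom count expected")
  if (length(lines) < 2 + n)
    stop("malformed GRO file: ", n, " atoms declared, ",
         length(lines) - 3, " atom lines present")
  rec <- lines[3:(2 + n)]
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v))
      stop("malformed GRO record at line ", which(is.na(v))[1] + 2)
    v
  }
  atoms <- data.frame(
    atom_id = seq_len(n),
    atom_name = trimws(substr(rec, 11, 15)),
    residue_seq = as.integer(num(rec, 1, 5)),
    residue_name = trimws(substr(rec, 6, 10)),
    chain = "A",
    x = num(rec, 21, 28) * 10,  # nm -> Angstrom
    y = num(rec, 29, 36) * 10,
    z = num(rec, 37, 44) * 10,
    stringsAsFactors = FALSE)
  atoms$element <- .guess_element(atoms$atom_name)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                              "\\s+")[[1]][1:3])) * 10
  if (anyNA(box)) box <- NULL
  structure_model(atoms, box = box, lipid_names = lipid_names)
}

#' Write a structure model (PDB or GRO)
#'
#' @param model structure_model.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), gro = "gro", "pdb")
  a <- model$atoms
  if (format == "pdb") {
    het <- a$role %in% c("heme", "lipid", "solvent", "other")
    bio3d::write.pdb(file = path, xyz = as.vector(t(coords(model))),
                     type = ifelse(het, "HETATM", "ATOM"),
                     resno = a$residue_seq, resid = a$residue_name,
                     eleno = a$atom_id, elety = a$atom_name,
                     chain = a$chain)
  } else {
    lines <- c("generated by memtun", sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_seq %% 100000, a$residue_name,
                       substr(a$atom_name, 1, 5), a$atom_id %% 100000,
                       a$x / 10, a$y / 10, a$z / 10),
               if (!is.null(model$box))
                 sprintf("%10.5f%10.5f%10.5f", model$box[1] / 10,
                         model$box[2] / 10, model$box[3] / 10)
               else sprintf("%10.5f%10.5f%10.5f", 0, 0, 0))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Construct a trajectory
#'
#' @param topology structure_model shared by all frames.
#' @param coords array `[natoms, 3, nframes]` or a list of n x 3 matrices.
#' @param frame_interval time between frames (ps), must be > 0.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, frame_interval = 150) {
  if (is.list(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("every frame must have the same atom count as the topology")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms, frame interval", x$frame_interval, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj trajectory.
#' @param i frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  traj$coords[, , i, drop = TRUE]
}

#' Structure model positioned at one trajectory frame
#' @param traj trajectory.
#' @param i frame index (1-based).
#' @return structure_model with frame-i coordinates.
#' @export
frame_model <- function(traj, i) {
  set_coords(traj$topology, frame_coords(traj, i))
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames; the first model provides the
#' topology.
#'
#' @param path multi-model PDB file.
#' @param frame_interval frame spacing (ps).
#' @param lipid_names residue names to tag as lipids.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, frame_interval = 150,
                            lipid_names = lipid_residue_names()) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- .read_pdb_model(path, lipid_names)
  xyz <- pdb$xyz
  nfr <- nrow(xyz)
  nat <- ncol(xyz) / 3
  arr <- array(NA_real_, dim = c(nat, 3, nfr))
  for (f in seq_len(nfr))
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(topo, arr, frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  nfr <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nfr, ncol = nrow(a) * 3)
  for (f in seq_len(nfr))
    xyz[f, ] <- as.vector(t(frame_coords(traj, f)))
  het <- a$role %in% c("heme", "lipid", "solvent", "other")
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$residue_seq, resid = a$residue_name,
                   eleno = a$atom_id, elety = a$atom_name, chain = a$chain)
  invisible(path)
}

#' Summarize a structure or trajectory file
#'
#' Prints the atom, residue and role composition of a structure file;
#' the console analogue of a quick `info` inspection.
#'
#' @param path structure file (PDB or GRO).
#' @return the parsed `structure_model`, invisibly.
#' @export
structure_info <- function(path) {
  m <- read_structure(path)
  print(m)
  invisible(m)
}
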