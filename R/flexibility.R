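# Superposition (Kabsch), residue-range RMSD series, B-factors.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' matched atom sets (no reflection, unweighted).
#'
#' @param mobile n x 3 coordinate matrix to be fitted.
#' @param reference n x 3 coordinate matrix.
#' @param rows optional row indices of the atoms used for the fit
#'   (default: all rows).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   fitted = mobile %*% t(R) + translation), `rmsd` (A, over the fit
#'   set) and `rows`.
#' @export
superpose <- function(mobile, reference, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(mobile))
  A <- mobile[rows, , drop = FALSE]
  B <- reference[rows, , drop = FALSE]
  if (nrow(A) < 3) stop("superposition needs at least 3 atoms")
  if (nrow(A) != nrow(B)) stop("atom-set size mismatch")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  # guard against degenerate (collinear) sets: rank < 2 leaves the
  # rotation about the line undetermined
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: fit atoms are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cb - as.vector(R %*% ca)
  fitted <- A %*% t(R) + matrix(tr, nrow(A), 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((fitted - B)^2))), rows = rows)
}

#' Apply a superposition result to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param fit result of [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, fit) {
  xyz %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose every trajectory frame onto a reference frame
#'
#' @param traj trajectory.
#' @param ref_frame reference frame index.
#' @param sel selection (expression, `atom_selection` or row indices)
#'   defining the fit atoms; default backbone atoms.
#' @return trajectory with all frames superposed.
#' @export
superpose_trajectory <- function(traj, ref_frame = 1, sel = "backbone") {
  rows <- .sel_rows(traj$topology, sel)
  ref <- frame_coords(traj, ref_frame)
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    fit <- superpose(frame_coords(traj, f), ref, rows)
    out$coords[, , f] <- apply_superposition(frame_coords(traj, f), fit)
  }
  out
}

#' Residue-range RMSD time series after superposition on a primary set
#'
#' Each frame is superposed on the reference frame using the backbone
#' atoms of the primary (first) set; the RMSD of every named set is then
#' reported without re-fitting, so motions of sub-regions are measured in
#' the frame of the fitted domain.
#'
#' @param traj trajectory.
#' @param sets named list of residue ranges `c(first, last)`; the first
#'   entry is the superposition set.
#' @param ref_frame reference frame index.
#' @param atoms `"backbone"` or `"calpha"` or `"heavy"`: atom filter
#'   applied inside each range.
#' @return data.frame with `frame`, `time` (ps) and one RMSD column (A)
#'   per named set.
#' @export
rmsd_series <- function(traj,
                        sets = list(domain = c(47, 492), BC = c(93, 116),
                                    FG = c(208, 230)),
                        ref_frame = 1, atoms = "backbone") {
  if (!length(sets) || is.null(names(sets)))
    stop("sets must be a named list of residue ranges")
  topo <- traj$topology
  rows <- lapply(sets, function(rg)
    .sel_rows(topo, sprintf("resid %d-%d and %s", rg[1], rg[2], atoms)))
  empty <- vapply(rows, length, 1L) == 0
  if (any(empty))
    stop("no atoms resolved for set(s): ",
         paste(names(sets)[empty], collapse = ", "))
  ref <- frame_coords(traj, ref_frame)
  nfr <- n_frames(traj)
  out <- matrix(NA_real_, nfr, length(sets),
                dimnames = list(NULL, names(sets)))
  for (f in seq_len(nfr)) {
    xyz <- frame_coords(traj, f)
    fit <- superpose(xyz, ref, rows[[1]])
    fitted <- apply_superposition(xyz, fit)
    for (s in seq_along(sets))
      out[f, s] <- .rmsd(fitted[rows[[s]], , drop = FALSE],
                         ref[rows[[s]], , drop = FALSE])
  }
  data.frame(frame = seq_len(nfr),
             time = (seq_len(nfr) - 1) * traj$frame_interval, out)
}

#' Crystallographic-style B-factors from positional fluctuations
#'
#' B_i = (8 pi^2 / 3) <|r_i - <r_i>|^2>, computed per atom over frames
#' and optionally averaged per residue. Frames are assumed to be already
#' superposed (see [superpose_trajectory()]); the statistic is otherwise
#' inflated by rigid-body motion.
#'
#' @param traj trajectory (at least 2 frames).
#' @param sel atom filter (selection expression, `atom_selection`, or row
#'   indices); default all heavy atoms.
#' @param per_residue average atom values per residue (default TRUE).
#' @return data.frame with `residue_seq` and `bfactor` (A^2) when
#'   `per_residue`, else per-atom `atom_id`, `residue_seq`, `bfactor`.
#' @export
bfactors <- function(traj, sel = "heavy", per_residue = TRUE) {
  if (n_frames(traj) < 2)
    stop("B-factors are undefined for a single frame")
  rows <- .sel_rows(traj$topology, sel)
  if (!length(rows)) stop("empty selection")
  xyz <- traj$coords[rows, , , drop = FALSE]
  mu <- apply(xyz, c(1, 2), mean)
  msf <- rowMeans(apply(xyz, 3, function(m) rowSums((m - mu)^2)))
  b <- (8 * pi^2 / 3) * msf
  a <- traj$topology$atoms[rows, ]
  if (!per_residue)
    return(data.frame(atom_id = a$atom_id, residue_seq = a$residue_seq,
                      bfactor = b))
  agg <- tapply(b, a$residue_seq, mean)
  data.frame(residue_seq = as.integer(names(agg)),
             bfactor = as.numeric(agg), row.names = NULL)
}
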