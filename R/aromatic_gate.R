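# Internal aromatic gate: ring-center distances d1/d2 with open/closed
# classification, heme-plane projection, and the binned min/max area
# estimator for phenyl-ring mobility.

.PHENYL_RING_ATOMS <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

#' Center of a phenyl ring
#'
#' Centroid of the six aromatic ring carbons of a phenylalanine.
#'
#' @param model structure_model.
#' @param resid residue number.
#' @param ring_atoms ring atom names (default CG/CD1/CD2/CE1/CE2/CZ).
#' @return numeric 3-vector.
#' @export
ring_center <- function(model, resid, ring_atoms = .PHENYL_RING_ATOMS) {
  a <- model$atoms
  rows <- which(a$residue_seq == resid & a$role == "protein" &
                  toupper(a$atom_name) %in% toupper(ring_atoms))
  found <- toupper(a$atom_name[rows])
  missing <- setdiff(toupper(ring_atoms), found)
  if (length(missing))
    stop("residue ", resid, " is missing ring atom(s) ",
         paste(missing, collapse = ", "))
  unname(colMeans(coords(model)[rows, , drop = FALSE]))
}

#' Aromatic gate state from inter-ring distances
#'
#' d1 = distance between the ring centers of the first and second gate
#' residues (position of the mobile phenylalanine); d2 = first to third.
#' The gate is open iff d2 > `open_threshold` (strict).
#'
#' @param model structure_model (one frame).
#' @param gate three residue numbers (mobile, partner, distal).
#' @param open_threshold open threshold on d2 (A).
#' @return list of class `gate_state`: `d1`, `d2`, `open`.
#' @export
gate_state <- function(model, gate = c(100, 114, 476),
                       open_threshold = 7) {
  c1 <- ring_center(model, gate[1])
  c2 <- ring_center(model, gate[2])
  c3 <- ring_center(model, gate[3])
  d1 <- sqrt(sum((c1 - c2)^2))
  d2 <- sqrt(sum((c1 - c3)^2))
  structure(list(d1 = d1, d2 = d2, open = d2 > open_threshold),
            class = "gate_state")
}

#' @export
print.gate_state <- function(x, ...) {
  cat(sprintf("gate_state: d1 = %.2f A, d2 = %.2f A, %s\n", x$d1, x$d2,
              if (x$open) "open" else "closed"))
  invisible(x)
}

#' Orthonormal heme-plane frame
#'
#' In-plane basis from the ring-nitrogen vectors: first axis along
#' NA->NC, second the component of NB->ND orthogonal to it, normal their
#' cross product; origin at the ring-atom centroid.
#'
#' @param model structure_model containing a heme group.
#' @return list of class `heme_plane`: `origin`, `e1`, `e2`, `normal`.
#' @export
heme_plane <- function(model) {
  a <- model$atoms
  rows <- which(a$role == "heme")
  if (!length(rows)) stop("no heme atoms in model")
  nm <- toupper(a$atom_name[rows])
  get <- function(x) {
    r <- rows[nm == x]
    if (!length(r)) stop("heme atom ", x, " not found")
    as.numeric(a[r[1], c("x", "y", "z")])
  }
  pna <- get("NA"); pnb <- get("NB"); pnc <- get("NC"); pnd <- get("ND")
  v1 <- pnc - pna
  v2 <- pnd - pnb
  if (sqrt(sum(pracma_cross(v1, v2)^2)) < 1e-9)
    stop("degenerate geometry: heme ring atoms are collinear")
  e1 <- .unit(v1)
  u2 <- v2 - sum(v2 * e1) * e1
  e2 <- .unit(u2)
  structure(list(origin = (pna + pnb + pnc + pnd) / 4, e1 = e1, e2 = e2,
                 normal = pracma_cross(e1, e2)), class = "heme_plane")
}

#' Project points onto the heme plane
#'
#' In-plane 2-D coordinates of each point; the out-of-plane component is
#' discarded (the projected z is zero by construction).
#'
#' @param points n x 3 matrix (or a 3-vector).
#' @param plane [heme_plane()] result.
#' @return n x 2 matrix of in-plane coordinates.
#' @export
project_to_plane <- function(points, plane) {
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, plane$origin)
  cbind(as.vector(rel %*% plane$e1), as.vector(rel %*% plane$e2))
}

#' Covered area of a 2-D point cloud (binned min/max estimator)
#'
#' The x-range is split into bins of width `bin`; in each bin the
#' current minimum-y and maximum-y points are discarded
#' `n_discard_iters` times (one min and one max per iteration, trimming
#' edge outliers); each bin then contributes bin width times the y-range
#' of its survivors, and bins left with fewer than 2 points contribute
#' zero. The total is the difference between the integrals of the
#' trimmed maximum and minimum graphs.
#'
#' @param points2d n x 2 matrix.
#' @param bin x bin width (A).
#' @param n_discard_iters outlier-trimming iterations per bin.
#' @return area (A^2).
#' @export
covered_area <- function(points2d, bin = 0.2, n_discard_iters = 3) {
  points2d <- matrix(points2d, ncol = 2)
  if (nrow(points2d) < 2) return(0)
  x <- points2d[, 1]
  y <- points2d[, 2]
  idx <- floor((x - min(x)) / bin)
  total <- 0
  for (b in unique(idx)) {
    yy <- y[idx == b]
    for (it in seq_len(n_discard_iters)) {
      if (length(yy) < 2) break
      yy <- yy[-c(which.min(yy), which.max(yy))]
    }
    if (length(yy) >= 2) total <- total + bin * (max(yy) - min(yy))
  }
  total
}

#' Per-frame gate states for a trajectory
#'
#' @param traj trajectory.
#' @param gate three gate residue numbers.
#' @param open_threshold open threshold on d2 (A).
#' @param every frame stride.
#' @return data.frame `frame`, `d1`, `d2`, `open`.
#' @export
gate_series <- function(traj, gate = c(100, 114, 476),
                        open_threshold = 7, every = 1) {
  frames <- seq(1, n_frames(traj), by = every)
  out <- data.frame(frame = frames, d1 = NA_real_, d2 = NA_real_,
                    open = NA)
  for (fi in seq_along(frames)) {
    gs <- gate_state(frame_model(traj, frames[fi]), gate, open_threshold)
    out$d1[fi] <- gs$d1
    out$d2[fi] <- gs$d2
    out$open[fi] <- gs$open
  }
  out
}

#' Percentage of sampled frames with an open gate
#'
#' @param traj trajectory.
#' @param gate three gate residue numbers.
#' @param open_threshold open threshold on d2 (A).
#' @param every frame stride (sampling interval in frames).
#' @return percentage of sampled frames classified open.
#' @export
gate_open_fraction <- function(traj, gate = c(100, 114, 476),
                               open_threshold = 7, every = 1) {
  gs <- gate_series(traj, gate, open_threshold, every)
  100 * mean(gs$open)
}

#' Heme-plane projected mobility areas of the gate rings
#'
#' Projects each gate ring center onto the heme plane at every frame and
#' applies the binned min/max [covered_area()] estimator: the larger the
#' area, the more mobile the ring.
#'
#' @param traj trajectory.
#' @param gate gate residue numbers.
#' @param bin x bin width (A).
#' @param n_discard_iters trimming iterations.
#' @return named numeric vector of areas (A^2), one per gate residue.
#' @export
gate_mobility_area <- function(traj, gate = c(100, 114, 476), bin = 0.2,
                               n_discard_iters = 3) {
  nfr <- n_frames(traj)
  proj <- lapply(gate, function(g) matrix(NA_real_, nfr, 2))
  names(proj) <- paste0("F", gate)
  for (f in seq_len(nfr)) {
    fm <- frame_model(traj, f)
    pl <- heme_plane(fm)
    for (gi in seq_along(gate))
      proj[[gi]][f, ] <- project_to_plane(ring_center(fm, gate[gi]), pl)
  }
  vapply(proj, covered_area, numeric(1), bin = bin,
         n_discard_iters = n_discard_iters)
}
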