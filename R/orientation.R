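# Orientation descriptors: insertion depth d (signed z-projection of the
# protein-membrane COM separation), direction angles alpha and beta of the
# two helix-based vectors v1/v2, helix and heme tilt, height above the
# membrane, histogram-peak representative selection and the
# internal-dynamics angle-variance control.

#' Orientation analysis configuration
#'
#' Residue windows defining the two orientation vectors (v1 along helix I,
#' between the C-alpha midpoints of its first and last helical turns; v2
#' between one helical turn in helix C and one in helix F), the
#' transmembrane helix range and the protein/membrane selections.
#'
#' @param v1_windows,v2_windows lists of two residue ranges
#'   `c(first, last)`.
#' @param tm_helix transmembrane helix residue range.
#' @param protein,membrane selection expressions for the two
#'   centers of mass.
#' @return list of class `orientation_config`.
#' @export
orientation_config <- function(v1_windows = list(c(285, 289), c(312, 316)),
                               v2_windows = list(c(127, 131), c(197, 201)),
                               tm_helix = c(1, 22),
                               protein = "protein",
                               membrane = "lipid") {
  for (w in c(v1_windows, v2_windows))
    if (w[2] < w[1]) stop("residue window must be non-empty")
  if (v1_windows[[1]][2] >= v1_windows[[2]][1] &&
      v1_windows[[2]][2] >= v1_windows[[1]][1])
    stop("v1 windows must be disjoint")
  structure(list(v1_windows = v1_windows, v2_windows = v2_windows,
                 tm_helix = tm_helix, protein = protein,
                 membrane = membrane), class = "orientation_config")
}

.window_ca_rows <- function(model, window) {
  rows <- .sel_rows(model, sprintf("resid %d-%d and calpha",
                                   window[1], window[2]))
  found <- model$atoms$residue_seq[rows]
  missing <- setdiff(window[1]:window[2], found)
  if (length(missing))
    stop("incomplete window ", window[1], "-", window[2],
         ": missing C-alpha for residue(s) ",
         paste(missing, collapse = ", "))
  rows
}

#' Compute the orientation vectors v1 and v2
#'
#' v1 = midpoint(C-alpha of the second v1 window) - midpoint(first
#' window); v2 analogously from its windows.
#'
#' @param model structure_model (one frame).
#' @param config [orientation_config()].
#' @return list with numeric 3-vectors `v1`, `v2`.
#' @export
compute_vectors <- function(model, config = orientation_config()) {
  xyz <- coords(model)
  mid <- function(w)
    unname(colMeans(xyz[.window_ca_rows(model, w), , drop = FALSE]))
  v1 <- mid(config$v1_windows[[2]]) - mid(config$v1_windows[[1]])
  v2 <- mid(config$v2_windows[[2]]) - mid(config$v2_windows[[1]])
  if (sqrt(sum(v1^2)) < 1e-9 || sqrt(sum(v2^2)) < 1e-9)
    stop("degenerate geometry: zero orientation vector")
  list(v1 = v1, v2 = v2)
}

#' Orientation angles of v1 and v2 relative to the membrane normal
#'
#' alpha = angle(v1, z), beta = angle(v2, z), both in [0, 180] degrees.
#'
#' @param v1,v2 numeric 3-vectors.
#' @return named numeric vector `c(alpha, beta)` (degrees).
#' @export
orientation_angles <- function(v1, v2) {
  ang <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("degenerate geometry: zero vector")
    acos(max(-1, min(1, v[3] / n))) * 180 / pi
  }
  c(alpha = ang(v1), beta = ang(v2))
}

#' Signed z-projection of the protein-membrane COM separation
#'
#' d = (COM_protein - COM_membrane) . z, mass-weighted with an
#' element-based mass table; positive on the cytosolic (protein) side.
#'
#' @param model structure_model.
#' @param protein,membrane selection expressions (or row indices).
#' @param euclidean return the full Euclidean COM distance instead of the
#'   z-projection.
#' @return numeric scalar (A).
#' @export
com_distance_z <- function(model, protein = "protein",
                           membrane = "lipid", euclidean = FALSE) {
  rp <- .sel_rows(model, protein)
  rm <- .sel_rows(model, membrane)
  if (!length(rp) || !length(rm)) stop("empty selection")
  xyz <- coords(model)
  mass <- element_mass(model$atoms$element)
  com <- function(rows) colSums(xyz[rows, , drop = FALSE] *
                                  (mass[rows] / sum(mass[rows])))
  dv <- com(rp) - com(rm)
  if (euclidean) sqrt(sum(dv^2)) else unname(dv[3])
}

.fold90 <- function(deg) ifelse(deg > 90, 180 - deg, deg)

#' Inclination of the transmembrane helix
#'
#' Angle between the helix axis and the membrane normal (z), folded into
#' [0, 90] degrees. The default axis estimator uses the second
#' differences of consecutive C-alpha positions, which lie exactly in the
#' plane perpendicular to the axis for an ideal helix (their common
#' normal is the axis); it is exact on ideal helices of any length.
#' `method = "pca"` uses the principal inertia axis of the C-alpha cloud
#' instead, which carries a small finite-length bias (~1.4 degrees for a
#' 22-residue helix).
#'
#' @param model structure_model.
#' @param tm_range helix residue range.
#' @param method `"second_difference"` (default) or `"pca"`.
#' @return tilt angle in degrees, in [0, 90].
#' @export
helix_tilt <- function(model, tm_range = c(1, 22),
                       method = c("second_difference", "pca")) {
  method <- match.arg(method)
  rows <- .sel_rows(model, sprintf("resid %d-%d and calpha",
                                   tm_range[1], tm_range[2]))
  a <- model$atoms[rows, ]
  rows <- rows[order(a$residue_seq)]
  if (length(rows) < 4)
    stop("degenerate geometry: need >= 4 C-alpha atoms in the helix range")
  xyz <- coords(model)[rows, , drop = FALSE]
  if (method == "pca") {
    m <- sweep(xyz, 2, colMeans(xyz))
    axis <- eigen(crossprod(m), symmetric = TRUE)$vectors[, 1]
  } else {
    v <- diff(xyz)
    w <- diff(v)
    wn <- sqrt(rowSums(w^2))
    if (all(wn < 1e-9)) {  # collinear points: the line itself is the axis
      axis <- .unit(xyz[nrow(xyz), ] - xyz[1, ])
    } else {
      w <- w[wn > 1e-9, , drop = FALSE] / wn[wn > 1e-9]
      axis <- eigen(crossprod(w), symmetric = TRUE)$vectors[, 3]
    }
  }
  .fold90(acos(max(-1, min(1, abs(axis[3])))) * 180 / pi)
}

#' Heme tilt angle relative to the membrane plane
#'
#' Dihedral between the heme plane (spanned by the NA->NC and NB->ND
#' ring-nitrogen vectors) and the membrane plane, i.e. the angle between
#' the heme-plane normal and z, folded into [0, 90] degrees.
#'
#' @param model structure_model containing a heme group.
#' @return tilt in degrees, [0, 90].
#' @export
heme_tilt <- function(model) {
  pl <- heme_plane(model)
  .fold90(acos(max(-1, min(1, abs(pl$normal[3])))) * 180 / pi)
}

#' Height of the protein above the membrane surface
#'
#' Maximum protein heavy-atom z minus the mean z of the upper-leaflet
#' head-group atoms. Negative when the protein lies entirely below the
#' head-group plane.
#'
#' @param model structure_model.
#' @param lipid_parts head/middle/tail atom naming, see
#'   [lipid_part_config()].
#' @param protein protein selection expression.
#' @return height (A).
#' @export
height_above_membrane <- function(model,
                                  lipid_parts = lipid_part_config("toy"),
                                  protein = "protein and heavy") {
  rp <- .sel_rows(model, protein)
  if (!length(rp)) stop("empty protein selection")
  a <- model$atoms
  lip <- a$role == "lipid"
  head <- lip & toupper(a$atom_name) %in% toupper(lipid_parts$head)
  if (!any(head)) stop("no head-group atoms found")
  mid_z <- mean(a$z[lip])
  upper <- head & a$z > mid_z
  if (!any(upper)) stop("no upper-leaflet head-group atoms found")
  max(a$z[rp]) - mean(a$z[upper])
}

#' Per-frame orientation records for a trajectory
#'
#' Computes d, alpha and beta for every frame, plus (optionally) the
#' helix tilt, heme tilt and height above the membrane.
#'
#' @param traj trajectory.
#' @param config [orientation_config()].
#' @param extras also compute helix_tilt, heme_tilt and height per frame.
#' @param lipid_parts lipid part naming (used for height).
#' @return data.frame with one row per frame: `frame`, `time` (ps), `d`,
#'   `alpha`, `beta` and, with `extras`, `helix_tilt`, `heme_tilt`,
#'   `height`.
#' @export
orient_trajectory <- function(traj, config = orientation_config(),
                              extras = FALSE,
                              lipid_parts = lipid_part_config("toy")) {
  topo <- traj$topology
  w <- c(config$v1_windows, config$v2_windows)
  wrows <- lapply(w, function(x) .window_ca_rows(topo, x))
  rp <- .sel_rows(topo, config$protein)
  rm <- .sel_rows(topo, config$membrane)
  if (!length(rp) || !length(rm)) stop("empty selection")
  mass <- element_mass(topo$atoms$element)
  wp <- mass[rp] / sum(mass[rp])
  wm <- mass[rm] / sum(mass[rm])
  nfr <- n_frames(traj)
  out <- data.frame(frame = seq_len(nfr),
                    time = (seq_len(nfr) - 1) * traj$frame_interval,
                    d = NA_real_, alpha = NA_real_, beta = NA_real_)
  if (extras) out$helix_tilt <- out$heme_tilt <- out$height <- NA_real_
  for (f in seq_len(nfr)) {
    xyz <- frame_coords(traj, f)
    mids <- lapply(wrows, function(r) colMeans(xyz[r, , drop = FALSE]))
    v1 <- mids[[2]] - mids[[1]]
    v2 <- mids[[4]] - mids[[3]]
    ang <- orientation_angles(v1, v2)
    out$d[f] <- sum(xyz[rp, 3] * wp) - sum(xyz[rm, 3] * wm)
    out$alpha[f] <- ang[["alpha"]]
    out$beta[f] <- ang[["beta"]]
    if (extras) {
      fm <- set_coords(topo, xyz)
      out$helix_tilt[f] <- helix_tilt(fm, config$tm_helix)
      out$heme_tilt[f] <- tryCatch(heme_tilt(fm), error = function(e) NA)
      out$height[f] <- tryCatch(
        height_above_membrane(fm, lipid_parts), error = function(e) NA)
    }
  }
  out
}

# histogram peak of a sample: max-count bin center, optionally refined by
# a local quadratic fit of bin counts (window ~ +/- 1 sample s.d.)
.hist_peak <- function(x, bw, refine = c("parabolic", "bin")) {
  refine <- match.arg(refine)
  br <- seq(floor(min(x) / bw) * bw - bw / 2, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  i <- which.max(h$counts)
  peak <- h$mids[i]
  if (refine == "parabolic" && length(h$counts) >= 5) {
    halfwin <- max(2L, as.integer(round(sd(x) / bw)))
    lo <- max(1L, i - halfwin)
    hi <- min(length(h$counts), i + halfwin)
    cc <- h$counts[lo:hi]
    xx <- h$mids[lo:hi]
    fit <- try(lm(cc ~ xx + I(xx^2)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      b <- coef(fit)
      if (is.finite(b[3]) && b[3] < 0) {
        v <- -b[2] / (2 * b[3])
        if (v >= min(xx) && v <= max(xx)) peak <- unname(v)
      }
    }
  }
  peak
}

#' Histogram peaks of the orientation parameters and representative frame
#'
#' Builds 1-D histograms of d, alpha and beta, estimates their peaks, and
#' returns the first (or last) frame whose three parameters all lie
#' within a window of the peak values - the rule used to pick snapshots
#' representative of a predominant orientation. The window is
#' `window_frac * |peak|` (multiplicative, default) or `window_frac` in
#' the parameter's own units (additive).
#'
#' @param records data.frame with columns `frame`, `d`, `alpha`, `beta`
#'   (see [orient_trajectory()]).
#' @param bins named bin widths `c(d = , alpha = , beta = )`.
#' @param window_frac window as a fraction of the peak value
#'   (multiplicative mode) or as an absolute half-width (additive mode).
#' @param window_mode `"multiplicative"` or `"additive"`.
#' @param refine peak estimator: `"parabolic"` (local quadratic fit of
#'   bin counts around the max bin) or `"bin"` (raw max-bin center).
#' @param which return the `"first"` or `"last"` qualifying frame.
#' @return list with `frame` (selected frame id), `peaks` (named numeric:
#'   d, alpha, beta) and `window` (named half-widths). Errors with the
#'   best per-parameter frames when no frame qualifies.
#' @export
histogram_peak_select <- function(records,
                                  bins = c(d = 0.5, alpha = 1, beta = 1),
                                  window_frac = 0.01,
                                  window_mode = c("multiplicative",
                                                  "additive"),
                                  refine = c("parabolic", "bin"),
                                  which = c("first", "last")) {
  window_mode <- match.arg(window_mode)
  which <- match.arg(which)
  refine <- match.arg(refine)
  if (!nrow(records)) stop("no orientation records")
  if (any(bins <= 0)) stop("bin widths must be positive")
  pars <- c("d", "alpha", "beta")
  peaks <- vapply(pars, function(p)
    .hist_peak(records[[p]], bins[[p]], refine), numeric(1))
  win <- if (window_mode == "multiplicative") window_frac * abs(peaks)
         else rep(window_frac, 3)
  names(win) <- pars
  ok <- rep(TRUE, nrow(records))
  for (p in pars) ok <- ok & abs(records[[p]] - peaks[[p]]) <= win[[p]]
  if (!any(ok)) {
    best <- vapply(pars, function(p)
      records$frame[which.min(abs(records[[p]] - peaks[[p]]))], numeric(1))
    stop("no frame within the window of all three peaks; closest frames: ",
         paste(pars, best, sep = "=", collapse = ", "))
  }
  idx <- if (which == "first") which(ok)[1] else rev(which(ok))[1]
  list(frame = records$frame[idx], peaks = peaks, window = win)
}

#' Angle variance due to internal dynamics (superposition control)
#'
#' Verifies that alpha and beta respond to whole-body reorientation, not
#' internal motion: a reference frame is chosen as the last frame with
#' (d, alpha, beta) within 3% of the histogram peaks, every frame's
#' protein backbone is superposed onto it (removing the rigid-body pose),
#' the angles are recomputed, and the reference values subtracted.
#'
#' @param traj trajectory.
#' @param config [orientation_config()].
#' @param window_frac peak window for reference selection (default 0.03).
#' @param fit_sel atom set used for the superposition.
#' @return data.frame `frame`, `dalpha`, `dbeta` (degrees); the selected
#'   reference frame is attached as attribute `reference_frame`.
#' @export
angle_variance_control <- function(traj, config = orientation_config(),
                                   window_frac = 0.03,
                                   fit_sel = "calpha") {
  records <- orient_trajectory(traj, config)
  ref <- histogram_peak_select(records, window_frac = window_frac,
                               which = "last")
  rows <- .sel_rows(traj$topology, fit_sel)
  refxyz <- frame_coords(traj, ref$frame)
  refm <- set_coords(traj$topology, refxyz)
  v <- compute_vectors(refm, config)
  ref_ang <- orientation_angles(v$v1, v$v2)
  nfr <- n_frames(traj)
  out <- data.frame(frame = seq_len(nfr), dalpha = NA_real_,
                    dbeta = NA_real_)
  for (f in seq_len(nfr)) {
    xyz <- frame_coords(traj, f)
    fit <- superpose(xyz, refxyz, rows)
    fm <- set_coords(traj$topology, apply_superposition(xyz, fit))
    vv <- compute_vectors(fm, config)
    ang <- orientation_angles(vv$v1, vv$v2)
    out$dalpha[f] <- ang[["alpha"]] - ref_ang[["alpha"]]
    out$dbeta[f] <- ang[["beta"]] - ref_ang[["beta"]]
  }
  attr(out, "reference_frame") <- ref$frame
  out
}
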