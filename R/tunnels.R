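# Tunnel detection: clearance grid, widest-path (maximin bottleneck)
# search from a buried start point to the surface, entrance assignment,
# open/closed classification, open fractions and opening/closing
# co-occurrence.

#' Default tunnel entrance definitions
#'
#' Residues whose C-alpha geometric centers define the entrances of the
#' named active-site tunnels (2a, 2b, 2c, 2ac, 2e, 2f and the solvent
#' tunnel S). Two conformer-specific sets ship; entrance sets are
#' per-run configuration.
#'
#' @param conformer `"helical_fg"` (F'/G' helices in the FG loop) or
#'   `"extended_fg"` (extended FG loop).
#' @return named list: label -> residue numbers.
#' @export
tunnel_entrance_config <- function(conformer = c("helical_fg",
                                                 "extended_fg")) {
  conformer <- match.arg(conformer)
  switch(conformer,
    helical_fg = list(`2a` = c(69, 72, 101), `2b` = c(72, 74, 97, 99),
                      `2c` = c(106, 108, 237, 288),
                      `2ac` = c(101, 106, 221, 230),
                      `2e` = c(98, 101, 106, 109),
                      `2f` = c(37, 45, 218, 221),
                      S = c(206, 300, 307, 476)),
    extended_fg = list(`2a` = c(72, 101, 220, 221),
                       `2b` = c(72, 74, 97, 99),
                       `2c` = c(106, 108, 237, 288),
                       `2ac` = c(102, 106, 222, 230),
                       `2e` = c(98, 101, 106, 109),
                       `2f` = c(42, 47, 215, 211),
                       S = c(206, 300, 307, 476)))
}

#' Compute a clearance grid around a structure
#'
#' At each node of a regular grid covering the structure's bounding box
#' (plus padding): clearance = distance to the nearest atom center minus
#' that atom's van der Waals radius, clipped at 0. The clearance at a
#' point is the radius of the largest probe centered there that touches
#' no atom.
#'
#' @param model structure_model (heavy atoms are used).
#' @param spacing grid spacing (A).
#' @param pad padding beyond the bounding box (A); must comfortably exceed
#'   the exterior flood-fill probe of [find_tunnels()] plus the largest
#'   vdW radius so the bulk exterior is contiguous around the molecule.
#' @param radii optional per-atom vdW radii; default from the bundled
#'   element table.
#' @return `clearance_grid`: list with `origin`, `spacing`, `dims` and
#'   `clearance` (3-d array).
#' @export
clearance_grid <- function(model, spacing = 0.6, pad = 5, radii = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  a <- model$atoms[model$atoms$element != "H", ]
  if (!nrow(a)) stop("geometry error: empty frame")
  if (is.null(radii)) radii <- vdw_radius(a$element)
  if (length(radii) != nrow(a)) stop("radii length mismatch")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  cl <- .cpp_clearance_field(xyz, radii, lo, dims, spacing)
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 clearance = array(cl, dim = dims)),
            class = "clearance_grid")
}

#' Clearance value at arbitrary points (nearest grid node)
#' @param grid `clearance_grid`.
#' @param points n x 3 matrix.
#' @return numeric clearances.
#' @export
grid_clearance_at <- function(grid, points) {
  points <- matrix(points, ncol = 3)
  idx <- sweep(points, 2, grid$origin)
  ijk <- round(idx / grid$spacing) + 1
  ijk <- pmin(pmax(ijk, 1), matrix(grid$dims, nrow(points), 3,
                                   byrow = TRUE))
  grid$clearance[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
}

.node_coords <- function(grid, lin) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  i <- (lin - 1) %% nx
  j <- ((lin - 1) %/% nx) %% ny
  k <- (lin - 1) %/% (nx * ny)
  cbind(grid$origin[1] + i * grid$spacing,
        grid$origin[2] + j * grid$spacing,
        grid$origin[3] + k * grid$spacing)
}

.surface_nodes <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- array(seq_len(nx * ny * nz), dim = dims)
  unique(c(idx[1, , ], idx[nx, , ], idx[, 1, ], idx[, ny, ],
           idx[, , 1], idx[, , nz]))
}

# resample a polyline (with a scalar field) to <= n equidistant points
.resample_path <- function(xyz, radii, n) {
  if (nrow(xyz) <= 2 || nrow(xyz) <= n) {
    if (nrow(xyz) <= n) return(list(centers = xyz, radii = radii))
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  so <- seq(0, s[length(s)], length.out = n)
  centers <- apply(xyz, 2, function(col) stats::approx(s, col, so)$y)
  list(centers = centers, radii = stats::approx(s, radii, so)$y)
}

#' Find tunnels from a buried start point to the surface
#'
#' Widest-bottleneck (maximin) paths on the 26-connected clearance grid:
#' for every node the best-first search computes the maximum over paths
#' from the start of the minimum clearance along the path. The bulk
#' exterior is identified by a flood fill from the grid boundary; each
#' tunnel is the widest path to a surface node (an interior node touching
#' the exterior), truncated at its first exterior contact. Tunnels are
#' extracted iteratively: after each one, blocking spheres are placed at
#' its exit (radius `d_sep / 2`) and over its bottleneck cross-section
#' (sealing the channel) and the search repeated, so that one wide
#' physical channel cannot claim several exits and narrower channels are
#' still found. Exits closer than `d_sep` to an earlier exit are
#' dropped. Each path is resampled to at most `max_segments` equidistant
#' segments carrying interpolated clearance radii.
#'
#' @param grid `clearance_grid`.
#' @param start 3-vector (A), must have positive clearance.
#' @param n_tunnels maximum number of tunnels.
#' @param d_sep minimum exit-point separation (A).
#' @param max_segments segment budget per tunnel.
#' @param exterior_probe probe radius (A) for the bulk-exterior flood
#'   fill: the exterior is every region reachable from the grid boundary
#'   through nodes with clearance >= this value, tunnels are truncated at
#'   their first exterior contact, and paths may not travel through the
#'   exterior (preventing one physical channel from claiming several
#'   wrap-around exits). `NULL` disables the fill and treats the grid
#'   boundary itself as the surface (the form checked against the
#'   exhaustive maximin oracle).
#' @return list of `tunnel_profile`s (possibly empty): each has
#'   `centers` (m x 3), `radii`, `min_radius`, `bottleneck`, `exit`,
#'   `label` (NA until assigned).
#' @export
find_tunnels <- function(grid, start, n_tunnels = 10, d_sep = 8,
                         max_segments = 200, exterior_probe = 2.5) {
  ijk <- round((start - grid$origin) / grid$spacing) + 1
  if (any(ijk < 1) || any(ijk > grid$dims))
    stop("start point outside the grid")
  lin <- ijk[1] + grid$dims[1] * ((ijk[2] - 1) +
                                    grid$dims[2] * (ijk[3] - 1))
  if (grid$clearance[ijk[1], ijk[2], ijk[3]] <= 0)
    stop("start point has zero clearance")
  clear <- as.vector(grid$clearance)
  bound <- .surface_nodes(grid$dims)
  ext <- NULL
  if (!is.null(exterior_probe)) {
    ext <- rep(FALSE, length(clear))
    seeds <- bound[clear[bound] >= exterior_probe]
    while (length(seeds)) {
      fl <- .cpp_widest_path(clear, as.integer(grid$dims),
                             as.integer(seeds[1] - 1))
      ext <- ext | fl$bottleneck >= exterior_probe
      seeds <- seeds[!ext[seeds]]
    }
    if (!any(ext) || ext[lin]) ext <- NULL  # degenerate: fall back
  }
  if (!is.null(ext)) clear[ext] <- 0
  if (is.null(ext)) {
    surf_mask <- rep(FALSE, length(clear))
    surf_mask[bound] <- TRUE
  } else {
    # surface = interior nodes touching the exterior (6-neighborhood)
    ea <- array(ext, dim = grid$dims)
    nb <- array(FALSE, dim = grid$dims)
    nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
    nb[-nx, , ] <- nb[-nx, , ] | ea[-1, , ]
    nb[-1, , ] <- nb[-1, , ] | ea[-nx, , ]
    nb[, -ny, ] <- nb[, -ny, ] | ea[, -1, ]
    nb[, -1, ] <- nb[, -1, ] | ea[, -ny, ]
    nb[, , -nz] <- nb[, , -nz] | ea[, , -1]
    nb[, , -1] <- nb[, , -1] | ea[, , -nz]
    surf_mask <- as.vector(nb) & !ext
  }
  clear0 <- as.vector(grid$clearance)
  all_xyz <- .node_coords(grid, seq_along(clear))
  out <- list()
  exits <- NULL
  repeat {
    if (length(out) >= n_tunnels) break
    wp <- .cpp_widest_path(clear, as.integer(grid$dims),
                           as.integer(lin - 1))
    bott <- wp$bottleneck
    parent <- wp$parent
    surf <- which(surf_mask & bott > 0)
    if (!length(surf)) break
    node <- surf[which.max(bott[surf])]
    # backtrack parents (0-based from the search) to a 1-based path
    # ordered start -> surface, truncated at the first surface contact
    path <- node
    repeat {
      pv <- parent[path[1]]
      if (pv < 0) break
      path <- c(pv + 1, path)
    }
    first_surf <- which(surf_mask[path])[1]
    path <- path[seq_len(first_surf)]
    exit <- as.vector(.node_coords(grid, path[length(path)]))
    pr_full <- clear0[path]
    # seal this channel before searching again: block a sphere at the
    # exit and one covering the bottleneck cross-section
    near <- rowSums(sweep(all_xyz, 2, exit)^2) < (d_sep / 2)^2
    bn <- as.vector(.node_coords(grid, path[which.min(pr_full)]))
    rblock <- min(pr_full) + 2 * grid$spacing
    near <- near | rowSums(sweep(all_xyz, 2, bn)^2) < rblock^2
    clear[near] <- 0
    keep <- is.null(exits) ||
      min(sqrt(rowSums(sweep(exits, 2, exit)^2))) >= d_sep
    if (keep) {
      exits <- rbind(exits, exit)
      pxyz <- .node_coords(grid, path)
      pr <- pr_full
      rs <- .resample_path(pxyz, pr, max_segments)
      out[[length(out) + 1]] <- structure(
        list(centers = rs$centers, radii = rs$radii,
             min_radius = min(pr),
             bottleneck = min(pr),
             exit = exit, label = NA_character_),
        class = "tunnel_profile")
    }
  }
  out
}

#' Tunnel entrance points from defining residues
#'
#' Per label, the geometric center of the C-alpha atoms of the defining
#' residues.
#'
#' @param model structure_model (one frame).
#' @param entrances named list label -> residue numbers
#'   ([tunnel_entrance_config()]).
#' @return matrix (labels x 3).
#' @export
entrance_points <- function(model, entrances = tunnel_entrance_config()) {
  out <- matrix(NA_real_, length(entrances), 3,
                dimnames = list(names(entrances), c("x", "y", "z")))
  for (l in names(entrances)) {
    rows <- .sel_rows(model, paste("calpha and resid",
                                   paste(entrances[[l]], collapse = " ")))
    found <- model$atoms$residue_seq[rows]
    missing <- setdiff(entrances[[l]], found)
    if (length(missing))
      stop("entrance error: label ", l, " missing C-alpha for residue(s) ",
           paste(missing, collapse = ", "))
    out[l, ] <- colMeans(coords(model)[rows, , drop = FALSE])
  }
  out
}

#' Assign a tunnel profile to a named entrance
#'
#' The profile is assigned label L iff at least one segment lies closer
#' than `cutoff` to entrance L while every other entrance is farther
#' than `cutoff` from every segment; ambiguous or distant profiles stay
#' unassigned.
#'
#' @param profile `tunnel_profile`.
#' @param entrance_pts matrix from [entrance_points()].
#' @param cutoff assignment distance (A).
#' @return label string or `NA_character_`.
#' @export
assign_tunnel <- function(profile, entrance_pts, cutoff = 5) {
  segs <- profile$centers
  dmin <- vapply(seq_len(nrow(entrance_pts)), function(i) {
    dif <- sweep(segs, 2, entrance_pts[i, ])
    sqrt(min(rowSums(dif^2)))
  }, numeric(1))
  near <- dmin < cutoff
  if (sum(near) == 1) rownames(entrance_pts)[near] else NA_character_
}

#' Open/closed classification of a tunnel profile
#'
#' Open iff the minimum segment radius exceeds `threshold` (strict), the
#' clearance needed to pass at least one water molecule.
#'
#' @param profile `tunnel_profile` (or a numeric min radius).
#' @param threshold open threshold (A).
#' @return logical.
#' @export
classify_open <- function(profile, threshold = 1.2) {
  r <- if (is.numeric(profile)) profile else profile$min_radius
  r > threshold
}

#' Per-frame, per-label tunnel time series for a trajectory
#'
#' For frames sampled every `every` frames: build the clearance grid,
#' find tunnels from the start point, assign them to entrances, and
#' record each label's minimum radius (NA when no profile is assigned
#' that frame).
#'
#' @param traj trajectory.
#' @param start buried start point (3-vector, A) or a function(model)
#'   returning one.
#' @param entrances named list label -> residues.
#' @param every frame stride.
#' @param spacing,pad grid parameters.
#' @param n_tunnels,d_sep search parameters.
#' @return data.frame of class `tunnel_series`: `frame`, then one
#'   min-radius column per label.
#' @export
tunnel_series <- function(traj, start,
                          entrances = tunnel_entrance_config(),
                          every = 1, spacing = 0.6, pad = 5,
                          n_tunnels = 10, d_sep = 8) {
  frames <- seq(1, n_frames(traj), by = every)
  labels <- names(entrances)
  out <- as.data.frame(matrix(NA_real_, length(frames), length(labels),
                              dimnames = list(NULL, labels)),
                       check.names = FALSE)
  for (fi in seq_along(frames)) {
    fm <- frame_model(traj, frames[fi])
    sp <- if (is.function(start)) start(fm) else start
    grid <- clearance_grid(fm, spacing = spacing, pad = pad)
    profs <- find_tunnels(grid, sp, n_tunnels = n_tunnels, d_sep = d_sep)
    ep <- entrance_points(fm, entrances)
    for (p in profs) {
      lab <- assign_tunnel(p, ep)
      if (!is.na(lab) &&
          (is.na(out[fi, lab]) || p$min_radius > out[fi, lab]))
        out[fi, lab] <- p$min_radius
    }
  }
  cbind(frame = frames, out)
}

#' Fraction of frames in which each tunnel is open
#'
#' Frames with no assigned profile for a label count as closed for that
#' label.
#'
#' @param series `tunnel_series` data.frame (or any data.frame of
#'   min-radius columns plus `frame`).
#' @param threshold open threshold (A), strict.
#' @return named numeric vector of percentages.
#' @export
open_fraction <- function(series, threshold = 1.2) {
  labs <- setdiff(names(series), "frame")
  vapply(labs, function(l) {
    r <- series[[l]]
    100 * sum(!is.na(r) & r > threshold) / length(r)
  }, numeric(1))
}

#' Opening/closing co-occurrence between tunnels
#'
#' Pairwise phi coefficient (Pearson correlation of the binary open
#' flags) between tunnel time series; pairs involving a constant series
#' are NA.
#'
#' @param series `tunnel_series` data.frame.
#' @param threshold open threshold (A).
#' @return labels x labels matrix of phi coefficients.
#' @export
tunnel_cooccurrence <- function(series, threshold = 1.2) {
  labs <- setdiff(names(series), "frame")
  flags <- vapply(labs, function(l) {
    r <- series[[l]]
    as.numeric(!is.na(r) & r > threshold)
  }, numeric(nrow(series)))
  n <- length(labs)
  out <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (sd(flags[, i]) > 0 && sd(flags[, j]) > 0)
      out[i, j] <- cor(flags[, i], flags[, j])
  }
  out
}

#' Entrance positional stability check
#'
#' The entrance assignment is reliable only while every entrance's
#' maximum displacement (from its trajectory-mean position) stays below
#' the minimum distance between any two entrances; this computes both
#' and flags violations.
#'
#' @param traj trajectory.
#' @param entrances named list label -> residues.
#' @return list with `max_displacement` (per label, A),
#'   `min_pairwise_distance` (A) and `violation` flag.
#' @export
entrance_stability_check <- function(traj,
                                     entrances =
                                       tunnel_entrance_config()) {
  nfr <- n_frames(traj)
  labs <- names(entrances)
  pts <- array(NA_real_, dim = c(length(labs), 3, nfr))
  for (f in seq_len(nfr))
    pts[, , f] <- entrance_points(frame_model(traj, f), entrances)
  mu <- apply(pts, c(1, 2), mean)
  disp <- apply(array(pts - array(mu, dim = dim(pts)), dim = dim(pts)),
                3, function(m) sqrt(rowSums(m^2)))
  max_disp <- apply(matrix(disp, nrow = length(labs)), 1, max)
  names(max_disp) <- labs
  dmu <- as.matrix(stats::dist(mu))
  diag(dmu) <- Inf
  min_pair <- min(dmu)
  list(max_displacement = max_disp, min_pairwise_distance = min_pair,
       violation = any(max_disp >= min_pair))
}
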