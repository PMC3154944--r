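# Shared fixtures, built in code at test time.

toy_system <- function(seed = 1, nx = 8, ny = 8) {
  combine_systems(build_toy_anchored_protein(),
                  build_toy_bilayer(nx, ny, 8, seed = seed))
}

# minimal hand-written PDB (3 atoms, exact coordinates)
tiny_pdb_lines <- function() {
  c(paste0("ATOM      1  N   ALA A   1       1.000   2.000   3.000",
           "  1.00  0.00           N"),
    paste0("ATOM      2  CA  ALA A   1       2.500   2.000   3.000",
           "  1.00  0.00           C"),
    paste0("HETATM    3  NA  HEM A   2       0.000  -1.250   4.750",
           "  1.00  0.00           N"),
    "END")
}

# minimal structure model from a coordinate matrix
model_from_xyz <- function(xyz, resname = "ALA", atom_name = "CA",
                           resid = NULL, element = "C", chain = "A") {
  n <- nrow(xyz)
  if (is.null(resid)) resid <- seq_len(n)
  structure_model(data.frame(
    atom_id = seq_len(n), atom_name = rep_len(atom_name, n),
    element = rep_len(element, n), residue_seq = rep_len(resid, n),
    residue_name = rep_len(resname, n), chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# independent Kabsch used as an oracle (kept deliberately separate from
# the package implementation)
oracle_fit_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  s <- svd(t(A0) %*% B0)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
}

# exhaustive maximin bottleneck from a start node to any boundary node:
# descending threshold + plain BFS connectivity check
oracle_grid_bottleneck <- function(grid, start_ijk) {
  dims <- grid$dims
  cl <- grid$clearance
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  is_boundary <- function(i, j, k)
    i == 1 || i == nx || j == 1 || j == ny || k == 1 || k == nz
  flood_reaches_boundary <- function(t) {
    ok <- cl >= t
    if (!ok[start_ijk[1], start_ijk[2], start_ijk[3]]) return(FALSE)
    seen <- array(FALSE, dims)
    queue <- matrix(start_ijk, ncol = 3)
    seen[start_ijk[1], start_ijk[2], start_ijk[3]] <- TRUE
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      if (is_boundary(cur[1], cur[2], cur[3])) return(TRUE)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        i <- cur[1] + di; j <- cur[2] + dj; k <- cur[3] + dk
        if (i < 1 || i > nx || j < 1 || j > ny || k < 1 || k > nz) next
        if (!ok[i, j, k] || seen[i, j, k]) next
        seen[i, j, k] <- TRUE
        queue <- rbind(queue, c(i, j, k))
      }
    }
    FALSE
  }
  levels <- sort(unique(as.vector(cl)), decreasing = TRUE)
  for (t in levels) {
    if (t <= 0) break
    if (flood_reaches_boundary(t)) return(t)
  }
  0
}
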