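# Membrane-relative residue classification (M / HG / C), residue-lipid
# contact tables by residue category and lipid part, and summary
# statistics (percent of domain in contact, area per lipid, gate-ring
# distance to the head-group plane).

.RESIDUE_CATEGORIES <- list(hydrophobic = c("L", "I", "V"),
                            aromatic = c("F", "Y", "W"),
                            hydrophilic = c("S", "T", "N", "Q"),
                            charged = c("D", "E", "R", "K"),
                            glycine = "G", proline = "P")
# residues with too few lipid contacts to categorize (excluded from
# category tables): H, C, M, A
.CATEGORY_EXCLUDED <- c("H", "C", "M", "A")

#' Per-frame membrane geometry
#'
#' Splits lipids into leaflets by the sign of the lipid center-of-mass z
#' relative to the bilayer midplane and records the head-group mean z of
#' each leaflet. The head-group (HG) region is a slab of half-width
#' `hg_halfwidth` about each head-group plane; the membrane (M, lipid
#' tail) region lies between the two inner HG boundaries; everything
#' outside the outer boundaries is cytosol/exoplasm (C).
#'
#' @param model structure_model with lipids.
#' @param lipid_parts head/middle/tail atom naming
#'   ([lipid_part_config()]).
#' @param hg_halfwidth HG slab half-width (A).
#' @return list of class `membrane_geometry`: `midplane`, `upper_head_z`,
#'   `lower_head_z`, `hg_halfwidth`, `leaflet` (named by residue_seq).
#' @export
frame_geometry <- function(model, lipid_parts = lipid_part_config("toy"),
                           hg_halfwidth = 4) {
  a <- model$atoms
  lip <- a$role == "lipid"
  if (!any(lip)) stop("geometry error: no lipid atoms")
  mid <- mean(a$z[lip])
  com_z <- tapply(a$z[lip], a$residue_seq[lip], mean)
  leaflet <- setNames(ifelse(as.numeric(com_z) > mid, "upper", "lower"),
                      names(com_z))
  head <- lip & toupper(a$atom_name) %in% toupper(lipid_parts$head)
  if (!any(head)) stop("geometry error: no head-group atoms")
  up_res <- names(leaflet)[leaflet == "upper"]
  hu <- mean(a$z[head & as.character(a$residue_seq) %in% up_res])
  hl <- mean(a$z[head & !(as.character(a$residue_seq) %in% up_res)])
  # a genuine bilayer has two well-separated head-group planes
  if (length(unique(leaflet)) < 2 || !is.finite(hu) || !is.finite(hl) ||
      (hu - hl) < 5)
    stop("geometry error: single-leaflet input")
  structure(list(midplane = mid, upper_head_z = hu, lower_head_z = hl,
                 hg_halfwidth = hg_halfwidth, leaflet = leaflet),
            class = "membrane_geometry")
}

.region_of_z <- function(z, geom) {
  hw <- geom$hg_halfwidth
  ifelse(z > geom$upper_head_z + hw | z < geom$lower_head_z - hw, "C",
  ifelse(z <= geom$upper_head_z + hw & z >= geom$upper_head_z - hw, "HG",
  ifelse(z >= geom$lower_head_z - hw & z <= geom$lower_head_z + hw, "HG",
         "M")))
}

#' Classify a residue relative to the membrane (M / HG / C)
#'
#' The residue's heavy-atom centroid z is classified against the region
#' intervals: M (lipid tail region), HG (head-group slab) or C (outside).
#'
#' @param model structure_model.
#' @param resid residue number.
#' @param geom [frame_geometry()] result.
#' @return one of `"M"`, `"HG"`, `"C"`.
#' @export
residue_region <- function(model, resid, geom) {
  a <- model$atoms
  rows <- which(a$residue_seq == resid & a$role == "protein" &
                  a$element != "H")
  if (!length(rows)) stop("residue ", resid, " has no heavy atoms")
  .region_of_z(mean(a$z[rows]), geom)
}

#' Location string of a peptide relative to the membrane
#'
#' Per-residue regions from the N- to the C-terminus, collapsed to the
#' ordered sequence of distinct consecutive regions joined with "-"
#' (revisits are kept), e.g. `"M-HG-C"` for a peptide whose N-terminal
#' residues sit in the membrane and C-terminal residues in the cytosol.
#'
#' @param model structure_model.
#' @param range residue range `c(first, last)`.
#' @param geom [frame_geometry()] result.
#' @return location string.
#' @export
peptide_location_string <- function(model, range, geom) {
  resids <- range[1]:range[2]
  present <- resids[resids %in%
                      model$atoms$residue_seq[model$atoms$role == "protein"]]
  if (!length(present)) stop("no protein residues in range")
  regs <- vapply(present, function(r) residue_region(model, r, geom),
                 character(1))
  paste(rle(regs)$values, collapse = "-")
}

#' Residue-lipid contact table by residue category and lipid part
#'
#' A residue contacts a lipid part when any of its heavy atoms lies
#' closer than `cutoff` to any heavy atom of that part (any lipid). Each
#' residue contributes at most one contact per lipid part per frame.
#' Counts are aggregated into six residue categories (hydrophobic L/I/V,
#' aromatic F/Y/W, hydrophilic S/T/N/Q, charged D/E/R/K, glycine,
#' proline); H, C, M and A residues are excluded from the table.
#'
#' @param model structure_model (one frame).
#' @param cutoff contact distance (A), strict inequality.
#' @param lipid_parts lipid part naming ([lipid_part_config()]).
#' @return list of class `contact_table`: `counts` (6 x 3 integer
#'   matrix category x part) and `residues` (data.frame residue_seq,
#'   aa, category, head/middle/tail contact flags).
#' @export
count_contacts <- function(model, cutoff = 4,
                           lipid_parts = lipid_part_config("toy")) {
  a <- model$atoms
  prot <- which(a$role == "protein" & a$element != "H")
  if (!length(prot)) stop("no protein heavy atoms")
  resids <- sort(unique(a$residue_seq[prot]))
  rindex <- match(a$residue_seq[prot], resids)
  xyz <- coords(model)
  parts <- names(lipid_parts)
  dmin <- matrix(Inf, length(resids), length(parts),
                 dimnames = list(resids, parts))
  for (p in parts) {
    lrows <- which(a$role == "lipid" & a$element != "H" &
                     toupper(a$atom_name) %in% toupper(lipid_parts[[p]]))
    if (!length(lrows)) next
    dmin[, p] <- .cpp_min_dist_by_group(xyz[prot, , drop = FALSE],
                                        as.integer(rindex),
                                        length(resids),
                                        xyz[lrows, , drop = FALSE])
  }
  contact <- dmin < cutoff
  rn <- vapply(resids, function(r)
    a$residue_name[a$residue_seq == r & a$role == "protein"][1],
    character(1))
  aa <- unname(.AA31[toupper(rn)])
  cat_of <- rep(NA_character_, length(aa))
  for (cn in names(.RESIDUE_CATEGORIES))
    cat_of[aa %in% .RESIDUE_CATEGORIES[[cn]]] <- cn
  counts <- matrix(0L, length(.RESIDUE_CATEGORIES), length(parts),
                   dimnames = list(names(.RESIDUE_CATEGORIES), parts))
  keep <- !is.na(cat_of) & !(aa %in% .CATEGORY_EXCLUDED)
  for (cn in names(.RESIDUE_CATEGORIES))
    counts[cn, ] <- colSums(contact[keep & cat_of == cn, , drop = FALSE])
  res <- data.frame(residue_seq = resids, aa = aa, category = cat_of,
                    contact, row.names = NULL)
  structure(list(counts = counts, residues = res, cutoff = cutoff),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat("contact_table (cutoff", x$cutoff, "A):\n")
  print(x$counts)
  invisible(x)
}

#' Percentage of a domain in contact with the lipid bilayer
#'
#' Per frame, the fraction of domain residues with at least one lipid
#' contact (any part, heavy-atom distance < cutoff), averaged over
#' frames.
#'
#' @param traj trajectory.
#' @param domain residue range of the domain.
#' @param cutoff contact distance (A).
#' @param lipid_parts lipid part naming.
#' @return list with `mean`, `sd` (percent) and per-frame `percent`.
#' @export
percent_domain_in_contact <- function(traj, domain, cutoff = 4,
                                      lipid_parts =
                                        lipid_part_config("toy")) {
  nfr <- n_frames(traj)
  pct <- numeric(nfr)
  for (f in seq_len(nfr)) {
    fm <- frame_model(traj, f)
    ct <- count_contacts(fm, cutoff, lipid_parts)
    res <- ct$residues
    dom <- res$residue_seq >= domain[1] & res$residue_seq <= domain[2]
    if (!any(dom)) stop("domain range matches no residues")
    any_contact <- rowSums(as.matrix(
      res[dom, names(lipid_parts), drop = FALSE])) > 0
    pct[f] <- 100 * mean(any_contact)
  }
  list(mean = mean(pct), sd = if (nfr > 1) sd(pct) else 0, percent = pct)
}

#' Area per lipid of one leaflet
#'
#' Naive box-based estimator: in-plane box area divided by the number of
#' lipids in the leaflet (the protein footprint is not subtracted).
#'
#' @param model structure_model with a recorded box.
#' @param leaflet `"upper"` or `"lower"`.
#' @param lipid_parts lipid part naming (leaflet assignment).
#' @return area per lipid (A^2).
#' @export
area_per_lipid <- function(model, leaflet = c("upper", "lower"),
                           lipid_parts = lipid_part_config("toy")) {
  leaflet <- match.arg(leaflet)
  if (is.null(model$box)) stop("geometry error: no box dimensions")
  geom <- frame_geometry(model, lipid_parts)
  n <- sum(geom$leaflet == leaflet)
  if (n == 0) stop("geometry error: no lipids in ", leaflet, " leaflet")
  model$box[1] * model$box[2] / n
}

#' Z-distance of gate phenyl-ring centers to the head-group plane
#'
#' Ring-center z minus the mean upper-leaflet head-group z, projected on
#' the membrane normal; negative when the ring lies below the reference
#' plane, closer to the lipid bilayer.
#'
#' @param model structure_model.
#' @param ring_residues residue numbers of the gate phenylalanines.
#' @param lipid_parts lipid part naming.
#' @return named numeric vector of signed z-distances (A).
#' @export
gate_membrane_distance <- function(model,
                                   ring_residues = c(100, 114, 476),
                                   lipid_parts =
                                     lipid_part_config("toy")) {
  a <- model$atoms
  lip <- a$role == "lipid"
  head <- lip & toupper(a$atom_name) %in% toupper(lipid_parts$head)
  if (!any(head)) stop("no head-group atoms found")
  upper <- head & a$z > mean(a$z[lip])
  ref_z <- mean(a$z[upper])
  out <- vapply(ring_residues, function(r)
    ring_center(model, r)[3] - ref_z, numeric(1))
  names(out) <- paste0("F", ring_residues)
  out
}
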