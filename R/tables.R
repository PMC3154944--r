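# Reference tables: amino acids, element masses, van der Waals radii,
# residue-name based role assignment, lipid part naming.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA31 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, FE = 55.845, "NA" = 22.990,
                   CL = 35.45, K = 39.098, MG = 24.305, ZN = 65.38)

# Bondi-style van der Waals radii (Angstrom)
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                FE = 1.80, CL = 1.75)

.HEME_NAMES <- c("HEM", "HEC", "HEA", "HEB")
.SOLVENT_NAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC", "NA", "CL",
                    "K", "MG", "ION")

#' Lipid residue names recognized by role tagging
#'
#' @return Character vector of residue names treated as lipids.
#' @export
lipid_residue_names <- function() {
  c("POPC", "POPE", "POPS", "DPPC", "DOPC", "DLPC", "DMPC", "LIP",
    "PLP", "TPL")
}

#' Atomic mass lookup by element symbol
#'
#' Unknown elements are assigned the mass of carbon with a warning, so
#' center-of-mass computations always succeed.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses (amu).
#' @export
element_mass <- function(element) {
  el <- toupper(element)
  m <- unname(.ELEMENT_MASS[el])
  if (anyNA(m)) {
    warning("unknown element(s) ",
            paste(unique(el[is.na(m)]), collapse = ", "),
            "; assigned carbon mass")
    m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  }
  m
}

#' Van der Waals radius lookup by element symbol
#'
#' @param element character vector of element symbols.
#' @param default radius used for elements not in the bundled table (A).
#' @return numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(element, default = 1.7) {
  r <- unname(.VDW_RADII[toupper(element)])
  r[is.na(r)] <- default
  r
}

#' Lipid part definitions (head / middle / tail) by atom name
#'
#' The contact and membrane-geometry analyses split each lipid into a head
#' group, a middle (glycerol/ester) band and the acyl tails. The mapping is
#' by atom name and must be explicit. `"toy"` matches the pseudo-lipids
#' produced by [build_toy_bilayer()]; `"template"` matches the idealized
#' lipid of [build_lipid_template_library()].
#'
#' @param style one of `"toy"`, `"template"`.
#' @return named list with character vectors `head`, `middle`, `tail`.
#' @export
lipid_part_config <- function(style = c("toy", "template")) {
  style <- match.arg(style)
  switch(style,
    toy = list(head = c("H1", "H2"), middle = "M1",
               tail = c("T1", "T2", "T3")),
    template = list(head = c("N1", "C1", "C2", "C3", "P1", "O1", "O2"),
                    middle = c("G1", "G2", "G3"),
                    tail = c(paste0("A", 1:8), paste0("B", 1:8))))
}

# Derive element symbol from a PDB/GRO atom name when no element column is
# available: first alphabetic character, two-letter elements recognized
# when unambiguous (FE, CL, MG, ZN).
.guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$|^[0-9]+", "", atom_name))
  nm <- toupper(gsub("^\\s+|\\s+$", "", nm))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  el[two %in% c("FE", "CL", "MG", "ZN", "BR")] <-
    two[two %in% c("FE", "CL", "MG", "ZN", "BR")]
  el[el == ""] <- "C"
  el
}
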