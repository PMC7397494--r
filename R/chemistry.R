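# Chemical reference data: elements, van der Waals radii, amino-acid
# side-chain topology (internal coordinates beyond CB), chi-angle
# definitions and covalent connectivity.
#
# The topology table drives three things: the synthetic polypeptide builder
# (atom placement), bonded-neighbour lookup for B-factor change features and
# clash exclusions, and chi-angle measurement for rotamer scoring. Ring
# geometries are idealized; closure bonds are listed explicitly so the bond
# graph is complete even though the last ring atom is placed by torsion.

ATOMIC_NUMBERS <- c(H = 1L, C = 6L, N = 7L, O = 8L, P = 15L, S = 16L, SE = 34L)

# Default van der Waals radii (Angstrom); configurable via options.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80)

DEFAULT_VDW_RADIUS <- 1.70

MAIN_CHAIN_ATOMS <- c("N", "CA", "CB", "O", "C")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

element_of <- function(atom_name) {
  nm <- gsub("[0-9']", "", toupper(atom_name))
  if (nm %in% c("SE", "SD", "SG")) return(ifelse(nm == "SE", "SE", "S"))
  first <- substr(nm, 1L, 1L)
  if (first %in% names(ATOMIC_NUMBERS)) first else "C"
}

vdw_radius <- function(element) {
  r <- getOption("rescorrect.vdw_radii", VDW_RADII)
  if (element %in% names(r)) unname(r[[element]]) else {
    warning("unknown element '", element, "': using default vdW radius ",
            DEFAULT_VDW_RADIUS, " A")
    DEFAULT_VDW_RADIUS
  }
}

# Side-chain internal-coordinate topology beyond CB.
# Each entry: name, p1/p2/p3 reference atoms, bond (A), angle (deg), and a
# torsion that is either list(chi = k, offset = deg) or list(fixed = deg).
sc_atom <- function(name, p1, p2, p3, bond, angle, chi = NULL, offset = 0,
                    fixed = NULL) {
  list(name = name, p = c(p1, p2, p3), bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)
}

AA_TOPOLOGY <- list(
  SER = list(sc_atom("OG",  "N", "CA", "CB", 1.417, 110.8, chi = 1L)),
  CYS = list(sc_atom("SG",  "N", "CA", "CB", 1.808, 113.8, chi = 1L)),
  THR = list(sc_atom("OG1", "N", "CA", "CB", 1.433, 109.6, chi = 1L),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1L, offset = -120)),
  VAL = list(sc_atom("CG1", "N", "CA", "CB", 1.527, 110.4, chi = 1L),
             sc_atom("CG2", "N", "CA", "CB", 1.527, 110.4, chi = 1L, offset = 120)),
  LEU = list(sc_atom("CG",  "N", "CA", "CB", 1.530, 116.3, chi = 1L),
             sc_atom("CD1", "CA", "CB", "CG", 1.521, 110.5, chi = 2L),
             sc_atom("CD2", "CA", "CB", "CG", 1.521, 110.5, chi = 2L, offset = 120)),
  ILE = list(sc_atom("CG1", "N", "CA", "CB", 1.530, 110.4, chi = 1L),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1L, offset = -120),
             sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.8, chi = 2L)),
  ASP = list(sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi = 1L),
             sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.4, chi = 2L),
             sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.4, chi = 2L, offset = 180)),
  ASN = list(sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi = 1L),
             sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, chi = 2L),
             sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.4, chi = 2L, offset = 180)),
  GLU = list(sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1L),
             sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi = 2L),
             sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.4, chi = 3L),
             sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.4, chi = 3L, offset = 180)),
  GLN = list(sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1L),
             sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi = 2L),
             sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, chi = 3L),
             sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.4, chi = 3L, offset = 180)),
  LYS = list(sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1L),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi = 2L),
             sc_atom("CE",  "CB", "CG", "CD", 1.520, 111.3, chi = 3L),
             sc_atom("NZ",  "CG", "CD", "CE", 1.489, 111.9, chi = 4L)),
  ARG = list(sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1L),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi = 2L),
             sc_atom("NE",  "CB", "CG", "CD", 1.461, 112.0, chi = 3L),
             sc_atom("CZ",  "CG", "CD", "NE", 1.329, 124.2, chi = 4L),
             sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.0, fixed = 0),
             sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.0, fixed = 180)),
  MET = list(sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1L),
             sc_atom("SD",  "CA", "CB", "CG", 1.803, 112.7, chi = 2L),
             sc_atom("CE",  "CB", "CG", "SD", 1.791, 100.9, chi = 3L)),
  HIS = list(sc_atom("CG",  "N", "CA", "CB", 1.497, 113.8, chi = 1L),
             sc_atom("ND1", "CA", "CB", "CG", 1.378, 122.7, chi = 2L),
             sc_atom("CD2", "CA", "CB", "CG", 1.354, 131.0, chi = 2L, offset = 180),
             sc_atom("CE1", "CB", "CG", "ND1", 1.321, 109.0, fixed = 180),
             sc_atom("NE2", "CB", "CG", "CD2", 1.374, 107.2, fixed = 180)),
  PHE = list(sc_atom("CG",  "N", "CA", "CB", 1.502, 113.8, chi = 1L),
             sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.7, chi = 2L),
             sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.7, chi = 2L, offset = 180),
             sc_atom("CE1", "CB", "CG", "CD1", 1.382, 120.7, fixed = 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.382, 120.7, fixed = 180),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, fixed = 0)),
  TYR = list(sc_atom("CG",  "N", "CA", "CB", 1.512, 113.8, chi = 1L),
             sc_atom("CD1", "CA", "CB", "CG", 1.389, 120.9, chi = 2L),
             sc_atom("CD2", "CA", "CB", "CG", 1.389, 120.9, chi = 2L, offset = 180),
             sc_atom("CE1", "CB", "CG", "CD1", 1.382, 121.1, fixed = 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.382, 121.1, fixed = 180),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.378, 119.6, fixed = 0),
             sc_atom("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, fixed = 180)),
  TRP = list(sc_atom("CG",  "N", "CA", "CB", 1.498, 113.6, chi = 1L),
             sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, chi = 2L),
             sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.6, chi = 2L, offset = 180),
             sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.2, fixed = 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.2, fixed = 180),
             sc_atom("CE3", "CD1", "CG", "CD2", 1.398, 133.9, fixed = 180),
             sc_atom("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, fixed = 180),
             sc_atom("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, fixed = 180),
             sc_atom("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, fixed = 0)),
  PRO = list(sc_atom("CG",  "N", "CA", "CB", 1.492, 104.5, chi = 1L),
             sc_atom("CD",  "CA", "CB", "CG", 1.503, 106.1, chi = 2L))
)

# Ring-closure (and PRO N-CD) bonds not implied by the placement order.
EXTRA_BONDS <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CE2", "CZ")),
  TYR = list(c("CE2", "CZ")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("N", "CD"))
)

# chi angle atom quadruples, per residue type, in chi order.
CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"))
)

# Intra-residue bonded pairs (heavy atoms) for a residue type, including
# backbone bonds. Used for B-change neighbours and clash exclusions.
residue_bonds <- function(res_type) {
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (res_type != "GLY") bonds <- c(bonds, list(c("CA", "CB")))
  topo <- AA_TOPOLOGY[[res_type]]
  if (!is.null(topo))
    bonds <- c(bonds, lapply(topo, function(a) c(a$p[3L], a$name)))
  extra <- EXTRA_BONDS[[res_type]]
  if (!is.null(extra)) bonds <- c(bonds, extra)
  bonds
}
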