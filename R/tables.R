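# Residue-level lookup tables shared across modules.

AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Clustal-X conservation groups ("strong" = conservative substitution,
# "weak" = semi-conservative), the convention jalview displays.
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                   "MILV", "MILF", "HY", "FYW")
WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
                 "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")

group_members <- function(groups) strsplit(groups, "")

# Element van der Waals radii (Angstrom), heavy-atom model.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas (Angstrom^2) for residue X in
# an extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical column);
# all-atom values, used as the denominator of relative accessibility.
MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Hydrogen-bond-capable heavy atoms by residue chemistry (no hydrogens in the
# model, so capability is tabulated, not inferred). Backbone N donates
# (except proline), backbone O/OXT accepts; side chains per residue.
SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  TRP = "NE1")
SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"))

# Side-chain charged atoms for salt bridges (His treated as chargeable,
# the Protein Interactions Calculator convention).
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))

HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET",
                          "PHE", "TRP", "PRO", "TYR")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

`%||%` <- function(a, b) if (is.null(a)) b else a
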