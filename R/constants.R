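# Amino-acid and geometry lookup tables shared across modules.

#' @noRd
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

names(AA3) <- AA1
AA1_FROM_3 <- stats::setNames(AA1, AA3)

# Backbone atom names used by the PDB reader and the mutant builder.
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Water residue names removed on read.
WATER_RESNAMES <- c("HOH", "WAT", "DOD")

# van der Waals radii by element (Angstrom); 1.70 for anything unlisted.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# Formal side-chain charges used by the coarse electrostatics term.
SIDECHAIN_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 0.5)

# Polar / apolar side-chain classification for the solvation proxies.
POLAR_AA  <- c("S", "T", "N", "Q", "Y", "C", "H", "K", "R", "D", "E", "W")
APOLAR_AA <- c("A", "V", "L", "I", "M", "F", "P")

# Number of side-chain chi angles; rotamer count proxy is 3^n_chi.
N_CHI <- c(G = 0, A = 0, S = 1, C = 1, T = 1, V = 1, P = 1,
           L = 2, I = 2, N = 2, D = 2, H = 2, F = 2, Y = 2, W = 2,
           M = 3, E = 3, Q = 3, K = 4, R = 4)

# Backbone flexibility weights for the main-chain entropy proxy.
BB_FLEX <- c(G = 1.5, P = 0.3)

# Mean side-chain extent (Angstrom) beyond C-beta along the CA->CB axis;
# used to place the single pseudo-atom standing in for the modelled side chain.
SIDECHAIN_LENGTH <- c(G = 0, A = 0, S = 0.9, C = 1.2, T = 0.9, V = 0.9,
                      P = 0.9, L = 1.6, I = 1.6, M = 2.1, F = 2.4, Y = 2.9,
                      W = 3.0, H = 2.2, K = 2.9, R = 3.6, D = 1.5, E = 2.2,
                      N = 1.5, Q = 2.2)

# Ideal covalent bond lengths (Angstrom) by sorted element pair.
IDEAL_BOND <- c("C-C" = 1.52, "C-N" = 1.43, "C-O" = 1.36, "C-S" = 1.81,
                "N-N" = 1.45, "N-O" = 1.40, "O-O" = 1.48, "S-S" = 2.05)

# Feature schema: the 29 structural features, fixed order.
FREQ_BIN_EDGES <- c(0, seq(2.1, 3.3, by = 0.1))

.freq_labels <- function() {
  lo <- FREQ_BIN_EDGES[-length(FREQ_BIN_EDGES)]
  hi <- FREQ_BIN_EDGES[-1]
  fmt <- function(v) ifelse(v == 0, "0", sprintf("%.1f", v))
  sprintf("Frequency_[%s,%s)", fmt(lo), fmt(hi))
}

FEATURE_NAMES <- c(
  "Total energy", "Backbone H-bond", "Sidechain H-bond",
  "Van der Waals forces", "Electrostatic attractions",
  "Solvation polar", "Solvation hydrophobic", "Van der Waals clashes",
  "Entropy side chain", "Entropy main chain", "Torsional clash",
  "Backbone clash", "Helix dipole",
  "Current energy", "Bond energy",
  "Stereochemical improper dihedral potential",
  .freq_labels()
)

N_FEATURES <- 29L
ENCODED_DIM <- 58L

MODEL_SCHEMA_VERSION <- "1.0"
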