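#' @useDynLib stackpep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train
#' @importFrom e1071 svm naiveBayes
#' @importFrom class knn
NULL

# Canonical residue ordering used for all composition features.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Standard amino-acid alphabet
#'
#' The 20 one-letter residue codes in the alphabetical order used for all
#' feature vectors produced by this package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA20

#' Five-class physicochemical residue grouping
#'
#' Grouping used by the grouped composition encoders (GAAC/GDPC/GTPC):
#' aliphatic (g1), aromatic (g2), positively charged (g3), negatively
#' charged (g4) and uncharged (g5) residues.
#'
#' @return Named list of five character vectors partitioning [aa_alphabet()].
#' @export
gaac_groups <- function() {
  list(
    g1 = strsplit("GAVLMI", "")[[1]],
    g2 = strsplit("FYW", "")[[1]],
    g3 = strsplit("KRH", "")[[1]],
    g4 = strsplit("DE", "")[[1]],
    g5 = strsplit("STCPNQ", "")[[1]]
  )
}

#' Conjoint-triad residue grouping
#'
#' Seven residue classes defined by side-chain dipole and volume, used by
#' the conjoint triad encoder.
#'
#' @return Named list of seven character vectors partitioning [aa_alphabet()].
#' @export
ctriad_groups <- function() {
  list(
    g1 = strsplit("AGV", "")[[1]],
    g2 = strsplit("ILFP", "")[[1]],
    g3 = strsplit("YMTS", "")[[1]],
    g4 = strsplit("HNQW", "")[[1]],
    g5 = strsplit("RK", "")[[1]],
    g6 = strsplit("DE", "")[[1]],
    g7 = strsplit("C", "")[[1]]
  )
}

# 13 physicochemical properties, each splitting the alphabet into 3 groups
# (iLearn/iFeature convention). Dimensions of the CTD encoders (39/39/195)
# follow from this table.
CTD_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE", "RAHCKMV", "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV", "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT", "GRHA", "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV", "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP", "SGTAW", "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD", "NTPG", "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity                  = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability            = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge                    = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct           = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solventaccess             = c("ALFCGIVW", "RKQEND", "MSPTHY")
)

#' Three-group physicochemical property table for CTD encoders
#'
#' Thirteen structural/physicochemical properties, each assigning every
#' residue to one of three groups (e.g. polar / neutral / hydrophobic).
#'
#' @return Named list of 13 elements; each a character vector of three
#'   strings whose residues partition the alphabet.
#' @export
ctd_groups <- function() CTD_GROUPS

# Sandberg et al. five z-scales per residue.
ZSCALE_TABLE <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,  # A
   0.84, -1.67,  3.71,  0.18, -2.65,  # C
   3.98,  0.93,  1.93, -2.46,  0.75,  # D
   3.11,  0.26, -0.11, -3.04, -0.25,  # E
  -4.22,  1.94,  1.06,  0.54, -0.62,  # F
   2.05, -4.06,  0.36, -0.82, -0.38,  # G
   2.47,  1.95,  0.26,  3.90,  0.09,  # H
  -3.89, -1.73, -1.71, -0.84,  0.26,  # I
   2.29,  0.89, -2.49,  1.49,  0.31,  # K
  -4.28, -1.30, -1.49, -0.72,  0.84,  # L
  -2.85, -0.22,  0.47,  1.94, -0.98,  # M
   3.05,  1.62,  1.04, -1.15,  1.61,  # N
  -1.66,  0.27,  1.84,  0.70,  2.00,  # P
   1.75,  0.50, -1.44, -1.34,  0.66,  # Q
   3.52,  2.50, -3.50,  1.99, -0.17,  # R
   2.39, -1.07,  1.15, -1.39,  0.67,  # S
   0.75, -2.18, -1.12, -1.46, -0.40,  # T
  -2.59, -2.64, -1.54, -0.85, -0.02,  # V
  -4.36,  3.94,  0.59,  3.44, -1.59,  # W
  -2.54,  2.44,  0.43,  0.04, -1.47   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA20, paste0("z", 1:5)))

#' Z-scale descriptor table
#'
#' Five physicochemical z-scale descriptors per residue (lipophilicity,
#' steric bulk/polarizability, polarity and two electronic-property scales).
#'
#' @return 20 x 5 numeric matrix, rows named by residue.
#' @export
zscale_table <- function() ZSCALE_TABLE

# Chou's standard PAAC property tables: hydrophobicity, hydrophilicity,
# side-chain mass (raw, standardized on the fly).
PAAC_PROPS <- matrix(c(
  # A      C      D      E      F      G      H      I      K      L
  0.62,  0.29, -0.90, -0.74,  1.19,  0.48, -0.40,  1.38, -1.50,  1.06,
  # M      N      P      Q      R      S      T      V      W      Y
  0.64, -0.78,  0.12, -0.85, -2.53, -0.18, -0.05,  1.08,  0.81,  0.26,
  -0.5,  -1.0,   3.0,   3.0,  -2.5,   0.0,  -0.5,  -1.8,   3.0,  -1.8,
  -1.3,   0.2,   0.0,   0.2,   3.0,   0.3,  -0.4,  -1.5,  -3.4,  -2.3,
  15.0,  47.0,  59.0,  73.0,  91.0,   1.0,  82.0,  57.0,  73.0,  57.0,
  75.0,  58.0,  42.0,  72.0, 101.0,  31.0,  45.0,  43.0, 130.0, 107.0
), nrow = 3, byrow = TRUE,
  dimnames = list(c("hydrophobicity", "hydrophilicity", "sidechainmass"), AA20))

#' Property tables for pseudo-amino-acid composition
#'
#' Hydrophobicity, hydrophilicity and side-chain mass values used by the
#' PAAC sequence-order correlation factors (raw scale; standardized to mean
#' zero / unit population variance across the 20 residues before use).
#'
#' @return 3 x 20 numeric matrix, columns named by residue.
#' @export
paac_properties <- function() PAAC_PROPS

#' BLOSUM62 substitution rows for the standard residues
#'
#' @return 20 x 20 integer matrix (symmetric), taken from the Biostrings
#'   substitution matrix collection and restricted to the standard alphabet.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "double"
  m
}

# Cache for the AAindex snapshot (built once per session).
.tables_env <- new.env(parent = emptyenv())

#' AAindex physicochemical property snapshot
#'
#' Residue-level property values from the AAindex collection distributed
#' with seqinr (544 indices); indices with a missing value for any residue
#' are dropped, leaving 531 complete indices.
#'
#' @param complete_only Drop indices containing NA (default TRUE).
#' @return Numeric matrix, one row per index (rownames = accession), one
#'   column per residue in [aa_alphabet()] order.
#' @export
aaindex_table <- function(complete_only = TRUE) {
  key <- if (complete_only) "aaindex_complete" else "aaindex_all"
  if (!is.null(.tables_env[[key]])) return(.tables_env[[key]])
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  three <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
             "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
             "Tyr", "Val")
  one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
           "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- t(vapply(e$aaindex, function(x) as.numeric(x$I[three]), numeric(20)))
  colnames(m) <- one
  m <- m[, AA20]
  if (complete_only) m <- m[!apply(m, 1L, anyNA), , drop = FALSE]
  .tables_env[[key]] <- m
  m
}

# Background residue frequencies resembling a large curated protein
# database, for the synthetic generator's "database" preset.
PROTEIN_BG_FREQS_RAW <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292
)
PROTEIN_BG_FREQS <- PROTEIN_BG_FREQS_RAW / sum(PROTEIN_BG_FREQS_RAW)
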