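# Embedded reference tables: vdW radii, side-chain physicochemical typing,
# and the BLOSUM62 background amino-acid distribution used by the
# Jensen-Shannon conservation score.

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# the carbon value.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, H = 1.20, D = 1.20)
.VDW_DEFAULT <- 1.70

#' Van der Waals radius by element symbol
#' @param element element symbol(s), case-insensitive.
#' @return radii in Angstrom (1.70 for unknown elements).
#' @export
vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Side-chain heavy-atom physicochemical typing. Backbone atoms never carry a
# property; a grid point contacted by several typed atoms carries them all.
.chargedPositive <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                         HIS = c("ND1", "NE2"))
.chargedNegative <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.donorExtra   <- list(SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1",
                      ASN = "ND2", GLN = "NE2", CYS = "SG")
.acceptorExtra <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                       GLN = "OE1", HIS = "ND1", MET = "SD")
.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "TRP")
.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

.mergeTyping <- function(...) {
  out <- list()
  for (tb in list(...)) for (res in names(tb))
    out[[res]] <- union(out[[res]], tb[[res]])
  out
}

.PROPERTY_ATOMS <- list(
  positive = .chargedPositive,
  negative = .chargedNegative,
  donor    = .mergeTyping(.chargedPositive, .donorExtra),
  acceptor = .mergeTyping(.chargedNegative, .acceptorExtra)
)

#' Physicochemical properties of one side-chain heavy atom
#'
#' @param resname 3-letter residue name.
#' @param atomName PDB atom name.
#' @param element element symbol.
#' @return character vector drawn from positive/negative/donor/acceptor/
#'   hydrophobic (possibly empty).
#' @export
atomProperties <- function(resname, atomName, element) {
  if (atomName %in% .BACKBONE_NAMES) return(character(0))
  props <- names(.PROPERTY_ATOMS)[vapply(.PROPERTY_ATOMS, function(tb)
    atomName %in% tb[[resname]], logical(1))]
  if (resname %in% .HYDROPHOBIC_RES && toupper(element) == "C")
    props <- c(props, "hydrophobic")
  props
}

.POCKET_PROPERTIES <- c("donor", "acceptor", "positive", "negative", "hydrophobic")

# Background amino-acid distribution associated with BLOSUM62, in the order
# A R N D C Q E G H I L K M F P S T W Y V (Capra & Singh's scorer ships the
# same table); normalized to sum exactly 1.
.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.BLOSUM62_BG_RAW <- c(0.078, 0.051, 0.041, 0.052, 0.024, 0.034, 0.059,
                      0.083, 0.025, 0.062, 0.092, 0.056, 0.024, 0.044,
                      0.043, 0.059, 0.055, 0.014, 0.034, 0.072)

#' BLOSUM62 background amino-acid frequencies
#'
#' The marginal amino-acid distribution of the BLOSUM62 substitution model,
#' used as the null distribution of the Jensen-Shannon conservation score.
#'
#' @return named 20-vector summing to 1, in the order
#'   A R N D C Q E G H I L K M F P S T W Y V.
#' @export
blosum62Background <- function() {
  stats::setNames(.BLOSUM62_BG_RAW / sum(.BLOSUM62_BG_RAW), .AA_ORDER)
}

# 3-letter -> 1-letter residue codes; nonstandard residues become 'X'.
.aa321 <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  out[is.na(out) | !out %in% .AA_ORDER] <- "X"
  out
}
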