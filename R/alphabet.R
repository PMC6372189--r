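#' @keywords internal
#' @useDynLib eicotriage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rnorm runif rbinom rgeom sd setNames
#' @importFrom utils data read.table write.table
"_PACKAGE"

## Amino-acid alphabet used throughout: the 20 standard residues plus
## selenocysteine (U) and unknown (X). Ambiguity codes B/Z/J are collapsed
## to X on input; scoring treats U as C.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA_STANDARD, "U", "X")
AA_AMBIGUOUS <- c("B", "Z", "J")

## Robinson & Robinson (1991) amino-acid background frequencies, the
## composition conventionally used with BLOSUM62 log-odds.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Normalize a raw residue string to the package alphabet
#'
#' Upper-cases, strips a single terminal stop (`*`), maps the ambiguity
#' codes B/Z/J to X (with a warning) and rejects anything else outside the
#' 22-letter alphabet.
#'
#' @param x character scalar of residue letters.
#' @param id record identifier used in error messages.
#' @return normalized residue string.
#' @keywords internal
normalize_residues <- function(x, id = "<sequence>") {
  x <- toupper(x)
  x <- sub("\\*$", "", x)
  letters <- strsplit(x, "", fixed = TRUE)[[1]]
  amb <- letters %in% AA_AMBIGUOUS
  if (any(amb)) {
    warning(sprintf("record '%s': ambiguity code(s) %s mapped to X",
                    id, paste(unique(letters[amb]), collapse = ",")),
            call. = FALSE)
    letters[amb] <- "X"
  }
  bad <- !(letters %in% AA_ALPHABET)
  if (any(bad)) {
    stop(sprintf("record '%s': illegal character '%s' at offset %d",
                 id, letters[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  paste(letters, collapse = "")
}

## 3-letter -> 1-letter residue codes for PDB parsing.  MSE -> M, SEC -> U,
## anything unrecognized -> X.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U")

three_to_one <- function(codes) {
  out <- AA_THREE_TO_ONE[toupper(codes)]
  out[is.na(out)] <- "X"
  unname(out)
}
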