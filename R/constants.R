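# Published constant tables used by the physicochemical property block and
# the motif scanner. Sources: Kyte & Doolittle (1982) J Mol Biol 157:105
# (hydropathy); Guruprasad, Reddy & Pandit (1990) Protein Eng 4:155 (DIWV
# dipeptide instability weights); Bjellqvist et al. (1993) Electrophoresis
# 14:1023 (pKa set, as used by the ExPASy ProtParam tool); average residue
# masses per the standard atomic-weight tables.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3)

# average (not monoisotopic) residue masses, Da; a free protein additionally
# carries one water (18.0153 Da)
WATER_MASS <- 18.0153
RESIDUE_MASS_AVG <- c(A = 71.0779, C = 103.1429, D = 115.0874, E = 129.114,
                      F = 147.1738, G = 57.0513, H = 137.1393, I = 113.1576,
                      K = 128.1723, L = 113.1576, M = 131.196, N = 114.1026,
                      P = 97.1152, Q = 128.1292, R = 156.1857, S = 87.0773,
                      T = 101.1039, V = 99.131, W = 186.2099, Y = 163.1732)

# DIWV[x, y] is the instability weight of the dipeptide xy (x followed by y)
DIWV <- matrix(c(
  1.0, 44.94, -7.49, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 33.6, 1.0, 1.0, 20.26, 33.6, 1.0, 20.26, -6.54, 1.0, 1.0, 33.6, -6.54, 24.68, 1.0,
  1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 20.26, -14.03, 1.0, 1.0, 1.0,
  1.0, 44.94, 20.26, 33.6, 1.0, 1.0, -6.54, 20.26, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 20.26, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, 13.34, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 33.601,
  -7.49, 1.0, 1.0, -6.54, 1.0, 13.34, 1.0, -7.49, -7.49, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 13.34, -7.49,
  1.0, 1.0, 1.0, 1.0, -9.37, -9.37, 1.0, 44.94, 24.68, 1.0, 1.0, 24.68, -1.88, 1.0, 1.0, 1.0, -6.54, 1.0, -1.88, 44.94,
  1.0, 1.0, 1.0, 44.94, 1.0, 1.0, 13.34, 1.0, -7.49, 20.26, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, -7.49, 1.0, -7.49, 33.6, 1.0, -6.54, 24.64, 33.6, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 20.26, 33.6, 20.26, 1.0, 1.0, 1.0, 24.68, 1.0,
  13.34, 1.0, 1.0, 1.0, 1.0, 1.0, 58.28, 1.0, 1.0, 1.0, -1.88, 1.0, 44.94, -6.54, -6.54, 44.94, -1.88, 1.0, 1.0, 24.68,
  1.0, -1.88, 1.0, 1.0, -14.03, -14.03, 1.0, 44.94, 24.68, 1.0, 1.0, 1.0, -1.88, -6.54, 1.0, 1.0, -7.49, 1.0, -9.37, 1.0,
  20.26, -6.54, -6.54, 18.38, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 20.26, 20.26, -6.54, 20.26, 1.0, 20.26, -1.88, 1.0,
  1.0, -6.54, 20.26, 20.26, -6.54, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 44.94, 1.0, -6.54, 1.0, -6.54,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 20.26, 1.0, 1.0, 1.0, 1.0, 13.34, 20.26, 20.26, 58.28, 44.94, 1.0, 1.0, 58.28, -6.54,
  1.0, 33.6, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 44.94, 20.26, 20.26, 20.26, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 1.0, 20.26, 13.34, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, -6.54, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, -14.03, 1.0, 1.0, -7.49, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, -6.54,
  -14.03, 1.0, 1.0, 1.0, 1.0, -9.37, 24.68, 1.0, 1.0, 13.34, 24.68, 13.34, 1.0, 1.0, 1.0, 1.0, -14.03, -7.49, 1.0, 1.0,
  24.68, 1.0, 24.68, -6.54, 1.0, -7.49, 13.34, 1.0, 1.0, 1.0, 44.94, 1.0, 13.34, 1.0, -15.91, 1.0, -7.49, 1.0, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))

# Bjellqvist pKa values; side chains plus residue-specific terminal values
PKA_POSITIVE <- c(K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM <- c(A = 7.59, E = 7.7, M = 7.0, P = 8.36, S = 6.93, T = 6.82, V = 7.44)
PKA_CTERM_DEFAULT <- 3.55
PKA_CTERM <- c(D = 4.55, E = 4.75)

# IUPAC degenerate nucleotide codes
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Built-in cis-element catalogue
#'
#' A small catalogue of named plant promoter cis-elements with canonical
#' consensus patterns in IUPAC code, covering the light-, hormone- and
#' stress-responsive elements commonly reported for CBF promoters (G-box,
#' ABRE, CGTCA-motif, MBS, LTR, ERE, TGA-element, TATC-box, GARE-motif and
#' others). These are canonical consensus sequences, not a snapshot of any
#' external database; pass your own table to [scan_catalogue()] to override.
#'
#' @return A data frame with columns `name` and `iupac`.
#' @export
#' @examples
#' head(default_cis_elements())
default_cis_elements <- function() {
  path <- system.file("extdata", "cis_elements.tsv", package = "cbfsurvey",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Built-in functional-category keyword map
#'
#' Keyword map for classifying surveyed target genes into the eleven
#' functional categories used for cold-responsive CBF targets (carbohydrate
#' metabolism, lipid metabolism, cell wall modification, circadian rhythm,
#' calcium signaling, transcription factor, hormone signaling, kinase,
#' chloroplast, transporter, other). Matching is case-insensitive substring
#' matching of gene annotations; see [classify_targets()].
#'
#' @return A data frame with columns `category` and `keyword`.
#' @export
default_category_keywords <- function() {
  path <- system.file("extdata", "functional_categories.tsv",
                      package = "cbfsurvey", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' The CRT/DRE motif
#'
#' The C-repeat / dehydration-responsive element bound by CBF transcription
#' factors, G/ACCGAC, written as the IUPAC degenerate pattern `RCCGAC`.
#'
#' @return A single character string, `"RCCGAC"`.
#' @export
crt_dre_motif <- function() "RCCGAC"
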