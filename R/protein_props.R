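# The physicochemical property block: length, molecular weight, isoelectric
# point, GRAVY, instability index and aliphatic index, computed exactly as
# the ExPASy ProtParam tool defines them (average residue masses; Bjellqvist
# pKa set with residue-specific terminal values; Kyte-Doolittle hydropathy;
# Guruprasad DIWV dipeptide weights). Computation runs at full precision;
# round_half_up() is the presentation rule for two-decimal tables.

check_residues <- function(protein) {
  res <- strsplit(toupper(protein), "")[[1]]
  bad <- which(!res %in% AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop(sprintf("ambiguous or invalid residue '%s' at position %d",
                 res[bad[1]], bad[1]), call. = FALSE)
  }
  res
}

#' Grand average of hydropathicity (GRAVY)
#'
#' The sum of Kyte-Doolittle hydropathy values of all residues divided by
#' the sequence length. Negative values indicate hydrophilic proteins.
#'
#' @param protein Protein sequence string (standard 20 residues).
#' @return Numeric GRAVY value.
#' @export
#' @examples
#' gravy(strrep("A", 10))  # 1.8, the alanine hydropathy
gravy <- function(protein) {
  res <- check_residues(protein)
  mean(KD_HYDROPATHY[res])
}

#' Molecular weight in kDa
#'
#' Sum of average residue masses plus one water (18.0153 Da), in kDa.
#'
#' @inheritParams gravy
#' @return Molecular weight in kilodaltons.
#' @export
molecular_weight <- function(protein) {
  res <- check_residues(protein)
  (sum(RESIDUE_MASS_AVG[res]) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch partial charges summed over the basic side chains
#' (K, R, H) and the N-terminus, minus the acidic side chains (D, E, C, Y)
#' and the C-terminus, under the Bjellqvist pKa set with residue-specific
#' terminal pKa values.
#'
#' @inheritParams gravy
#' @param pH pH at which to evaluate the charge.
#' @return Net charge (dimensionless).
#' @export
net_charge <- function(protein, pH) {
  res <- check_residues(protein)
  counts <- table(factor(res, levels = AMINO_ACIDS))
  pka_nt <- PKA_NTERM[res[1]]
  if (is.na(pka_nt)) pka_nt <- PKA_NTERM_DEFAULT
  pka_ct <- PKA_CTERM[res[length(res)]]
  if (is.na(pka_ct)) pka_ct <- PKA_CTERM_DEFAULT
  pos_pks <- c(PKA_POSITIVE, Nterm = unname(pka_nt))
  pos_n <- c(counts[names(PKA_POSITIVE)], Nterm = 1)
  neg_pks <- c(PKA_NEGATIVE, Cterm = unname(pka_ct))
  neg_n <- c(counts[names(PKA_NEGATIVE)], Cterm = 1)
  sum(pos_n / (10^(pH - pos_pks) + 1)) - sum(neg_n / (10^(neg_pks - pH) + 1))
}

#' Isoelectric point
#'
#' The pH at which [net_charge()] crosses zero, found by bisection on
#' `[0, 14]` to `|charge| < 1e-4`. The charge function is monotone
#' decreasing in pH, so the root is unique.
#'
#' @inheritParams gravy
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(protein, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-9) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Instability index
#'
#' The Guruprasad dipeptide-weight statistic: `(10 / L) * sum(DIWV(x_i,
#' x_{i+1}))` over adjacent residue pairs. Values below 40 predict an
#' in-vitro-stable protein.
#'
#' @inheritParams gravy
#' @return Numeric instability index.
#' @export
instability_index <- function(protein) {
  res <- check_residues(protein)
  L <- length(res)
  if (L < 2L) stop("instability index requires length >= 2", call. = FALSE)
  (10 / L) * sum(DIWV[cbind(res[-L], res[-1])])
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' `X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` where X is the mole
#' percent of each residue.
#'
#' @inheritParams gravy
#' @return Numeric aliphatic index.
#' @export
#' @examples
#' aliphatic_index(strrep("A", 8))  # 100
aliphatic_index <- function(protein) {
  res <- check_residues(protein)
  x <- 100 * table(factor(res, levels = AMINO_ACIDS)) / length(res)
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Round half away from zero
#'
#' Presentation rounding used for two-decimal property tables (R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  # small epsilon counters binary representation of decimals like 0.285
  sign(x) * floor(abs(x) * 10^digits + 0.5 + sqrt(.Machine$double.eps)) /
    10^digits
}

#' Full physicochemical property block for a set of proteins
#'
#' Computes, per protein, the characterization table familiar from gene
#' family surveys: length in residues, molecular weight (kDa), isoelectric
#' point, instability index (with the < 40 stability call), aliphatic index
#' and GRAVY.
#'
#' @param proteins Named character vector of protein sequences.
#' @param digits Decimal places for the rounded presentation columns; use
#'   `NULL` to keep full precision.
#' @return Data frame with columns `protein_id`, `length`, `mw_kda`, `pi`,
#'   `instability`, `aliphatic`, `gravy`, `stable`.
#' @export
protein_properties <- function(proteins, digits = 2L) {
  stopifnot(length(proteins) > 0L)
  out <- data.frame(
    protein_id = names(proteins) %||% as.character(seq_along(proteins)),
    length = nchar(proteins),
    mw_kda = vapply(proteins, molecular_weight, numeric(1)),
    pi = vapply(proteins, isoelectric_point, numeric(1)),
    instability = vapply(proteins, instability_index, numeric(1)),
    aliphatic = vapply(proteins, aliphatic_index, numeric(1)),
    gravy = vapply(proteins, gravy, numeric(1)),
    row.names = NULL)
  out$stable <- out$instability < 40
  if (!is.null(digits)) {
    num <- c("mw_kda", "pi", "instability", "aliphatic", "gravy")
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}
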