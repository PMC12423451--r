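## Protein-level statistics: molecular weight (average isotopic residue
## masses) and theoretical pI (Bjellqvist pK set, bisection on net charge).

## average residue masses, Da (monoisotopic not used; these are the
## conventional average masses summed per peptide bond residue)
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

## Bjellqvist pK values (as used by the ExPASy pI tool): C-terminus
## 3.55 throughout; N-terminal pK depends on the first residue.
PK_SIDE_POS <- c(K = 10.0, R = 12.0, H = 5.98)
PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_CTERM <- 3.55
PK_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.7)
PK_NTERM_DEFAULT <- 7.5

## net charge of a peptide at a given pH (Henderson-Hasselbalch per
## ionizable group, N and C termini included)
peptide_charge <- function(aa_counts, first_aa, pH) {
  nterm_pk <- if (first_aa %in% names(PK_NTERM)) PK_NTERM[[first_aa]]
              else PK_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - nterm_pk))
  for (a in names(PK_SIDE_POS)) {
    if (aa_counts[[a]] > 0)
      pos <- pos + aa_counts[[a]] / (1 + 10^(pH - PK_SIDE_POS[[a]]))
  }
  neg <- 1 / (1 + 10^(PK_CTERM - pH))
  for (a in names(PK_SIDE_NEG)) {
    if (aa_counts[[a]] > 0)
      neg <- neg + aa_counts[[a]] / (1 + 10^(PK_SIDE_NEG[[a]] - pH))
  }
  pos - neg
}

#' Protein statistics: residue count, molecular weight, theoretical pI
#'
#' Molecular weight is the sum of average residue masses plus one water
#' mass (18.0153 Da).  The theoretical pI is found by bisection on the
#' net charge (Henderson-Hasselbalch per ionizable group with the
#' Bjellqvist pK set, N and C termini included) to a tolerance of
#' 0.001 pH units.
#'
#' @param protein_sequence peptide string over the 20 standard amino
#'   acids.
#' @return list with `aa_count`, `molecular_weight_da`, `theoretical_pi`.
#' @export
protein_stats <- function(protein_sequence) {
  ch <- chars(protein_sequence)
  bad <- setdiff(ch, names(RESIDUE_MASS))
  if (length(bad)) stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  if (!length(ch)) stop("empty protein sequence")
  counts <- table(factor(ch, levels = names(RESIDUE_MASS)))
  mw <- sum(RESIDUE_MASS * as.numeric(counts)) + WATER_MASS
  aa_counts <- as.list(counts)
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (peptide_charge(aa_counts, ch[1], mid) > 0) lo <- mid else hi <- mid
  }
  list(aa_count = length(ch), molecular_weight_da = mw,
       theoretical_pi = (lo + hi) / 2)
}
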