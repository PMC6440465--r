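# ExPASy/ProtParam-convention protein physicochemistry: residue count,
# average-isotopic molecular weight, Bjellqvist isoelectric point and
# Kyte-Doolittle GRAVY. Tables are module-level data so an alternative
# convention can be substituted.

# average residue masses (Da), ExPASy convention
AVG_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Bjellqvist pK set (the one behind the ExPASy pI tool): side chains,
# C-terminus, and residue-specific N-terminal pKs
PK_SIDE <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0, R = 12.0)
PK_CTERM <- 3.55
PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.70, G = 7.50)
PK_NTERM_DEFAULT <- 7.50

.check_protein <- function(protein) {
  if (!nzchar(protein)) stop("empty protein sequence")
  if (grepl(sprintf("[^%s]", VALID_AA), protein))
    stop("illegal residue in protein sequence")
  strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
}

#' Molecular weight of a protein (kDa)
#'
#' Sum of average residue masses plus one water, ExPASy convention.
#' `X` contributes the mean of the twenty residue masses.
#'
#' @param protein Protein string (20 AA + X).
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(protein) {
  res <- .check_protein(protein)
  mass <- AVG_RESIDUE_MASS[res]
  mass[res == "X"] <- mean(AVG_RESIDUE_MASS)
  (sum(mass) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson--Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R) with the Bjellqvist pK set.
#'
#' @param protein Protein string.
#' @param pH pH in \[0, 14\].
#' @return Net charge in elementary charges (strictly decreasing in pH).
#' @export
net_charge <- function(protein, pH) {
  res <- .check_protein(protein)
  stopifnot(pH >= 0, pH <= 14)
  pos_term <- function(pk) 1 / (1 + 10^(pH - pk))   # basic group
  neg_term <- function(pk) -1 / (1 + 10^(pk - pH))  # acidic group
  nterm_pk <- PK_NTERM[res[1L]]
  if (is.na(nterm_pk)) nterm_pk <- PK_NTERM_DEFAULT
  q <- pos_term(nterm_pk) + neg_term(PK_CTERM)
  counts <- table(factor(res, levels = names(PK_SIDE)))
  for (aa in c("D", "E", "C", "Y")) q <- q + counts[[aa]] * neg_term(PK_SIDE[[aa]])
  for (aa in c("H", "K", "R"))      q <- q + counts[[aa]] * pos_term(PK_SIDE[[aa]])
  unname(q)
}

#' Isoelectric point
#'
#' Bisection root of [net_charge()] on pH \[0, 14\] to |charge| < 1e-4
#' (at most 100 iterations).
#'
#' @param protein Protein string.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein) {
  lo <- 0; hi <- 14
  qlo <- net_charge(protein, lo); qhi <- net_charge(protein, hi)
  if (qlo < 0 || qhi > 0) stop("no sign change of net charge on [0, 14]")
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- net_charge(protein, mid)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte--Doolittle hydropathy over residues; `X` is excluded from
#' both numerator and denominator.
#'
#' @param protein Protein string.
#' @return Dimensionless GRAVY value in \[-4.5, 4.5\].
#' @export
gravy <- function(protein) {
  res <- .check_protein(protein)
  res <- res[res != "X"]
  if (length(res) == 0L) stop("no standard residues for GRAVY")
  mean(KYTE_DOOLITTLE[res])
}

#' All physicochemical parameters of a protein
#'
#' @param protein Protein string.
#' @return Object of class `protein_params`: `aa_count`, `mw_kda`, `pi`,
#'   `gravy` (the columns of a classic family characterization table).
#' @export
protein_params <- function(protein) {
  structure(list(aa_count = nchar(protein),
                 mw_kda = molecular_weight(protein),
                 pi = isoelectric_point(protein),
                 gravy = gravy(protein)),
            class = "protein_params")
}

#' @export
print.protein_params <- function(x, ...) {
  cat(sprintf("<protein_params> %d aa, %.1f kDa, pI %.2f, GRAVY %.3f\n",
              x$aa_count, x$mw_kda, x$pi, x$gravy))
  invisible(x)
}

#' Physicochemistry table for a set of proteins
#'
#' @param seqs Named character vector of protein sequences.
#' @return Data frame with columns `gene_id`, `aa_count`, `mw_kda`, `pi`,
#'   `gravy`.
#' @export
protparam_table <- function(seqs) {
  rows <- lapply(names(seqs), function(id) {
    p <- protein_params(seqs[[id]])
    data.frame(gene_id = id, aa_count = p$aa_count, mw_kda = p$mw_kda,
               pi = p$pi, gravy = p$gravy)
  })
  do.call(rbind, rows)
}
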