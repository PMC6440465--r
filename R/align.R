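# Global pairwise alignment (Needleman-Wunsch, affine gaps) for proteins
# and DNA, identity conventions, and protein-guided codon alignment.
# The dynamic programme itself is Biostrings::pairwiseAlignment; this
# module fixes the scoring scheme and the identity bookkeeping shared by
# the identification, duplication, Ka/Ks and synteny stages.

.dna_submat <- local({
  m <- matrix(-3, 5L, 5L, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(m) <- 2
  m["N", ] <- 0; m[, "N"] <- 0   # ambiguous base: neutral, never rewarded
  m
})

#' Global pairwise alignment
#'
#' Needleman--Wunsch optimal global alignment with affine gap penalties.
#' Protein mode scores with BLOSUM62 (gap open 10, extend 0.5); DNA mode
#' scores match +2 / mismatch -3 (gap open 5, extend 2), with N neutral.
#'
#' @param a,b Sequences (plain strings) of the stated alphabet.
#' @param mode `"protein"` or `"dna"`.
#' @return Object of class `alignment`: gapped strings `a` and `b` of
#'   equal length, `score`, and `identity` (fraction, terminal gap
#'   overhangs excluded -- see [alignment_identity()]).
#' @export
global_align <- function(a, b, mode = c("protein", "dna")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  valid <- if (mode == "protein") VALID_AA else VALID_NT
  if (grepl(sprintf("[^%s]", valid), a) || grepl(sprintf("[^%s]", valid), b))
    stop("illegal character for ", mode, " alignment")
  if (mode == "protein") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = .dna_submat, gapOpening = 5, gapExtension = 2)
  }
  aln <- structure(list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa), mode = mode), class = "alignment")
  aln$identity <- alignment_identity(aln)
  aln
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s, %d columns, score %.1f, identity %.3f\n",
              x$mode, nchar(x$a), x$score, x$identity))
  invisible(x)
}

#' Fraction of identical columns in a pairwise alignment
#'
#' The default convention excludes terminal gap overhangs from the
#' denominator but counts internal gap columns as mismatches, the
#' reading used for the ">80% coding-sequence similarity" duplication
#' rule, where the compared sequences may differ in length.
#'
#' @param aln An `alignment`.
#' @param convention `"exclude_terminal_gaps"` (default) or `"all_columns"`.
#' @return Identity fraction in \[0, 1\].
#' @export
alignment_identity <- function(aln,
                               convention = c("exclude_terminal_gaps",
                                              "all_columns")) {
  convention <- match.arg(convention)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1L]]
  n <- length(ca)
  keep <- rep(TRUE, n)
  if (convention == "exclude_terminal_gaps") {
    gap <- ca == "-" | cb == "-"
    lead <- cumsum(!gap) == 0L
    trail <- rev(cumsum(rev(!gap)) == 0L)
    keep <- !(gap & (lead | trail))
  }
  if (!any(keep)) return(0)
  sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep)
}

# vectorized helpers: one pairwiseAlignment call for many patterns
# against one subject (identical scoring to global_align)
.batch_pa <- function(patterns, subject, mode) {
  if (mode == "protein") {
    Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
      type = "global", substitutionMatrix = .dna_submat,
      gapOpening = 5, gapExtension = 2)
  }
}

.batch_scores <- function(patterns, subject, mode) {
  if (length(patterns) == 0L) return(numeric(0))
  Biostrings::score(.batch_pa(patterns, subject, mode))
}

.batch_identities <- function(patterns, subject, mode,
                              convention = "exclude_terminal_gaps") {
  if (length(patterns) == 0L) return(numeric(0))
  pa <- .batch_pa(patterns, subject, mode)
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  vapply(seq_along(ga), function(i)
    alignment_identity(list(a = ga[[i]], b = gb[[i]]), convention),
    numeric(1L))
}

#' Protein-guided codon alignment
#'
#' Projects a protein alignment onto the two coding sequences: each
#' protein residue becomes its codon and each protein gap a 3-bp gap.
#'
#' @param protein_aln An `alignment` of the two translated proteins.
#' @param cds_a,cds_b In-frame coding sequences (no stop codon), with
#'   `nchar(cds) == 3 * nchar(ungapped protein)` and translation equal to
#'   the aligned protein.
#' @return List with gapped codon strings `a` and `b` (equal length,
#'   divisible by 3).
#' @export
codon_align <- function(protein_aln, cds_a, cds_b) {
  project <- function(gapped, cds, label) {
    res <- strsplit(gapped, "", fixed = TRUE)[[1L]]
    ungapped <- res[res != "-"]
    if (nchar(cds) != 3L * length(ungapped))
      stop("CDS length of ", label, " (", nchar(cds),
           ") does not equal 3 x protein length (", length(ungapped), ")")
    prot <- translate_cds(cds, strip_stop = FALSE)
    pr <- strsplit(prot, "", fixed = TRUE)[[1L]]
    mism <- which(pr != ungapped)
    if (length(mism) > 0L)
      stop("translation of ", label, " CDS differs from protein at residue ",
           mism[[1L]])
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- codons
    paste(out, collapse = "")
  }
  list(a = project(protein_aln$a, cds_a, "a"),
       b = project(protein_aln$b, cds_b, "b"))
}
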