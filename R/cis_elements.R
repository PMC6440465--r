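# Promoter cis-acting element scanning: IUPAC-pattern catalog, two-strand
# occurrence search (via Biostrings with ambiguity expansion; N in the
# promoter never matches), and per-gene / per-functional-class summaries.

#' Load a cis-element catalog
#'
#' Tab-separated file with columns `element`, `pattern` (IUPAC alphabet),
#' `class`; one row per pattern (an element may carry several patterns).
#'
#' @param path Catalog file.
#' @return Data frame of class `cis_catalog`.
#' @export
load_cis_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "pattern", "class")
  if (!all(need %in% names(cat)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  cat$pattern <- toupper(cat$pattern)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", cat$pattern) | !nzchar(cat$pattern)
  if (any(bad))
    stop("non-IUPAC pattern(s): ", paste(cat$element[bad], collapse = ", "))
  class(cat) <- c("cis_catalog", "data.frame")
  cat
}

#' The catalog of plant cis-acting elements shipped with the package
#'
#' PlantCARE-style consensus strings for the elements commonly reported
#' in plant promoter surveys (G-Box, ABRE, the CGTCA/TGACG MeJA motifs,
#' P-box/GARE GA elements, TGA-element, TCA-element, HSE, MBS, TC-rich
#' repeats, CAT-box, CCGTCC-box). Exact database patterns vary by
#' PlantCARE version; the catalog is data, not code, and can be replaced
#' via [load_cis_catalog()].
#'
#' @return A `cis_catalog` data frame.
#' @export
default_cis_catalog <- function() {
  load_cis_catalog(system.file("extdata", "cis_catalog.tsv",
                               package = "iddfam", mustWork = TRUE))
}

.iupac_hits <- function(pattern, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = c(pattern = FALSE, subject = TRUE))
  if (length(m) == 0L)
    return(data.frame(position = integer(), matched = character()))
  matched <- as.character(m)
  keep <- !grepl("N", matched, fixed = TRUE)  # N never matches a motif
  data.frame(position = Biostrings::start(m)[keep], matched = matched[keep])
}

#' Scan a promoter for catalog elements on both strands
#'
#' Reports every occurrence of every catalog pattern on the given strand
#' and on the reverse complement, per strand separately (reverse
#' complement equivalences are not collapsed). Positions are 1-based
#' offsets in the promoter as given; minus-strand hits report the
#' position of the site's leftmost base in promoter coordinates.
#'
#' @param promoter Nucleotide string (the extracted upstream region).
#' @param catalog A `cis_catalog` (default: the shipped catalog).
#' @return Data frame: `element`, `class`, `strand`, `position`,
#'   `matched` (the promoter substring; for minus-strand hits the site as
#'   read on the minus strand).
#' @export
scan_promoter <- function(promoter, catalog = default_cis_catalog()) {
  promoter <- toupper(promoter)
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    pat <- catalog$pattern[i]
    plus <- .iupac_hits(pat, promoter)
    if (nrow(plus) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        element = catalog$element[i], class = catalog$class[i],
        strand = "+", position = plus$position, matched = plus$matched)
    minus <- .iupac_hits(revcomp(pat), promoter)
    if (nrow(minus) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        element = catalog$element[i], class = catalog$class[i],
        strand = "-", position = minus$position,
        matched = vapply(minus$matched, revcomp, character(1L),
                         USE.NAMES = FALSE))
  }
  if (length(out) == 0L)
    return(data.frame(element = character(), class = character(),
                      strand = character(), position = integer(),
                      matched = character()))
  res <- do.call(rbind, out)
  res[order(res$position, res$element, res$strand), , drop = FALSE]
}

#' Scan the promoters of many genes
#'
#' @param promoters Named character vector (names = gene ids).
#' @param catalog A `cis_catalog`.
#' @return Data frame as [scan_promoter()] with a leading `gene_id`
#'   column.
#' @export
scan_promoters <- function(promoters, catalog = default_cis_catalog()) {
  rows <- lapply(names(promoters), function(g) {
    h <- scan_promoter(promoters[[g]], catalog)
    if (nrow(h) == 0L) return(NULL)
    cbind(gene_id = g, h)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), element = character(),
                      class = character(), strand = character(),
                      position = integer(), matched = character()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-gene element and functional-class count tables
#'
#' Two counting conventions are reported. `by_element` and `by_class`
#' count every reported hit (both strands), so their totals equal the
#' number of hit rows. `by_class_sites` counts unique genomic sites
#' (gene, class, position) once: a palindromic element (G-Box) or a
#' reverse-complement pattern pair (CGTCA-motif / TGACG-motif) occupies
#' one site even though it is reported on both strands, which is the
#' convention used for "n elements of class X" statements.
#'
#' @param gene_ids All gene ids to report (genes without hits get
#'   all-zero rows).
#' @param hits Data frame from [scan_promoters()].
#' @param catalog A `cis_catalog` (defines element/class universe).
#' @return List with matrices `by_element` (gene x element hit counts),
#'   `by_class` (gene x class hit counts), `by_class_sites` (gene x class
#'   unique-site counts) and `presence` (gene x element 0/1).
#' @export
element_summary <- function(gene_ids, hits, catalog = default_cis_catalog()) {
  elements <- unique(catalog$element)
  classes <- unique(catalog$class)
  count_mat <- function(df, cols, levels2, col2) {
    tab <- table(factor(df$gene_id, levels = gene_ids),
                 factor(df[[col2]], levels = levels2))
    m <- matrix(as.integer(tab), length(gene_ids), length(levels2),
                dimnames = list(gene_ids, levels2))
    m
  }
  empty <- function(levels2) matrix(0L, length(gene_ids), length(levels2),
                                    dimnames = list(gene_ids, levels2))
  if (nrow(hits) == 0L) {
    by_el <- empty(elements); by_cl <- empty(classes)
    by_sites <- empty(classes)
  } else {
    by_el <- count_mat(hits, NULL, elements, "element")
    by_cl <- count_mat(hits, NULL, classes, "class")
    sites <- unique(hits[, c("gene_id", "class", "position")])
    by_sites <- count_mat(sites, NULL, classes, "class")
  }
  list(by_element = by_el, by_class = by_cl, by_class_sites = by_sites,
       presence = (by_el > 0L) * 1L)
}
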