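# Readers/writers for FASTA and GFF3, coordinate helpers, exon counting and
# strand-aware promoter extraction. Sequences are plain named character
# vectors (names = record ids, optional "desc" attribute); gene models are
# lists of class "gene_model" with 1-based inclusive coordinates, the
# GFF3/IRanges convention used throughout the package.

VALID_AA  <- "ACDEFGHIKLMNPQRSTVWYX"
VALID_NT  <- "ACGTN"

#' Read a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param alphabet One of `"auto"`, `"protein"`, `"dna"`; when not
#'   `"auto"` the sequences are validated against the stated alphabet
#'   (20 amino acids plus X, or ACGTN). Lowercase/softmasked residues are
#'   uppercased on read.
#' @return Named character vector of sequences (names = ids, the first
#'   whitespace-delimited token of each header); full header descriptions
#'   are kept in the `"desc"` attribute.
#' @export
read_fasta <- function(path, alphabet = c("auto", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  if (alphabet != "auto") {
    valid <- if (alphabet == "protein") VALID_AA else VALID_NT
    bad <- grepl(sprintf("[^%s]", valid), seqs)
    if (any(bad)) stop("sequence(s) with characters outside the ", alphabet,
                       " alphabet: ", paste(ids[bad], collapse = ", "))
  }
  attr(seqs, "desc") <- stats::setNames(headers, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#' @param seq Nucleotide string (ACGTN).
#' @return Reverse complement, as a plain string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a CDS to protein
#' @param cds In-frame nucleotide string (length divisible by 3).
#' @param strip_stop Drop a single trailing stop codon, if present.
#' @return Protein string (stop codons as `*`).
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  if (strip_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Construct a gene model
#'
#' 1-based inclusive coordinates, exons sorted and non-overlapping.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals.
#' @param cds In-frame coding sequence (optional).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NA_character_) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) stop("exon end < start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("overlapping exons in ", gene_id)
  flagged <- FALSE
  if (!is.na(cds) && nchar(cds) %% 3L != 0L) {
    warning("CDS length of ", gene_id, " not divisible by 3; record flagged")
    flagged <- TRUE
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(exons[, 1L]), end = max(exons[, 2L]),
                 exons = exons, cds = cds, flagged = flagged),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s)%s\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons),
              if (!is.na(x$cds)) sprintf(", CDS %d bp", nchar(x$cds)) else ""))
  invisible(x)
}

#' Number of exons of a gene model
#' @param model A `gene_model`.
#' @return Integer exon count.
#' @export
exon_count <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  nrow(model$exons)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features linked by `Parent` attributes into
#' one `gene_model` per gene. When a gene carries several mRNAs the
#' isoform with the longest CDS is kept as the gene's representative.
#' CDS segments are assembled in transcription order (reverse-complemented
#' on the minus strand) when `genome` is supplied.
#'
#' @param path GFF3 file.
#' @param genome Optional named character vector of chromosome sequences,
#'   used to fill in each model's CDS.
#' @return Named list of `gene_model` objects.
#' @export
read_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  parent_of <- function(row) {
    p <- df$Parent[[row]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  df$parent <- vapply(seq_len(nrow(df)), parent_of, character(1L))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss  <- df[df$type == "CDS",  , drop = FALSE]
  known_parents <- c(mrnas$ID, genes$ID)
  if (nrow(exons) > 0L && any(!exons$parent %in% known_parents))
    stop("orphan exon(s) with unknown Parent in ", path)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    mr <- mrnas[mrnas$parent == gid, , drop = FALSE]
    tx_ids <- if (nrow(mr) > 0L) mr$ID else gid
    # choose representative isoform: longest total CDS
    cds_len <- vapply(tx_ids, function(tx)
      sum(cdss$width[cdss$parent == tx]), numeric(1L))
    tx <- tx_ids[which.max(cds_len)]
    ex <- exons[exons$parent == tx, , drop = FALSE]
    if (nrow(ex) == 0L) ex <- genes[i, , drop = FALSE]  # single-exon fallback
    cd <- cdss[cdss$parent == tx, , drop = FALSE]
    cds_seq <- NA_character_
    if (!is.null(genome) && nrow(cd) > 0L) {
      if (!genes$seqnames[i] %in% names(genome))
        stop("chromosome ", genes$seqnames[i], " missing from genome")
      cd <- cd[order(cd$start), , drop = FALSE]
      chromseq <- genome[[genes$seqnames[i]]]
      pieces <- substring(chromseq, cd$start, cd$end)
      cds_seq <- paste(pieces, collapse = "")
      if (genes$strand[i] == "-") cds_seq <- revcomp(cds_seq)
    }
    out[[gid]] <- gene_model(gid, genes$seqnames[i], genes$strand[i],
                             cbind(ex$start, ex$end), cds_seq)
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (CDS intervals taken equal to
#' exon intervals, the convention of the synthetic generator whose exons
#' are fully coding).
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, src, type, s, e, strand, attr)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type, s, e, strand, attr)
  for (m in models) {
    writeLines(fmt(m$chrom, "iddfam", "gene", m$start, m$end, m$strand,
                   sprintf("ID=%s", m$gene_id)), con)
    tx <- paste0(m$gene_id, ".t1")
    writeLines(fmt(m$chrom, "iddfam", "mRNA", m$start, m$end, m$strand,
                   sprintf("ID=%s;Parent=%s", tx, m$gene_id)), con)
    for (j in seq_len(nrow(m$exons))) {
      writeLines(fmt(m$chrom, "iddfam", "exon", m$exons[j, 1L], m$exons[j, 2L],
                     m$strand, sprintf("ID=%s.e%d;Parent=%s", tx, j, tx)), con)
      writeLines(fmt(m$chrom, "iddfam", "CDS", m$exons[j, 1L], m$exons[j, 2L],
                     m$strand, sprintf("ID=%s.c%d;Parent=%s", tx, j, tx)), con)
    }
  }
  invisible(path)
}

#' Extract the promoter region upstream of a gene
#'
#' Returns the `length` bp immediately 5' of the translation start on the
#' coding strand, excluding the start codon itself (set
#' `include_start = TRUE` to append it). On the minus strand the slice
#' lies downstream in chromosome coordinates and is reverse-complemented.
#' Truncated with a warning when the gene sits within `length` bp of the
#' chromosome edge.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param model A `gene_model`.
#' @param length Promoter length in bp (default 1500).
#' @param include_start Also include the ATG (default `FALSE`).
#' @return Single named character string (name = `<gene_id>_promoter`).
#' @export
extract_upstream <- function(genome, model, length = 1500L,
                             include_start = FALSE) {
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " missing from genome")
  chromseq <- genome[[model$chrom]]
  clen <- nchar(chromseq)
  if (model$strand == "+") {
    to <- model$start - 1L
    from <- model$start - length
    if (from < 1L) {
      warning("promoter of ", model$gene_id, " truncated to ", to, " bp")
      from <- 1L
    }
    out <- if (to >= from) substring(chromseq, from, to) else ""
    if (include_start) out <- paste0(out, substring(chromseq, model$start,
                                                    model$start + 2L))
  } else {
    from <- model$end + 1L
    to <- model$end + length
    if (to > clen) {
      warning("promoter of ", model$gene_id, " truncated to ",
              max(0L, clen - from + 1L), " bp")
      to <- clen
    }
    out <- if (to >= from) revcomp(substring(chromseq, from, to)) else ""
    if (include_start) out <- paste0(out, revcomp(substring(chromseq,
                                                            model$end - 2L,
                                                            model$end)))
  }
  stats::setNames(out, paste0(model$gene_id, "_promoter"))
}
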