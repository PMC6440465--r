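# Family identification: zinc-finger scanning against the C2H2/C2HC
# consensus, assembly of the four-finger ID domain, NLS and C-terminal
# motif annotation, and the proteome-level identification pipeline
# (similarity prefilter -> domain assembly -> locus deduplication).

# (F/Y)-X-C-X(2,5)-C-X3-(F/Y)-X5-psi-X2-H-X(3,5)-H consensus, with the
# hydrophobic psi position instantiated as [AVLIMFWC]; the C2HC variant
# replaces the terminal histidine with cysteine. Capture groups mark the
# four coordinating residues.
ZF_PATTERNS <- c(
  C2H2 = "[FY].(C).{2,5}(C).{3}[FY].{5}[AVLIMFWC].{2}(H).{3,5}(H)",
  C2HC = "[FY].(C).{2,5}(C).{3}[FY].{5}[AVLIMFWC].{2}(H).{3,5}(C)")

NLS_MOTIFS <- c("KKKR", "KRKR")
CTERM_MOTIFS <- c(MSATALLQKAA = "MSATALLQKAA", TRDFLG = "TRDFLG")

# leftmost match of `pattern` starting at or after `from` (1-based);
# returns NULL or list(start, end, coordinating)
.zf_match_from <- function(protein, pattern, from) {
  m <- regexpr(pattern, substring(protein, from), perl = TRUE)
  if (m == -1L) return(NULL)
  start <- from + as.integer(m) - 1L
  cs <- as.integer(attr(m, "capture.start")) + from - 1L
  list(start = start, end = start + attr(m, "match.length") - 1L,
       coordinating = cs)
}

#' Scan a protein for C2H2 and C2HC zinc fingers
#'
#' Finds all non-overlapping matches of the family consensus
#' `(F/Y)-X-C-X(2,5)-C-X3-(F/Y)-X5-psi-X2-H-X(3,5)-H` (C2H2) and of the
#' C2HC variant (terminal H replaced by C), resolved leftmost-greedy;
#' when both kinds match at the same position the canonical C2H2 wins.
#'
#' @param protein Protein string.
#' @return Data frame with columns `kind`, `start`, `end` (1-based
#'   inclusive) and `coordinating` (list column: positions of the four
#'   Zn-coordinating residues). Zero rows when no finger is found.
#' @export
scan_zinc_fingers <- function(protein) {
  out <- list()
  pos <- 1L
  n <- nchar(protein)
  while (pos <= n) {
    cand <- lapply(ZF_PATTERNS, function(p) .zf_match_from(protein, p, pos))
    ok <- !vapply(cand, is.null, logical(1L))
    if (!any(ok)) break
    starts <- vapply(cand[ok], `[[`, integer(1L), "start")
    # earliest start wins; ties go to C2H2 (listed first)
    pick <- names(which(ok))[which.min(starts)]
    hit <- cand[[pick]]
    out[[length(out) + 1L]] <- data.frame(
      kind = pick, start = hit$start, end = hit$end)
    out[[length(out)]]$coordinating <- list(hit$coordinating)
    pos <- hit$end + 1L
  }
  if (length(out) == 0L)
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      coordinating = I(list())))
  do.call(rbind, out)
}

#' Assemble the ID domain from scanned zinc fingers
#'
#' The ID domain is the first (leftmost) run of four consecutive fingers
#' with kinds C2H2, C2H2, C2HC, C2HC in order whose total span does not
#' exceed `max_domain_span`.
#'
#' @param zfs Data frame from [scan_zinc_fingers()] (sorted by start).
#' @param max_domain_span Maximum domain span in residues (default 220).
#' @return List with `zfs` (the four rows), `start`, `end`; or `NULL`
#'   when no valid quartet exists.
#' @export
assemble_id_domain <- function(zfs, max_domain_span = 220L) {
  if (nrow(zfs) < 4L) return(NULL)
  for (i in seq_len(nrow(zfs) - 3L)) {
    kinds <- zfs$kind[i:(i + 3L)]
    if (identical(kinds, c("C2H2", "C2H2", "C2HC", "C2HC"))) {
      span <- zfs$end[i + 3L] - zfs$start[i] + 1L
      if (span <= max_domain_span)
        return(list(zfs = zfs[i:(i + 3L), , drop = FALSE],
                    start = zfs$start[i], end = zfs$end[i + 3L]))
    }
  }
  NULL
}

#' Find the N-terminal nuclear localization signal
#'
#' Leftmost occurrence of KKKR or KRKR lying entirely N-terminal of the
#' assembled ID domain. Absence is legal: several family members lack
#' the NLS.
#'
#' @param protein Protein string.
#' @param domain Domain from [assemble_id_domain()].
#' @return List `(motif, start)` or `NULL`.
#' @export
find_nls <- function(protein, domain) {
  prefix <- substring(protein, 1L, domain$start - 1L)
  best <- NULL
  for (motif in NLS_MOTIFS) {
    m <- regexpr(motif, prefix, fixed = TRUE)
    if (m != -1L && (is.null(best) || m < best$start))
      best <- list(motif = motif, start = as.integer(m))
  }
  best
}

#' Find the C-terminal MSATALLQKAA and TRDFLG motifs
#'
#' Best-scoring ungapped occurrence of each motif, searched only
#' C-terminal of the ID domain, allowing up to `max_mismatch` mismatches
#' (2 for MSATALLQKAA, 1 for TRDFLG by default); ties resolved leftmost.
#'
#' @param protein Protein string.
#' @param domain Domain from [assemble_id_domain()].
#' @param max_mismatch Named integer vector of per-motif mismatch budgets.
#' @return Data frame with columns `motif`, `start` (position in the full
#'   protein), `mismatches`; zero rows if neither motif is found.
#' @export
find_cterm_motifs <- function(protein, domain,
                              max_mismatch = c(MSATALLQKAA = 2L, TRDFLG = 1L)) {
  region_start <- domain$end + 1L
  region <- substring(protein, region_start)
  res <- strsplit(region, "", fixed = TRUE)[[1L]]
  out <- list()
  for (name in names(CTERM_MOTIFS)) {
    motif <- strsplit(CTERM_MOTIFS[[name]], "", fixed = TRUE)[[1L]]
    k <- length(motif)
    if (length(res) < k) next
    best_mm <- Inf; best_at <- NA_integer_
    for (at in seq_len(length(res) - k + 1L)) {
      mm <- sum(res[at:(at + k - 1L)] != motif)
      if (mm < best_mm) { best_mm <- mm; best_at <- at }
    }
    if (best_mm <= max_mismatch[[name]])
      out[[name]] <- data.frame(motif = name,
                                start = region_start + best_at - 1L,
                                mismatches = best_mm)
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(), start = integer(),
                      mismatches = integer()))
  rownames_to_null <- do.call(rbind, out)
  rownames(rownames_to_null) <- NULL
  rownames_to_null
}

# locus id: strip a trailing isoform suffix like ".1" / ".t2"
.locus_of <- function(id) sub("\\.[A-Za-z]?\\d+$", "", id)

#' Identify family members in a proteome
#'
#' Pipeline replacing the classic TBLASTN + domain-database + manual
#' check: (1) similarity prefilter -- keep proteins whose best global
#' alignment identity to any query reaches `min_query_identity`;
#' (2) require successful ID-domain assembly; (3) deduplicate isoforms of
#' the same locus, keeping the longest protein. Members are returned with
#' NLS, C-terminal motif and physicochemistry annotations filled in.
#'
#' @param proteome Named character vector of protein sequences.
#' @param queries Named character vector of known family proteins used as
#'   search queries.
#' @param min_query_identity Prefilter identity threshold (default 0.25,
#'   deliberately loose: the domain test is the real filter).
#' @param max_domain_span Passed to [assemble_id_domain()].
#' @return List of `family_member` objects (fields `gene_id`, `protein`,
#'   `domain`, `nls`, `cterm`, `params`).
#' @export
identify_family <- function(proteome, queries, min_query_identity = 0.25,
                            max_domain_span = 220L) {
  if (length(queries) == 0L) stop("queries must be non-empty")
  if (length(proteome) == 0L) return(list())
  members <- list()
  for (id in names(proteome)) {
    seq <- proteome[[id]]
    best_ident <- max(.batch_identities(queries, seq, "protein"))
    if (best_ident < min_query_identity) next
    zfs <- scan_zinc_fingers(seq)
    domain <- assemble_id_domain(zfs, max_domain_span)
    if (is.null(domain)) next
    members[[id]] <- structure(list(
      gene_id = id, protein = seq, domain = domain,
      nls = find_nls(seq, domain),
      cterm = find_cterm_motifs(seq, domain),
      params = protein_params(seq)), class = "family_member")
  }
  # deduplicate by locus, keeping the longest isoform
  if (length(members) > 1L) {
    loci <- vapply(names(members), .locus_of, character(1L))
    keep <- vapply(split(names(members), loci), function(ids) {
      ids[which.max(nchar(proteome[ids]))]
    }, character(1L))
    members <- members[sort(match(keep, names(members)))]
  }
  members
}

#' @export
print.family_member <- function(x, ...) {
  cat(sprintf("<family_member> %s: ID domain %d-%d (%s)%s%s\n",
              x$gene_id, x$domain$start, x$domain$end,
              paste(x$domain$zfs$kind, collapse = ","),
              if (!is.null(x$nls)) sprintf(", NLS %s@%d", x$nls$motif,
                                           x$nls$start) else "",
              if (nrow(x$cterm) > 0L)
                paste0(", C-term ", paste(x$cterm$motif, collapse = "+"))
              else ""))
  invisible(x)
}

#' Summary table of identified family members
#'
#' @param members List from [identify_family()].
#' @return Data frame with one row per member (domain coordinates, finger
#'   kinds, NLS, C-terminal motifs and mismatch counts).
#' @export
members_table <- function(members) {
  rows <- lapply(members, function(m) data.frame(
    gene_id = m$gene_id,
    domain_start = m$domain$start, domain_end = m$domain$end,
    zf_kinds = paste(m$domain$zfs$kind, collapse = ","),
    nls = if (is.null(m$nls)) "" else m$nls$motif,
    cterm_motifs = paste(m$cterm$motif, collapse = ","),
    mismatches = paste(m$cterm$mismatches, collapse = ",")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
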