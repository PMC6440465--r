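# Simplified MCScanX-style microsynteny: protein-similarity anchors
# between two annotated genomes, longest-chain dynamic programming with a
# gap constraint (per chromosome pair and orientation), greedy extraction
# of disjoint collinear blocks, and family ortholog-pair extraction.

# per-chromosome gene order index (0-based ranks, by start coordinate)
.gene_ranks <- function(annot) {
  annot$rank <- NA_integer_
  for (ch in unique(annot$chrom)) {
    idx <- which(annot$chrom == ch)
    annot$rank[idx][order(annot$start[idx])] <- seq_along(idx) - 1L
  }
  annot
}

#' Find anchors between two annotated proteomes
#'
#' For each gene in genome A, the up-to-`top_hits` best-scoring genes in
#' genome B by global protein alignment score (minimum `min_score`).
#' Ranks are gene order indices per chromosome, by start coordinate.
#'
#' @param proteome_a,proteome_b Named character vectors of proteins.
#' @param annot_a,annot_b Data frames with columns `gene_id`, `chrom`,
#'   `start`.
#' @param top_hits Hits kept per query gene (default 5).
#' @param min_score Minimum alignment score for an anchor (default 50).
#' @return Data frame of anchors: `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `rank_a`, `rank_b`, `score`.
#' @export
find_anchors <- function(proteome_a, proteome_b, annot_a, annot_b,
                         top_hits = 5L, min_score = 50) {
  annot_a <- .gene_ranks(annot_a)
  annot_b <- .gene_ranks(annot_b)
  skip_a <- setdiff(names(proteome_a), annot_a$gene_id)
  skip_b <- setdiff(names(proteome_b), annot_b$gene_id)
  if (length(c(skip_a, skip_b)) > 0L)
    warning("unannotated gene(s) skipped: ",
            paste(c(skip_a, skip_b), collapse = ", "))
  genes_a <- intersect(names(proteome_a), annot_a$gene_id)
  genes_b <- intersect(names(proteome_b), annot_b$gene_id)
  out <- list()
  for (ga in genes_a) {
    scores <- stats::setNames(
      .batch_scores(proteome_b[genes_b], proteome_a[[ga]], "protein"),
      genes_b)
    keep <- which(scores >= min_score)
    if (length(keep) == 0L) next
    keep <- keep[order(scores[keep], decreasing = TRUE)]
    keep <- keep[seq_len(min(top_hits, length(keep)))]
    ra <- annot_a[annot_a$gene_id == ga, ]
    for (j in keep) {
      rb <- annot_b[annot_b$gene_id == genes_b[j], ]
      out[[length(out) + 1L]] <- data.frame(
        gene_a = ga, gene_b = genes_b[j],
        chrom_a = ra$chrom, chrom_b = rb$chrom,
        rank_a = ra$rank, rank_b = rb$rank, score = scores[[j]])
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), chrom_b = character(),
                      rank_a = integer(), rank_b = integer(),
                      score = numeric()))
  do.call(rbind, out)
}

# longest chain (by anchor count) among anchors of one chromosome pair and
# one orientation; anchors must be strictly increasing in rank_a and
# strictly increasing (same) / decreasing (inverted) in rank_b, with
# adjacent rank gaps <= max_gap on both genomes. O(n^2) DP.
.max_chain <- function(anch, orientation, max_gap) {
  n <- nrow(anch)
  if (n == 0L) return(integer())
  rb <- if (orientation == "same") anch$rank_b else -anch$rank_b
  ord <- order(anch$rank_a, rb)
  a <- anch$rank_a[ord]; b <- rb[ord]
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- a[i] - a[j]; db <- b[i] - b[j]
      if (da >= 1L && db >= 1L && da <= max_gap && db <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer()
  while (best != 0L) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  ord[chain]
}

#' Chain anchors into collinear blocks
#'
#' Per chromosome pair and orientation, maximum-cardinality chains are
#' found by longest-increasing-subsequence dynamic programming under a
#' rank-gap constraint; disjoint chains are extracted greedily in
#' decreasing size and chains shorter than `min_block` are discarded.
#'
#' @param anchors Data frame from [find_anchors()].
#' @param min_block Minimum anchors per block (default 5).
#' @param max_gap Maximum adjacent rank gap on either genome (default 25).
#' @return List of blocks; each block is a list with `chrom_a`,
#'   `chrom_b`, `orientation` (`"same"` or `"inverted"`) and `anchors`
#'   (the ordered anchor rows).
#' @export
chain_collinear <- function(anchors, min_block = 5L, max_gap = 25L) {
  blocks <- list()
  if (nrow(anchors) == 0L) return(blocks)
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  for (k in unique(key)) {
    sub <- anchors[key == k, , drop = FALSE]
    for (orientation in c("same", "inverted")) {
      pool <- sub
      repeat {
        idx <- .max_chain(pool, orientation, max_gap)
        if (length(idx) < min_block) break
        blk <- pool[idx, , drop = FALSE]
        rownames(blk) <- NULL
        blocks[[length(blocks) + 1L]] <- list(
          chrom_a = blk$chrom_a[1L], chrom_b = blk$chrom_b[1L],
          orientation = orientation, anchors = blk)
        pool <- pool[-idx, , drop = FALSE]
      }
    }
  }
  # decreasing size, for reproducible output order
  if (length(blocks) > 1L)
    blocks <- blocks[order(vapply(blocks, function(b) nrow(b$anchors),
                                  integer(1L)), decreasing = TRUE)]
  blocks
}

#' Family ortholog pairs inside collinear blocks
#'
#' Anchor pairs within blocks where both genes are family members. A
#' member may pair with several partners (no uniqueness constraint).
#'
#' @param blocks List from [chain_collinear()].
#' @param members_a,members_b Character vectors of family-member gene ids
#'   in each genome.
#' @return Deduplicated data frame with columns `gene_a`, `gene_b`.
#' @export
family_ortho_pairs <- function(blocks, members_a, members_b) {
  out <- list()
  for (b in blocks) {
    hit <- b$anchors$gene_a %in% members_a & b$anchors$gene_b %in% members_b
    if (any(hit))
      out[[length(out) + 1L]] <- b$anchors[hit, c("gene_a", "gene_b")]
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(), gene_b = character()))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
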