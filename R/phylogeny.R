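# Deterministic grouping support: pairwise p-distance matrices over family
# proteins, Saitou-Nei neighbor-joining (via ape) with negative branch
# lengths clamped to zero, Newick round-trip, and reference-guided group
# assignment by path length.

#' Pairwise p-distance matrix
#'
#' For each pair of sequences, the mismatch fraction over gap-free
#' columns of their global pairwise protein alignment.
#'
#' @param seqs Named character vector of at least three protein
#'   sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    rest <- seq((i + 1L), n)
    pa <- .batch_pa(seqs[rest], seqs[[i]], "protein")
    ga <- as.character(Biostrings::alignedPattern(pa))
    gb <- as.character(Biostrings::alignedSubject(pa))
    for (k in seq_along(rest)) {
      a <- strsplit(ga[[k]], "", fixed = TRUE)[[1L]]
      b <- strsplit(gb[[k]], "", fixed = TRUE)[[1L]]
      keep <- a != "-" & b != "-"
      if (!any(keep))
        stop("no comparable columns between ", names(seqs)[i], " and ",
             names(seqs)[rest[k]])
      d[i, rest[k]] <- d[rest[k], i] <- mean(a[keep] != b[keep])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou--Nei neighbor joining on a distance matrix; for additive
#' matrices the generating tree is recovered exactly. Negative branch
#' length estimates are clamped to zero and counted in the
#' `"clamped_branches"` attribute.
#'
#' @param d Symmetric distance matrix (labels as dimnames), n >= 3.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d)))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tree <- ape::nj(d)
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_branches") <- clamped
  tree
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers kept so every pipeline stage has an explicit file
#' interface; branch lengths are preserved.
#'
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo]; `write_newick` the path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Assign phylogenetic groups from reference leaves
#'
#' Each unlabeled leaf takes the group of its nearest reference leaf by
#' path length (sum of branch lengths); ties go to the lexicographically
#' smallest group name and are flagged.
#'
#' @param tree An [ape::phylo] tree.
#' @param reference_groups Named character vector: leaf label -> group
#'   name, with at least one reference per group.
#' @return Named character vector label -> group for every leaf, with a
#'   `"ties"` attribute listing leaves whose assignment was ambiguous.
#' @export
assign_groups <- function(tree, reference_groups) {
  refs <- names(reference_groups)
  missing_refs <- setdiff(refs, tree$tip.label)
  if (length(missing_refs) > 0L)
    stop("reference leaf/leaves not in tree: ",
         paste(missing_refs, collapse = ", "))
  if (length(unique(reference_groups)) < 1L)
    stop("no reference groups given")
  pd <- ape::cophenetic.phylo(tree)
  out <- character(0)
  ties <- character(0)
  for (leaf in tree$tip.label) {
    if (leaf %in% refs) {
      out[leaf] <- reference_groups[[leaf]]
      next
    }
    dr <- pd[leaf, refs]
    best <- refs[dr == min(dr)]
    groups <- sort(unique(reference_groups[best]))
    if (length(groups) > 1L) ties <- c(ties, leaf)
    out[leaf] <- groups[[1L]]
  }
  attr(out, "ties") <- ties
  out
}
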