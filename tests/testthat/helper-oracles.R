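# Independent oracles, implemented separately from the package code paths
# they check.

# --- exhaustive-pathway NG86 oracle -----------------------------------
# Counts synonymous/nonsynonymous differences between two sense codons by
# explicitly enumerating every substitution order; translation goes
# through seqinr, not the package's codon table.

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1L]])
}

oracle_pair_diffs <- function(ca, cb) {
  da <- strsplit(ca, "")[[1L]]
  db <- strsplit(cb, "")[[1L]]
  pos <- which(da != db)
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1L) matrix(pos, 1L) else {
    m <- gtools_permutations(pos)
    m
  }
  paths <- list()
  for (r in seq_len(nrow(perms))) {
    cur <- da
    sd <- 0; nd <- 0
    blocked <- FALSE
    for (p in perms[r, ]) {
      nxt <- cur
      nxt[p] <- db[p]
      if (oracle_translate(paste(nxt, collapse = "")) == "*") {
        blocked <- TRUE
        break
      }
      if (oracle_translate(paste(nxt, collapse = "")) ==
          oracle_translate(paste(cur, collapse = ""))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (length(paths) == 0L) return(NULL)  # all pathways blocked
  colMeans(do.call(rbind, paths))
}

# small permutation enumerator (rows = orderings)
gtools_permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- gtools_permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

oracle_site_counts <- function(codon) {
  nucs <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    res <- strsplit(codon, "")[[1L]]
    syn <- 0; tot <- 0
    for (nt in setdiff(nucs, res[pos])) {
      m <- res
      m[pos] <- nt
      maa <- oracle_translate(paste(m, collapse = ""))
      if (maa == "*") next
      tot <- tot + 1
      if (maa == aa) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

# --- brute-force global alignment oracle ------------------------------
# Enumerates every global alignment of two short sequences and returns
# the maximum score under the package's affine-gap scoring.

oracle_best_score <- function(a, b, mode = "dna") {
  stopifnot(mode == "dna")
  subs <- function(x, y) if (x == y) 2 else -3
  open <- 5; ext <- 2
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  best <- -Inf
  # state: (i, j, last op), score accumulated with affine gaps
  rec <- function(i, j, last, acc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, "m", acc + subs(ca[i], cb[j]))
    if (i <= length(ca))  # gap in b
      rec(i + 1L, j, "a", acc - ext - if (last != "a") open else 0)
    if (j <= length(cb))  # gap in a
      rec(i, j + 1L, "b", acc - ext - if (last != "b") open else 0)
  }
  rec(1L, 1L, "none", 0)
  best
}

# --- brute-force longest collinear chain ------------------------------
# Checks every subset of anchors for validity (monotone ranks, gap
# bound); returns the maximum valid subset size.

oracle_max_chain <- function(rank_a, rank_b, orientation, max_gap) {
  n <- length(rank_a)
  rb <- if (orientation == "same") rank_b else -rank_b
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    idx <- idx[order(rank_a[idx])]
    da <- diff(rank_a[idx]); db <- diff(rb[idx])
    if (length(idx) >= 2L &&
        !(all(da >= 1L) && all(db >= 1L) &&
          all(da <= max_gap) && all(db <= max_gap))) next
    best <- length(idx)
  }
  best
}
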