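# Synthetic-data generator: genomes, proteomes, annotations, promoters
# and Ct tables with planted ground truth, so every downstream stage has
# a no-download test surface. All outputs are pure functions of the
# configuration (single RNG stream seeded from cfg$seed).

# linker/filler alphabet: hydrophilic-ish residues that can never seed a
# zinc finger (no C/H/F/Y), an NLS (no K/R) or a C-terminal motif (no
# A/L/M) -- planted motifs are therefore unambiguous ground truth
FILLER_AA <- c("S", "T", "N", "Q", "D", "E", "G", "P")

.rand_filler <- function(n) paste(sample(FILLER_AA, n, replace = TRUE),
                                  collapse = "")
.rand_dna <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# reverse codon table for uniform back-translation
.codons_of <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- split(names(GENETIC_CODE_TABLE),
                                    GENETIC_CODE_TABLE)
    tab
  }
})

.back_translate <- function(protein) {
  tab <- .codons_of()
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(res, function(aa) {
    cands <- tab[[aa]]
    cands[[sample.int(length(cands), 1L)]]
  }, character(1L)), collapse = "")
}

# one zinc finger matching the family consensus exactly; broken fingers
# substitute the first coordinating Cys with Ser
.make_zf <- function(kind = c("C2H2", "C2HC"), broken = FALSE) {
  kind <- match.arg(kind)
  first_c <- if (broken) "S" else "C"
  paste0("F", .rand_filler(1L), first_c, .rand_filler(sample(2:5, 1L)), "C",
         .rand_filler(3L), "F", .rand_filler(5L), "L", .rand_filler(2L), "H",
         .rand_filler(sample(3:5, 1L)), if (kind == "C2H2") "H" else "C")
}

# full family protein for a group template; groups 1-3 carry both
# C-terminal motifs, group 4 carries none
.make_family_protein <- function(group, nls) {
  domain <- paste0(.make_zf("C2H2"), .rand_filler(sample(5:10, 1L)),
                   .make_zf("C2H2"), .rand_filler(sample(8:15, 1L)),
                   .make_zf("C2HC"), .rand_filler(sample(5:10, 1L)),
                   .make_zf("C2HC"))
  cterm <- if (group <= 3L)
    paste0(.rand_filler(sample(20:40, 1L)), "MSATALLQKAA",
           .rand_filler(sample(5:10, 1L)), "TRDFLG",
           .rand_filler(sample(10:20, 1L)))
  else .rand_filler(sample(40:70, 1L))
  paste0("M", .rand_filler(sample(5:15, 1L)),
         if (nls) sample(c("KKKR", "KRKR"), 1L) else "",
         .rand_filler(sample(10:25, 1L)), domain, cterm)
}

.make_decoy_protein <- function(kind = c("few_fingers", "broken")) {
  kind <- match.arg(kind)
  if (kind == "few_fingers") {
    core <- paste0(.make_zf("C2H2"), .rand_filler(sample(5:10, 1L)),
                   .make_zf("C2HC"))
  } else {
    core <- paste0(.make_zf("C2H2", broken = TRUE),
                   .rand_filler(sample(5:10, 1L)), .make_zf("C2H2"),
                   .rand_filler(sample(8:15, 1L)), .make_zf("C2HC"),
                   .rand_filler(sample(5:10, 1L)), .make_zf("C2HC"))
  }
  paste0("M", .rand_filler(sample(15:30, 1L)), core,
         .rand_filler(sample(40:80, 1L)))
}

#' Configuration for the synthetic genome generator
#'
#' Defaults define the package's reference study conditions: 20 family
#' genes across four group templates, 20 decoys, five chromosomes, two
#' tandem and two segmental duplicate pairs evolved to Ka 0.05 / Ks 0.25,
#' NLS planted with probability 0.8, and promoters carrying three
#' CGTCA-motif and two G-Box sites each.
#'
#' @param seed Integer seed; all outputs are deterministic given the
#'   configuration.
#' @param n_family,n_decoys Family-member and decoy counts.
#' @param chromosomes Named integer vector of chromosome lengths (bp).
#' @param dup_pairs Data frame with columns `type`
#'   (`"tandem"`/`"segmental"`), `target_ka`, `target_ks` (rates in
#'   \[0, 0.7\]); pair members are taken from the family genes.
#' @param nls_prob Probability that a family member carries the NLS.
#' @param cis_plan Named integer vector: catalog element -> planted count
#'   per promoter.
#' @param ct_noise_sd Gaussian Ct noise (cycles) for [simulate_ct_table()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_family = 20L, n_decoys = 20L,
                       chromosomes = c(chr1 = 500000L, chr2 = 500000L,
                                       chr3 = 400000L, chr4 = 400000L,
                                       chr5 = 400000L),
                       dup_pairs = data.frame(
                         type = c("tandem", "tandem", "segmental", "segmental"),
                         target_ka = 0.05, target_ks = 0.25),
                       nls_prob = 0.8,
                       cis_plan = c("CGTCA-motif" = 3L, "G-Box" = 2L),
                       ct_noise_sd = 0.2) {
  stopifnot(n_family >= 0L, n_decoys >= 0L, all(chromosomes > 0L),
            nls_prob >= 0, nls_prob <= 1, ct_noise_sd >= 0)
  if (nrow(dup_pairs) > 0L) {
    stopifnot(all(dup_pairs$type %in% c("tandem", "segmental")),
              all(dup_pairs$target_ka >= 0 & dup_pairs$target_ka <= 0.7),
              all(dup_pairs$target_ks >= 0 & dup_pairs$target_ks <= 0.7))
    if (2L * nrow(dup_pairs) > n_family)
      stop("dup_pairs need ", 2L * nrow(dup_pairs),
           " family genes but n_family = ", n_family)
  }
  structure(list(seed = as.integer(seed), n_family = as.integer(n_family),
                 n_decoys = as.integer(n_decoys), chromosomes = chromosomes,
                 dup_pairs = dup_pairs, nls_prob = nls_prob,
                 cis_plan = cis_plan, ct_noise_sd = ct_noise_sd),
            class = "sim_config")
}

# build a promoter: A/T background with planted elements at non-adjacent
# offsets; verified by rescanning (plus-strand occurrence counts of the
# planted elements must equal the plan exactly)
.make_promoter <- function(cis_plan, catalog, length = 1500L) {
  if (length(cis_plan) == 0L)
    return(.rand_dna(length, c("A", "T")))
  pats <- vapply(names(cis_plan), function(el) {
    row <- catalog[catalog$element == el, ]
    if (nrow(row) == 0L) stop("cis_plan element not in catalog: ", el)
    row$pattern[[1L]]
  }, character(1L))
  for (attempt in seq_len(20L)) {
    prom <- .rand_dna(length, c("A", "T"))
    want <- rep(names(cis_plan), cis_plan)
    sizes <- nchar(pats[want])
    # non-overlapping placements with >= 10 bp clearance
    offs <- integer(0)
    ok <- TRUE
    for (i in seq_along(want)) {
      for (try in seq_len(50L)) {
        o <- sample.int(length - sizes[i] + 1L, 1L)
        if (all(abs(o - offs) >= max(sizes) + 10L)) break
        o <- NA_integer_
      }
      if (is.na(o)) { ok <- FALSE; break }
      offs <- c(offs, o)
      substr(prom, o, o + sizes[i] - 1L) <- pats[want[i]]
    }
    if (!ok) next
    hits <- scan_promoter(prom, catalog)
    counts <- vapply(names(cis_plan), function(el)
      sum(hits$element == el & hits$strand == "+"), integer(1L))
    if (identical(unname(counts), unname(as.integer(cis_plan)))) return(prom)
  }
  stop("could not construct a promoter matching the cis plan")
}

# split a CDS into n_exons pieces and join with GT..AG introns; returns
# the plus-orientation gene sequence and exon intervals (1-based, within
# the gene, transcription order)
.gene_structure <- function(cds, n_exons) {
  L <- nchar(cds)
  cuts <- if (n_exons > 1L)
    sort(sample(seq(40L, L - 40L), n_exons - 1L)) else integer(0)
  bounds <- cbind(c(1L, cuts + 1L), c(cuts, L))
  pieces <- substring(cds, bounds[, 1L], bounds[, 2L])
  introns <- vapply(seq_len(max(0L, n_exons - 1L)), function(i)
    paste0("GT", .rand_dna(sample(80:200, 1L)), "AG"), character(1L))
  seqs <- character(0)
  exons <- matrix(0L, n_exons, 2L)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    exons[i, ] <- c(pos + 1L, pos + nchar(pieces[i]))
    seqs <- c(seqs, pieces[i])
    pos <- pos + nchar(pieces[i])
    if (i < n_exons) {
      seqs <- c(seqs, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(seq = paste(seqs, collapse = ""), exons = exons)
}

#' Generate a synthetic genome bundle with planted family ground truth
#'
#' Emits a genome, gene models, proteome, CDS set, coding-strand
#' promoters and a truth table. Family genes contain ZF1--ZF4 in the
#' canonical order (two C2H2 then two C2HC) with an N-terminal KKKR/KRKR
#' planted with probability `nls_prob`, and MSATALLQKAA + TRDFLG near the
#' C terminus for groups 1--3 (group 4 lacks both). Decoys contain at
#' most two zinc fingers or a broken finger (coordinating Cys -> Ser).
#' Duplicate pairs are placed per their type (tandem: same chromosome,
#' nearest-boundary separation at least 200 kb, matching the printed
#' rule; segmental: different chromosomes) with the second copy evolved
#' by [evolve_duplicate()]. Deterministic given the configuration.
#'
#' @param cfg A [sim_config()].
#' @param catalog Cis-element catalog used for promoter planting.
#' @return List: `genome`, `models`, `proteome`, `cds`, `promoters`,
#'   `queries` (one clean protein per group template, for use as
#'   identification queries), `truth` (data frames `members`, `decoys`,
#'   `dup_pairs`, `cis`) and `config`.
#' @export
generate_family_genome <- function(cfg, catalog = default_cis_catalog()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_pairs <- nrow(cfg$dup_pairs)
    groups <- if (cfg$n_family > 0L)
      rep_len(1:4, cfg$n_family) else integer(0)
    nls <- if (cfg$n_family > 0L)
      stats::runif(cfg$n_family) < cfg$nls_prob else logical(0)
    fam_ids <- sprintf("FAM%03d", seq_len(cfg$n_family))
    dec_ids <- sprintf("DEC%03d", seq_len(cfg$n_decoys))

    proteins <- character(0)
    cds <- character(0)
    # codon indices of planted diagnostic residues (zinc-finger consensus
    # anchors, NLS, C-terminal motifs, initial Met), kept free of
    # nonsynonymous change when a duplicate is evolved
    diagnostic_codons <- function(protein) {
      zfs <- scan_zinc_fingers(protein)
      keep <- 1L
      for (r in seq_len(nrow(zfs))) {
        cc <- zfs$coordinating[[r]]
        # fixed consensus residues: leading F/Y, C, C, second F/Y,
        # hydrophobic psi, H, terminal H/C
        keep <- c(keep, zfs$start[r], cc[1L], cc[2L], cc[2L] + 4L,
                  cc[2L] + 10L, cc[3L], cc[4L])
      }
      domain <- assemble_id_domain(zfs)
      if (!is.null(domain)) {
        hit <- find_nls(protein, domain)
        if (!is.null(hit)) keep <- c(keep, hit$start + 0:3)
        ct <- find_cterm_motifs(protein, domain)
        for (r in seq_len(nrow(ct)))
          keep <- c(keep, ct$start[r] +
                      seq_len(nchar(CTERM_MOTIFS[[ct$motif[r]]])) - 1L)
      }
      sort(unique(keep))
    }
    # duplicate-pair members occupy the first 2*n_pairs family slots:
    # gene 2k derives from gene 2k-1 by controlled coding divergence and
    # inherits its group template and motif complement
    for (i in seq_len(cfg$n_family)) {
      k <- ceiling(i / 2)
      if (i %% 2L == 0L && k <= n_pairs) {
        groups[i] <- groups[i - 1L]
        nls[i] <- nls[i - 1L]
        src <- cds[[fam_ids[i - 1L]]]
        cds[[fam_ids[i]]] <- evolve_duplicate(
          src, cfg$dup_pairs$target_ka[k], cfg$dup_pairs$target_ks[k],
          seed = sample.int(.Machine$integer.max, 1L),
          protect_nonsyn = diagnostic_codons(proteins[[fam_ids[i - 1L]]]))
        proteins[[fam_ids[i]]] <- translate_cds(cds[[fam_ids[i]]])
      } else {
        p <- .make_family_protein(groups[i], nls[i])
        proteins[[fam_ids[i]]] <- p
        cds[[fam_ids[i]]] <- .back_translate(p)
      }
    }
    for (i in seq_len(cfg$n_decoys)) {
      p <- .make_decoy_protein(if (i %% 2L == 0L) "broken" else "few_fingers")
      proteins[[dec_ids[i]]] <- p
      cds[[dec_ids[i]]] <- .back_translate(p)
    }
    queries <- stats::setNames(
      vapply(1:4, function(g) .make_family_protein(g, nls = TRUE),
             character(1L)),
      sprintf("QRY_G%d", 1:4))

    # chromosome slot grid
    slot_df <- do.call(rbind, lapply(names(cfg$chromosomes), function(ch) {
      pos <- seq(20000L, cfg$chromosomes[[ch]] - 20000L, by = 25000L)
      if (length(pos) == 0L) return(NULL)
      data.frame(chrom = ch, pos = pos)
    }))
    all_ids <- c(fam_ids, dec_ids)
    if (is.null(slot_df) || nrow(slot_df) < length(all_ids))
      stop("chromosomes too short for the requested number of genes")
    slot_df$taken <- FALSE

    assign_slot <- function(i) slot_df$taken[i] <<- TRUE
    placement <- data.frame(gene_id = all_ids, chrom = NA_character_,
                            pos = NA_integer_)
    # duplicate pairs first (they constrain chromosome/separation)
    for (k in seq_len(n_pairs)) {
      a <- fam_ids[2L * k - 1L]; b <- fam_ids[2L * k]
      if (cfg$dup_pairs$type[k] == "tandem") {
        done <- FALSE
        for (ch in unique(slot_df$chrom)) {
          free <- which(slot_df$chrom == ch & !slot_df$taken)
          if (length(free) < 2L) next
          far <- which(outer(slot_df$pos[free], slot_df$pos[free], "-") >=
                         225000L, arr.ind = TRUE)
          if (nrow(far) == 0L) next
          i2 <- free[far[1L, 1L]]; i1 <- free[far[1L, 2L]]
          placement[placement$gene_id == a, c("chrom", "pos")] <-
            list(ch, slot_df$pos[i1])
          placement[placement$gene_id == b, c("chrom", "pos")] <-
            list(ch, slot_df$pos[i2])
          assign_slot(i1); assign_slot(i2)
          done <- TRUE
          break
        }
        if (!done) stop("no chromosome can host a tandem pair ",
                        "(needs two free slots >= 225 kb apart)")
      } else {
        chs <- unique(slot_df$chrom[!slot_df$taken])
        if (length(chs) < 2L) stop("need two chromosomes for a segmental pair")
        i1 <- which(slot_df$chrom == chs[1L] & !slot_df$taken)[1L]
        i2 <- which(slot_df$chrom == chs[2L] & !slot_df$taken)[1L]
        placement[placement$gene_id == a, c("chrom", "pos")] <-
          list(chs[1L], slot_df$pos[i1])
        placement[placement$gene_id == b, c("chrom", "pos")] <-
          list(chs[2L], slot_df$pos[i2])
        assign_slot(i1); assign_slot(i2)
      }
    }
    rest <- placement$gene_id[is.na(placement$chrom)]
    free <- which(!slot_df$taken)
    picks <- sample(free, length(rest))
    placement[match(rest, placement$gene_id), "chrom"] <- slot_df$chrom[picks]
    placement[match(rest, placement$gene_id), "pos"] <- slot_df$pos[picks]

    # assemble chromosomes
    genome <- vapply(cfg$chromosomes, .rand_dna, character(1L))
    names(genome) <- names(cfg$chromosomes)
    models <- list()
    promoters <- character(0)
    cis_rows <- list()
    meta <- data.frame(gene_id = all_ids, n_exons = sample(2:4, length(all_ids),
                                                           replace = TRUE),
                       strand = sample(c("+", "-"), length(all_ids),
                                       replace = TRUE))
    for (i in seq_len(nrow(placement))) {
      gid <- placement$gene_id[i]
      ch <- placement$chrom[i]; p <- placement$pos[i]
      st <- meta$strand[meta$gene_id == gid]
      ne <- meta$n_exons[meta$gene_id == gid]
      gs <- .gene_structure(cds[[gid]], ne)
      glen <- nchar(gs$seq)
      prom <- .make_promoter(cfg$cis_plan, catalog)
      if (st == "+") {
        substr(genome[[ch]], p, p + glen - 1L) <- gs$seq
        substr(genome[[ch]], p - 1500L, p - 1L) <- prom
        exons <- cbind(p + gs$exons[, 1L] - 1L, p + gs$exons[, 2L] - 1L)
      } else {
        substr(genome[[ch]], p, p + glen - 1L) <- revcomp(gs$seq)
        substr(genome[[ch]], p + glen, p + glen + 1499L) <- revcomp(prom)
        exons <- cbind(p + glen - gs$exons[, 2L], p + glen - gs$exons[, 1L])
      }
      models[[gid]] <- gene_model(gid, ch, st, exons, cds[[gid]])
      promoters[[gid]] <- prom
      if (length(cfg$cis_plan) > 0L)
        cis_rows[[gid]] <- data.frame(gene_id = gid,
                                      element = names(cfg$cis_plan),
                                      planted = as.integer(cfg$cis_plan))
    }

    truth_members <- data.frame(
      gene_id = fam_ids,
      group = groups,
      has_nls = nls,
      has_cterm = groups <= 3L,
      chrom = placement$chrom[match(fam_ids, placement$gene_id)],
      strand = meta$strand[match(fam_ids, meta$gene_id)],
      n_exons = meta$n_exons[match(fam_ids, meta$gene_id)],
      start = vapply(fam_ids, function(g) models[[g]]$start, integer(1L)),
      end = vapply(fam_ids, function(g) models[[g]]$end, integer(1L)))
    truth_dups <- if (n_pairs > 0L) data.frame(
      gene_a = fam_ids[2L * seq_len(n_pairs) - 1L],
      gene_b = fam_ids[2L * seq_len(n_pairs)],
      type = cfg$dup_pairs$type,
      target_ka = cfg$dup_pairs$target_ka,
      target_ks = cfg$dup_pairs$target_ks)
    else data.frame(gene_a = character(), gene_b = character(),
                    type = character(), target_ka = numeric(),
                    target_ks = numeric())
    list(genome = genome, models = models, proteome = proteins, cds = cds,
         promoters = promoters, queries = queries,
         truth = list(members = truth_members,
                      decoys = data.frame(gene_id = dec_ids),
                      dup_pairs = truth_dups,
                      cis = if (length(cis_rows) > 0L)
                        do.call(rbind, cis_rows)
                      else data.frame(gene_id = character(),
                                      element = character(),
                                      planted = integer())),
         config = cfg)
  })
}

#' Evolve a duplicate coding sequence to target Ka and Ks
#'
#' Introduces nonsynonymous and synonymous point substitutions whose
#' expected NG86 + Jukes--Cantor estimates equal the targets: the number
#' of changes of each class is `round(sites * p)`, with `p` obtained by
#' inverting the Jukes--Cantor map at the target rate, and each change is
#' drawn uniformly from the currently available single-nucleotide changes
#' of that class. Stop codons are never created.
#'
#' @param cds In-frame coding sequence, no internal stop codons.
#' @param target_ka,target_ks Target corrected rates in \[0, 0.7\].
#' @param seed Integer seed.
#' @param protect_nonsyn Optional codon indices at which nonsynonymous
#'   changes are disallowed (used by the genome generator to keep planted
#'   diagnostic residues intact; synonymous changes remain possible).
#' @return Mutated CDS of equal length.
#' @export
evolve_duplicate <- function(cds, target_ka, target_ks, seed = 1L,
                             protect_nonsyn = integer(0)) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- .split_codons(toupper(cds))
  if (any(codons %in% STOP_CODONS)) stop("CDS contains internal stop codon")
  if (any(!codons %in% SENSE_CODONS)) stop("CDS contains ambiguous codons")
  p_of <- function(d) {
    if (d < 0 || d > 0.7) stop("target rate must lie in [0, 0.7]")
    p <- 0.75 * (1 - exp(-4 * d / 3))
    if (p >= 0.75) stop("target beyond Jukes-Cantor saturation")
    p
  }
  sites <- .ng86_sites_table()
  S <- sum(sites[codons, "s"]); N <- sum(sites[codons, "n"])
  n_syn <- round(S * p_of(target_ks))
  n_non <- round(N * p_of(target_ka))
  with_seed(seed, {
    touched <- vector("list", length(codons))  # positions already mutated
    # per-codon candidate single-nucleotide changes by class; each codon
    # position is mutated at most once, so the applied change count is
    # the observed difference count the Jukes-Cantor inversion expects
    mut_lists <- function(codon, idx) {
      syn <- list(); non <- list()
      for (pos in setdiff(1:3, touched[[idx]])) {
        for (nt in NUCS[NUCS != substring(codon, pos, pos)]) {
          m <- codon
          substring(m, pos, pos) <- nt
          if (m %in% STOP_CODONS) next
          if (.codon_aa(m) == .codon_aa(codon)) syn[[length(syn) + 1L]] <- c(pos, nt)
          else if (!idx %in% protect_nonsyn) non[[length(non) + 1L]] <- c(pos, nt)
        }
      }
      list(syn = syn, non = non)
    }
    cand <- lapply(seq_along(codons), function(i) mut_lists(codons[i], i))
    counts <- vapply(cand, function(x)
      c(syn = length(x$syn), non = length(x$non)), numeric(2L))
    apply_one <- function(class) {
      avail <- counts[class, ]
      total <- sum(avail)
      if (total == 0L) stop("no available ", class, " changes left")
      ci <- sample.int(length(codons), 1L, prob = avail / total)
      mu <- cand[[ci]][[class]][[sample.int(avail[ci], 1L)]]
      m <- codons[ci]
      substring(m, as.integer(mu[1L]), as.integer(mu[1L])) <- mu[2L]
      codons[ci] <<- m
      touched[[ci]] <<- c(touched[[ci]], as.integer(mu[1L]))
      cand[[ci]] <<- mut_lists(m, ci)
      counts[, ci] <<- c(length(cand[[ci]]$syn), length(cand[[ci]]$non))
    }
    todo <- sample(c(rep("syn", n_syn), rep("non", n_non)))
    for (cl in todo) apply_one(cl)
  })
  paste(codons, collapse = "")
}

#' Generate a two-genome bundle with planted collinear blocks
#'
#' Genome A carries `genes_per_chrom` genes per chromosome with mutually
#' dissimilar random proteins. Genome B contains, for each row of
#' `block_spec`, a contiguous run of `n_anchors` genes copied from A in
#' the same (`"same"`) or reversed (`"inverted"`) order, separated by
#' unrelated filler genes.
#'
#' @param seed Integer seed.
#' @param n_chrom_a Chromosomes in genome A.
#' @param genes_per_chrom Genes per A chromosome.
#' @param block_spec Data frame with columns `n_anchors`, `orientation`.
#' @return List: `proteome_a`, `proteome_b`, `annot_a`, `annot_b` (gene
#'   order tables with `gene_id`, `chrom`, `start`) and `truth` (list of
#'   planted blocks, each a data frame of `gene_a`, `gene_b` anchor
#'   pairs in A order).
#' @export
generate_synteny_pair <- function(seed = 1L, n_chrom_a = 2L,
                                  genes_per_chrom = 20L,
                                  block_spec = data.frame(
                                    n_anchors = c(8L, 6L),
                                    orientation = c("same", "inverted"))) {
  with_seed(seed, {
    # full-alphabet random proteins: mutually dissimilar, so only the
    # copied block genes produce anchors above the score threshold
    rand_protein <- function()
      paste0("M", paste(sample(names(AVG_RESIDUE_MASS), sample(50:70, 1L),
                               replace = TRUE), collapse = ""))
    annot_a <- do.call(rbind, lapply(seq_len(n_chrom_a), function(c) {
      data.frame(gene_id = sprintf("A%d_%03d", c, seq_len(genes_per_chrom)),
                 chrom = sprintf("chrA%d", c),
                 start = seq_len(genes_per_chrom) * 10000L)
    }))
    proteome_a <- stats::setNames(
      vapply(seq_len(nrow(annot_a)), function(i) rand_protein(),
             character(1L)), annot_a$gene_id)
    # choose non-overlapping A runs for the blocks
    total_needed <- sum(block_spec$n_anchors)
    if (total_needed > nrow(annot_a))
      stop("block_spec needs more genes than genome A has")
    used <- logical(nrow(annot_a))
    b_genes <- character(0); b_chrom <- character(0); b_prot <- character(0)
    truth <- list()
    # each planted block lives on its own B chromosome, flanked by
    # unrelated filler genes, so planted anchor sets are unambiguous
    add_filler <- function(n, ch) {
      for (i in seq_len(n)) {
        id <- sprintf("B_f%03d", length(b_genes) + 1L)
        b_genes <<- c(b_genes, id)
        b_chrom <<- c(b_chrom, ch)
        b_prot[[id]] <<- rand_protein()
      }
    }
    for (k in seq_len(nrow(block_spec))) {
      ch_b <- sprintf("chrB%d", k)
      add_filler(3L, ch_b)
      n <- block_spec$n_anchors[k]
      # find a free run of n consecutive A genes on one chromosome
      run <- NULL
      for (ch in unique(annot_a$chrom)) {
        idx <- which(annot_a$chrom == ch & !used)
        if (length(idx) < n) next
        consec <- idx[seq_len(n)]
        if (all(diff(consec) == 1L)) { run <- consec; break }
      }
      if (is.null(run)) stop("no free run of ", n, " genes for block ", k)
      used[run] <- TRUE
      a_ids <- annot_a$gene_id[run]
      b_ids <- sprintf("B_b%d_%02d", k, seq_len(n))
      order_b <- if (block_spec$orientation[k] == "same") seq_len(n)
                 else rev(seq_len(n))
      for (j in seq_len(n)) {
        # B gene j (in B chromosome order) copies A gene order_b[j]
        b_genes <- c(b_genes, b_ids[j])
        b_chrom <- c(b_chrom, ch_b)
        b_prot[[b_ids[j]]] <- proteome_a[[a_ids[order_b[j]]]]
      }
      truth[[k]] <- data.frame(gene_a = a_ids,
                               gene_b = b_ids[order(order_b)])
      add_filler(3L, ch_b)
    }
    annot_b <- do.call(rbind, lapply(unique(b_chrom), function(ch) {
      idx <- which(b_chrom == ch)
      data.frame(gene_id = b_genes[idx], chrom = ch,
                 start = seq_along(idx) * 10000L)
    }))
    list(proteome_a = proteome_a, proteome_b = unlist(b_prot),
         annot_a = annot_a, annot_b = annot_b, truth = truth)
  })
}

#' Generate a star-like protein family from four group templates
#'
#' One full-length family protein is drawn per group as the template;
#' members of a group perturb a fraction `divergence` of the template's
#' linker/filler residues (diagnostic residues -- zinc fingers, NLS,
#' C-terminal motifs -- are never in the filler alphabet, so they stay
#' intact). Within-group distances are therefore small and between-group
#' distances large, giving an unambiguous grouping ground truth.
#'
#' @param n_per_group Members per group (default 3).
#' @param divergence Fraction of filler residues resampled per member.
#' @param seed Integer seed.
#' @return List: `proteins` (named vector, `G<g>_M<i>`), `templates`
#'   (named vector `G1`..`G4`, usable as group references) and `truth`
#'   (data frame `gene_id`, `group`).
#' @export
generate_group_family <- function(n_per_group = 3L, divergence = 0.15,
                                  seed = 1L) {
  with_seed(seed, {
    templates <- stats::setNames(
      vapply(1:4, function(g) .make_family_protein(g, nls = TRUE),
             character(1L)), paste0("G", 1:4))
    perturb <- function(template) {
      res <- strsplit(template, "", fixed = TRUE)[[1L]]
      filler <- which(res %in% FILLER_AA)
      n_mut <- round(divergence * length(filler))
      at <- sample(filler, n_mut)
      res[at] <- sample(FILLER_AA, n_mut, replace = TRUE)
      paste(res, collapse = "")
    }
    ids <- character(0); prot <- character(0); grp <- integer(0)
    for (g in 1:4) for (i in seq_len(n_per_group)) {
      id <- sprintf("G%d_M%d", g, i)
      ids <- c(ids, id)
      prot[[id]] <- perturb(templates[[paste0("G", g)]])
      grp <- c(grp, g)
    }
    list(proteins = prot, templates = templates,
         truth = data.frame(gene_id = ids, group = paste0("G", grp)))
  })
}

#' Simulate a replicated qPCR Ct table with known fold changes
#'
#' Reference-gene Ct is constant in expectation across samples; target
#' Ct is `ref + base_dct - log2(fold)` plus Gaussian noise, with
#' `replicates` measurements per (sample, gene) cell. The calibrator
#' sample must carry fold 1 for every gene, so that the planted fold is
#' exactly the 2^-ddCt truth.
#'
#' @param design Data frame with columns `gene`, `sample`, `fold`
#'   (true fold change relative to the calibrator; > 0).
#' @param calibrator Calibrator sample label.
#' @param reference Reference gene label (default `"REF"`).
#' @param replicates Replicates per cell (default 3).
#' @param ct_noise_sd Gaussian noise SD in cycles.
#' @param seed Integer seed.
#' @param base_ref_ct,base_dct Baseline reference Ct and target offset.
#' @return Long-format Ct table (`sample`, `gene`, `replicate`, `ct`).
#' @export
simulate_ct_table <- function(design, calibrator, reference = "REF",
                              replicates = 3L, ct_noise_sd = 0.2, seed = 1L,
                              base_ref_ct = 20, base_dct = 5) {
  stopifnot(nrow(design) > 0L, all(c("gene", "sample", "fold") %in%
                                     names(design)))
  if (any(design$fold <= 0)) stop("fold changes must be > 0")
  cal <- design[design$sample == calibrator, ]
  if (nrow(cal) == 0L || any(cal$fold != 1))
    stop("calibrator sample must be in the design with fold 1")
  with_seed(seed, {
    rows <- list()
    for (s in unique(design$sample)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = reference, replicate = seq_len(replicates),
        ct = base_ref_ct + stats::rnorm(replicates, 0, ct_noise_sd))
      sub <- design[design$sample == s, ]
      for (i in seq_len(nrow(sub))) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = sub$gene[i], replicate = seq_len(replicates),
          ct = base_ref_ct + base_dct - log2(sub$fold[i]) +
            stats::rnorm(replicates, 0, ct_noise_sd))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
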