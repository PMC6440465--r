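test_that("zinc-finger scanning finds planted consensus matches only", {
  expect_identical(nrow(scan_zinc_fingers("MAAA")), 0L)

  zf <- exact_zf("C2H2")
  prot <- paste0(strrep("A", 10), zf, strrep("A", 10))
  hits <- scan_zinc_fingers(prot)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$kind, "C2H2")
  expect_identical(hits$start, 11L)
  expect_identical(hits$end, 10L + nchar(zf))

  broken <- sub("C", "S", zf)  # first coordinating Cys -> Ser
  expect_identical(nrow(scan_zinc_fingers(
    paste0(strrep("A", 10), broken, strrep("A", 10)))), 0L)

  chc <- exact_zf("C2HC")
  hits2 <- scan_zinc_fingers(paste0("MSS", chc, "SS"))
  expect_identical(hits2$kind, "C2HC")
})

test_that("scanning is non-overlapping and leftmost-greedy", {
  prot <- paste0("M", exact_zf("C2H2"), "SS", exact_zf("C2H2"), "SSS",
                 exact_zf("C2HC"), "SS", exact_zf("C2HC"))
  hits <- scan_zinc_fingers(prot)
  expect_identical(hits$kind, c("C2H2", "C2H2", "C2HC", "C2HC"))
  expect_true(all(diff(hits$start) > 0))
  expect_true(all(hits$start[-1] > hits$end[-4]))
  # coordinating positions lie inside their finger
  for (r in 1:4) {
    cc <- hits$coordinating[[r]]
    expect_true(all(cc >= hits$start[r] & cc <= hits$end[r]))
    expect_identical(length(cc), 4L)
  }
})

test_that("domain assembly demands the canonical kind order and span", {
  mk <- function(kinds, gap = 8L) {
    start <- 1L
    rows <- list()
    for (k in kinds) {
      zf <- exact_zf(k)
      rows[[length(rows) + 1L]] <- data.frame(kind = k, start = start,
                                              end = start + nchar(zf) - 1L)
      start <- start + nchar(zf) + gap
    }
    out <- do.call(rbind, rows)
    out$coordinating <- replicate(nrow(out), integer(4), simplify = FALSE)
    out
  }
  good <- mk(c("C2H2", "C2H2", "C2HC", "C2HC"))
  d <- assemble_id_domain(good)
  expect_false(is.null(d))
  expect_identical(d$start, good$start[1])
  expect_identical(d$end, good$end[4])

  expect_null(assemble_id_domain(mk(c("C2H2", "C2HC", "C2H2", "C2HC"))))

  # quartet found inside a longer run of fingers
  five <- mk(c("C2HC", "C2H2", "C2H2", "C2HC", "C2HC"))
  d5 <- assemble_id_domain(five)
  expect_identical(d5$start, five$start[2])
  # sliding-window check: the reported quartet is the first valid one
  for (i in 1:2) {
    kinds <- five$kind[i:(i + 3)]
    if (identical(kinds, c("C2H2", "C2H2", "C2HC", "C2HC")))
      expect_identical(d5$start, five$start[i])
  }

  # span constraint: fingers spread beyond the limit do not assemble
  spread <- mk(c("C2H2", "C2H2", "C2HC", "C2HC"), gap = 80L)
  expect_null(assemble_id_domain(spread))
  expect_false(is.null(assemble_id_domain(spread, max_domain_span = 500L)))
})

test_that("NLS detection is positional", {
  domain <- list(start = 50L, end = 150L)
  expect_identical(find_nls(paste0("M", "KKKR", strrep("S", 200)), domain),
                   list(motif = "KKKR", start = 2L))
  # motif only C-terminal of the domain start: no hit
  expect_null(find_nls(paste0(strrep("S", 60), "KKKR", strrep("S", 100)),
                       domain))
  # leftmost of the two variants wins
  hit <- find_nls(paste0("MSS", "KRKR", "SS", "KKKR", strrep("S", 100)),
                  domain)
  expect_identical(hit$motif, "KRKR")
})

test_that("C-terminal motifs allow bounded mismatches", {
  domain <- list(start = 10L, end = 40L)
  base <- strrep("G", 60)
  p_exact <- paste0(base, "MSATALLQKAA", "GGG", "TRDFLG", "GG")
  hits <- find_cterm_motifs(p_exact, domain)
  expect_setequal(hits$motif, c("MSATALLQKAA", "TRDFLG"))
  expect_identical(hits$mismatches, c(0L, 0L))

  p_one <- paste0(base, "MSATALLQKAV", strrep("G", 20))
  h1 <- find_cterm_motifs(p_one, domain)
  expect_identical(h1$motif, "MSATALLQKAA")
  expect_identical(h1$mismatches, 1L)

  # over budget: three mismatches in MSATALLQKAA, two in TRDFLG
  p_bad <- paste0(base, "MSATAGGGKAA", "GGG", "TGGFLG")
  expect_identical(nrow(find_cterm_motifs(p_bad, domain)), 0L)

  # motifs N-terminal of the domain are not searched
  p_before <- paste0("MSATALLQKAA", strrep("G", 80))
  expect_identical(nrow(find_cterm_motifs(p_before,
                                          list(start = 20L, end = 60L))), 0L)
})

test_that("identification keeps queries and rejects decoy-only proteomes", {
  b <- default_bundle()
  qs <- b$queries
  self <- identify_family(qs, qs)
  expect_setequal(names(self), names(qs))

  decoys <- b$proteome[b$truth$decoys$gene_id]
  expect_identical(length(identify_family(decoys, qs)), 0L)
  expect_identical(length(identify_family(character(0), qs)), 0L)
  expect_error(identify_family(b$proteome, character(0)), "non-empty")
})

test_that("identification separates planted members from decoys perfectly", {
  b <- default_bundle()
  members <- identify_family(b$proteome, b$queries)
  expect_setequal(names(members), b$truth$members$gene_id)
  # every member carries the canonical finger quartet
  for (m in members)
    expect_identical(m$domain$zfs$kind, c("C2H2", "C2H2", "C2HC", "C2HC"))
  # idempotence: re-running on the member proteins returns the same set
  again <- identify_family(vapply(members, `[[`, character(1), "protein"),
                           b$queries)
  expect_setequal(names(again), names(members))
})

test_that("annotation of members matches the planted truth", {
  b <- default_bundle()
  members <- identify_family(b$proteome, b$queries)
  truth <- b$truth$members
  nls_found <- vapply(members[truth$gene_id], function(m) !is.null(m$nls),
                      logical(1))
  expect_identical(unname(nls_found), truth$has_nls)
  both_motifs <- vapply(members[truth$gene_id], function(m)
    setequal(m$cterm$motif, c("MSATALLQKAA", "TRDFLG")), logical(1))
  expect_identical(unname(both_motifs), truth$has_cterm)
  # group-4-style members lack both motifs entirely
  g4 <- truth$gene_id[truth$group == 4]
  for (id in g4) expect_identical(nrow(members[[id]]$cterm), 0L)
})

test_that("locus deduplication keeps the longest isoform", {
  b <- default_bundle()
  m1 <- b$proteome[[b$truth$members$gene_id[1]]]
  proteome <- c("LOC1.1" = m1, "LOC1.2" = paste0(m1, "SSSSSS"))
  members <- identify_family(proteome, b$queries)
  expect_identical(names(members), "LOC1.2")
})

test_that("the members table summarizes annotations", {
  b <- default_bundle()
  members <- identify_family(b$proteome, b$queries)
  tab <- members_table(members)
  expect_identical(nrow(tab), length(members))
  expect_true(all(tab$domain_end > tab$domain_start))
  expect_true(all(tab$zf_kinds == "C2H2,C2H2,C2HC,C2HC"))
})
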