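test_that("FASTA reading preserves records, order and ids", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  recs <- read_fasta(f)
  expect_identical(as.character(recs), "ACGT")
  expect_identical(names(recs), "a")

  writeLines(c(">b desc text", "acgt", "ACGT", ">a", "TTTT"), f)
  recs <- read_fasta(f)
  expect_identical(names(recs), c("b", "a"))
  expect_identical(unname(recs[["b"]]), "ACGTACGT")  # uppercased, joined

  writeLines(c(">x", "ACGT", ">x", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate.*x")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("FASTA write/read round-trip is the identity", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    seqs <- setNames(
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), sample(1:200, 1), replace = TRUE),
              collapse = ""), character(1)),
      paste0("rec", seq_len(n)))
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(seqs, f)
    back <- read_fasta(f)
    expect_identical(as.character(back), as.character(seqs))
    expect_identical(names(back), names(seqs))
  }
})

test_that("alphabet validation rejects out-of-alphabet residues", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p", "MKVJ"), f)
  expect_error(read_fasta(f, alphabet = "protein"), "alphabet")
  writeLines(c(">d", "ACGU"), f)
  expect_error(read_fasta(f, alphabet = "dna"), "alphabet")
})

test_that("exon counting reflects the exon intervals", {
  m3 <- gene_model("g1", "chr1", "+",
                   rbind(c(100, 200), c(301, 400), c(501, 550)),
                   cds = paste(rep("ATG", 84), collapse = ""))
  expect_identical(exon_count(m3), 3L)
  m1 <- gene_model("g2", "chr1", "-", rbind(c(10, 90)))
  expect_identical(exon_count(m1), 1L)
  expect_error(gene_model("g3", "chr1", "+", rbind(c(100, 200), c(150, 300))),
               "overlap")
})

test_that("GFF3 round-trip recovers the generator's truth", {
  cfg <- sim_config(seed = 7, n_family = 3, n_decoys = 2,
                    dup_pairs = data.frame(type = character(),
                                           target_ka = numeric(),
                                           target_ks = numeric()),
                    cis_plan = integer(0))
  b <- generate_family_genome(cfg)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(b$models, gff)
  back <- read_gff3(gff, genome = b$genome)
  expect_setequal(names(back), names(b$models))
  for (id in names(b$models)) {
    expect_identical(exon_count(back[[id]]), exon_count(b$models[[id]]))
    expect_identical(back[[id]]$strand, b$models[[id]]$strand)
    expect_identical(back[[id]]$start, b$models[[id]]$start)
    # CDS reassembled from the genome equals the planted CDS
    expect_identical(back[[id]]$cds, b$models[[id]]$cds)
  }
})

test_that("CDS length not divisible by three flags the record", {
  expect_warning(m <- gene_model("g", "chr1", "+", rbind(c(1, 10)),
                                 cds = "ATGAA"),
                 "not divisible")
  expect_true(m$flagged)
})

test_that("upstream extraction follows strand and coordinates", {
  chrom <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  plus <- gene_model("gp", "chr1", "+", rbind(c(2001, 2600)))
  expect_identical(unname(extract_upstream(genome, plus, 1500)),
                   substring(chrom, 501, 2000))
  minus <- gene_model("gm", "chr1", "-", rbind(c(101, 500)))
  expect_identical(unname(extract_upstream(genome, minus, 1500)),
                   revcomp(substring(chrom, 501, 2000)))
  near <- gene_model("gn", "chr1", "+", rbind(c(801, 900)))
  expect_warning(p <- extract_upstream(genome, near, 1500), "truncated")
  expect_identical(nchar(unname(p)), 800L)
  expect_identical(unname(p), substring(chrom, 1, 800))
  expect_error(extract_upstream(genome,
                                gene_model("gx", "chr9", "+",
                                           rbind(c(10, 20))), 1500),
               "chr9")
})

test_that("upstream extraction is strand-symmetric", {
  chrom <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                 collapse = "")
  genome <- c(c1 = chrom)
  mirrored <- c(c1 = revcomp(chrom))
  plus <- gene_model("g", "c1", "+", rbind(c(2001, 2300)))
  minus <- gene_model("g", "c1", "-", rbind(c(4000 - 2300 + 1, 4000 - 2001 + 1)))
  expect_identical(unname(extract_upstream(genome, plus, 1000)),
                   unname(extract_upstream(mirrored, minus, 1000)))
})

test_that("the start codon is excluded unless requested", {
  genome <- c(c1 = paste0(strrep("T", 100), "ATGAAACCC", strrep("G", 50)))
  m <- gene_model("g", "c1", "+", rbind(c(101, 109)))
  expect_identical(unname(extract_upstream(genome, m, 10)), strrep("T", 10))
  expect_identical(unname(extract_upstream(genome, m, 10,
                                           include_start = TRUE)),
                   paste0(strrep("T", 10), "ATG"))
})
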