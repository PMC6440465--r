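no_dups <- data.frame(type = character(), target_ka = numeric(),
                      target_ks = numeric())

test_that("generation is deterministic in the configuration", {
  cfg <- sim_config(seed = 21, n_family = 4, n_decoys = 2,
                    dup_pairs = no_dups)
  b1 <- generate_family_genome(cfg)
  b2 <- generate_family_genome(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$proteome, b2$proteome)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_family_genome(sim_config(seed = 22, n_family = 4,
                                          n_decoys = 2, dup_pairs = no_dups))
  expect_false(identical(b1$proteome, b3$proteome))
})

test_that("a family-free configuration emits decoys only", {
  cfg <- sim_config(seed = 23, n_family = 0, n_decoys = 5,
                    dup_pairs = no_dups)
  b <- generate_family_genome(cfg)
  expect_identical(length(b$proteome), 5L)
  expect_identical(nrow(b$truth$members), 0L)
  expect_true(all(grepl("^DEC", names(b$proteome))))
})

test_that("configuration invariants are validated", {
  expect_error(sim_config(dup_pairs = data.frame(type = "tandem",
                                                 target_ka = 0.9,
                                                 target_ks = 0.2)))
  expect_error(sim_config(n_family = 2,
                          dup_pairs = data.frame(type = rep("tandem", 2),
                                                 target_ka = 0.1,
                                                 target_ks = 0.1)),
               "family genes")
  expect_error(sim_config(ct_noise_sd = -1))
  cfg_small <- sim_config(seed = 1, n_family = 10, n_decoys = 10,
                          chromosomes = c(chr1 = 60000L), dup_pairs = no_dups)
  expect_error(generate_family_genome(cfg_small), "too short")
})

test_that("planted gene models agree with their own truth table", {
  b <- default_bundle()
  truth <- b$truth$members
  for (i in seq_len(nrow(truth))) {
    m <- b$models[[truth$gene_id[i]]]
    expect_identical(exon_count(m), truth$n_exons[i])
    expect_identical(m$chrom, truth$chrom[i])
    expect_identical(m$strand, truth$strand[i])
    # the CDS re-translates to the emitted protein
    expect_identical(translate_cds(m$cds), b$proteome[[truth$gene_id[i]]])
  }
})

test_that("duplicate evolution hits its targets and never creates stops", {
  cds <- random_cds(200)
  expect_identical(evolve_duplicate(cds, 0, 0, seed = 1), cds)

  mut <- evolve_duplicate(cds, 0.1, 0.3, seed = 2)
  expect_identical(nchar(mut), nchar(cds))
  expect_false(grepl("\\*", translate_cds(mut, strip_stop = FALSE)))
  expect_error(evolve_duplicate(cds, 0.8, 0.1), "\\[0, 0.7\\]")
  expect_error(evolve_duplicate(paste0(cds, "TAA"), 0.1, 0.1),
               "stop")
  expect_error(evolve_duplicate("ATGAA", 0.1, 0.1), "divisible")

  # protected codons keep their amino acid
  prot_idx <- c(3L, 10L, 50L)
  mut_p <- evolve_duplicate(cds, 0.3, 0.1, seed = 3,
                            protect_nonsyn = prot_idx)
  aa_in <- strsplit(translate_cds(cds), "")[[1]]
  aa_out <- strsplit(translate_cds(mut_p), "")[[1]]
  expect_identical(aa_out[prot_idx], aa_in[prot_idx])
})

test_that("the grouped-family generator separates groups by construction", {
  fam <- generate_group_family(n_per_group = 2, seed = 7)
  expect_identical(length(fam$proteins), 8L)
  # every member still carries a full ID domain and the planted NLS
  for (p in fam$proteins) {
    zfs <- scan_zinc_fingers(p)
    expect_false(is.null(assemble_id_domain(zfs)))
  }
  # within-group protein distance is far below between-group distance
  d <- pdistance_matrix(c(fam$proteins, fam$templates))
  within <- d["G1_M1", "G1_M2"]
  across <- d["G1_M1", "G2_M1"]
  expect_lt(within, 0.3)
  expect_gt(across, 0.4)
})

test_that("simulated Ct tables encode the design exactly at zero noise", {
  des <- data.frame(gene = rep(c("G1", "G2"), each = 2),
                    sample = rep(c("ctrl", "trt"), 2),
                    fold = c(1, 1, 1, 8))
  ct <- simulate_ct_table(des, calibrator = "ctrl", ct_noise_sd = 0)
  expect_identical(nrow(ct), 2L * 3L + 4L * 3L)  # REF + two targets
  expect_true(all(table(ct$sample, ct$gene) %in% c(0L, 3L)))
  fc1 <- delta_delta_ct(ct, "G1", "REF", "ctrl")
  expect_true(all(fc1$delta_delta_ct == 0))
  fc2 <- delta_delta_ct(ct, "G2", "REF", "ctrl")
  expect_equal(fc2$fold[fc2$sample == "trt"], 8)
  expect_error(simulate_ct_table(des[des$sample == "trt", ],
                                 calibrator = "ctrl"), "calibrator")
})

test_that("synteny bundles are deterministic and respect the block spec", {
  sp1 <- generate_synteny_pair(seed = 9)
  sp2 <- generate_synteny_pair(seed = 9)
  expect_identical(sp1$proteome_b, sp2$proteome_b)
  expect_identical(sp1$truth, sp2$truth)
  expect_identical(vapply(sp1$truth, nrow, integer(1)), c(8L, 6L))
  # block genes carry the same protein as their A partners
  for (tr in sp1$truth)
    for (r in seq_len(nrow(tr)))
      expect_identical(sp1$proteome_b[[tr$gene_b[r]]],
                       sp1$proteome_a[[tr$gene_a[r]]])
  expect_error(generate_synteny_pair(seed = 1, genes_per_chrom = 3,
                                     block_spec = data.frame(
                                       n_anchors = 10L,
                                       orientation = "same")),
               "more genes|free run")
})
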