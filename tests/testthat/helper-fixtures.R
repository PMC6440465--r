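# Shared fixtures: the default synthetic bundle is expensive (whole
# genome + proteome), so it is generated once per test run and reused.

default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_family_genome(sim_config(seed = 1))
    cache
  }
})

member_coords <- function(bundle) {
  do.call(rbind, lapply(bundle$models[bundle$truth$members$gene_id],
                        function(m) data.frame(gene_id = m$gene_id,
                                               chrom = m$chrom,
                                               start = m$start, end = m$end)))
}

# a consensus-exact zinc finger with fixed spacers, for planted-offset tests
exact_zf <- function(kind = "C2H2") {
  paste0("FA", "C", "ST", "C", "TTT", "F", "SSSSS", "L", "SS", "H", "TTT",
         if (kind == "C2H2") "H" else "C")
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1L]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
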