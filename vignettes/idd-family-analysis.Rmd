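---
title: "Methods: IDD gene-family analysis with iddfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IDD gene-family analysis with iddfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iddfam)
```

`iddfam` re-implements, as ordinary tested R code, the chain of analyses
that makes up a genome-wide survey of the plant INDETERMINATE DOMAIN
(IDD) gene family: identification of family members in a proteome,
protein physicochemistry, duplicate-pair classification and
selection-pressure analysis, microsynteny, promoter cis-element
scanning, phylogenetic grouping, and qPCR quantification. This vignette
is the package's methodological record: the models and their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the underlying procedure was
genuinely open.

## The family model

IDD proteins are defined here operationally, by what the identification
stage can check:

* an **ID domain**: four zinc fingers in the order C2H2, C2H2, C2HC,
  C2HC, each matching the consensus
  `(F/Y)-X-C-X(2,5)-C-X3-(F/Y)-X5-ψ-X2-H-X(3,5)-H`
  (C2HC: terminal H replaced by C), the whole domain spanning at most
  `max_domain_span = 220` residues;
* optionally, an **NLS** — the tetrapeptide KKKR or KRKR — strictly
  N-terminal of the domain;
* optionally, the **C-terminal motifs** MSATALLQKAA (up to 2
  mismatches) and TRDFLG (up to 1), searched only C-terminal of the
  domain. Family groups differ in their motif complement; the group-4
  template carries neither.

Three of these constants deserve comment. The hydrophobic position ψ is
instantiated as the residue class `[AVLIMFWC]`; the consensus itself
does not enumerate it, and widening or narrowing this class directly
trades recall against decoy admission. `max_domain_span = 220` bounds
the inter-finger spacing, which the consensus leaves free; published
alignments of the domain show it to be compact, and the bound mostly
guards against assembling a "domain" from fingers scattered across an
entire protein. Both are exposed as arguments. Finally, the similarity
prefilter threshold (`min_query_identity = 0.25`) is deliberately loose:
its job is to emulate the role of a BLAST search — cheap candidate
reduction — while the domain test does the actual discrimination.

Fingers are scanned non-overlapping and leftmost-greedy; when both
finger kinds match at one position the canonical C2H2 wins. The domain
is the *first* window of four consecutive fingers with the canonical
kind order. Proteins are deduplicated per locus (isoform suffixes such
as `.1`, `.t2` stripped) keeping the longest isoform — the natural
reading of "redundant sequences discarded" when no criterion is stated.

## Physicochemistry

`protparam_table` reproduces the ExPASy-style quantities reported in
family tables: residue count; molecular weight as the sum of average
residue masses plus one water; pI as the bisection root of the
Henderson–Hasselbalch net charge over N-terminus, C-terminus and the
D/E/C/Y/H/K/R side chains, using the Bjellqvist pK set (the set behind
the ExPASy pI tool, which produced the published tables this mirrors);
and GRAVY as mean Kyte–Doolittle hydropathy. Bisection runs on pH
[0, 14] to |charge| < 1e−4 with at most 100 iterations; with both
termini always present a sign change is guaranteed. `X` residues
contribute the mean residue mass, no charge, and are excluded from the
GRAVY denominator. All four tables are package data, so another pK or
mass convention can be substituted without touching code.

## Duplication and selection pressure

Duplicate pairs are all unordered gene pairs whose coding sequences
align globally at **more than 80% identity**. Identity is computed with
internal gap columns counted as mismatches but terminal overhangs
excluded from the denominator — the two members of a duplicate pair
often differ in length, and penalizing the overhang would conflate
length difference with divergence. The convention is exposed
(`alignment_identity(..., convention = "all_columns")`).

Classification follows the three printed rules exactly: same chromosome
and nearest-boundary separation **at least 200 kb** → tandem; different
chromosomes → segmental. This inverts the usual field convention (tandem
duplicates are normally the *close* pairs), so the rule is implemented
as printed under `tandem_rule = "as_printed"` with a
`"conventional"` switch that swaps the distance test; pairs on one
chromosome that fail the active rule are reported `unclassified` rather
than silently reassigned. Separation is measured between nearest gene
boundaries, the only reading compatible with "separated by".

Ka/Ks uses the Nei–Gojobori (1986) counting method, written here from
first principles:

* **Sites.** For each codon position, the fraction of synonymous
  changes among the non-stop single-nucleotide mutants at that position;
  every position contributes one site, so S + N = 3 per codon; sites are
  averaged between the two sequences.
* **Differences.** For each differing codon pair, all orderings of the
  differing positions are enumerated; pathways passing through a stop
  codon are excluded and the synonymous/nonsynonymous step counts of the
  surviving pathways are averaged with equal weight. In the rare case
  that *every* pathway is blocked, the average falls back to all
  pathways (a stop-crossing step counts as nonsynonymous). Codon
  columns containing gaps, N, or stop codons are skipped.
* **Correction.** pS = Sd/S and pN = Nd/N are corrected with the
  Jukes–Cantor map d = −(3/4)·ln(1 − (4/3)p); p ≥ 3/4 is reported as
  saturated (NA), and the ratio is undefined when Ks = 0 — profiles and
  tables never carry infinities. The Ka/Ks = 1 cut-off labels each
  result purifying/neutral/positive.

Per-codon site counts and per-codon-pair pathway averages are memoized,
which is what makes sliding-window profiles cheap. Windows are 150
alignment bp advanced by 9 bp (both multiples of 3), all windows fully
inside the alignment: count = floor((L−150)/9) + 1.

Pairwise alignment everywhere in the package (prefilter, duplicate
identity, Ka/Ks codon alignment, anchors, p-distances) is global
Needleman–Wunsch via `Biostrings::pairwiseAlignment`, with BLOSUM62 and
affine gaps open 10 / extend 0.5 for proteins, and match +2 / mismatch
−3, open 5 / extend 2 for DNA (N scoring 0 against everything). The
codon alignment is protein-guided: each protein gap becomes a 3-bp gap,
with both length and translation consistency checked.

## Microsynteny

Anchors are, for each gene of genome A, the up-to-5 best genes of
genome B by global protein alignment score (floor 50); ranks are gene
order indices per chromosome. Blocks are maximum-cardinality chains per
chromosome pair and orientation — strictly increasing in both ranks for
`same`, decreasing in B for `inverted` — found by O(n²)
longest-increasing-subsequence dynamic programming with adjacent rank
gaps bounded by `max_gap` on both genomes, extracted greedily in
decreasing size, discarding chains shorter than `min_block`.
`min_block = 5`, `max_gap = 25` and `top_hits = 5` follow the MCScanX
documented defaults, since surveys built on that tool rarely state
parameters; block score is anchor count (the e-value-weighted scoring of
MCScanX is not reproduced — counts are deterministic and sufficient for
ortholog-pair extraction). Family ortholog pairs are anchor pairs inside
blocks where both genes are family members; one member may pair with
several partners.

**The shuffled-order null.** A meaningful null for "are these blocks
real?" permutes each genome's gene order independently and asks how
often chaining still finds blocks. The anchor set under this null is
the set of homologous gene pairs — a sparse set (the synthetic
two-genome bundle has 14 anchors among 200 gene positions). At that
density, chaining finds zero blocks in ≈100% of permutations. The null
is *not* run on a dense identity mapping (one anchor per gene): with
200 anchors over 200 ranks the expected number of forward neighbors
within a 25×25 rank window is ≈3, and spurious 5-chains are then
guaranteed (~25 blocks per permutation, measured) — a property of the
chaining parameters, not of the data, and not a test any practitioner
would run.

## Promoters and cis-elements

Promoters are the 1,500 bp immediately 5′ of the translation start on
the coding strand, excluding the ATG itself ("upstream of" read
strictly; `include_start = TRUE` appends it), reverse-complemented for
minus-strand genes and truncated with a warning at chromosome edges.
Scanning matches every catalog pattern on both strands (via Biostrings
with IUPAC expansion in the pattern only; an N in the promoter never
matches), reporting strands separately. The shipped catalog holds
PlantCARE-style consensus strings for the commonly reported plant
elements; exact database patterns vary by PlantCARE version, so the
catalog is data (`inst/extdata/cis_catalog.tsv`), replaceable via
`load_cis_catalog`, and per-gene counts against any particular database
export are not guaranteed.

Summaries report two conventions deliberately: raw hit counts (totals
equal the number of reported hits) and unique-site counts per
functional class, where a palindromic element (G-Box) or a
reverse-complement pattern pair (CGTCA-motif/TGACG-motif) occupies one
site — the convention behind statements like "41 MeJA-associated
elements".

## Grouping

The package groups family members with p-distances (mismatch fraction
over gap-free columns of pairwise global alignments) and Saitou–Nei
neighbor joining (`ape::nj`), writing Newick. NJ replaces the
maximum-likelihood + bootstrap tree of a typical survey deliberately:
group *identity* is anchored by reference members, not by tree-shape
fidelity, and NJ is deterministic and exactly testable — on additive
distance matrices it provably recovers the generating tree, which the
tests exercise. Negative branch-length estimates are clamped to zero
and counted in a tree attribute. `assign_groups` gives each unlabeled
leaf the group of its nearest reference leaf by path length, breaking
ties toward the lexicographically smallest group and flagging them.
Published group sizes from ML trees with unstated rooting are therefore
not reproduced here, by design.

## Expression

`delta_delta_ct` implements the Livak method: ΔCt = mean Ct(target) −
mean Ct(reference) per sample, ΔΔCt relative to a calibrator sample,
fold = 2^−ΔΔCt, with the replicate SD of ΔCt propagated as the
asymmetric range 2^−(ΔΔCt ± sd). Per-replicate ΔCt pairs target and
reference replicates by index, which keeps the replicate ΔCt values
independent — subtracting the reference *mean* instead would correlate
them and distort the test below. Undetected targets (no Ct rows) are
reported as missing, not as zero fold. Significance is a two-sided
Welch t-test on the per-replicate ΔCt values of sample versus
calibrator, starred at raw P < 0.05 / P < 0.01 with no multiple-testing
correction (matching the raw-threshold convention of qPCR figures).
The method is standard for 2^−ΔΔCt designs; note that with three
replicates Welch's test is conservative — its true size under a normal
null measures ≈0.034 at nominal 0.05 (40,000-draw estimate), at the
lower edge of the [0.03, 0.07] band the test suite checks over 1,000
simulated nulls, so that check sits close to its own Monte-Carlo noise
floor. Amplification-efficiency correction (Pfaffl) is out of scope.

## The synthetic-data generator

Every stage above is tested against `generate_family_genome` and its
companions, whose defaults define the package's reference study
conditions: 20 family members over four group templates, 20 decoys,
five chromosomes (0.4–0.5 Mb), two tandem and two segmental duplicate
pairs with divergence targets Ka = 0.05 / Ks = 0.25 (typical of young
segmental duplicates under purifying selection), NLS planted with
probability 0.8, three CGTCA-motifs and two G-Boxes per promoter, and
Ct noise of 0.2 cycles with three replicates.

Construction choices are made for unambiguous ground truth rather than
realism:

* Linkers and fillers are drawn from an alphabet of hydrophilic-ish
  residues containing no C/H/F/Y (cannot seed a finger), no K/R (cannot
  seed an NLS) and no A/L/M (cannot approximate the C-terminal motifs);
  decoys are either two-finger proteins or four-finger proteins with a
  coordinating Cys→Ser break.
* Back-translation draws uniformly over synonymous codons (no codon
  bias; nothing downstream depends on it).
* `evolve_duplicate` inverts the Jukes–Cantor map at the target rates
  to get expected *observed* difference proportions, applies
  round(sites × p) changes of each class, each drawn uniformly from the
  currently available single-nucleotide changes of that class, at most
  one change per codon position (so applied changes are observed
  differences, which is what the correction expects), never creating a
  stop. In the genome bundle, codons of diagnostic residues are
  protected from nonsynonymous change so evolved duplicates remain
  identifiable family members; the estimator still sees the full site
  denominator, leaving recovery unbiased.
* Planted promoters use an A/T-only background (no catalog pattern
  survives without C or G), and placements are rescanned and retried
  until planted-element counts verify exactly.
* Each planted collinear block occupies its own chromosome in genome B,
  flanked by unrelated filler genes, so planted anchor sets cannot
  merge.

What the generator does **not** emulate: realistic base or residue
composition (synthetic "proteins" are acidic and low-complexity —
physicochemistry on them exercises the arithmetic, not the family's
published value ranges), intergenic structure, indel evolution
(substitutions only, matching a substitution-based Ka/Ks analysis),
UTRs, alternative splicing, codon bias, and expression dynamics beyond
the ΔΔCt model. Green tests therefore demonstrate algorithmic
correctness and exact bookkeeping, not that thresholds tuned on real
genomes will transfer.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run at sizes chosen to keep a
full check of every stage comfortable on a laptop: the 40-protein
reference bundle, 900-codon × 20-replicate divergence recovery,
450-bp × 20-replicate window ranking, all 61×61 sense-codon pairs
against an exhaustive-pathway oracle, 2 two-genome bundles plus a
100-permutation null for synteny, 50 additive 8-leaf trees for NJ, and
1,000 simulated nulls for the expression test. Every generator is a
pure function of its configuration (one RNG stream seeded from
`cfg$seed`, global RNG state restored afterwards), and the acceptance
script derives all of its seeds from `--seed`, so results are
reproducible byte for byte.

## Known limitations

* The domain consensus is a regular expression, not a profile HMM;
  genuinely divergent fingers (unusual spacing, ψ outside the chosen
  class) are missed by construction, and borderline members of real
  proteomes may differ from published member lists whose final step was
  a manual check.
* DnaSP-style implementations of NG86 may differ in correction details;
  this implementation is validated against its own exhaustive-pathway
  oracle, not against any particular tool's output.
* The published per-protein physicochemistry and pear duplicate-pair
  Ka/Ks values can only be recomputed from the study's supplementary
  sequence list, which is not redistributable with the package; the two
  acceptance tests that consume those inputs fail until the files are
  supplied (`inst/extdata/pbidd_proteins.fasta`, `pbidd_cds.fasta`,
  `pbidd_genes.gff3`).
* Tandem arrays larger than two genes are reported as their constituent
  pairs; no multi-gene clustering is attempted.
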