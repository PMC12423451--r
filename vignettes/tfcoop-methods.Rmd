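---
title: "tfcoop: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfcoop: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoop)
```

`tfcoop` analyses a transcription-factor (TF) repertoire from five
angles: genomic organisation (clustering), promoter binding sites,
candidate dimer cooperation, co-expression, and sequence variation.
Every analysis has a synthetic-data generator with machine-readable
planted truth, so the whole pipeline can be verified end to end.  This
vignette states the exact conventions each stage uses.

## TF catalog and chromosomal clustering

`load_catalog()` reads a GFF3 annotation, a genome FASTA and a
TF-family table and yields per-gene coordinates, exon/CDS/UTR
intervals and spliced CDS sequences.  `cluster_tfs()` tiles each
chromosome with consecutive, non-overlapping windows of `window_bp`
(default 250 kb) anchored at coordinate 1; a TF belongs to the window
containing its start coordinate.  Windows holding at least two TFs are
*primary* clusters.  Primary clusters in consecutive windows of one
chromosome are merged — transitively — when the two adjacent windows
share at least one TF family; note that the merge decision always
compares the two adjacent windows' own families, never the accumulated
family set of a growing cluster.  Windows with exactly one TF
contribute *singlets*, so singlets plus cluster members always
partition the placed TFs.

```{r cluster-example}
genes <- data.frame(
  gene_id = c("t1", "t2", "t3", "t4", "t5"),
  chrom   = "chr1",
  start   = c(10000, 60000, 260000, 280000, 900000),
  family  = c("F1", "F2", "F2", "F3", "F1"),
  is_tf   = TRUE)
cs <- cluster_tfs(structure(list(genes = genes), class = "tf_catalog"),
                  window_bp = 250000)
cs$clusters[, c("chrom", "kind", "span_start", "span_end", "n_members")]
cs$singlets
```

Windows 0 and 1 both hold two TFs and share family F2, so they merge
into one cluster spanning both windows; the remaining TF is a singlet.

## Promoter scanning with an exact null

Promoters are the 500 bp upstream of the transcription start site
(TSS), read on the coding strand.  Motifs are position weight matrices
(PWMs, MEME format via `read_meme()`/`write_meme()`).  `pwm_scan()`
scores every offset with integer log2-odds scores (probabilities get a
pseudocount, scores are scaled by 1000 and rounded) and computes the
p-value from the *exact* null distribution of the score under the
background model, obtained by dynamic-programming convolution over
motif columns — no sampling and no approximation.  Coordinates are
reported upstream of the TSS, 1-based: a hit's `start_upstream` is its
5'-most base (the larger number) and `end_upstream` its 3'-most base.

```{r scan-example}
site <- "AAAGATCAAAATAAGAGAAG"
pwm <- one_hot_pwm("example", site)
set.seed(1)
promoter <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
## place the site so its 3'-most base is 313 bp upstream of the TSS
substr(promoter, 500 - 332 + 1, 500 - 313 + 1) <- site
pwm_scan(pwm, data.frame(gene_id = "G1", seq = promoter), p_max = 1e-4)
```

A 20-nt site ending 313 bp upstream therefore occupies 332–313.

## Palindromic dimer cooperation

Two TFs are candidate cooperating dimer partners when a fragment of
one motif consensus concatenated with a fragment of the other equals
its own reverse complement.  Equivalently, the second fragment is the
reverse complement of the first, both of length `k >= min_len / 2`.
`find_palindromes()` enumerates *all* such fragment pairs;
`build_coop_network()` turns the maximal palindrome per TF pair
(self-pairs included) into a network edge labelled within- or
cross-family.

```{r palindrome-example}
find_palindromes("AAAGGG", "CCCTTT", min_len = 6)
```

## Co-expression modules

`filter_low_expression()` removes genes whose TPM is below 1 in at
least 90% of samples (both cut-offs configurable).  The unsigned
adjacency is `|cor|^beta` with `beta` chosen by `pick_soft_power()` as
the smallest power whose connectivity distribution reaches the
scale-free fit cut-off (falling back, with a warning, to the
best-fitting power).  `compute_tom()` forms the topological overlap
matrix `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 -
a_ij)`.  `detect_modules()` clusters `1 - TOM` with average linkage,
applies a static cut (by default at the merge height yielding the most
clusters of at least `min_module_size` genes, tie-broken at the lower
edge of the widest merge-height gap), and iteratively merges modules
whose eigengene dissimilarity falls below 0.25.  The eigengene is the
sign-oriented, unit-norm first principal component of the
row-standardised module expression.

## Variation rates and NG86 Ka/Ks

Variants are annotated to CDS, UTR, intron or intergenic (CDS > UTR >
intron inside a gene), with SNV coding effects by strand-aware codon
substitution.  `project_region_rate()` divides the count of *unique*
variant sites in a region by region length times sample count;
`family_region_rate()` additionally divides by the number of family
members actually possessing the region.  `ng86_kaks()` implements
Nei–Gojobori (1986) counting with pathway averaging over codons
differing at several positions (pathways through intermediate stop
codons are excluded when any stop-free pathway exists) and the
Jukes–Cantor correction.

```{r ng86-example}
unclass(ng86_kaks("TTT", "TTC"))[c("syn_diffs", "nonsyn_diffs", "ka")]
```

## Synthetic data and the pipeline

`simulate_dataset()` writes a complete synthetic input set — genome
with planted TF clusters, motif library with planted palindromic pairs
and certified decoys, promoter hits at requested coordinates, a TPM
matrix with planted modules, and a VCF with planted per-region rates —
plus JSON truth files.  The motif generator proves, by 3-mer set
logic plus an independent exhaustive check, that the only palindromic
pairs in the emitted library are the planted ones, or raises an error
when a requested configuration is infeasible.  `run_pipeline()` runs
all stages with per-stage input/parameter/output digests in a manifest
(unchanged stages are reused as `"cached"`), and `compare_to_truth()`
scores a run against a truth bundle: cluster co-membership precision
and recall, promoter-hit coordinate exactness, planted-pair precision
and recall, module adjusted Rand index, and rate deltas.
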