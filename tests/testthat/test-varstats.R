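test_that("codon_syn_sites matches hand counts", {
  ## TTT (Phe): only TTT->TTC at position 3 is synonymous -> 1/3
  expect_equal(tfcoop:::codon_syn_sites("TTT"), 1 / 3)
  ## ATG (Met) and TGG (Trp) have no synonymous change
  expect_equal(tfcoop:::codon_syn_sites("ATG"), 0)
  expect_equal(tfcoop:::codon_syn_sites("TGG"), 0)
  ## GGG (Gly): all three third-position changes synonymous -> 1
  expect_equal(tfcoop:::codon_syn_sites("GGG"), 1)
})

test_that("ng86_kaks validates its input", {
  expect_error(ng86_kaks("ATGGCT", "ATG"), "length")
  expect_error(ng86_kaks("ATGG", "ATGC"), "divisible")
  expect_error(ng86_kaks("ATGN", "ATGC"))
})

test_that("generated variants annotate back to their planted regions", {
  gb <- gen_genome(genome_sim_config(n_chromosomes = 2,
                                     chrom_length_bp = 1000000,
                                     n_tf_genes = 6, n_sg_genes = 4,
                                     n_families = 3, seed = 9),
                   tempfile())
  vcfg <- variant_sim_config(n_samples = 5, seed = 9)
  vb <- gen_variants(gb, vcfg, tempfile())
  catalog <- load_catalog(gb$paths$gff3, gb$paths$genome, gb$paths$families)
  rec <- read_vcf_records(vb$paths$vcf)
  ann <- annotate_variants(rec, catalog)
  ## the annotator reproduces the generator's gene and region calls
  key <- function(d) paste(d$chrom, d$pos)
  m <- match(key(vb$records), key(ann))
  expect_false(anyNA(m))
  expect_identical(ann$region[m], vb$records$region)
  expect_identical(ann$gene_id[m], vb$records$gene_id)
  cds <- vb$records$region == "CDS"
  expect_identical(ann$effect[m][cds], vb$records$effect[cds])

  ## planted counts invert to the configured rates exactly
  lens <- catalog_region_lengths(catalog)
  rr <- project_region_rate(ann[!is.na(ann$region), ], lens,
                            n_samples = vcfg$n_samples)
  for (rg in rr$region) {
    planted <- round(vcfg$target_rates[[rg]] * lens[[rg]] * vcfg$n_samples)
    expect_identical(rr$rate[rr$region == rg],
                     planted / (lens[[rg]] * vcfg$n_samples))
  }

  ## per-family Ka/Ks is computable and nonnegative where defined
  fk <- family_kaks_from_variants(ann, catalog)
  if (nrow(fk)) expect_true(all(fk$mean_kaks >= 0 | is.na(fk$mean_kaks)))
})
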