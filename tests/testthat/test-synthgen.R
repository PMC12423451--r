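test_that("motif_sim_config rejects invalid planted-pair layouts", {
  pp <- function(...) data.frame(...)
  expect_error(motif_sim_config(planted_pairs = pp(
    motif_i = 1L, motif_j = 2L, half_site_length = 2L)), "half-site")
  expect_error(motif_sim_config(n_motifs = 3, planted_pairs = pp(
    motif_i = 1L, motif_j = 5L, half_site_length = 3L)), "out of range")
  expect_error(motif_sim_config(n_motifs = 4, planted_pairs = pp(
    motif_i = c(1L, 2L), motif_j = c(2L, 3L),
    half_site_length = 3L)), "at most one")
  expect_error(motif_sim_config(motif_length_range = c(4, 16)))
  ## a self-pair island of 2 x 13 bp cannot fit a 16-bp motif
  cfg <- motif_sim_config(planted_pairs = pp(
    motif_i = 1L, motif_j = 1L, half_site_length = 13L))
  expect_error(gen_motif_library(cfg, tempfile()), "length range")
})

test_that("generated library is palindrome-clean apart from planted pairs", {
  pp <- data.frame(motif_i = c(1L, 3L), motif_j = c(2L, 3L),
                   half_site_length = c(4L, 3L))
  mb <- gen_motif_library(motif_sim_config(n_motifs = 6, planted_pairs = pp,
                                           n_decoys = 8, seed = 12),
                          tempfile())
  cons <- mb$consensus
  expect_identical(length(cons), 14L)
  planted <- with(mb$truth$planted_pairs, paste(motif_a, motif_b))
  ids <- names(cons)
  for (i in seq_along(cons)) {
    for (j in seq_len(i)) {
      k <- max_palindrome_k(cons[[j]], cons[[i]], 6)
      is_planted <- paste(ids[j], ids[i]) %in% planted
      expect_identical(k > 0, is_planted)
      if (is_planted) {
        want <- mb$truth$planted_pairs$half_site_length[
          planted == paste(ids[j], ids[i])]
        expect_gte(k, want)
      }
    }
  }
})

test_that("genome generator plants clusters that cluster_tfs recovers", {
  cs <- data.frame(chrom = c(1L, 1L, 2L), window = c(1L, 2L, 5L))
  cs$families <- list(c("F1", "F2"), c("F2", "F3"), c("F4", "F4"))
  gcfg <- genome_sim_config(cluster_spec = cs, seed = 21)
  gb <- gen_genome(gcfg, tempfile())
  catalog <- load_catalog(gb$paths$gff3, gb$paths$genome, gb$paths$families)
  cls <- cluster_tfs(catalog, window_bp = gcfg$window_bp)
  truth_sets <- lapply(gb$truth$clusters, function(cl)
    sort(unlist(cl$members)))
  got_sets <- lapply(cls$clusters$members, sort)
  expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                  vapply(truth_sets, paste, character(1), collapse = ","))
  ## windows 1 and 2 on chr1 share F2 and must merge into one cluster
  merged <- vapply(gb$truth$clusters, function(cl) cl$kind, character(1))
  expect_identical(sum(merged == "merged"), 1L)
  expect_identical(sum(cls$clusters$kind == "merged"), 1L)
})

test_that("expression generator respects module sizes and low-expression genes", {
  eb <- gen_expression(expr_sim_config(seed = 4), tempfile())
  tab <- table(eb$truth$modules)
  expect_identical(as.integer(tab[c("M1", "M2", "M3")]), rep(50L, 3))
  expect_identical(as.integer(tab["low"]), 20L)
  low_genes <- names(eb$truth$modules)[eb$truth$modules == "low"]
  expect_true(all(eb$matrix[low_genes, ] < 1))
  expect_identical(dim(eb$matrix), c(200L, 60L))
})
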