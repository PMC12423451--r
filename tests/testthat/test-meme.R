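test_that("MEME round trip preserves motifs", {
  set.seed(5)
  ## probabilities exactly representable at the 6-decimal MEME precision
  mk <- function(id, w) {
    m <- t(replicate(w, sample(c(0.1, 0.2, 0.3, 0.4))))
    colnames(m) <- c("A", "C", "G", "T")
    motif_pwm(id, m)
  }
  motifs <- list(M1 = mk("M1", 8), M2 = mk("M2", 12))
  path <- tempfile(fileext = ".meme")
  write_meme(motifs, path)
  back <- read_meme(path)
  expect_identical(names(back), c("M1", "M2"))
  for (nm in names(motifs)) {
    expect_identical(back[[nm]]$motif_id, motifs[[nm]]$motif_id)
    expect_identical(back[[nm]]$width, motifs[[nm]]$width)
    expect_lt(max(abs(back[[nm]]$matrix - motifs[[nm]]$matrix)), 1e-5)
  }
})

test_that("one_hot_pwm and consensus are inverse; revcomp_pwm reverses", {
  s <- "ACGTTGCA"
  p <- one_hot_pwm("X", s)
  expect_identical(consensus(p)$consensus, s)
  rc <- revcomp_pwm(p)
  expect_identical(consensus(rc)$consensus, "TGCAACGT")
  ## double reverse complement restores the original
  expect_equal(revcomp_pwm(rc)$matrix, p$matrix)
})

test_that("motif_pwm validates its matrix", {
  bad <- matrix(c(0.5, 0.5, 0.5, 0.5), nrow = 1,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(motif_pwm("B", bad))
})
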