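test_that("find_palindromes handles canonical cases", {
  ## GAATTC is its own reverse complement: the whole 6-mer pairs with
  ## the whole 6-mer (half length 6), and GAA pairs with TTC at k = 3
  m <- find_palindromes("GAATTC", "GAATTC", 6)
  expect_gt(nrow(m), 0)
  expect_identical(max(m$k), 6L)
  expect_true(any(m$k == 3 & m$half_a == "GAA" & m$half_b == "TTC"))
  ## every reported palindrome really is one
  rc_self <- function(s) {
    r <- vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
                function(ch) paste(rev(ch), collapse = ""), character(1))
    s == r
  }
  expect_true(all(rc_self(m$palindrome)))
  ## AT-free strings over {A, C} can never pair
  expect_identical(nrow(find_palindromes("ACCACA", "CCAACC", 6)), 0L)
  expect_error(find_palindromes("ACGT", "ACGT", 5), "even")
})

test_that("build_coop_network labels edges and counts degrees", {
  tfs <- data.frame(
    tf_id = c("T1", "T2", "T3"),
    family = c("F1", "F1", "F2"),
    consensus = c("AAAGGG", "CCCTTT", "ACACAC"),
    stringsAsFactors = FALSE)
  net <- build_coop_network(tfs, min_len = 6, include_self = TRUE)
  ## AAAGGG + CCCTTT: GGG/CCC (and more) pair; ACACAC pairs with nobody
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$tf_a, "T1")
  expect_identical(net$edges$tf_b, "T2")
  expect_true(net$edges$within_family)
  expect_false("T3" %in% c(net$edges$tf_a, net$edges$tf_b))
  deg <- net$family_degrees
  expect_identical(deg$mean_within_degree[deg$family == "F1"], 1)
  expect_identical(deg$mean_cross_degree[deg$family == "F1"], 0)
})

test_that("self-pairs appear as self-loops when requested", {
  tfs <- data.frame(tf_id = "T1", family = "F1",
                    consensus = "AAAGAATTCAAA", stringsAsFactors = FALSE)
  with_self <- build_coop_network(tfs, include_self = TRUE)
  expect_identical(nrow(with_self$edges), 1L)
  expect_identical(with_self$edges$tf_a, with_self$edges$tf_b)
  without <- build_coop_network(tfs, include_self = FALSE)
  expect_identical(nrow(without$edges), 0L)
})
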