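#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree hclust as.dist prcomp sd setNames runif rnorm
#' @importFrom utils read.delim write.table head tail
#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## reverse complement for plain character vectors (per-element)
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    bad <- !ch %in% names(COMPLEMENT)
    if (any(bad)) stop("non-ACGTN character in sequence: ", ch[bad][1])
    paste(COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## all substrings of length k (in order of offset)
kmers <- function(s, k) {
  n <- nchar(s)
  if (k > n) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

## check a DNA string is strictly ACGT
assert_acgt <- function(s, what = "sequence") {
  if (grepl("[^ACGT]", s)) {
    stop(what, " contains characters outside {A,C,G,T}: ", s)
  }
  invisible(s)
}

## sample standard deviation / mean
cv_sd_over_mean <- function(x) stats::sd(x) / mean(x)

## deterministic TSV writer (fixed conventions so outputs are byte-stable)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

## format numbers without scientific notation, trailing-zero trimmed
fmt_num <- function(x, digits = 6) {
  formatC(x, format = "f", digits = digits)
}

## standard genetic code on DNA codons
GENETIC_CODE_DNA <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), chartr("U", "T", names(gc)))
}

translate_cds <- function(cds) {
  assert_acgt(cds, "CDS")
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE_DNA[cods]
  paste(aa, collapse = "")
}

translate_codon <- function(codon) GENETIC_CODE_DNA[[codon]]

is_stop_codon <- function(codon) GENETIC_CODE_DNA[[codon]] == "*"

## intervals given as data.frame(start, end); total bp covered
interval_bp <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0L)
  sum(iv$end - iv$start + 1L)
}

## sorted, non-overlapping check
check_intervals <- function(iv, what = "intervals") {
  if (is.null(iv) || nrow(iv) == 0) return(invisible(TRUE))
  if (any(iv$start > iv$end)) stop(what, ": start > end")
  if (nrow(iv) > 1) {
    o <- order(iv$start)
    if (!identical(o, seq_len(nrow(iv)))) stop(what, ": not sorted")
    if (any(iv$start[-1] <= iv$end[-nrow(iv)])) stop(what, ": overlapping")
  }
  invisible(TRUE)
}
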