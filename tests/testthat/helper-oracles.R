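## Independent brute-force oracles used by the test suite.  Each one
## re-derives the quantity under test from first principles, sharing no
## code with the package implementation.

## reverse complement of each string in a character vector, computed
## locally (complement table + explicit character reversal)
oracle_revcomp <- function(xs) {
  vapply(strsplit(chartr("ACGT", "TGCA", xs), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## all-substring-pairs palindrome oracle: every (offset_a, offset_b, k)
## with k >= min_len/2 such that the length-k substring of a equals the
## reverse complement of the length-k substring of b
oracle_palindromes <- function(a, b, min_len = 6) {
  kmin <- min_len %/% 2
  na <- nchar(a); nb <- nchar(b)
  rows <- list()
  k <- kmin
  while (k <= min(na, nb)) {
    sa <- substring(a, 1:(na - k + 1), k:na)
    sb <- substring(b, 1:(nb - k + 1), k:nb)
    eq <- outer(sa, oracle_revcomp(sb), "==")
    hit <- which(eq, arr.ind = TRUE)
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        offset_a = as.integer(hit[, 1]), offset_b = as.integer(hit[, 2]),
        k = k)
    }
    k <- k + 1L
  }
  if (!length(rows)) {
    return(data.frame(offset_a = integer(), offset_b = integer(),
                      k = integer()))
  }
  do.call(rbind, rows)
}

## exhaustive window/merge clustering oracle over a plain gene table
## (gene_id, chrom, start, family, is_tf).  Returns member sets plus
## kinds and window spans, and the singlet gene ids.
oracle_clusters <- function(genes, window_bp, max_gap = 0) {
  tf <- genes[genes$is_tf, , drop = FALSE]
  tf$window <- (tf$start - 1L) %/% as.integer(window_bp)
  singlets <- character(0)
  clusters <- list()
  for (ch in sort(unique(tf$chrom))) {
    sub <- tf[tf$chrom == ch, , drop = FALSE]
    for (w in sort(unique(sub$window))) {
      g <- sub$gene_id[sub$window == w]
      if (length(g) == 1) singlets <- c(singlets, g)
    }
    wins <- sort(unique(sub$window[duplicated(sub$window) |
                                     duplicated(sub$window, fromLast = TRUE)]))
    if (!length(wins)) next
    ## merge graph: an edge joins two successive primary windows when
    ## their gap is <= max_gap and THEIR OWN families intersect (the
    ## accumulated group's family union plays no role); clusters are
    ## the connected components
    lab <- seq_along(wins)
    if (length(wins) > 1) {
      for (i in 2:length(wins)) {
        fa <- unique(sub$family[sub$window == wins[i - 1]])
        fb <- unique(sub$family[sub$window == wins[i]])
        if (wins[i] - wins[i - 1] <= max_gap + 1 &&
            length(intersect(fa, fb)) > 0) {
          lab[lab == lab[i]] <- lab[i - 1]
        }
      }
    }
    for (l in unique(lab)) {
      grp <- wins[lab == l]
      mem <- sub$gene_id[sub$window %in% grp]
      clusters[[length(clusters) + 1L]] <- list(
        chrom = ch,
        members = sort(mem),
        families = sort(unique(sub$family[sub$window %in% grp])),
        kind = if (length(grp) > 1) "merged" else "primary",
        span_start = min(grp) * as.integer(window_bp) + 1L,
        span_end = (max(grp) + 1L) * as.integer(window_bp))
    }
  }
  list(clusters = clusters, singlets = sort(singlets))
}

## triple-loop topological overlap oracle
oracle_tom <- function(mat, beta) {
  a <- abs(cor(t(mat)))^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

## exhaustive null distribution of an integer-scaled score matrix:
## enumerate every length-L word, sum its per-column scores, weight by
## the background.  Returns P(score = s) aggregated by score.
oracle_null <- function(int_scores, background) {
  L <- nrow(int_scores)
  grid <- expand.grid(rep(list(1:4), L))
  score <- integer(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (p in seq_len(L)) {
    score <- score + int_scores[p, grid[[p]]]
    prob <- prob * background[grid[[p]]]
  }
  agg <- tapply(prob, score, sum)
  list(scores = as.numeric(names(agg)), probs = as.numeric(agg))
}

## pathway-enumeration NG86 difference-count oracle for one codon pair,
## using Biostrings' genetic code as the independent translation source.
## Pathways through an intermediate stop codon are dropped unless every
## pathway passes through one.
oracle_codon_diffs <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  names(gc_tab) <- chartr("U", "T", names(gc_tab))
  aa <- function(codon) unname(gc_tab[codon])
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(pos) == 1) matrix(pos, 1) else {
    pm <- as.matrix(expand.grid(rep(list(seq_along(pos)), length(pos))))
    pm <- pm[apply(pm, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
    matrix(pos[pm], nrow = nrow(pm))
  }
  res <- apply(perms, 1, function(ord) {
    cur <- c1; syn <- 0; nonsyn <- 0; stopped <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substring(c2, p, p)
      if (aa(cur) == aa(nxt)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      if (aa(nxt) == "*" && nxt != c2) stopped <- TRUE
      cur <- nxt
    }
    c(syn, nonsyn, stopped)
  })
  ok <- res[3, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(syn = mean(res[1, ok]), nonsyn = mean(res[2, ok]))
}

## random DNA string helper for tests
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
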