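## FIMO-style PWM scanning of promoter sequences with an exact null
## score distribution computed by dynamic programming.

## Integer-scaled log-odds score matrix.  Probabilities get a pseudocount
## and renormalization before log2 odds vs the background; scores are
## rounded to 1e-3 granularity (stored as integers x1000) so the null
## distribution is exact on the same grid as the observed scores.
scaled_score_matrix <- function(pwm, pseudocount = 1e-3) {
  p <- (pwm$matrix + pseudocount) / (1 + 4 * pseudocount)
  b <- pwm$background
  s <- log2(sweep(p, 2, b, "/"))
  round(s * 1000)
}

## Exact null distribution of the integer-scaled score under the
## background model.  Returns list(scores = integer vector, probs).
pwm_null_distribution <- function(int_scores, background) {
  dist <- c(1)   # P(score == cur_lo) over zero positions
  cur_lo <- 0L
  for (i in seq_len(nrow(int_scores))) {
    row <- int_scores[i, ]
    new_lo <- cur_lo + min(row)
    new_hi <- cur_lo + length(dist) - 1L + max(row)
    new <- numeric(new_hi - new_lo + 1)
    for (j in 1:4) {
      sh <- cur_lo + row[j] - new_lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[j]
    }
    dist <- new
    cur_lo <- new_lo
  }
  list(scores = seq.int(cur_lo, cur_lo + length(dist) - 1L), probs = dist)
}

## P(null >= s) for each s, from a null distribution
null_pvalue <- function(null, s) {
  tail_p <- rev(cumsum(rev(null$probs)))
  idx <- s - null$scores[1] + 1L
  out <- numeric(length(s))
  out[idx <= 0] <- 1
  inr <- idx > 0 & idx <= length(tail_p)
  out[inr] <- tail_p[idx[inr]]
  out[idx > length(tail_p)] <- 0
  out
}

## score all offsets of an integer score matrix along an encoded sequence
## (x: integer vector in 1..4); returns integer vector of window sums
score_offsets <- function(int_scores, x) {
  L <- nrow(int_scores)
  n <- length(x)
  if (n < L) return(integer(0))
  n_off <- n - L + 1L
  tot <- integer(n_off)
  for (j in seq_len(L)) {
    tot <- tot + int_scores[j, x[seq.int(j, j + n_off - 1L)]]
  }
  tot
}

encode_dna <- function(seq) {
  ch <- chars(seq)
  idx <- match(ch, DNA_BASES)
  if (anyNA(idx)) idx[is.na(idx)] <- NA_integer_
  idx
}

#' Scan promoter sequences with a PWM
#'
#' Scores every offset on both strands of each promoter with the
#' log-odds of the pseudocount-regularized PWM against the background,
#' and reports matches whose p-value (from the exact null score
#' distribution, computed by dynamic programming on a 1e-3 score grid)
#' is at most `p_max`.
#'
#' Coordinates are reported as 1-based distances upstream of the TSS:
#' `start_upstream` is the 5'-most (far) edge, `end_upstream` the
#' 3'-most (near) edge, so `start_upstream >= end_upstream` and
#' `start_upstream - end_upstream + 1` equals the motif width.
#'
#' @param motif a [motif_pwm()].
#' @param promoter_set data frame from [extract_promoters()] (columns
#'   `gene_id`, `seq`, `length`), or any data frame with those columns.
#' @param p_max p-value threshold (default 1e-4).
#' @param pseudocount added to PWM probabilities before log-odds.
#' @return data frame with columns gene_id, motif_id, start_upstream,
#'   end_upstream, strand, score, p_value.
#' @export
pwm_scan <- function(motif, promoter_set, p_max = 1e-4, pseudocount = 1e-3) {
  stopifnot(is(motif, "motif_pwm"))
  fw <- scaled_score_matrix(motif, pseudocount)
  rc <- scaled_score_matrix(revcomp_pwm(motif), pseudocount)
  null_fw <- pwm_null_distribution(fw, motif$background)
  null_rc <- pwm_null_distribution(rc, motif$background)
  L <- motif$width
  res <- list()
  for (i in seq_len(nrow(promoter_set))) {
    seq <- promoter_set$seq[i]
    n <- nchar(seq)
    if (n < L) next
    x <- encode_dna(seq)
    if (anyNA(x)) next  # ambiguous bases: skip promoter
    for (str in c("+", "-")) {
      m <- if (str == "+") fw else rc
      null <- if (str == "+") null_fw else null_rc
      sc <- score_offsets(m, x)
      pv <- null_pvalue(null, sc)
      keep <- which(pv <= p_max)
      if (!length(keep)) next
      ## offset o occupies promoter positions [o, o+L-1];
      ## promoter position j lies (n - j + 1) bp upstream of the TSS
      res[[length(res) + 1L]] <- data.frame(
        gene_id = promoter_set$gene_id[i],
        motif_id = motif$motif_id,
        start_upstream = n - keep + 1L,
        end_upstream = n - (keep + L - 1L) + 1L,
        strand = str,
        score = sc[keep] / 1000,
        p_value = pv[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(gene_id = character(), motif_id = character(),
                      start_upstream = integer(), end_upstream = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$gene_id, -out$start_upstream, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan a set of motifs over promoters
#'
#' Convenience wrapper applying [pwm_scan()] for each motif and binding
#' the results.
#'
#' @param motifs list of [motif_pwm()] objects.
#' @inheritParams pwm_scan
#' @return data frame as in [pwm_scan()].
#' @export
scan_motifs <- function(motifs, promoter_set, p_max = 1e-4, pseudocount = 1e-3) {
  do.call(rbind, c(lapply(motifs, pwm_scan, promoter_set = promoter_set,
                          p_max = p_max, pseudocount = pseudocount),
                   list(make.row.names = FALSE)))
}
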