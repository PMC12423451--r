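## Best-hit CDS homology for motif transfer: ungapped local alignment
## (+1 match / -2 mismatch) with Karlin-Altschul e-values.

KA_LAMBDA <- 1.33
KA_K <- 0.621

## best ungapped local alignment score between two DNA strings:
## maximum-sum run along every diagonal (Kadane), +1/-2 scoring.
ungapped_local_score <- function(a, b) {
  xa <- encode_dna(a)
  xb <- encode_dna(b)
  if (anyNA(xa) || anyNA(xb)) stop("sequence with non-ACGT characters")
  na <- length(xa); nb <- length(xb)
  best <- 0L
  for (d in seq.int(-(na - 1L), nb - 1L)) {
    if (d >= 0) { ia <- 1L; ib <- d + 1L } else { ia <- 1L - d; ib <- 1L }
    len <- min(na - ia + 1L, nb - ib + 1L)
    sc <- ifelse(xa[seq.int(ia, length.out = len)] ==
                 xb[seq.int(ib, length.out = len)], 1L, -2L)
    cs <- cumsum(sc)
    run <- cs - cummin(c(0L, cs[-len]))
    m <- max(run)
    if (m > best) best <- m
  }
  best
}

## Karlin-Altschul e-value for raw score S with search space m x n
ka_evalue <- function(S, m, n, lambda = KA_LAMBDA, K = KA_K) {
  K * m * n * exp(-lambda * S)
}

#' Transfer reference motifs to query TFs by best-hit CDS homology
#'
#' Each query CDS is compared against every reference CDS that carries a
#' motif, using an ungapped local aligner (match +1, mismatch -2); raw
#' scores are converted to e-values with the Karlin-Altschul formula
#' `E = K m n exp(-lambda S)` (lambda = 1.33, K = 0.621, the standard
#' parameters for +1/-2 nucleotide scoring).  The reference with the
#' lowest e-value wins when it passes `e_max`; ties are broken by
#' higher raw score, then lexicographically smaller reference id.
#'
#' A precomputed tabular hit set (`hits` with columns query, subject,
#' score, e_value) can be supplied to bypass the internal aligner.
#'
#' @param query_cds named character vector (or FASTA path) of query CDS.
#' @param reference_cds named character vector (or FASTA path) of
#'   reference CDS.
#' @param ref_motif_map data frame with columns `tf_id`, `motif_id`
#'   mapping reference TFs to their motif; references absent from the
#'   map are excluded from candidacy.
#' @param e_max e-value threshold (default 0.001).
#' @param hits optional precomputed data frame (query, subject, score,
#'   e_value) replacing the internal aligner.
#' @return data frame with one row per assigned query: `query_id`,
#'   `subject_id`, `motif_id`, `score`, `bit_score`, `e_value`.
#' @export
best_hit_assign <- function(query_cds, reference_cds, ref_motif_map,
                            e_max = 0.001, hits = NULL) {
  read_seqs <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      ss <- Biostrings::readDNAStringSet(x)
      stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
    } else x
  }
  query_cds <- read_seqs(query_cds)
  reference_cds <- read_seqs(reference_cds)
  motif_of <- stats::setNames(as.character(ref_motif_map$motif_id),
                              ref_motif_map$tf_id)
  cand <- intersect(names(reference_cds), names(motif_of))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      motif_id = character(), score = numeric(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(query_cds) || !length(cand)) return(empty)

  if (is.null(hits)) {
    rows <- list()
    for (q in names(query_cds)) {
      for (s in sort(cand)) {
        S <- ungapped_local_score(query_cds[[q]], reference_cds[[s]])
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, subject = s, score = S,
          e_value = ka_evalue(S, nchar(query_cds[[q]]),
                              nchar(reference_cds[[s]])),
          stringsAsFactors = FALSE)
      }
    }
    hits <- do.call(rbind, rows)
  } else {
    hits <- hits[hits$subject %in% cand, , drop = FALSE]
  }
  hits <- hits[hits$e_value <= e_max, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  out <- do.call(rbind, lapply(split(hits, hits$query), function(h) {
    h <- h[order(h$e_value, -h$score, h$subject), , drop = FALSE]
    h[1, , drop = FALSE]
  }))
  data.frame(query_id = out$query,
             subject_id = out$subject,
             motif_id = unname(motif_of[out$subject]),
             score = out$score,
             bit_score = (KA_LAMBDA * out$score - log(KA_K)) / log(2),
             e_value = out$e_value,
             row.names = NULL, stringsAsFactors = FALSE)
}
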