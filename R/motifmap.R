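## Promoter extraction, motif-hit summaries and self-regulation.

#' Extract promoter sequences (upstream of the TSS, coding strand)
#'
#' For a plus-strand gene the promoter is the genomic interval
#' `[start - length, start - 1]`; for a minus-strand gene it is
#' `[end + 1, end + length]` reverse-complemented, so the returned
#' sequence always reads 5' to 3' towards the TSS on the coding strand.
#' Promoters are truncated at chromosome bounds and the actual length
#' recorded.
#'
#' @param catalog a `tf_catalog`.
#' @param length promoter length in bp (default 500).
#' @param genes optional character vector restricting to these gene ids.
#' @return data frame: gene_id, chrom, strand, tss, promoter_start,
#'   promoter_end (genomic, forward coordinates), length, truncated, seq.
#' @export
extract_promoters <- function(catalog, length = 500, genes = NULL) {
  g <- catalog$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, , drop = FALSE]
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    chrlen <- catalog$chrom_lengths[[g$chrom[i]]]
    if (g$strand[i] == "+") {
      tss <- g$start[i]
      p_end <- tss - 1L
      p_start <- max(1L, tss - as.integer(length))
      if (p_end < p_start) {
        warning("gene ", g$gene_id[i], ": no upstream sequence (promoter empty)")
        seq <- ""
        p_start <- NA_integer_; p_end <- NA_integer_
      } else {
        seq <- as.character(Biostrings::subseq(catalog$genome[[g$chrom[i]]],
                                               p_start, p_end))
      }
    } else {
      tss <- g$end[i]
      p_start <- tss + 1L
      p_end <- min(chrlen, tss + as.integer(length))
      if (p_end < p_start) {
        warning("gene ", g$gene_id[i], ": no upstream sequence (promoter empty)")
        seq <- ""
        p_start <- NA_integer_; p_end <- NA_integer_
      } else {
        seq <- revcomp(as.character(
          Biostrings::subseq(catalog$genome[[g$chrom[i]]], p_start, p_end)))
      }
    }
    rows[[i]] <- data.frame(
      gene_id = g$gene_id[i], chrom = g$chrom[i], strand = g$strand[i],
      tss = tss, promoter_start = p_start, promoter_end = p_end,
      length = nchar(seq), truncated = nchar(seq) < length,
      seq = seq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-family motif-hit totals in SG versus TF promoters
#'
#' For each TF family, the total number of occurrences of that family's
#' assigned motifs in structural-gene (SG) promoters and in TF
#' promoters, plus the per-motif averages.
#'
#' @param hits data frame of motif hits (from [pwm_scan()] /
#'   [scan_motifs()]) over both gene classes.
#' @param catalog a `tf_catalog` (provides gene class and family).
#' @param assignment data frame from [best_hit_assign()] mapping query
#'   TFs to motifs.
#' @return data frame: family, n_motifs, sg_hits, tf_hits,
#'   sg_avg_per_motif, tf_avg_per_motif.  Families with no assigned
#'   motif are omitted.
#' @export
distribution_summary <- function(hits, catalog, assignment) {
  fam_of <- stats::setNames(catalog$genes$family, catalog$genes$gene_id)
  is_tf <- stats::setNames(catalog$genes$is_tf, catalog$genes$gene_id)
  ## family of each motif = families of the TFs it was assigned to
  asg <- assignment
  asg$family <- unname(fam_of[asg$query_id])
  fams <- sort(unique(asg$family))
  out <- lapply(fams, function(f) {
    mots <- unique(asg$motif_id[asg$family == f])
    h <- hits[hits$motif_id %in% mots, , drop = FALSE]
    sg <- sum(!is_tf[h$gene_id], na.rm = TRUE)
    tf <- sum(is_tf[h$gene_id], na.rm = TRUE)
    data.frame(family = f, n_motifs = length(mots),
               sg_hits = sg, tf_hits = tf,
               sg_avg_per_motif = sg / length(mots),
               tf_avg_per_motif = tf / length(mots),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(
    family = character(), n_motifs = integer(), sg_hits = integer(),
    tf_hits = integer(), sg_avg_per_motif = numeric(),
    tf_avg_per_motif = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Detect self-regulating TFs
#'
#' A TF is flagged as self-regulating when a hit of its own assigned
#' motif lies in its own promoter.
#'
#' @param hits data frame of motif hits over TF promoters.
#' @param assignment data frame from [best_hit_assign()].
#' @return data frame: tf_id, motif_id, start_upstream, end_upstream,
#'   strand (one row per own-promoter hit).
#' @export
detect_self_regulation <- function(hits, assignment) {
  own <- merge(hits, assignment[, c("query_id", "motif_id")],
               by.x = c("gene_id", "motif_id"),
               by.y = c("query_id", "motif_id"))
  if (!nrow(own)) {
    return(data.frame(tf_id = character(), motif_id = character(),
                      start_upstream = integer(), end_upstream = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(tf_id = own$gene_id, motif_id = own$motif_id,
                    start_upstream = own$start_upstream,
                    end_upstream = own$end_upstream,
                    strand = own$strand, stringsAsFactors = FALSE)
  out <- out[order(out$tf_id, -out$start_upstream), ]
  rownames(out) <- NULL
  out
}
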