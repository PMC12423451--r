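## TF catalog: gene models + family labels + sequences, gene-structure
## statistics, and chromosomal TF cluster detection.

#' Load a TF catalog from annotation, genome and family labels
#'
#' Builds gene models (exon/CDS/UTR interval lists, strand-aware) from a
#' GFF3 file, attaches TF family labels, splices and translates each CDS
#' (standard genetic code, trailing stop trimmed).  Genes without a
#' family label are retained as structural genes (family `"SG"`).
#'
#' @param gff3 path to a GFF3 file with gene/mRNA/exon/CDS/UTR features.
#' @param genome_fasta path to the genome FASTA (or a `DNAStringSet`).
#' @param family_table path to a TSV with columns `gene_id`, `family`,
#'   or an equivalent data frame.  May be `NULL` (all genes become SG).
#' @return an object of class `tf_catalog`: list with `genes` (data
#'   frame gene_id, family, is_tf, chrom, strand, start, end), `parts`
#'   (per-gene interval lists), `genome`, `chrom_lengths`, `cds_seq`,
#'   `protein`.
#' @export
load_catalog <- function(gff3, genome_fasta, family_table = NULL) {
  genome <- if (is(genome_fasta, "DNAStringSet")) genome_fasta
            else Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  gr <- rtracklayer::import(gff3)
  type <- as.character(gr$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chrom %in% names(genome))) {
    stop("GFF3 references unknown chromosome(s): ",
         paste(setdiff(unique(chrom), names(genome)), collapse = ", "))
  }
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type == "mRNA")
  mrna2gene <- stats::setNames(parents[mrna_idx], ids[mrna_idx])

  fam <- NULL
  if (!is.null(family_table)) {
    ft <- if (is.data.frame(family_table)) family_table else read_tsv(family_table)
    fam <- stats::setNames(as.character(ft$family), ft$gene_id)
  }

  genes <- data.frame(
    gene_id = ids[gene_idx],
    chrom = chrom[gene_idx],
    strand = as.character(GenomicRanges::strand(gr))[gene_idx],
    start = GenomicRanges::start(gr)[gene_idx],
    end = GenomicRanges::end(gr)[gene_idx],
    stringsAsFactors = FALSE)
  genes$family <- if (is.null(fam)) NA_character_ else unname(fam[genes$gene_id])
  genes$family[is.na(genes$family)] <- "SG"
  genes$is_tf <- genes$family != "SG"
  genes <- genes[order(genes$chrom, genes$start),
                 c("gene_id", "family", "is_tf", "chrom", "strand",
                   "start", "end")]
  rownames(genes) <- NULL

  ## per-gene parts (genomic coordinates, sorted)
  part_types <- c(exons = "exon", cds = "CDS",
                  utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  parts <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  part_rows <- which(type %in% part_types)
  part_gene <- mrna2gene[parents[part_rows]]
  for (g in genes$gene_id) parts[[g]] <- list(
    exons = data.frame(start = integer(), end = integer()),
    cds = data.frame(start = integer(), end = integer()),
    utr5 = data.frame(start = integer(), end = integer()),
    utr3 = data.frame(start = integer(), end = integer()))
  for (k in seq_along(part_rows)) {
    r <- part_rows[k]
    g <- part_gene[k]
    if (is.na(g) || !g %in% names(parts)) next
    slot <- names(part_types)[match(type[r], part_types)]
    parts[[g]][[slot]] <- rbind(parts[[g]][[slot]],
      data.frame(start = GenomicRanges::start(gr)[r],
                 end = GenomicRanges::end(gr)[r]))
  }
  for (g in genes$gene_id) {
    for (slot in names(part_types)) {
      iv <- parts[[g]][[slot]]
      iv <- iv[order(iv$start), , drop = FALSE]
      rownames(iv) <- NULL
      check_intervals(iv, paste0(g, " ", slot))
      parts[[g]][[slot]] <- iv
    }
  }

  ## splice CDS (coding strand) and translate
  cds_seq <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  protein <- cds_seq
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    iv <- parts[[g]]$cds
    if (nrow(iv) == 0) next
    pieces <- vapply(seq_len(nrow(iv)), function(j)
      as.character(Biostrings::subseq(genome[[genes$chrom[i]]],
                                      iv$start[j], iv$end[j])),
      character(1))
    s <- paste(pieces, collapse = "")
    if (genes$strand[i] == "-") s <- revcomp(s)
    cds_seq[g] <- s
    if (nchar(s) %% 3 != 0) {
      warning("gene ", g, ": CDS length not divisible by 3; protein skipped")
      next
    }
    aa <- translate_cds(s)
    protein[g] <- sub("\\*$", "", aa)
  }

  structure(list(genes = genes, parts = parts, genome = genome,
                 chrom_lengths = stats::setNames(Biostrings::width(genome),
                                                 names(genome)),
                 cds_seq = cds_seq, protein = protein),
            class = "tf_catalog")
}

#' @export
print.tf_catalog <- function(x, ...) {
  cat("<tf_catalog> ", nrow(x$genes), " genes (",
      sum(x$genes$is_tf), " TFs) on ", length(x$genome),
      " sequences\n", sep = "")
  invisible(x)
}

## intron intervals of a gene (gaps between sorted exons)
gene_introns <- function(catalog, gene_id) {
  ex <- catalog$parts[[gene_id]]$exons
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Per-gene and per-family gene-structure statistics
#'
#' Gene length (genomic span), exon count, and GC fraction over the
#' genomic span `[start, end]`; ambiguous bases are excluded from both
#' the numerator and the denominator of the GC fraction.
#'
#' @param catalog a `tf_catalog`.
#' @return list with `per_gene` (gene_id, family, gene_length_bp,
#'   exon_count, gc_fraction) and `per_family` (mean and CV of each
#'   statistic; CV only for families with >= 2 members).
#' @export
gene_structure_stats <- function(catalog) {
  genes <- catalog$genes
  gc <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- as.character(Biostrings::subseq(catalog$genome[[genes$chrom[i]]],
                                         genes$start[i], genes$end[i]))
    if (!nchar(s)) stop("gene ", genes$gene_id[i], ": empty sequence")
    tab <- table(factor(chars(s), levels = c(DNA_BASES, "N")))
    denom <- sum(tab[DNA_BASES])
    gc[i] <- if (denom == 0) NA_real_ else (tab[["G"]] + tab[["C"]]) / denom
  }
  per_gene <- data.frame(
    gene_id = genes$gene_id, family = genes$family,
    gene_length_bp = genes$end - genes$start + 1L,
    exon_count = vapply(genes$gene_id, function(g)
      max(1L, nrow(catalog$parts[[g]]$exons)), integer(1)),
    gc_fraction = gc, stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL

  fams <- sort(unique(per_gene$family))
  summ <- function(x) c(mean = mean(x),
                        cv = if (length(x) >= 2) cv_sd_over_mean(x) else NA_real_)
  per_family <- do.call(rbind, lapply(fams, function(f) {
    sub <- per_gene[per_gene$family == f, ]
    data.frame(family = f, n_members = nrow(sub),
               t(c(length = summ(sub$gene_length_bp),
                   exons = summ(sub$exon_count),
                   gc = summ(sub$gc_fraction))),
               stringsAsFactors = FALSE)
  }))
  rownames(per_family) <- NULL
  list(per_gene = per_gene, per_family = per_family)
}

#' Detect TF clusters with a fixed nonoverlapping genomic window
#'
#' Each chromosome is tiled with consecutive windows of `window_bp`
#' anchored at coordinate 1; a TF belongs to the window containing its
#' start coordinate.  Windows holding >= 2 TFs are primary clusters;
#' primary clusters in consecutive windows of one chromosome that share
#' at least one TF family are merged, transitively, into merged
#' clusters.  Windows with a single TF yield singlets.
#'
#' @param catalog a `tf_catalog`.
#' @param window_bp window width in bp (default 250000).
#' @param max_gap maximal number of empty windows allowed between
#'   "adjacent" primary clusters when merging (default 0: consecutive
#'   window indices only).
#' @param chroms optional character vector restricting the analysis to
#'   placed chromosomes (unplaced contigs are excluded by omission).
#' @return a list of class `cluster_set`: `singlets` (gene ids),
#'   `clusters` data frame (cluster_id, chrom, kind, span_start,
#'   span_end, n_members, members, families, windows; members/families/
#'   windows are list columns).
#' @export
cluster_tfs <- function(catalog, window_bp = 250000, max_gap = 0,
                        chroms = NULL) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  tf <- catalog$genes[catalog$genes$is_tf, , drop = FALSE]
  if (!is.null(chroms)) tf <- tf[tf$chrom %in% chroms, , drop = FALSE]
  tf$window <- (tf$start - 1L) %/% as.integer(window_bp)
  singlets <- character(0)
  clusters <- list()
  for (ch in unique(tf$chrom)) {
    sub <- tf[tf$chrom == ch, , drop = FALSE]
    wins <- split(sub, sub$window)
    counts <- vapply(wins, nrow, integer(1))
    singlets <- c(singlets,
                  unlist(lapply(wins[counts == 1], function(w) w$gene_id),
                         use.names = FALSE))
    prim <- wins[counts >= 2]
    if (!length(prim)) next
    widx <- as.integer(names(prim))
    o <- order(widx)
    prim <- prim[o]; widx <- widx[o]
    ## union-find over primary clusters: merge runs of consecutive
    ## windows (gap <= max_gap) sharing >= 1 family, transitively
    grp <- seq_along(prim)
    find <- function(i) { i <- as.integer(i); while (grp[i] != i) i <- grp[i]; i }
    for (i in seq_along(prim)[-1]) {
      if (widx[i] - widx[i - 1] <= max_gap + 1 &&
          length(intersect(prim[[i]]$family, prim[[i - 1]]$family)) > 0) {
        grp[find(i)] <- find(i - 1)
      }
    }
    roots <- vapply(seq_along(prim), find, integer(1))
    for (r in unique(roots)) {
      members_idx <- which(roots == r)
      mem <- do.call(rbind, prim[members_idx])
      kind <- if (length(members_idx) >= 2) "merged" else "primary"
      w <- widx[members_idx]
      clusters[[length(clusters) + 1L]] <- data.frame(
        chrom = ch, kind = kind,
        span_start = min(w) * as.integer(window_bp) + 1L,
        span_end = (max(w) + 1L) * as.integer(window_bp),
        n_members = nrow(mem),
        members = I(list(mem$gene_id)),
        families = I(list(sort(unique(mem$family)))),
        windows = I(list(w)),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(chrom = character(), kind = character(),
               span_start = integer(), span_end = integer(),
               n_members = integer(), members = I(list()),
               families = I(list()), windows = I(list()),
               stringsAsFactors = FALSE)
  if (nrow(clusters)) {
    clusters <- clusters[order(clusters$chrom, clusters$span_start), ]
    clusters$cluster_id <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  } else clusters$cluster_id <- integer(0)
  structure(list(singlets = sort(singlets), clusters = clusters,
                 window_bp = window_bp, n_tf_placed = nrow(tf)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$singlets), " singlets, ",
      sum(x$clusters$kind == "primary"), " primary and ",
      sum(x$clusters$kind == "merged"), " merged clusters\n", sep = "")
  invisible(x)
}

#' Family and chromosome level summary of the TF catalog
#'
#' Per-chromosome TF counts, the Pearson correlation between TF count
#' and chromosome length, per-family member counts and mean/CV of gene
#' structure and protein statistics, and per-family cluster
#' participation.
#'
#' @param catalog a `tf_catalog`.
#' @param cluster_set optional `cluster_set` from [cluster_tfs()].
#' @return list with `per_chromosome`, `tf_length_pearson_r` (NA with a
#'   warning when < 3 chromosomes or zero variance), `per_family`.
#' @export
family_chrom_summary <- function(catalog, cluster_set = NULL) {
  tf <- catalog$genes[catalog$genes$is_tf, , drop = FALSE]
  chroms <- names(catalog$chrom_lengths)
  per_chrom <- data.frame(
    chrom = chroms,
    length_bp = unname(catalog$chrom_lengths),
    n_tf = vapply(chroms, function(ch) sum(tf$chrom == ch), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_chrom) <- NULL
  r <- NA_real_
  if (nrow(per_chrom) < 3) {
    warning("fewer than 3 chromosomes: TF-count vs length correlation omitted")
  } else if (stats::sd(per_chrom$n_tf) == 0 ||
             stats::sd(per_chrom$length_bp) == 0) {
    warning("zero variance: TF-count vs length correlation undefined")
  } else {
    r <- stats::cor(per_chrom$n_tf, per_chrom$length_bp)
  }

  gs <- gene_structure_stats(catalog)
  per_family <- gs$per_family[gs$per_family$family != "SG", , drop = FALSE]
  if (!is.null(cluster_set) && nrow(per_family)) {
    in_cluster <- unlist(cluster_set$clusters$members, use.names = FALSE)
    per_family$n_in_clusters <- vapply(per_family$family, function(f)
      sum(tf$gene_id[tf$family == f] %in% in_cluster), integer(1))
  }
  rownames(per_family) <- NULL
  list(per_chromosome = per_chrom, tf_length_pearson_r = r,
       per_family = per_family)
}
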