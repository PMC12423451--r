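## Variant classification by gene region and coding effect, per-scope
## variation rates, and NG86 Ka/Ks.

## coding-strand position of a genomic position within a gene's spliced
## CDS; NA when the position is not in the CDS
cds_position <- function(catalog, gene_id, pos) {
  iv <- catalog$parts[[gene_id]]$cds
  if (!nrow(iv)) return(NA_integer_)
  strand <- catalog$genes$strand[catalog$genes$gene_id == gene_id]
  off <- 0L
  if (strand == "+") {
    for (j in seq_len(nrow(iv))) {
      if (pos >= iv$start[j] && pos <= iv$end[j]) {
        return(off + pos - iv$start[j] + 1L)
      }
      off <- off + iv$end[j] - iv$start[j] + 1L
    }
  } else {
    for (j in rev(seq_len(nrow(iv)))) {
      if (pos >= iv$start[j] && pos <= iv$end[j]) {
        return(off + iv$end[j] - pos + 1L)
      }
      off <- off + iv$end[j] - iv$start[j] + 1L
    }
  }
  NA_integer_
}

in_intervals <- function(iv, pos) {
  nrow(iv) > 0 && any(pos >= iv$start & pos <= iv$end)
}

#' Annotate variants with gene region and coding effect
#'
#' Assigns each variant the region of the gene it falls in (precedence
#' CDS > UTR > intron within a gene; outside all genes: intergenic) and,
#' for single-nucleotide variants in CDS, the coding effect by codon
#' substitution under the standard genetic code, strand-aware.
#' Multi-nucleotide or indel alleles get effect `other`.  Multi-allelic
#' records must be split beforehand (one alt per record;
#' [read_vcf_records()] does this).
#'
#' @param vcf path to a VCF file, or a data frame with columns `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param catalog a `tf_catalog`.
#' @return data frame: chrom, pos, ref, alt, gene_id, region
#'   (CDS/UTR/intron/intergenic), effect (synonymous_SNV,
#'   nonsynonymous_SNV, other, not_applicable).
#' @export
annotate_variants <- function(vcf, catalog) {
  rec <- if (is.data.frame(vcf)) vcf else read_vcf_records(vcf)
  genes <- catalog$genes
  out <- rec[, c("chrom", "pos", "ref", "alt")]
  out$gene_id <- NA_character_
  out$region <- "intergenic"
  out$effect <- "not_applicable"
  for (i in seq_len(nrow(rec))) {
    pos <- rec$pos[i]
    hit_gene <- NA_character_; hit_region <- "intergenic"
    cand <- genes[genes$chrom == rec$chrom[i] &
                  genes$start <= pos & genes$end >= pos, , drop = FALSE]
    rank <- c(CDS = 1L, UTR = 2L, intron = 3L)
    best <- 4L
    for (g in cand$gene_id) {
      p <- catalog$parts[[g]]
      region <- if (in_intervals(p$cds, pos)) "CDS"
        else if (in_intervals(p$utr5, pos) || in_intervals(p$utr3, pos)) "UTR"
        else "intron"
      if (rank[[region]] < best) {
        best <- rank[[region]]; hit_gene <- g; hit_region <- region
      }
    }
    out$gene_id[i] <- hit_gene
    out$region[i] <- hit_region
    if (hit_region != "CDS") next
    if (nchar(rec$ref[i]) != 1 || nchar(rec$alt[i]) != 1) {
      out$effect[i] <- "other"
      next
    }
    ## verify the reference allele against the genome
    gref <- as.character(Biostrings::subseq(
      catalog$genome[[rec$chrom[i]]], pos, pos))
    if (gref != rec$ref[i]) {
      stop("ref allele mismatch at ", rec$chrom[i], ":", pos,
           " (VCF ", rec$ref[i], ", genome ", gref, ")")
    }
    strand <- genes$strand[genes$gene_id == hit_gene]
    cpos <- cds_position(catalog, hit_gene, pos)
    cds <- catalog$cds_seq[[hit_gene]]
    if (is.na(cpos) || is.na(cds) || nchar(cds) %% 3 != 0) {
      out$effect[i] <- "other"
      next
    }
    alt_coding <- if (strand == "+") rec$alt[i] else COMPLEMENT[[rec$alt[i]]]
    cod_i <- (cpos - 1L) %/% 3L
    within <- cpos - cod_i * 3L
    codon <- substring(cds, cod_i * 3L + 1L, cod_i * 3L + 3L)
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt_coding
    out$effect[i] <- if (translate_codon(codon) == translate_codon(alt_codon))
      "synonymous_SNV" else "nonsynonymous_SNV"
  }
  out
}

#' Read VCF records into a plain data frame
#'
#' Uses `vcfR` to parse; multi-allelic records are split into one
#' record per alternate allele.
#'
#' @param path path to a VCF (v4.x) file.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = a, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-project, per-region variation rates
#'
#' `rate = site count / (region length x sample count)`, computed per
#' region from annotated variant records.  Sites are unique positions.
#'
#' @param records data frame from [annotate_variants()].
#' @param region_lengths named numeric vector of total region lengths
#'   in bp (names among CDS, intron, UTR).
#' @param n_samples sample count of the project.
#' @return data frame: region, n_sites, region_length_bp, n_samples,
#'   rate.  Regions with zero length are omitted with a warning.
#' @export
project_region_rate <- function(records, region_lengths, n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  regions <- names(region_lengths)
  zero <- regions[region_lengths <= 0]
  if (length(zero)) {
    warning("zero-length region(s) omitted: ", paste(zero, collapse = ", "))
    regions <- setdiff(regions, zero)
  }
  out <- do.call(rbind, lapply(regions, function(rg) {
    sub <- records[records$region == rg, , drop = FALSE]
    n <- nrow(unique(sub[, c("chrom", "pos")]))
    data.frame(region = rg, n_sites = n,
               region_length_bp = unname(region_lengths[[rg]]),
               n_samples = n_samples,
               rate = n / (region_lengths[[rg]] * n_samples),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(
    region = character(), n_sites = integer(),
    region_length_bp = numeric(), n_samples = integer(), rate = numeric(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## total bp of a region over a set of genes
region_lengths_for <- function(catalog, gene_ids) {
  cds <- sum(vapply(gene_ids, function(g)
    interval_bp(catalog$parts[[g]]$cds), numeric(1)))
  utr <- sum(vapply(gene_ids, function(g)
    interval_bp(catalog$parts[[g]]$utr5) +
      interval_bp(catalog$parts[[g]]$utr3), numeric(1)))
  intr <- sum(vapply(gene_ids, function(g)
    interval_bp(gene_introns(catalog, g)), numeric(1)))
  c(CDS = cds, intron = intr, UTR = utr)
}

#' Total CDS/intron/UTR lengths over the TF genes of a catalog
#'
#' @param catalog a `tf_catalog`.
#' @param tf_only restrict to TF genes (default TRUE).
#' @return named numeric vector with elements CDS, intron, UTR.
#' @export
catalog_region_lengths <- function(catalog, tf_only = TRUE) {
  g <- catalog$genes
  if (tf_only) g <- g[g$is_tf, , drop = FALSE]
  region_lengths_for(catalog, g$gene_id)
}

#' Per-family, per-region variation rates
#'
#' `rate = site count / (region length x n_samples x members with the
#' region)`: the denominator length is the family total of that region
#' and members lacking the region (e.g. intronless genes) are excluded
#' from the member count.  Families with no member possessing a region
#' get no row for it.
#'
#' @param records data frame from [annotate_variants()].
#' @param catalog a `tf_catalog`.
#' @param n_samples pooled sample count (default 90).
#' @return data frame: family, region, n_sites, region_length_bp,
#'   n_members_with_region, n_samples, rate.
#' @export
family_region_rate <- function(records, catalog, n_samples = 90) {
  tf <- catalog$genes[catalog$genes$is_tf, , drop = FALSE]
  fams <- sort(unique(tf$family))
  rows <- list()
  for (f in fams) {
    gid <- tf$gene_id[tf$family == f]
    per_gene_len <- lapply(gid, function(g) region_lengths_for(catalog, g))
    for (rg in c("CDS", "intron", "UTR")) {
      lens <- vapply(per_gene_len, function(x) x[[rg]], numeric(1))
      members <- sum(lens > 0)
      if (members == 0) next
      tot_len <- sum(lens)
      sub <- records[records$region == rg & records$gene_id %in% gid, ,
                     drop = FALSE]
      n <- nrow(unique(sub[, c("chrom", "pos")]))
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, region = rg, n_sites = n,
        region_length_bp = tot_len, n_members_with_region = members,
        n_samples = n_samples,
        rate = n / (tot_len * n_samples * members),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(), region = character(),
               n_sites = integer(), region_length_bp = numeric(),
               n_members_with_region = integer(), n_samples = integer(),
               rate = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## ---- NG86 ----------------------------------------------------------

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

## synonymous site fraction of one codon: per position, the fraction of
## the three possible single-nucleotide changes that preserve the amino
## acid; changes creating a stop codon count as nonsynonymous.
codon_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    for (b in DNA_BASES) {
      if (b == substring(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (!is_stop_codon(alt) && translate_codon(alt) == aa) s <- s + 1 / 3
    }
  }
  s
}

## pathway-averaged synonymous / nonsynonymous difference counts for a
## codon pair; pathways through intermediate stop codons are excluded
## unless every pathway passes through one.
codon_pair_diffs <- function(c1, c2) {
  pos <- which(chars(c1) != chars(c2))
  d <- length(pos)
  if (d == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1) list(pos) else
    if (d == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  eval_path <- function(order) {
    cur <- c1
    syn <- 0; nonsyn <- 0; through_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substring(c2, p, p)
      if (translate_codon(cur) == translate_codon(nxt)) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      if (is_stop_codon(nxt) && nxt != c2) through_stop <- TRUE
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, through_stop = through_stop)
  }
  paths <- lapply(perms, eval_path)
  ok <- !vapply(paths, `[[`, logical(1), "through_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(syn = mean(vapply(paths[ok], `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(paths[ok], `[[`, numeric(1), "nonsyn")))
}

#' NG86 Ka/Ks between two aligned coding sequences
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions
#' averaged over the two sequences; pathway-averaged synonymous and
#' nonsynonymous difference counts for codons differing at multiple
#' positions (pathways through intermediate stop codons excluded when
#' any stop-free pathway exists); proportions converted to distances
#' with the Jukes-Cantor correction `d = -3/4 ln(1 - 4p/3)`.
#'
#' @param cds_a,cds_b gap-free coding sequences of equal length
#'   divisible by 3.
#' @return list of class `kaks_result`: `ka`, `ks`, `ratio` (NA when
#'   `ks` is 0 or a correction is undefined), `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `ps`, `pn`.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  assert_acgt(cds_a, "cds_a"); assert_acgt(cds_b, "cds_b")
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences differ in length")
  if (nchar(cds_a) %% 3 != 0) stop("length not divisible by 3")
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  syn_sites <- (sum(vapply(ca, codon_syn_sites, numeric(1))) +
                sum(vapply(cb, codon_syn_sites, numeric(1)))) / 2
  nonsyn_sites <- 3 * length(ca) - syn_sites
  diffs <- vapply(seq_along(ca), function(i)
    codon_pair_diffs(ca[i], cb[i]), numeric(2))
  syn_d <- sum(diffs["syn", ]); nonsyn_d <- sum(diffs["nonsyn", ])
  ps <- if (syn_sites > 0) syn_d / syn_sites else 0
  pn <- if (nonsyn_sites > 0) nonsyn_d / nonsyn_sites else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                 syn_diffs = syn_d, nonsyn_diffs = nonsyn_d,
                 ps = ps, pn = pn),
            class = "kaks_result")
}

#' Per-family mean Ka/Ks from annotated variants
#'
#' For each gene, all its CDS SNVs are applied to the reference CDS to
#' form an alternate CDS; `ng86_kaks(reference, alternate)` gives the
#' gene's ratio, and the family value is the mean over members with a
#' defined ratio (genes with no CDS SNV, or an undefined correction,
#' are excluded).
#'
#' @param records data frame from [annotate_variants()].
#' @param catalog a `tf_catalog`.
#' @return data frame: family, n_genes_with_ratio, mean_kaks.  Empty
#'   when no gene has a defined ratio.
#' @export
family_kaks_from_variants <- function(records, catalog) {
  tf <- catalog$genes[catalog$genes$is_tf, , drop = FALSE]
  snv <- records[records$region == "CDS" &
                 records$effect %in% c("synonymous_SNV", "nonsynonymous_SNV") &
                 !is.na(records$gene_id), , drop = FALSE]
  gene_ratio <- stats::setNames(rep(NA_real_, nrow(tf)), tf$gene_id)
  gene_ka <- gene_ratio
  for (g in unique(snv$gene_id)) {
    if (!g %in% tf$gene_id) next
    cds <- catalog$cds_seq[[g]]
    if (is.na(cds)) next
    strand <- tf$strand[tf$gene_id == g]
    alt_cds <- cds
    sub <- snv[snv$gene_id == g, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      cpos <- cds_position(catalog, g, sub$pos[i])
      if (is.na(cpos)) next
      a <- if (strand == "+") sub$alt[i] else COMPLEMENT[[sub$alt[i]]]
      substr(alt_cds, cpos, cpos) <- a
    }
    kk <- ng86_kaks(cds, alt_cds)
    ## a gene with only synonymous SNVs has Ka = 0: keep ratio 0
    gene_ratio[g] <- kk$ratio
    gene_ka[g] <- kk$ka
  }
  fams <- sort(unique(tf$family))
  rows <- lapply(fams, function(f) {
    r <- gene_ratio[tf$gene_id[tf$family == f]]
    r <- r[!is.na(r)]
    if (!length(r)) return(NULL)
    data.frame(family = f, n_genes_with_ratio = length(r),
               mean_kaks = mean(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    family = character(), n_genes_with_ratio = integer(),
    mean_kaks = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
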