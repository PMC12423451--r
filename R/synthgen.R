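## Synthetic data with machine-readable planted truth: genomes with
## clustered TF genes, motif libraries with planted palindromic
## half-site pairs and certified decoys, expression matrices with
## planted modules, and variant sets with planted per-region rates.

rand_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

non_stop_codons <- function() {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                            stringsAsFactors = FALSE), 1, paste, collapse = "")
  all3[vapply(all3, function(c) GENETIC_CODE_DNA[[c]] != "*", logical(1))]
}

## deterministic FASTA writer (70-column wrap)
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Genome simulation configuration
#'
#' @param n_chromosomes,chrom_length_bp number and length of chromosomes.
#' @param n_tf_genes,n_sg_genes TF and structural gene counts.
#' @param n_families number of TF families (labels `F1`, `F2`, ...).
#' @param cluster_spec data frame with columns `chrom` (1-based index),
#'   `window` (0-based 250-kb window index) and a list column
#'   `families` giving the family label of each planted member; each
#'   row is one planted primary-cluster window.  `NULL` plants none.
#' @param exon_count_range integer range for per-gene exon counts.
#' @param gc_target genomic GC fraction.
#' @param window_bp window width used for planting (must match the
#'   clustering window downstream).
#' @param seed integer seed; all draws flow from it.
#' @return list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_chromosomes = 3, chrom_length_bp = 2000000,
                              n_tf_genes = 24, n_sg_genes = 40,
                              n_families = 8, cluster_spec = NULL,
                              exon_count_range = c(1, 4), gc_target = 0.36,
                              window_bp = 250000, seed = 1) {
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0,1]")
  n_win <- chrom_length_bp %/% window_bp
  if (!is.null(cluster_spec)) {
    stopifnot(all(c("chrom", "window", "families") %in% names(cluster_spec)))
    if (any(cluster_spec$chrom < 1 | cluster_spec$chrom > n_chromosomes))
      stop("cluster_spec chromosome out of range")
    if (any(cluster_spec$window < 0 | cluster_spec$window >= n_win))
      stop("cluster_spec window index out of range")
    if (anyDuplicated(cluster_spec[, c("chrom", "window")]))
      stop("duplicate cluster_spec window")
    n_planted <- sum(vapply(cluster_spec$families, length, integer(1)))
    if (n_planted > n_tf_genes)
      stop("cluster_spec plants more TF genes than n_tf_genes")
    bad <- setdiff(unlist(cluster_spec$families),
                   paste0("F", seq_len(n_families)))
    if (length(bad)) stop("unknown family label(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 n_tf_genes = n_tf_genes, n_sg_genes = n_sg_genes,
                 n_families = n_families, cluster_spec = cluster_spec,
                 exon_count_range = exon_count_range,
                 gc_target = gc_target, window_bp = window_bp, seed = seed),
            class = "genome_sim_config")
}

## build one gene: transcript = 5'UTR + (ATG..stop) + 3'UTR split into
## exons with introns; returns local (gene-relative, forward-genomic)
## intervals plus the forward-genomic sequence and spliced CDS
build_gene <- function(cfg, strand) {
  n_cod <- sample(60:150, 1)
  cds <- paste0("ATG",
                paste(sample(non_stop_codons(), n_cod, replace = TRUE),
                      collapse = ""),
                "TAA")
  u5 <- rand_dna(sample(30:80, 1), cfg$gc_target)
  u3 <- rand_dna(sample(30:80, 1), cfg$gc_target)
  tx <- paste0(u5, cds, u3)
  tlen <- nchar(tx)
  E <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1)
  E <- min(E, tlen)
  cuts <- if (E > 1) sort(sample(seq_len(tlen - 1), E - 1)) else integer(0)
  ex_t_start <- c(1L, cuts + 1L)
  ex_t_end <- c(cuts, tlen)
  intr_len <- if (E > 1) sample(80:200, E - 1, replace = TRUE) else integer(0)
  ## transcript coord -> gene-local coord (forward, transcript order)
  shift <- c(0L, cumsum(intr_len))
  ex_g_start <- ex_t_start + shift
  ex_g_end <- ex_t_end + shift
  glen <- ex_g_end[E]
  ## assemble forward gene sequence (transcript orientation)
  pieces <- character(0)
  for (k in seq_len(E)) {
    pieces <- c(pieces, substring(tx, ex_t_start[k], ex_t_end[k]))
    if (k < E) pieces <- c(pieces, rand_dna(intr_len[k], cfg$gc_target))
  }
  gseq <- paste(pieces, collapse = "")
  stopifnot(nchar(gseq) == glen)
  ## feature intervals in transcript coords
  feats <- list(utr5 = c(1L, nchar(u5)),
                cds = c(nchar(u5) + 1L, nchar(u5) + nchar(cds)),
                utr3 = c(nchar(u5) + nchar(cds) + 1L, tlen))
  map_feature <- function(fr) {
    res <- list()
    for (k in seq_len(E)) {
      s <- max(fr[1], ex_t_start[k]); e <- min(fr[2], ex_t_end[k])
      if (s <= e) res[[length(res) + 1L]] <-
          c(s + shift[k], e + shift[k])
    }
    if (!length(res)) return(data.frame(start = integer(), end = integer()))
    m <- do.call(rbind, res)
    data.frame(start = m[, 1], end = m[, 2])
  }
  parts <- list(exons = data.frame(start = ex_g_start, end = ex_g_end),
                cds = map_feature(feats$cds),
                utr5 = if (nchar(u5)) map_feature(feats$utr5) else
                  data.frame(start = integer(), end = integer()),
                utr3 = if (nchar(u3)) map_feature(feats$utr3) else
                  data.frame(start = integer(), end = integer()))
  if (strand == "-") {
    gseq <- revcomp(gseq)
    flip <- function(iv) {
      if (!nrow(iv)) return(iv)
      out <- data.frame(start = glen - iv$end + 1L, end = glen - iv$start + 1L)
      out[order(out$start), , drop = FALSE]
    }
    parts <- lapply(parts, flip)
  }
  list(seq = gseq, length = glen, parts = parts, cds_seq = cds)
}

## independent application of the window-merge rule to the planted
## layout (used for cluster truth; not the production cluster_tfs)
derive_cluster_truth <- function(spec_rows) {
  truth <- list()
  for (ch in unique(spec_rows$chrom)) {
    sub <- spec_rows[spec_rows$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$window), , drop = FALSE]
    i <- 1
    while (i <= nrow(sub)) {
      members <- sub$members[[i]]
      fams <- sub$families[[i]]
      wins <- sub$window[i]
      j <- i + 1
      while (j <= nrow(sub) && sub$window[j] == sub$window[j - 1] + 1 &&
             length(intersect(fams_last <- sub$families[[j - 1]],
                              sub$families[[j]])) > 0) {
        members <- c(members, sub$members[[j]])
        fams <- union(fams, sub$families[[j]])
        wins <- c(wins, sub$window[j])
        j <- j + 1
      }
      truth[[length(truth) + 1L]] <- list(
        chrom = sub$chrom_name[i], windows = wins, members = members,
        families = sort(unique(fams)),
        kind = if (length(wins) > 1) "merged" else "primary")
      i <- j
    }
  }
  truth
}

#' Generate a synthetic genome with planted TF clusters
#'
#' Chromosome backgrounds are random sequence at the target GC; genes
#' (full exon/intron/UTR structure with a valid ORF) are written into
#' non-overlapping slots.  Planted cluster members go to the windows
#' given in `cluster_spec` (with uniform jitter inside per-member
#' slots); every remaining TF gene gets a window of its own so no
#' cluster beyond the planted ones can arise; SG genes fill any free
#' slot.
#'
#' @param cfg a [genome_sim_config()].
#' @param out_dir output directory (created).  Emits `genome.fa`,
#'   `annotation.gff3`, `families.tsv`, `truth_genome.json`.
#' @return list of class `genome_bundle`: `paths`, `genes`, `parts`,
#'   `genome` (named character), `cds_seq`, `truth` (planted clusters
#'   and per-gene windows), `cfg`.
#' @export
gen_genome <- function(cfg, out_dir) {
  stopifnot(is(cfg, "genome_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  W <- cfg$window_bp
  n_win <- cfg$chrom_length_bp %/% W
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  genome <- stats::setNames(
    vapply(chroms, function(ch) rand_dna(cfg$chrom_length_bp, cfg$gc_target),
           character(1)), chroms)

  ## assignment bookkeeping
  placements <- list()   # per gene: chrom, window, slot_count, slot
  spec_rows <- NULL
  tf_left <- cfg$n_tf_genes
  tf_id <- 0L
  next_tf_id <- function() { tf_id <<- tf_id + 1L
    sprintf("TF%04d", tf_id) }
  used_windows <- matrix(FALSE, nrow = cfg$n_chromosomes, ncol = n_win)

  if (!is.null(cfg$cluster_spec)) {
    spec_rows <- cfg$cluster_spec
    spec_rows$chrom_name <- chroms[spec_rows$chrom]
    spec_rows$members <- vector("list", nrow(spec_rows))
    for (r in seq_len(nrow(spec_rows))) {
      fams <- spec_rows$families[[r]]
      ids <- vapply(fams, function(f) next_tf_id(), character(1))
      spec_rows$members[[r]] <- unname(ids)
      used_windows[spec_rows$chrom[r], spec_rows$window[r] + 1L] <- TRUE
      for (k in seq_along(fams)) {
        placements[[ids[k]]] <- list(chrom = spec_rows$chrom_name[r],
                                     window = spec_rows$window[r],
                                     slot = k, n_slots = length(fams),
                                     family = fams[k], is_tf = TRUE)
      }
      tf_left <- tf_left - length(fams)
    }
  }
  ## remaining TFs: one per fresh window
  free <- which(!used_windows, arr.ind = TRUE)
  if (tf_left > nrow(free)) stop("not enough free windows for singleton TFs")
  if (tf_left > 0) {
    pick <- free[sample(nrow(free), tf_left), , drop = FALSE]
    for (k in seq_len(tf_left)) {
      id <- next_tf_id()
      used_windows[pick[k, 1], pick[k, 2]] <- TRUE
      placements[[id]] <- list(chrom = chroms[pick[k, 1]],
                               window = pick[k, 2] - 1L,
                               slot = 1L, n_slots = 5L,
                               family = paste0("F", sample(cfg$n_families, 1)),
                               is_tf = TRUE)
    }
  }
  ## SG genes fill free slots anywhere (slot 2..5 of any window, or any
  ## slot of windows without TFs); track per-window slot occupancy
  slot_used <- new.env(parent = emptyenv())
  for (p in placements) {
    key <- paste(p$chrom, p$window, sep = ":")
    cur <- if (!is.null(slot_used[[key]])) slot_used[[key]] else integer(0)
    slot_used[[key]] <- c(cur, p$slot)
  }
  sg_pool <- list()
  for (ci in seq_len(cfg$n_chromosomes)) for (w in seq_len(n_win) - 1L) {
    key <- paste(chroms[ci], w, sep = ":")
    taken <- if (!is.null(slot_used[[key]])) slot_used[[key]] else integer(0)
    n_slots <- max(5L, length(taken))
    for (s in setdiff(seq_len(n_slots), taken)) {
      sg_pool[[length(sg_pool) + 1L]] <- list(chrom = chroms[ci], window = w,
                                              slot = s, n_slots = n_slots)
    }
  }
  if (cfg$n_sg_genes > length(sg_pool)) stop("not enough room for SG genes")
  sg_pick <- sample(length(sg_pool), cfg$n_sg_genes)
  for (k in seq_len(cfg$n_sg_genes)) {
    id <- sprintf("SG%04d", k)
    p <- sg_pool[[sg_pick[k]]]
    p$family <- "SG"; p$is_tf <- FALSE
    placements[[id]] <- p
  }

  ## realize genes in deterministic id order
  ids <- names(placements)
  ids <- ids[order(ids)]
  genes <- list(); parts <- list(); cds_seqs <- character(0)
  for (id in ids) {
    p <- placements[[id]]
    strand <- sample(c("+", "-"), 1)
    g <- build_gene(cfg, strand)
    slot_len <- W %/% p$n_slots
    if (g$length > slot_len - 40L) stop("gene longer than slot")
    jitter <- sample.int(slot_len - 40L - g$length + 1L, 1) - 1L
    start <- p$window * W + (p$slot - 1L) * slot_len + 20L + jitter
    end <- start + g$length - 1L
    substr(genome[[p$chrom]], start, end) <- g$seq
    genes[[id]] <- data.frame(gene_id = id, family = p$family,
                              is_tf = p$is_tf, chrom = p$chrom,
                              strand = strand, start = start, end = end,
                              window = p$window, stringsAsFactors = FALSE)
    pp <- lapply(g$parts, function(iv) {
      if (!nrow(iv)) return(iv)
      data.frame(start = iv$start + start - 1L, end = iv$end + start - 1L)
    })
    parts[[id]] <- pp
    cds_seqs[[id]] <- g$cds_seq
  }
  gene_df <- do.call(rbind, genes)
  gene_df <- gene_df[order(gene_df$chrom, gene_df$start), ]
  rownames(gene_df) <- NULL

  ## overlap invariant
  for (ch in chroms) {
    sub <- gene_df[gene_df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      stop("overlapping planted gene intervals on ", ch)
  }

  paths <- list(genome = file.path(out_dir, "genome.fa"),
                gff3 = file.path(out_dir, "annotation.gff3"),
                families = file.path(out_dir, "families.tsv"),
                truth = file.path(out_dir, "truth_genome.json"))
  write_fasta(genome, paths$genome)
  write_gff3(gene_df, parts, paths$gff3)
  write_tsv(data.frame(gene_id = gene_df$gene_id[gene_df$is_tf],
                       family = gene_df$family[gene_df$is_tf]),
            paths$families)

  truth_clusters <- if (!is.null(spec_rows)) derive_cluster_truth(spec_rows)
                    else list()
  truth <- list(
    clusters = truth_clusters,
    gene_windows = gene_df[gene_df$is_tf,
                           c("gene_id", "family", "chrom", "window")],
    n_tf = sum(gene_df$is_tf), n_sg = sum(!gene_df$is_tf))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  structure(list(paths = paths, genes = gene_df, parts = parts,
                 genome = genome, cds_seq = cds_seqs, truth = truth,
                 cfg = cfg),
            class = "genome_bundle")
}

## minimal deterministic GFF3 writer with gene/mRNA/exon/CDS/UTR rows
write_gff3 <- function(gene_df, parts, path) {
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, s, e, strand, phase, attrs) {
    paste(chrom, "tfcoopsim", type, s, e, ".", strand, phase, attrs,
          sep = "\t")
  }
  for (i in seq_len(nrow(gene_df))) {
    g <- gene_df[i, ]
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               fmt(g$chrom, "gene", g$start, g$end, g$strand, ".",
                   paste0("ID=", g$gene_id)),
               fmt(g$chrom, "mRNA", g$start, g$end, g$strand, ".",
                   paste0("ID=", mid, ";Parent=", g$gene_id)))
    pp <- parts[[g$gene_id]]
    for (j in seq_len(nrow(pp$exons))) {
      lines <- c(lines, fmt(g$chrom, "exon", pp$exons$start[j],
                            pp$exons$end[j], g$strand, ".",
                            paste0("Parent=", mid)))
    }
    cds <- pp$cds
    ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    sofar <- 0L
    for (j in ord) {
      phase <- (3L - (sofar %% 3L)) %% 3L
      lines <- c(lines, fmt(g$chrom, "CDS", cds$start[j], cds$end[j],
                            g$strand, phase, paste0("Parent=", mid)))
      sofar <- sofar + cds$end[j] - cds$start[j] + 1L
    }
    for (slot in c("utr5", "utr3")) {
      typ <- if (slot == "utr5") "five_prime_UTR" else "three_prime_UTR"
      iv <- pp[[slot]]
      for (j in seq_len(nrow(iv))) {
        lines <- c(lines, fmt(g$chrom, typ, iv$start[j], iv$end[j],
                              g$strand, ".", paste0("Parent=", mid)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- motif library --------------------------------------------------

#' Motif library simulation configuration
#'
#' @param n_motifs number of (non-decoy) motifs.
#' @param motif_length_range motif widths, within 6..25.
#' @param planted_pairs data frame with columns `motif_i`, `motif_j`
#'   (1-based indices into the motifs; `i == j` plants a self-pair) and
#'   `half_site_length` (>= 3).
#' @param n_decoys number of certified palindrome-free decoy motifs.
#' @param seed integer seed.
#' @return list of class `motif_sim_config`.
#' @export
motif_sim_config <- function(n_motifs = 10, motif_length_range = c(10, 16),
                             planted_pairs = NULL, n_decoys = 10, seed = 1) {
  if (motif_length_range[1] < 6 || motif_length_range[2] > 25)
    stop("motif lengths must lie in [6, 25]")
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("motif_i", "motif_j", "half_site_length") %in%
                    names(planted_pairs)))
    if (any(planted_pairs$half_site_length < 3))
      stop("planted half-site length must be >= 3 (palindrome >= 6 bp)")
    if (any(planted_pairs$motif_i > n_motifs |
            planted_pairs$motif_j > n_motifs))
      stop("planted pair index out of range")
    self <- planted_pairs$motif_i == planted_pairs$motif_j
    idx <- c(planted_pairs$motif_i, planted_pairs$motif_j[!self])
    if (anyDuplicated(idx))
      stop("each motif may participate in at most one planted pair")
  }
  structure(list(n_motifs = n_motifs,
                 motif_length_range = motif_length_range,
                 planted_pairs = planted_pairs, n_decoys = n_decoys,
                 seed = seed),
            class = "motif_sim_config")
}

## exhaustive minimal-width palindrome check, independent of
## find_palindromes: any reverse-complement palindrome of >= min_len
## contains one of exactly min_len, so testing half width min_len/2
## alone is complete.  Substrings are enumerated explicitly and each
## one reverse-complemented on its own.
has_palindrome <- function(a, b, min_len = 6) {
  k <- min_len %/% 2
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  sa <- substring(a, seq_len(nchar(a) - k + 1L), seq.int(k, nchar(a)))
  sb <- substring(b, seq_len(nchar(b) - k + 1L), seq.int(k, nchar(b)))
  rc <- vapply(sb, function(s)
    paste(rev(chars(chartr("ACGT", "TGCA", s))), collapse = ""), character(1))
  any(sa %in% rc)
}

## TRUE when candidate `s` forms no reverse-complement palindrome of
## >= 6 bp with any accepted consensus (or with itself) other than
## those sanctioned by the planted-pair design.  `sanction` holds the
## names of members `s` is allowed to pair with; `self_ok` sanctions a
## palindrome within `s` itself (planted self pairs).
certify_member <- function(s, accepted, sanction = character(0),
                           self_ok = FALSE, min_len = 6) {
  if (!self_ok && has_palindrome(s, s, min_len)) return(FALSE)
  for (nm in names(accepted)) {
    if (nm %in% sanction) next
    if (has_palindrome(s, accepted[[nm]], min_len)) return(FALSE)
  }
  TRUE
}

## The unique 3-mers of a string.
km3 <- function(s) unique(kmers(s, 3))

## Candidate half sites of length k: strings over {A,C,G} whose every
## 3-bp window contains at least one G (so no window can hide in an
## {A,C} background) and at least one of {A,C} (so no window's
## reverse complement is an {A,C}-pure background word).  Enumerated
## exhaustively for small k, sampled for large k.
half_site_candidates <- function(k, n_sample = 2000L) {
  ok_windows <- function(h) {
    all(vapply(km3(h), function(t) {
      tc <- chars(t)
      any(tc == "G") && any(tc %in% c("A", "C"))
    }, logical(1)))
  }
  if (3^k <= 6561) {
    g <- expand.grid(rep(list(c("A", "C", "G")), k),
                     stringsAsFactors = FALSE)
    hs <- apply(g, 1, paste, collapse = "")
  } else {
    hs <- unique(replicate(n_sample, paste(
      sample(c("A", "C", "G"), k, replace = TRUE), collapse = "")))
  }
  hs[vapply(hs, ok_windows, logical(1))]
}

## Island flush against one motif edge, padded with A to length L.
place_island <- function(island, L, at_start) {
  pad <- strrep("A", max(0L, L - nchar(island)))
  if (at_start) paste0(island, pad) else paste0(pad, island)
}

## Backtracking search for a jointly admissible set of planted-pair
## motifs.  For min_len 6, "a >= 6 bp reverse-complement palindrome
## exists between strings a and b" is exactly "some 3-mer of a equals
## the reverse complement of a 3-mer of b", so admissibility reduces
## to 3-mer set logic: no 3-mer of a new motif may complement a 3-mer
## already present in the library ({A,C}-pure words stand in for all
## backgrounds and decoys), no motif may complement itself, and within
## a planted pair any overlap is the planted palindrome's own doing
## and therefore harmless.  The search assigns half sites, island
## edges and lengths pair by pair and backtracks on conflict;
## randomized restarts cut off pathological orderings.
search_planted <- function(tp, lens, max_nodes = 3000L, restarts = 60L) {
  n <- nrow(tp)
  ks <- sort(unique(tp$half_site_length))
  cand <- lapply(ks, half_site_candidates)
  names(cand) <- as.character(ks)
  ac_words <- apply(expand.grid(rep(list(c("A", "C")), 3)), 1,
                    paste, collapse = "")
  out <- vector("list", n)
  nodes <- 0L
  rec <- function(r, P) {
    if (r > n) return(TRUE)
    k <- tp$half_site_length[r]
    i <- tp$motif_i[r]; j <- tp$motif_j[r]
    for (h in sample(cand[[as.character(k)]])) {
      nodes <<- nodes + 1L
      if (nodes > max_nodes) return(NA)
      if (i == j) {
        island <- paste0(h, revcomp(h))
        ikm <- km3(island)
        for (ori in c(TRUE, FALSE)) {
          s <- place_island(island, max(lens[i], nchar(island)), ori)
          K <- km3(s)
          if (any(revcomp(K) %in% P)) next
          ## within the motif, only island kmers may complement each
          ## other (that is the planted self palindrome)
          bad <- any(vapply(K, function(t) {
            rt <- revcomp(t)
            rt %in% K && !(t %in% ikm && rt %in% ikm)
          }, logical(1)))
          if (bad) next
          res <- rec(r + 1, union(P, K))
          if (isTRUE(res)) {
            out[[r]] <<- list(half_site = h, motif_i = s)
            return(TRUE)
          }
          if (is.na(res)) return(NA)
        }
      } else {
        for (oi in c(TRUE, FALSE)) for (oj in c(TRUE, FALSE)) {
          si <- place_island(h, max(lens[i], k), oi)
          sj <- place_island(revcomp(h), max(lens[j], k), oj)
          K_i <- km3(si); K_j <- km3(sj)
          if (any(revcomp(K_i) %in% P) || any(revcomp(K_j) %in% P)) next
          if (any(revcomp(K_i) %in% K_i) ||
              any(revcomp(K_j) %in% K_j)) next
          res <- rec(r + 1, union(P, union(K_i, K_j)))
          if (isTRUE(res)) {
            out[[r]] <<- list(half_site = h, motif_i = si, motif_j = sj)
            return(TRUE)
          }
          if (is.na(res)) return(NA)
        }
      }
    }
    FALSE
  }
  for (attempt in seq_len(restarts)) {
    nodes <- 0L
    res <- rec(1L, ac_words)
    if (isTRUE(res)) return(out)
    if (isFALSE(res) && attempt == 1L)
      stop("planted pair configuration is infeasible: the half-site ",
           "3-mer budget at min palindrome length 6 is exhausted")
  }
  stop("could not find an admissible planted-pair layout within the ",
       "restart budget")
}

#' Generate a synthetic motif library with planted palindromic pairs
#'
#' Motif backgrounds, fillers and decoys are drawn over the \{A,C\}
#' sub-alphabet; planted half sites live over \{A,C,G\} with at least
#' one G and one A/C per 3-bp window and sit flush against a motif
#' edge on an A-padded background.  A backtracking search assigns half
#' sites and island placements jointly: at the minimum palindrome
#' length of 6 bp, "two motifs form a palindrome" is exactly "a 3-mer
#' of one equals the reverse complement of a 3-mer of the other", so
#' the search can prove with 3-mer set logic that the only pairs in
#' the emitted library are the planted ones (or raise a generation
#' error when the configuration is infeasible).  As defense in depth,
#' the finished library is certified by an independent exhaustive
#' minimal-width palindrome check over every pair of members -- any
#' longer palindrome would contain a minimal-width one, so the check
#' is complete -- and decoys are additionally certified one by one
#' before acceptance.
#'
#' PWMs put probability 0.91 on the consensus letter and 0.03 on the
#' others.
#'
#' @param cfg a [motif_sim_config()].
#' @param out_dir output directory.  Emits `motifs.meme` and
#'   `truth_motifs.json`.
#' @return list of class `motif_bundle`: `paths`, `motifs` (list of
#'   [motif_pwm()]), `consensus` (named character), `truth`
#'   (`planted_pairs` data frame with motif ids and half sites,
#'   `decoys` ids), `cfg`.
#' @export
gen_motif_library <- function(cfg, out_dir) {
  stopifnot(is(cfg, "motif_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  lr <- cfg$motif_length_range
  ids <- sprintf("MP%03d", seq_len(cfg$n_motifs))
  lens <- sample(seq(lr[1], lr[2]), cfg$n_motifs, replace = TRUE)
  cons <- stats::setNames(rep(NA_character_, cfg$n_motifs), ids)
  accepted <- list()   # consensi certified so far, named by motif id
  truth_pairs <- NULL

  if (!is.null(cfg$planted_pairs)) {
    tp <- cfg$planted_pairs
    need <- ifelse(tp$motif_i == tp$motif_j,
                   2L * tp$half_site_length, tp$half_site_length)
    if (any(need > lr[2]))
      stop("planted island longer than the motif length range allows")
    layout <- search_planted(tp, lens)
    tp$half_site <- vapply(layout, `[[`, character(1), "half_site")
    for (r in seq_len(nrow(tp))) {
      i <- tp$motif_i[r]; j <- tp$motif_j[r]
      cons[i] <- layout[[r]]$motif_i
      accepted[[ids[i]]] <- cons[i]
      if (i != j) {
        cons[j] <- layout[[r]]$motif_j
        accepted[[ids[j]]] <- cons[j]
      }
      lens[i] <- nchar(cons[i])
      lens[j] <- nchar(cons[j])
    }
    truth_pairs <- data.frame(
      motif_a = ids[pmin(tp$motif_i, tp$motif_j)],
      motif_b = ids[pmax(tp$motif_i, tp$motif_j)],
      half_site_length = tp$half_site_length,
      half_site = tp$half_site, stringsAsFactors = FALSE)
  }
  ## non-pair motifs: plain {A,C} backgrounds (certified all the same)
  for (i in which(is.na(cons))) {
    ok <- FALSE
    for (try in seq_len(200)) {
      s <- paste(sample(c("A", "C"), lens[i], replace = TRUE),
                 collapse = "")
      if (certify_member(s, accepted)) {
        cons[i] <- s
        accepted[[ids[i]]] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not certify motif ", ids[i],
                  " within the retry budget")
  }
  ## decoys: {A,C} strings certified by the brute-force oracle
  decoy_ids <- if (cfg$n_decoys > 0)
    sprintf("DY%03d", seq_len(cfg$n_decoys)) else character(0)
  for (d in decoy_ids) {
    ok <- FALSE
    for (try in seq_len(200)) {
      s <- paste(sample(c("A", "C"), sample(seq(lr[1], lr[2]), 1),
                        replace = TRUE), collapse = "")
      others <- c(cons[!is.na(cons)], s)  # include self-check
      if (!any(vapply(others, function(o)
        has_palindrome(s, o, 6), logical(1)))) {
        cons[[d]] <- s; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not generate decoy ", d, " within the retry budget")
  }
  ## defense in depth: brute-force certify the emitted library -- every
  ## planted pair must be detectable and nothing else may pair up
  sanct <- if (!is.null(truth_pairs))
    paste(truth_pairs$motif_a, truth_pairs$motif_b) else character(0)
  nms <- names(cons)
  for (a in seq_along(cons)) {
    for (b in seq_len(a)) {
      key <- paste(min(nms[a], nms[b]), max(nms[a], nms[b]))
      if (has_palindrome(cons[[a]], cons[[b]], 6) != (key %in% sanct))
        stop("internal error: library certification failed for ", key)
    }
  }
  motifs <- lapply(names(cons), function(id) {
    ch <- chars(cons[[id]])
    m <- matrix(0.03, nrow = length(ch), ncol = 4,
                dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_along(ch), match(ch, DNA_BASES))] <- 0.91
    motif_pwm(id, m)
  })
  names(motifs) <- names(cons)
  paths <- list(meme = file.path(out_dir, "motifs.meme"),
                truth = file.path(out_dir, "truth_motifs.json"))
  write_meme(motifs, paths$meme)
  truth <- list(planted_pairs = truth_pairs, decoys = decoy_ids,
                n_motifs = cfg$n_motifs)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  structure(list(paths = paths, motifs = motifs, consensus = cons,
                 truth = truth, cfg = cfg),
            class = "motif_bundle")
}

## ---- promoter hit planting -----------------------------------------

#' Plant motif consensus occurrences in gene promoters
#'
#' Writes each motif's consensus string into the requested promoter
#' interval, strand-aware (a minus-strand gene carries the reverse
#' complement on the forward genomic strand; a hit requested on the
#' promoter's "-" strand plants the reverse complement relative to the
#' coding strand).
#'
#' @param genome_bundle a `genome_bundle` from [gen_genome()].
#' @param motif_bundle a `motif_bundle` from [gen_motif_library()].
#' @param spec data frame with columns `gene_id`, `motif_id`,
#'   `end_upstream` (distance of the 3'-most motif base upstream of the
#'   TSS, 1-based) and optionally `strand` (default "+").
#' @param promoter_bp promoter length in bp (default 500).
#' @return the genome bundle with modified genome, updated FASTA on
#'   disk, and `truth$promoter_hits` (gene_id, motif_id,
#'   start_upstream, end_upstream, strand).
#' @export
plant_promoter_hits <- function(genome_bundle, motif_bundle, spec,
                                promoter_bp = 500) {
  gb <- genome_bundle
  if (!"strand" %in% names(spec)) spec$strand <- "+"
  occupied <- list()
  hits <- list()
  for (r in seq_len(nrow(spec))) {
    g <- spec$gene_id[r]
    gi <- gb$genes[gb$genes$gene_id == g, , drop = FALSE]
    if (!nrow(gi)) stop("unknown gene ", g)
    mid <- spec$motif_id[r]
    if (!mid %in% names(motif_bundle$consensus)) stop("unknown motif ", mid)
    cns <- motif_bundle$consensus[[mid]]
    wlen <- nchar(cns)
    end_up <- spec$end_upstream[r]
    start_up <- end_up + wlen - 1L
    if (end_up < 1 || start_up > promoter_bp)
      stop("requested interval outside the ", promoter_bp, "-bp promoter")
    iv <- c(end_up, start_up)
    for (o in occupied[[g]]) {
      if (iv[1] <= o[2] && o[1] <= iv[2])
        stop("offset collides with another planted hit in ", g)
    }
    occupied[[g]] <- c(occupied[[g]], list(iv))
    ## the string as read on the coding-strand promoter
    s_cod <- if (spec$strand[r] == "+") cns else revcomp(cns)
    if (gi$strand == "+") {
      tss <- gi$start
      gs <- tss - start_up; ge <- tss - end_up
      if (gs < 1) stop("promoter interval outside chromosome")
      substr(gb$genome[[gi$chrom]], gs, ge) <- s_cod
    } else {
      tss <- gi$end
      gs <- tss + end_up; ge <- tss + start_up
      if (ge > nchar(gb$genome[[gi$chrom]]))
        stop("promoter interval outside chromosome")
      substr(gb$genome[[gi$chrom]], gs, ge) <- revcomp(s_cod)
    }
    hits[[length(hits) + 1L]] <- data.frame(
      gene_id = g, motif_id = mid, start_upstream = start_up,
      end_upstream = end_up, strand = spec$strand[r],
      stringsAsFactors = FALSE)
  }
  write_fasta(gb$genome, gb$paths$genome)
  gb$truth$promoter_hits <- if (length(hits)) do.call(rbind, hits) else NULL
  jsonlite::write_json(gb$truth, gb$paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  gb
}

## ---- expression -----------------------------------------------------

#' Expression simulation configuration
#'
#' @param n_genes total gene count.
#' @param n_samples sample count.
#' @param module_spec list of `list(size, profile, noise_sd)` where
#'   `profile` is a named numeric vector over tissue labels (the
#'   eigengene tissue profile).
#' @param n_low_expression genes forced below the TPM filter.
#' @param tissue_labels character vector of length `n_samples` giving
#'   each sample's tissue.
#' @param projects optional character vector of per-sample project ids.
#' @param seed integer seed.
#' @return list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 200, n_samples = 60,
                            module_spec = default_module_spec(),
                            n_low_expression = 20,
                            tissue_labels = rep(c("leaf", "peel", "seed",
                                                  "pulp"), each = 15),
                            projects = NULL, seed = 1) {
  if (length(tissue_labels) != n_samples)
    stop("tissue_labels must have length n_samples")
  sizes <- vapply(module_spec, function(m) m$size, numeric(1))
  if (sum(sizes) > n_genes) stop("module sizes exceed the gene pool")
  if (sum(sizes) + n_low_expression > n_genes)
    stop("modules plus low-expression genes exceed the gene pool")
  for (m in module_spec) if (m$noise_sd <= 0) stop("noise sd must be > 0")
  if (is.null(projects)) projects <- rep("P1", n_samples)
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 module_spec = module_spec,
                 n_low_expression = n_low_expression,
                 tissue_labels = tissue_labels, projects = projects,
                 seed = seed),
            class = "expr_sim_config")
}

#' Default planted-module specification: three modules of 50 genes,
#' each tissue-specific, noise sd 0.3
#' @export
default_module_spec <- function() {
  list(
    list(size = 50, profile = c(leaf = 1, peel = 0, seed = 0, pulp = 0),
         noise_sd = 0.3),
    list(size = 50, profile = c(leaf = 0, peel = 1, seed = 0, pulp = 0),
         noise_sd = 0.3),
    list(size = 50, profile = c(leaf = 0, peel = 0, seed = 1, pulp = 0),
         noise_sd = 0.3))
}

#' Generate a synthetic TPM matrix with planted co-expression modules
#'
#' Module genes are eigengene x loading plus Gaussian noise, shifted
#' and scaled to nonnegative TPM; low-expression genes sit below 1 TPM
#' in every sample; the remaining genes are unstructured background.
#'
#' @param cfg an [expr_sim_config()].
#' @param out_dir output directory.  Emits `tpm.tsv`, `samples.tsv`,
#'   `truth_expression.json`.
#' @param gene_ids optional gene identifiers (default `G0001`...).
#' @return list of class `expr_bundle`: `paths`, `matrix` (genes x
#'   samples), `metadata`, `truth` (`modules`: named gene -> label
#'   among `M1..`, `low`, `background`), `cfg`.
#' @export
gen_expression <- function(cfg, out_dir, gene_ids = NULL) {
  stopifnot(is(cfg, "expr_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (length(gene_ids) != cfg$n_genes) stop("gene_ids length mismatch")
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  mat <- matrix(0, nrow = cfg$n_genes, ncol = cfg$n_samples,
                dimnames = list(gene_ids, samples))
  labels <- stats::setNames(rep("background", cfg$n_genes), gene_ids)
  idx <- 1L
  for (mi in seq_along(cfg$module_spec)) {
    spec <- cfg$module_spec[[mi]]
    prof <- spec$profile[cfg$tissue_labels]
    z <- as.numeric(scale(prof))
    if (anyNA(z)) z <- rep(0, cfg$n_samples)
    rows <- seq.int(idx, idx + spec$size - 1L)
    for (g in rows) {
      loading <- stats::runif(1, 0.7, 1.3)
      mat[g, ] <- pmax(0, 5 + 2 * loading * z +
                         stats::rnorm(cfg$n_samples, 0, spec$noise_sd))
    }
    labels[rows] <- paste0("M", mi)
    idx <- idx + spec$size
  }
  if (cfg$n_low_expression > 0) {
    rows <- seq.int(idx, idx + cfg$n_low_expression - 1L)
    for (g in rows) mat[g, ] <- stats::runif(cfg$n_samples, 0, 0.9)
    labels[rows] <- "low"
    idx <- idx + cfg$n_low_expression
  }
  if (idx <= cfg$n_genes) {
    rows <- seq.int(idx, cfg$n_genes)
    for (g in rows) mat[g, ] <- pmax(0, 5 + stats::rnorm(cfg$n_samples, 0, 1.5))
  }
  mat <- round(mat, 4)
  metadata <- data.frame(sample = samples, tissue = cfg$tissue_labels,
                         project = cfg$projects, stringsAsFactors = FALSE)
  paths <- list(tpm = file.path(out_dir, "tpm.tsv"),
                metadata = file.path(out_dir, "samples.tsv"),
                truth = file.path(out_dir, "truth_expression.json"))
  write_tsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
            paths$tpm)
  write_tsv(metadata, paths$metadata)
  truth <- list(modules = as.list(labels))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  structure(list(paths = paths, matrix = mat, metadata = metadata,
                 truth = list(modules = labels), cfg = cfg),
            class = "expr_bundle")
}

## ---- variants -------------------------------------------------------

#' Variant simulation configuration
#'
#' @param target_rates named vector of per-bp-per-sample variant rates
#'   over regions CDS, intron, UTR.
#' @param n_samples sample count of the simulated project.
#' @param synonymous_fraction fraction of CDS SNVs forced synonymous.
#' @param seed integer seed.
#' @return list of class `variant_sim_config`.
#' @export
variant_sim_config <- function(target_rates = c(CDS = 4.0e-4,
                                                intron = 1.7e-4,
                                                UTR = 4.9e-4),
                               n_samples = 9, synonymous_fraction = 0.5,
                               seed = 1) {
  if (any(target_rates < 0)) stop("rates must be >= 0")
  if (synonymous_fraction < 0 || synonymous_fraction > 1)
    stop("synonymous_fraction must be in [0,1]")
  structure(list(target_rates = target_rates, n_samples = n_samples,
                 synonymous_fraction = synonymous_fraction, seed = seed),
            class = "variant_sim_config")
}

## genomic positions of a region over the TF genes of a bundle
region_positions <- function(bundle, region) {
  tf <- bundle$genes[bundle$genes$is_tf, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tf))) {
    g <- tf$gene_id[i]
    iv <- switch(region,
                 CDS = bundle$parts[[g]]$cds,
                 UTR = rbind(bundle$parts[[g]]$utr5, bundle$parts[[g]]$utr3),
                 intron = {
                   ex <- bundle$parts[[g]]$exons
                   if (nrow(ex) < 2) data.frame(start = integer(),
                                                end = integer())
                   else data.frame(start = ex$end[-nrow(ex)] + 1L,
                                   end = ex$start[-1] - 1L)
                 })
    if (!nrow(iv)) next
    pos <- unlist(lapply(seq_len(nrow(iv)), function(j)
      seq.int(iv$start[j], iv$end[j])))
    out[[length(out) + 1L]] <- data.frame(
      chrom = tf$chrom[i], pos = pos, gene_id = g,
      strand = tf$strand[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chrom = character(), pos = integer(),
                                      gene_id = character(),
                                      strand = character(),
                                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## CDS coordinate of a genomic position inside a bundle gene
bundle_cds_position <- function(bundle, gene_id, pos) {
  iv <- bundle$parts[[gene_id]]$cds
  strand <- bundle$genes$strand[bundle$genes$gene_id == gene_id]
  off <- 0L
  idx <- if (strand == "+") seq_len(nrow(iv)) else rev(seq_len(nrow(iv)))
  for (j in idx) {
    if (pos >= iv$start[j] && pos <= iv$end[j]) {
      return(off + if (strand == "+") pos - iv$start[j] + 1L
             else iv$end[j] - pos + 1L)
    }
    off <- off + iv$end[j] - iv$start[j] + 1L
  }
  NA_integer_
}

#' Generate a synthetic VCF with planted per-region variant rates
#'
#' The planted site count of each region is
#' `round(rate x region length x n_samples)` exactly; positions are
#' sampled without replacement within the TF-gene regions.  CDS SNVs
#' are constructed synonymous or nonsynonymous by codon arithmetic,
#' honouring `synonymous_fraction`.
#'
#' @param genome_bundle a `genome_bundle` from [gen_genome()] (possibly
#'   after [plant_promoter_hits()]).
#' @param cfg a [variant_sim_config()].
#' @param out_dir output directory.  Emits `variants.vcf`,
#'   `truth_variants.json`.
#' @return list of class `variant_bundle`: `paths`, `records` (data
#'   frame chrom, pos, ref, alt, gene_id, region, effect), `truth`
#'   (per-region planted counts and lengths), `cfg`.
#' @export
gen_variants <- function(genome_bundle, cfg, out_dir) {
  stopifnot(is(cfg, "variant_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  gb <- genome_bundle
  records <- list()
  counts <- list()
  lengths <- list()
  for (region in names(cfg$target_rates)) {
    pos_df <- region_positions(gb, region)
    len <- nrow(pos_df)
    if (len == 0) {
      warning("region ", region, " absent from the annotation; rate skipped")
      next
    }
    n_sites <- round(cfg$target_rates[[region]] * len * cfg$n_samples)
    counts[[region]] <- n_sites
    lengths[[region]] <- len
    if (n_sites == 0) next
    if (n_sites > len) stop("target rate too high for region ", region)
    if (region != "CDS") {
      pick <- pos_df[sample(len, n_sites), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        ref <- substring(gb$genome[[pick$chrom[i]]], pick$pos[i], pick$pos[i])
        alt <- sample(setdiff(DNA_BASES, ref), 1)
        records[[length(records) + 1L]] <- data.frame(
          chrom = pick$chrom[i], pos = pick$pos[i], ref = ref, alt = alt,
          gene_id = pick$gene_id[i], region = region,
          effect = "not_applicable", stringsAsFactors = FALSE)
      }
    } else {
      n_syn <- round(n_sites * cfg$synonymous_fraction)
      n_non <- n_sites - n_syn
      pos_df <- pos_df[sample(len), , drop = FALSE]  # shuffled scan order
      placed_syn <- 0L; placed_non <- 0L
      for (i in seq_len(nrow(pos_df))) {
        if (placed_syn == n_syn && placed_non == n_non) break
        g <- pos_df$gene_id[i]
        cpos <- bundle_cds_position(gb, g, pos_df$pos[i])
        cds <- gb$cds_seq[[g]]
        cod_i <- (cpos - 1L) %/% 3L
        within <- cpos - cod_i * 3L
        codon <- substring(cds, cod_i * 3L + 1L, cod_i * 3L + 3L)
        aa <- translate_codon(codon)
        alts_coding <- setdiff(DNA_BASES, substring(codon, within, within))
        syn_alts <- character(0); non_alts <- character(0)
        for (b in alts_coding) {
          alt_codon <- codon
          substr(alt_codon, within, within) <- b
          if (translate_codon(alt_codon) == aa) syn_alts <- c(syn_alts, b)
          else non_alts <- c(non_alts, b)
        }
        want_syn <- placed_syn < n_syn && length(syn_alts)
        want_non <- placed_non < n_non && length(non_alts)
        if (want_syn) {
          b <- if (length(syn_alts) == 1) syn_alts else sample(syn_alts, 1)
          placed_syn <- placed_syn + 1L
          eff <- "synonymous_SNV"
        } else if (want_non) {
          b <- if (length(non_alts) == 1) non_alts else sample(non_alts, 1)
          placed_non <- placed_non + 1L
          eff <- "nonsynonymous_SNV"
        } else next
        alt_fwd <- if (pos_df$strand[i] == "+") b else COMPLEMENT[[b]]
        ref <- substring(gb$genome[[pos_df$chrom[i]]],
                         pos_df$pos[i], pos_df$pos[i])
        records[[length(records) + 1L]] <- data.frame(
          chrom = pos_df$chrom[i], pos = pos_df$pos[i], ref = ref,
          alt = alt_fwd, gene_id = g, region = "CDS", effect = eff,
          stringsAsFactors = FALSE)
      }
      if (placed_syn + placed_non < n_sites) {
        stop("could not place the requested number of CDS SNVs")
      }
    }
  }
  rec <- if (length(records)) do.call(rbind, records) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene_id = character(), region = character(),
               effect = character(), stringsAsFactors = FALSE)
  if (nrow(rec)) rec <- rec[order(rec$chrom, rec$pos), ]
  rownames(rec) <- NULL
  paths <- list(vcf = file.path(out_dir, "variants.vcf"),
                truth = file.path(out_dir, "truth_variants.json"))
  write_vcf(rec, paths$vcf)
  truth <- list(region_counts = counts, region_lengths = lengths,
                n_samples = cfg$n_samples,
                target_rates = as.list(cfg$target_rates),
                effects = as.list(table(rec$effect[rec$region == "CDS"])))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  structure(list(paths = paths, records = rec, truth = truth, cfg = cfg),
            class = "variant_bundle")
}

## minimal sites-only VCF v4.2 writer
write_vcf <- function(rec, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=tfcoopsim",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(rec)) paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt,
                               ".", "PASS", ".", sep = "\t") else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
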