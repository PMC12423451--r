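## End-to-end orchestration: a single configuration drives all stages
## in dependency order, with digest-based caching and a machine-
## readable run manifest, plus truth comparison for synthetic runs.

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

digest_files <- function(paths) {
  paths <- paths[!is.na(paths)]
  out <- lapply(paths, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  })
  stats::setNames(out, paths)
}

params_digest <- function(params) {
  md5_of_string(paste(deparse(params[order(names(params))]), collapse = ""))
}

#' Pipeline configuration
#'
#' Collects the input paths and the fixed stage parameters of the
#' analysis pipeline.  All referenced input files must exist.
#'
#' @param genome,annotation,families genome FASTA, GFF3 and TF family
#'   table (TSV: gene_id, family).
#' @param motifs MEME motif library.
#' @param motif_map TSV (tf_id, motif_id) assigning motifs to TFs;
#'   alternative to running homology transfer.
#' @param expression,metadata TPM matrix TSV (first column gene_id) and
#'   sample table (sample, tissue, ...); optional.
#' @param vcf sites-only VCF; optional.
#' @param out_dir output directory.
#' @param window_bp,promoter_bp,e_max,p_max,min_palindrome,tpm_min,low_fraction,r2_min,merge_height,min_module_size,n_samples
#'   stage parameters (defaults: 250000, 500, 0.001, 1e-4, 6, 1, 0.9,
#'   0.9, 0.25, 30, 90).
#' @param seed integer seed applied before stochastic-free but
#'   order-sensitive steps for reproducibility.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, families, motifs, motif_map,
                            expression = NULL, metadata = NULL, vcf = NULL,
                            out_dir, window_bp = 250000, promoter_bp = 500,
                            e_max = 0.001, p_max = 1e-4, min_palindrome = 6,
                            tpm_min = 1, low_fraction = 0.9, r2_min = 0.9,
                            merge_height = 0.25, min_module_size = 30,
                            n_samples = 90, seed = 1) {
  req <- c(genome = genome, annotation = annotation, families = families,
           motifs = motifs, motif_map = motif_map)
  for (nm in names(req)) {
    if (!file.exists(req[[nm]]))
      stop("input file for '", nm, "' does not exist: ", req[[nm]])
  }
  for (nm in c("expression", "metadata", "vcf")) {
    p <- get(nm)
    if (!is.null(p) && !file.exists(p))
      stop("input file for '", nm, "' does not exist: ", p)
  }
  if (window_bp <= 0 || promoter_bp <= 0 || p_max <= 0 || p_max > 1 ||
      e_max <= 0 || min_palindrome < 2 || min_palindrome %% 2 != 0 ||
      tpm_min < 0 || low_fraction <= 0 || low_fraction > 1 ||
      r2_min <= 0 || r2_min > 1 || merge_height < 0 || merge_height > 1 ||
      min_module_size < 1 || n_samples < 1)
    stop("pipeline parameter out of its documented range")
  structure(list(genome = genome, annotation = annotation,
                 families = families, motifs = motifs, motif_map = motif_map,
                 expression = expression, metadata = metadata, vcf = vcf,
                 out_dir = out_dir, window_bp = window_bp,
                 promoter_bp = promoter_bp, e_max = e_max, p_max = p_max,
                 min_palindrome = min_palindrome, tpm_min = tpm_min,
                 low_fraction = low_fraction, r2_min = r2_min,
                 merge_height = merge_height,
                 min_module_size = min_module_size,
                 n_samples = n_samples, seed = seed),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

## returns TRUE when the previous manifest entry for this stage matches
## the current input digests + params and all outputs are intact
stage_cached <- function(prev, stage, in_dig, pdig) {
  e <- prev[[stage]]
  if (is.null(e)) return(FALSE)
  if (!identical(e$params_digest, pdig)) return(FALSE)
  old_in <- unlist(e$inputs)
  new_in <- unlist(in_dig)
  if (length(old_in) != length(new_in) ||
      !identical(sort(names(old_in)), sort(names(new_in))) ||
      !identical(old_in[sort(names(old_in))], new_in[sort(names(new_in))]))
    return(FALSE)
  outs <- unlist(e$outputs)
  if (!length(outs)) return(FALSE)
  cur <- unlist(digest_files(names(outs)))
  all(!is.na(cur)) && identical(unname(cur), unname(outs))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: catalog (genes, structure stats,
#' clusters), motifs (promoter extraction + PWM scan +
#' self-regulation), palindromes (cooperation network), coexpress
#' (modules; only when expression inputs are present), variants (only
#' when a VCF is present), and finally the cooperation/module
#' intersection.  Each stage logs to stderr with a stage-prefixed
#' line, and the manifest records input digests, a parameter snapshot,
#' output digests and a timestamp per stage.  A stage whose input
#' digests and parameters match the previous manifest and whose
#' outputs are intact is not rewritten (status "cached").
#'
#' @param config a [pipeline_config()].
#' @return list with the manifest and all in-memory stage results
#'   (`catalog`, `stats`, `clusters`, `promoters`, `motifs`,
#'   `motif_map`, `hits`, `self_regulation`, `network`, `modules`,
#'   `rates`, `family_rates`, `kaks`, `intersection`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  manifest <- list()
  out <- list(paths = list())

  run_stage <- function(stage, inputs, params, compute, writers) {
    in_dig <- digest_files(inputs)
    pdig <- params_digest(params)
    res <- tryCatch(compute(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out_paths <- names(writers)
    if (stage_cached(prev, stage, in_dig, pdig)) {
      stage_log(stage, "inputs unchanged; outputs reused")
      status <- "cached"
    } else {
      for (p in out_paths) writers[[p]](p, res)
      stage_log(stage, "wrote ", length(out_paths), " output file(s)")
      status <- "ran"
    }
    manifest[[stage]] <<- list(
      status = status, inputs = in_dig, params = params,
      params_digest = pdig, outputs = digest_files(out_paths),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    res
  }
  od <- function(f) file.path(config$out_dir, f)

  ## ---- catalog ----
  cat_res <- run_stage(
    "catalog",
    c(config$genome, config$annotation, config$families),
    list(window_bp = config$window_bp),
    compute = function() {
      catalog <- load_catalog(config$annotation, config$genome,
                              read_tsv(config$families))
      stats <- gene_structure_stats(catalog)
      clusters <- cluster_tfs(catalog, window_bp = config$window_bp)
      list(catalog = catalog, stats = stats, clusters = clusters)
    },
    writers = stats::setNames(list(
      function(p, r) write_tsv(
        r$catalog$genes[r$catalog$genes$is_tf, , drop = FALSE], p),
      function(p, r) write_tsv(r$stats$per_gene, p),
      function(p, r) write_tsv(flatten_clusters(r$clusters), p),
      function(p, r) write_tsv(data.frame(gene_id = r$clusters$singlets), p)),
      c(od("tf_genes.tsv"), od("gene_stats.tsv"),
        od("clusters.tsv"), od("singlets.tsv"))))
  out$catalog <- cat_res$catalog
  out$stats <- cat_res$stats
  out$clusters <- cat_res$clusters

  ## ---- motifs ----
  motif_map <- read_tsv(config$motif_map)
  mot_res <- run_stage(
    "motifs",
    c(config$genome, config$annotation, config$motifs, config$motif_map),
    list(promoter_bp = config$promoter_bp, p_max = config$p_max),
    compute = function() {
      motifs <- read_meme(config$motifs)
      promoters <- extract_promoters(out$catalog, length = config$promoter_bp)
      hits <- scan_motifs(motifs, promoters, p_max = config$p_max)
      asg <- data.frame(query_id = motif_map$tf_id,
                        motif_id = motif_map$motif_id,
                        stringsAsFactors = FALSE)
      selfreg <- detect_self_regulation(hits, asg)
      dist <- distribution_summary(hits, out$catalog, asg)
      list(motifs = motifs, promoters = promoters, hits = hits,
           self_regulation = selfreg, distribution = dist)
    },
    writers = stats::setNames(list(
      function(p, r) write_tsv(r$hits, p),
      function(p, r) write_tsv(r$self_regulation, p),
      function(p, r) write_tsv(r$distribution, p)),
      c(od("motif_hits.tsv"), od("self_regulation.tsv"),
        od("motif_distribution.tsv"))))
  out$motifs <- mot_res$motifs
  out$promoters <- mot_res$promoters
  out$hits <- mot_res$hits
  out$self_regulation <- mot_res$self_regulation
  out$distribution <- mot_res$distribution
  out$motif_map <- motif_map

  ## ---- palindromes / cooperation network ----
  pal_res <- run_stage(
    "palindromes",
    c(config$motifs, config$motif_map, config$families),
    list(min_palindrome = config$min_palindrome),
    compute = function() {
      fam <- stats::setNames(out$catalog$genes$family,
                             out$catalog$genes$gene_id)
      tfc <- data.frame(
        tf_id = motif_map$tf_id,
        family = unname(fam[motif_map$tf_id]),
        consensus = vapply(motif_map$motif_id, function(m)
          consensus(out$motifs[[m]])$consensus, character(1)),
        stringsAsFactors = FALSE)
      if (anyNA(tfc$family))
        stop("motif_map references TFs absent from the catalog: ",
             paste(tfc$tf_id[is.na(tfc$family)], collapse = ", "))
      build_coop_network(tfc, min_len = config$min_palindrome)
    },
    writers = stats::setNames(list(
      function(p, r) write_tsv(r$edges, p),
      function(p, r) write_tsv(r$family_degrees, p)),
      c(od("network_edges.tsv"), od("family_degrees.tsv"))))
  out$network <- pal_res

  ## ---- coexpress ----
  if (!is.null(config$expression)) {
    co_res <- run_stage(
      "coexpress",
      c(config$expression, config$metadata),
      list(tpm_min = config$tpm_min, low_fraction = config$low_fraction,
           r2_min = config$r2_min, merge_height = config$merge_height,
           min_module_size = config$min_module_size, seed = config$seed),
      compute = function() {
        tpm <- read_tsv(config$expression)
        mat <- as.matrix(tpm[, -1, drop = FALSE])
        rownames(mat) <- tpm[[1]]
        meta <- if (!is.null(config$metadata)) read_tsv(config$metadata)
                else NULL
        cfg <- coexpr_config(tpm_min = config$tpm_min,
                             low_fraction = config$low_fraction,
                             r2_min = config$r2_min,
                             merge_height = config$merge_height,
                             min_module_size = config$min_module_size)
        set.seed(config$seed)
        kept <- filter_low_expression(mat, cfg)$matrix
        pw <- pick_soft_power(kept, cfg)
        tom <- compute_tom(kept, pw$beta)
        mods <- detect_modules(tom, cfg, kept)
        profile <- if (!is.null(meta) && "tissue" %in% names(meta))
          module_tissue_profile(mods, meta) else NULL
        list(matrix = kept, power = pw, modules = mods, profile = profile)
      },
      writers = stats::setNames(list(
        function(p, r) write_tsv(data.frame(
          gene_id = names(r$modules$modules),
          module = unname(r$modules$modules)), p),
        function(p, r) write_tsv(data.frame(
          sample = rownames(r$modules$eigengenes),
          r$modules$eigengenes, check.names = FALSE), p),
        function(p, r) writeLines(as.character(r$power$beta), p)),
        c(od("modules.tsv"), od("eigengenes.tsv"), od("soft_power.txt"))))
    out$expr_matrix <- co_res$matrix
    out$power <- co_res$power
    out$modules_obj <- co_res$modules
    out$modules <- co_res$modules$modules
    out$tissue_profile <- co_res$profile
  }

  ## ---- variants ----
  if (!is.null(config$vcf)) {
    var_res <- run_stage(
      "variants",
      c(config$vcf, config$genome, config$annotation),
      list(n_samples = config$n_samples),
      compute = function() {
        ann <- annotate_variants(config$vcf, out$catalog)
        lens <- catalog_region_lengths(out$catalog, tf_only = TRUE)
        rates <- project_region_rate(ann[ann$region %in% names(lens), ,
                                         drop = FALSE],
                                     lens, n_samples = config$n_samples)
        frates <- family_region_rate(ann, out$catalog,
                                     n_samples = config$n_samples)
        kaks <- family_kaks_from_variants(ann, out$catalog)
        list(annotation = ann, rates = rates, family_rates = frates,
             kaks = kaks)
      },
      writers = stats::setNames(list(
        function(p, r) write_tsv(r$annotation, p),
        function(p, r) write_tsv(r$rates, p),
        function(p, r) write_tsv(r$family_rates, p),
        function(p, r) write_tsv(r$kaks, p)),
        c(od("variant_annotation.tsv"), od("rates.tsv"),
          od("family_rates.tsv"), od("family_kaks.tsv"))))
    out$variant_annotation <- var_res$annotation
    out$rates <- var_res$rates
    out$family_rates <- var_res$family_rates
    out$kaks <- var_res$kaks
  }

  ## ---- intersection (last) ----
  if (!is.null(config$expression)) {
    int_res <- run_stage(
      "intersect",
      c(config$motifs, config$motif_map, config$expression),
      list(min_palindrome = config$min_palindrome, seed = config$seed),
      compute = function() {
        mm <- out$modules[names(out$modules) %in% out$network$nodes$tf_id]
        intersect_with_modules(out$network, mm)
      },
      writers = stats::setNames(list(
        function(p, r) write_tsv(r$sets, p),
        function(p, r) write_tsv(r$edges, p)),
        c(od("coop_modules.tsv"), od("coop_edges.tsv"))))
    out$intersection <- int_res
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  out$manifest <- manifest
  out$config <- config
  out$paths$manifest <- manifest_path
  class(out) <- "pipeline_run"
  out
}

flatten_clusters <- function(cs) {
  cl <- cs$clusters
  if (!nrow(cl)) return(data.frame(cluster_id = character(),
                                   chrom = character(), kind = character(),
                                   members = character(),
                                   families = character(),
                                   stringsAsFactors = FALSE))
  data.frame(cluster_id = cl$cluster_id, chrom = cl$chrom, kind = cl$kind,
             span_start = cl$span_start, span_end = cl$span_end,
             members = vapply(cl$members, paste, character(1),
                              collapse = ","),
             families = vapply(cl$families, paste, character(1),
                               collapse = ","),
             stringsAsFactors = FALSE)
}

#' Read a synthetic-truth bundle from a directory
#'
#' Collects whichever of `truth_genome.json`, `truth_motifs.json`,
#' `truth_expression.json`, `truth_variants.json` are present.
#'
#' @param dir directory holding truth files from the generators.
#' @return list with elements `genome`, `motifs`, `expression`,
#'   `variants` (those present).
#' @export
read_truth_bundle <- function(dir) {
  out <- list()
  for (nm in c("genome", "motifs", "expression", "variants")) {
    p <- file.path(dir, paste0("truth_", nm, ".json"))
    if (file.exists(p)) out[[nm]] <- jsonlite::read_json(p,
                                                         simplifyVector = TRUE)
  }
  out
}

co_membership_pairs <- function(groups) {
  ## groups: list of character vectors of gene ids
  pairs <- character(0)
  for (g in groups) {
    g <- sort(unique(g))
    if (length(g) < 2) next
    idx <- utils::combn(length(g), 2)
    pairs <- c(pairs, paste(g[idx[1, ]], g[idx[2, ]], sep = "|"))
  }
  unique(pairs)
}

#' Compare a pipeline run against the planted truth
#'
#' @param run a `pipeline_run` from [run_pipeline()].
#' @param truth a truth bundle from [read_truth_bundle()] (or the
#'   in-memory `truth` entries of the generator bundles).
#' @return list report with `clusters` (pairwise co-membership
#'   precision/recall), `hits` (coordinate exactness), `palindromes`
#'   (planted-pair precision/recall), `modules` (adjusted Rand index)
#'   and `rates` (computed minus target per region) — each present only
#'   when the matching truth component is.  Empty truth gives an empty
#'   report.
#' @export
compare_to_truth <- function(run, truth) {
  report <- list()
  if (!length(truth)) return(report)
  known_genes <- run$catalog$genes$gene_id

  if (!is.null(truth$genome) && !is.null(truth$genome$clusters)) {
    tcl <- truth$genome$clusters
    truth_groups <- if (is.data.frame(tcl)) tcl$members else
      lapply(tcl, function(cl) unlist(cl$members))
    tg <- unlist(truth_groups)
    if (length(tg) && !all(tg %in% known_genes))
      stop("truth cluster members unknown to the run: ",
           paste(setdiff(tg, known_genes), collapse = ", "))
    tp_pairs <- co_membership_pairs(truth_groups)
    pp_pairs <- co_membership_pairs(run$clusters$clusters$members)
    inter <- intersect(tp_pairs, pp_pairs)
    report$clusters <- list(
      precision = if (length(pp_pairs)) length(inter) / length(pp_pairs)
                  else NA_real_,
      recall = if (length(tp_pairs)) length(inter) / length(tp_pairs)
               else NA_real_,
      n_truth_pairs = length(tp_pairs), n_pred_pairs = length(pp_pairs))
  }

  th <- truth$genome$promoter_hits
  if (!is.null(th) && NROW(th)) {
    th <- as.data.frame(th)
    if (!all(th$gene_id %in% known_genes))
      stop("truth hit genes unknown to the run: ",
           paste(setdiff(th$gene_id, known_genes), collapse = ", "))
    key <- function(d) paste(d$gene_id, d$motif_id, d$start_upstream,
                             d$end_upstream, d$strand, sep = "|")
    found <- key(th) %in% key(run$hits)
    report$hits <- list(n_truth = nrow(th), n_exact = sum(found),
                        n_mismatch = sum(!found),
                        exact_fraction = mean(found))
  }

  if (!is.null(truth$motifs)) {
    tp <- truth$motifs$planted_pairs
    motif_of <- stats::setNames(run$motif_map$motif_id, run$motif_map$tf_id)
    ed <- run$network$edges
    pred <- if (nrow(ed)) {
      a <- unname(motif_of[ed$tf_a]); b <- unname(motif_of[ed$tf_b])
      unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
    } else character(0)
    tpk <- if (!is.null(tp) && NROW(tp)) {
      tp <- as.data.frame(tp)
      unique(paste(pmin(tp$motif_a, tp$motif_b),
                   pmax(tp$motif_a, tp$motif_b), sep = "|"))
    } else character(0)
    inter <- intersect(pred, tpk)
    report$palindromes <- list(
      precision = if (length(pred)) length(inter) / length(pred)
                  else NA_real_,
      recall = if (length(tpk)) length(inter) / length(tpk) else NA_real_,
      n_truth_pairs = length(tpk), n_pred_pairs = length(pred))
  }

  if (!is.null(truth$expression) && !is.null(run$modules)) {
    tl <- unlist(truth$expression$modules)
    common <- intersect(names(tl)[tl != "low"], names(run$modules))
    if (!length(common)) stop("no genes shared between run modules and truth")
    report$modules <- list(
      ari = mclust::adjustedRandIndex(tl[common], run$modules[common]),
      n_genes = length(common))
  }

  if (!is.null(truth$variants) && !is.null(run$rates)) {
    tr <- unlist(truth$variants$target_rates)
    cr <- stats::setNames(run$rates$rate, run$rates$region)
    regions <- intersect(names(tr), names(cr))
    report$rates <- data.frame(
      region = regions, target = unname(tr[regions]),
      computed = unname(cr[regions]),
      delta = unname(cr[regions] - tr[regions]),
      stringsAsFactors = FALSE)
  }
  report
}

#' Simulate a complete coherent dataset
#'
#' Convenience wrapper wiring all generators together: a genome with
#' planted clusters, a motif library whose motifs (and decoys) are
#' assigned one-to-one to TF genes of matching count, planted promoter
#' occurrences, a TPM matrix over the TF genes plus filler genes, and a
#' planted-rate VCF.  Emits every input [run_pipeline()] needs plus the
#' truth files.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param genome_cfg,motif_cfg,expr_cfg,variant_cfg optional generator
#'   configurations; defaults are constructed from `seed`.
#' @param plant_hits data frame for [plant_promoter_hits()] or NULL.
#' @return list with the four generator bundles, the `motif_map` data
#'   frame and a ready [pipeline_config()].
#' @export
simulate_dataset <- function(out_dir, seed = 1,
                             genome_cfg = NULL, motif_cfg = NULL,
                             expr_cfg = NULL, variant_cfg = NULL,
                             plant_hits = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(genome_cfg)) {
    cluster_spec <- data.frame(chrom = c(1L, 1L, 2L), window = c(1L, 2L, 4L))
    cluster_spec$families <- list(c("F1", "F2"), c("F2", "F3"), c("F4", "F4"))
    genome_cfg <- genome_sim_config(cluster_spec = cluster_spec, seed = seed)
  }
  if (is.null(motif_cfg)) {
    pp <- data.frame(motif_i = c(1L, 3L, 5L), motif_j = c(2L, 4L, 5L),
                     half_site_length = c(4L, 3L, 4L))
    motif_cfg <- motif_sim_config(n_motifs = 10, planted_pairs = pp,
                                  n_decoys = 10, seed = seed)
  }
  gb <- gen_genome(genome_cfg, out_dir)
  mb <- gen_motif_library(motif_cfg, out_dir)

  tf_ids <- sort(gb$genes$gene_id[gb$genes$is_tf])
  n_lib <- length(mb$consensus)
  if (n_lib > length(tf_ids))
    stop("motif library larger than the TF complement")
  motif_map <- data.frame(tf_id = tf_ids[seq_len(n_lib)],
                          motif_id = names(mb$consensus),
                          stringsAsFactors = FALSE)
  map_path <- file.path(out_dir, "motif_map.tsv")
  write_tsv(motif_map, map_path)

  if (is.null(plant_hits)) {
    plant_hits <- data.frame(
      gene_id = motif_map$tf_id[1:3],
      motif_id = motif_map$motif_id[1:3],
      end_upstream = c(313L, 50L, 120L),
      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  }
  if (NROW(plant_hits)) gb <- plant_promoter_hits(gb, mb, plant_hits)

  if (is.null(expr_cfg)) expr_cfg <- expr_sim_config(seed = seed)
  ## name the first genes after TF genes so modules can intersect the
  ## cooperation network
  gene_ids <- c(tf_ids,
                sprintf("G%04d", seq_len(max(0, expr_cfg$n_genes -
                                                length(tf_ids)))))
  gene_ids <- gene_ids[seq_len(expr_cfg$n_genes)]
  eb <- gen_expression(expr_cfg, out_dir, gene_ids = gene_ids)

  if (is.null(variant_cfg)) variant_cfg <- variant_sim_config(seed = seed)
  vb <- gen_variants(gb, variant_cfg, out_dir)

  cfg <- pipeline_config(
    genome = gb$paths$genome, annotation = gb$paths$gff3,
    families = gb$paths$families, motifs = mb$paths$meme,
    motif_map = map_path, expression = eb$paths$tpm,
    metadata = eb$paths$metadata, vcf = vb$paths$vcf,
    out_dir = file.path(out_dir, "run"),
    min_module_size = 20, n_samples = variant_cfg$n_samples, seed = seed)
  list(genome = gb, motifs = mb, expression = eb, variants = vb,
       motif_map = motif_map, pipeline_config = cfg)
}
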