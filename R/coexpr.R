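## Co-expression analysis: TPM filtering, CV, soft-threshold adjacency,
## topological overlap, module detection by static tree cut with
## eigengene merging, and module-by-tissue profiles.

#' Co-expression configuration
#'
#' Holds the tunable parameters of the co-expression stage.
#'
#' @param tpm_min expression floor: a sample "expresses" a gene when
#'   TPM >= `tpm_min` (default 1).
#' @param low_fraction a gene is removed when the fraction of samples
#'   below `tpm_min` is at least this value (default 0.9).
#' @param powers candidate soft-threshold powers (default 1:20).
#' @param r2_min scale-free fit cutoff (default 0.9).
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram;
#'   `NULL` picks the height yielding the most modules of at least
#'   `min_module_size` genes.
#' @param min_module_size smallest admissible module (default 30).
#' @param merge_height eigengene dissimilarity below which modules are
#'   merged (default 0.25).
#' @param cv_convention `"sd_over_mean"` (standard) or `"mean_over_sd"`.
#' @return list of class `coexpr_config`.
#' @export
coexpr_config <- function(tpm_min = 1, low_fraction = 0.9, powers = 1:20,
                          r2_min = 0.9, cut_height = NULL,
                          min_module_size = 30, merge_height = 0.25,
                          cv_convention = c("sd_over_mean", "mean_over_sd")) {
  cv_convention <- match.arg(cv_convention)
  if (low_fraction <= 0 || low_fraction > 1) stop("low_fraction must be in (0,1]")
  if (r2_min <= 0 || r2_min > 1) stop("r2_min must be in (0,1]")
  if (merge_height < 0 || merge_height > 1) stop("merge_height must be in [0,1]")
  structure(list(tpm_min = tpm_min, low_fraction = low_fraction,
                 powers = powers, r2_min = r2_min, cut_height = cut_height,
                 min_module_size = min_module_size,
                 merge_height = merge_height,
                 cv_convention = cv_convention),
            class = "coexpr_config")
}

#' Filter genes with low expression across samples
#'
#' A gene is removed when its TPM is below `tpm_min` in at least
#' `low_fraction` of the samples.
#'
#' @param matrix numeric genes x samples TPM matrix (rownames = genes).
#' @param cfg a [coexpr_config()].
#' @return list with `matrix` (kept genes), `kept`, `removed` (gene id
#'   vectors).
#' @export
filter_low_expression <- function(matrix, cfg = coexpr_config()) {
  if (!nrow(matrix)) stop("empty expression matrix")
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  frac_low <- rowMeans(matrix < cfg$tpm_min)
  removed <- rownames(matrix)[frac_low >= cfg$low_fraction]
  kept <- setdiff(rownames(matrix), removed)
  if (!length(kept)) stop("all genes removed by the low-expression filter")
  list(matrix = matrix[kept, , drop = FALSE], kept = kept, removed = removed)
}

#' Per-gene expression coefficient of variation
#'
#' The default convention is SD/mean with the sample (n-1) standard
#' deviation; the reciprocal mean/SD convention is available via the
#' configuration (undefined for zero-variance genes, reported as NA).
#'
#' @inheritParams filter_low_expression
#' @return named numeric vector of CVs.
#' @export
expression_cv <- function(matrix, cfg = coexpr_config()) {
  if (ncol(matrix) < 2) stop("need >= 2 samples for a CV")
  m <- rowMeans(matrix)
  s <- apply(matrix, 1, stats::sd)
  if (cfg$cv_convention == "sd_over_mean") {
    s / m
  } else {
    out <- m / s
    out[s == 0] <- NA_real_
    out
  }
}

## unsigned soft-threshold adjacency |cor|^beta with zero diagonal
soft_adjacency <- function(matrix, beta) {
  if (any(apply(matrix, 1, stats::sd) == 0)) {
    stop("constant gene rows present; filter before building the network")
  }
  a <- abs(stats::cor(t(matrix)))^beta
  diag(a) <- 0
  a
}

## scale-free topology fit: R^2 of log10 p(k) vs log10 k over >= 10 bins
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(log10(km[ok]), log10(pk[ok]))^2
}

#' Pick the soft-threshold power for the co-expression network
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is
#' formed, connectivities summed, and the scale-free topology fit R^2
#' computed as the squared correlation of log10 p(k) against log10 k
#' over 10 connectivity bins.  The smallest power reaching `r2_min`
#' wins; if none does, the power maximizing R^2 is returned with a
#' warning.
#'
#' @inheritParams filter_low_expression
#' @return list with `beta`, `r2` (fit at the chosen power) and
#'   `fit_table` (power, r2, mean_k).
#' @export
pick_soft_power <- function(matrix, cfg = coexpr_config()) {
  if (nrow(matrix) < 20) stop("need >= 20 genes to assess scale-free fit")
  if (ncol(matrix) < 4) stop("need >= 4 samples")
  fits <- vapply(cfg$powers, function(b) {
    a <- soft_adjacency(matrix, b)
    k <- rowSums(a)
    c(r2 = scale_free_r2(k), mean_k = mean(k))
  }, numeric(2))
  tab <- data.frame(power = cfg$powers, r2 = fits["r2", ],
                    mean_k = fits["mean_k", ])
  ok <- which(!is.na(tab$r2) & tab$r2 >= cfg$r2_min)
  if (length(ok)) {
    i <- ok[1]
  } else {
    i <- which.max(tab$r2)
    warning("no candidate power reached the scale-free R2 cutoff; ",
            "using the best-fitting power ", tab$power[i])
  }
  list(beta = tab$power[i], r2 = tab$r2[i], fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal, computed from the unsigned soft-threshold adjacency.
#'
#' @inheritParams filter_low_expression
#' @param beta soft-threshold power (>= 1).
#' @return symmetric genes x genes TOM matrix with entries between 0 and 1.
#' @export
compute_tom <- function(matrix, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- soft_adjacency(matrix, beta)
  if (any(!is.finite(a))) stop("non-finite correlation in adjacency")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

## module eigengene: first principal component over samples of the
## standardized module expression, sign-oriented to correlate
## positively with the module mean expression; unit norm.
module_eigengene <- function(matrix) {
  z <- t(scale(t(matrix)))   # standardize each gene across samples
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  mprof <- colMeans(matrix)
  if (stats::sd(mprof) > 0 && stats::cor(e, mprof) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut
#' (at `cut_height`, or by default at the merge height yielding the
#' most clusters of at least `min_module_size` genes), assignment of
#' undersized clusters to the background, eigengene computation, and
#' iterative merging of module pairs whose eigengene dissimilarity
#' (1 - correlation) falls below `merge_height`.
#'
#' @param tom TOM matrix from [compute_tom()].
#' @param cfg a [coexpr_config()].
#' @param matrix the genes x samples expression matrix (same genes).
#' @param background_label label for unassigned genes.
#' @return list of class `module_set`: `modules` (named character
#'   vector gene -> module label `"M1"`, `"M2"`, ... or background),
#'   `eigengenes` (samples x modules matrix), `sizes`, `cut_height`.
#' @export
detect_modules <- function(tom, cfg = coexpr_config(), matrix,
                           background_label = "grey") {
  genes <- rownames(tom)
  if (nrow(tom) < cfg$min_module_size) {
    warning("fewer genes than min_module_size; single background module")
    labels <- stats::setNames(rep(background_label, nrow(tom)), genes)
    return(structure(list(modules = labels,
                          eigengenes = NULL,
                          sizes = integer(0), cut_height = NA_real_),
                     class = "module_set"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- cfg$cut_height
  if (is.null(cut_h)) {
    cand <- sort(unique(hc$height))
    n_valid <- vapply(cand, function(h) {
      cl <- stats::cutree(hc, h = h)
      sum(table(cl) >= cfg$min_module_size)
    }, integer(1))
    tied <- cand[n_valid == max(n_valid)]
    ## among heights tied on module count, cut at the lower edge of
    ## the widest gap between consecutive merge heights: module
    ## assembly finishes below the gap, stray attachments happen above
    cut_h <- if (length(tied) > 1) tied[which.max(diff(tied))] else tied
  }
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  valid <- names(sizes)[sizes >= cfg$min_module_size]
  labels <- stats::setNames(rep(background_label, length(genes)), genes)
  for (i in seq_along(valid)) {
    labels[names(cl)[cl == valid[i]]] <- paste0("M", i)
  }
  mods <- setdiff(unique(labels), background_label)
  if (!length(mods)) {
    warning("no cluster reached min_module_size; single background module")
    return(structure(list(modules = labels, eigengenes = NULL,
                          sizes = integer(0), cut_height = cut_h),
                     class = "module_set"))
  }
  eig <- sapply(mods, function(m)
    module_eigengene(matrix[names(labels)[labels == m], , drop = FALSE]))
  colnames(eig) <- mods

  ## iterative eigengene merge: closest pair below merge_height first
  repeat {
    mods <- colnames(eig)
    if (length(mods) < 2) break
    dis <- 1 - stats::cor(eig)
    diag(dis) <- Inf
    mn <- min(dis)
    if (mn >= cfg$merge_height) break
    ij <- which(dis == mn, arr.ind = TRUE)[1, ]
    keep <- mods[min(ij)]; drop <- mods[max(ij)]
    labels[labels == drop] <- keep
    eig <- eig[, setdiff(mods, drop), drop = FALSE]
    eig[, keep] <- module_eigengene(
      matrix[names(labels)[labels == keep], , drop = FALSE])
  }
  ## relabel modules in decreasing size order
  mods <- setdiff(unique(labels), background_label)
  sz <- vapply(mods, function(m) sum(labels == m), integer(1))
  new <- stats::setNames(paste0("M", seq_along(mods)),
                         mods[order(-sz, mods)])
  labels[labels != background_label] <- new[labels[labels != background_label]]
  final_mods <- paste0("M", seq_along(mods))
  eig2 <- vapply(final_mods, function(m)
    module_eigengene(matrix[names(labels)[labels == m], , drop = FALSE]),
    numeric(ncol(matrix)))
  eig2 <- matrix(eig2, ncol = length(final_mods),
                 dimnames = list(colnames(matrix), final_mods))
  structure(list(modules = labels, eigengenes = eig2,
                 sizes = vapply(colnames(eig2), function(m)
                   sum(labels == m), integer(1)),
                 cut_height = cut_h),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("<module_set> ", length(x$sizes), " modules; sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean module eigengene by tissue
#'
#' @param modules a `module_set` from [detect_modules()].
#' @param metadata data frame with columns `sample`, `tissue` matching
#'   the expression matrix columns.
#' @return list with `profile` (module x tissue matrix of mean
#'   eigengene values) and `top_tissue` (named character vector).
#' @export
module_tissue_profile <- function(modules, metadata) {
  if (is.null(modules$eigengenes)) stop("module set has no eigengenes")
  samples <- rownames(modules$eigengenes)
  tissue <- stats::setNames(as.character(metadata$tissue), metadata$sample)
  tl <- tissue[samples]
  if (anyNA(tl)) {
    stop("missing tissue label for sample(s): ",
         paste(samples[is.na(tl)], collapse = ", "))
  }
  tissues <- sort(unique(tl))
  prof <- t(vapply(colnames(modules$eigengenes), function(m) {
    vapply(tissues, function(tt)
      mean(modules$eigengenes[tl == tt, m]), numeric(1))
  }, numeric(length(tissues))))
  colnames(prof) <- tissues
  list(profile = prof,
       top_tissue = stats::setNames(
         tissues[apply(prof, 1, which.max)], rownames(prof)))
}
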