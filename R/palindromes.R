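## Reverse-complement palindrome detection between motif consensus
## sequences and the TF dimer-cooperation network built from it.

#' Find reverse-complement palindromes formed by two consensus sequences
#'
#' Two motif fragments "form a complete palindrome" when a fragment of
#' `cons_a` concatenated with a fragment of `cons_b` equals its own
#' reverse complement; equivalently the `cons_b` fragment is the reverse
#' complement of the `cons_a` fragment, both of length `k >= min_len/2`,
#' so the palindrome has even length `2k >= min_len`.
#'
#' @param cons_a,cons_b consensus strings over A,C,G,T.
#' @param min_len minimum palindrome length in bp (even, >= 2).
#' @return data frame of all matches with columns `offset_a`, `offset_b`
#'   (1-based), `k` (half length), `half_a`, `half_b`, `palindrome`,
#'   ordered by decreasing `k` (maximal matches first).  Zero rows when
#'   no fragment pair qualifies.
#' @export
find_palindromes <- function(cons_a, cons_b, min_len = 6) {
  if (min_len %% 2 != 0) {
    stop("min_len must be even: reverse-complement palindromes have even length")
  }
  if (min_len < 2) stop("min_len must be >= 2")
  assert_acgt(cons_a, "consensus A")
  assert_acgt(cons_b, "consensus B")
  kmin <- min_len %/% 2
  kmax <- min(nchar(cons_a), nchar(cons_b))
  out <- list()
  if (kmax >= kmin) {
    rc_b <- revcomp(cons_b)
    nb <- nchar(cons_b)
    for (k in seq.int(kmax, kmin)) {
      ka <- kmers(cons_a, k)
      kb <- kmers(rc_b, k)   # kb[j] = revcomp of cons_b substring at offset nb-k-j+2
      hits <- which(outer(ka, kb, "=="), arr.ind = TRUE)
      if (nrow(hits)) {
        offset_a <- hits[, 1]
        ## offset in rc_b -> offset in cons_b
        offset_b <- nb - k - hits[, 2] + 2L
        half_a <- ka[offset_a]
        half_b <- substring(cons_b, offset_b, offset_b + k - 1L)
        out[[length(out) + 1L]] <- data.frame(
          offset_a = offset_a, offset_b = offset_b, k = k,
          half_a = half_a, half_b = half_b,
          palindrome = paste0(half_a, half_b),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(offset_a = integer(), offset_b = integer(),
                      k = integer(), half_a = character(),
                      half_b = character(), palindrome = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$k, res$offset_a, res$offset_b), ]
  rownames(res) <- NULL
  res
}

#' Maximal palindrome half-length between two consensus sequences
#'
#' @inheritParams find_palindromes
#' @return integer, 0 when no palindrome of at least `min_len` exists.
#' @export
max_palindrome_k <- function(cons_a, cons_b, min_len = 6) {
  m <- find_palindromes(cons_a, cons_b, min_len)
  if (nrow(m) == 0) 0L else max(m$k)
}

#' Build the TF dimer-cooperation network from palindromic motif pairs
#'
#' Every unordered TF pair (optionally including self-pairs) whose
#' assigned motif consensus sequences can form a reverse-complement
#' palindrome of at least `min_len` bp becomes one edge, carrying the
#' maximal palindrome.  Edges are labeled within- or cross-family, and
#' per-family mean within- and cross-family degrees are computed over
#' all family members present in the network.
#'
#' @param tf_consensus data frame with columns `tf_id`, `family`,
#'   `consensus` (one row per TF carrying a motif).
#' @param min_len minimum palindrome length in bp.
#' @param include_self also test each TF against itself (self-loops).
#' @return a list of class `coop_network` with elements `nodes`,
#'   `edges` (tf_a, tf_b, family_a, family_b, max_palindrome_bp, half_a,
#'   offset_a, half_b, offset_b, within_family), `matches` (all
#'   sub-maximal matches per edge), and `family_degrees`.
#' @export
build_coop_network <- function(tf_consensus, min_len = 6, include_self = TRUE) {
  stopifnot(all(c("tf_id", "family", "consensus") %in% names(tf_consensus)))
  n <- nrow(tf_consensus)
  edges <- list()
  matches <- list()
  if (n > 0) {
    for (i in seq_len(n)) {
      j0 <- if (include_self) i else i + 1L
      if (j0 > n) next
      for (j in seq.int(j0, n)) {
        m <- find_palindromes(tf_consensus$consensus[i],
                              tf_consensus$consensus[j], min_len)
        if (nrow(m) == 0) next
        best <- m[1, ]
        edges[[length(edges) + 1L]] <- data.frame(
          tf_a = tf_consensus$tf_id[i], tf_b = tf_consensus$tf_id[j],
          family_a = tf_consensus$family[i], family_b = tf_consensus$family[j],
          max_palindrome_bp = 2L * best$k,
          half_a = best$half_a, offset_a = best$offset_a,
          half_b = best$half_b, offset_b = best$offset_b,
          within_family = tf_consensus$family[i] == tf_consensus$family[j],
          stringsAsFactors = FALSE)
        m$tf_a <- tf_consensus$tf_id[i]
        m$tf_b <- tf_consensus$tf_id[j]
        matches[[length(matches) + 1L]] <- m
      }
    }
  }
  empty_edges <- data.frame(tf_a = character(), tf_b = character(),
                            family_a = character(), family_b = character(),
                            max_palindrome_bp = integer(),
                            half_a = character(), offset_a = integer(),
                            half_b = character(), offset_b = integer(),
                            within_family = logical(), stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges
  matches <- if (length(matches)) do.call(rbind, matches) else NULL
  fam_deg <- family_degrees(tf_consensus, edges)
  structure(list(nodes = tf_consensus[, c("tf_id", "family")],
                 edges = edges, matches = matches,
                 family_degrees = fam_deg),
            class = "coop_network")
}

## per-family mean within-family and cross-family degree.
## A self-loop contributes 1 to its TF's within-family degree.
family_degrees <- function(nodes, edges) {
  deg_w <- stats::setNames(numeric(nrow(nodes)), nodes$tf_id)
  deg_c <- deg_w
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges$tf_a[r]; b <- edges$tf_b[r]
      if (edges$within_family[r]) {
        deg_w[a] <- deg_w[a] + 1
        if (a != b) deg_w[b] <- deg_w[b] + 1
      } else {
        deg_c[a] <- deg_c[a] + 1
        deg_c[b] <- deg_c[b] + 1
      }
    }
  }
  fams <- sort(unique(nodes$family))
  data.frame(
    family = fams,
    n_members = vapply(fams, function(f) sum(nodes$family == f), integer(1)),
    mean_within_degree = vapply(fams, function(f)
      mean(deg_w[nodes$tf_id[nodes$family == f]]), numeric(1)),
    mean_cross_degree = vapply(fams, function(f)
      mean(deg_c[nodes$tf_id[nodes$family == f]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.coop_network <- function(x, ...) {
  cat("<coop_network> ", nrow(x$nodes), " TFs, ", nrow(x$edges),
      " palindromic pairs\n", sep = "")
  invisible(x)
}

#' Intersect the cooperation network with co-expression modules
#'
#' Keeps the edges whose two endpoints belong to the same non-background
#' co-expression module (self-loops are kept when the TF is in a
#' module), and reports the connected components of the kept subgraph as
#' co-expressed cooperation sets.
#'
#' @param network a `coop_network` from [build_coop_network()].
#' @param module_map named character vector or data frame
#'   (`gene_id`, `module`) mapping TFs to module labels; the background
#'   label marks unassigned genes.
#' @param background_label module label treated as unassigned.
#' @return list with `edges` (kept subset, plus `module` column), `sets`
#'   (data frame set_id, tf_id, degree, set_size).  Degree counts a
#'   self-loop once.
#' @export
intersect_with_modules <- function(network, module_map,
                                   background_label = "grey") {
  if (is.data.frame(module_map)) {
    module_map <- stats::setNames(as.character(module_map$module),
                                  module_map$gene_id)
  }
  if (!length(module_map)) {
    warning("empty module map; no co-expressed pairs")
    return(list(edges = cbind(network$edges[0, ],
                              module = character(0)),
                sets = data.frame(set_id = integer(), tf_id = character(),
                                  degree = integer(), set_size = integer(),
                                  stringsAsFactors = FALSE)))
  }
  ed <- network$edges
  mod_a <- unname(module_map[ed$tf_a])
  mod_b <- unname(module_map[ed$tf_b])
  keep <- !is.na(mod_a) & !is.na(mod_b) & mod_a == mod_b &
    mod_a != background_label
  kept <- ed[keep, , drop = FALSE]
  kept$module <- mod_a[keep]
  rownames(kept) <- NULL
  if (nrow(kept) == 0) {
    return(list(edges = kept,
                sets = data.frame(set_id = integer(), tf_id = character(),
                                  degree = integer(), set_size = integer(),
                                  stringsAsFactors = FALSE)))
  }
  g <- igraph::graph_from_data_frame(kept[, c("tf_a", "tf_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  ## degree counting each incident kept edge once (self-loop = 1)
  vs <- igraph::V(g)$name
  deg <- vapply(vs, function(v)
    sum(kept$tf_a == v | kept$tf_b == v), integer(1))
  sets <- data.frame(set_id = unname(comp$membership[vs]),
                     tf_id = vs,
                     degree = unname(deg),
                     stringsAsFactors = FALSE)
  sizes <- table(sets$set_id)
  sets$set_size <- as.integer(sizes[as.character(sets$set_id)])
  sets <- sets[order(sets$set_id, sets$tf_id), ]
  rownames(sets) <- NULL
  list(edges = kept, sets = sets)
}
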