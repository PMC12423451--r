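## MEME minimal motif format IO and the MotifPWM container.

#' Construct a position probability matrix motif
#'
#' A `motif_pwm` holds a position probability matrix (PPM) over A,C,G,T,
#' the background letter frequencies used for log-odds scoring, and an
#' optional source TF identifier (the reference TF the motif was derived
#' from).
#'
#' @param motif_id character scalar, unique motif identifier.
#' @param matrix numeric L x 4 matrix of probabilities; columns A,C,G,T.
#'   Each row must sum to 1 within 1e-6.
#' @param background numeric length-4 vector of background frequencies
#'   (default uniform).
#' @param source_tf_id optional source TF identifier.
#' @return an object of class `motif_pwm`.
#' @export
motif_pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                      source_tf_id = NA_character_) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 1) stop("PWM must have width >= 1")
  if (any(matrix < 0)) stop("PWM probabilities must be >= 0")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("motif '", motif_id, "': PWM row(s) ",
         paste(which(abs(rs - 1) > 1e-6), collapse = ","),
         " do not sum to 1 within 1e-6")
  }
  colnames(matrix) <- DNA_BASES
  structure(list(motif_id = motif_id, width = nrow(matrix),
                 matrix = matrix, background = background,
                 source_tf_id = source_tf_id),
            class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat("<motif_pwm> ", x$motif_id, " width=", x$width, "\n", sep = "")
  invisible(x)
}

#' Build a one-hot (deterministic) PWM from a consensus sequence
#'
#' Each position puts probability 1 on the consensus letter. Used for
#' planting exact motif occurrences and for worked examples.
#'
#' @param motif_id motif identifier.
#' @param sequence DNA string over A,C,G,T.
#' @inheritParams motif_pwm
#' @return a `motif_pwm`.
#' @export
one_hot_pwm <- function(motif_id, sequence, background = rep(0.25, 4)) {
  assert_acgt(sequence, "consensus")
  ch <- chars(sequence)
  m <- matrix(0, nrow = length(ch), ncol = 4, dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(ch), match(ch, DNA_BASES))] <- 1
  motif_pwm(motif_id, m, background = background)
}

## reverse complement of a PWM: reverse rows, swap A<->T, C<->G columns
revcomp_pwm <- function(pwm) {
  m <- pwm$matrix[rev(seq_len(pwm$width)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- DNA_BASES
  motif_pwm(paste0(pwm$motif_id, "_rc"), m, background = pwm$background,
            source_tf_id = pwm$source_tf_id)
}

#' Read motifs from a MEME minimal format file
#'
#' Parses the MEME minimal motif format (version line, optional alphabet,
#' strand and background lines, then `MOTIF` blocks with
#' `letter-probability matrix` sections).
#'
#' @param path path to a MEME format file.
#' @return a named list of [motif_pwm()] objects (possibly empty).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  background <- rep(0.25, 4)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "Background letter frequencies")) {
      ## frequencies are on the following line(s)
      j <- i + 1L
      toks <- character(0)
      while (j <= n && !startsWith(trimws(lines[[j]]), "MOTIF") &&
             nzchar(trimws(lines[[j]]))) {
        toks <- c(toks, strsplit(trimws(lines[[j]]), "\\s+")[[1]])
        j <- j + 1L
      }
      if (length(toks) >= 8) {
        vals <- suppressWarnings(as.numeric(toks[seq(2, 8, 2)]))
        lets <- toks[seq(1, 7, 2)]
        if (!anyNA(vals) && identical(lets, DNA_BASES)) background <- vals
      }
      i <- j
      next
    }
    if (startsWith(ln, "MOTIF")) {
      toks <- strsplit(ln, "\\s+")[[1]]
      motif_id <- toks[2]
      alt <- if (length(toks) >= 3) toks[3] else NA_character_
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", trimws(lines[[j]]))) {
        if (startsWith(trimws(lines[[j]]), "MOTIF")) {
          stop("motif '", motif_id, "': no letter-probability matrix")
        }
        j <- j + 1L
      }
      if (j > n) stop("motif '", motif_id, "': no letter-probability matrix")
      hdr <- trimws(lines[[j]])
      w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr)))
      j <- j + 1L
      rows <- list()
      while (j <= n) {
        rl <- trimws(lines[[j]])
        if (!nzchar(rl) || startsWith(rl, "MOTIF") || grepl("^URL", rl)) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "\\s+")[[1]]))
        if (anyNA(vals) || length(vals) != 4) break
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      m <- do.call(rbind, rows)
      if (!is.na(w) && nrow(m) != w) {
        stop("motif '", motif_id, "': matrix has ", nrow(m),
             " rows but header says w=", w)
      }
      motifs[[motif_id]] <- motif_pwm(motif_id, m, background = background,
                                      source_tf_id = alt)
      i <- j
      next
    }
    i <- i + 1L
  }
  motifs
}

#' Write motifs to a MEME minimal format file
#'
#' @param motifs a list of [motif_pwm()] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_meme <- function(motifs, path) {
  bg <- if (length(motifs)) motifs[[1]]$background else rep(0.25, 4)
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(DNA_BASES, fmt_num(bg, 6), collapse = " "),
           "")
  for (m in motifs) {
    src <- if (!is.na(m$source_tf_id)) paste0(" ", m$source_tf_id) else ""
    out <- c(out,
             paste0("MOTIF ", m$motif_id, src),
             paste0("letter-probability matrix: alength= 4 w= ", m$width,
                    " nsites= 20 E= 0"),
             apply(m$matrix, 1, function(r) paste(fmt_num(r, 6), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Consensus string of a PWM
#'
#' Per column the letter of maximal probability; ties broken by the fixed
#' order A < C < G < T.
#'
#' @param pwm a [motif_pwm()].
#' @return a list with `motif_id` and `consensus` (character scalar).
#' @export
consensus <- function(pwm) {
  idx <- apply(pwm$matrix, 1, which.max)  # which.max takes the first max: A<C<G<T
  list(motif_id = pwm$motif_id,
       consensus = paste(DNA_BASES[idx], collapse = ""))
}
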