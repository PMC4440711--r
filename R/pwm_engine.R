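# P3-P2' window around the bond after residue i covers residues i-2 .. i+2
# (Schechter-Berger: P3 P2 P1 | P1' P2'). A full window exists for
# 3 <= i <= nchar(seq) - 2.
window_at <- function(sequence, cleavage_index) {
  substring(sequence, cleavage_index - 2L, cleavage_index + 2L)
}

has_full_window <- function(sequence, cleavage_index) {
  cleavage_index >= 3L & cleavage_index <= nchar(sequence) - 2L
}

#' Foreground and background residue frequencies
#'
#' Aligns substrates along the scissile bond and tabulates, for each of the
#' five P3-P2' subsites, the relative frequency of each residue over all
#' substrates contributing a full window. Foreground frequencies are later
#' normalised by the residue composition of the background peptide set, which
#' has no cleavage alignment: by default its pooled composition is broadcast
#' to all five columns (`background = "pooled"`); `"positional"` instead pools
#' per-column counts over every full 5-residue window of each background
#' peptide.
#'
#' @param substrates a `substrate_set` data frame.
#' @param background a `background_set`.
#' @param background_mode `"pooled"` (default) or `"positional"`.
#' @param quiet suppress the excluded-substrate message.
#' @return A `frequency_matrix`: list with `P` (20 x 5 column-stochastic
#'   matrix), `Pbckgr` (20 x 5, columns identical in pooled mode),
#'   `n_substrates` (contributing count) and `n_excluded`.
#' @export
compute_frequencies <- function(substrates, background,
                                background_mode = c("pooled", "positional"),
                                quiet = FALSE) {
  background_mode <- match.arg(background_mode)
  usable <- has_full_window(substrates$sequence, substrates$cleavage_index)
  n_excl <- sum(!usable)
  if (n_excl > 0L && !quiet)
    message(n_excl, " substrate(s) lack a full P3-P2' window and were excluded")
  sub <- substrates[usable, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no substrate has a full P3-P2' window", call. = FALSE)

  windows <- window_at(sub$sequence, sub$cleavage_index)
  P <- matrix(0, 20L, 5L, dimnames = list(AA_ALPHABET, SUBSITES))
  chars <- do.call(rbind, strsplit(windows, ""))
  for (j in 1:5) {
    tab <- table(factor(chars[, j], levels = AA_ALPHABET))
    P[, j] <- as.numeric(tab) / nrow(sub)
  }

  Pb <- matrix(0, 20L, 5L, dimnames = list(AA_ALPHABET, SUBSITES))
  if (background_mode == "pooled") {
    all_res <- unlist(strsplit(background$peptides, ""))
    tab <- table(factor(all_res, levels = AA_ALPHABET))
    comp <- as.numeric(tab) / length(all_res)
    Pb[] <- comp
  } else {
    counts <- matrix(0, 20L, 5L, dimnames = list(AA_ALPHABET, SUBSITES))
    for (pep in background$peptides) {
      n <- nchar(pep)
      if (n < 5L) next
      ch <- strsplit(pep, "")[[1]]
      for (start in 1:(n - 4L)) {
        idx <- match(ch[start:(start + 4L)], AA_ALPHABET)
        for (j in 1:5) counts[idx[j], j] <- counts[idx[j], j] + 1
      }
    }
    if (any(colSums(counts) == 0))
      stop("background peptides too short for positional composition",
           call. = FALSE)
    Pb <- sweep(counts, 2, colSums(counts), "/")
  }
  if (any(Pb == 0))
    stop("background coverage: residue(s) ",
         paste(AA_ALPHABET[rowSums(Pb == 0) > 0], collapse = ", "),
         " absent from the background set", call. = FALSE)

  fm <- list(P = P, Pbckgr = Pb, n_substrates = nrow(sub), n_excluded = n_excl)
  class(fm) <- "frequency_matrix"
  fm
}

#' Construct a position weight matrix object
#'
#' Low-level constructor used by [build_pwm()] and [read_pwm_file()]. Derives
#' the minimal and maximal achievable window scores as the sums of per-column
#' minima and maxima.
#'
#' @param M 20 x 5 numeric matrix of log2 values, rows named by residue,
#'   columns P3..P2'.
#' @param offset log2 penalty substituted where a residue was unobserved.
#' @param threshold decision cutoff: a bond scoring `>= threshold` is
#'   predicted cleaved.
#' @param enzyme enzyme identifier.
#' @return a `pwm` object.
#' @export
pwm <- function(M, offset, threshold, enzyme = "enzyme") {
  stopifnot(is.matrix(M), nrow(M) == 20L, ncol(M) == 5L, is.numeric(M))
  if (!all(is.finite(M))) stop("non-finite PWM element", call. = FALSE)
  M <- M[AA_ALPHABET, ]
  colnames(M) <- SUBSITES
  score_min <- sum(apply(M, 2, min))
  score_max <- sum(apply(M, 2, max))
  if (score_min >= score_max)
    stop("degenerate PWM: score_min >= score_max (matrix carries no signal)",
         call. = FALSE)
  obj <- list(enzyme = enzyme, M = M, offset = offset, threshold = threshold,
              score_min = score_min, score_max = score_max)
  class(obj) <- "pwm"
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  threshold %.3f  offset %.3f  score range [%.3f, %.3f]\n",
              x$enzyme, x$threshold, x$offset, x$score_min, x$score_max))
  invisible(x)
}

#' Build a PWM from frequency tables
#'
#' Each matrix element is the log2 ratio of the foreground to the background
#' frequency of that residue at that subsite. Where the foreground frequency
#' is zero (the residue was never observed at that subsite in training) the
#' `offset` penalty is substituted — no pseudocounts are applied.
#'
#' @param freq a `frequency_matrix` from [compute_frequencies()].
#' @param offset substitution penalty in log2 units (negative by convention).
#' @param threshold decision cutoff in log2 units.
#' @param enzyme enzyme identifier.
#' @return a [pwm] object.
#' @export
build_pwm <- function(freq, offset, threshold, enzyme = "enzyme") {
  stopifnot(inherits(freq, "frequency_matrix"))
  if (any(freq$Pbckgr <= 0))
    stop("background frequencies must be strictly positive", call. = FALSE)
  M <- ifelse(freq$P > 0, log2(freq$P / freq$Pbckgr), offset)
  dimnames(M) <- dimnames(freq$P)
  pwm(M, offset = offset, threshold = threshold, enzyme = enzyme)
}

#' Score a P3-P2' window
#'
#' The score of a peptide bond is the sum over the five subsites of the PWM
#' entry for the residue found there. Windows containing a nonstandard
#' residue are unscorable and yield `NA` (distinct from any low score).
#'
#' @param x a [pwm].
#' @param window character vector of 5-residue windows.
#' @return numeric vector of scores (`NA` where unscorable).
#' @export
score_window <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  if (any(nchar(window) != 5L))
    stop("score_window requires 5-residue windows", call. = FALSE)
  vapply(window, function(w) {
    idx <- match(strsplit(w, "")[[1]], AA_ALPHABET)
    if (anyNA(idx)) return(NA_real_)
    sum(x$M[cbind(idx, 1:5)])
  }, numeric(1), USE.NAMES = FALSE)
}

# 10-residue context around the bond after residue i, '-'-padded at termini.
context10 <- function(sequence, cleavage_index) {
  n <- nchar(sequence)
  vapply(cleavage_index, function(i) {
    left <- substr(sequence, max(1L, i - 4L), i)
    right <- substr(sequence, i + 1L, min(n, i + 5L))
    paste0(strrep("-", 5L - nchar(left)), left, right,
           strrep("-", 5L - nchar(right)))
  }, character(1))
}

#' Scan a protein sequence for candidate cleavage sites
#'
#' Scores every peptide bond with a full P3-P2' window (P1 positions 3 to
#' `nchar(sequence) - 2`). Bonds whose window touches a nonstandard residue
#' are skipped with a warning.
#'
#' @param x a [pwm].
#' @param sequence amino-acid string.
#' @param sequence_id identifier carried into the result.
#' @return A `scored_sites` data frame: `sequence_id`, `p1_position` (1-based
#'   index of the P1 residue), `window`, `context10`, `score`,
#'   `above_threshold` (`score >= threshold`), ordered by position.
#' @export
scan_sequence <- function(x, sequence, sequence_id = "seq") {
  stopifnot(inherits(x, "pwm"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- data.frame(sequence_id = character(0), p1_position = integer(0),
                      window = character(0), context10 = character(0),
                      score = numeric(0), above_threshold = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("scored_sites", "data.frame")
  if (n < 5L) {
    warning("sequence '", sequence_id, "' shorter than 5 residues: no scorable bond")
    return(empty)
  }
  pos <- 3:(n - 2L)
  win <- window_at(sequence, pos)
  sc <- score_window(x, win)
  if (anyNA(sc)) {
    warning(sum(is.na(sc)), " window(s) in '", sequence_id,
            "' contain nonstandard residues and were skipped")
    keep <- !is.na(sc)
    pos <- pos[keep]; win <- win[keep]; sc <- sc[keep]
  }
  out <- data.frame(sequence_id = rep(sequence_id, length(pos)),
                    p1_position = pos, window = win,
                    context10 = context10(sequence, pos),
                    score = sc, above_threshold = sc >= x$threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("scored_sites", "data.frame")
  out
}

#' Label and score every bond of annotated substrate peptides
#'
#' For peptide-level evaluation: the annotated scissile bond of each
#' substrate is the positive case and every other scorable full-window bond
#' of the same peptide (constant flanks included) is a negative case.
#' Substrates whose annotated bond lacks a full window contribute negatives
#' only.
#'
#' @param x a [pwm].
#' @param substrates a `substrate_set` data frame.
#' @param quiet suppress the message about positives without a full window.
#' @return data frame with `substrate` (row index), `p1_position`, `score`,
#'   `label` (1 positive / 0 negative).
#' @export
classify_bonds <- function(x, substrates, quiet = TRUE) {
  out <- vector("list", nrow(substrates))
  n_dropped <- 0L
  for (i in seq_len(nrow(substrates))) {
    s <- substrates$sequence[[i]]
    ci <- substrates$cleavage_index[[i]]
    sites <- suppressWarnings(scan_sequence(x, s, sequence_id = as.character(i)))
    if (nrow(sites) == 0L) next
    lab <- as.integer(sites$p1_position == ci)
    if (!has_full_window(s, ci)) n_dropped <- n_dropped + 1L
    out[[i]] <- data.frame(substrate = i, p1_position = sites$p1_position,
                           score = sites$score, label = lab)
  }
  if (n_dropped > 0L && !quiet)
    message(n_dropped, " annotated bond(s) lack a full window; ",
            "those substrates contribute negatives only")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(substrate = integer(0), p1_position = integer(0),
                      score = numeric(0), label = integer(0))
  res
}
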