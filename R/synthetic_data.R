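#' Specification of a simulated phage-display substrate library
#'
#' Emulates the phage construct used to profile MMP specificity: a variable
#' hexamer flanked by the constant sequences `ggsg` and `tasgaet`, cleaved
#' inside the variable region. The planted cleavage motif is given as five
#' probability vectors over the 20 residues for the P3-P2' subsites of the
#' designated bond; remaining variable residues are drawn uniformly (or from
#' `background_composition`).
#'
#' @param columns 20 x 5 matrix of per-subsite residue probabilities (rows
#'   named by residue, columns P3..P2'), or a 5-character consensus string
#'   (e.g. `"PSALD"`) expanded to deterministic columns. Each column must sum
#'   to 1.
#' @param flank_n,flank_c constant flank sequences.
#' @param hexamer_len variable-region length.
#' @param cleavage_pos position of the scissile bond within the hexamer
#'   (bond after this hexamer residue; default 3, as in `PSA-LDA`).
#' @param n_substrates,n_background set sizes (defaults 300 and 766, the
#'   scale of one enzyme's phage-display training data).
#' @param background_composition optional 20-vector of residue probabilities
#'   for variable regions without the motif (default uniform).
#' @param seed integer seed.
#' @return a `motif_spec` list.
#' @export
motif_spec <- function(columns = "PSALD", flank_n = "ggsg",
                       flank_c = "tasgaet", hexamer_len = 6L,
                       cleavage_pos = 3L, n_substrates = 300L,
                       n_background = 766L, background_composition = NULL,
                       seed = 1L) {
  if (is.character(columns)) {
    stopifnot(nchar(columns) == 5L)
    res <- strsplit(toupper(columns), "")[[1]]
    stopifnot(all(res %in% AA_ALPHABET))
    cm <- matrix(0, 20L, 5L, dimnames = list(AA_ALPHABET, SUBSITES))
    for (j in 1:5) cm[res[[j]], j] <- 1
    columns <- cm
  }
  stopifnot(is.matrix(columns), nrow(columns) == 20L, ncol(columns) == 5L,
            all(columns >= 0))
  rownames(columns) <- AA_ALPHABET
  colnames(columns) <- SUBSITES
  if (any(abs(colSums(columns) - 1) > 1e-9))
    stop("each motif column must sum to 1", call. = FALSE)
  if (is.null(background_composition))
    background_composition <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  stopifnot(length(background_composition) == 20L,
            abs(sum(background_composition) - 1) < 1e-9)
  # P3..P2' of the designated bond must fall inside the hexamer
  stopifnot(cleavage_pos - 2L >= 1L, cleavage_pos + 2L <= hexamer_len)
  spec <- list(columns = columns, flank_n = toupper(flank_n),
               flank_c = toupper(flank_c), hexamer_len = as.integer(hexamer_len),
               cleavage_pos = as.integer(cleavage_pos),
               n_substrates = as.integer(n_substrates),
               n_background = as.integer(n_background),
               background_composition = background_composition,
               seed = as.integer(seed))
  class(spec) <- "motif_spec"
  spec
}

#' Residue composition of the full simulated peptide scaffold
#'
#' Expected composition of a generated peptide: constant flank residues plus
#' the variable region drawn from `background_composition`. Planting this as
#' the motif columns of a [motif_spec()] yields a null library in which the
#' foreground window distribution equals the background composition, so the
#' trained matrix carries no signal — the no-information control for
#' cross-validated F1.
#'
#' @param spec a [motif_spec()].
#' @return named 20-vector of residue probabilities summing to 1.
#' @export
scaffold_composition <- function(spec) {
  stopifnot(inherits(spec, "motif_spec"))
  flank <- strsplit(paste0(spec$flank_n, spec$flank_c), "")[[1]]
  counts <- table(factor(flank, levels = AA_ALPHABET))
  len <- length(flank) + spec$hexamer_len
  comp <- (as.numeric(counts) +
             spec$hexamer_len * spec$background_composition) / len
  stats::setNames(comp, AA_ALPHABET)
}

draw_residues <- function(n, prob) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = prob)
}

#' Generate cleavage-annotated substrates with a planted motif
#'
#' Each substrate is `flank_n + hexamer + flank_c` with the P3-P2' residues
#' of the designated bond drawn column-wise from `spec$columns` and the
#' remaining variable residues drawn from the background composition. The
#' cleavage index is set at the designated bond. Reproducible under
#' `spec$seed`.
#'
#' @param spec a [motif_spec()].
#' @param enzyme enzyme label for the records.
#' @return a `substrate_set` data frame.
#' @export
generate_substrates <- function(spec, enzyme = "synthetic") {
  stopifnot(inherits(spec, "motif_spec"))
  if (spec$n_substrates == 0L)
    return(substrate_table(list())[0, , drop = FALSE])
  motif_start <- spec$cleavage_pos - 2L   # hexamer index of P3
  with_seed(spec$seed, {
    recs <- vector("list", spec$n_substrates)
    for (i in seq_len(spec$n_substrates)) {
      hex <- draw_residues(spec$hexamer_len, spec$background_composition)
      for (j in 1:5)
        hex[motif_start + j - 1L] <- draw_residues(1L, spec$columns[, j])
      rec <- list(enzyme = enzyme,
                  sequence = paste0(spec$flank_n, paste(hex, collapse = ""),
                                    spec$flank_c),
                  cleavage_index = nchar(spec$flank_n) + spec$cleavage_pos,
                  source_tag = "synthetic")
      class(rec) <- "substrate_record"
      recs[[i]] <- rec
    }
    substrate_table(recs)
  })
}

#' Generate motif-free background peptides
#'
#' Same flank scaffold with fully random variable regions (uniform by
#' default, or `spec$background_composition`).
#'
#' @param spec a [motif_spec()].
#' @return a `background_set`.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "motif_spec"))
  with_seed(spec$seed + 1L, {
    peps <- vapply(seq_len(spec$n_background), function(i)
      paste0(spec$flank_n,
             paste(draw_residues(spec$hexamer_len, spec$background_composition),
                   collapse = ""),
             spec$flank_c),
      character(1))
    background_set(peps, name = "synthetic-background")
  })
}

#' Write a simulated library to disk in the substrate-table dialect
#'
#' Emits the substrate TSV (dash notation plus enzyme column), the
#' background TSV, and a small key-value provenance file recording the
#' generator settings.
#'
#' @param spec a [motif_spec()].
#' @param dir output directory (created if absent).
#' @param enzyme enzyme label.
#' @return invisible character vector of the three file paths.
#' @export
write_simulated_library <- function(spec, dir, enzyme = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- generate_substrates(spec, enzyme = enzyme)
  bg <- generate_background(spec)
  sub_path <- file.path(dir, "substrates.tsv")
  bg_path <- file.path(dir, "background.tsv")
  spec_path <- file.path(dir, "motif_spec.txt")
  lines <- vapply(seq_len(nrow(subs)), function(i) {
    rec <- list(sequence = subs$sequence[[i]],
                cleavage_index = subs$cleavage_index[[i]])
    paste(format_substrate(rec), subs$enzyme[[i]], sep = "\t")
  }, character(1))
  writeLines(c("# simulated phage-display substrates", lines), sub_path)
  writeLines(c("# simulated background peptides", bg$peptides), bg_path)
  consensus <- apply(spec$columns, 2, function(p) AA_ALPHABET[which.max(p)])
  writeLines(c(
    sprintf("flank_n\t%s", spec$flank_n),
    sprintf("flank_c\t%s", spec$flank_c),
    sprintf("hexamer_len\t%d", spec$hexamer_len),
    sprintf("cleavage_pos\t%d", spec$cleavage_pos),
    sprintf("n_substrates\t%d", spec$n_substrates),
    sprintf("n_background\t%d", spec$n_background),
    sprintf("seed\t%d", spec$seed),
    sprintf("motif_argmax\t%s", paste(consensus, collapse = ""))), spec_path)
  invisible(c(sub_path, bg_path, spec_path))
}
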