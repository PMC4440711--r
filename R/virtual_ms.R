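# Standard monoisotopic residue masses (Da, 6 dp); water added per peptide.
MONOISOTOPIC_RESIDUE_MASS <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414)
MONOISOTOPIC_WATER <- 18.010565

#' Normalise a PWM score to a cleavage-efficiency weight
#'
#' Linear rescaling of a window score onto `[0, 1]` between the minimal and
#' maximal achievable scores of the matrix, clipped at both ends.
#'
#' @param x a [pwm].
#' @param score numeric window score(s).
#' @return weight(s) in `[0, 1]`.
#' @export
normalize_score <- function(x, score) {
  stopifnot(inherits(x, "pwm"))
  if (x$score_max <= x$score_min)
    stop("degenerate PWM: score range is empty", call. = FALSE)
  pmin(1, pmax(0, (score - x$score_min) / (x$score_max - x$score_min)))
}

#' Monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus one water
#' (18.010565 Da). Uncharged, unmodified.
#'
#' @param residues character vector of peptide strings (standard residues
#'   only).
#' @return monoisotopic neutral mass(es) in Da.
#' @export
fragment_mass <- function(residues) {
  vapply(residues, function(s) {
    m <- MONOISOTOPIC_RESIDUE_MASS[strsplit(toupper(s), "")[[1]]]
    if (anyNA(m))
      stop("nonstandard residue in '", s, "'", call. = FALSE)
    sum(m) + MONOISOTOPIC_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Virtual mass spectrum of a predicted digest
#'
#' Fragment boundaries are the protein termini plus every predicted cleavage
#' site. In `"partial"` digestion mode (default) one fragment is produced for
#' every ordered boundary pair — with n sites, (n+1)(n+2)/2 fragments; in
#' `"complete"` mode only adjacent boundary pairs are kept. Each fragment's
#' intensity is `100 * ws1 * ws2`, where ws1/ws2 are the normalised PWM
#' scores of its N- and C-side cleavage events ([normalize_score()]); at the
#' protein termini the weight is 1.
#'
#' @param x a [pwm].
#' @param sequence protein sequence (standard residues only).
#' @param sites a `scored_sites` data frame of predicted (above-threshold)
#'   sites from [scan_sequence()]; rows with `above_threshold == FALSE` are
#'   dropped.
#' @param mode `"partial"` or `"complete"` digestion.
#' @return A `mass_spectrum` data frame sorted by mass: `start`, `end`
#'   (1-based inclusive residue span), `sequence`, `mass` (Da), `ws1`, `ws2`,
#'   `intensity`.
#' @export
virtual_spectrum <- function(x, sequence, sites, mode = c("partial", "complete")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "pwm"))
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  sites <- sites[sites$above_threshold, , drop = FALSE]
  cut_pos <- sort(unique(sites$p1_position))
  # boundary b = number of residues N-terminal of the cut; termini are 0 and n
  boundaries <- c(0L, cut_pos, n)
  w <- c(1, normalize_score(x, sites$score[match(cut_pos, sites$p1_position)]), 1)
  nb <- length(boundaries)
  pairs <- if (mode == "partial") {
    which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  } else {
    cbind(seq_len(nb - 1L), 2:nb)
  }
  frag_seq <- substring(sequence, boundaries[pairs[, 1]] + 1L,
                        boundaries[pairs[, 2]])
  out <- data.frame(
    start = boundaries[pairs[, 1]] + 1L,
    end = boundaries[pairs[, 2]],
    sequence = frag_seq,
    mass = fragment_mass(frag_seq),
    ws1 = w[pairs[, 1]],
    ws2 = w[pairs[, 2]],
    stringsAsFactors = FALSE)
  out$intensity <- 100 * out$ws1 * out$ws2
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mass_spectrum", "data.frame")
  out
}

#' Write a virtual mass spectrum as TSV
#'
#' Columns `start`, `end`, `sequence`, `mass` (6 dp), `intensity` (2 dp).
#'
#' @param spectrum a `mass_spectrum` data frame.
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @export
write_spectrum <- function(spectrum, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines("start\tend\tsequence\tmass\tintensity", con)
  if (nrow(spectrum) > 0L)
    writeLines(sprintf("%d\t%d\t%s\t%.6f\t%.2f", spectrum$start, spectrum$end,
                       spectrum$sequence, spectrum$mass, spectrum$intensity),
               con)
  invisible(path)
}
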