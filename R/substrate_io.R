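# Canonical 20-letter amino acid alphabet and subsite column labels.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
SUBSITES <- c("P3", "P2", "P1", "P1'", "P2'")

#' Parse a dash-annotated phage-display substrate line
#'
#' Phage-display substrate peptides are written with lowercase constant flanks
#' around an uppercase variable region, with a single dash marking the scissile
#' bond, e.g. `"ggsgPSA-LDAtasgaet"`. The dash is removed, the sequence is
#' uppercased, and the cleavage position is carried as an integer: the number
#' of residues preceding the scissile bond (the bond lies between residues
#' `cleavage_index` and `cleavage_index + 1`, 1-based).
#'
#' @param line character scalar, one peptide with exactly one internal dash.
#' @param enzyme enzyme identifier attached to the record (e.g. `"MMP-2"`).
#' @param source_tag free-text provenance stored with the record.
#' @return A `substrate_record`: list with `enzyme`, `sequence`,
#'   `cleavage_index`, `source_tag`.
#' @examples
#' parse_substrate_line("ggsgPSA-LDAtasgaet", "MMP-9")
#' @export
parse_substrate_line <- function(line, enzyme = NA_character_,
                                 source_tag = NA_character_) {
  stopifnot(is.character(line), length(line) == 1L)
  line <- trimws(line)
  ndash <- lengths(regmatches(line, gregexpr("-", line, fixed = TRUE)))
  if (ndash == 0L)
    stop("no cleavage dash in substrate line '", line, "'", call. = FALSE)
  if (ndash > 1L)
    stop("multiple dashes in substrate line '", line, "'", call. = FALSE)
  dash_at <- regexpr("-", line, fixed = TRUE)
  if (dash_at == 1L || dash_at == nchar(line))
    stop("cleavage dash at the end of substrate line '", line, "'",
         call. = FALSE)
  seq <- toupper(gsub("-", "", line, fixed = TRUE))
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(bad) > 0L)
    stop("non-amino-acid character '", bad[[1]], "' in substrate line '",
         line, "'", call. = FALSE)
  rec <- list(enzyme = enzyme, sequence = seq,
              cleavage_index = as.integer(dash_at - 1L),
              source_tag = source_tag)
  class(rec) <- "substrate_record"
  rec
}

#' Serialise a substrate record back to dash notation
#'
#' Inverse of [parse_substrate_line()] up to letter case (the in-memory form
#' is fully uppercased).
#'
#' @param record a `substrate_record`.
#' @return character scalar with the dash re-inserted at the scissile bond.
#' @export
format_substrate <- function(record) {
  s <- record$sequence
  i <- record$cleavage_index
  paste0(substr(s, 1L, i), "-", substr(s, i + 1L, nchar(s)))
}

#' @export
print.substrate_record <- function(x, ...) {
  cat(sprintf("<substrate_record> %s  %s (bond after residue %d)\n",
              ifelse(is.na(x$enzyme), "?", x$enzyme), format_substrate(x),
              x$cleavage_index))
  invisible(x)
}

# Bind a list of substrate_record into the canonical substrate table.
substrate_table <- function(records) {
  df <- data.frame(
    enzyme = vapply(records, `[[`, character(1), "enzyme"),
    sequence = vapply(records, `[[`, character(1), "sequence"),
    cleavage_index = vapply(records, `[[`, integer(1), "cleavage_index"),
    source_tag = vapply(records, `[[`, character(1), "source_tag"),
    stringsAsFactors = FALSE
  )
  class(df) <- c("substrate_set", "data.frame")
  df
}

#' Read a cleavage-annotated substrate table
#'
#' One peptide per row in dash notation; an optional second column names the
#' enzyme (otherwise `enzyme` is taken from the argument). Fields are tab- or
#' whitespace-separated; `#` starts a comment.
#'
#' @param path file path.
#' @param enzyme default enzyme identifier for rows lacking an enzyme column.
#' @param quiet suppress the record-count message.
#' @return A `substrate_set` data frame with columns `enzyme`, `sequence`,
#'   `cleavage_index`, `source_tag`.
#' @export
read_substrate_table <- function(path, enzyme = NA_character_, quiet = FALSE) {
  lines <- read_data_lines(path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "[ \t]+")[[1]]
    enz <- if (length(fields) >= 2L) fields[[2]] else enzyme
    recs[[i]] <- tryCatch(
      parse_substrate_line(fields[[1]], enzyme = enz, source_tag = basename(path)),
      error = function(e) stop("row ", i, " of ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  if (!quiet)
    message("read ", length(recs), " substrate records from ", path)
  substrate_table(recs)
}

#' Read a background peptide list
#'
#' Plain peptides (no cleavage annotation), one per row, `#` comments ignored.
#' Mixed-case flank/variable notation is uppercased.
#'
#' @param path file path.
#' @param name label for the set (defaults to the file name).
#' @param quiet suppress the count message.
#' @return A `background_set`: list with `peptides` (uppercase character
#'   vector) and `name`.
#' @export
read_background <- function(path, name = basename(path), quiet = FALSE) {
  lines <- read_data_lines(path)
  peps <- toupper(vapply(lines, function(l) strsplit(l, "[ \t]+")[[1]][[1]],
                         character(1), USE.NAMES = FALSE))
  for (i in seq_along(peps)) {
    bad <- setdiff(strsplit(peps[[i]], "")[[1]], AA_ALPHABET)
    if (length(bad) > 0L)
      stop("row ", i, " of ", path, ": non-amino-acid character '",
           bad[[1]], "'", call. = FALSE)
  }
  if (!quiet)
    message("read ", length(peps), " background peptides from ", path)
  background_set(peps, name)
}

#' Construct a background peptide set
#' @param peptides uppercase peptide strings.
#' @param name label.
#' @return a `background_set`.
#' @export
background_set <- function(peptides, name = "background") {
  if (length(peptides) == 0L) stop("empty background set", call. = FALSE)
  bg <- list(peptides = toupper(peptides), name = name)
  class(bg) <- "background_set"
  bg
}

# Shared line reader: strip comments/blank lines, error on empty files.
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no records in ", path, call. = FALSE)
  lines
}

#' Read protein sequences from a FASTA file
#'
#' Accepts multi-record files with wrapped lines. Sequences are uppercased;
#' nonstandard residue codes (X, B, Z, U, ...) are retained — downstream
#' scanning skips any scoring window that touches them.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(as.character(aas))
  # keep only the id token of each header
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Read a PWM matrix file
#'
#' The on-disk dialect is: `#` comment lines; three `key<TAB>value` header
#' lines (`enzyme`, `threshold`, `offset`); a column-label line
#' (`residue P3 P2 P1 P1' P2'`); then exactly 20 residue rows of 5 decimal
#' log2 values each. Cells where the residue was never observed in training
#' already hold the offset value.
#'
#' @param path file path.
#' @return a [pwm] object.
#' @export
read_pwm_file <- function(path) {
  lines <- read_data_lines(path)
  header <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^(enzyme|threshold|offset)\\b", lines[[i]])) {
    kv <- strsplit(lines[[i]], "[ \t]+")[[1]]
    header[[kv[[1]]]] <- kv[[2]]
    i <- i + 1L
  }
  for (key in c("enzyme", "threshold", "offset"))
    if (is.null(header[[key]]))
      stop("PWM file ", path, ": missing header line '", key, "'", call. = FALSE)
  if (i > length(lines) || !grepl("^residue\\b", lines[[i]]))
    stop("PWM file ", path, ": missing column-label line", call. = FALSE)
  labels <- strsplit(lines[[i]], "[ \t]+")[[1]][-1]
  if (!identical(labels, SUBSITES))
    stop("PWM file ", path, ": expected columns ",
         paste(SUBSITES, collapse = " "), call. = FALSE)
  rows <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  if (length(rows) != 20L)
    stop("PWM file ", path, ": expected 20 residue rows, found ",
         length(rows), call. = FALSE)
  M <- matrix(NA_real_, 20L, 5L, dimnames = list(AA_ALPHABET, SUBSITES))
  seen <- character(0)
  for (r in rows) {
    fields <- strsplit(r, "[ \t]+")[[1]]
    aa <- fields[[1]]
    if (!(aa %in% AA_ALPHABET))
      stop("PWM file ", path, ": unknown residue row '", aa, "'", call. = FALSE)
    if (aa %in% seen)
      stop("PWM file ", path, ": duplicate residue row '", aa, "'", call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (length(vals) != 5L || anyNA(vals))
      stop("PWM file ", path, ": malformed row for residue '", aa, "'",
           call. = FALSE)
    M[aa, ] <- vals
    seen <- c(seen, aa)
  }
  pwm(M, offset = as.numeric(header$offset),
      threshold = as.numeric(header$threshold), enzyme = header$enzyme)
}

#' Write a PWM matrix file
#'
#' Inverse of [read_pwm_file()]; round-trips to 6 decimal places.
#'
#' @param x a [pwm] object.
#' @param path output path.
#' @param comment optional `#` comment lines for the file head.
#' @export
write_pwm_file <- function(x, path, comment = character(0)) {
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  writeLines(sprintf("enzyme\t%s", x$enzyme), con)
  writeLines(sprintf("threshold\t%.6f", x$threshold), con)
  writeLines(sprintf("offset\t%.6f", x$offset), con)
  writeLines(paste(c("residue", SUBSITES), collapse = "\t"), con)
  for (aa in AA_ALPHABET)
    writeLines(paste(c(aa, sprintf("%.6f", x$M[aa, ])), collapse = "\t"), con)
  invisible(path)
}

#' Write a scored-site prediction table
#'
#' TSV with one row per site: `sequence_id`, `p1_position`, `context10`,
#' `window`, `score`, `above_threshold`, plus `mass_n` / `mass_c` columns when
#' present (complete-digest fragment masses at that bond). Scores are printed
#' at 4 decimal places, masses at 6.
#'
#' @param sites a `scored_sites` data frame from [scan_sequence()] (optionally
#'   augmented with fragment masses).
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @export
write_predictions <- function(sites, path, header = character(0)) {
  out <- sites
  out$score <- sprintf("%.4f", out$score)
  for (col in intersect(c("mass_n", "mass_c"), names(out)))
    out[[col]] <- sprintf("%.6f", out[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}
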