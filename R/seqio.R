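# Sequence records, alphabets, genetic code, FASTA / GenBank I/O.
#
# Internally every coordinate is 0-based half-open; anything printed for a
# human (GenBank features, reports) is 1-based closed.

DNA_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Normalise and validate a DNA sequence
#'
#' Uppercases, converts RNA `U` to `T` (with a notice), and rejects any symbol
#' outside `A`, `C`, `G`, `T`. Ambiguity codes (`N`, `R`, `Y`, ...) are
#' rejected rather than expanded: this package designs sequences and must
#' never emit ambiguity.
#'
#' @param x A character scalar of nucleotide bases.
#' @param id Identifier used in error messages.
#' @return The canonical uppercase DNA string.
#' @examples
#' dna("gcggccgcc")
#' @export
dna <- function(x, id = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  if (grepl("U", x, fixed = TRUE)) {
    inform(paste0("RNA input for '", id, "': U converted to T"))
    x <- gsub("U", "T", x, fixed = TRUE)
  }
  bad <- setdiff(unique(strsplit(x, "")[[1]]), DNA_ALPHABET)
  if (length(bad) > 0) {
    abort(
      paste0(
        "invalid nucleotide symbol(s) ", paste(sQuote(bad), collapse = ", "),
        " in '", id, "'"
      ),
      class = "optoxr_alphabet_error"
    )
  }
  x
}

#' Validate a protein sequence
#'
#' Accepts only the 20 standard amino-acid letters; internal stop symbols
#' (`*`) are rejected.
#'
#' @param x A character scalar of amino-acid residues.
#' @param id Identifier used in error messages.
#' @return The canonical uppercase residue string.
#' @export
aa <- function(x, id = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(
      paste0(
        "invalid amino-acid symbol(s) ", paste(sQuote(bad), collapse = ", "),
        " in '", id, "'"
      ),
      class = "optoxr_alphabet_error"
    )
  }
  x
}

#' The standard genetic code as a tidy table
#'
#' One row per codon (64 rows), with its single-letter amino acid and a stop
#' flag. Backed by the standard code table shipped with Biostrings; alternate
#' tables can be supplied wherever a code table is accepted, but none ship
#' enabled.
#'
#' @return A tibble with columns `codon`, `aa`, `is_stop`.
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble(
    codon = names(gc),
    aa = unname(gc),
    is_stop = unname(gc) == "*"
  )
}

#' Translate a DNA sequence
#'
#' Translates successive codons from `frame` until the end of the sequence or
#' the first stop codon; a trailing partial codon is ignored. The returned
#' string carries attributes `stopped` (was a stop codon met?) and
#' `stop_codon` (0-based codon index of that stop, or `NA`).
#'
#' @param x DNA string (validated by [dna()]).
#' @param frame Reading frame offset: 0, 1 or 2.
#' @param code Genetic-code table as returned by [genetic_code()].
#' @return Amino-acid string with attributes `stopped` and `stop_codon`.
#' @examples
#' translate_dna("GCGGCCGCC") # the fusion linker: Ala-Ala-Ala
#' @export
translate_dna <- function(x, frame = 0L, code = genetic_code()) {
  x <- dna(x)
  stopifnot(frame %in% 0:2)
  if (nchar(x) - frame < 3) {
    abort("sequence too short to translate in this frame",
      class = "optoxr_length_error"
    )
  }
  n_codons <- (nchar(x) - frame) %/% 3
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(x, starts, starts + 2L)
  aas <- code$aa[match(codons, code$codon)]
  stop_at <- which(aas == "*")
  if (length(stop_at) > 0) {
    first <- stop_at[1]
    res <- paste(aas[seq_len(first - 1L)], collapse = "")
    structure(res, stopped = TRUE, stop_codon = first - 1L)
  } else {
    structure(paste(aas, collapse = ""), stopped = FALSE, stop_codon = NA_integer_)
  }
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string.
#' @return The reverse-complemented string. Applying it twice is the identity.
#' @export
revcomp <- function(x) {
  x <- dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file into a tibble
#'
#' Sequences are validated against the requested alphabet. Duplicate ids are
#' disambiguated with a numeric suffix and a warning.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` or `"aa"`.
#' @return A tibble with columns `id`, `description`, `seq`, record order
#'   preserved.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "optoxr_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    warn("duplicate FASTA ids; disambiguating with numeric suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    switch(type, dna = dna(seqs[i], id = ids[i]), aa = aa(seqs[i], id = ids[i]))
  }, character(1))
  tibble(id = ids, description = descs, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `id`, `seq` and optionally `description`,
#'   or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    x <- tibble(id = names(x) %||% paste0("seq", seq_along(x)),
                description = "", seq = unname(x))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- if (nzchar(desc[i])) paste(x$id[i], desc[i]) else x$id[i]
    writeLines(paste0(">", header), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- GenBank (minimal flat file, for annotated cassettes) -----------------

#' Write an annotated record as a GenBank flat file
#'
#' Minimal writer covering LOCUS, DEFINITION, a FEATURES table and ORIGIN.
#' Feature locations are printed 1-based closed, per GenBank convention.
#'
#' @param record A list with elements `locus` (id), `definition`, `seq`
#'   (DNA string), and `features`: a tibble with columns `key`, `start`,
#'   `end` (0-based half-open), `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(is.list(record), !is.null(record$seq))
  seq <- dna(record$seq)
  n <- nchar(seq)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN",
                     record$locus %||% "record", n), con)
  writeLines(paste0("DEFINITION  ", record$definition %||% "."), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  feats <- record$features
  if (!is.null(feats) && nrow(feats) > 0) {
    for (i in seq_len(nrow(feats))) {
      loc <- sprintf("%d..%d", feats$start[i] + 1L, feats$end[i])
      writeLines(sprintf("     %-16s%s", feats$key[i], loc), con)
      writeLines(sprintf("                     /label=\"%s\"", feats$label[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substring(seq, p, min(p + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(blocks), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path Path to the flat file.
#' @return A record list with `locus`, `definition`, `seq`, `features`
#'   (tibble, coordinates converted back to 0-based half-open).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "optoxr_io_error")
  }
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) {
    abort(paste0("malformed GenBank record: no LOCUS line (line 1)"),
      class = "optoxr_parse_error"
    )
  }
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]
  def_i <- grep("^DEFINITION", lines)
  definition <- if (length(def_i)) trimws(sub("^DEFINITION", "", lines[def_i[1]])) else ""
  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0) {
    abort("malformed GenBank record: no ORIGIN section",
      class = "optoxr_parse_error"
    )
  }
  keys <- character(); starts <- integer(); ends <- integer(); labels <- character()
  if (length(feat_i)) {
    i <- feat_i[1] + 1L
    while (i < orig_i[1]) {
      ln <- lines[i]
      m <- regmatches(ln, regexec("^     (\\S+)\\s+(\\d+)\\.\\.(\\d+)", ln))[[1]]
      if (length(m) == 4) {
        keys <- c(keys, m[2])
        starts <- c(starts, as.integer(m[3]) - 1L)
        ends <- c(ends, as.integer(m[4]))
        lab <- ""
        if (i + 1L < orig_i[1] && grepl("/label=", lines[i + 1L])) {
          lab <- sub('.*?/label="([^"]*)".*', "\\1", lines[i + 1L])
          i <- i + 1L
        }
        labels <- c(labels, lab)
      }
      i <- i + 1L
    }
  }
  body <- lines[(orig_i[1] + 1L):length(lines)]
  body <- body[!grepl("^//", body)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
  list(
    locus = locus, definition = definition, seq = dna(seq),
    features = tibble(key = keys, start = starts, end = ends, label = labels)
  )
}
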