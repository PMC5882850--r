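# Global pairwise alignment (affine gaps) and reference-centric star MSA,
# used to transfer homolog topology boundaries onto a reference protein.

#' Load a protein substitution matrix
#'
#' Returns the named scoring matrix as a symmetric numeric matrix restricted
#' to the 20 standard residues. `BLOSUM62` (the default everywhere in this
#' package) ships with Biostrings; a path to a square whitespace-delimited
#' matrix file with residue row/column headers is also accepted.
#'
#' @param name Matrix name (`"BLOSUM62"`, `"BLOSUM45"`, `"BLOSUM80"`,
#'   `"PAM250"`) or a file path.
#' @return A symmetric numeric matrix with residue dimnames and a `name`
#'   attribute.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (file.exists(name)) {
    m <- as.matrix(utils::read.table(name, header = TRUE, row.names = 1,
                                     check.names = FALSE))
    tag <- basename(name)
  } else {
    e <- new.env()
    ok <- tryCatch(
      { utils::data(list = name, package = "Biostrings", envir = e); TRUE },
      warning = function(w) FALSE
    )
    if (!ok || !exists(name, envir = e)) {
      abort(paste0("unknown substitution matrix: ", name),
        class = "optoxr_parameter_error"
      )
    }
    m <- get(name, envir = e)
    tag <- name
  }
  keep <- intersect(rownames(m), AA_ALPHABET)
  m <- m[keep, keep, drop = FALSE]
  storage.mode(m) <- "double"
  if (!isSymmetric(unname(m))) {
    abort("substitution matrix must be symmetric", class = "optoxr_parameter_error")
  }
  attr(m, "name") <- tag
  m
}

encode_seq <- function(x, alphabet) {
  codes <- match(strsplit(x, "")[[1]], alphabet)
  if (anyNA(codes)) {
    abort("sequence contains symbols absent from the scoring matrix",
      class = "optoxr_alphabet_error"
    )
  }
  codes - 1L
}

#' Optimal global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch over the full lengths of both sequences (no terminal-gap
#' discounting: boundaries near the termini matter for domain transfer). A
#' gap of length L costs `gap_open + (L - 1) * gap_extend`. Ties in the
#' traceback are broken deterministically: diagonal, then gap-in-`b`, then
#' gap-in-`a`.
#'
#' @param a,b Protein strings (reference first by convention).
#' @param matrix Scoring matrix from [substitution_matrix()]; any symmetric
#'   matrix with single-letter dimnames works (used by the tests' small
#'   alphabets too).
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 and 1).
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, and `column_map`
#'   (for each position of `a`, its 1-based alignment column).
#' @export
global_align <- function(a, b, matrix = substitution_matrix(),
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("global_align requires non-empty sequences",
      class = "optoxr_precondition_error"
    )
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  alphabet <- rownames(matrix)
  ea <- encode_seq(a, alphabet)
  eb <- encode_seq(b, alphabet)
  res <- nw_affine_cpp(ea, eb, matrix, gap_open, gap_extend)
  ops <- res$ops
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  out_a <- character(length(ops))
  out_b <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      i <- i + 1L; j <- j + 1L
      out_a[k] <- ca[i]; out_b[k] <- cb[j]
    } else if (ops[k] == 1L) {
      i <- i + 1L
      out_a[k] <- ca[i]; out_b[k] <- "-"
    } else {
      j <- j + 1L
      out_a[k] <- "-"; out_b[k] <- cb[j]
    }
  }
  structure(
    list(
      aligned_a = paste(out_a, collapse = ""),
      aligned_b = paste(out_b, collapse = ""),
      score = res$score,
      column_map = which(out_a != "-")
    ),
    class = "pairwise_alignment"
  )
}

#' Score an existing (gapped) alignment
#'
#' Recomputes the affine-gap score of a pair of equal-length gapped strings;
#' used to assert that emitted alignments score what the DP claims.
#'
#' @inheritParams global_align
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return Numeric score.
#' @export
score_alignment <- function(aligned_a, aligned_b, matrix = substitution_matrix(),
                            gap_open = 10, gap_extend = 1) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  score <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-" && cb[k] == "-") abort("double-gap column")
    if (ca[k] == "-") {
      score <- score - (if (in_gap_a) gap_extend else gap_open)
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      score <- score - (if (in_gap_b) gap_extend else gap_open)
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      score <- score + matrix[ca[k], cb[k]]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  score
}

#' Star multiple alignment around a reference
#'
#' Aligns every family member pairwise to the reference and merges the
#' pairwise gap structures into shared reference coordinates ("once a gap,
#' always a gap"). Row order is preserved, reference first. A star layout is
#' used instead of a progressive tree because the workflow only ever needs
#' homolog-to-reference coordinate transfer, which the star construction
#' makes exact.
#'
#' @param reference Reference protein string.
#' @param others Character vector (or list) of homolog protein strings.
#' @inheritParams global_align
#' @return An object of class `star_msa`: list with `rows` (tibble: `id`,
#'   `aligned`), reference in row 1.
#' @export
star_msa <- function(reference, others, matrix = substitution_matrix(),
                     gap_open = 10, gap_extend = 1) {
  others <- unlist(others, use.names = TRUE)
  if (length(others) < 1) {
    abort("star_msa needs at least one non-reference sequence",
      class = "optoxr_precondition_error"
    )
  }
  n <- nchar(reference)
  alns <- lapply(others, function(s) {
    global_align(reference, s, matrix, gap_open, gap_extend)
  })
  # insertions relative to the reference: ins[[k]][p+1] = number of gap
  # columns in the reference row immediately before reference position p
  # (0-based; slot n+1 = insertions after the last residue)
  ins <- lapply(alns, function(al) {
    ca <- strsplit(al$aligned_a, "")[[1]]
    slots <- integer(n + 1L)
    p <- 0L
    for (ch in ca) {
      if (ch == "-") slots[p + 1L] <- slots[p + 1L] + 1L else p <- p + 1L
    }
    slots
  })
  merged <- Reduce(pmax, ins, integer(n + 1L))
  ref_chars <- strsplit(reference, "")[[1]]
  build <- function(al) {
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    out <- character(0)
    k <- 1L
    for (p in 0:n) {
      taken <- 0L
      while (k <= length(ca) && ca[k] == "-") {
        out <- c(out, cb[k]); k <- k + 1L; taken <- taken + 1L
      }
      if (taken < merged[p + 1L]) {
        out <- c(out, rep("-", merged[p + 1L] - taken))
      }
      if (p < n) {
        # consume the reference residue column
        stopifnot(ca[k] == ref_chars[p + 1L])
        out <- c(out, cb[k]); k <- k + 1L
      }
    }
    paste(out, collapse = "")
  }
  ref_row <- {
    out <- character(0)
    for (p in 0:n) {
      out <- c(out, rep("-", merged[p + 1L]))
      if (p < n) out <- c(out, ref_chars[p + 1L])
    }
    paste(out, collapse = "")
  }
  rows <- tibble(
    id = c("reference", names(others) %||% paste0("seq", seq_along(others))),
    aligned = c(ref_row, vapply(alns, build, character(1)))
  )
  if (any(!nzchar(rows$id))) {
    rows$id[!nzchar(rows$id)] <- paste0("seq", which(!nzchar(rows$id)) - 1L)
  }
  widths <- nchar(rows$aligned)
  stopifnot(all(widths == widths[1]))
  structure(list(rows = rows), class = "star_msa")
}

#' Map a row position to reference coordinates through a star MSA
#'
#' @param msa A `star_msa`.
#' @param row Row index (1 = reference).
#' @param pos 0-based residue position within that row's ungapped sequence.
#' @return The 0-based reference position of the column holding that residue,
#'   or `NA_integer_` when that column is a gap in the reference.
#' @export
map_position <- function(msa, row, pos) {
  stopifnot(inherits(msa, "star_msa"))
  rows <- msa$rows
  if (row < 1 || row > nrow(rows)) {
    abort("row out of range", class = "optoxr_bounds_error")
  }
  rchars <- strsplit(rows$aligned[row], "")[[1]]
  res_cols <- which(rchars != "-")
  if (pos < 0 || pos >= length(res_cols)) {
    abort("position out of range", class = "optoxr_bounds_error")
  }
  col <- res_cols[pos + 1L]
  ref_chars <- strsplit(rows$aligned[1], "")[[1]]
  if (ref_chars[col] == "-") {
    return(NA_integer_)
  }
  sum(ref_chars[seq_len(col)] != "-") - 1L
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (affine gaps), score", x$score, "\n")
  cat(x$aligned_a, "\n")
  cat(x$aligned_b, "\n")
  invisible(x)
}

#' Export a star MSA as aligned FASTA
#'
#' @param msa A `star_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  write_fasta(tibble(id = msa$rows$id, description = "", seq = msa$rows$aligned),
              path)
}

#' @export
tidy.star_msa <- function(x, ...) x$rows
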