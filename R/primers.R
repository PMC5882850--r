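# Junction-spanning qPCR primer design, in-silico PCR specificity screening,
# and primer property computation.

#' Compute primer properties
#'
#' GC fraction is a direct tally. Melting temperature uses the Wallace rule
#' `2*(A+T) + 4*(G+C)` for oligos shorter than 14 nt and the GC formula
#' `64.9 + 41*(G + C - 16.4)/length` otherwise — adequate for ranking
#' candidates; nearest-neighbour thermodynamics is a listed extension.
#'
#' @param oligo DNA string, 5'->3'.
#' @return A tibble with columns `oligo`, `length`, `gc`, `tm`.
#' @export
primer_properties <- function(oligo) {
  oligo <- dna(oligo)
  n <- nchar(oligo)
  chars <- strsplit(oligo, "")[[1]]
  gc_n <- sum(chars %in% c("G", "C"))
  at_n <- n - gc_n
  tm <- if (n < 14) 2 * at_n + 4 * gc_n else 64.9 + 41 * (gc_n - 16.4) / n
  tibble(oligo = oligo, length = n, gc = gc_n / n, tm = tm)
}

# all match start positions (0-based) of `primer` along the top strand of
# `template`, allowing <= max_mismatch mismatches but requiring the
# three_prime_exact bases at the primer's 3' end to match exactly.
# three_prime = "right" when the primer's 3' end is the right end of the
# top-strand match (forward orientation), "left" when the match is of the
# primer's reverse complement.
primer_matches <- function(primer, template, max_mismatch, three_prime_exact,
                           three_prime = c("right", "left")) {
  three_prime <- match.arg(three_prime)
  k <- nchar(primer)
  n <- nchar(template)
  if (k > n) {
    return(tibble(start = integer(0), mismatches = integer(0)))
  }
  subj <- Biostrings::DNAString(template)
  m <- Biostrings::matchPattern(primer, subj, max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0) {
    return(tibble(start = integer(0), mismatches = integer(0)))
  }
  starts <- Biostrings::start(m) - 1L
  pv <- strsplit(primer, "")[[1]]
  tv <- strsplit(template, "")[[1]]
  mm <- vapply(starts, function(s) {
    sum(tv[(s + 1L):(s + k)] != pv)
  }, numeric(1))
  exact_idx <- if (three_prime == "right") (k - three_prime_exact + 1L):k else
    seq_len(three_prime_exact)
  ok <- vapply(starts, function(s) {
    all(tv[s + exact_idx] == pv[exact_idx])
  }, logical(1))
  tibble(start = starts[ok], mismatches = as.integer(mm[ok]))
}

#' In-silico PCR
#'
#' Finds every convergent forward/reverse binding-site pair on a template,
#' on either strand, allowing up to `max_mismatch` mismatches per primer but
#' requiring the `three_prime_exact` 3'-terminal bases to match exactly
#' (extension starts there). Hits are reported in top-strand coordinates;
#' a template and its reverse complement give the same products.
#'
#' @param template DNA string.
#' @param forward,reverse Primer strings, both written 5'->3'.
#' @param max_mismatch Mismatches tolerated per primer (default 2).
#' @param three_prime_exact 3'-terminal bases that must match (default 5).
#' @param max_product Longest product reported (default 2000).
#' @param template_id Id recorded in hits.
#' @return A tibble of class `amplicon_hits`: columns `template_id`, `start`,
#'   `end` (0-based half-open), `product_length`, `fwd_strand`, `fwd_mismatches`,
#'   `rev_mismatches`, sorted by `start`. Zero rows = no product.
#' @export
in_silico_pcr <- function(template, forward, reverse,
                          max_mismatch = 2L, three_prime_exact = 5L,
                          max_product = 2000L, template_id = "template") {
  template <- dna(template)
  forward <- dna(forward)
  reverse <- dna(reverse)
  collect <- function(fp, rp, strand_label) {
    # fp binds the top strand reading rightward; rp's reverse complement
    # appears downstream on the top strand
    f_hits <- primer_matches(fp, template, max_mismatch, three_prime_exact, "right")
    r_hits <- primer_matches(revcomp(rp), template, max_mismatch,
                             three_prime_exact, "left")
    if (nrow(f_hits) == 0 || nrow(r_hits) == 0) {
      return(tibble())
    }
    purrr::map_dfr(seq_len(nrow(f_hits)), function(i) {
      fs <- f_hits$start[i]
      re <- r_hits$start + nchar(rp)
      ok <- re - fs >= nchar(fp) + nchar(rp) & re - fs <= max_product
      if (!any(ok)) {
        return(tibble())
      }
      tibble(
        template_id = template_id,
        start = fs, end = re[ok],
        product_length = re[ok] - fs,
        fwd_strand = strand_label,
        fwd_mismatches = f_hits$mismatches[i],
        rev_mismatches = r_hits$mismatches[ok]
      )
    })
  }
  hits <- bind_rows(
    collect(forward, reverse, "+"),
    collect(reverse, forward, "-")
  )
  if (nrow(hits) == 0) {
    return(structure(
      tibble(template_id = character(0), start = integer(0), end = integer(0),
             product_length = integer(0), fwd_strand = character(0),
             fwd_mismatches = integer(0), rev_mismatches = integer(0)),
      class = c("amplicon_hits", class(tibble()))
    ))
  }
  hits <- hits[!duplicated(hits[, c("start", "end")]), , drop = FALSE]
  structure(arrange(hits, .data$start, .data$end),
            class = c("amplicon_hits", class(tibble())))
}

#' Design a junction-spanning qPCR primer pair
#'
#' Designs a pair whose amplicon strictly contains a chimera splice junction
#' and which amplifies the chimera but neither parent. The forward primer
#' straddles the junction with at least `anchor` bases on each side, so its
#' sequence is a composite neither parent carries and neither parent alone
#' can template the pair; the reverse primer binds downstream. Candidates
#' are ranked by melting-temperature balance, then GC-closeness to 50%, and
#' screened with [in_silico_pcr()] against the chimera and every parent; the
#' first candidate passing the screen is returned.
#'
#' @param template Chimera DNA string (CDS or cassette).
#' @param junction 0-based junction position in `template` coordinates.
#' @param parents Character vector of parent DNA strings (names used as
#'   ids). May be empty: the pair is then returned `"unscreened"`.
#' @param primer_len Candidate primer length range (default 18-25).
#' @param amplicon_len Accepted product-length range (default 70-250).
#' @param anchor Minimum bases of the straddling primer on each side of the
#'   junction (default 6).
#' @param gc_range Acceptable primer GC range (default 0.30-0.70).
#' @param max_mismatch,three_prime_exact,max_product Screen settings passed
#'   to [in_silico_pcr()].
#' @param max_candidates Candidate pairs screened before giving up
#'   (default 60).
#' @return An object of class `primer_pair`: list with `forward`, `reverse`
#'   (5'->3'), `amplicon` (`start`, `end` on the template), `properties`
#'   (tibble, one row per primer), `specificity` (`"specific"` or
#'   `"unscreened"`), `junction`.
#' @export
design_junction_primers <- function(template, junction, parents = character(0),
                                    primer_len = c(18L, 25L),
                                    amplicon_len = c(70L, 250L),
                                    anchor = 6L, gc_range = c(0.30, 0.70),
                                    max_mismatch = 2L, three_prime_exact = 5L,
                                    max_product = 2000L,
                                    max_candidates = 60L) {
  template <- dna(template)
  n <- nchar(template)
  if (junction < anchor + primer_len[1] || junction > n - anchor - primer_len[1]) {
    abort("junction too close to a template end to anchor primers",
      class = "optoxr_precondition_error"
    )
  }
  annotate <- function(cand) {
    if (nrow(cand) == 0) {
      return(cand)
    }
    len <- nchar(cand$oligo)
    gc_n <- len - nchar(gsub("[GC]", "", cand$oligo))
    cand$gc <- gc_n / len
    cand$tm <- ifelse(len < 14, 2 * (len - gc_n) + 4 * gc_n,
                      64.9 + 41 * (gc_n - 16.4) / len)
    cand <- cand[cand$gc >= gc_range[1] & cand$gc <= gc_range[2], , drop = FALSE]
    cand[order(abs(cand$gc - 0.5)), , drop = FALSE]
  }
  # forward candidates straddle the junction: >= anchor bases on each side
  fwd_cand <- annotate(bind_rows(lapply(primer_len[1]:primer_len[2], function(len) {
    ends <- (junction + anchor):(junction + len - anchor) # 0-based exclusive
    ends <- ends[ends <= n & ends - len >= 0]
    if (length(ends) == 0) {
      return(tibble())
    }
    tibble(
      start = ends - len, end = ends,
      oligo = substring(template, ends - len + 1L, ends)
    )
  })))
  # reverse candidates bind downstream of the straddling primer; reverse
  # complement the whole downstream window once and slice it
  region_start <- junction + anchor # 0-based
  region_end <- min(n, junction + 200L + primer_len[2])
  rc_region <- revcomp(substr(template, region_start + 1L, region_end))
  rc_len <- nchar(rc_region)
  rev_cand <- annotate(bind_rows(lapply(primer_len[1]:primer_len[2], function(len) {
    starts <- region_start:(region_end - len) # template coords of site start
    if (length(starts) == 0 || starts[1] > starts[length(starts)]) {
      return(tibble())
    }
    # site [s, s+len) on the template is rc_region[region_end-s-len .. )
    rc_from <- region_end - starts - len
    tibble(
      start = starts, end = starts + len,
      oligo = substring(rc_region, rc_from + 1L, rc_from + len)
    )
  })))
  if (nrow(fwd_cand) == 0 || nrow(rev_cand) == 0) {
    abort("no primer candidates satisfy the GC constraints near the junction",
      class = "optoxr_design_error"
    )
  }
  # pair candidates, rank by Tm balance then joint GC-closeness to 50%
  pairs <- tidyr::expand_grid(fi = seq_len(nrow(fwd_cand)),
                              ri = seq_len(nrow(rev_cand)))
  pairs$prod_len <- rev_cand$end[pairs$ri] - fwd_cand$start[pairs$fi]
  # the reverse site must lie fully downstream of the forward site
  pairs <- pairs[rev_cand$start[pairs$ri] >= fwd_cand$end[pairs$fi] &
                   pairs$prod_len >= amplicon_len[1] &
                   pairs$prod_len <= amplicon_len[2], , drop = FALSE]
  if (nrow(pairs) == 0) {
    abort("no candidate pair yields an amplicon in the accepted length range",
      class = "optoxr_design_error"
    )
  }
  pairs$tm_diff <- abs(fwd_cand$tm[pairs$fi] - rev_cand$tm[pairs$ri])
  pairs$gc_score <- abs(fwd_cand$gc[pairs$fi] - 0.5) + abs(rev_cand$gc[pairs$ri] - 0.5)
  pairs <- pairs[order(pairs$tm_diff, pairs$gc_score), , drop = FALSE]
  pairs <- head(pairs, max_candidates)

  parent_ids <- names(parents) %||% paste0("parent", seq_along(parents))
  rejected <- list()
  for (i in seq_len(nrow(pairs))) {
    f <- fwd_cand[pairs$fi[i], ]
    r <- rev_cand[pairs$ri[i], ]
    self <- in_silico_pcr(template, f$oligo, r$oligo, max_mismatch,
                          three_prime_exact, max_product, "chimera")
    if (nrow(self) < 1) {
      rejected[[length(rejected) + 1L]] <- list(pair = c(f$oligo, r$oligo),
                                                reason = "no product on chimera")
      next
    }
    parent_hits <- 0L
    if (length(parents) > 0) {
      for (pi in seq_along(parents)) {
        ph <- in_silico_pcr(parents[[pi]], f$oligo, r$oligo, max_mismatch,
                            three_prime_exact, max_product, parent_ids[pi])
        parent_hits <- parent_hits + nrow(ph)
        if (parent_hits > 0) break
      }
    }
    if (parent_hits > 0) {
      rejected[[length(rejected) + 1L]] <- list(pair = c(f$oligo, r$oligo),
                                                reason = "amplifies a parent")
      next
    }
    props <- bind_rows(primer_properties(f$oligo), primer_properties(r$oligo))
    props$role <- c("forward", "reverse")
    return(structure(
      list(
        forward = f$oligo, reverse = r$oligo,
        amplicon = c(start = f$start, end = r$end),
        properties = props,
        specificity = if (length(parents) > 0) "specific" else "unscreened",
        junction = junction
      ),
      class = "primer_pair"
    ))
  }
  abort(
    "no candidate pair passed the specificity screen",
    class = "optoxr_design_error",
    rejected = utils::head(rejected, 5)
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("junction-spanning primer pair (junction at", x$junction, "):\n")
  cat("  forward 5'-", x$forward, "-3'\n", sep = "")
  cat("  reverse 5'-", x$reverse, "-3'\n", sep = "")
  cat("  amplicon [", x$amplicon["start"], ", ", x$amplicon["end"], "), ",
      "specificity: ", x$specificity, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.primer_pair <- function(x, ...) {
  out <- x$properties
  out$amplicon_start <- unname(x$amplicon["start"])
  out$amplicon_end <- unname(x$amplicon["end"])
  out
}

#' @export
glance.primer_pair <- function(x, ...) {
  tibble(
    junction = x$junction,
    amplicon_length = unname(x$amplicon["end"] - x$amplicon["start"]),
    tm_difference = abs(x$properties$tm[1] - x$properties$tm[2]),
    specificity = x$specificity
  )
}

#' Write primer pairs as 3-column tab text
#'
#' @param pairs A `primer_pair` or list of them.
#' @param path Output path.
#' @param names Pair names.
#' @return `path`, invisibly.
#' @export
write_primers <- function(pairs, path, names = NULL) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  names <- names %||% paste0("pair", seq_along(pairs))
  df <- data.frame(
    name = names,
    forward = vapply(pairs, `[[`, character(1), "forward"),
    reverse = vapply(pairs, `[[`, character(1), "reverse")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
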