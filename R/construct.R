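# Expression-cassette compilation: codon-optimized back-translation,
# restriction-site audit and removal, reporter fusion, cassette assembly.

#' Common restriction enzymes
#'
#' The cloning pair used throughout the workflow is KpnI/BamHI; NotI matters
#' because the standard direct-fusion linker GCGGCCGCC carries a NotI core.
#'
#' @param names Optional subset of enzyme names.
#' @return A tibble with columns `name`, `site`.
#' @export
restriction_enzymes <- function(names = NULL) {
  tab <- tibble(
    name = c("KpnI", "BamHI", "NotI", "EcoRI", "XhoI", "HindIII", "NheI", "SalI"),
    site = c("GGTACC", "GGATCC", "GCGGCCGC", "GAATTC", "CTCGAG", "AAGCTT", "GCTAGC", "GTCGAC")
  )
  if (!is.null(names)) {
    missing <- setdiff(names, tab$name)
    if (length(missing)) {
      abort(paste0("unknown enzyme(s): ", paste(missing, collapse = ", ")),
        class = "optoxr_parameter_error"
      )
    }
    tab <- tab[match(names, tab$name), ]
  }
  for (s in tab$site) {
    if (nchar(s) < 4) abort("recognition sites must be at least 4 bp")
  }
  tab
}

#' Load a codon-usage table
#'
#' Reads a host codon-usage table (tab-delimited: amino acid, codon,
#' fraction), renormalises fractions within each amino acid, and checks every
#' codon against the standard genetic code. The mouse table ships with the
#' package (the usual expression host for neuroscience constructs); any
#' table in the same layout can be supplied.
#'
#' @param host `"mouse"` or a path to a table in the same format.
#' @return A tibble of class `codon_usage` with columns `aa`, `codon`,
#'   `fraction`, sorted within each amino acid by decreasing fraction (ties
#'   broken alphabetically); attribute `host`.
#' @export
codon_usage <- function(host = "mouse") {
  path <- if (file.exists(host)) {
    host
  } else if (host == "mouse") {
    system.file("extdata", "codon_usage_mouse.tsv", package = "optoxr")
  } else {
    abort(paste0("unknown codon-usage host: ", host),
      class = "optoxr_parameter_error"
    )
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df <- as_tibble(df)
  code <- genetic_code()
  expected <- code$aa[match(df$codon, code$codon)]
  if (any(expected != df$aa)) {
    abort("codon table disagrees with the standard genetic code",
      class = "optoxr_table_error"
    )
  }
  df <- df |>
    group_by(.data$aa) |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    ungroup() |>
    arrange(.data$aa, desc(.data$fraction), .data$codon)
  if (!all(AA_ALPHABET %in% df$aa)) {
    abort("codon table must cover all 20 amino acids",
      class = "optoxr_table_error"
    )
  }
  structure(df, class = c("codon_usage", class(tibble())),
            host = if (file.exists(host)) basename(host) else host)
}

#' Back-translate a protein with host codon preferences
#'
#' Deterministic mode picks each amino acid's highest-frequency codon (ties
#' broken alphabetically); sampled mode draws codons proportionally to their
#' fractions under the seed. In every mode
#' `translate_dna(back_translate(p)) == p`.
#'
#' @param p Protein string.
#' @param table A [codon_usage()] table.
#' @param mode `"deterministic"` (default) or `"sampled"`.
#' @param seed Integer seed for sampled mode.
#' @return DNA string (no stop codon appended).
#' @export
back_translate <- function(p, table = codon_usage(), mode = c("deterministic", "sampled"),
                           seed = 1L) {
  mode <- match.arg(mode)
  p <- aa(p)
  residues <- strsplit(p, "")[[1]]
  missing <- setdiff(unique(residues), table$aa)
  if (length(missing)) {
    abort(paste0("amino acid(s) absent from codon table: ",
                 paste(missing, collapse = ", ")),
      class = "optoxr_table_error"
    )
  }
  if (mode == "deterministic") {
    # table is sorted by decreasing fraction within aa; first match wins
    best <- table[!duplicated(table$aa), ]
    codons <- best$codon[match(residues, best$aa)]
  } else {
    by_aa <- split(table, table$aa)
    codons <- withr::with_seed(seed, vapply(residues, function(r) {
      sub <- by_aa[[r]]
      sample(sub$codon, 1L, prob = sub$fraction)
    }, character(1)))
  }
  paste(codons, collapse = "")
}

#' Scan a sequence for restriction sites
#'
#' Finds all occurrences of each enzyme's recognition site on the given
#' strand and its reverse complement, reported in top-strand coordinates and
#' deduplicated for palindromic sites.
#'
#' @param nt DNA string.
#' @param enzymes Tibble from [restriction_enzymes()].
#' @return A tibble with columns `name`, `site`, `position` (0-based, top
#'   strand), `strand` (`"+"`/`"-"`), sorted by position.
#' @export
scan_sites <- function(nt, enzymes = restriction_enzymes(c("KpnI", "BamHI"))) {
  nt <- dna(nt)
  subject <- Biostrings::DNAString(nt)
  n <- nchar(nt)
  hits <- purrr::map_dfr(seq_len(nrow(enzymes)), function(k) {
    site <- enzymes$site[k]
    fwd <- Biostrings::matchPattern(site, subject)
    out <- tibble(
      name = enzymes$name[k], site = site,
      position = Biostrings::start(fwd) - 1L, strand = "+"
    )
    rc <- revcomp(site)
    if (rc != site) {
      rev <- Biostrings::matchPattern(rc, subject)
      out <- bind_rows(out, tibble(
        name = enzymes$name[k], site = site,
        position = Biostrings::start(rev) - 1L, strand = "-"
      ))
    }
    out
  })
  hits |> arrange(.data$position, .data$name)
}

codon_index_overlapping <- function(hit_start, hit_end, frame_start) {
  first <- (hit_start - frame_start) %/% 3L
  last <- (hit_end - 1L - frame_start) %/% 3L
  first:last
}

#' Remove restriction sites from an ORF by synonymous substitution
#'
#' Iteratively takes the leftmost remaining hit and replaces one codon
#' overlapping it by that amino acid's next-most-frequent synonym, leaving
#' the translation unchanged. Regions listed in `protected` (0-based
#' half-open intervals) are exempt — the standard fusion linker deliberately
#' carries a NotI core and must survive.
#'
#' @param nt DNA string; positions from `frame_start` onward must form a
#'   whole-codon ORF.
#' @param frame_start 0-based offset of the reading frame.
#' @param enzymes Tibble from [restriction_enzymes()].
#' @param table A [codon_usage()] table.
#' @param protected Optional list of `c(start, end)` 0-based half-open
#'   intervals whose hits are retained.
#' @param max_iter Safety bound on substitution rounds (default 100).
#' @return DNA string free of unprotected hits, same translation.
#' @export
remove_sites <- function(nt, frame_start = 0L,
                         enzymes = restriction_enzymes(c("KpnI", "BamHI")),
                         table = codon_usage(), protected = list(),
                         max_iter = 100L) {
  nt <- dna(nt)
  orf_len <- nchar(nt) - frame_start
  if (orf_len < 3 || orf_len %% 3 != 0) {
    abort("region from frame_start must be a whole-codon ORF",
      class = "optoxr_precondition_error"
    )
  }
  is_protected <- function(s, e) {
    any(vapply(protected, function(iv) s < iv[2] && e > iv[1], logical(1)))
  }
  by_aa <- split(table, table$aa)
  code <- genetic_code()
  for (iter in seq_len(max_iter)) {
    hits <- scan_sites(nt, enzymes)
    if (nrow(hits) > 0) {
      keep <- !vapply(seq_len(nrow(hits)), function(i) {
        is_protected(hits$position[i], hits$position[i] + nchar(hits$site[i]))
      }, logical(1))
      hits <- hits[keep, , drop = FALSE]
    }
    if (nrow(hits) == 0) {
      return(nt)
    }
    h <- hits[1, ]
    site_len <- nchar(h$site)
    cods <- codon_index_overlapping(h$position, h$position + site_len, frame_start)
    cods <- cods[cods >= 0 & cods < orf_len %/% 3]
    if (length(cods) == 0) {
      abort(paste0("restriction site at position ", h$position,
                   " lies outside the ORF and cannot be recoded"),
        class = "optoxr_unresolvable_site_error"
      )
    }
    fixed <- FALSE
    for (ci in cods) {
      cstart <- frame_start + 3L * ci
      cur <- substr(nt, cstart + 1L, cstart + 3L)
      aa_here <- code$aa[match(cur, code$codon)]
      syns <- by_aa[[aa_here]]
      syns <- syns$codon[syns$codon != cur]
      for (syn in syns) {
        cand <- paste0(substr(nt, 1, cstart), syn,
                       substr(nt, cstart + 4L, nchar(nt)))
        # did the substitution clear this exact hit? (adjacent hits are
        # handled on later iterations)
        at_hit <- substr(cand, h$position + 1L, h$position + site_len)
        still <- at_hit == h$site || at_hit == revcomp(h$site)
        if (!still) {
          nt <- cand
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      abort(paste0("no synonymous substitution removes the ", h$name,
                   " site at position ", h$position),
        class = "optoxr_unresolvable_site_error"
      )
    }
  }
  abort("site removal did not converge within max_iter rounds",
    class = "optoxr_unresolvable_site_error"
  )
}

strip_terminal_stop <- function(orf, label = "ORF") {
  if (nchar(orf) %% 3 != 0) {
    abort(paste0(label, " length is not a multiple of 3"),
      class = "optoxr_frame_error"
    )
  }
  last <- substr(orf, nchar(orf) - 2L, nchar(orf))
  if (last %in% c("TAA", "TAG", "TGA")) {
    inform(paste0("terminal stop codon ", last, " stripped from ", label,
                  " before fusion"))
    orf <- substr(orf, 1L, nchar(orf) - 3L)
  }
  orf
}

#' Fuse an ORF to a fluorescent reporter
#'
#' Two cassette styles are supported. `direct_fusion`: ORF + in-frame linker
#' + reporter with its initiator ATG deleted + a single stop codon — one
#' continuous reading frame, so the receptor carries the fluorophore.
#' `t2a_bicistronic`: ORF + self-cleaving 2A peptide + intact reporter
#' (initiator retained), the AAV-vector layout in which receptor and
#' reporter separate during translation. Terminal stop codons on the inputs
#' are stripped with a notice.
#'
#' @param orf DNA string of the receptor ORF.
#' @param reporter DNA string of the reporter CDS (must begin with ATG in
#'   direct-fusion style).
#' @param linker In-frame linker for direct fusion; default `"GCGGCCGCC"`
#'   (encodes Ala-Ala-Ala and carries a NotI core usable for cloning).
#'   Length must be a multiple of 3.
#' @param style `"direct_fusion"` or `"t2a_bicistronic"`.
#' @param t2a DNA string of the 2A peptide (required for the bicistronic
#'   style; no default is baked in).
#' @param stop_codon Terminal stop emitted, default `"TAA"`.
#' @return An object of class `cassette_fragment`: tibble of elements
#'   (`role`, `seq`) with attribute `style`.
#' @export
fuse_reporter <- function(orf, reporter, linker = "GCGGCCGCC",
                          style = c("direct_fusion", "t2a_bicistronic"),
                          t2a = NULL, stop_codon = "TAA") {
  style <- match.arg(style)
  orf <- strip_terminal_stop(dna(orf), "receptor ORF")
  reporter <- dna(reporter)
  stopifnot(stop_codon %in% c("TAA", "TAG", "TGA"))
  if (style == "direct_fusion") {
    linker <- dna(linker)
    if (nchar(linker) %% 3 != 0) {
      abort("direct-fusion linker length must be a multiple of 3",
        class = "optoxr_frame_error"
      )
    }
    if (substr(reporter, 1, 3) != "ATG") {
      abort("reporter must begin with ATG for start-codon deletion",
        class = "optoxr_input_error"
      )
    }
    rep_body <- strip_terminal_stop(reporter, "reporter CDS")
    rep_body <- substr(rep_body, 4L, nchar(rep_body))
    elements <- tibble(
      role = c("orf", "linker", "reporter", "stop"),
      seq = c(orf, linker, rep_body, stop_codon)
    )
  } else {
    if (is.null(t2a)) {
      abort("t2a_bicistronic style requires a 2A peptide sequence",
        class = "optoxr_input_error"
      )
    }
    t2a <- dna(t2a)
    if (nchar(t2a) %% 3 != 0) {
      abort("2A peptide length must be a multiple of 3",
        class = "optoxr_frame_error"
      )
    }
    rep_body <- strip_terminal_stop(reporter, "reporter CDS")
    elements <- tibble(
      role = c("orf", "t2a", "reporter", "stop"),
      seq = c(orf, t2a, rep_body, stop_codon)
    )
  }
  structure(elements, class = c("cassette_fragment", class(tibble())),
            style = style)
}

#' Build a cloning-ready expression cassette
#'
#' Flanks the fused insert with the upstream and downstream cloning sites
#' and attaches promoter metadata. Refuses to proceed while the insert
#' carries either cloning site internally (run [remove_sites()] first, or
#' pass `check_sites = FALSE` deliberately).
#'
#' @param promoter Promoter name recorded as annotation metadata (the vector
#'   backbone itself is not reconstructed), e.g. `"hSyn"` or `"EF1a"`.
#' @param insert A `cassette_fragment` from [fuse_reporter()].
#' @param upstream,downstream Single-row enzyme tibbles
#'   (see [restriction_enzymes()]); defaults KpnI upstream, BamHI downstream.
#' @param check_sites Audit the insert for internal cloning sites (default
#'   TRUE).
#' @param host Codon host recorded in metadata.
#' @param id Cassette identifier.
#' @return An object of class `expression_cassette`: tibble of elements
#'   (`role`, `name`, `seq`, `start`, `end`, 0-based half-open) with
#'   attributes `seq`, `style`, `promoter`, `host`, `id`.
#' @export
build_cassette <- function(promoter, insert,
                           upstream = restriction_enzymes("KpnI"),
                           downstream = restriction_enzymes("BamHI"),
                           check_sites = TRUE, host = "mouse",
                           id = "cassette") {
  stopifnot(inherits(insert, "cassette_fragment"))
  insert_seq <- paste(insert$seq, collapse = "")
  if (check_sites) {
    hits <- scan_sites(insert_seq, bind_rows(upstream, downstream))
    if (nrow(hits) > 0) {
      abort(
        paste0("insert carries internal cloning site(s): ",
               paste(sprintf("%s@%d", hits$name, hits$position), collapse = ", ")),
        class = "optoxr_cassette_error",
        positions = hits$position
      )
    }
  }
  roles <- c("cloning_site", insert$role, "cloning_site")
  names_ <- c(upstream$name, insert$role, downstream$name)
  seqs <- c(upstream$site, insert$seq, downstream$site)
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs)
  elements <- tibble(
    role = roles, name = names_, seq = seqs,
    start = as.integer(starts), end = as.integer(ends)
  )
  full <- paste(seqs, collapse = "")
  cass <- structure(
    elements,
    class = c("expression_cassette", class(tibble())),
    seq = full, style = attr(insert, "style"),
    promoter = promoter, host = host, id = id
  )
  validate_cassette(cass)
  cass
}

#' Validate an expression cassette's reading frame
#'
#' Checks that element substrings concatenate to the full sequence and that
#' the fused ORF (orf + linker + reporter in direct-fusion style) is one
#' uninterrupted reading frame with no internal stop and exactly one
#' terminal stop, with the reporter initiator absent in direct fusion.
#'
#' @param cass An `expression_cassette`.
#' @return `cass`, invisibly; aborts on violation.
#' @export
validate_cassette <- function(cass) {
  full <- attr(cass, "seq")
  if (paste(cass$seq, collapse = "") != full) {
    abort("cassette elements do not concatenate to the full sequence",
      class = "optoxr_cassette_error"
    )
  }
  style <- attr(cass, "style")
  frame_roles <- if (style == "direct_fusion") {
    c("orf", "linker", "reporter", "stop")
  } else {
    c("orf", "t2a", "reporter", "stop")
  }
  cds <- paste(cass$seq[match(frame_roles, cass$role)], collapse = "")
  prot <- translate_dna(cds)
  if (!attr(prot, "stopped")) {
    abort("cassette ORF lacks a terminal stop codon", class = "optoxr_cassette_error")
  }
  if ((attr(prot, "stop_codon") + 1L) * 3L != nchar(cds)) {
    abort("cassette ORF contains an internal stop codon",
      class = "optoxr_cassette_error"
    )
  }
  if (style == "direct_fusion") {
    rep_seq <- cass$seq[cass$role == "reporter"]
    orf_lnk <- sum(nchar(cass$seq[cass$role %in% c("orf", "linker")]))
    # the reporter body must continue the frame without re-initiating
    if (orf_lnk %% 3 != 0) {
      abort("direct-fusion reporter is out of frame", class = "optoxr_cassette_error")
    }
  }
  invisible(cass)
}

#' Cassette as an annotated GenBank record
#'
#' @param cass An `expression_cassette`.
#' @return A record list suitable for [write_genbank()]; the promoter is
#'   emitted as a zero-length-free annotation on the whole record
#'   definition, each element as a feature.
#' @export
cassette_record <- function(cass) {
  key_for <- function(role) {
    switch(role,
      orf = "CDS", reporter = "CDS", linker = "misc_feature",
      t2a = "misc_feature", stop = "misc_feature",
      cloning_site = "misc_feature", "misc_feature"
    )
  }
  list(
    locus = attr(cass, "id"),
    definition = paste0(attr(cass, "style"), " cassette; promoter=",
                        attr(cass, "promoter"), "; host=", attr(cass, "host")),
    seq = attr(cass, "seq"),
    features = tibble(
      key = vapply(cass$role, key_for, character(1)),
      start = cass$start, end = cass$end, label = cass$name
    )
  )
}

#' @export
tidy.expression_cassette <- function(x, ...) {
  tibble(role = x$role, name = x$name, start = x$start, end = x$end,
         length = x$end - x$start)
}

#' @export
glance.expression_cassette <- function(x, ...) {
  tibble(
    id = attr(x, "id"), style = attr(x, "style"),
    promoter = attr(x, "promoter"), host = attr(x, "host"),
    length = nchar(attr(x, "seq")), n_elements = nrow(x)
  )
}

#' @export
print.expression_cassette <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("expression cassette '%s' (%s, promoter %s, host %s), %d bp\n",
              g$id, g$style, g$promoter, g$host, g$length))
  print(tidy(x))
  invisible(x)
}
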