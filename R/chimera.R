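# Chimera assembly: replace intracellular parts of a light-sensing backbone
# with those of a target GPCR. Splice junctions fall exactly at the
# backbone's TM boundaries: the backbone TMs carry the light-sensing
# function and must stay intact, and whole loops are swapped whatever the
# target loop's length (the chimera simply changes length).

SWAPPABLE <- c("IL1", "IL2", "IL3", "Ct")

#' Assemble an opto-XR chimera
#'
#' Takes every segment from the backbone except those named in `swap`, which
#' come from the target. Only intracellular parts (`IL1`, `IL2`, `IL3`,
#' `Ct`) may be swapped; the default swap set is the full set, the classic
#' opto-XR design.
#'
#' @param backbone,target Protein strings.
#' @param backbone_map,target_map Their `topology_map`s.
#' @param swap Character vector, non-empty subset of
#'   `c("IL1","IL2","IL3","Ct")`.
#' @param junction_offset Integer; shifts every splice junction into the
#'   backbone (+) or target (-) loop by this many residues. Default 0 (cut
#'   exactly at the backbone TM boundary); exposed because published
#'   constructs sometimes retain TM-proximal anchor residues.
#' @param backbone_id,target_id Identifiers recorded in the design.
#' @return An object of class `chimera_design`: a tibble of 15 parts
#'   (`label`, `source`, `seq`, `src_start`, `src_end`) with attributes
#'   `protein` (the assembled sequence), `backbone_id`, `target_id`, `swap`.
#' @export
assemble_chimera <- function(backbone, backbone_map, target, target_map,
                             swap = c("IL1", "IL2", "IL3", "Ct"),
                             junction_offset = 0L,
                             backbone_id = attr(backbone_map, "seq_id"),
                             target_id = attr(target_map, "seq_id")) {
  backbone <- aa(backbone)
  target <- aa(target)
  validate_topology_map(backbone_map)
  validate_topology_map(target_map)
  if (length(swap) == 0 || !all(swap %in% SWAPPABLE)) {
    bad <- setdiff(swap, SWAPPABLE)
    if (any(grepl("^TM", bad))) {
      warn("a swap touching a TM segment was requested and rejected")
    }
    abort(
      "swap must be a non-empty subset of {IL1, IL2, IL3, Ct}",
      class = "optoxr_swap_error"
    )
  }
  stopifnot(junction_offset == 0L || is.numeric(junction_offset))

  parts <- purrr::map_dfr(seq_along(SEGMENT_ORDER), function(k) {
    lab <- SEGMENT_ORDER[k]
    from_target <- lab %in% swap
    map <- if (from_target) target_map else backbone_map
    src <- if (from_target) target else backbone
    i <- match(lab, map$label)
    s <- map$start[i]
    e <- map$end[i]
    if (from_target && lab != "Ct" && junction_offset != 0L) {
      s <- s + junction_offset
      e <- e - junction_offset
    }
    if (from_target && e <= s) {
      abort(paste0("swapped segment ", lab, " is empty in the target"),
        class = "optoxr_assembly_error"
      )
    }
    tibble(
      label = lab,
      source = if (from_target) "target" else "backbone",
      seq = substr(src, s + 1L, e),
      src_start = as.integer(s), src_end = as.integer(e)
    )
  })
  assembled <- paste(parts$seq, collapse = "")
  structure(
    parts,
    class = c("chimera_design", class(tibble())),
    protein = assembled,
    backbone_id = backbone_id %||% "backbone",
    target_id = target_id %||% "target",
    swap = sort(swap)
  )
}

#' Assembled chimera protein
#'
#' @param design A `chimera_design`.
#' @return The assembled protein string.
#' @export
chimera_protein <- function(design) {
  stopifnot(inherits(design, "chimera_design"))
  attr(design, "protein")
}

#' Topology map of an assembled chimera, in chimera coordinates
#'
#' Re-derives segment coordinates from the recorded part lengths (not by
#' re-calling topology), so re-assembly from a design is exact.
#'
#' @param design A `chimera_design`.
#' @return A `topology_map` over the assembled protein.
#' @export
chimera_topology <- function(design) {
  stopifnot(inherits(design, "chimera_design"))
  lens <- nchar(design$seq)
  ends <- cumsum(lens)
  starts <- ends - lens
  new_topology_map(
    tibble(label = design$label, start = as.integer(starts), end = as.integer(ends)),
    seq_id = paste0(attr(design, "backbone_id"), "-", attr(design, "target_id")),
    length = sum(lens),
    orientation = "extracellular"
  )
}

#' Per-residue provenance track of a chimera design
#'
#' One provenance symbol per residue of the assembled protein; counts by
#' source always sum to the total length.
#'
#' @param design A `chimera_design`.
#' @return A tibble with columns `position` (1-based), `label`, `source`.
#' @export
diff_report <- function(design) {
  stopifnot(inherits(design, "chimera_design"))
  lens <- nchar(design$seq)
  tibble(
    position = seq_len(sum(lens)),
    label = rep(design$label, lens),
    source = rep(design$source, lens)
  )
}

#' Splice junction positions of a design
#'
#' A junction is a boundary between a backbone-sourced and a target-sourced
#' part, in 0-based chimera protein coordinates. These are the positions
#' junction-spanning qPCR primers are designed against (times 3 in CDS
#' coordinates).
#'
#' @param design A `chimera_design`.
#' @return Tibble with columns `junction` (0-based position), `left_label`,
#'   `right_label`.
#' @export
chimera_junctions <- function(design) {
  lens <- nchar(design$seq)
  ends <- cumsum(lens)
  idx <- which(design$source[-1] != design$source[-length(design$source)])
  tibble(
    junction = as.integer(ends[idx]),
    left_label = design$label[idx],
    right_label = design$label[idx + 1L]
  )
}

#' Export a chimera design: FASTA plus provenance sidecar
#'
#' Writes the assembled protein as FASTA and a tab-delimited provenance
#' table (part label, source, start, end in chimera coordinates).
#'
#' @param design A `chimera_design`.
#' @param fasta_path,provenance_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_chimera <- function(design, fasta_path, provenance_path) {
  id <- paste0("chimera|", attr(design, "backbone_id"), "|", attr(design, "target_id"))
  write_fasta(tibble(id = id, description = paste("swap:", paste(attr(design, "swap"), collapse = ",")),
                     seq = chimera_protein(design)), fasta_path)
  cm <- chimera_topology(design)
  df <- data.frame(
    label = design$label, source = design$source,
    start = cm$start, end = cm$end
  )
  utils::write.table(df, provenance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' @export
tidy.chimera_design <- function(x, ...) {
  cm <- chimera_topology(x)
  tibble(
    label = x$label, source = x$source,
    start = cm$start, end = cm$end, length = nchar(x$seq),
    src_start = x$src_start, src_end = x$src_end
  )
}

#' @export
glance.chimera_design <- function(x, ...) {
  lens <- nchar(x$seq)
  tibble(
    backbone_id = attr(x, "backbone_id"),
    target_id = attr(x, "target_id"),
    swap = paste(attr(x, "swap"), collapse = ","),
    length = sum(lens),
    n_backbone_residues = sum(lens[x$source == "backbone"]),
    n_target_residues = sum(lens[x$source == "target"]),
    n_junctions = nrow(chimera_junctions(x))
  )
}

#' @export
print.chimera_design <- function(x, ...) {
  g <- glance(x)
  cat("opto-XR chimera design:", g$backbone_id, "x", g$target_id, "\n")
  cat("  swap:", g$swap, " length:", g$length,
      sprintf("(%d backbone + %d target residues)\n",
              g$n_backbone_residues, g$n_target_residues))
  print(tidy(x))
  invisible(x)
}
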