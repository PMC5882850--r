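# 7TM topology calling: Kyte-Doolittle hydropathy -> candidate TM runs ->
# canonical 15-segment partition (Nt, TM1-7, IL1-3, EL1-3, Ct) -> optional
# consensus over an aligned homolog family.

#' Kyte-Doolittle hydropathy values
#'
#' @return Named numeric vector of per-residue hydropathy for the 20 standard
#'   amino acids.
#' @export
kyte_doolittle <- function() {
  c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )
}

SEGMENT_ORDER <- c(
  "Nt", "TM1", "IL1", "TM2", "EL1", "TM3", "IL2", "TM4",
  "EL2", "TM5", "IL3", "TM6", "EL3", "TM7", "Ct"
)

# canonical 15-segment order for a given N-terminus orientation; loops
# alternate sides starting opposite the N-terminus
segment_order <- function(orientation = "extracellular") {
  if (orientation == "extracellular") {
    SEGMENT_ORDER
  } else {
    loop <- c("EL1", "IL1", "EL2", "IL2", "EL3", "IL3")
    c("Nt", as.vector(rbind(paste0("TM", 1:7), c(loop, "Ct"))))
  }
}

#' Windowed hydropathy profile
#'
#' Position `i` holds the arithmetic mean of Kyte-Doolittle values over a
#' window centred at `i`. Windows are truncated at the sequence ends and
#' averaged over the residues actually present — no padding, so no hydropathy
#' is fabricated at the termini.
#'
#' @param p Protein string.
#' @param window Odd window length, between 5 and 31 and at most the protein
#'   length (default 19, the classical choice for TM helix detection).
#' @return A tibble of class `hydropathy_profile` with columns `position`
#'   (1-based) and `hydropathy`; attributes `window`, `scale`, `seq`.
#' @export
hydropathy_profile <- function(p, window = 19L) {
  p <- aa(p)
  n <- nchar(p)
  if (window %% 2 == 0 || window < 5 || window > 31 || window > n) {
    abort("window must be odd, within [5, 31], and at most the protein length",
      class = "optoxr_parameter_error"
    )
  }
  kd <- unname(kyte_doolittle()[strsplit(p, "")[[1]]])
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(kd))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  prof <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  structure(
    tibble(position = i, hydropathy = prof),
    class = c("hydropathy_profile", class(tibble())),
    window = as.integer(window), scale = "Kyte-Doolittle", seq = p
  )
}

# change-point refinement of one run edge on the *unwindowed* KD values:
# pick the cut in [lo, hi] (0-based half-open boundary positions) that best
# separates hydrophobic (inside) from hydrophilic (outside). KD zero is the
# natural midpoint between the two classes, so the optimal cut is the
# argmin/argmax of the KD prefix sum over the search window. Detected run
# edges always lie inside the true helix (the windowed profile crosses the
# threshold only once most of the window is hydrophobic), so the search
# extends outward from the run only.
refine_edge <- function(kd, lo, hi, side = c("left", "right")) {
  side <- match.arg(side)
  cand <- lo:hi
  cs <- c(0, cumsum(kd))
  pre <- cs[cand + 1L] # sum of kd[1..cand] (0-based prefix)
  if (side == "left") {
    # boundary b: loop on [.., b), TM on [b, ..): minimise prefix sum
    cand[which.min(pre)]
  } else {
    # boundary b: TM on [.., b), loop on [b, ..): maximise prefix sum
    cand[which.max(pre)]
  }
}

#' Call candidate transmembrane segments from a hydropathy profile
#'
#' Detection proceeds on the windowed profile: maximal runs at or above
#' `threshold`; runs separated by fewer than `min_loop_len` positions are
#' merged; runs longer than `max_tm_len` are split at their interior profile
#' minimum. Each run edge is then refined by a change-point fit on the raw
#' per-residue hydropathy (the windowed profile smears each boundary inward
#' by roughly half a window, so raw run edges under-call the helix),
#' searching within half a window of the detected edge. Only after
#' refinement are intervals shorter than `min_tm_len` dropped — a true
#' minimum-length helix yields an above-threshold run well below
#' `min_tm_len` positions long, so filtering raw runs would discard real
#' helices.
#'
#' @param profile A [hydropathy_profile()].
#' @param threshold Profile threshold for a TM run (default 1.6).
#' @param min_tm_len,max_tm_len Accepted TM length range (defaults 15, 30).
#' @param min_loop_len Minimum separation between distinct runs (default 4).
#' @param refine Refine edges on the unwindowed hydropathy (default TRUE).
#' @return A tibble with columns `start`, `end` (0-based half-open), sorted
#'   by `start`. May hold any number of rows; [partition_7tm()] insists on 7.
#' @export
call_tm_segments <- function(profile, threshold = 1.6,
                             min_tm_len = 15L, max_tm_len = 30L,
                             min_loop_len = 4L, refine = TRUE) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  prof <- profile$hydropathy
  n <- length(prof)
  above <- prof >= threshold
  if (!any(above)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values] - 1L, end = ends[r$values]) # 0-based half-open

  # merge runs separated by short gaps
  if (nrow(runs) > 1) {
    keep_start <- runs$start[1]
    merged <- list()
    cur <- c(runs$start[1], runs$end[1])
    for (k in 2:nrow(runs)) {
      if (runs$start[k] - cur[2] < min_loop_len) {
        cur[2] <- runs$end[k]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(runs$start[k], runs$end[k])
      }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- tibble(
      start = vapply(merged, `[`, numeric(1), 1),
      end = vapply(merged, `[`, numeric(1), 2)
    )
  }

  # split over-long runs at the interior profile minimum (recursively)
  split_run <- function(s, e) {
    if (e - s <= max_tm_len) {
      return(list(c(s, e)))
    }
    interior <- (s + 4L):(e - 4L)
    cut <- interior[which.min(prof[interior + 1L])]
    c(split_run(s, cut), split_run(cut + 1L, e))
  }
  pieces <- do.call(c, lapply(seq_len(nrow(runs)), function(k) {
    split_run(runs$start[k], runs$end[k])
  }))
  runs <- tibble(
    start = as.integer(vapply(pieces, `[`, numeric(1), 1)),
    end = as.integer(vapply(pieces, `[`, numeric(1), 2))
  )
  runs <- runs[order(runs$start), , drop = FALSE]

  if (refine && nrow(runs) > 0) {
    kd <- unname(kyte_doolittle()[strsplit(attr(profile, "seq"), "")[[1]]])
    span <- attr(profile, "window")
    for (k in seq_len(nrow(runs))) {
      lo_lim <- if (k == 1) 0L else runs$end[k - 1L]
      hi_lim <- if (k == nrow(runs)) n else runs$start[k + 1L]
      s <- refine_edge(kd, max(lo_lim, runs$start[k] - span), runs$start[k], "left")
      e <- refine_edge(kd, runs$end[k], min(hi_lim, runs$end[k] + span), "right")
      if (e - s > max_tm_len) {
        # pull the edges back toward the detected run symmetrically
        excess <- (e - s) - max_tm_len
        s <- s + excess %/% 2L
        e <- e - (excess - excess %/% 2L)
      }
      runs$start[k] <- s
      runs$end[k] <- e
    }
  }
  # length filter on the refined intervals, with a 2-residue allowance for
  # boundary-estimate uncertainty
  runs <- runs[runs$end - runs$start >= min_tm_len - 2L, , drop = FALSE]
  runs
}

#' Partition a protein into the canonical 15-segment 7TM topology
#'
#' Loops between consecutive TMs alternate sides starting from the declared
#' orientation of the N-terminus: with an extracellular N-terminus (the
#' default, true of both channelrhodopsins and GPCRs) the loops after TM1,
#' TM3, TM5 are intracellular (IL1-3) and those after TM2, TM4, TM6
#' extracellular (EL1-3). The span before TM1 is Nt, after TM7 is Ct.
#'
#' @param p Protein string.
#' @param tm_intervals Tibble of exactly 7 sorted, non-overlapping `start`,
#'   `end` intervals (0-based half-open), e.g. from [call_tm_segments()].
#' @param orientation `"extracellular"` (default) or `"intracellular"` side
#'   of the N-terminus.
#' @param id Sequence identifier recorded in the map.
#' @return A tibble of class `topology_map` with columns `label`, `start`,
#'   `end`; attributes `seq_id`, `length`, `orientation`.
#' @export
partition_7tm <- function(p, tm_intervals,
                          orientation = c("extracellular", "intracellular"),
                          id = "protein") {
  orientation <- match.arg(orientation)
  p <- aa(p)
  n <- nchar(p)
  tm <- as_tibble(tm_intervals)
  if (nrow(tm) != 7) {
    abort(
      paste0("expected exactly 7 TM intervals, got ", nrow(tm),
             "; adjust the calling threshold"),
      class = "optoxr_topology_error",
      candidates = tm
    )
  }
  tm <- tm[order(tm$start), , drop = FALSE]
  if (any(tm$start[-1] < tm$end[-7]) || tm$start[1] < 0 || tm$end[7] > n) {
    abort("TM intervals must be non-overlapping and within the protein",
      class = "optoxr_topology_error"
    )
  }
  loop_labels <- if (orientation == "extracellular") {
    c("IL1", "EL1", "IL2", "EL2", "IL3", "EL3")
  } else {
    c("EL1", "IL1", "EL2", "IL2", "EL3", "IL3")
  }
  labels <- c("Nt", rbind(paste0("TM", 1:7),
                          c(loop_labels, "Ct")))
  starts <- integer(15)
  ends <- integer(15)
  starts[1] <- 0L; ends[1] <- tm$start[1]
  for (k in 1:7) {
    starts[2 * k] <- tm$start[k]
    ends[2 * k] <- tm$end[k]
    starts[2 * k + 1] <- tm$end[k]
    ends[2 * k + 1] <- if (k < 7) tm$start[k + 1] else n
  }
  map <- tibble(label = labels, start = as.integer(starts), end = as.integer(ends))
  new_topology_map(map, seq_id = id, length = n, orientation = orientation)
}

new_topology_map <- function(map, seq_id, length, orientation) {
  out <- structure(
    as_tibble(map),
    class = c("topology_map", class(tibble())),
    seq_id = seq_id, length = as.integer(length), orientation = orientation
  )
  validate_topology_map(out)
  out
}

#' Validate a 15-segment topology map
#'
#' Checks the fixed segment order, contiguous full coverage of the protein,
#' and non-negative segment lengths. Used internally on every construction.
#'
#' @param map A `topology_map`.
#' @return `map`, invisibly; aborts with class `optoxr_topology_error` on any
#'   violation.
#' @export
validate_topology_map <- function(map) {
  expected <- segment_order(attr(map, "orientation") %||% "extracellular")
  if (!identical(map$label, expected)) {
    abort("topology map must hold the 15 canonical segments in order",
      class = "optoxr_topology_error"
    )
  }
  n <- attr(map, "length")
  if (map$start[1] != 0L || map$end[15] != n) {
    abort("topology map must cover the protein from 0 to length",
      class = "optoxr_topology_error"
    )
  }
  if (any(map$end < map$start)) {
    abort("topology segments must have non-negative length",
      class = "optoxr_topology_error"
    )
  }
  if (any(map$start[-1] != map$end[-15])) {
    abort("topology segments must be contiguous", class = "optoxr_topology_error")
  }
  invisible(map)
}

#' Call the full 7TM topology of a protein in one step
#'
#' Convenience wrapper: [hydropathy_profile()] then [call_tm_segments()] then
#' [partition_7tm()].
#'
#' @inheritParams hydropathy_profile
#' @inheritParams call_tm_segments
#' @inheritParams partition_7tm
#' @return A `topology_map`.
#' @export
call_topology <- function(p, window = 19L, threshold = 1.6,
                          min_tm_len = 15L, max_tm_len = 30L,
                          min_loop_len = 4L,
                          orientation = "extracellular", id = "protein") {
  prof <- hydropathy_profile(p, window)
  tm <- call_tm_segments(prof, threshold, min_tm_len, max_tm_len, min_loop_len)
  partition_7tm(p, tm, orientation, id = id)
}

#' Consensus topology over an aligned homolog family
#'
#' Each internal boundary of the reference map is replaced by the median of
#' the homolog boundaries projected into reference coordinates through the
#' star MSA (the reference's own call votes too). The median, not the mean,
#' is used: it returns an integral coordinate and shrugs off one divergent
#' homolog. Homologs whose boundary falls in a reference-gap column are
#' skipped for that boundary with a notice. The result is clipped so segment
#' order is preserved and every TM keeps at least `min_tm_len` residues.
#'
#' @param reference_map `topology_map` of the reference.
#' @param family_maps List of `topology_map`s for MSA rows 2, 3, ... in order.
#' @param msa A [star_msa()] with the reference in row 1.
#' @param min_tm_len Minimum TM length preserved by clipping (default 15).
#' @return A consensus `topology_map` in reference coordinates.
#' @export
consensus_topology <- function(reference_map, family_maps, msa,
                               min_tm_len = 15L) {
  stopifnot(inherits(reference_map, "topology_map"), inherits(msa, "star_msa"))
  if (length(family_maps) != nrow(msa$rows) - 1L) {
    abort("need one family map per non-reference MSA row",
      class = "optoxr_precondition_error"
    )
  }
  n <- attr(reference_map, "length")
  # the 14 internal boundaries are the segment starts of segments 2..15
  ref_bounds <- reference_map$start[-1]
  votes <- matrix(NA_real_, nrow = length(family_maps) + 1L, ncol = 14L)
  votes[1, ] <- ref_bounds
  for (h in seq_along(family_maps)) {
    fb <- family_maps[[h]]$start[-1]
    len_h <- attr(family_maps[[h]], "length")
    for (b in seq_len(14L)) {
      pos <- fb[b]
      # a boundary at the row's length projects just past the last residue
      mapped <- if (pos >= len_h) {
        n
      } else {
        m <- map_position(msa, h + 1L, pos)
        if (is.na(m)) NA_real_ else m
      }
      if (is.na(mapped)) {
        inform(paste0("homolog ", h, ": boundary ", b,
                      " falls in a reference gap; vote skipped"))
      }
      votes[h + 1L, b] <- mapped
    }
  }
  cons <- vapply(seq_len(14L), function(b) {
    v <- votes[, b]
    v <- v[!is.na(v)]
    as.integer(floor(median(v) + 0.5))
  }, integer(1))
  # clip: enforce non-decreasing boundaries and minimum TM lengths
  is_tm_seg <- grepl("^TM", reference_map$label) # segments 1..15
  lower <- 0L
  for (b in seq_len(14L)) {
    cons[b] <- max(cons[b], lower)
    cons[b] <- min(cons[b], n)
    # segment b runs from cons[b-1] to cons[b]; keep TMs >= min_tm_len
    seg_start <- if (b == 1) 0L else cons[b - 1L]
    if (is_tm_seg[b] && cons[b] - seg_start < min_tm_len) {
      cons[b] <- min(seg_start + min_tm_len, n)
    }
    lower <- cons[b]
  }
  map <- tibble(
    label = SEGMENT_ORDER,
    start = as.integer(c(0L, cons)),
    end = as.integer(c(cons, n))
  )
  new_topology_map(map,
    seq_id = attr(reference_map, "seq_id"), length = n,
    orientation = attr(reference_map, "orientation")
  )
}

#' Extract a segment's substring
#'
#' @param p Protein string the map describes.
#' @param map A `topology_map`.
#' @param label Segment label, e.g. `"IL2"`.
#' @return The segment substring (may be empty for zero-length termini).
#' @export
segment_seq <- function(p, map, label) {
  k <- match(label, map$label)
  if (is.na(k)) abort(paste0("unknown segment label: ", label))
  substr(p, map$start[k] + 1L, map$end[k])
}

# ---- import/export --------------------------------------------------------

#' Write a topology map as BED-like tab-delimited text
#'
#' Columns: sequence id, start, end, label (0-based half-open, matching BED).
#'
#' @param map A `topology_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(map, path) {
  df <- data.frame(
    seq_id = attr(map, "seq_id"), start = map$start, end = map$end,
    label = map$label
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a topology map written by [write_topology()]
#'
#' @param path Path to the BED-like file.
#' @param orientation N-terminus orientation to record (not stored in BED).
#' @return A `topology_map`.
#' @export
read_topology <- function(path, orientation = "extracellular") {
  df <- utils::read.table(path, sep = "\t", col.names = c("seq_id", "start", "end", "label"))
  new_topology_map(
    tibble(label = df$label, start = as.integer(df$start), end = as.integer(df$end)),
    seq_id = df$seq_id[1], length = max(df$end), orientation = orientation
  )
}

#' @export
tidy.topology_map <- function(x, ...) {
  tibble(
    label = x$label, start = x$start, end = x$end,
    length = x$end - x$start,
    compartment = dplyr::case_when(
      grepl("^TM", x$label) ~ "membrane",
      x$label %in% c("IL1", "IL2", "IL3") ~ "intracellular",
      x$label %in% c("EL1", "EL2", "EL3") ~ "extracellular",
      x$label == "Nt" & attr(x, "orientation") == "extracellular" ~ "extracellular",
      x$label == "Nt" ~ "intracellular",
      x$label == "Ct" & attr(x, "orientation") == "extracellular" ~ "intracellular",
      TRUE ~ "extracellular"
    )
  )
}

#' @export
glance.topology_map <- function(x, ...) {
  tm <- x[grepl("^TM", x$label), ]
  tibble(
    seq_id = attr(x, "seq_id"), length = attr(x, "length"),
    orientation = attr(x, "orientation"),
    n_tm = nrow(tm),
    mean_tm_length = mean(tm$end - tm$start)
  )
}
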