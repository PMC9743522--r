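#' Structural-variant event for the simulator
#'
#' The event grammar covers the rearrangement mechanisms the downstream
#' analysis must detect: `tandem_duplication` (the canonical head-to-tail
#' duplication fusing a downstream partner to the kept gene terminal),
#' `deletion`, `insertion_translocation` (a target segment is lost and a
#' segment copied from another chromosome is inserted in its place — the
#' 151 kb loss / 263 kb insertion mechanism) and `balanced_translocation`
#' (reciprocal arm exchange). Breakpoints are bin-aligned by the simulator;
#' sub-bin breakpoints are out of scope because all downstream analysis is
#' binned.
#'
#' @param type One of `tandem_duplication`, `deletion`,
#'   `insertion_translocation`, `balanced_translocation`.
#' @param chrom,start,end Target interval on the affected chromosome. For a
#'   balanced translocation, `start` is the breakpoint and `end` is ignored.
#' @param source_chrom,source_start,source_end Source segment for
#'   `insertion_translocation` (inserted copy) or partner breakpoint
#'   (`source_chrom`, `source_start`) for `balanced_translocation`.
#' @param orientation `"forward"` or `"inverted"` orientation of the inserted
#'   source segment.
#' @return An `sv_event`.
#' @export
sv_event <- function(type = c("tandem_duplication", "deletion",
                              "insertion_translocation", "balanced_translocation"),
                     chrom, start, end = NA,
                     source_chrom = NULL, source_start = NULL, source_end = NULL,
                     orientation = c("forward", "inverted")) {
  type <- match.arg(type)
  orientation <- match.arg(orientation)
  if (type == "insertion_translocation") {
    if (is.null(source_chrom) || is.null(source_start) || is.null(source_end))
      stop_fmt("insertion_translocation needs a source segment (source_chrom/start/end)")
    if (source_chrom == chrom)
      stop_fmt("insertion_translocation source must be on another chromosome")
  }
  if (type == "balanced_translocation") {
    if (is.null(source_chrom) || is.null(source_start))
      stop_fmt("balanced_translocation needs a partner breakpoint (source_chrom/start)")
    if (source_chrom == chrom)
      stop_fmt("balanced_translocation partner must be on another chromosome")
  }
  structure(list(type = type, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 source_chrom = source_chrom,
                 source_start = if (is.null(source_start)) NULL else as.numeric(source_start),
                 source_end = if (is.null(source_end)) NULL else as.numeric(source_end),
                 orientation = orientation),
            class = "sv_event")
}

snap_down <- function(x, bin) floor(x / bin) * bin
snap_up <- function(x, bin) ceiling(x / bin) * bin

# bin-align an event's intervals; error when off the chromosome
align_event <- function(ev, bin_size, chrom_lengths) {
  check_chrom <- function(ch) {
    if (!ch %in% names(chrom_lengths))
      stop_fmt("event chromosome '%s' is not in the reference", ch)
  }
  check_chrom(ev$chrom)
  ev$start <- snap_down(ev$start, bin_size)
  if (ev$type == "balanced_translocation") {
    check_chrom(ev$source_chrom)
    ev$source_start <- snap_down(ev$source_start, bin_size)
    if (ev$start <= 0 || ev$start >= chrom_lengths[[ev$chrom]] ||
        ev$source_start <= 0 || ev$source_start >= chrom_lengths[[ev$source_chrom]])
      stop_fmt("balanced translocation breakpoint off chromosome")
    return(ev)
  }
  ev$end <- snap_up(ev$end, bin_size)
  if (ev$start < 0 || ev$end > chrom_lengths[[ev$chrom]])
    stop_fmt("event interval [%s, %s) extends past chromosome '%s' (length %s)",
             format(ev$start, big.mark = ","), format(ev$end, big.mark = ","),
             ev$chrom, format(chrom_lengths[[ev$chrom]], big.mark = ","))
  if (ev$end - ev$start < bin_size)
    stop_fmt("event interval narrower than one %s bp bin", format(bin_size, big.mark = ","))
  if (ev$type == "insertion_translocation") {
    check_chrom(ev$source_chrom)
    ev$source_start <- snap_down(ev$source_start, bin_size)
    ev$source_end <- snap_up(ev$source_end, bin_size)
    if (ev$source_start < 0 || ev$source_end > chrom_lengths[[ev$source_chrom]])
      stop_fmt("insertion source segment extends past chromosome '%s'", ev$source_chrom)
    if (ev$source_end - ev$source_start < bin_size)
      stop_fmt("insertion source narrower than one bin")
  }
  ev
}

#' Build a derived (rearranged) genome
#'
#' Applies a set of non-overlapping structural-variant events to a reference
#' and returns the derived chromosomes as ordered lists of oriented reference
#' segments, together with a bin-level lift-over table mapping every derived
#' bin back to its reference bin. Walking a derived chromosome and
#' concatenating its reference segments reproduces the rearranged molecule;
#' with no events the derived genome is the reference, segment for segment.
#'
#' The inserted segment of an `insertion_translocation` is copied (its source
#' chromosome stays intact), mirroring the observed co-occurring duplication
#' at the source locus for this mechanism. A `balanced_translocation` cannot
#' be combined with other events on the same chromosomes.
#'
#' @param reference Named numeric vector (or data.frame `chrom`/`length`) of
#'   chromosome lengths; lengths must be multiples of `bin_size`.
#' @param events List of [sv_event()]s; intervals are snapped outward to bin
#'   boundaries and must not overlap after snapping.
#' @param bin_size Simulator bin width in bp.
#' @return A `derived_genome`: list with `segments` (data.frame `dchrom`,
#'   `chrom`, `start`, `end`, `orientation`), `derived_lengths`, `liftover`
#'   (data.frame `dchrom`, `dbin`, `ref_bin`, `orientation`),
#'   `bins_derived`, `bins_reference`, `breakpoints` (novel junctions in
#'   reference coordinates), `events`, `bin_size`, `reference`.
#' @export
build_derived_genome <- function(reference, events = list(), bin_size) {
  chrom_lengths <- as_chrom_lengths(reference)
  if (any(chrom_lengths %% bin_size != 0))
    stop_fmt("reference chromosome lengths must be multiples of bin_size")
  if (inherits(events, "sv_event")) events <- list(events)
  events <- lapply(events, align_event, bin_size = bin_size,
                   chrom_lengths = chrom_lengths)

  # reject overlapping target intervals on the same chromosome
  target_iv <- function(ev) {
    if (ev$type == "balanced_translocation")
      gi(ev$chrom, ev$start, chrom_lengths[[ev$chrom]])
    else gi(ev$chrom, ev$start, ev$end)
  }
  if (length(events) >= 2L) {
    ivs <- lapply(events, target_iv)
    for (a in seq_len(length(events) - 1L)) for (b in (a + 1L):length(events)) {
      if (gi_overlaps(ivs[[a]], ivs[[b]]))
        stop_fmt("events %d and %d overlap on %s after bin alignment: [%s, %s) vs [%s, %s)",
                 a, b, ivs[[a]]$chrom,
                 format(ivs[[a]]$start, big.mark = ","), format(ivs[[a]]$end, big.mark = ","),
                 format(ivs[[b]]$start, big.mark = ","), format(ivs[[b]]$end, big.mark = ","))
    }
  }
  bal <- events[vapply(events, function(e) e$type == "balanced_translocation", TRUE)]
  std <- events[vapply(events, function(e) e$type != "balanced_translocation", TRUE)]
  bal_chroms <- unlist(lapply(bal, function(e) c(e$chrom, e$source_chrom)))
  std_chroms <- unlist(lapply(std, function(e) {
    c(e$chrom, if (e$type == "insertion_translocation") e$source_chrom)
  }))
  if (length(intersect(bal_chroms, std_chroms)) > 0L ||
      anyDuplicated(bal_chroms) > 0L)
    stop_fmt("balanced translocations cannot be combined with other events on the same chromosome")

  seg_rows <- list()
  emit <- function(dchrom, chrom, start, end, orientation = "forward") {
    if (end > start)
      seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
        dchrom = dchrom, chrom = chrom, start = start, end = end,
        orientation = orientation, stringsAsFactors = FALSE)
  }
  breakpoints <- list()
  bp <- function(chrom1, pos1, chrom2, pos2, type, event_id) {
    breakpoints[[length(breakpoints) + 1L]] <<- data.frame(
      chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
      sv_type = type, event_id = event_id, stringsAsFactors = FALSE)
  }
  ev_ids <- seq_along(events)
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    if (ch %in% bal_chroms) {
      e <- bal[[which(vapply(bal, function(x) ch %in% c(x$chrom, x$source_chrom), TRUE))[1L]]]
      eid <- ev_ids[vapply(events, identical, TRUE, y = e)]
      if (ch == e$chrom) {
        emit(ch, ch, 0, e$start)
        emit(ch, e$source_chrom, e$source_start, chrom_lengths[[e$source_chrom]])
        bp(e$chrom, e$start, e$source_chrom, e$source_start, "TRA", eid)
      } else {
        emit(ch, ch, 0, e$source_start)
        emit(ch, e$chrom, e$start, chrom_lengths[[e$chrom]])
      }
      next
    }
    evs <- std[vapply(std, function(x) x$chrom == ch, TRUE)]
    if (length(evs) > 0L)
      evs <- evs[order(vapply(evs, function(x) x$start, 0))]
    pos <- 0
    for (e in evs) {
      eid <- ev_ids[vapply(events, identical, TRUE, y = e)]
      if (e$type == "tandem_duplication") {
        emit(ch, ch, pos, e$end)
        emit(ch, ch, e$start, e$end)
        bp(ch, e$start, ch, e$end, "DUP", eid)
        pos <- e$end
      } else if (e$type == "deletion") {
        emit(ch, ch, pos, e$start)
        bp(ch, e$start, ch, e$end, "DEL", eid)
        pos <- e$end
      } else if (e$type == "insertion_translocation") {
        emit(ch, ch, pos, e$start)
        emit(ch, e$source_chrom, e$source_start, e$source_end, e$orientation)
        if (e$orientation == "forward") {
          bp(ch, e$start, e$source_chrom, e$source_start, "TRA", eid)
          bp(e$source_chrom, e$source_end, ch, e$end, "TRA", eid)
        } else {
          bp(ch, e$start, e$source_chrom, e$source_end, "TRA", eid)
          bp(e$source_chrom, e$source_start, ch, e$end, "TRA", eid)
        }
        pos <- e$end
      }
    }
    emit(ch, ch, pos, len)
  }
  segments <- do.call(rbind, seg_rows)
  derived_lengths <- stats::setNames(
    vapply(names(chrom_lengths), function(ch)
      sum(segments$end[segments$dchrom == ch] - segments$start[segments$dchrom == ch]), 0),
    names(chrom_lengths))
  bins_derived <- bin_table(derived_lengths, bin_size)
  bins_reference <- bin_table(chrom_lengths, bin_size)
  lift_rows <- list()
  for (ch in names(chrom_lengths)) {
    segs <- segments[segments$dchrom == ch, , drop = FALSE]
    dpos <- 0
    for (i in seq_len(nrow(segs))) {
      nb <- (segs$end[i] - segs$start[i]) / bin_size
      ref_first <- locate_bins(bins_reference, segs$chrom[i], segs$start[i])
      refs <- ref_first + seq_len(nb) - 1L
      if (segs$orientation[i] == "inverted") refs <- rev(refs)
      dfirst <- locate_bins(bins_derived, ch, dpos)
      lift_rows[[length(lift_rows) + 1L]] <- data.frame(
        dchrom = ch, dbin = dfirst + seq_len(nb) - 1L, ref_bin = refs,
        orientation = segs$orientation[i], stringsAsFactors = FALSE)
      dpos <- dpos + (segs$end[i] - segs$start[i])
    }
  }
  liftover <- do.call(rbind, lift_rows)
  liftover <- liftover[order(liftover$dbin), , drop = FALSE]
  rownames(liftover) <- NULL
  bps <- if (length(breakpoints) > 0L) {
    b <- do.call(rbind, breakpoints)
    sv_calls(b$chrom1, b$pos1, b$chrom2, b$pos2, sv_type = b$sv_type,
             caller = "truth", truth_id = b$event_id)
  } else empty_sv_calls()
  structure(list(segments = segments, derived_lengths = derived_lengths,
                 liftover = liftover, bins_derived = bins_derived,
                 bins_reference = bins_reference, breakpoints = bps,
                 events = events, bin_size = bin_size,
                 reference = chrom_lengths),
            class = "derived_genome")
}

#' @export
print.derived_genome <- function(x, ...) {
  cat(sprintf("derived_genome: %d chromosome(s), %d segment(s), %d planted junction(s)\n",
              length(x$derived_lengths), nrow(x$segments), nrow(x$breakpoints)))
  print(x$segments)
  invisible(x)
}

#' Lift derived bins to reference bins and back
#'
#' `lift_to_reference` maps derived bin indices to reference bin indices
#' (total: every derived bin maps to exactly one reference bin).
#' `reference_copies` returns, for a reference bin, all derived bins carrying
#' it (more than one inside a duplication).
#'
#' @param genome A `derived_genome`.
#' @param dbin,ref_bin Bin indices.
#' @return Integer vector of bin indices.
#' @export
lift_to_reference <- function(genome, dbin) {
  genome$liftover$ref_bin[match(dbin, genome$liftover$dbin)]
}

#' @rdname lift_to_reference
#' @export
reference_copies <- function(genome, ref_bin) {
  genome$liftover$dbin[genome$liftover$ref_bin %in% ref_bin]
}
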