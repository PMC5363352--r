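#' Structural events at a two-unit segmental duplication
#'
#' Constructors for the events that [build_allele()] applies to the normal
#' two-unit haplotype. Nonallelic homologous recombination (NAHR) between
#' the proximal (A) and distal (B) repeat units generates the reciprocal
#' deletion (one chimeric unit) and duplication (three units, the middle one
#' chimeric) products; gene conversion copies a tract from one paralog onto
#' the other without changing unit count.
#'
#' @param breakpoint Crossover position in bp, strictly inside
#'   `(1, unit_length)`. The deletion chimera is A-source on
#'   `[1, breakpoint]` and B-source beyond; the duplication's middle unit is
#'   the reciprocal chimera (B then A).
#' @param unit Index of the unit (within the allele) receiving the
#'   conversion tract.
#' @param donor Donor paralog, `"A"` or `"B"`; the tract's source becomes
#'   the donor.
#' @param start,end Tract interval, 1-based inclusive. `end == start - 1`
#'   denotes an empty tract (a no-op).
#' @return An event object consumed by [build_allele()].
#' @name structural_events
NULL

#' @rdname structural_events
#' @export
nahr_deletion <- function(breakpoint) {
  structure(list(type = "nahr_deletion", breakpoint = as.integer(breakpoint)),
            class = "locus_event")
}

#' @rdname structural_events
#' @export
nahr_duplication <- function(breakpoint) {
  structure(list(type = "nahr_duplication", breakpoint = as.integer(breakpoint)),
            class = "locus_event")
}

#' @rdname structural_events
#' @export
gene_conversion <- function(unit, donor, start, end) {
  stopifnot(donor %in% c("A", "B"))
  structure(list(type = "gene_conversion", unit = as.integer(unit),
                 donor = donor, start = as.integer(start),
                 end = as.integer(end)),
            class = "locus_event")
}

new_unit <- function(start, end, source) {
  data.frame(start = as.integer(start), end = as.integer(end),
             source = source, stringsAsFactors = FALSE)
}

# Merge adjacent segments with the same source label.
merge_segments <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  keep <- c(TRUE, seg$source[-1] != seg$source[-nrow(seg)])
  grp <- cumsum(keep)
  out <- do.call(rbind, lapply(split(seg, grp), function(s)
    new_unit(min(s$start), max(s$end), s$source[1])))
  rownames(out) <- NULL
  out
}

apply_conversion <- function(unit, donor, start, end, L) {
  if (end == start - 1L) return(unit)  # empty tract: no-op
  if (start < 1L || end > L || start > end)
    stop("conversion tract outside the unit", call. = FALSE)
  pieces <- list()
  for (i in seq_len(nrow(unit))) {
    s <- unit[i, ]
    lo <- max(s$start, start); hi <- min(s$end, end)
    if (lo > hi) { pieces[[length(pieces) + 1L]] <- s; next }
    if (s$start < lo)
      pieces[[length(pieces) + 1L]] <- new_unit(s$start, lo - 1L, s$source)
    pieces[[length(pieces) + 1L]] <- new_unit(lo, hi, donor)
    if (s$end > hi)
      pieces[[length(pieces) + 1L]] <- new_unit(hi + 1L, s$end, s$source)
  }
  merge_segments(do.call(rbind, pieces))
}

#' Build a structural allele from a list of events
#'
#' Starts from the normal haplotype (two units: a full A-source unit then a
#' full B-source unit) and applies at most one NAHR event plus any number of
#' non-overlapping gene-conversion tracts. Each resulting unit is a mosaic
#' of A/B-sourced segments tiling `[1, unit_length]`; the events are kept as
#' truth annotations for downstream evaluation.
#'
#' @param pair A [simulate_paralog_pair()] object.
#' @param events List of event objects from [nahr_deletion()],
#'   [nahr_duplication()] or [gene_conversion()]; `list()` gives the normal
#'   allele.
#' @return An object of class `structural_allele`: list with `units` (each a
#'   data.frame of `start`, `end`, `source` segments) and `events`.
#' @examples
#' pair <- simulate_paralog_pair(1000, 0.01, seed = 1)
#' del <- build_allele(pair, list(nahr_deletion(400)))
#' length(del$units)  # 1
#' @export
build_allele <- function(pair, events = list()) {
  stopifnot(inherits(pair, "paralog_pair"))
  if (inherits(events, "locus_event")) events <- list(events)
  L <- pair$unit_length
  nahr <- Filter(function(e) e$type != "gene_conversion", events)
  conv <- Filter(function(e) e$type == "gene_conversion", events)
  if (length(nahr) > 1L)
    stop("at most one NAHR event per allele", call. = FALSE)

  units <- list(new_unit(1L, L, "A"), new_unit(1L, L, "B"))
  if (length(nahr) == 1L) {
    b <- nahr[[1]]$breakpoint
    if (b <= 1L || b >= L)
      stop("NAHR breakpoint must lie strictly inside (1, unit_length)",
           call. = FALSE)
    units <- switch(nahr[[1]]$type,
      nahr_deletion = list(
        rbind(new_unit(1L, b, "A"), new_unit(b + 1L, L, "B"))),
      nahr_duplication = list(
        new_unit(1L, L, "A"),
        rbind(new_unit(1L, b, "B"), new_unit(b + 1L, L, "A")),
        new_unit(1L, L, "B")))
  }

  # reject overlapping (non-empty) conversion tracts on the same unit
  by_unit <- split(conv, vapply(conv, `[[`, integer(1), "unit"))
  for (g in by_unit) {
    iv <- do.call(rbind, lapply(g, function(e) c(e$start, e$end)))
    iv <- iv[iv[, 2] >= iv[, 1], , drop = FALSE]
    if (nrow(iv) > 1L) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("overlapping conversion tracts on one unit", call. = FALSE)
    }
  }
  for (e in conv) {
    if (e$unit < 1L || e$unit > length(units))
      stop("conversion refers to a unit the allele does not have",
           call. = FALSE)
    units[[e$unit]] <- apply_conversion(units[[e$unit]], e$donor,
                                        e$start, e$end, L)
  }
  structure(list(units = units, events = events),
            class = "structural_allele")
}

#' @export
print.structural_allele <- function(x, ...) {
  cat(sprintf("structural_allele: %d unit(s), %d event(s)\n",
              length(x$units), length(x$events)))
  invisible(x)
}

#' Paralog source of a unit at given positions
#'
#' @param unit A unit (segment data.frame) from a `structural_allele`.
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of `"A"`/`"B"` source labels.
#' @export
unit_source_at <- function(unit, pos) {
  unit$source[findInterval(pos, unit$start)]
}

#' Realize the DNA sequence of each unit of an allele
#'
#' Every position takes the base of its segment's source paralog, so a unit
#' with a B-sourced tract differs from `seq_a` exactly at the PSVs inside
#' the tract.
#'
#' @param allele A `structural_allele`.
#' @param pair The `paralog_pair` it was built on.
#' @return Character vector with one sequence per unit.
#' @export
realize_sequence <- function(allele, pair) {
  stopifnot(inherits(allele, "structural_allele"),
            inherits(pair, "paralog_pair"))
  vapply(allele$units, function(u) {
    paste(vapply(seq_len(nrow(u)), function(i) {
      s <- if (u$source[i] == "A") pair$seq_a else pair$seq_b
      substr(s, u$start[i], u$end[i])
    }, character(1)), collapse = "")
  }, character(1))
}
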