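#' Alignment/assignment configuration
#'
#' @param min_span Minimal aligned span (bp) for a contig to contribute to
#'   paralog assignment; shorter placements are reported but excluded
#'   (default 400, the span filter used for clone-contig alignments).
#' @param tie_policy How to label a contig whose identities to the two
#'   paralogs are exactly equal: `"ambiguous"` (default) leaves it
#'   unassigned, reflecting that PSV-free contigs carry no paralog
#'   information.
#' @return An object of class `alignment_config`.
#' @export
alignment_config <- function(min_span = 400L, tie_policy = "ambiguous") {
  stopifnot(min_span >= 1L, tie_policy %in% c("ambiguous", "A", "B"))
  structure(list(min_span = as.integer(min_span), tie_policy = tie_policy),
            class = "alignment_config")
}

#' Sequence identity of a contig against a reference window
#'
#' Fraction of matching aligned bases between the contig and the reference
#' segment starting at `offset` (gap-free placement; the simulator emits
#' substitution-only errors).
#'
#' @param contig_seq Contig sequence (character string).
#' @param reference Full reference sequence (character string).
#' @param offset 1-based start of the placement on the reference.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(contig_seq, reference, offset = 1L) {
  n <- nchar(contig_seq)
  if (offset < 1L || offset + n - 1L > nchar(reference))
    stop("placement exceeds the reference", call. = FALSE)
  a <- seq_chars(contig_seq)
  b <- seq_chars(substr(reference, offset, offset + n - 1L))
  mean(a == b)
}

#' Assign contigs to paralog A or B by sequence identity
#'
#' Each contig is compared at its placement against both paralog
#' references and assigned to the paralog of the highest sequence identity.
#' Placements shorter than `min_span` are flagged and left unlabelled;
#' exact identity ties follow the configured tie policy.
#'
#' @param contigs A `contig_set` (or data.frame with `contig_id`,
#'   `sequence`, `start`).
#' @param pair A `paralog_pair`.
#' @param config An [alignment_config()].
#' @return Data.frame with columns `contig_id`, `identity_a`, `identity_b`,
#'   `aligned_span`, `label` (`"A"`, `"B"`, `"ambiguous"` or `NA` when the
#'   span filter applies) and `reason`.
#' @export
assign_paralog <- function(contigs, pair, config = alignment_config()) {
  stopifnot(inherits(pair, "paralog_pair"),
            inherits(config, "alignment_config"))
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    s <- contigs$sequence[i]
    off <- contigs$start[i]
    ia <- sequence_identity(s, pair$seq_a, off)
    ib <- sequence_identity(s, pair$seq_b, off)
    span <- nchar(s)
    if (span < config$min_span) {
      label <- NA_character_; reason <- "span_below_min"
    } else if (ia > ib) {
      label <- "A"; reason <- ""
    } else if (ib > ia) {
      label <- "B"; reason <- ""
    } else {
      label <- config$tie_policy
      reason <- if (label == "ambiguous") "identity_tie" else "tie_broken"
    }
    data.frame(contig_id = contigs$contig_id[i], identity_a = ia,
               identity_b = ib, aligned_span = span, label = label,
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Place a contig on the paralog references by exact-match seeding
#'
#' Label-free alternative to the simulator's truth coordinates: a short
#' seed from the contig is looked up exactly in both references and each
#' hit is extended to a full-length gap-free placement; the offset with
#' the highest identity against either reference wins. Several seed
#' positions are tried so that a sequencing error inside one seed does
#' not lose the placement. Suited to substitution-only contigs; gapped
#' placement is out of scope.
#'
#' @param contig_seq Contig sequence (character string).
#' @param pair A `paralog_pair`.
#' @param seed_length Exact-match seed length (default 32).
#' @param max_tries Number of distinct seed positions to try (default 5).
#' @return The best 1-based offset, with attribute `identity`; `NA` if no
#'   seed matches either reference.
#' @export
place_contig <- function(contig_seq, pair, seed_length = 32L,
                         max_tries = 5L) {
  n <- nchar(contig_seq)
  stopifnot(n >= seed_length)
  L <- pair$unit_length
  starts <- unique(pmax(1L, round(seq(1L, n - seed_length + 1L,
                                      length.out = max_tries))))
  best_off <- NA_integer_; best_id <- -1
  for (s in starts) {
    seed <- substr(contig_seq, s, s + seed_length - 1L)
    for (ref in c(pair$seq_a, pair$seq_b)) {
      hits <- gregexpr(seed, ref, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (h in hits) {
        off <- h - s + 1L
        if (off < 1L || off + n - 1L > L) next
        id <- max(sequence_identity(contig_seq, pair$seq_a, off),
                  sequence_identity(contig_seq, pair$seq_b, off))
        if (id > best_id) { best_id <- id; best_off <- off }
      }
    }
  }
  if (is.na(best_off)) return(NA_integer_)
  structure(best_off, identity = best_id)
}

#' Maximal non-overlapping subset of placed alignments
#'
#' Weighted interval scheduling: among pairwise non-overlapping alignments
#' (1-based inclusive reference intervals), selects the subset maximizing
#' total score (aligned span by default). Output is independent of input
#' order.
#'
#' @param alignments Data.frame with columns `start`, `end` and optionally
#'   `score` (defaults to `end - start + 1`).
#' @return The selected rows of `alignments`, ordered by `start`.
#' @export
select_nonoverlapping <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  if (is.null(alignments$score))
    alignments$score <- alignments$end - alignments$start + 1
  ord <- order(alignments$end, alignments$start, -alignments$score)
  a <- alignments[ord, , drop = FALSE]
  n <- nrow(a)
  # p[i]: rightmost j < i with end_j < start_i (inclusive intervals overlap
  # when start_i <= end_j)
  p <- findInterval(a$start - 0.5, a$end)
  opt <- numeric(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- a$score[i] + opt[p[i] + 1L]
    opt[i + 1L] <- max(opt[i], with_i)
    take[i] <- with_i >= opt[i]
  }
  sel <- logical(n)
  i <- n
  while (i >= 1L) {
    if (take[i] && (a$score[i] + opt[p[i] + 1L]) >= opt[i]) {
      sel[i] <- TRUE
      i <- p[i]
    } else i <- i - 1L
  }
  out <- a[sel, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' PSV-state profile of a contig
#'
#' For every cataloged PSV covered by the contig's placement, reports the
#' state of the contig base: `"A"` if it equals the A-paralog base, `"B"`
#' if the B-paralog base, `"other"` otherwise (e.g. sequencing error).
#' Uncovered PSVs are omitted.
#'
#' @param contig One row of a `contig_set`, or a list with `sequence` and
#'   `start`.
#' @param pair A `paralog_pair`.
#' @param placement Optional 1-based start overriding `contig$start`.
#' @return Data.frame of class `psv_profile` with columns `pos`, `state`.
#' @export
psv_profile <- function(contig, pair, placement = NULL) {
  stopifnot(inherits(pair, "paralog_pair"))
  s <- contig$sequence
  start <- if (is.null(placement)) contig$start else placement
  end <- start + nchar(s) - 1L
  cat_ <- pair$psv_catalog
  cov <- cat_[cat_$pos >= start & cat_$pos <= end, , drop = FALSE]
  if (nrow(cov) == 0L) {
    out <- data.frame(pos = integer(0), state = character(0),
                      stringsAsFactors = FALSE)
  } else {
    base <- substring(s, cov$pos - start + 1L, cov$pos - start + 1L)
    state <- ifelse(base == cov$a_base, "A",
                    ifelse(base == cov$b_base, "B", "other"))
    out <- data.frame(pos = cov$pos, state = state, stringsAsFactors = FALSE)
  }
  class(out) <- c("psv_profile", "data.frame")
  out
}

#' Consensus PSV profile across the contigs of one sample
#'
#' Merges per-contig profiles; PSVs with conflicting informative states
#' across contigs (e.g. a conversion on one chromosome obscuring the other)
#' are set to `"other"` and listed in the `conflicts` attribute so that
#' switch detection treats them as masked.
#'
#' @param profiles List of `psv_profile` objects.
#' @return A `psv_profile` with attribute `conflicts` (positions).
#' @export
consensus_profile <- function(profiles) {
  all <- do.call(rbind, profiles)
  if (is.null(all) || nrow(all) == 0L) {
    out <- data.frame(pos = integer(0), state = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("psv_profile", "data.frame")
    return(out)
  }
  by_pos <- split(all$state, all$pos)
  pos <- as.integer(names(by_pos))
  state <- vapply(by_pos, function(s) {
    inf <- unique(s[s %in% c("A", "B")])
    if (length(inf) == 1L) inf else if (length(inf) > 1L) "other"
    else unique(s)[1]
  }, character(1))
  conflicts <- pos[vapply(by_pos, function(s)
    length(unique(s[s %in% c("A", "B")])) > 1L, logical(1))]
  ord <- order(pos)
  out <- data.frame(pos = pos[ord], state = unname(state)[ord],
                    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- conflicts
  class(out) <- c("psv_profile", "data.frame")
  out
}
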