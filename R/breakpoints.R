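#' Genomic intervals (1-based, inclusive)
#'
#' @param start,end Interval bounds in bp, `start <= end`.
#' @param name Optional label.
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(start, end, name = "") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("start must be <= end", call. = FALSE)
  structure(list(name = name, start = start, end = end),
            class = "genomic_interval")
}

#' Length of a 1-based inclusive interval
#'
#' `end - start + 1`, the convention under which a tract quoted by its
#' first and last coordinate (e.g. a 9,139-bp conversion tract printed as
#' "about 9.1 kb") has the conventional length.
#'
#' @param interval A [genomic_interval()], or a numeric `start` when `end`
#'   is given.
#' @param end Optional numeric end when `interval` is a start coordinate.
#' @return Length in bp.
#' @examples
#' interval_length(159806619, 159815757)  # 9139
#' @export
interval_length <- function(interval, end = NULL) {
  if (!is.null(end)) interval <- genomic_interval(interval, end)
  stopifnot(inherits(interval, "genomic_interval"))
  interval$end - interval$start + 1
}

# Choose the maximal subset of informative states to keep such that every
# maximal run of the kept sequence has length >= min_run (a single run of
# any length is allowed: it supports no switch either way). Exact dynamic
# program over (run state, capped run length, whether a run has been
# completed); masked = dropped positions.
mask_short_runs <- function(states, min_run) {
  n <- length(states)
  if (n == 0L) return(logical(0))
  if (min_run <= 1L) return(rep(TRUE, n))
  si <- match(states, c("A", "B"))
  # dp key: (s, l, f); encode as s + 2*(l-1) + 2*min_run*f, plus start state 0
  n_key <- 2L * min_run * 2L
  NEG <- -1e9
  dp <- rep(NEG, n_key)
  start_val <- 0
  # choice bookkeeping for traceback: for each i, the transition taken into
  # each key (previous key, or 0 for start) when keeping i; NA = not kept
  from <- matrix(NA_integer_, n, n_key)
  key <- function(s, l, f) s + 2L * (l - 1L) + 2L * min_run * f
  hist_dp <- vector("list", n)
  for (i in seq_len(n)) {
    new_dp <- dp  # masking i carries everything over
    new_from <- rep(NA_integer_, n_key)
    s <- si[i]
    # from start
    k <- key(s, 1L, 0L)
    if (start_val + 1 > new_dp[k]) { new_dp[k] <- start_val + 1; new_from[k] <- 0L }
    for (ps in 1:2) for (pl in seq_len(min_run)) for (pf in 0:1) {
      pk <- key(ps, pl, pf)
      if (dp[pk] <= NEG) next
      if (ps == s) {
        k <- key(s, min(pl + 1L, min_run), pf)
        if (dp[pk] + 1 > new_dp[k]) { new_dp[k] <- dp[pk] + 1; new_from[k] <- pk }
      } else if (pl == min_run) {
        k <- key(s, 1L, 1L)
        if (dp[pk] + 1 > new_dp[k]) { new_dp[k] <- dp[pk] + 1; new_from[k] <- pk }
      }
    }
    dp <- new_dp
    from[i, ] <- new_from
    hist_dp[[i]] <- dp
  }
  # valid final keys: single run (f=0, any l) or completed final run
  best_val <- 0; best_key <- NA_integer_
  for (s in 1:2) for (l in seq_len(min_run)) for (f in 0:1) {
    if (f == 1L && l < min_run) next
    k <- key(s, l, f)
    if (dp[k] > best_val) { best_val <- dp[k]; best_key <- k }
  }
  keep <- rep(FALSE, n)
  if (is.na(best_key) || best_val <= 0) return(keep)
  # traceback: at each step i the value at key k either carried over from
  # i-1 (i masked) or was set by keeping i (from[i, k] records the source)
  k <- best_key; val <- best_val; i <- n
  while (i >= 1L && val > 0) {
    if (i > 1L && hist_dp[[i - 1L]][k] == val) { i <- i - 1L; next }
    pk <- from[i, k]
    keep[i] <- TRUE
    val <- val - 1
    if (is.na(pk) || pk == 0L) break
    k <- pk
    i <- i - 1L
  }
  keep
}

#' Detect A/B state switches along a PSV profile
#'
#' Scans the informative (A or B) states of a PSV profile for boundaries
#' between maximal runs. Runs shorter than `min_run` are treated as noise
#' or ambiguity — masked, recorded, and removed before re-segmentation —
#' mirroring the practice of blacking out single discordant PSVs in
#' breakpoint plots. Each emitted switch carries the open interval between
#' the last informative PSV of the outgoing state and the first of the
#' incoming state; the true crossover lies strictly inside it.
#'
#' @param profile A `psv_profile`.
#' @param min_run Minimal run length on both sides of a switch (default 2).
#' @return Data.frame of class `switch_events` with columns `from_state`,
#'   `to_state`, `start`, `end`, `n_left`, `n_right`; attribute `masked`
#'   lists masked PSV positions.
#' @export
detect_switches <- function(profile, min_run = 2L) {
  stopifnot(min_run >= 1L)
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  inf <- profile[profile$state %in% c("A", "B"), , drop = FALSE]
  masked <- profile$pos[!profile$state %in% c("A", "B")]
  empty <- data.frame(from_state = character(0), to_state = character(0),
                      start = integer(0), end = integer(0),
                      n_left = integer(0), n_right = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(inf) == 0L) {
    warning("profile has no informative PSV state")
    attr(empty, "masked") <- masked
    class(empty) <- c("switch_events", "data.frame")
    return(empty)
  }
  keep <- mask_short_runs(inf$state, min_run)
  masked <- c(masked, inf$pos[!keep])
  pos <- inf$pos[keep]; st <- inf$state[keep]
  if (length(st) == 0L) {
    attr(empty, "masked") <- sort(masked)
    class(empty) <- c("switch_events", "data.frame")
    return(empty)
  }
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$lengths)
  if (k == 1L) {
    out <- empty
  } else {
    out <- data.frame(
      from_state = r$values[-k], to_state = r$values[-1],
      start = pos[ends[-k]], end = pos[starts[-1]],
      n_left = r$lengths[-k], n_right = r$lengths[-1],
      stringsAsFactors = FALSE)
  }
  attr(out, "masked") <- sort(masked)
  class(out) <- c("switch_events", "data.frame")
  out
}

#' Classify switches into NAHR breakpoints and gene-conversion tracts
#'
#' A pair of opposite switches returning to the original state brackets a
#' conversion tract (reported inclusive of its inner PSVs, with donor and
#' acceptor paralog); an unpaired switch is an NAHR breakpoint interval.
#' PSVs falling where a breakpoint interval overlaps a known conversion
#' tract are moved to the ambiguous list rather than used as support.
#'
#' @param switches Output of [detect_switches()].
#' @param profile The profile the switches came from.
#' @param min_tract_psvs Minimal PSV support inside a conversion tract
#'   (default 2).
#' @param known_tracts Optional data.frame of known conversion tracts
#'   (`start`, `end`) used to mask ambiguous breakpoint PSVs.
#' @return List with `breakpoints` (data.frame `start`, `end`,
#'   `from_state`, `to_state`, `hotspot_label`, and list-column
#'   `ambiguous_psvs`) and `conversions` (data.frame `start`, `end`,
#'   `donor`, `acceptor`, `n_psvs`).
#' @export
classify_events <- function(switches, profile, min_tract_psvs = 2L,
                            known_tracts = NULL) {
  bp <- list(); cv <- list()
  n <- nrow(switches)
  i <- 1L
  while (i <= n) {
    s <- switches[i, ]
    if (i < n &&
        switches$from_state[i + 1L] == s$to_state &&
        switches$to_state[i + 1L] == s$from_state &&
        switches$n_right[i] >= min_tract_psvs) {
      cv[[length(cv) + 1L]] <- data.frame(
        start = s$end, end = switches$start[i + 1L],
        donor = s$to_state, acceptor = s$from_state,
        n_psvs = s$n_right, stringsAsFactors = FALSE)
      i <- i + 2L
    } else {
      amb <- integer(0)
      if (!is.null(known_tracts) && nrow(known_tracts)) {
        for (j in seq_len(nrow(known_tracts))) {
          lo <- max(s$start, known_tracts$start[j])
          hi <- min(s$end, known_tracts$end[j])
          if (lo <= hi)
            amb <- c(amb, profile$pos[profile$pos >= lo & profile$pos <= hi])
        }
      }
      bp[[length(bp) + 1L]] <- data.frame(
        start = s$start, end = s$end, from_state = s$from_state,
        to_state = s$to_state, hotspot_label = "unassigned",
        ambiguous_psvs = I(list(sort(unique(amb)))),
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  list(
    breakpoints = if (length(bp)) do.call(rbind, bp) else
      data.frame(start = integer(0), end = integer(0),
                 from_state = character(0), to_state = character(0),
                 hotspot_label = character(0),
                 ambiguous_psvs = I(list()), stringsAsFactors = FALSE),
    conversions = if (length(cv)) do.call(rbind, cv) else
      data.frame(start = integer(0), end = integer(0), donor = character(0),
                 acceptor = character(0), n_psvs = integer(0),
                 stringsAsFactors = FALSE))
}

#' Label breakpoint intervals with the overlapping hotspot
#'
#' Assigns each breakpoint interval the name of the catalog region it
#' overlaps most (in bp); intervals overlapping nothing get
#' `"unassigned"`, and exact overlap ties are reported in a `tie` column.
#'
#' @param breakpoints Breakpoint data.frame from [classify_events()].
#' @param catalog Hotspot catalog (data.frame `name`, `start`, `end`).
#' @return `breakpoints` with `hotspot_label` (and `tie`) filled in.
#' @export
assign_hotspot <- function(breakpoints, catalog) {
  stopifnot(nrow(catalog) > 0L, !anyDuplicated(catalog$name))
  breakpoints$tie <- FALSE
  for (i in seq_len(nrow(breakpoints))) {
    ov <- pmin(breakpoints$end[i], catalog$end) -
      pmax(breakpoints$start[i], catalog$start) + 1
    ov[ov < 0] <- 0
    if (all(ov == 0)) {
      breakpoints$hotspot_label[i] <- "unassigned"
    } else {
      best <- which(ov == max(ov))
      breakpoints$hotspot_label[i] <- catalog$name[best[1]]
      breakpoints$tie[i] <- length(best) > 1L
    }
  }
  breakpoints
}

#' Compare two mapped deletion alleles for identity-by-descent support
#'
#' Two alleles are consistent with a single mutational origin
#' (`"consistent_IBD"`) when their breakpoint intervals are identical and
#' every informative PSV state present in both flanking profiles agrees;
#' any difference indicates identity-by-state, i.e. recurrent NAHR
#' (`"distinct"`).
#'
#' @param a,b Lists with `interval` (`c(start, end)` or one-row data.frame)
#'   and `profile` (a `psv_profile` of flanking PSVs).
#' @return `"consistent_IBD"` or `"distinct"`.
#' @export
compare_alleles <- function(a, b) {
  iv <- function(x) if (is.data.frame(x$interval))
    c(x$interval$start[1], x$interval$end[1]) else x$interval
  if (!isTRUE(all(iv(a) == iv(b)))) return("distinct")
  pa <- a$profile[a$profile$state %in% c("A", "B"), ]
  pb <- b$profile[b$profile$state %in% c("A", "B"), ]
  shared <- intersect(pa$pos, pb$pos)
  sa <- pa$state[match(shared, pa$pos)]
  sb <- pb$state[match(shared, pb$pos)]
  if (all(sa == sb)) "consistent_IBD" else "distinct"
}

#' Pairwise-difference separation of A- and B-derived sequences
#'
#' Computes the Hamming difference matrix among equal-length realized unit
#' sequences and a separation statistic, the ratio of the mean
#' between-label to mean within-label distance. Values above 1 indicate
#' that the two paralog lineages form distinguishable clusters — a
#' pairwise-distance stand-in for a phylogenetic median network.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param labels Character vector of truth labels (e.g. `"A"`/`"B"`).
#' @return List with `dist` (matrix), `statistic` and `separable`.
#' @export
divergence_separation <- function(sequences, labels) {
  n <- length(sequences)
  stopifnot(n >= 2L, length(labels) == n)
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  within <- d[which(same & upper.tri(d))]
  between <- d[which(!same & upper.tri(d))]
  if (length(within) == 0L || length(between) == 0L)
    return(list(dist = d, statistic = NA_real_, separable = FALSE))
  mw <- mean(within); mb <- mean(between)
  if (mb == 0) return(list(dist = d, statistic = NA_real_, separable = FALSE))
  stat <- if (mw == 0) Inf else mb / mw
  list(dist = d, statistic = stat, separable = isTRUE(stat > 1))
}
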