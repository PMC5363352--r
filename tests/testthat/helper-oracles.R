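# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# Per-position source lookup on a unit's segment list (linear scan).
oracle_unit_source <- function(unit, pos) {
  vapply(pos, function(p) {
    for (i in seq_len(nrow(unit)))
      if (p >= unit$start[i] && p <= unit$end[i]) return(unit$source[i])
    NA_character_
  }, character(1))
}

# Source labels of every unit in a list at one position.
oracle_unit_source_list <- function(units, pos) {
  vapply(units, function(u) oracle_unit_source(u, pos), character(1))
}

# Position-wise comparison of two sequences: positions where they differ.
oracle_mismatch_positions <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  which(a != b)
}

# PSV states of a contig by direct catalog lookup.
oracle_psv_states <- function(contig_seq, start, catalog) {
  end <- start + nchar(contig_seq) - 1L
  cov <- catalog[catalog$pos >= start & catalog$pos <= end, , drop = FALSE]
  bases <- strsplit(contig_seq, "")[[1]]
  st <- character(nrow(cov))
  for (i in seq_len(nrow(cov))) {
    b <- bases[cov$pos[i] - start + 1L]
    st[i] <- if (b == cov$a_base[i]) "A" else if (b == cov$b_base[i]) "B"
      else "other"
  }
  data.frame(pos = cov$pos, state = st, stringsAsFactors = FALSE)
}

# Exhaustive maximum-score non-overlapping subset (<= ~12 intervals).
oracle_best_subset_score <- function(intervals) {
  n <- nrow(intervals)
  if (is.null(intervals$score))
    intervals$score <- intervals$end - intervals$start + 1
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1L) {
      for (i in 1:(length(idx) - 1L)) {
        for (j in (i + 1L):length(idx)) {
          ii <- idx[i]; jj <- idx[j]
          if (!(intervals$end[ii] < intervals$start[jj] ||
                intervals$end[jj] < intervals$start[ii])) ok <- FALSE
        }
      }
    }
    if (ok) best <- max(best, sum(intervals$score[idx]))
  }
  best
}

# Exhaustive switch localization on a small profile: mask the fewest PSVs
# such that the remaining informative states form runs all >= min_run;
# among minimal maskings, return the run boundaries.
oracle_switch_enum <- function(profile, min_run) {
  inf <- profile[profile$state %in% c("A", "B"), ]
  n <- nrow(inf)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) == 0)
    if (length(keep) == 0L) next
    st <- inf$state[keep]
    r <- rle(st)
    if (length(r$lengths) > 1L && any(r$lengths < min_run)) next
    n_masked <- n - length(keep)
    if (is.null(best) || n_masked < best$n_masked) {
      ends <- cumsum(r$lengths)
      k <- length(r$lengths)
      sw <- if (k > 1L) data.frame(
        start = inf$pos[keep][ends[-k]],
        end = inf$pos[keep][ends[-k] + 1L]) else
          data.frame(start = integer(0), end = integer(0))
      best <- list(n_masked = n_masked, switches = sw)
    }
  }
  best
}

# Two-sided Fisher p by full hypergeometric enumeration (point-probability
# rule: sum probabilities of all tables with the observed margins whose
# probability is <= that of the observed table, with a small relative
# tolerance against ties in floating point).
oracle_fisher_enum <- function(a, b, c_, d) {
  m <- a + c_          # cases
  n <- b + d           # controls
  k <- a + b           # carriers
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  p <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Noncentral hypergeometric pmf over the table support at odds ratio `or`.
oracle_nchg_pmf <- function(m, n, k, or) {
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  lw <- lchoose(m, x) + lchoose(n, k - x) + x * log(or)
  w <- exp(lw - max(lw))
  list(x = x, p = w / sum(w))
}

# Exact conditional CI bounds by fine grid inversion of the noncentral
# hypergeometric tail probabilities.
oracle_ci_grid <- function(a, b, c_, d, level = 0.95) {
  m <- a + c_; n <- b + d; k <- a + b
  alpha <- (1 - level) / 2
  ors <- exp(seq(log(1e-4), log(1e4), length.out = 40001))
  upper_tail <- vapply(ors, function(or) {
    f <- oracle_nchg_pmf(m, n, k, or)
    sum(f$p[f$x >= a])
  }, numeric(1))
  lower_tail <- vapply(ors, function(or) {
    f <- oracle_nchg_pmf(m, n, k, or)
    sum(f$p[f$x <= a])
  }, numeric(1))
  lo <- if (a == max(0L, k - n)) 0 else max(ors[upper_tail <= alpha])
  hi <- if (a == min(k, m)) Inf else min(ors[lower_tail <= alpha])
  c(lo, hi)
}

# PC1 by brute-force eigendecomposition of the covariance of the centered
# matrix.
oracle_pc1 <- function(m) {
  mc <- sweep(m, 2, colMeans(m))
  ev <- eigen(crossprod(mc), symmetric = TRUE)
  v <- ev$vectors[, 1]
  unname(drop(mc %*% v))
}

# Shared small fixture: a pair plus a deletion allele, used across files.
make_test_pair <- function(unit_length = 2000L, divergence = 0.01,
                           seed = 7L) {
  simulate_paralog_pair(unit_length, divergence, seed = seed)
}
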