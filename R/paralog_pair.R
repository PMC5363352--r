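#' Simulate a pair of paralogous repeat units
#'
#' Generates two repeat-unit reference sequences of identical length that
#' differ only at a catalog of paralog sequence variants (PSVs). PSVs are the
#' fixed nucleotide differences that distinguish one segmental-duplication
#' copy from the other; all analysis downstream (contig assignment,
#' breakpoint mapping, probe cross-hybridization) keys off this catalog.
#'
#' The number of PSVs is `round(divergence * unit_length)` and their
#' positions are drawn uniformly without replacement, so the realized
#' pairwise identity of the two sequences is exactly
#' `1 - n_psv / unit_length`. A two-unit tandem duplication at ~98.5%
#' identity over a ~16 kb analysis window corresponds to the defaults used
#' throughout the package.
#'
#' @param unit_length Length of each repeat unit in bp (>= 100).
#' @param divergence Fraction of positions that are PSVs, in `[0, 0.2)`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param psv_desert Optional `c(start, end)` interval (1-based, inclusive)
#'   in which PSV density is reduced by `desert_factor`, emulating a
#'   PSV-poor region of the real locus. Default `NULL` (off).
#' @param desert_factor Relative PSV density inside `psv_desert` (default
#'   0.1).
#'
#' @return An object of class `paralog_pair`: a list with elements `seq_a`,
#'   `seq_b` (character strings), `unit_length`, `divergence`, and
#'   `psv_catalog`, a data.frame with columns `pos` (1-based), `a_base`,
#'   `b_base`.
#' @examples
#' pair <- simulate_paralog_pair(2000, 0.015, seed = 1)
#' nrow(pair$psv_catalog)  # 30 PSVs
#' @export
simulate_paralog_pair <- function(unit_length, divergence, seed = NULL,
                                  psv_desert = NULL, desert_factor = 0.1) {
  stopifnot_scalar_number(unit_length, "unit_length")
  stopifnot_scalar_number(divergence, "divergence")
  unit_length <- as.integer(unit_length)
  if (unit_length < 100L)
    stop("unit_length must be at least 100 bp", call. = FALSE)
  if (divergence < 0 || divergence >= 0.2)
    stop("divergence must be in [0, 0.2)", call. = FALSE)
  n_psv <- round(divergence * unit_length)
  if (n_psv > unit_length)
    stop("divergence too high: cannot place that many distinct PSVs",
         call. = FALSE)

  with_seed(seed, {
    seq_a <- sample(DNA_BASES, unit_length, replace = TRUE)
    if (n_psv > 0L) {
      if (!is.null(psv_desert)) {
        stopifnot(length(psv_desert) == 2L, psv_desert[1] <= psv_desert[2])
        w <- rep(1, unit_length)
        w[psv_desert[1]:psv_desert[2]] <- desert_factor
        pos <- sort(sample.int(unit_length, n_psv, prob = w))
      } else {
        pos <- sort(sample.int(unit_length, n_psv))
      }
      # pick, at each PSV, a B base different from the A base
      alt <- vapply(seq_a[pos], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
    } else {
      pos <- integer(0)
      alt <- character(0)
    }
    seq_b <- seq_a
    seq_b[pos] <- alt
    structure(list(
      seq_a = paste(seq_a, collapse = ""),
      seq_b = paste(seq_b, collapse = ""),
      unit_length = unit_length,
      divergence = divergence,
      psv_catalog = data.frame(pos = as.integer(pos),
                               a_base = unname(seq_a[pos]),
                               b_base = unname(alt),
                               stringsAsFactors = FALSE)
    ), class = "paralog_pair")
  })
}

#' @export
print.paralog_pair <- function(x, ...) {
  cat(sprintf("paralog_pair: 2 x %d bp, %d PSVs (identity %.4f)\n",
              x$unit_length, nrow(x$psv_catalog),
              1 - nrow(x$psv_catalog) / x$unit_length))
  invisible(x)
}

#' Pairwise identity of the two paralog references
#'
#' Fraction of positions at which the two unit sequences agree; equals
#' `1 - nrow(psv_catalog) / unit_length` by construction.
#'
#' @param pair A `paralog_pair`.
#' @return A fraction in `[0, 1]`.
#' @export
pair_identity <- function(pair) {
  stopifnot(inherits(pair, "paralog_pair"))
  1 - nrow(pair$psv_catalog) / pair$unit_length
}

# Base of paralog `source` ("A" or "B") at 1-based positions `pos`.
paralog_base <- function(pair, source, pos) {
  s <- if (identical(source, "A")) pair$seq_a else pair$seq_b
  substring(s, pos, pos)
}
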