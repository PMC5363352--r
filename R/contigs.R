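#' Simulate fosmid-like contigs tiling the units of an allele
#'
#' Stands in for assembled clone contigs: each realized unit sequence is
#' tiled by fixed-length windows at a regular step (plus a terminal window
#' flush with the unit end), and i.i.d. substitution errors are applied at
#' `error_rate`. Truth placement (unit index, start) is carried with each
#' contig so that downstream assignment can be evaluated against the
#' generating structure.
#'
#' @param allele A `structural_allele`.
#' @param pair The `paralog_pair` it was built on.
#' @param contig_length Window length in bp (>= 1 and <= unit length).
#' @param step Distance between successive window starts (>= 1).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A data.frame of class `contig_set` with columns `contig_id`,
#'   `unit`, `start`, `end`, `strand`, `sequence`.
#' @export
simulate_contigs <- function(allele, pair, contig_length, step,
                             error_rate = 0, seed = NULL) {
  stopifnot(inherits(allele, "structural_allele"),
            inherits(pair, "paralog_pair"))
  contig_length <- as.integer(contig_length)
  step <- as.integer(step)
  if (contig_length < 1L) stop("contig_length must be >= 1", call. = FALSE)
  if (contig_length > pair$unit_length)
    stop("contig_length exceeds unit_length", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]", call. = FALSE)

  seqs <- realize_sequence(allele, pair)
  L <- pair$unit_length
  last_start <- L - contig_length + 1L
  starts <- seq.int(1L, last_start, by = step)
  if (starts[length(starts)] != last_start) starts <- c(starts, last_start)

  with_seed(seed, {
    rows <- list()
    for (u in seq_along(seqs)) {
      for (s in starts) {
        contig <- substr(seqs[u], s, s + contig_length - 1L)
        if (error_rate > 0) {
          bases <- seq_chars(contig)
          hit <- which(runif(contig_length) < error_rate)
          if (length(hit)) {
            bases[hit] <- vapply(bases[hit], function(b)
              sample(setdiff(DNA_BASES, b), 1L), character(1))
            contig <- paste(bases, collapse = "")
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = sprintf("u%d_s%d", u, s),
          unit = u, start = as.integer(s),
          end = as.integer(s + contig_length - 1L),
          strand = "+", sequence = contig, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("contig_set", "data.frame")
    out
  })
}
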