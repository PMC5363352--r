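#' Default NAHR hotspot catalog for the synthetic locus
#'
#' Two crossover hotspots on the unit coordinate system. A crossover in the
#' proximal hotspot deletes the gene content analogous to FCGR3A (the
#' retained chimeric unit is B-source over the region between the hotspots);
#' a crossover in the distal hotspot deletes the FCGR3B analog (the chimera
#' is A-source there). The region strictly between the two hotspots is the
#' deletion-determining region used to discriminate the two deletion types.
#'
#' @param unit_length Unit length in bp; hotspot coordinates scale with it.
#' @return A data.frame with columns `name`, `start`, `end`, `del_type`.
#' @export
default_hotspot_catalog <- function(unit_length = 16000L) {
  f <- unit_length / 16000
  data.frame(
    name = c("breakpoint_A", "breakpoint_B"),
    start = as.integer(round(c(2500, 12500) * f)),
    end = as.integer(round(c(3500, 13500) * f)),
    del_type = c("A", "B"),
    stringsAsFactors = FALSE)
}

#' Design a synthetic aCGH probe set over the repeat unit
#'
#' 33 probes spanning the unit, of which `n_between` (default 20) lie
#' strictly between the two breakpoint hotspots — the subset whose paralog
#' identity differs between the two heterozygous deletion types — and the
#' rest lie proximal/distal of the hotspots. Design paralog alternates
#' between A and B so that both paralog-specific responses are represented
#' throughout the unit.
#'
#' @param unit_length Unit length in bp.
#' @param hotspots Hotspot catalog as from [default_hotspot_catalog()].
#' @param n_between,n_outside Probe counts inside/outside the
#'   deletion-determining region (defaults 20 and 13).
#' @return A data.frame with columns `probe_id`, `unit_position`,
#'   `design_paralog`.
#' @export
design_probes <- function(unit_length = 16000L,
                          hotspots = default_hotspot_catalog(unit_length),
                          n_between = 20L, n_outside = 13L) {
  prox <- hotspots[which.min(hotspots$start), ]
  dist <- hotspots[which.max(hotspots$start), ]
  span <- dist$start - prox$end
  between <- prox$end + round(seq_len(n_between) * span / (n_between + 1))
  n_left <- ceiling(n_outside / 2)
  n_right <- n_outside - n_left
  left <- round(seq(0.02, 0.9, length.out = n_left) * (prox$start - 1)) + 1L
  right <- dist$end +
    round(seq(0.1, 0.95, length.out = n_right) * (unit_length - dist$end))
  pos <- sort(unique(as.integer(c(between, left, right))))
  data.frame(
    probe_id = sprintf("p%02d", seq_along(pos)),
    unit_position = pos,
    design_paralog = rep(c("A", "B"), length.out = length(pos)),
    stringsAsFactors = FALSE)
}

#' aCGH simulation parameters
#'
#' @param gamma Cross-hybridization weight in `[0, 1]`: relative signal a
#'   probe receives from the non-target paralog (1 = no paralog
#'   discrimination).
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param cohort_offsets Named numeric of per-cohort log2 shifts; `NULL`
#'   draws them once per simulation (first cohort fixed at 0 as reference)
#'   and records them on the result.
#' @param floor Minimal effective copy count before the log (guards
#'   homozygous deletions at `gamma = 0`); must be > 0.
#' @param seed Integer seed for noise and offset draws.
#' @return An object of class `acgh_params`.
#' @export
acgh_params <- function(gamma = 0.3, noise_sd = 0.15, cohort_offsets = NULL,
                        floor = 0.05, seed = NULL) {
  stopifnot(gamma >= 0, gamma <= 1, noise_sd >= 0, floor > 0)
  structure(list(gamma = gamma, noise_sd = noise_sd,
                 cohort_offsets = cohort_offsets, floor = floor, seed = seed),
            class = "acgh_params")
}

#' A diploid genotype: two structural alleles plus sample metadata
#'
#' @param sample_id Unique sample label.
#' @param allele1,allele2 `structural_allele` objects.
#' @param cohort Cohort label.
#' @param status `"case"` or `"control"`.
#' @return An object of class `diploid_genotype`.
#' @export
diploid_genotype <- function(sample_id, allele1, allele2,
                             cohort = "cohort1", status = "control") {
  stopifnot(inherits(allele1, "structural_allele"),
            inherits(allele2, "structural_allele"),
            status %in% c("case", "control"))
  structure(list(sample_id = sample_id, allele1 = allele1,
                 allele2 = allele2, cohort = cohort, status = status),
            class = "diploid_genotype")
}

#' Simulate an aCGH log2-ratio matrix
#'
#' The response of probe p (position x, design paralog T) in a sample is
#' driven by the unit count at x matching T (`m`) and the count sourced from
#' the other paralog (`u`), relative to the normal diploid reference
#' (2 matched + 2 mismatched units):
#' `log2(max(m + gamma*u, floor) / (2 + 2*gamma)) + cohort_offset + noise`.
#' Copy number and paralog identity therefore both shape the signal, and at
#' `gamma = 1` paralog discrimination vanishes.
#'
#' @param genotypes List of [diploid_genotype()] objects.
#' @param probes Probe annotation as from [design_probes()].
#' @param params [acgh_params()].
#' @return An object of class `intensity_matrix`: list with `values`
#'   (samples x probes matrix), `samples` (metadata data.frame), `probes`,
#'   and `cohort_offsets` as realized.
#' @export
simulate_acgh <- function(genotypes, probes, params = acgh_params()) {
  if (length(genotypes) == 0L)
    stop("empty genotype list", call. = FALSE)
  stopifnot(inherits(params, "acgh_params"))
  ids <- vapply(genotypes, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  cohorts <- vapply(genotypes, `[[`, character(1), "cohort")
  status <- vapply(genotypes, `[[`, character(1), "status")
  pos <- probes$unit_position
  design <- probes$design_paralog
  g <- params$gamma

  with_seed(params$seed, {
    offs <- params$cohort_offsets
    levs <- unique(cohorts)
    if (is.null(offs)) {
      offs <- setNames(c(0, round(rnorm(length(levs) - 1L, 0, 0.1), 4)), levs)
    } else {
      missing <- setdiff(levs, names(offs))
      if (length(missing)) offs[missing] <- 0
    }
    vals <- t(vapply(genotypes, function(gt) {
      units <- c(gt$allele1$units, gt$allele2$units)
      src <- vapply(units, unit_source_at, character(length(pos)), pos = pos)
      if (length(pos) == 1L) src <- matrix(src, nrow = 1L)
      m <- rowSums(src == matrix(design, nrow = length(pos),
                                 ncol = length(units)))
      u <- length(units) - m
      log2(pmax(m + g * u, params$floor) / (2 + 2 * g))
    }, numeric(length(pos))))
    if (length(pos) == 1L) vals <- matrix(vals, ncol = 1L)
    vals <- vals + offs[cohorts]
    if (params$noise_sd > 0)
      vals <- vals + matrix(rnorm(length(vals), 0, params$noise_sd),
                            nrow = nrow(vals))
    dimnames(vals) <- list(ids, probes$probe_id)
    structure(list(
      values = vals,
      samples = data.frame(sample_id = ids, cohort = cohorts,
                           status = status, stringsAsFactors = FALSE),
      probes = probes,
      cohort_offsets = offs), class = "intensity_matrix")
  })
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d samples x %d probes, cohorts: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$cohort), collapse = ", ")))
  invisible(x)
}
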