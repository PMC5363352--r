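#' Deletion-type concordance against a known-type validation panel
#'
#' Simulates the standard validation study — a 400-sample single-cohort
#' aCGH experiment (cross-hybridization weight 0.3, log2 noise sd 0.15,
#' 33 probes of which 20 are discriminating) containing heterozygous A-
#' and B-type deletion carriers of which 15 form a held-out known-type
#' panel — runs copy-number calling, homozygote exclusion and the
#' two-component deletion-type classifier, and reports percent agreement
#' between the classifier's calls and the panel's generating truth. The
#' panel labels are never seen by the classifier.
#'
#' @param seed Integer seed driving every stage.
#' @param gamma,noise_sd Array simulation parameters.
#' @param n Cohort size.
#' @return List with `concordance_pct`, `n_known`, `calls` (the panel
#'   with its calls), and the full `typed` stage output.
#' @export
validation_concordance <- function(seed = 1L, gamma = 0.3,
                                   noise_sd = 0.15, n = 400L) {
  pair <- simulate_paralog_pair(16000L, 0.015, seed = derive_seed(seed, 11L))
  hotspots <- default_hotspot_catalog(16000L)
  probes <- design_probes(16000L, hotspots)
  vc <- simulate_validation_cohort(pair, hotspots, n = n,
                                   seed = derive_seed(seed, 12L))
  mat <- simulate_acgh(vc$genotypes, probes,
                       acgh_params(gamma = gamma, noise_sd = noise_sd,
                                   seed = derive_seed(seed, 13L)))
  typed <- type_deletions(mat, hotspots, seed = derive_seed(seed, 14L))
  known <- vc$known
  known$call <- if (is.null(typed$type_calls)) NA_character_ else
    typed$type_calls$label[match(known$sample_id,
                                 typed$type_calls$sample_id)]
  agree <- !is.na(known$call) & known$call == known$true_label
  list(concordance_pct = 100 * mean(agree), n_known = nrow(known),
       calls = known, typed = typed)
}

#' Copy-number calling and deletion typing from an intensity matrix
#'
#' Runs the analysis core shared by [run_pipeline()] and standalone use:
#' PC1 on the full probe set, three-component cohort-adjusted mixture and
#' loss/normal/gain calling; exclusion of homozygous deletions among the
#' loss-called samples (auto threshold guarded by the loss-to-normal
#' component spacing); then PC1 on the discriminating probes and the
#' two-component status-adjusted mixture assigning each remaining
#' heterozygous deletion to A-type or B-type.
#'
#' @param mat An `intensity_matrix`.
#' @param hotspots Hotspot catalog defining the discriminating region.
#' @param classifier A [classifier_config()].
#' @param seed Integer seed; stage seeds derive from it.
#' @param anchors Optional known-type panel forwarded to
#'   [classify_deletion_type()].
#' @return List with `pc`, `cn_fit`, `cn_calls`, `filter` (kept/removed/
#'   threshold), `type_calls` (NULL when fewer than 4 deletion carriers
#'   are available).
#' @export
type_deletions <- function(mat, hotspots,
                           classifier = classifier_config(
                             homozygote_threshold = "auto"),
                           seed = NULL, anchors = NULL) {
  stopifnot(inherits(mat, "intensity_matrix"))
  pc <- pc_scores(mat)
  cn_fit <- fit_gaussian_mixture(pc$scores, k = 3L,
                                 cohort = mat$samples$cohort,
                                 seed = derive_seed(seed, 1L))
  cn_calls <- call_copy_number(cn_fit, classifier$min_posterior)
  del_ids <- cn_calls$sample_id[cn_calls$class == "loss"]
  out <- list(pc = pc, cn_fit = cn_fit, cn_calls = cn_calls,
              filter = NULL, type_calls = NULL)
  if (length(del_ids) < 4L) return(out)
  mu <- sort(cn_fit$means, decreasing = TRUE)
  gap <- mu[1] - mu[2]  # loss-to-normal spacing on oriented PC1
  out$filter <- filter_homozygotes(
    pc$scores[del_ids], threshold = classifier$homozygote_threshold,
    seed = derive_seed(seed, 2L), reference_gap = gap)
  if (length(out$filter$kept) < 2L) return(out)
  disc <- select_discriminating_probes(mat$probes, hotspots)
  sub <- mat$values[out$filter$kept, disc$probe_id, drop = FALSE]
  status <- mat$samples$status[match(out$filter$kept,
                                     mat$samples$sample_id)]
  out$type_calls <- classify_deletion_type(
    sub, status = status, seed = derive_seed(seed, 3L), anchors = anchors,
    min_posterior = classifier$min_posterior)
  out
}
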