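#' Configuration for the deletion-type classifier
#'
#' @param homozygote_threshold PC1 cutoff above which a deletion-called
#'   sample is treated as a deletion homozygote and excluded (default 3.8,
#'   matching the cutoff used on quantile-normalized whole-genome aCGH
#'   data; the value is data-scale specific). `"auto"` derives the cutoff
#'   from the valley between the two rightmost mixture components of the
#'   deletion-carrier PC1 distribution.
#' @param min_posterior Posterior below which a type call is flagged.
#' @param seed Integer seed for the classifier's mixture fit.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(homozygote_threshold = 3.8,
                              min_posterior = 0.5, seed = NULL) {
  stopifnot(identical(homozygote_threshold, "auto") ||
              (is.numeric(homozygote_threshold) &&
                 is.finite(homozygote_threshold)))
  structure(list(homozygote_threshold = homozygote_threshold,
                 min_posterior = min_posterior, seed = seed),
            class = "classifier_config")
}

#' Select probes in the deletion-determining region
#'
#' Keeps the probes whose position lies strictly between the proximal and
#' distal breakpoint hotspots — the region whose paralog identity on the
#' retained chimeric unit differs between A-type and B-type deletion
#' chromosomes, and hence the only probes carrying type information. With
#' the default synthetic design this retains 20 of the 33 probes.
#'
#' @param probes Probe annotation (as from [design_probes()]).
#' @param hotspots Hotspot catalog.
#' @return The retained rows of `probes`.
#' @export
select_discriminating_probes <- function(probes, hotspots) {
  prox_end <- hotspots$end[which.min(hotspots$start)]
  dist_start <- hotspots$start[which.max(hotspots$start)]
  keep <- probes$unit_position > prox_end & probes$unit_position < dist_start
  if (!any(keep))
    stop("no probes fall between the breakpoint hotspots; ",
         "widen the discriminating region", call. = FALSE)
  probes[keep, , drop = FALSE]
}

#' Exclude homozygous deletions by PC1 cutoff
#'
#' Among deletion-called samples, those with PC1 strictly greater than the
#' threshold are removed as deletion homozygotes: having no retained
#' chimeric unit, they cannot be typed as A- or B-deletions. A score
#' exactly equal to the threshold is kept (strict inequality). With
#' `threshold = "auto"` the cutoff is the equal-posterior crossing between
#' the two components of a two-component mixture fitted to the scores; if
#' those components are not separable (means within one pooled standard
#' deviation) no sample is removed.
#'
#' The deletion-carrier PC1 distribution can be structured by more than
#' zygosity (the A-type/B-type contrast also projects onto full-probe
#' PC1), so in auto mode a candidate split is only accepted as the
#' het/hom boundary when the component separation is commensurate with a
#' whole copy-number class: at least `gap_factor` times `reference_gap`,
#' the loss-to-normal component spacing from the genome-wide
#' three-component fit. Without a reference gap the fallback guard is
#' separation of at least one pooled standard deviation.
#'
#' @param scores Named numeric PC1 scores of deletion-called samples (from
#'   the full probe set), or a `pc_result`.
#' @param threshold Numeric cutoff or `"auto"`.
#' @param seed Seed for the auto-threshold mixture fit.
#' @param reference_gap Optional spacing between the loss and normal
#'   component means of the copy-number fit, on the same PC1 scale.
#' @param gap_factor Minimal component separation, as a fraction of
#'   `reference_gap`, for auto-mode removal (default 0.75).
#' @return List with `kept`, `removed` (sample id vectors) and
#'   `threshold` as applied.
#' @export
filter_homozygotes <- function(scores, threshold = 3.8, seed = NULL,
                               reference_gap = NULL, gap_factor = 0.75) {
  if (inherits(scores, "pc_result")) scores <- scores$scores
  if (is.null(names(scores)))
    names(scores) <- sprintf("sample%04d", seq_along(scores))
  if (identical(threshold, "auto")) {
    fit <- fit_gaussian_mixture(scores, k = 2L, seed = seed)
    ord <- order(fit$means)
    dmu <- diff(fit$means[ord])
    pooled <- sqrt(sum(fit$weights * fit$sds^2))
    separable <- if (!is.null(reference_gap))
      dmu > gap_factor * reference_gap else dmu >= pooled
    if (!separable) {
      threshold <- Inf
    } else {
      f <- function(x)
        fit$weights[ord[1]] * dnorm(x, fit$means[ord[1]], fit$sds[ord[1]]) -
        fit$weights[ord[2]] * dnorm(x, fit$means[ord[2]], fit$sds[ord[2]])
      threshold <- tryCatch(
        uniroot(f, lower = fit$means[ord[1]], upper = fit$means[ord[2]])$root,
        error = function(e) mean(fit$means))
    }
  }
  removed <- names(scores)[scores > threshold]
  kept <- setdiff(names(scores), removed)
  list(kept = kept, removed = removed, threshold = threshold)
}

#' Classify heterozygous deletions as A-type or B-type
#'
#' PC1 is recomputed on the deletion heterozygotes restricted to the
#' discriminating probes; because all these samples share the same total
#' copy number, the leading component of variation reflects the paralog
#' identity of the retained chimeric unit. A two-component Gaussian
#' mixture (case/control status as the additive factor) splits the
#' samples; the component holding the majority of samples is labelled
#' `B_deletion` — B-type deletions being the common type — unless an
#' anchor panel of known-type samples is supplied, in which case component
#' labels follow the anchors' majority vote.
#'
#' @param x Numeric matrix of deletion heterozygotes by discriminating
#'   probes (or an `intensity_matrix` already restricted).
#' @param status Character vector of `"case"`/`"control"` per sample,
#'   used as the mixture factor.
#' @param seed Integer seed.
#' @param anchors Optional data.frame (`sample_id`, `true_label`) of
#'   known-type samples used to orient component labels.
#' @param min_posterior Posterior below which a call is flagged.
#' @return Data.frame with `sample_id`, `label`
#'   (`A_deletion`/`B_deletion`), `posterior`, `low_confidence`; attribute
#'   `separation` records the standardized component separation.
#' @export
classify_deletion_type <- function(x, status = NULL, seed = NULL,
                                   anchors = NULL, min_posterior = 0.5) {
  m <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  pc <- pc_scores(m)
  degenerate <- FALSE
  fit <- withCallingHandlers(
    fit_gaussian_mixture(pc$scores, k = 2L, cohort = status, seed = seed),
    warning = function(w) {
      if (grepl("degenerate", conditionMessage(w))) {
        degenerate <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  dmu <- abs(diff(fit$means))
  pooled <- sqrt(sum(fit$weights * fit$sds^2))
  separable <- !degenerate && dmu >= pooled
  if (!separable)
    warning("mixture components are not separable; ",
            "deletion-type calls are low confidence")
  comp <- max.col(fit$responsibilities, ties.method = "first")
  post <- fit$responsibilities[cbind(seq_along(comp), comp)]
  labels <- c("", "")
  if (!is.null(anchors) && nrow(anchors) > 0L) {
    idx <- match(anchors$sample_id, rownames(m))
    ok <- !is.na(idx)
    vote_b <- tapply(anchors$true_label[ok] == "B_deletion", comp[idx[ok]],
                     mean)
    b_comp <- as.integer(names(vote_b)[which.max(vote_b)])
    labels[b_comp] <- "B_deletion"
    labels[3L - b_comp] <- "A_deletion"
  } else {
    major <- if (sum(comp == 1L) >= sum(comp == 2L)) 1L else 2L
    labels[major] <- "B_deletion"
    labels[3L - major] <- "A_deletion"
  }
  out <- data.frame(sample_id = rownames(m), label = labels[comp],
                    posterior = post,
                    low_confidence = !separable | post < min_posterior,
                    stringsAsFactors = FALSE)
  attr(out, "separation") <- dmu / pooled
  attr(out, "fit") <- fit
  attr(out, "pc") <- pc
  out
}
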