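#' Pipeline configuration
#'
#' Bundles locus, cohort, array and classifier parameters for
#' [run_pipeline()]. Defaults mirror the synthetic study design used
#' throughout the package: a 16-kb unit at 1.5% divergence, two breakpoint
#' hotspots, 33 probes (20 discriminating), case/control arms of 2,000
#' with a generating carrier odds ratio of 1.6.
#'
#' @param unit_length,divergence Locus scale and PSV density.
#' @param cohort_design Data.frame (`cohort`, `n`, `status`).
#' @param q_del_b,q_del_a,q_dup Control allele frequencies.
#' @param carrier_or Generating case/control carrier odds ratio.
#' @param acgh [acgh_params()].
#' @param classifier [classifier_config()]; the default uses the
#'   auto homozygote threshold appropriate for synthetic PC1 scales.
#' @param n_fosmid_alleles Number of deletion alleles run through the
#'   contig-level breakpoint-mapping stage.
#' @param contig_length,contig_step,contig_error_rate Contig simulation.
#' @param min_run,min_tract_psvs Switch-detection parameters.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(unit_length = 16000L, divergence = 0.015,
                            cohort_design = data.frame(
                              cohort = c("ctrl", "case"),
                              n = c(2000L, 2000L),
                              status = c("control", "case"),
                              stringsAsFactors = FALSE),
                            q_del_b = 0.0126, q_del_a = 0.005,
                            q_dup = 0.01, carrier_or = 1.6,
                            acgh = acgh_params(),
                            classifier = classifier_config(
                              homozygote_threshold = "auto"),
                            n_fosmid_alleles = 4L,
                            contig_length = 4000L, contig_step = 3000L,
                            contig_error_rate = 0.001,
                            min_run = 2L, min_tract_psvs = 2L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

truth_cn_class <- function(class) {
  n_units <- function(cl) {
    parts <- strsplit(cl, "/", fixed = TRUE)[[1]]
    sum(vapply(parts, function(p)
      switch(p, normal = 2L, dup = 3L, 1L), integer(1)))
  }
  u <- vapply(class, n_units, integer(1))
  ifelse(u < 4L, "loss", ifelse(u > 4L, "gain", "normal"))
}

#' Run the full synthetic CNV analysis pipeline
#'
#' Simulates the locus and cohort, then runs the inference stages in
#' order: contig-level paralog assignment and breakpoint mapping on a
#' panel of deletion alleles; PC1 + three-component cohort-adjusted
#' mixture copy-number calling; homozygote exclusion; deletion-type
#' classification on the discriminating probes; and exact case/control
#' association of B-type deletion carriage. Inference stages never read
#' truth annotations; truth is used only to build the evaluation tables
#' in the report. All outputs (FASTA, BED, TSV, JSON) are written under
#' `outdir` and are byte-identical across runs with the same config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The run report (list), invisibly also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), warnings = list())
  seed <- config$seed

  ## stage 1: locus
  pair <- simulate_paralog_pair(config$unit_length, config$divergence,
                                seed = derive_seed(seed, 1L))
  hotspots <- default_hotspot_catalog(config$unit_length)
  probes <- design_probes(config$unit_length, hotspots)
  write_fasta(c(paralog_A = pair$seq_a, paralog_B = pair$seq_b),
              file.path(outdir, "references.fasta"))
  write_bed(data.frame(start = pair$psv_catalog$pos,
                       end = pair$psv_catalog$pos,
                       name = sprintf("psv_%s>%s", pair$psv_catalog$a_base,
                                      pair$psv_catalog$b_base)),
            file.path(outdir, "psvs.bed"))
  write_bed(data.frame(start = hotspots$start, end = hotspots$end,
                       name = hotspots$name),
            file.path(outdir, "hotspots.bed"))
  report$stages$locus <- list(unit_length = config$unit_length,
                              n_psvs = nrow(pair$psv_catalog),
                              n_probes = nrow(probes))

  ## stage 2: fosmid-like breakpoint mapping on a deletion-allele panel
  fosmid <- with_seed(derive_seed(seed, 2L), {
    lapply(seq_len(config$n_fosmid_alleles), function(i) {
      type <- if (i %% 2L == 0L) "A" else "B"
      b <- random_breakpoint(hotspots, type)
      allele <- build_allele(pair, list(nahr_deletion(b)))
      contigs <- simulate_contigs(allele, pair, config$contig_length,
                                  config$contig_step,
                                  config$contig_error_rate,
                                  seed = derive_seed(seed, 100L + i))
      asg <- assign_paralog(contigs, pair)
      prof <- consensus_profile(lapply(seq_len(nrow(contigs)), function(j)
        psv_profile(contigs[j, ], pair)))
      sw <- detect_switches(prof, config$min_run)
      ev <- classify_events(sw, prof, config$min_tract_psvs)
      ev$breakpoints <- assign_hotspot(ev$breakpoints, hotspots)
      list(true_type = type, true_breakpoint = b, assignments = asg,
           breakpoints = ev$breakpoints, conversions = ev$conversions)
    })
  })
  unit_seqs <- unlist(lapply(seq_along(fosmid), function(i) {
    allele <- build_allele(pair, list(nahr_deletion(fosmid[[i]]$true_breakpoint)))
    setNames(realize_sequence(allele, pair), sprintf("allele%d_unit1", i))
  }))
  write_fasta(unit_seqs, file.path(outdir, "realized_units.fasta"))
  called_bp <- do.call(rbind, lapply(seq_along(fosmid), function(i) {
    b <- fosmid[[i]]$breakpoints
    if (nrow(b)) cbind(allele = i, b[, c("start", "end", "hotspot_label")])
  }))
  if (!is.null(called_bp) && nrow(called_bp))
    write_bed(data.frame(start = called_bp$start, end = called_bp$end,
                         name = sprintf("allele%d_%s", called_bp$allele,
                                        called_bp$hotspot_label)),
              file.path(outdir, "called_breakpoints.bed"))
  bp_contained <- vapply(fosmid, function(f) {
    nrow(f$breakpoints) >= 1L &&
      any(f$breakpoints$start <= f$true_breakpoint &
            f$breakpoints$end >= f$true_breakpoint + 1L)
  }, logical(1))
  report$stages$breakpoint_mapping <- list(
    n_alleles = length(fosmid),
    n_breakpoint_contained = sum(bp_contained),
    hotspot_concordant = sum(vapply(fosmid, function(f) {
      nrow(f$breakpoints) >= 1L &&
        hotspots$del_type[match(f$breakpoints$hotspot_label[1],
                                hotspots$name)] == f$true_type
    }, logical(1))))

  ## stage 3: cohort + aCGH
  cohort <- simulate_case_control_cohort(
    pair, design = config$cohort_design, hotspots = hotspots,
    q_del_b = config$q_del_b, q_del_a = config$q_del_a,
    q_dup = config$q_dup, carrier_or = config$carrier_or,
    seed = derive_seed(seed, 3L))
  acgh <- config$acgh
  if (is.null(acgh$seed)) acgh$seed <- derive_seed(seed, 4L)
  mat <- simulate_acgh(cohort$genotypes, probes, acgh)
  write_matrix_tsv(mat$values, file.path(outdir, "intensity.tsv"))
  report$stages$cohort <- list(
    n_samples = nrow(mat$values),
    cohort_offsets = as.list(mat$cohort_offsets),
    truth_classes = as.list(table(cohort$truth$class)))

  ## stages 4-6: CN calling, homozygote exclusion, deletion typing
  typed <- withCallingHandlers(
    type_deletions(mat, hotspots, classifier = config$classifier,
                   seed = derive_seed(seed, 5L)),
    warning = function(w) {
      report$warnings$typing <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  cn <- typed$cn_calls
  write_calls(cn, file.path(outdir, "cn_calls.tsv"))
  truth_cn <- truth_cn_class(cohort$truth$class)
  report$stages$cn_calling <- list(
    n_in = nrow(cn),
    calls = as.list(table(cn$class)),
    confusion = as.list(table(paste(truth_cn, cn$class, sep = "->"))))

  if (is.null(typed$type_calls)) {
    report$warnings$association <- "too few deletion-called samples"
    report$association <- list(aborted = TRUE,
                               reason = "empty carrier cells")
    report <- write_report(report, config, outdir)
    return(invisible(report))
  }
  hz <- typed$filter
  n_del <- sum(cn$class == "loss")
  stopifnot(length(hz$kept) + length(hz$removed) == n_del)
  report$stages$homozygote_filter <- list(
    n_in = n_del, n_kept = length(hz$kept),
    n_removed = length(hz$removed), threshold = hz$threshold)

  type_calls <- typed$type_calls
  status_kept <- mat$samples$status[match(hz$kept, mat$samples$sample_id)]
  write_calls(type_calls, file.path(outdir, "type_calls.tsv"))
  report$stages$classification <- list(
    n_in = length(hz$kept),
    calls = as.list(table(type_calls$label)),
    separation = attr(type_calls, "separation"))

  ## stage 7: association of B-deletion carriage
  n_cases <- sum(config$cohort_design$n[config$cohort_design$status == "case"])
  n_controls <- sum(config$cohort_design$n[config$cohort_design$status == "control"])
  tab <- carrier_table(type_calls, status_kept, n_cases, n_controls)
  if (tab$case_carriers + tab$control_carriers == 0L) {
    report$association <- list(aborted = TRUE, reason = "empty carrier cells")
  } else {
    res <- associate(tab)
    report$association <- list(
      aborted = FALSE,
      table = unclass(tab), or_sample = res$or_sample,
      or_cmle = res$or_cmle, p_two_sided = res$p_two_sided,
      ci = res$ci, level = res$level)
  }

  report <- write_report(report, config, outdir)
  invisible(report)
}

write_report <- function(report, config, outdir) {
  cfg_path <- file.path(outdir, "config.json")
  cfg <- config
  cfg$acgh <- unclass(cfg$acgh)
  cfg$classifier <- unclass(cfg$classifier)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("paralogCNV")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}
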