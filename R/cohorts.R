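# Cohort-level genotype generators: frequency-driven case/control cohorts
# for association studies, and a fixed-composition validation cohort with
# known-type deletion carriers for classifier benchmarking.

random_breakpoint <- function(hotspots, del_type) {
  h <- hotspots[hotspots$del_type == del_type, ]
  sample(seq.int(h$start, h$end), 1L)
}

# `normal` is the prebuilt two-unit allele, shared across draws: normal
# alleles are identical, so rebuilding one per haplotype would only cost
# time.
draw_allele <- function(pair, hotspots, q_del_b, q_del_a, q_dup, normal) {
  r <- runif(1)
  if (r < q_del_b) {
    build_allele(pair, list(nahr_deletion(random_breakpoint(hotspots, "B"))))
  } else if (r < q_del_b + q_del_a) {
    build_allele(pair, list(nahr_deletion(random_breakpoint(hotspots, "A"))))
  } else if (r < q_del_b + q_del_a + q_dup) {
    build_allele(pair, list(nahr_duplication(random_breakpoint(hotspots, "B"))))
  } else {
    normal
  }
}

genotype_truth_class <- function(gt, hotspots) {
  classify1 <- function(a) {
    if (length(a$units) == 3L) return("dup")
    if (length(a$units) == 2L) return("normal")
    b <- Filter(function(e) e$type == "nahr_deletion", a$events)[[1]]$breakpoint
    ov <- hotspots$del_type[b >= hotspots$start & b <= hotspots$end]
    paste0("del_", if (length(ov)) ov[1] else "unassigned")
  }
  paste(sort(c(classify1(gt$allele1), classify1(gt$allele2))), collapse = "/")
}

#' Simulate a case/control cohort with enriched deletion carriage in cases
#'
#' Alleles are drawn independently per haplotype: B-type NAHR deletion at
#' frequency `q_del_b` in controls, A-type deletion at `q_del_a`, duplication
#' at `q_dup`, otherwise the normal two-unit allele. In cases the B-deletion
#' carrier probability is enriched to the target carrier odds ratio
#' `carrier_or` (on the carrier scale, the quantity the association stage
#' estimates).
#'
#' Default control carrier frequency ~2.5% matches the scale of reported
#' control carriage of the B-type deletion (82 carriers among 3,271
#' controls); A deletions are configured rarer than B deletions so the
#' two-component deletion-type classifier sees a clear majority class.
#'
#' @param pair A `paralog_pair`.
#' @param design Data.frame with columns `cohort`, `n`, `status` describing
#'   cohort sizes and case/control status.
#' @param hotspots Hotspot catalog.
#' @param q_del_b,q_del_a,q_dup Control-population allele frequencies.
#' @param carrier_or Target case/control carrier odds ratio for the B-type
#'   deletion (default 1.6).
#' @param seed Integer seed.
#' @return List with `genotypes` (list of [diploid_genotype()]) and `truth`
#'   (data.frame with `sample_id`, `cohort`, `status`, `class`,
#'   `carrier_b`).
#' @export
simulate_case_control_cohort <- function(pair,
                                         design = data.frame(
                                           cohort = c("ctrl", "case"),
                                           n = c(2000L, 2000L),
                                           status = c("control", "case"),
                                           stringsAsFactors = FALSE),
                                         hotspots = default_hotspot_catalog(pair$unit_length),
                                         q_del_b = 0.0126,
                                         q_del_a = 0.005,
                                         q_dup = 0.01,
                                         carrier_or = 1.6,
                                         seed = NULL) {
  stopifnot(all(c("cohort", "n", "status") %in% names(design)))
  # carrier probability in controls -> enriched case carrier probability at
  # the target odds ratio, then back to a per-allele frequency
  p0 <- 1 - (1 - q_del_b)^2
  odds1 <- carrier_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  q_del_b_case <- 1 - sqrt(1 - p1)

  with_seed(seed, {
    normal <- build_allele(pair, list())
    genotypes <- vector("list", sum(design$n))
    k <- 0L
    for (i in seq_len(nrow(design))) {
      qb <- if (design$status[i] == "case") q_del_b_case else q_del_b
      for (j in seq_len(design$n[i])) {
        k <- k + 1L
        genotypes[[k]] <- diploid_genotype(
          sprintf("s%05d", k),
          draw_allele(pair, hotspots, qb, q_del_a, q_dup, normal),
          draw_allele(pair, hotspots, qb, q_del_a, q_dup, normal),
          cohort = design$cohort[i], status = design$status[i])
      }
    }
    truth <- data.frame(
      sample_id = vapply(genotypes, `[[`, character(1), "sample_id"),
      cohort = vapply(genotypes, `[[`, character(1), "cohort"),
      status = vapply(genotypes, `[[`, character(1), "status"),
      class = vapply(genotypes, genotype_truth_class, character(1),
                     hotspots = hotspots),
      stringsAsFactors = FALSE)
    truth$carrier_b <- grepl("del_B", truth$class)
    list(genotypes = genotypes, truth = truth)
  })
}

#' Simulate a fixed-composition validation cohort with known-type carriers
#'
#' Builds a cohort of `n` samples with a fixed number of heterozygous
#' B-type and A-type deletion carriers, homozygous B deletions, and
#' duplication carriers (the remainder normal diploid), and marks
#' `n_known` heterozygous deletion carriers (majority B-type) as a held-out
#' truth panel — the synthetic analog of carriers typed by an orthogonal
#' PCR assay. Case/control status is assigned at random so it can serve as
#' the mixture-model factor.
#'
#' @param pair A `paralog_pair`.
#' @param hotspots Hotspot catalog.
#' @param n Total samples (default 400).
#' @param n_het_b,n_het_a Heterozygous deletion carrier counts (24 / 10).
#' @param n_hom_b Homozygous B-deletion count (4).
#' @param n_dup Duplication carrier count (8).
#' @param n_known Size of the known-type panel (default 15, drawn 2:1
#'   B-type to A-type).
#' @param seed Integer seed.
#' @return List with `genotypes`, `truth` (per-sample class and deletion
#'   type) and `known` (data.frame `sample_id`, `true_label` in
#'   `A_deletion`/`B_deletion`).
#' @export
simulate_validation_cohort <- function(pair,
                                       hotspots = default_hotspot_catalog(pair$unit_length),
                                       n = 400L, n_het_b = 24L, n_het_a = 10L,
                                       n_hom_b = 4L, n_dup = 8L,
                                       n_known = 15L, seed = NULL) {
  n_norm <- n - n_het_b - n_het_a - n_hom_b - n_dup
  stopifnot(n_norm >= 0L, n_known <= n_het_b + n_het_a)
  with_seed(seed, {
    classes <- sample(c(rep("het_b", n_het_b), rep("het_a", n_het_a),
                        rep("hom_b", n_hom_b), rep("dup", n_dup),
                        rep("normal", n_norm)))
    normal <- function() build_allele(pair, list())
    del <- function(type) build_allele(
      pair, list(nahr_deletion(random_breakpoint(hotspots, type))))
    dup <- function() build_allele(
      pair, list(nahr_duplication(random_breakpoint(hotspots, "B"))))
    genotypes <- lapply(seq_len(n), function(i) {
      al <- switch(classes[i],
        normal = list(normal(), normal()),
        het_b = list(del("B"), normal()),
        het_a = list(del("A"), normal()),
        hom_b = list(del("B"), del("B")),
        dup = list(dup(), normal()))
      diploid_genotype(sprintf("v%04d", i), al[[1]], al[[2]],
                       cohort = "validation",
                       status = sample(c("case", "control"), 1L))
    })
    truth <- data.frame(
      sample_id = vapply(genotypes, `[[`, character(1), "sample_id"),
      class = classes, stringsAsFactors = FALSE)
    n_known_b <- min(round(n_known * 2 / 3), n_het_b)
    n_known_a <- n_known - n_known_b
    kb <- sample(truth$sample_id[classes == "het_b"], n_known_b)
    ka <- sample(truth$sample_id[classes == "het_a"], n_known_a)
    known <- data.frame(
      sample_id = c(kb, ka),
      true_label = rep(c("B_deletion", "A_deletion"), c(n_known_b, n_known_a)),
      stringsAsFactors = FALSE)
    list(genotypes = genotypes, truth = truth, known = known)
  })
}
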