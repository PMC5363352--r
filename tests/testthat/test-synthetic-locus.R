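test_that("paralog pair has the requested PSV density and identity", {
  pair <- simulate_paralog_pair(16000, 0.015, seed = 1)
  expect_equal(nrow(pair$psv_catalog), 240)
  expect_equal(pair_identity(pair), 0.985)
  expect_equal(nchar(pair$seq_a), 16000)
  expect_equal(nchar(pair$seq_b), 16000)
  # PSV invariants
  expect_true(all(diff(pair$psv_catalog$pos) > 0))
  expect_true(all(pair$psv_catalog$a_base != pair$psv_catalog$b_base))
})

test_that("zero divergence gives identical sequences and an empty catalog", {
  pair <- simulate_paralog_pair(1000, 0, seed = 99)
  expect_identical(pair$seq_a, pair$seq_b)
  expect_equal(nrow(pair$psv_catalog), 0)
})

test_that("PSV catalog equals brute-force position-wise comparison", {
  pair <- simulate_paralog_pair(2000, 0.01, seed = 7)
  expect_equal(pair$psv_catalog$pos,
               oracle_mismatch_positions(pair$seq_a, pair$seq_b))
  # and at non-PSV positions the sequences agree (implied by the equality)
  expect_equal(length(oracle_mismatch_positions(pair$seq_a, pair$seq_b)),
               round(0.01 * 2000))
})

test_that("pair generation is deterministic given the seed and validates input", {
  expect_identical(simulate_paralog_pair(500, 0.02, seed = 3),
                   simulate_paralog_pair(500, 0.02, seed = 3))
  expect_error(simulate_paralog_pair(50, 0.01), "at least 100")
  expect_error(simulate_paralog_pair(1000, 0.25), "divergence")
})

test_that("NAHR deletion yields one chimeric unit switching A to B at the breakpoint", {
  pair <- make_test_pair()
  b <- 900L
  del <- build_allele(pair, list(nahr_deletion(b)))
  expect_length(del$units, 1)
  seqs <- realize_sequence(del, pair)
  cat_ <- pair$psv_catalog
  st <- oracle_psv_states(seqs[1], 1L, cat_)
  expect_true(all(st$state[st$pos <= b] == "A"))
  expect_true(all(st$state[st$pos > b] == "B"))
})

test_that("NAHR duplication realizes the reciprocal string splice", {
  pair <- make_test_pair()
  b <- 700L
  dup <- build_allele(pair, list(nahr_duplication(b)))
  expect_length(dup$units, 3)
  seqs <- realize_sequence(dup, pair)
  L <- pair$unit_length
  spliced <- c(pair$seq_a,
               paste0(substr(pair$seq_b, 1, b), substr(pair$seq_a, b + 1, L)),
               pair$seq_b)
  expect_identical(paste(seqs, collapse = ""), paste(spliced, collapse = ""))
})

test_that("deletion and duplication at one breakpoint are reciprocal products", {
  pair <- make_test_pair()
  for (b in c(250L, 1000L, 1750L)) {
    del <- build_allele(pair, list(nahr_deletion(b)))
    dup <- build_allele(pair, list(nahr_duplication(b)))
    expect_length(del$units, 1)
    expect_length(dup$units, 3)
    # deletion chimera: one A->B switch; duplication middle unit: one B->A
    del_src <- oracle_unit_source(del$units[[1]], c(b, b + 1L))
    dup_src <- oracle_unit_source(dup$units[[2]], c(b, b + 1L))
    expect_identical(del_src, c("A", "B"))
    expect_identical(dup_src, c("B", "A"))
  }
})

test_that("gene conversion rewrites exactly the tract and rejects bad input", {
  pair <- make_test_pair()
  al <- build_allele(pair, list(gene_conversion(1, "B", 400, 800)))
  seqs <- realize_sequence(al, pair)
  diffs <- oracle_mismatch_positions(seqs[1], pair$seq_a)
  expect_setequal(diffs, pair$psv_catalog$pos[pair$psv_catalog$pos >= 400 &
                                                pair$psv_catalog$pos <= 800])
  # empty tract is a no-op
  al0 <- build_allele(pair, list(gene_conversion(1, "B", 500, 499)))
  expect_identical(realize_sequence(al0, pair)[1], pair$seq_a)
  # overlapping tracts rejected
  expect_error(build_allele(pair, list(gene_conversion(1, "B", 100, 300),
                                       gene_conversion(1, "B", 200, 400))),
               "overlapping")
  expect_error(build_allele(pair, list(nahr_deletion(0))), "strictly inside")
  expect_error(build_allele(pair, list(nahr_deletion(1),
                                       nahr_duplication(5))),
               "at most one NAHR")
})

test_that("realized mosaics equal per-position brute-force lookup", {
  pair <- make_test_pair()
  al <- build_allele(pair, list(nahr_duplication(1200),
                                gene_conversion(1, "B", 100, 350),
                                gene_conversion(3, "A", 900, 1500)))
  seqs <- realize_sequence(al, pair)
  for (u in seq_along(al$units)) {
    src <- oracle_unit_source(al$units[[u]], seq_len(pair$unit_length))
    expected <- ifelse(src == "A",
                       strsplit(pair$seq_a, "")[[1]],
                       strsplit(pair$seq_b, "")[[1]])
    expect_identical(strsplit(seqs[u], "")[[1]], expected)
  }
  # segments tile the unit exactly
  for (u in al$units) {
    expect_equal(u$start[1], 1)
    expect_equal(u$end[nrow(u)], pair$unit_length)
    if (nrow(u) > 1) expect_equal(u$start[-1], u$end[-nrow(u)] + 1)
  }
})

test_that("contig tiling arithmetic, error-free substrings and determinism", {
  pair <- simulate_paralog_pair(16000, 0.015, seed = 2)
  al <- build_allele(pair, list())
  ct <- simulate_contigs(al, pair, 4000, 3000, error_rate = 0, seed = 5)
  # per unit: starts 1, 3001, 6001, 9001, 12001 plus terminal 12001 (dedup)
  expect_equal(sum(ct$unit == 1), 5)
  expect_equal(ct$start[ct$unit == 1], c(1, 3001, 6001, 9001, 12001))
  seqs <- realize_sequence(al, pair)
  for (i in seq_len(nrow(ct)))
    expect_identical(ct$sequence[i],
                     substr(seqs[ct$unit[i]], ct$start[i], ct$end[i]))
  expect_identical(simulate_contigs(al, pair, 500, 400, 0.01, seed = 9),
                   simulate_contigs(al, pair, 500, 400, 0.01, seed = 9))
  expect_error(simulate_contigs(al, pair, 0, 10), "contig_length")
})

test_that("normal diploid intensity is zero for any gamma without noise", {
  pair <- make_test_pair()
  probes <- design_probes(pair$unit_length)
  gt <- diploid_genotype("s1", build_allele(pair, list()),
                         build_allele(pair, list()))
  for (g in c(0, 0.3, 1)) {
    m <- simulate_acgh(list(gt, gt2 <- diploid_genotype("s2",
      build_allele(pair, list()), build_allele(pair, list()))),
      probes, acgh_params(gamma = g, noise_sd = 0,
                          cohort_offsets = c(cohort1 = 0)))
    expect_equal(unname(as.vector(m$values)), rep(0, 2 * nrow(probes)))
  }
})

test_that("intensity matches brute-force unit counting under the closed form", {
  pair <- make_test_pair()
  probes <- design_probes(pair$unit_length)
  g <- 0.3; fl <- 0.05
  hot <- default_hotspot_catalog(pair$unit_length)
  gts <- list(
    diploid_genotype("het_b", build_allele(pair, list(nahr_deletion(hot$start[2]))),
                     build_allele(pair, list())),
    diploid_genotype("hom_b", build_allele(pair, list(nahr_deletion(hot$start[2]))),
                     build_allele(pair, list(nahr_deletion(hot$start[2])))),
    diploid_genotype("dup", build_allele(pair, list(nahr_duplication(hot$start[1]))),
                     build_allele(pair, list())))
  m <- simulate_acgh(gts, probes,
                     acgh_params(gamma = g, noise_sd = 0,
                                 cohort_offsets = c(cohort1 = 0), floor = fl))
  for (i in seq_along(gts)) {
    units <- c(gts[[i]]$allele1$units, gts[[i]]$allele2$units)
    for (p in seq_len(nrow(probes))) {
      src <- oracle_unit_source_list(units, probes$unit_position[p])
      mm <- sum(src == probes$design_paralog[p])
      uu <- length(src) - mm
      expect_equal(length(src), mm + uu)  # conservation for any gamma
      expect_equal(m$values[i, p],
                   log2(max(mm + g * uu, fl) / (2 + 2 * g)))
    }
  }
})

test_that("gamma = 1 removes paralog discrimination", {
  pair <- make_test_pair()
  # paired probes at the same position, one designed to each paralog
  probes <- data.frame(probe_id = c("pa", "pb"),
                       unit_position = c(1000L, 1000L),
                       design_paralog = c("A", "B"), stringsAsFactors = FALSE)
  gts <- list(
    diploid_genotype("del", build_allele(pair, list(nahr_deletion(600))),
                     build_allele(pair, list())),
    diploid_genotype("dup", build_allele(pair, list(nahr_duplication(1500))),
                     build_allele(pair, list())))
  m <- simulate_acgh(gts, probes,
                     acgh_params(gamma = 1, noise_sd = 0,
                                 cohort_offsets = c(cohort1 = 0)))
  expect_equal(m$values[, "pa"], m$values[, "pb"])
})

test_that("aCGH simulation is deterministic and rejects empty input", {
  pair <- make_test_pair()
  probes <- design_probes(pair$unit_length)
  gt <- diploid_genotype("s1", build_allele(pair, list()),
                         build_allele(pair, list()))
  p <- acgh_params(seed = 11)
  expect_identical(simulate_acgh(list(gt), probes, p),
                   simulate_acgh(list(gt), probes, p))
  expect_error(simulate_acgh(list(), probes, p), "empty")
})
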