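toy_profile <- function(states, pos = NULL) {
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = length(states))
  structure(data.frame(pos = pos, state = states, stringsAsFactors = FALSE),
            class = c("psv_profile", "data.frame"))
}

test_that("interval lengths reproduce the published tract sizes", {
  expect_equal(interval_length(159806619, 159815757), 9139)
  expect_equal(round(interval_length(159806619, 159815757) / 1000, 1), 9.1)
  expect_equal(interval_length(159888397, 159890836), 2440)
  expect_equal(round(interval_length(159888397, 159890836) / 1000, 1), 2.4)
  expect_equal(interval_length(159824223, 159830623), 6401)
  expect_equal(round(interval_length(159824223, 159830623) / 1000, 1), 6.4)
  expect_equal(interval_length(5, 5), 1)
  expect_error(genomic_interval(10, 5), "start")
  # translation invariance
  expect_equal(interval_length(1000 + 159806619, 1000 + 159815757), 9139)
})

test_that("switch detection finds no switch in a pure profile and one in a clean chimera", {
  expect_equal(nrow(detect_switches(toy_profile(rep("A", 6)))), 0)
  sw <- detect_switches(toy_profile(c("A", "A", "A", "B", "B", "B")))
  expect_equal(nrow(sw), 1)
  expect_equal(sw$from_state, "A")
  expect_equal(sw$to_state, "B")
  expect_equal(sw$start, 300L)
  expect_equal(sw$end, 400L)
  expect_equal(sw$n_left, 3L)
  expect_equal(sw$n_right, 3L)
})

test_that("short discordant runs are masked and localization matches enumeration", {
  prof <- toy_profile(c("A", "A", "B", "A", "A", "B", "B", "B"))
  sw <- detect_switches(prof, min_run = 2)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "masked"), 300L)
  oracle <- oracle_switch_enum(prof, min_run = 2)
  expect_equal(oracle$n_masked, 1)
  expect_equal(sw$start, oracle$switches$start)
  expect_equal(sw$end, oracle$switches$end)
  # random small profiles: minimal masking count agrees with enumeration
  set.seed(5)
  for (i in 1:20) {
    states <- sample(c("A", "B"), 9, replace = TRUE, prob = c(0.6, 0.4))
    p <- toy_profile(states)
    got <- detect_switches(p, min_run = 2)
    oc <- oracle_switch_enum(p, min_run = 2)
    expect_equal(length(attr(got, "masked")), oc$n_masked)
  }
})

test_that("profiles without informative PSVs warn and return empty", {
  expect_warning(sw <- detect_switches(toy_profile(rep("other", 4))),
                 "no informative")
  expect_equal(nrow(sw), 0)
  expect_error(detect_switches(toy_profile(character(0))), "empty")
})

test_that("classify_events separates conversions from terminal breakpoints", {
  # interior tract returning to the original state -> conversion
  prof <- toy_profile(c("A", "A", "B", "B", "A", "A"))
  sw <- detect_switches(prof, min_run = 2)
  ev <- classify_events(sw, prof)
  expect_equal(nrow(ev$conversions), 1)
  expect_equal(nrow(ev$breakpoints), 0)
  expect_equal(ev$conversions$donor, "B")
  expect_equal(ev$conversions$acceptor, "A")
  expect_equal(ev$conversions$start, 300L)  # inclusive of inner PSVs
  expect_equal(ev$conversions$end, 400L)
  # single switch -> breakpoint
  prof2 <- toy_profile(c("A", "A", "A", "B", "B"))
  ev2 <- classify_events(detect_switches(prof2, 2), prof2)
  expect_equal(nrow(ev2$breakpoints), 1)
  expect_equal(nrow(ev2$conversions), 0)
  # empty switches -> both empty
  ev3 <- classify_events(detect_switches(toy_profile(rep("B", 4)), 2),
                         toy_profile(rep("B", 4)))
  expect_equal(nrow(ev3$breakpoints), 0)
  expect_equal(nrow(ev3$conversions), 0)
  # conversion followed by a real breakpoint
  prof4 <- toy_profile(c("A", "A", "B", "B", "A", "A", "B", "B"))
  ev4 <- classify_events(detect_switches(prof4, 2), prof4)
  expect_equal(nrow(ev4$conversions), 1)
  expect_equal(nrow(ev4$breakpoints), 1)
})

test_that("breakpoint intervals overlapping known conversion tracts are masked", {
  prof <- toy_profile(c("A", "A", "A", "B", "B", "B"))
  sw <- detect_switches(prof, 2)
  ev <- classify_events(sw, prof,
                        known_tracts = data.frame(start = 250, end = 450))
  expect_equal(ev$breakpoints$ambiguous_psvs[[1]], c(300L, 400L))
})

test_that("hotspot assignment maximizes overlap and matches brute force", {
  catalog <- data.frame(name = c("h1", "h2", "h3", "h4", "h5"),
                        start = c(100, 300, 600, 900, 1300),
                        end = c(250, 500, 800, 1100, 1500))
  bp <- data.frame(start = 120, end = 200, from_state = "A", to_state = "B",
                   hotspot_label = "unassigned", stringsAsFactors = FALSE)
  expect_equal(assign_hotspot(bp, catalog)$hotspot_label, "h1")
  bp$start <- 2000; bp$end <- 2100
  expect_equal(assign_hotspot(bp, catalog)$hotspot_label, "unassigned")
  set.seed(8)
  for (i in 1:20) {
    s <- sample(1:1600, 1); e <- s + sample(10:400, 1)
    bp$start <- s; bp$end <- e
    got <- assign_hotspot(bp, catalog)$hotspot_label
    ov <- pmax(0, pmin(e, catalog$end) - pmax(s, catalog$start) + 1)
    want <- if (all(ov == 0)) "unassigned" else
      catalog$name[which.max(ov)]
    expect_identical(got, want)
  }
})

test_that("called breakpoint intervals contain the generating breakpoint", {
  pair <- simulate_paralog_pair(4000, 0.015, seed = 21)
  set.seed(31)
  for (i in 1:100) {
    b <- sample(200:3800, 1)
    del <- build_allele(pair, list(nahr_deletion(b)))
    contig <- list(sequence = realize_sequence(del, pair)[1], start = 1L)
    prof <- psv_profile(contig, pair)
    sw <- detect_switches(prof, min_run = 1)
    ev <- classify_events(sw, prof, min_tract_psvs = 1)
    expect_equal(nrow(ev$breakpoints), 1)
    expect_lte(ev$breakpoints$start, b)
    expect_gte(ev$breakpoints$end, b + 1)
  }
})

test_that("adding PSVs inside the current interval never widens it", {
  pair <- simulate_paralog_pair(4000, 0.01, seed = 22)
  b <- 2000L
  del <- build_allele(pair, list(nahr_deletion(b)))
  contig <- list(sequence = realize_sequence(del, pair)[1], start = 1L)
  prof <- psv_profile(contig, pair)
  sw <- detect_switches(prof, min_run = 1)
  w0 <- sw$end - sw$start
  # densify: add a PSV strictly inside the called interval on each side of b
  extra <- data.frame(pos = c(sw$start + (b - sw$start) %/% 2,
                              sw$end - (sw$end - b - 1) %/% 2),
                      state = c("A", "B"), stringsAsFactors = FALSE)
  extra <- extra[extra$pos > sw$start & extra$pos < sw$end &
                   ((extra$state == "A" & extra$pos <= b) |
                      (extra$state == "B" & extra$pos > b)), ]
  prof2 <- rbind(as.data.frame(prof), extra)
  prof2 <- structure(prof2[order(prof2$pos), ],
                     class = c("psv_profile", "data.frame"))
  sw2 <- detect_switches(prof2, min_run = 1)
  expect_lte(sw2$end - sw2$start, w0)
  expect_lte(sw2$start - sw$start, sw2$end - sw$start)  # still bracketing b
  expect_lte(sw2$start, b); expect_gte(sw2$end, b + 1)
})

test_that("generated conversion tracts covering enough PSVs are recovered", {
  pair <- simulate_paralog_pair(4000, 0.015, seed = 23)
  set.seed(41)
  recovered <- 0; eligible <- 0
  for (i in 1:50) {
    s <- sample(300:3000, 1); e <- s + sample(200:800, 1)
    n_cov <- sum(pair$psv_catalog$pos >= s & pair$psv_catalog$pos <= e)
    if (n_cov < 2) next
    eligible <- eligible + 1
    conv <- build_allele(pair, list(gene_conversion(1, "B", s, e)))
    contig <- list(sequence = realize_sequence(conv, pair)[1], start = 1L)
    prof <- psv_profile(contig, pair)
    ev <- classify_events(detect_switches(prof, 2), prof)
    if (nrow(ev$conversions) == 1 &&
        ev$conversions$start >= s && ev$conversions$end <= e &&
        ev$conversions$donor == "B")
      recovered <- recovered + 1
  }
  expect_gt(eligible, 20)
  expect_equal(recovered, eligible)
})

test_that("allele comparison distinguishes shared from recurrent breakpoints", {
  prof <- toy_profile(c("A", "A", "B", "B"))
  a <- list(interval = c(200, 300), profile = prof)
  expect_equal(compare_alleles(a, a), "consistent_IBD")
  b <- list(interval = c(300, 400),
            profile = toy_profile(c("A", "A", "A", "B")))
  expect_equal(compare_alleles(a, b), "distinct")
  # simulation: same generating breakpoint vs different, 100 replicates
  pair <- simulate_paralog_pair(4000, 0.015, seed = 24)
  mk <- function(bp) {
    del <- build_allele(pair, list(nahr_deletion(bp)))
    contig <- list(sequence = realize_sequence(del, pair)[1], start = 1L)
    prof <- psv_profile(contig, pair)
    sw <- detect_switches(prof, min_run = 1)
    list(interval = c(sw$start[1], sw$end[1]), profile = prof)
  }
  set.seed(51)
  correct <- 0
  for (i in 1:100) {
    b1 <- sample(300:3700, 1)
    # a distinct breakpoint with at least one PSV between the two
    repeat {
      b2 <- sample(300:3700, 1)
      if (any(pair$psv_catalog$pos > min(b1, b2) &
                pair$psv_catalog$pos <= max(b1, b2))) break
    }
    same <- compare_alleles(mk(b1), mk(b1)) == "consistent_IBD"
    diff <- compare_alleles(mk(b1), mk(b2)) == "distinct"
    if (same && diff) correct <- correct + 1
  }
  expect_equal(correct, 100)
})

test_that("A and B derived units separate by pairwise differences", {
  pair <- simulate_paralog_pair(1500, 0.015, seed = 25)
  set.seed(61)
  mutate <- function(s, n) {
    b <- strsplit(s, "")[[1]]
    idx <- sample(length(b), n)
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }
  seqs <- c(vapply(1:10, function(i) mutate(pair$seq_a, 3), character(1)),
            vapply(1:10, function(i) mutate(pair$seq_b, 3), character(1)))
  labels <- rep(c("A", "B"), each = 10)
  res <- divergence_separation(seqs, labels)
  # matrix properties
  expect_true(isSymmetric(res$dist))
  expect_true(all(diag(res$dist) == 0))
  # statistic equals brute-force pairwise counting
  d <- res$dist
  within <- c(d[1:10, 1:10][upper.tri(d[1:10, 1:10])],
              d[11:20, 11:20][upper.tri(d[11:20, 11:20])])
  between <- as.vector(d[1:10, 11:20])
  expect_equal(res$statistic, mean(between) / mean(within))
  expect_gt(res$statistic, 1)
  expect_true(res$separable)
  # identical sequences -> not separable
  res0 <- divergence_separation(rep(pair$seq_a, 4), c("A", "A", "B", "B"))
  expect_false(res0$separable)
  expect_true(is.na(res0$statistic))
  expect_error(divergence_separation(c("ACGT", "ACG"), c("A", "B")),
               "equal length")
})
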