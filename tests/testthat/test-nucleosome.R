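test_that("mononucleosome filter keeps inclusive bounds and proper pairs only", {
  aln <- manual_aln(
    qname = c("a", "b", "c", "d", "e"),
    contig = "c1",
    pos = c(0L, 0L, 0L, 0L, 0L),
    cigar = "50M",
    flag = c(99L, 99L, 99L, 99L, 1L),      # e: paired but not proper
    tlen = c(147L, 99L, 100L, 175L, 150L)
  )
  fr <- filter_nucleosomal_pairs(aln)
  expect_setequal(fr$qname, c("a", "c", "d"))  # 99 dropped, 100/175 kept
  expect_equal(fr$end - fr$start, fr$outer)

  single <- manual_aln("x", "c1", 0L, "50M", flag = 0L)
  expect_error(filter_nucleosomal_pairs(single), "paired-end")
})

test_that("kept fraction of simulated fragments matches the truncated-normal mass", {
  toy <- toy_dataset()
  cfg <- toy$cfg
  ft <- toy$nuc$fragment_truth
  lo <- pnorm(cfg$frag_min, cfg$frag_mean, cfg$frag_sd)
  hi <- pnorm(cfg$frag_max, cfg$frag_mean, cfg$frag_sd)
  p_keep <- (pnorm(175.5, cfg$frag_mean, cfg$frag_sd) -
               pnorm(99.5, cfg$frag_mean, cfg$frag_sd)) / (hi - lo)
  kept <- mean(ft$outer >= 100 & ft$outer <= 175)
  n <- nrow(ft)
  expect_lt(abs(kept - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / n))
})

test_that("per-IES counting applies the minimum aligned-overlap rule", {
  ann <- tibble::tibble(ies_id = "i1", contig = "c1", start = 100L,
                        end = 130L, length = 30L)
  aln <- manual_aln(
    qname = c("ov8", "ov9", "inside", "del_span", "far"),
    contig = "c1",
    pos = c(62L, 61L, 105L, 70L, 500L),
    cigar = c("46M", "48M", "20M", "30M30D30M", "50M")
  )
  # ov8: [62,108) -> 8 aligned bp inside; ov9: [61,109) -> 9 bp
  # del_span: blocks [70,100) and [130,160): zero aligned bases inside
  cnt <- count_ies_reads(aln, ann, min_overlap = 9)
  expect_equal(cnt$count, 2L)  # ov9 + inside

  # fragment-interval counting (no cigar)
  fr <- tibble::tibble(qname = "f", contig = "c1", start = 95L, end = 110L,
                       outer = 15L)
  expect_equal(count_ies_reads(fr, ann)$count, 1L)
  expect_equal(count_ies_reads(fr, ann, min_overlap = 11)$count, 0L)
})

test_that("downsampling is pair-coherent, seeded, and binomial", {
  toy <- toy_dataset()
  aln <- toy$nuc$alignments
  expect_identical(downsample_reads(aln, 1, seed = 1), aln)
  s1 <- downsample_reads(aln, 0.5, seed = 7)
  s2 <- downsample_reads(aln, 0.5, seed = 7)
  expect_identical(s1, s2)
  # both mates kept or dropped together
  expect_true(all(table(s1$qname) == 2))
  n_pairs <- length(unique(aln$qname))
  kept <- length(unique(s1$qname))
  expect_lt(abs(kept - 0.5 * n_pairs), 3 * sqrt(n_pairs * 0.25))
  expect_error(downsample_reads(aln, 0, seed = 1), "fraction")
  expect_error(downsample_reads(aln, 1.2, seed = 1), "fraction")
})

test_that("normalized density follows r = (n/N)/(d/D) with scale invariance", {
  expect_equal(normalized_density(50, 1000, 25, 1000), 2)
  expect_equal(normalized_density(10, 100, 10, 100), 1)
  expect_true(is.na(normalized_density(5, 100, 0, 100)))
  expect_error(normalized_density(5, 0, 5, 100), "positive")
  k <- 13
  expect_equal(normalized_density(50 * k, 1000 * k, 25 * k, 1000 * k),
               normalized_density(50, 1000, 25, 1000))
})

test_that("two-sample KS equals a quadratic-time ECDF oracle and stats::ks.test", {
  brute_D <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(t) {
      abs(mean(x <= t) - mean(y <= t))
    }, numeric(1)))
  }
  set.seed(8)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:50, 1)), 2)
    y <- round(rnorm(sample(3:50, 1), mean = runif(1, -1, 1)), 2)
    got <- ks_two_sample(x, y)
    expect_equal(got$D, brute_D(x, y), tolerance = 1e-12)
    expect_equal(got$D,
                 suppressWarnings(stats::ks.test(x, y)$statistic[[1]]),
                 tolerance = 1e-12)
  }
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
  # asymptotic p agrees with ks.test exact=FALSE up to its finite-n variant
  x <- rnorm(100); y <- rnorm(100, 0.5)
  p_ours <- ks_two_sample(x, y)$p_value
  p_ref <- stats::ks.test(x, y, exact = FALSE)$p.value
  expect_lt(abs(p_ours - p_ref), 0.02)
})

test_that("density stratification groups by retention and length like a brute-force filter", {
  ann <- tibble::tibble(ies_id = paste0("i", 1:8), contig = "c",
                        start = 0L, end = 1L,
                        length = c(28L, 29L, 30L, 160L, 170L, 80L, 28L, 200L))
  irs <- c(0.1, 0.5, 0.05, 0.9, 0.1, 0.3, NA, 0.25)
  dens <- tibble::tibble(ies_id = ann$ies_id,
                         r = c(1, 2, 1.5, 3, 0.5, 2.5, 1, NA))
  st <- stratified_density_distributions(dens, ann, irs)
  v <- st$values
  expect_setequal(v$ies_id[v$stratum == "all" & v$group == "weak"],
                  c("i1", "i3", "i5"))  # NA irs / NA r excluded
  expect_setequal(v$ies_id[v$stratum == "peak1"], c("i1", "i2", "i3"))
  expect_setequal(v$ies_id[v$stratum == "long"], c("i4", "i5"))
  ks_all <- st$ks[st$ks$stratum == "all", ]
  expect_equal(ks_all$n_weak + ks_all$n_strong, 6L)  # i7 (NA irs), i8 (NA r) out

  # brute-force group check for one stratum
  brute <- ann$ies_id[!is.na(irs) & irs >= 0.2 & !is.na(dens$r)]
  expect_setequal(v$ies_id[v$stratum == "all" & v$group == "strong"], brute)
})

test_that("fragment-length histogram tallies outer distances in 1-bp bins", {
  toy <- toy_dataset()
  h <- fragment_length_histogram(toy$nuc$alignments)
  ft <- toy$nuc$fragment_truth
  brute <- table(factor(ft$outer[ft$outer <= 500], levels = 1:500))
  expect_equal(h$count, as.integer(brute))
  expect_equal(sum(h$count), sum(ft$outer <= 500))
  expect_equal(sum(h$density), 1)
  expect_error(fragment_length_histogram(manual_aln("x", "c", 0L, "50M")),
               "paired")
})

test_that("per-IES density recovers the simulated multiplier for long IESs", {
  # IESs must be a small fraction of the genome (as in the organism) for the
  # library-total normalization to anchor r = 1 at the background rate, and
  # long relative to the nucleosome footprint so that boundary-straddling
  # fragments do not dilute the per-IES contrast
  lam <- rep(c(1, 2, 3), each = 25)
  cfg <- sim_config(seed = 19, n_contigs = 1, contig_length = 1700000L,
                    n_ies = 75, ies_peaks = 2000L, ies_peak_weights = 1,
                    coverage = 5)
  gen <- generate_genome(cfg)
  truth <- simulate_truth(gen$annotations, retention_prob = 1, alt_prob = 0,
                          density_multiplier = lam, cryptic_rate = 0)
  nuc <- simulate_nucleosomal_fragments(gen$mac_plus_ies, gen$annotations,
                                        truth, cfg)
  dna <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, truth, cfg)
  dens <- density_records(gen$annotations, nuc$alignments, dna$alignments)
  med <- tapply(dens$r, lam, median)
  # residual edge dilution from fragments straddling IES boundaries keeps
  # the estimate a little below lambda; 15% covers it at this length
  for (l in c(1, 2, 3)) {
    expect_lt(abs(med[[as.character(l)]] - l) / l, 0.15)
  }
})
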