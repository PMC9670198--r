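test_that("gap extraction applies length and anchor filters per CIGAR op", {
  aln <- manual_aln(
    qname = c("r1", "r2", "r3", "r4"),
    contig = "c1",
    pos = c(0L, 0L, 0L, 0L),
    cigar = c("40M28D35M",     # one qualifying gap
              "5M28D70M",      # left anchor too short
              "30M26N30M10D5M",# N qualifies, trailing 10D fails min_gap
              "75M")           # no gap
  )
  gaps <- extract_gaps(aln, min_gap = 20, min_anchor = 10)
  expect_equal(nrow(gaps), 2)
  g1 <- gaps[gaps$qname == "r1", ]
  expect_equal(c(g1$gap_start, g1$gap_end), c(40L, 68L))
  expect_equal(c(g1$left_anchor, g1$right_anchor), c(40L, 35L))
  g3 <- gaps[gaps$qname == "r3", ]
  expect_equal(g3$gap_end - g3$gap_start, 26L)
  expect_equal(extract_gaps(manual_aln("r", "c", 0L, "50M")), gaps[0, ])
})

test_that("classification enforces the TA rule and interval geometry", {
  # contig with one annotated IES at [30, 58); planted TA sites around it
  set.seed(9)
  base <- paste(sample(c("C", "G"), 200, replace = TRUE), collapse = "")
  s <- base
  put <- function(s, p0) { substr(s, p0 + 1, p0 + 2) <- "TA"; s }
  for (p in c(30, 58, 22, 36, 48, 66, 100, 130)) s <- put(s, p)
  g <- genome_assembly(c(c1 = s), "MAC_PLUS_IES")
  ann <- tibble::tibble(ies_id = "i1", contig = "c1", start = 30L, end = 58L,
                        length = 28L)

  mk <- function(gs, ge) tibble::tibble(qname = "q", contig = "c1",
                                        gap_start = gs, gap_end = ge,
                                        left_anchor = 20L, right_anchor = 20L)
  cls <- function(gs, ge) classify_gaps(mk(gs, ge), ann, g)$events$class

  expect_equal(cls(30L, 58L), "CORRECT")
  expect_equal(cls(36L, 48L), "ALT_INTERNAL")
  expect_equal(cls(22L, 66L), "ALT_EXTERNAL")
  expect_equal(cls(22L, 48L), "ALT_OVERLAPPING")
  expect_equal(cls(100L, 130L), "CRYPTIC")

  # gaps without the two-TA structure are rejected with reasons
  no_ta <- classify_gaps(mk(31L, 58L), ann, g)
  expect_equal(nrow(no_ta$events), 0)
  expect_equal(no_ta$rejections$reason, "no-TA-left")
  no_ta_r <- classify_gaps(mk(30L, 59L), ann, g)
  expect_equal(no_ta_r$rejections$reason, "no-TA-right")
})

test_that("identical gaps aggregate with accumulated read support", {
  toy <- toy_dataset()
  ev <- call_excision_events(toy$dna$alignments, toy$gen$annotations,
                             toy$gen$mac_plus_ies)
  expect_true(all(ev$support == lengths(ev$read_ids)))
  expect_false(any(duplicated(
    paste(ev$contig, ev$gap_start, ev$gap_end, ev$class)
  )))
  # an interval classified CORRECT for one IES is never ALT for another
  cor_keys <- with(ev[ev$class == "CORRECT", ],
                   paste(contig, gap_start, gap_end))
  alt_keys <- with(ev[grepl("^ALT", ev$class), ],
                   paste(contig, gap_start, gap_end))
  expect_length(intersect(cor_keys, alt_keys), 0)

  agg <- aggregate_events(ev, toy$gen$annotations)
  expect_setequal(agg$per_ies$ies_id, toy$gen$annotations$ies_id)
  expect_true(all(agg$cryptic$class == "CRYPTIC"))

  # empty input
  ev0 <- call_excision_events(toy$dna$alignments[0, ], toy$gen$annotations,
                              toy$gen$mac_plus_ies)
  expect_equal(nrow(ev0), 0)
})

test_that("event calling matches the brute-force TA-pair oracle on random toy genomes", {
  for (seed in 1:6) {
    cfg <- sim_config(seed = seed, n_contigs = 1, contig_length = 4000,
                      n_ies = 8, coverage = 25, error_rate = 0)
    gen <- generate_genome(cfg)
    truth <- simulate_truth(gen$annotations, retention_prob = 0.4,
                            alt_prob = 0.3, cryptic_rate = 0.05)
    dna <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, truth, cfg)
    got <- call_excision_events(dna$alignments, gen$annotations,
                                gen$mac_plus_ies)
    seqs <- list(contig_1 = as.character(gen$mac_plus_ies$contigs[[1]]))
    exp <- oracle_events(dna$alignments, gen$annotations, seqs)
    got_df <- data.frame(contig = got$contig, gap_start = got$gap_start,
                         gap_end = got$gap_end, class = got$class,
                         matched_ies_id = got$matched_ies_id,
                         support = as.integer(got$support),
                         stringsAsFactors = FALSE)
    exp <- exp[, names(got_df)]
    rownames(got_df) <- rownames(exp) <- NULL
    expect_equal(got_df, exp, info = paste("seed", seed))
  }
})

test_that("noise-free simulated excision reads are recovered with their true class", {
  cfg <- sim_config(seed = 21, n_contigs = 1, contig_length = 9000,
                    n_ies = 18, coverage = 50, error_rate = 0)
  gen <- generate_genome(cfg)
  truth <- simulate_truth(gen$annotations, retention_prob = 0.3,
                          alt_prob = 0.2, cryptic_rate = 0.03)
  dna <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, truth, cfg)
  ev <- call_excision_events(dna$alignments, gen$annotations,
                             gen$mac_plus_ies)
  called <- tibble::tibble(
    qname = unlist(ev$read_ids),
    class = rep(ev$class, ev$support),
    gap_start = rep(ev$gap_start, ev$support),
    gap_end = rep(ev$gap_end, ev$support)
  )
  truth_gapped <- dna$read_truth[
    dna$read_truth$category %in% c("correct", "alternative", "cryptic"), ]
  j <- dplyr::inner_join(truth_gapped, called, by = "qname")
  # every truth gap with sufficient anchors appears among called events with
  # matching coordinates and a compatible class
  matched <- j[j$gap_start.x == j$gap_start.y & j$gap_end.x == j$gap_end.y, ]
  compat <- with(matched,
    (category == "correct" & class == "CORRECT") |
    (category == "alternative" & grepl("^ALT", class)) |
    (category == "cryptic" & class == "CRYPTIC"))
  expect_true(all(compat))
  # recall over truth reads whose gap has >= min_anchor aligned around it
  gaps <- extract_gaps(dna$alignments, min_gap = 20, min_anchor = 10)
  anchored <- dplyr::semi_join(truth_gapped, gaps,
                               by = c("qname", "gap_start", "gap_end"))
  expect_true(all(anchored$qname %in% called$qname))
})
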