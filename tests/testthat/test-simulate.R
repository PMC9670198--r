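test_that("genome generation is deterministic and structurally valid", {
  cfg <- sim_config(seed = 1, n_contigs = 2, contig_length = 9000,
                    n_ies = 20, coverage = 10)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  d1 <- withr::local_tempdir()
  write_genome_fasta(g1$mac_plus_ies, file.path(d1, "a.fa"))
  write_genome_fasta(g2$mac_plus_ies, file.path(d1, "b.fa"))
  write_ies_gff3(g1$annotations, file.path(d1, "a.gff3"))
  write_ies_gff3(g2$annotations, file.path(d1, "b.gff3"))
  expect_identical(readLines(file.path(d1, "a.fa")),
                   readLines(file.path(d1, "b.fa")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d1, "b.gff3")))

  # every IES TA-bounded; separated by >= read_length of MDS
  v <- validate_ta_boundaries(g1$mac_plus_ies, g1$annotations)
  expect_true(all(v$pass))
  gaps <- g1$annotations |>
    dplyr::group_by(contig) |>
    dplyr::summarise(min_sep = min(start - dplyr::lag(end), na.rm = TRUE))
  expect_true(all(gaps$min_sep >= cfg$read_length))

  # MAC length arithmetic
  expect_equal(
    sum(Biostrings::width(g1$mac$contigs)),
    sum(Biostrings::width(g1$mac_plus_ies$contigs)) - sum(g1$annotations$length)
  )

  # alternative TA sites exist within +/-20 bp of each canonical boundary
  for (i in seq_len(nrow(g1$annotations))) {
    a <- g1$annotations[i, ]
    lsites <- enumerate_ta_sites(g1$mac_plus_ies, a$contig,
                                 a$start - 20L, a$start + 22L)
    rsites <- enumerate_ta_sites(g1$mac_plus_ies, a$contig,
                                 a$end - 20L, a$end + 22L)
    expect_gt(length(setdiff(lsites, a$start)), 0)
    expect_gt(length(setdiff(rsites, a$end)), 0)
  }

  # infeasible placement errors out
  expect_error(
    generate_genome(sim_config(seed = 1, n_contigs = 1, contig_length = 500,
                               n_ies = 50)),
    "cannot place"
  )
})

test_that("retention endpoints control gap presence in simulated reads", {
  cfg <- sim_config(seed = 3, n_contigs = 1, contig_length = 8000,
                    n_ies = 15, coverage = 40, error_rate = 0)
  gen <- generate_genome(cfg)

  # full retention, no cryptic: no gapped reads at all
  t1 <- simulate_truth(gen$annotations, retention_prob = 1, alt_prob = 0,
                       cryptic_rate = 0)
  r1 <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, t1, cfg)
  expect_false(any(grepl("[DN]", r1$alignments$cigar)))

  # complete canonical excision: every gap matches an annotated interval
  t0 <- simulate_truth(gen$annotations, retention_prob = 0, alt_prob = 0,
                       cryptic_rate = 0)
  r0 <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, t0, cfg)
  gapped <- r0$alignments[grepl("D", r0$alignments$cigar), ]
  expect_gt(nrow(gapped), 0)
  expect_true(all(stringr_count <- lengths(regmatches(
    gapped$cigar, gregexpr("D", gapped$cigar))) == 1L))
  gaps <- extract_gaps(gapped, min_gap = 1, min_anchor = 1)
  key_ann <- paste(gen$annotations$start, gen$annotations$end)
  expect_true(all(paste(gaps$gap_start, gaps$gap_end) %in% key_ann))
})

test_that("retained fraction of IES-spanning reads follows the binomial", {
  cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 10000,
                    n_ies = 20, coverage = 100, error_rate = 0)
  gen <- generate_genome(cfg)
  tt <- simulate_truth(gen$annotations, retention_prob = 0.5, alt_prob = 0,
                       cryptic_rate = 0)
  rr <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, tt, cfg)
  cat_tab <- table(rr$read_truth$category)
  n_ret <- cat_tab[["retained"]]; n_exc <- cat_tab[["correct"]]
  n <- n_ret + n_exc
  p_hat <- n_ret / n
  # a fragment records "retained" when it overlaps the interval at all
  # (window length + read - 1 start positions) but "correct" only when the
  # excision junction is interior to the read (read - 1 positions); the
  # binomial oracle for the retained share follows from those windows
  rl <- cfg$read_length
  w_ret <- sum(0.5 * (gen$annotations$length + rl - 1))
  w_exc <- sum(0.5 * (rl - 1 + 0 * gen$annotations$length))
  p_exp <- w_ret / (w_ret + w_exc)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # category conservation: every read has exactly one category
  expect_setequal(unique(rr$read_truth$category),
                  intersect(c("retained", "correct", "non_ies", "alternative",
                              "cryptic"),
                            unique(rr$read_truth$category)))
  expect_equal(nrow(rr$read_truth), length(unique(rr$read_truth$qname)))
})

test_that("nucleosomal fragments: uniform lambda matches MDS rate, sizes truncated normal", {
  cfg <- sim_config(seed = 7, n_contigs = 1, contig_length = 15000,
                    n_ies = 20, coverage = 80)
  gen <- generate_genome(cfg)
  tt <- simulate_truth(gen$annotations, retention_prob = 0.5, alt_prob = 0,
                       density_multiplier = 1, cryptic_rate = 0)
  nuc <- simulate_nucleosomal_fragments(gen$mac_plus_ies, gen$annotations,
                                        tt, cfg)
  ft <- nuc$fragment_truth
  ies_bp <- sum(gen$annotations$length)
  mds_bp <- sum(Biostrings::width(gen$mac_plus_ies$contigs)) - ies_bp
  n_ies_mid <- sum(!is.na(ft$ies_id))
  n_mds_mid <- sum(is.na(ft$ies_id))
  rate_ies <- n_ies_mid / ies_bp
  rate_mds <- n_mds_mid / mds_bp
  # Poisson comparison of per-bp midpoint rates
  se <- sqrt(n_ies_mid) / ies_bp + sqrt(n_mds_mid) / mds_bp
  expect_lt(abs(rate_ies - rate_mds), 3 * se)

  # outer sizes respect the truncation bounds
  expect_true(all(ft$outer >= cfg$frag_min & ft$outer <= cfg$frag_max))

  # proper-pair structure: two records per fragment, opposite tlen signs
  expect_equal(nrow(nuc$alignments) %% 2, 0)
  expect_true(all(bitwAnd(nuc$alignments$flag, 2L) > 0))

  # zero fragments -> header-only SAM
  empty <- simulate_nucleosomal_fragments(gen$mac_plus_ies, gen$annotations,
                                          tt, cfg, n_fragments = 0)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(empty$alignments, sam, gen$mac_plus_ies)
  expect_true(all(grepl("^@", readLines(sam))))
})

test_that("SAM round trip preserves reads through Rsamtools parsing", {
  toy <- toy_dataset()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(toy$dna$alignments, sam, toy$gen$mac_plus_ies)
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), nrow(toy$dna$alignments))
  expect_setequal(aln$qname, toy$dna$alignments$qname)
  ref <- toy$dna$alignments[match(paste(aln$qname, aln$mate),
                                  paste(toy$dna$alignments$qname,
                                        toy$dna$alignments$mate)), ]
  expect_equal(aln$pos, ref$pos)
  expect_equal(aln$cigar, ref$cigar)
})
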