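# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small genome + mixed-retention dataset used across several test files.
toy_dataset <- function() {
  cached("toy", function() {
    cfg <- sim_config(seed = 42, n_contigs = 1, contig_length = 12000,
                      n_ies = 30, coverage = 60)
    gen <- generate_genome(cfg)
    truth <- simulate_truth(gen$annotations, retention_prob = 0.5,
                            alt_prob = 0.1, density_multiplier = 1,
                            cryptic_rate = 0.02)
    dna <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, truth, cfg)
    nuc <- simulate_nucleosomal_fragments(gen$mac_plus_ies, gen$annotations,
                                          truth, cfg)
    list(cfg = cfg, gen = gen, truth = truth, dna = dna, nuc = nuc)
  })
}

# Brute-force, implementation-independent event-calling oracle: parses CIGAR
# strings character by character, applies the gap/anchor filters, checks the
# TA rule by direct substring comparison, and matches gaps to IESs with the
# documented tie-break, all in base R.
oracle_events <- function(aln, annotations, contig_seqs, min_gap = 20,
                          min_anchor = 10) {
  rows <- list()
  for (i in seq_len(nrow(aln))) {
    cig <- aln$cigar[i]
    m <- gregexpr("[0-9]+[MIDNSHP=X]", cig)[[1]]
    toks <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    ref_pos <- aln$pos[i]
    aligned_before <- 0L
    total_aligned <- sum(lens[ops %in% c("M", "=", "X")])
    for (j in seq_along(ops)) {
      w <- lens[j]
      if (ops[j] %in% c("D", "N")) {
        la <- aligned_before
        ra <- total_aligned - aligned_before
        if (w >= min_gap && la >= min_anchor && ra >= min_anchor) {
          gs <- ref_pos; ge <- ref_pos + w
          s <- contig_seqs[[aln$contig[i]]]
          if (substr(s, gs + 1, gs + 2) == "TA" &&
              ge + 2 <= nchar(s) && substr(s, ge + 1, ge + 2) == "TA") {
            rows[[length(rows) + 1L]] <- data.frame(
              qname = aln$qname[i], contig = aln$contig[i],
              gap_start = gs, gap_end = ge, stringsAsFactors = FALSE
            )
          }
        }
      }
      if (ops[j] %in% c("M", "=", "X")) {
        aligned_before <- aligned_before + w
        ref_pos <- ref_pos + w
      } else if (ops[j] %in% c("D", "N")) {
        ref_pos <- ref_pos + w
      }
      # I, S, H, P consume no reference
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), gap_start = integer(0),
                      gap_end = integer(0), class = character(0),
                      matched_ies_id = character(0), support = integer(0)))
  }
  g <- do.call(rbind, rows)
  # classify each gap against every IES by exhaustive scan
  cls <- character(nrow(g)); match_id <- rep(NA_character_, nrow(g))
  for (k in seq_len(nrow(g))) {
    ann <- annotations[annotations$contig == g$contig[k], ]
    best <- NULL; best_key <- NULL
    for (j in seq_len(nrow(ann))) {
      ov <- min(g$gap_end[k], ann$end[j]) - max(g$gap_start[k], ann$start[j])
      if (ov <= 0) next
      gw <- g$gap_end[k] - g$gap_start[k]
      iw <- ann$end[j] - ann$start[j]
      recip <- min(ov / gw, ov / iw)
      key <- c(-recip, abs(gw - iw), ann$start[j])
      if (is.null(best) ||
          isTRUE(key[1] < best_key[1] ||
                 (key[1] == best_key[1] && key[2] < best_key[2]) ||
                 (key[1] == best_key[1] && key[2] == best_key[2] &&
                  key[3] < best_key[3]))) {
        best <- ann[j, ]; best_key <- key
      }
    }
    if (is.null(best)) {
      cls[k] <- "CRYPTIC"
    } else if (g$gap_start[k] == best$start && g$gap_end[k] == best$end) {
      cls[k] <- "CORRECT"; match_id[k] <- best$ies_id
    } else if (g$gap_start[k] >= best$start && g$gap_end[k] <= best$end) {
      cls[k] <- "ALT_INTERNAL"; match_id[k] <- best$ies_id
    } else if (g$gap_start[k] <= best$start && g$gap_end[k] >= best$end) {
      cls[k] <- "ALT_EXTERNAL"; match_id[k] <- best$ies_id
    } else {
      cls[k] <- "ALT_OVERLAPPING"; match_id[k] <- best$ies_id
    }
  }
  g$class <- cls
  g$matched_ies_id <- match_id
  agg <- aggregate(qname ~ contig + gap_start + gap_end + class +
                     matched_ies_id, data = transform(g,
                     matched_ies_id = ifelse(is.na(matched_ies_id), "",
                                             matched_ies_id)),
                   FUN = length)
  names(agg)[names(agg) == "qname"] <- "support"
  agg$matched_ies_id[agg$matched_ies_id == ""] <- NA_character_
  agg[order(agg$contig, agg$gap_start, agg$gap_end), ]
}

# Build an alignment tibble directly (for unit tests that need exact CIGARs).
manual_aln <- function(qname, contig, pos, cigar, flag = 0L, tlen = 0L,
                       mapq = 60L) {
  n <- max(length(qname), length(pos), length(cigar))
  tibble::tibble(
    qname = rep_len(qname, n), flag = rep_len(as.integer(flag), n),
    contig = rep_len(contig, n), pos = rep_len(as.integer(pos), n),
    cigar = rep_len(cigar, n), mapq = rep_len(as.integer(mapq), n),
    tlen = rep_len(as.integer(tlen), n),
    paired = bitwAnd(rep_len(as.integer(flag), n), 1L) > 0L,
    proper_pair = bitwAnd(rep_len(as.integer(flag), n), 2L) > 0L,
    mate = dplyr::if_else(bitwAnd(rep_len(as.integer(flag), n), 128L) > 0L,
                          2L, 1L)
  )
}
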