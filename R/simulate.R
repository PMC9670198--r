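#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genome, read and nucleosomal
#' fragment generators. Defaults emulate the organism's germline genome
#' structure at toy scale: AT-rich sequence (~72% AT), TA-bounded IESs with
#' a periodic length distribution whose second ("forbidden", ~35 bp) peak is
#' strongly suppressed, IESs separated by at least a read length of
#' MAC-destined sequence, and mononucleosome-sized fragments around 147 bp.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig (bp) in the MAC+IES assembly.
#' @param n_ies total number of IESs across contigs.
#' @param ies_peaks,ies_peak_weights centers (bp) and weights of the periodic
#'   IES length mixture. Lengths are drawn as `center + U{-2..2}`.
#' @param read_length read length (bp).
#' @param coverage mean sequencing depth over the MAC+IES assembly.
#' @param paired emit paired-end DNA-seq reads (nucleosomal fragments are
#'   always paired).
#' @param insert_mean,insert_sd paired-end outer-distance model for DNA-seq.
#' @param error_rate per-base uniform substitution error rate.
#' @param at_content genomic AT fraction.
#' @param frag_mean,frag_sd,frag_min,frag_max truncated-normal outer-size
#'   model for nucleosomal fragments.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_contigs = 2L,
                       contig_length = 20000L,
                       n_ies = 100L,
                       ies_peaks = c(28L, 35L, 45L, 55L),
                       ies_peak_weights = c(0.55, 0.02, 0.25, 0.18),
                       read_length = 100L,
                       coverage = 100,
                       paired = FALSE,
                       insert_mean = 300,
                       insert_sd = 30,
                       error_rate = 0.001,
                       at_content = 0.72,
                       frag_mean = 147,
                       frag_sd = 15,
                       frag_min = 80,
                       frag_max = 250) {
  if (missing(seed)) stop("sim_config(): seed is mandatory")
  stopifnot(
    n_contigs >= 1, contig_length > 0, n_ies >= 0,
    length(ies_peaks) == length(ies_peak_weights),
    all(ies_peak_weights >= 0), sum(ies_peak_weights) > 0,
    read_length >= 20, coverage > 0, error_rate >= 0, error_rate < 1,
    at_content > 0, at_content < 1,
    frag_min > 0, frag_max > frag_min
  )
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_ies = as.integer(n_ies),
    ies_peaks = as.integer(ies_peaks),
    ies_peak_weights = ies_peak_weights / sum(ies_peak_weights),
    read_length = as.integer(read_length), coverage = coverage,
    paired = isTRUE(paired), insert_mean = insert_mean,
    insert_sd = insert_sd, error_rate = error_rate,
    at_content = at_content, frag_mean = frag_mean, frag_sd = frag_sd,
    frag_min = frag_min, frag_max = frag_max
  ), class = "sim_config")
}

random_dna_chars <- function(n, at_content) {
  p <- c(A = at_content / 2, T = at_content / 2,
         C = (1 - at_content) / 2, G = (1 - at_content) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

draw_ies_lengths <- function(n, cfg) {
  peak <- sample(seq_along(cfg$ies_peaks), n, replace = TRUE,
                 prob = cfg$ies_peak_weights)
  pmax(20L, cfg$ies_peaks[peak] + sample(-2:2, n, replace = TRUE))
}


#' Generate a synthetic MAC+IES genome with TA-bounded IESs
#'
#' Builds each contig as alternating MAC-destined segments and IES
#' sequences. Every IES begins with `TA` and is immediately followed by the
#' retained downstream `TA` copy; additional TA sites are planted within
#' 20 bp of each canonical boundary (one internal and one external per side)
#' so that alternative excision is always possible. IESs are separated by at
#' least `read_length` of MAC-destined sequence. The MAC assembly is the
#' MAC+IES assembly with every IES interval deleted.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `mac_plus_ies`, `mac` (both
#'   `genome_assembly`), and `annotations` (IES tibble).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_genome_impl(cfg))
}

generate_genome_impl <- function(cfg) {
  per_contig <- diff(round(seq(0, cfg$n_ies, length.out = cfg$n_contigs + 1)))
  lens_all <- draw_ies_lengths(cfg$n_ies, cfg)
  need <- sum(lens_all) + (cfg$n_ies + cfg$n_contigs) * (cfg$read_length + 20)
  if (need > cfg$n_contigs * cfg$contig_length) {
    stop("cannot place ", cfg$n_ies, " IESs in ",
         cfg$n_contigs * cfg$contig_length, " bp; increase contig_length")
  }
  contigs <- character(cfg$n_contigs)
  names(contigs) <- sprintf("contig_%d", seq_len(cfg$n_contigs))
  ann <- list()
  k <- 0L
  for (ci in seq_len(cfg$n_contigs)) {
    n_i <- per_contig[ci]
    lens <- lens_all[seq_len(n_i) + k]
    # MDS segment lengths: minimum read_length + 20, remainder spread evenly
    min_mds <- cfg$read_length + 20L
    slack <- cfg$contig_length - sum(lens) - (n_i + 1L) * min_mds
    if (slack < 0) stop("contig ", ci, " too short for its IES load")
    extra <- if (n_i + 1L > 0) {
      as.integer(diff(round(seq(0, slack, length.out = n_i + 2L))))
    } else integer(0)
    mds_len <- min_mds + extra
    chars <- random_dna_chars(cfg$contig_length, cfg$at_content)
    pos <- 0L
    starts <- ends <- integer(n_i)
    for (j in seq_len(n_i)) {
      pos <- pos + mds_len[j]           # IES starts after the MDS segment
      starts[j] <- pos
      ends[j] <- pos + lens[j]
      # canonical boundary TAs, plus guaranteed alternative TA sites close
      # to each boundary (erroneous excision uses the next closest
      # available TA sites); positions are 0-based
      ta_at <- c(starts[j], ends[j],              # canonical / retained copy
                 starts[j] - 4L, starts[j] + 3L,  # left: external, internal
                 ends[j] - 3L, ends[j] + 4L)      # right: internal, external
      chars[ta_at + 1L] <- "T"
      chars[ta_at + 2L] <- "A"
      pos <- ends[j]
    }
    contigs[ci] <- paste(chars, collapse = "")
    if (n_i > 0) {
      ann[[ci]] <- tibble::tibble(
        ies_id = sprintf("IES.%s.%d", names(contigs)[ci], seq_len(n_i)),
        contig = names(contigs)[ci],
        start = starts, end = ends, length = lens
      )
    }
    k <- k + n_i
  }
  annotations <- dplyr::bind_rows(ann)
  mac_plus_ies <- genome_assembly(contigs, "MAC_PLUS_IES")
  mac_contigs <- vapply(names(contigs), function(ct) {
    d <- annotations[annotations$contig == ct, ]
    s <- contigs[[ct]]
    if (nrow(d) == 0) return(s)
    keep_start <- c(0L, d$end)
    keep_end <- c(d$start, nchar(s))
    paste(substring(s, keep_start + 1L, keep_end), collapse = "")
  }, character(1))
  list(
    mac_plus_ies = mac_plus_ies,
    mac = genome_assembly(mac_contigs, "MAC"),
    annotations = annotations
  )
}

#' Ground-truth excision parameters for a synthetic genome
#'
#' @param annotations IES annotation tibble.
#' @param retention_prob per-IES probability that a fragment overlapping the
#'   IES keeps it (scalar or vector); recovered downstream as the IRS.
#' @param alt_prob per-IES probability that an excision event uses an
#'   alternative TA pair (scalar or vector).
#' @param density_multiplier per-IES relative nucleosomal fragment rate.
#' @param cryptic_rate expected cryptic excisions per mapped read per kb of
#'   MAC-destined sequence spanned.
#' @return a `truth_table` tibble with attribute `cryptic_rate`.
#' @export
simulate_truth <- function(annotations,
                           retention_prob = 0.5,
                           alt_prob = 0.1,
                           density_multiplier = 1,
                           cryptic_rate = 0.02) {
  n <- nrow(annotations)
  tt <- tibble::tibble(
    ies_id = annotations$ies_id,
    retention_prob = rep_len(retention_prob, n),
    alt_prob = rep_len(alt_prob, n),
    density_multiplier = rep_len(density_multiplier, n)
  )
  stopifnot(all(tt$retention_prob >= 0 & tt$retention_prob <= 1),
            all(tt$alt_prob >= 0 & tt$alt_prob <= 1),
            all(tt$density_multiplier > 0), cryptic_rate >= 0)
  attr(tt, "cryptic_rate") <- cryptic_rate
  class(tt) <- c("truth_table", class(tt))
  tt
}

# Precompute, per IES, the candidate alternative TA boundary pairs with
# geometric-by-rank weights (nearer offsets favored).
alt_boundary_candidates <- function(genome, annotations, max_offset = 20L,
                                    min_gap = 20L) {
  lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    clen <- contig_lengths(genome)[[a$contig]]
    lw <- enumerate_ta_sites(genome, a$contig,
                             max(0L, a$start - max_offset),
                             min(clen, a$start + max_offset + 2L))
    rw <- enumerate_ta_sites(genome, a$contig,
                             max(0L, a$end - max_offset),
                             min(clen, a$end + max_offset + 2L))
    wt <- function(sites, canon) 0.5 ^ rank(abs(sites - canon),
                                            ties.method = "first")
    list(left = lw, right = rw,
         wl = wt(lw, a$start), wr = wt(rw, a$end))
  })
}

draw_alt_pair <- function(cand, canon_start, canon_end, min_gap = 20L) {
  for (try in 1:20) {
    p <- sample(cand$left, 1L, prob = cand$wl)
    q <- sample(cand$right, 1L, prob = cand$wr)
    if (q - p >= min_gap && !(p == canon_start && q == canon_end)) {
      return(c(p, q))
    }
  }
  NULL  # caller falls back to canonical
}

#' Simulate anlagen DNA-seq reads with known excision truth
#'
#' Fragments are drawn uniformly over the MAC+IES assembly. A fragment
#' overlapping IES `i` retains it with probability `retention_prob[i]`;
#' otherwise the IES is excised — at the canonical boundaries with
#' probability `1 - alt_prob[i]`, else at an alternative TA pair drawn from
#' sites within 20 bp of the canonical boundaries with geometric-by-rank
#' weights. Independent cryptic excisions between MAC-destined TA pairs are
#' added at `cryptic_rate` per read per kb spanned. Excision gaps appear in
#' the alignments as CIGAR deletions; reads are emitted pre-aligned (true
#' coordinates) so the pipeline is testable without an external mapper.
#'
#' @param genome list from [generate_genome()] (or a MAC+IES
#'   `genome_assembly`), with `annotations` supplied separately if so.
#' @param annotations IES annotation tibble.
#' @param truth a [simulate_truth()] table.
#' @param cfg a [sim_config()].
#' @param n_reads number of reads (or fragments when `cfg$paired`);
#'   default from `cfg$coverage`.
#' @return list with `alignments` (tibble, one row per read: `qname`,
#'   `flag`, `contig`, `pos` 0-based, `cigar`, `seq`, `mapq`, `tlen`,
#'   `mate`), and `read_truth` (tibble: `qname`, `category`, `ies_id`,
#'   `gap_start`, `gap_end`).
#' @export
simulate_dna_reads <- function(genome, annotations, truth, cfg,
                               n_reads = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(genome) && !inherits(genome, "genome_assembly")) {
    genome <- genome$mac_plus_ies
  }
  stopifnot(setequal(truth$ies_id, annotations$ies_id))
  withr::with_seed(
    cfg$seed + 1L,
    simulate_dna_reads_impl(genome, annotations, truth, cfg, n_reads)
  )
}

simulate_dna_reads_impl <- function(genome, annotations, truth, cfg,
                                    n_reads) {
  clen <- contig_lengths(genome)
  glen <- sum(clen)
  if (is.null(n_reads)) {
    n_reads <- ceiling(cfg$coverage * glen / cfg$read_length /
                         (if (cfg$paired) 2 else 1))
  }
  ann <- dplyr::arrange(
    dplyr::left_join(annotations, truth, by = "ies_id"),
    .data$contig, .data$start
  )
  cand <- alt_boundary_candidates(genome, ann)
  ann_by_contig <- split(seq_len(nrow(ann)), ann$contig)
  seqs <- lapply(stats::setNames(names(clen), names(clen)),
                 function(ct) contig_string(genome, ct))
  # MDS TA sites per contig (for cryptic gaps), excluding IES neighborhoods
  mds_ta <- lapply(stats::setNames(names(clen), names(clen)), function(ct) {
    sites <- enumerate_ta_sites(genome, ct)
    d <- ann[ann$contig == ct, ]
    if (nrow(d)) {
      bad <- rep(FALSE, length(sites))
      for (j in seq_len(nrow(d))) {
        bad <- bad | (sites >= d$start[j] - 25L & sites < d$end[j] + 25L)
      }
      sites <- sites[!bad]
    }
    sites
  })

  kappa <- attr(truth, "cryptic_rate") %||% 0
  contig_pick <- sample(names(clen), n_reads, replace = TRUE,
                        prob = clen / glen)
  # plain-vector views of the annotation, indexed per contig, for speed
  annv <- list(start = ann$start, end = ann$end, id = ann$ies_id,
               rho = ann$retention_prob, alpha = ann$alt_prob)
  per_read <- if (cfg$paired) 2L else 1L
  cap <- n_reads * per_read
  o_qname <- o_contig <- o_cigar <- o_seq <- character(cap)
  o_flag <- o_pos <- o_tlen <- o_mate <- integer(cap)
  t_qname <- t_cat <- t_ies <- character(n_reads)
  t_gs <- t_ge <- integer(n_reads)
  k_out <- 0L; k_tr <- 0L
  for (r in seq_len(n_reads)) {
    ct <- contig_pick[r]
    need <- if (cfg$paired) {
      max(2L * cfg$read_length,
          round(stats::rnorm(1, cfg$insert_mean, cfg$insert_sd)))
    } else cfg$read_length
    L <- sample.int(clen[[ct]], 1L) - 1L
    walk <- walk_molecule(L, need, annv, ann_by_contig[[ct]], cand,
                          clen[[ct]], mds_ta[[ct]], kappa)
    if (is.null(walk)) next
    qname <- sprintf("read_%06d", r)
    if (cfg$paired) {
      m1 <- mate_from_segments(walk$segments, 0L, cfg$read_length)
      m2 <- mate_from_segments(walk$segments,
                               walk$mol_len - cfg$read_length,
                               cfg$read_length)
      if (is.null(m1) || is.null(m2)) next
      outer <- m2$ref_end - m1$ref_start
      i <- k_out + 1:2
      o_qname[i] <- qname; o_contig[i] <- ct
      o_flag[i] <- c(99L, 147L)
      o_pos[i] <- c(m1$ref_start, m2$ref_start)
      o_cigar[i] <- c(m1$cigar, m2$cigar)
      o_tlen[i] <- c(outer, -outer); o_mate[i] <- c(1L, 2L)
      o_seq[i] <- c(read_sequence(seqs[[ct]], m1, cfg$error_rate),
                    read_sequence(seqs[[ct]], m2, cfg$error_rate))
      k_out <- k_out + 2L
    } else {
      m1 <- mate_from_segments(walk$segments, 0L, cfg$read_length)
      if (is.null(m1)) next
      i <- k_out + 1L
      o_qname[i] <- qname; o_contig[i] <- ct
      o_flag[i] <- 0L; o_pos[i] <- m1$ref_start
      o_cigar[i] <- m1$cigar; o_tlen[i] <- 0L; o_mate[i] <- 1L
      o_seq[i] <- read_sequence(seqs[[ct]], m1, cfg$error_rate)
      k_out <- k_out + 1L
    }
    k_tr <- k_tr + 1L
    t_qname[k_tr] <- qname; t_cat[k_tr] <- walk$category
    t_ies[k_tr] <- walk$ies_id
    t_gs[k_tr] <- walk$gap_start; t_ge[k_tr] <- walk$gap_end
  }
  sel <- seq_len(k_out)
  aln <- tibble::tibble(
    qname = o_qname[sel], flag = o_flag[sel], contig = o_contig[sel],
    pos = o_pos[sel], cigar = o_cigar[sel], mapq = 60L,
    tlen = o_tlen[sel],
    paired = bitwAnd(o_flag[sel], 1L) > 0L,
    proper_pair = bitwAnd(o_flag[sel], 2L) > 0L,
    mate = o_mate[sel], seq = o_seq[sel]
  )
  aln <- dplyr::arrange(aln, .data$contig, .data$pos, .data$qname)
  selt <- seq_len(k_tr)
  list(alignments = aln,
       read_truth = tibble::tibble(qname = t_qname[selt],
                                   category = t_cat[selt],
                                   ies_id = t_ies[selt],
                                   gap_start = t_gs[selt],
                                   gap_end = t_ge[selt]))
}

# Walk the reference from position L, consuming `need` molecule bases.
# IESs are decided (retained vs excised, canonical vs alternative) in order
# of encounter; excised intervals appear as gap segments consuming no
# molecule bases. Returns aligned/gap segments in reference coordinates plus
# the truth category of the resulting fragment.
walk_molecule <- function(L, need, ann, ann_idx, cand, clen, mds_ta,
                          kappa) {
  gaps <- list()
  retained_ids <- character(0)
  gap_ids <- character(0)
  gap_classes <- character(0)

  decide <- function(i) {
    if (stats::runif(1) < ann$rho[i]) {
      return(NULL)  # retained: no gap
    }
    if (stats::runif(1) < ann$alpha[i]) {
      pq <- draw_alt_pair(cand[[i]], ann$start[i], ann$end[i])
      if (!is.null(pq)) {
        return(list(gs = pq[1], ge = pq[2], class = "alternative"))
      }
    }
    list(gs = ann$start[i], ge = ann$end[i], class = "correct")
  }

  segs <- list()  # each: c(type, ref_start, ref_end); type 1=M, 2=D
  pos <- L
  consumed <- 0L
  # candidate IESs in encounter order: gap starts can precede the annotated
  # start by up to 20 bp (external alternative boundaries)
  queue <- if (length(ann_idx)) ann_idx[ann$end[ann_idx] > L - 25L] else integer(0)
  for (j in queue) {
    if (consumed >= need || pos >= clen) break
    # unreachable: even the earliest possible gap start (20 bp before the
    # annotated start) lies beyond the remaining molecule span
    if (ann$start[j] - 25L >= pos + (need - consumed)) break
    d <- decide(j)
    if (is.null(d)) {
      # retained: record if the fragment can still span into the interval
      if (pos < ann$end[j] && pos + (need - consumed) > ann$start[j]) {
        retained_ids <- c(retained_ids, ann$id[j])
      }
      next
    }
    if (d$ge <= pos) next             # gap entirely behind the fragment
    if (d$gs <= pos) {                # fragment starts inside the gap
      pos <- d$ge
      next
    }
    take <- min(d$gs, pos + (need - consumed)) - pos
    if (take > 0) {
      segs[[length(segs) + 1L]] <- c(1L, pos, pos + take)
      consumed <- consumed + take
      pos <- pos + take
    }
    if (consumed >= need) break
    if (pos == d$gs) {
      segs[[length(segs) + 1L]] <- c(2L, d$gs, d$ge)
      gaps[[length(gaps) + 1L]] <- c(d$gs, d$ge)
      gap_ids <- c(gap_ids, ann$id[j])
      gap_classes <- c(gap_classes, d$class)
      pos <- d$ge
    }
  }
  if (consumed < need && pos < clen) {
    take <- min(clen, pos + (need - consumed)) - pos
    if (take > 0) {
      segs[[length(segs) + 1L]] <- c(1L, pos, pos + take)
      consumed <- consumed + take
      pos <- pos + take
    }
  }
  if (consumed < need) return(NULL)  # ran off the contig; drop fragment

  # merge adjacent aligned segments
  segs <- do.call(rbind, segs)
  segs <- merge_segments(segs)

  # cryptic excision: with prob kappa * span_kb, cut between a nearby MDS
  # TA pair inside an aligned segment
  category <- NA_character_
  cryptic <- NULL
  if (kappa > 0) {
    span_kb <- (pos - L) / 1000
    if (stats::runif(1) < kappa * span_kb) {
      cr <- place_cryptic(segs, mds_ta)
      if (!is.null(cr)) {
        segs <- cr$segs
        cryptic <- cr$gap
      }
    }
  }

  if (!is.null(cryptic)) {
    category <- "cryptic"
    ies_id <- NA_character_
    gs <- cryptic[1]; ge <- cryptic[2]
  } else if (length(gap_classes) && any(gap_classes == "alternative")) {
    j <- which(gap_classes == "alternative")[1]
    category <- "alternative"; ies_id <- gap_ids[j]
    gs <- gaps[[j]][1]; ge <- gaps[[j]][2]
  } else if (length(gap_classes)) {
    category <- "correct"; ies_id <- gap_ids[1]
    gs <- gaps[[1]][1]; ge <- gaps[[1]][2]
  } else if (length(retained_ids)) {
    category <- "retained"; ies_id <- retained_ids[1]
    gs <- NA_integer_; ge <- NA_integer_
  } else {
    category <- "non_ies"; ies_id <- NA_character_
    gs <- NA_integer_; ge <- NA_integer_
  }
  list(segments = segs, mol_len = sum(segs[segs[, 1] == 1L, 3] -
                                        segs[segs[, 1] == 1L, 2]),
       category = category, ies_id = ies_id,
       gap_start = gs, gap_end = ge)
}

merge_segments <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  out <- segs[1, , drop = FALSE]
  for (i in 2:nrow(segs)) {
    last <- nrow(out)
    if (segs[i, 1] == 1L && out[last, 1] == 1L &&
        segs[i, 2] == out[last, 3]) {
      out[last, 3] <- segs[i, 3]
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  out
}

place_cryptic <- function(segs, mds_ta, min_gap = 20L, max_gap = 60L) {
  m <- segs[segs[, 1] == 1L, , drop = FALSE]
  for (i in sample(nrow(m))) {
    sites <- mds_ta[mds_ta >= m[i, 2] + 10L & mds_ta <= m[i, 3] - 12L]
    if (length(sites) < 2) next
    p <- sites[sample.int(length(sites), 1L)]
    qs <- sites[sites - p >= min_gap & sites - p <= max_gap &
                  sites <= m[i, 3] - 12L]
    if (!length(qs)) next
    q <- qs[sample.int(length(qs), 1L)]
    # rebuild: split the aligned segment around [p, q)
    pieces <- list()
    for (j in seq_len(nrow(segs))) {
      s <- segs[j, ]
      if (s[1] == 1L && s[2] <= p && q <= s[3]) {
        if (p > s[2]) pieces[[length(pieces) + 1L]] <- c(1L, s[2], p)
        pieces[[length(pieces) + 1L]] <- c(2L, p, q)
        if (q < s[3]) pieces[[length(pieces) + 1L]] <- c(1L, q, s[3])
      } else {
        pieces[[length(pieces) + 1L]] <- s
      }
    }
    return(list(segs = do.call(rbind, pieces), gap = c(p, q)))
  }
  NULL
}

# Extract one mate's alignment from fragment segments: molecule-base window
# [mol_from, mol_from + len). Leading/trailing gaps are trimmed.
mate_from_segments <- function(segs, mol_from, len) {
  ops <- character(0); lens <- integer(0)
  ref_start <- NA_integer_; ref_end <- NA_integer_
  mol <- 0L
  mseq <- list()
  for (j in seq_len(nrow(segs))) {
    s <- segs[j, ]
    w <- s[3] - s[2]
    if (s[1] == 1L) {
      lo <- max(mol, mol_from); hi <- min(mol + w, mol_from + len)
      if (hi > lo) {
        rs <- s[2] + (lo - mol); re <- s[2] + (hi - mol)
        if (is.na(ref_start)) ref_start <- rs
        ref_end <- re
        ops <- c(ops, "M"); lens <- c(lens, hi - lo)
        mseq[[length(mseq) + 1L]] <- c(rs, re)
      }
      mol <- mol + w
    } else {
      # deletion: contributes only if mates align on both sides
      if (mol > mol_from && mol < mol_from + len && !is.na(ref_start) &&
          length(ops) && ops[length(ops)] == "M") {
        ops <- c(ops, "D"); lens <- c(lens, w)
      }
    }
    if (mol >= mol_from + len) break
  }
  # trim trailing D
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (!length(ops) || sum(lens[ops == "M"]) < 1) return(NULL)
  # collapse adjacent identical ops
  cig <- paste0(lens, ops, collapse = "")
  list(ref_start = ref_start, ref_end = ref_end, cigar = cig,
       blocks = do.call(rbind, mseq))
}

read_sequence <- function(contig_seq, mate, error_rate) {
  b <- mate$blocks
  parts <- substring(contig_seq, b[, 1] + 1L, b[, 2])
  s <- if (length(parts) == 1L) parts else paste(parts, collapse = "")
  if (error_rate > 0) {
    n <- nchar(s)
    nerr <- stats::rbinom(1L, n, error_rate)
    if (nerr > 0) {
      pos <- sample.int(n, nerr)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      s <- paste(ch, collapse = "")
    }
  }
  s
}

#' Simulate nucleosomal (mononucleosome-protected) paired-end fragments
#'
#' Fragment midpoints are drawn with base rate 1 per bp over MAC-destined
#' sequence and rate `density_multiplier[i]` over IES `i`. Outer sizes follow
#' a truncated normal (`frag_mean`, `frag_sd` on `[frag_min, frag_max]`) so
#' the downstream mononucleosome size filter is exercised on both sides.
#' Fragments align contiguously (no gaps) to the MAC+IES reference.
#'
#' @inheritParams simulate_dna_reads
#' @param n_fragments number of fragments; default from `cfg$coverage`.
#' @return list with `alignments` (paired, proper-pair flags) and
#'   `fragment_truth` (tibble: `qname`, `ies_id` of the IES whose interval
#'   contains the midpoint, or `NA`).
#' @export
simulate_nucleosomal_fragments <- function(genome, annotations, truth, cfg,
                                           n_fragments = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(genome) && !inherits(genome, "genome_assembly")) {
    genome <- genome$mac_plus_ies
  }
  withr::with_seed(
    cfg$seed + 2L,
    simulate_nucleosomal_impl(genome, annotations, truth, cfg, n_fragments)
  )
}

simulate_nucleosomal_impl <- function(genome, annotations, truth, cfg,
                                      n_fragments) {
  clen <- contig_lengths(genome)
  glen <- sum(clen)
  if (is.null(n_fragments)) {
    n_fragments <- ceiling(cfg$coverage * glen / cfg$frag_mean)
  }
  if (n_fragments == 0) {
    return(list(alignments = empty_alignments(),
                fragment_truth = tibble::tibble(qname = character(0),
                                                ies_id = character(0))))
  }
  ann <- dplyr::left_join(annotations, truth, by = "ies_id")
  # build weighted intervals: MDS weight 1, IES weight lambda
  ivs <- list()
  for (ct in names(clen)) {
    d <- dplyr::arrange(ann[ann$contig == ct, ], .data$start)
    bnd <- c(0L, rbind(d$start, d$end), clen[[ct]])
    st <- bnd[-length(bnd)]; en <- bnd[-1]
    keep <- en > st
    is_ies <- rep(c(FALSE, TRUE), length.out = length(st))
    lam <- rep(1, length(st))
    lam[is_ies] <- d$density_multiplier
    id <- rep(NA_character_, length(st))
    id[is_ies] <- d$ies_id
    ivs[[ct]] <- tibble::tibble(contig = ct, start = st, end = en,
                                w = lam * (en - st), ies_id = id)[keep, ]
  }
  ivs <- dplyr::bind_rows(ivs)
  pick <- sample.int(nrow(ivs), n_fragments, replace = TRUE,
                     prob = ivs$w / sum(ivs$w))
  mid <- ivs$start[pick] +
    floor(stats::runif(n_fragments) * (ivs$end[pick] - ivs$start[pick]))
  # truncated normal outer sizes via inverse CDF
  lo <- stats::pnorm(cfg$frag_min, cfg$frag_mean, cfg$frag_sd)
  hi <- stats::pnorm(cfg$frag_max, cfg$frag_mean, cfg$frag_sd)
  size <- round(stats::qnorm(stats::runif(n_fragments, lo, hi),
                             cfg$frag_mean, cfg$frag_sd))
  size <- pmax(size, 2L * 10L)
  fstart <- mid - size %/% 2L
  fend <- fstart + size
  ct <- ivs$contig[pick]
  ok <- fstart >= 0 & fend <= clen[ct]
  fstart <- fstart[ok]; fend <- fend[ok]; ct <- ct[ok]; size <- size[ok]
  mid <- mid[ok]; pick <- pick[ok]
  n <- length(fstart)
  rl <- pmin(cfg$read_length, size)
  qname <- sprintf("nuc_%07d", seq_len(n))
  seqs <- lapply(stats::setNames(names(clen), names(clen)),
                 function(x) contig_string(genome, x))
  seq1 <- substring_by_contig(seqs, ct, fstart, fstart + rl)
  seq2 <- substring_by_contig(seqs, ct, fend - rl, fend)
  aln <- tibble::tibble(
    qname = rep(qname, each = 2L),
    flag = rep(c(99L, 147L), n),
    contig = rep(ct, each = 2L),
    pos = as.integer(rbind(fstart, fend - rl)),
    cigar = paste0(rep(rl, each = 2L), "M"),
    mapq = 60L,
    tlen = as.integer(rbind(size, -size)),
    paired = TRUE,
    proper_pair = TRUE,
    mate = rep(c(1L, 2L), n),
    seq = as.character(rbind(seq1, seq2))
  )
  aln <- dplyr::arrange(aln, .data$contig, .data$pos, .data$qname)
  list(
    alignments = aln,
    fragment_truth = tibble::tibble(qname = qname, ies_id = ivs$ies_id[pick],
                                    outer = size, midpoint = mid)
  )
}

substring_by_contig <- function(seqs, contig, start0, end0) {
  out <- character(length(contig))
  for (ct in unique(contig)) {
    i <- contig == ct
    out[i] <- substring(seqs[[ct]], start0[i] + 1L, end0[i])
  }
  out
}

empty_alignments <- function() {
  tibble::tibble(qname = character(0), flag = integer(0),
                 contig = character(0), pos = integer(0),
                 cigar = character(0), mapq = integer(0), tlen = integer(0),
                 paired = logical(0), proper_pair = logical(0),
                 mate = integer(0), seq = character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulated alignments as a coordinate-sorted SAM file
#'
#' @param alignments alignment tibble from the simulators.
#' @param path output path (`.sam`).
#' @param genome the reference `genome_assembly` (for `@SQ` header lines).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, genome) {
  clen <- contig_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(clen), clen))
  if (nrow(alignments) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  a <- dplyr::arrange(alignments, .data$contig, .data$pos, .data$qname)
  paired <- bitwAnd(a$flag, 1L) > 0L
  # mate coordinates for paired records
  rnext <- ifelse(paired, "=", "*")
  pnext <- rep(0L, nrow(a))
  if (any(paired)) {
    key <- paste(a$qname, a$mate)
    other <- paste(a$qname, 3L - a$mate)
    pnext[paired] <- (a$pos[match(other, key)] + 1L)[paired]
  }
  qual <- strrep("I", nchar(a$seq))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  a$qname, a$flag, a$contig, a$pos + 1L, a$mapq, a$cigar,
                  rnext, pnext, a$tlen, a$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' Reverse-strand records are reverse-complemented back to read orientation.
#' With paired data two files (`_1.fastq`, `_2.fastq`) are written.
#'
#' @param alignments alignment tibble from the simulators.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_fastq <- function(alignments, prefix) {
  emit <- function(a, path) {
    s <- a$seq
    rev <- bitwAnd(a$flag, 16L) > 0L
    if (any(rev)) {
      s[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s[rev]))
      )
    }
    lines <- as.vector(rbind(paste0("@", a$qname), s, "+",
                             strrep("I", nchar(s))))
    writeLines(lines, path)
    path
  }
  if (any(bitwAnd(alignments$flag, 1L) > 0L)) {
    p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
    emit(alignments[alignments$mate == 1L, ], p1)
    emit(alignments[alignments$mate == 2L, ], p2)
    invisible(c(p1, p2))
  } else {
    invisible(emit(alignments, paste0(prefix, ".fastq")))
  }
}
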