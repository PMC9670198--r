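#' Extract candidate excision gaps from gapped alignments
#'
#' Deletion (`D`) and skip (`N`) CIGAR operations of length `min_gap` or
#' more, flanked by at least `min_anchor` aligned bases on both sides of the
#' gap within the read, become candidate excision gaps. A read may yield
#' several gaps.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @param min_gap minimum gap length (bp).
#' @param min_anchor minimum aligned bases flanking the gap on each side.
#' @return tibble `qname`, `contig`, `gap_start`, `gap_end` (0-based
#'   half-open), `left_anchor`, `right_anchor`.
#' @export
extract_gaps <- function(aln, min_gap = 20, min_anchor = 10) {
  empty <- tibble::tibble(qname = character(0), contig = character(0),
                          gap_start = integer(0), gap_end = integer(0),
                          left_anchor = integer(0), right_anchor = integer(0))
  if (nrow(aln) == 0) return(empty)
  has_gap <- grepl("[DN]", aln$cigar)
  if (!any(has_gap)) return(empty)
  sub <- aln[has_gap, ]
  ops <- GenomicAlignments::explodeCigarOps(sub$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(sub$cigar)
  out <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    op <- ops[[i]]; ln <- lens[[i]]
    ref_w <- ifelse(op %in% c("M", "=", "X", "D", "N"), ln, 0L)
    aligned <- ifelse(op %in% c("M", "=", "X"), ln, 0L)
    ref_before <- cumsum(c(0L, ref_w))[seq_along(op)]
    gap_j <- which(op %in% c("D", "N") & ln >= min_gap)
    if (!length(gap_j)) next
    la <- vapply(gap_j, function(j) sum(aligned[seq_len(j - 1L)]), numeric(1))
    ra <- vapply(gap_j, function(j) sum(aligned[-seq_len(j)]), numeric(1))
    keep <- la >= min_anchor & ra >= min_anchor
    if (!any(keep)) next
    gap_j <- gap_j[keep]
    out[[i]] <- tibble::tibble(
      qname = sub$qname[i], contig = sub$contig[i],
      gap_start = sub$pos[i] + as.integer(ref_before[gap_j]),
      gap_end = sub$pos[i] + as.integer(ref_before[gap_j] + ln[gap_j]),
      left_anchor = as.integer(la[keep]), right_anchor = as.integer(ra[keep])
    )
  }
  dplyr::bind_rows(empty, dplyr::bind_rows(out))
}

#' Classify candidate gaps against the IES annotation
#'
#' A gap is accepted only when the excised segment begins with `TA` and the
#' reference carries a `TA` immediately downstream of the gap — the same
#' two-TA/one-retained structure as canonical IESs. Accepted gaps are matched
#' to annotated IESs by interval arithmetic: an exact interval match is
#' `CORRECT`; a gap contained in the matched IES is `ALT_INTERNAL`; one
#' containing it is `ALT_EXTERNAL`; a one-sided partial overlap is
#' `ALT_OVERLAPPING`; a gap overlapping no IES is `CRYPTIC`. When several
#' IESs overlap a gap the one with maximal reciprocal overlap wins; ties go
#' to the smaller length difference, then the leftmost IES.
#'
#' @param gaps tibble from [extract_gaps()].
#' @param annotations IES annotation tibble.
#' @param genome the MAC+IES `genome_assembly`.
#' @return list with `events` (tibble `qname`, `contig`, `gap_start`,
#'   `gap_end`, `excised_length`, `class`, `matched_ies_id`) and
#'   `rejections` (tibble `qname`, `contig`, `gap_start`, `gap_end`,
#'   `reason`).
#' @export
classify_gaps <- function(gaps, annotations, genome) {
  stopifnot(genome$flavor == "MAC_PLUS_IES")
  empty_ev <- tibble::tibble(qname = character(0), contig = character(0),
                             gap_start = integer(0), gap_end = integer(0),
                             excised_length = integer(0), class = character(0),
                             matched_ies_id = character(0))
  empty_rej <- tibble::tibble(qname = character(0), contig = character(0),
                              gap_start = integer(0), gap_end = integer(0),
                              reason = character(0))
  if (nrow(gaps) == 0) return(list(events = empty_ev, rejections = empty_rej))

  clen <- contig_lengths(genome)
  seqs <- lapply(stats::setNames(names(clen), names(clen)),
                 function(ct) contig_string(genome, ct))
  left_ok <- right_ok <- logical(nrow(gaps))
  for (ct in unique(gaps$contig)) {
    i <- gaps$contig == ct
    s <- seqs[[ct]]
    left_ok[i] <- substring(s, gaps$gap_start[i] + 1L,
                            gaps$gap_start[i] + 2L) == "TA"
    re <- gaps$gap_end[i]
    right_ok[i] <- re + 2L <= clen[[ct]] &
      substring(s, re + 1L, re + 2L) == "TA"
  }
  reason <- dplyr::case_when(!left_ok ~ "no-TA-left",
                             !right_ok ~ "no-TA-right",
                             TRUE ~ NA_character_)
  rejections <- dplyr::bind_rows(
    empty_rej,
    dplyr::mutate(gaps[!is.na(reason), c("qname", "contig", "gap_start",
                                         "gap_end")],
                  reason = reason[!is.na(reason)])
  )
  acc <- gaps[is.na(reason), ]
  if (nrow(acc) == 0) return(list(events = empty_ev, rejections = rejections))

  matched <- match_gaps_to_ies(acc, annotations)
  events <- dplyr::bind_rows(empty_ev, matched)
  list(events = events, rejections = rejections)
}

match_gaps_to_ies <- function(acc, annotations) {
  gr_gap <- IRanges::IRanges(acc$gap_start + 1L, acc$gap_end)
  res <- tibble::tibble(
    qname = acc$qname, contig = acc$contig,
    gap_start = acc$gap_start, gap_end = acc$gap_end,
    excised_length = acc$gap_end - acc$gap_start,
    class = "CRYPTIC", matched_ies_id = NA_character_
  )
  for (ct in unique(acc$contig)) {
    gi <- which(acc$contig == ct)
    ann <- annotations[annotations$contig == ct, ]
    if (nrow(ann) == 0) next
    ir_gap <- IRanges::IRanges(acc$gap_start[gi] + 1L, acc$gap_end[gi])
    ir_ies <- IRanges::IRanges(ann$start + 1L, ann$end)
    hits <- IRanges::findOverlaps(ir_gap, ir_ies)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ovl <- IRanges::width(IRanges::pintersect(ir_gap[qh], ir_ies[sh]))
    gap_w <- IRanges::width(ir_gap)[qh]
    ies_w <- IRanges::width(ir_ies)[sh]
    recip <- pmin(ovl / gap_w, ovl / ies_w)
    cand <- tibble::tibble(q = qh, s = sh, recip = recip,
                           len_diff = abs(gap_w - ies_w),
                           ies_start = ann$start[sh])
    best <- cand |>
      dplyr::arrange(.data$q, dplyr::desc(.data$recip), .data$len_diff,
                     .data$ies_start) |>
      dplyr::distinct(.data$q, .keep_all = TRUE)
    gidx <- gi[best$q]
    gs <- acc$gap_start[gidx]; ge <- acc$gap_end[gidx]
    is_ <- ann$start[best$s]; ie_ <- ann$end[best$s]
    cls <- dplyr::case_when(
      gs == is_ & ge == ie_ ~ "CORRECT",
      gs >= is_ & ge <= ie_ ~ "ALT_INTERNAL",
      gs <= is_ & ge >= ie_ ~ "ALT_EXTERNAL",
      TRUE ~ "ALT_OVERLAPPING"
    )
    res$class[gidx] <- cls
    res$matched_ies_id[gidx] <- ann$ies_id[best$s]
  }
  res
}

#' Call and aggregate excision events from an alignment file or tibble
#'
#' Convenience wrapper: extracts candidate gaps, classifies them against the
#' annotation, and merges identical gaps, accumulating read support.
#'
#' @param aln alignment tibble (or path to SAM/BAM, parsed with
#'   [read_alignments()]).
#' @param annotations IES annotation tibble.
#' @param genome the MAC+IES `genome_assembly`.
#' @param min_gap,min_anchor gap filters, see [extract_gaps()].
#' @param min_mapq used only when `aln` is a path.
#' @return tibble of aggregated events: `contig`, `gap_start`, `gap_end`,
#'   `excised_length`, `class`, `matched_ies_id`, `support`, `read_ids`
#'   (list column), with attributes `rejections` (tibble) and `n_reads`.
#' @export
call_excision_events <- function(aln, annotations, genome, min_gap = 20,
                                 min_anchor = 10, min_mapq = 10) {
  if (is.character(aln)) aln <- read_alignments(aln, min_mapq = min_mapq)
  gaps <- extract_gaps(aln, min_gap = min_gap, min_anchor = min_anchor)
  cls <- classify_gaps(gaps, annotations, genome)
  events <- cls$events |>
    dplyr::group_by(.data$contig, .data$gap_start, .data$gap_end,
                    .data$excised_length, .data$class,
                    .data$matched_ies_id) |>
    dplyr::summarise(support = dplyr::n(),
                     read_ids = list(sort(.data$qname)), .groups = "drop") |>
    dplyr::arrange(.data$contig, .data$gap_start, .data$gap_end)
  attr(events, "rejections") <- cls$rejections
  attr(events, "n_reads") <- nrow(aln)
  events
}

#' Per-IES correct/alternative read support and genome-wide cryptic table
#'
#' @param events aggregated event tibble from [call_excision_events()].
#' @param annotations IES annotation tibble (defines the IES universe).
#' @return list with `per_ies` (tibble `ies_id`, `n_correct`, `n_alt`) over
#'   all annotated IESs, and `cryptic` (tibble of cryptic events).
#' @export
aggregate_events <- function(events, annotations) {
  alt_classes <- c("ALT_INTERNAL", "ALT_EXTERNAL", "ALT_OVERLAPPING")
  per <- events |>
    dplyr::filter(.data$class != "CRYPTIC") |>
    dplyr::group_by(ies_id = .data$matched_ies_id) |>
    dplyr::summarise(
      n_correct = sum(.data$support[.data$class == "CORRECT"]),
      n_alt = sum(.data$support[.data$class %in% alt_classes]),
      .groups = "drop"
    )
  per_ies <- tibble::tibble(ies_id = annotations$ies_id) |>
    dplyr::left_join(per, by = "ies_id") |>
    tidyr::replace_na(list(n_correct = 0L, n_alt = 0L))
  list(per_ies = per_ies,
       cryptic = dplyr::filter(events, .data$class == "CRYPTIC"))
}

#' Write aggregated excision events as GFF3
#'
#' @param events event tibble from [call_excision_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_gff3 <- function(events, path) {
  attrs <- sprintf(
    "ID=event_%d;class=%s%s;support=%d;read_ids=%s",
    seq_len(nrow(events)), events$class,
    ifelse(is.na(events$matched_ies_id), "",
           paste0(";matched_ies=", events$matched_ies_id)),
    events$support,
    vapply(events$read_ids, paste, character(1), collapse = ",")
  )
  lines <- c("##gff-version 3",
             sprintf("%s\tiestools\texcision\t%d\t%d\t.\t+\t.\t%s",
                     events$contig, events$gap_start + 1L, events$gap_end,
                     attrs))
  writeLines(lines, path)
  invisible(path)
}
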