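#' IES retention score from boundary counts
#'
#' The retention score is `(a + b) / (a + b + 2c)`, where `a` and `b` are
#' reads supporting retention at the left and right boundary and `c` is the
#' number of correctly excised reads. The factor 2 compensates for retained
#' reads being countable at both boundaries, so the score runs from 0
#' (complete excision) to 1 (complete retention failure to excise).
#' Undefined (`a + b + 2c == 0`) scores are `NA`.
#'
#' @param a,b,c non-negative integer vectors (recycled).
#' @return numeric vector of retention scores in `[0, 1]`.
#' @export
compute_irs <- function(a, b, c) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE),
            all(c >= 0, na.rm = TRUE))
  denom <- a + b + 2 * c
  ifelse(denom > 0, (a + b) / denom, NA_real_)
}

#' Count boundary-supporting reads and score retention per IES
#'
#' A read supports retention at the left (right) boundary when one of its
#' aligned blocks covers at least `min_flank` bases on each side of that
#' boundary with no gap at the boundary itself. A retained read spanning a
#' whole short IES counts at both boundaries. A read counts toward excision
#' (`c`) when it carries a gap exactly matching the IES interval with at
#' least `min_flank` aligned bases on each side of the junction — the same
#' flank rule as the retention counts, so the score is an unbiased estimate
#' of the per-molecule retention probability.
#'
#' @param aln alignment tibble (or SAM/BAM path).
#' @param annotations IES annotation tibble.
#' @param genome ignored; retained for call compatibility.
#' @param min_flank minimum aligned bases on each side of a boundary or
#'   excision junction.
#' @param min_gap minimum gap length treated as a candidate excision when
#'   counting `c`.
#' @return tibble `ies_id`, `a`, `b`, `c`, `irs`.
#' @export
score_retention <- function(aln, annotations, genome = NULL,
                            min_flank = 5, min_gap = 20) {
  if (is.character(aln)) aln <- read_alignments(aln)
  blocks <- aligned_blocks(aln)
  count_boundary <- function(boundary_pos, contig) {
    # reads with an aligned block covering [pos - f, pos + f)
    n <- integer(length(boundary_pos))
    for (ct in unique(contig)) {
      bi <- which(contig == ct)
      bl <- blocks[blocks$contig == ct, ]
      if (nrow(bl) == 0) next
      win <- IRanges::IRanges(boundary_pos[bi] - min_flank + 1L,
                              boundary_pos[bi] + min_flank)
      blk <- IRanges::IRanges(bl$start + 1L, bl$end)
      hits <- IRanges::findOverlaps(win, blk, type = "within")
      # distinct reads per window
      cnt <- tibble::tibble(w = S4Vectors::queryHits(hits),
                            r = bl$read_idx[S4Vectors::subjectHits(hits)]) |>
        dplyr::distinct() |>
        dplyr::count(.data$w)
      n[bi[cnt$w]] <- cnt$n
    }
    n
  }
  a <- count_boundary(annotations$start, annotations$contig)
  b <- count_boundary(annotations$end, annotations$contig)
  gaps <- extract_gaps(aln, min_gap = min_gap, min_anchor = min_flank)
  correct <- gaps |>
    dplyr::inner_join(
      annotations[, c("ies_id", "contig", "start", "end")],
      by = dplyr::join_by("contig", gap_start == start, gap_end == end)
    ) |>
    dplyr::count(.data$ies_id, name = "c")
  out <- tibble::tibble(ies_id = annotations$ies_id, a = a, b = b) |>
    dplyr::left_join(correct, by = "ies_id") |>
    tidyr::replace_na(list(c = 0L))
  out$irs <- compute_irs(out$a, out$b, out$c)
  out
}

#' Retention-score matrix across samples
#'
#' @param samples named list of alignment tibbles (or SAM/BAM paths), one
#'   per sample.
#' @param annotations IES annotation tibble.
#' @param genome the MAC+IES `genome_assembly`.
#' @param ... passed to [score_retention()].
#' @return tibble with `ies_id` and one retention-score column per sample.
#' @export
irs_table <- function(samples, annotations, genome, ...) {
  stopifnot(length(samples) >= 1, !is.null(names(samples)))
  out <- tibble::tibble(ies_id = annotations$ies_id)
  for (nm in names(samples)) {
    sc <- score_retention(samples[[nm]], annotations, genome, ...)
    out[[nm]] <- sc$irs[match(out$ies_id, sc$ies_id)]
  }
  out
}

#' Pearson correlation between two retention-score vectors
#'
#' Pairwise-complete; returns `NA` with fewer than 3 complete pairs or zero
#' variance in either vector.
#'
#' @param x,y numeric vectors of retention scores.
#' @return Pearson's r, or `NA`.
#' @export
irs_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = "pearson")
}

#' Retention score summarized by IES length bin
#'
#' Default binning: 1-bp bins up to 150 bp, then `[150, 200)` and
#' `[200, Inf)`.
#'
#' @param irs numeric vector of retention scores, aligned with
#'   `annotations` rows.
#' @param annotations IES annotation tibble.
#' @param breaks optional numeric vector of left-closed bin edges.
#' @return tibble `bin`, `length_min`, `length_max`, `n`, `mean_irs`,
#'   `median_irs` (summaries `NA` for empty bins).
#' @export
irs_by_length <- function(irs, annotations, breaks = NULL) {
  stopifnot(length(irs) == nrow(annotations))
  if (is.null(breaks)) breaks <- c(seq(0, 150, by = 1), 200)
  edges <- c(breaks, Inf)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  bin_of <- findInterval(annotations$length, edges)
  dat <- tibble::tibble(bin = bin_of, irs = irs)
  out <- tibble::tibble(bin = seq_along(lo), length_min = lo,
                        length_max = hi) |>
    dplyr::left_join(
      dat |>
        dplyr::filter(.data$bin >= 1, .data$bin <= length(lo)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = sum(!is.na(.data$irs)),
                         mean_irs = mean(.data$irs, na.rm = TRUE),
                         median_irs = stats::median(.data$irs, na.rm = TRUE),
                         .groups = "drop"),
      by = "bin"
    ) |>
    tidyr::replace_na(list(n = 0L))
  out$mean_irs[out$n == 0] <- NA_real_
  out$median_irs[out$n == 0] <- NA_real_
  out
}

#' Base frequencies just inside the IES ends, stratified by retention score
#'
#' For each IES, the three bases following the terminal `TA` are read at both
#' ends: positions `start+2 .. start+4` on the forward strand at the left
#' end, and the reverse complement of positions `end-3 .. end-1` at the right
#' end (the downstream retained `TA` sits at `[end, end+2)`). Frequencies per
#' retention-score bin sum to 1 at each of positions 1-3.
#'
#' @param annotations IES annotation tibble.
#' @param genome the MAC+IES `genome_assembly`.
#' @param irs retention scores aligned with `annotations` rows.
#' @param irs_bins left-closed bin edges over `[0, 1]`.
#' @param length_range optional `c(min, max)` IES length filter (inclusive),
#'   e.g. `c(26, 31)` for the first length peak.
#' @return tibble `irs_bin`, `position` (1-3), `base`, `count`, `freq`.
#' @export
subterminal_base_frequencies <- function(annotations, genome, irs,
                                         irs_bins = seq(0, 1, by = 0.2),
                                         length_range = NULL) {
  stopifnot(length(irs) == nrow(annotations))
  keep <- !is.na(irs)
  if (!is.null(length_range)) {
    keep <- keep & annotations$length >= length_range[1] &
      annotations$length <= length_range[2]
  }
  short <- annotations$length < 5
  if (any(short & keep)) {
    warning(sum(short & keep), " IES(s) shorter than 5 bp skipped")
    keep <- keep & !short
  }
  ann <- annotations[keep, ]
  irs <- irs[keep]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (ct in unique(ann$contig)) {
    s <- contig_string(genome, ct)
    d <- ann[ann$contig == ct, ]
    v <- irs[ann$contig == ct]
    left <- substring(s, d$start + 3L, d$start + 5L)
    right_fwd <- substring(s, d$end - 2L, d$end)   # positions end-3..end-1
    for (p in 1:3) {
      lb <- substr(left, p, p)
      # reverse strand: first base after the right TA is complement(end-1)
      rb <- comp[substr(right_fwd, 4L - p, 4L - p)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        irs = rep(v, 2L), position = p, base = c(lb, unname(rb))
      )
    }
  }
  dat <- dplyr::bind_rows(rows)
  edges <- unique(c(irs_bins, 1 + 1e-9))
  dat$irs_bin <- cut(dat$irs, breaks = edges, right = FALSE,
                     include.lowest = TRUE)
  dat |>
    dplyr::filter(.data$base %in% c("A", "C", "G", "T")) |>
    dplyr::count(.data$irs_bin, .data$position, .data$base,
                 name = "count", .drop = FALSE) |>
    dplyr::group_by(.data$irs_bin, .data$position) |>
    dplyr::mutate(freq = ifelse(sum(.data$count) > 0,
                                .data$count / sum(.data$count), NA_real_)) |>
    dplyr::ungroup()
}

#' Write a retention-score table as TSV
#'
#' @param retention tibble from [score_retention()] (or [irs_table()]).
#' @param path output path.
#' @export
write_retention_tsv <- function(retention, path) {
  readr::write_tsv(retention, path)
  invisible(path)
}
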