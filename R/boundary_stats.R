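#' Alternative excision percentage
#'
#' `100 * n_alt / (n_alt + n_correct)`: the share of excised reads that used
#' an alternative TA boundary pair. `NA` when no excised reads exist.
#'
#' @param n_alt,n_correct read counts (vectors recycled).
#' @return percentage in `[0, 100]`, `NA` where both counts are zero.
#' @export
alt_excision_percent <- function(n_alt, n_correct) {
  denom <- n_alt + n_correct
  ifelse(denom > 0, 100 * n_alt / denom, NA_real_)
}

#' Cryptic excision percentage
#'
#' `100 * n_cryptic / n_all`: cryptically excised reads as a share of all
#' mapped reads.
#'
#' @param n_cryptic_reads,n_all_reads read counts.
#' @return percentage, `NA` when `n_all_reads` is zero.
#' @export
cryptic_excision_percent <- function(n_cryptic_reads, n_all_reads) {
  ifelse(n_all_reads > 0, 100 * n_cryptic_reads / n_all_reads, NA_real_)
}

#' Fraction of annotated IESs with alternative excision support
#'
#' @param per_ies tibble with `ies_id` and `n_alt` covering the whole
#'   annotated universe (see [aggregate_events()]).
#' @param min_reads minimum supporting reads for an IES to count.
#' @return fraction in `[0, 1]`.
#' @export
fraction_ies_with_alt <- function(per_ies, min_reads = 1) {
  if (nrow(per_ies) == 0) stop("empty annotation universe")
  mean(per_ies$n_alt >= min_reads)
}

#' Median and mean per-IES alternative excision percentage
#'
#' Computed over IESs with at least one excised (correct or alternative)
#' read.
#'
#' @param per_ies tibble with `n_alt` and `n_correct` per IES.
#' @return tibble `n_eligible`, `median_alt_percent`, `mean_alt_percent`.
#' @export
per_ies_alt_summary <- function(per_ies) {
  eligible <- per_ies[per_ies$n_alt + per_ies$n_correct > 0, ]
  if (nrow(eligible) == 0) stop("no IES with excised reads")
  p <- alt_excision_percent(eligible$n_alt, eligible$n_correct)
  tibble::tibble(n_eligible = nrow(eligible),
                 median_alt_percent = stats::median(p),
                 mean_alt_percent = mean(p))
}

#' Excised-length histograms (1-bp bins)
#'
#' Builds histograms of (i) annotated reference IES lengths, (ii)
#' alternatively excised lengths split into internal and external, and (iii)
#' cryptic excised lengths. Alternative and cryptic histograms are weighted
#' by supporting reads by default; `ALT_OVERLAPPING` events count as
#' external (they extend beyond the annotated interval on one side).
#'
#' @param events aggregated event tibble from [call_excision_events()].
#' @param annotations IES annotation tibble.
#' @param weight `"reads"` (each supporting read counts once) or
#'   `"events"`.
#' @return tibble `component` (`reference`, `alt_internal`, `alt_external`,
#'   `cryptic`), `length`, `count`.
#' @export
excision_length_histograms <- function(events, annotations,
                                       weight = c("reads", "events")) {
  weight <- match.arg(weight)
  w <- if (weight == "reads") events$support else rep(1L, nrow(events))
  comp <- dplyr::case_when(
    events$class == "ALT_INTERNAL" ~ "alt_internal",
    events$class %in% c("ALT_EXTERNAL", "ALT_OVERLAPPING") ~ "alt_external",
    events$class == "CRYPTIC" ~ "cryptic",
    TRUE ~ NA_character_
  )
  ev <- tibble::tibble(component = comp, length = events$excised_length,
                       count = w) |>
    dplyr::filter(!is.na(.data$component))
  ref <- tibble::tibble(component = "reference",
                        length = annotations$length, count = 1L)
  dplyr::bind_rows(ref, ev) |>
    dplyr::group_by(.data$component, .data$length) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$component, .data$length)
}

#' Fraction of histogram mass in the "forbidden" length window
#'
#' The second IES length peak (around 35 bp) is strongly suppressed in
#' wild-type excision; this measures the mass a length histogram places in
#' that window.
#'
#' @param histogram tibble with `length` and `count` columns (e.g., one
#'   component of [excision_length_histograms()]).
#' @param window inclusive `c(min, max)` length window.
#' @return fraction in `[0, 1]`, `NA` for an empty histogram.
#' @export
forbidden_peak_mass <- function(histogram, window = c(32, 38)) {
  total <- sum(histogram$count)
  if (!is.finite(total) || total == 0) return(NA_real_)
  inside <- histogram$length >= window[1] & histogram$length <= window[2]
  sum(histogram$count[inside]) / total
}

#' Boundary-offset distributions of alternative excision events
#'
#' For every non-cryptic event matched to an IES, reports the signed length
#' difference (excised length minus annotated length) and per-boundary
#' offsets (gap boundary minus canonical boundary), read-weighted, plus the
#' fraction of events whose boundaries both fall within 20 bp of the
#' canonical ones.
#'
#' @param events aggregated event tibble.
#' @param annotations IES annotation tibble.
#' @param max_offset window (bp) for the "near-canonical" fraction.
#' @return list: `length_offset` (tibble `offset`, `count`),
#'   `boundary_offset` (tibble `side`, `offset`, `count`),
#'   `fraction_within` (read-weighted share with both offsets within
#'   `max_offset`).
#' @export
boundary_offset_distribution <- function(events, annotations,
                                         max_offset = 20) {
  ev <- events |>
    dplyr::filter(.data$class != "CRYPTIC") |>
    dplyr::left_join(annotations[, c("ies_id", "start", "end", "length")],
                     by = c(matched_ies_id = "ies_id"))
  left_off <- ev$gap_start - ev$start
  right_off <- ev$gap_end - ev$end
  len_off <- ev$excised_length - ev$length
  length_offset <- tibble::tibble(offset = len_off, count = ev$support) |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$offset)
  boundary_offset <- dplyr::bind_rows(
    tibble::tibble(side = "left", offset = left_off, count = ev$support),
    tibble::tibble(side = "right", offset = right_off, count = ev$support)
  ) |>
    dplyr::group_by(.data$side, .data$offset) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  within <- abs(left_off) <= max_offset & abs(right_off) <= max_offset
  fraction_within <- if (sum(ev$support) > 0) {
    sum(ev$support[within]) / sum(ev$support)
  } else NA_real_
  list(length_offset = length_offset, boundary_offset = boundary_offset,
       fraction_within = fraction_within)
}

#' Genome-wide excision summary for one sample
#'
#' Combines the per-IES event table into the headline excision statistics:
#' global alternative excision percentage, fraction of IESs with alternative
#' excision, per-IES alternative percentage summaries, cryptic percentage,
#' length histograms and the forbidden-peak mass of the alternative-length
#' histogram.
#'
#' @param events aggregated event tibble from [call_excision_events()].
#' @param annotations IES annotation tibble.
#' @param n_all_reads total mapped reads in the sample (defaults to the
#'   `n_reads` attribute of `events`).
#' @param forbidden_window inclusive length window for
#'   [forbidden_peak_mass()].
#' @return an `excision_summary` list: `per_ies`, `global_alt_percent`,
#'   `fraction_ies_with_alt`, `alt_summary`, `cryptic_percent`,
#'   `histograms`, `forbidden_mass`, `offsets`.
#' @export
summarize_excision <- function(events, annotations, n_all_reads = NULL,
                               forbidden_window = c(32, 38)) {
  if (is.null(n_all_reads)) n_all_reads <- attr(events, "n_reads")
  agg <- aggregate_events(events, annotations)
  per <- agg$per_ies
  n_alt <- sum(per$n_alt); n_corr <- sum(per$n_correct)
  n_cry <- sum(agg$cryptic$support)
  hist <- excision_length_histograms(events, annotations)
  alt_hist <- hist[hist$component %in% c("alt_internal", "alt_external"), ]
  structure(list(
    per_ies = per,
    global_alt_percent = alt_excision_percent(n_alt, n_corr),
    fraction_ies_with_alt = fraction_ies_with_alt(per),
    alt_summary = if (any(per$n_alt + per$n_correct > 0)) {
      per_ies_alt_summary(per)
    } else NULL,
    cryptic_percent = cryptic_excision_percent(n_cry, n_all_reads %||% NA),
    histograms = hist,
    forbidden_mass = forbidden_peak_mass(alt_hist, forbidden_window),
    offsets = boundary_offset_distribution(events, annotations)
  ), class = "excision_summary")
}

#' @export
print.excision_summary <- function(x, ...) {
  cat("<excision_summary>\n")
  cat(sprintf("  global alternative excision: %.2f%%\n",
              x$global_alt_percent))
  cat(sprintf("  IESs with >=1 alternative read: %.1f%%\n",
              100 * x$fraction_ies_with_alt))
  if (!is.null(x$alt_summary)) {
    cat(sprintf("  per-IES alt%% median %.2f, mean %.2f (n=%d)\n",
                x$alt_summary$median_alt_percent,
                x$alt_summary$mean_alt_percent, x$alt_summary$n_eligible))
  }
  cat(sprintf("  cryptic excision: %.3f%%\n", x$cryptic_percent))
  cat(sprintf("  forbidden-peak mass (alt lengths): %.3f\n",
              x$forbidden_mass))
  invisible(x)
}
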