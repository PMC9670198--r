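#' Select mononucleosome-sized proper pairs
#'
#' Keeps properly paired reads whose outer distance (template length) lies in
#' the mononucleosome range, inclusive on both ends, and reduces each pair to
#' a single fragment interval.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @param min_outer,max_outer inclusive outer-distance bounds (bp).
#' @return tibble of fragments: `qname`, `contig`, `start`, `end` (0-based
#'   half-open outer interval), `outer`.
#' @export
filter_nucleosomal_pairs <- function(aln, min_outer = 100, max_outer = 175) {
  if (!any(aln$paired)) {
    stop("mononucleosome filtering requires paired-end alignments with ",
         "template lengths")
  }
  fw <- aln[aln$paired & aln$proper_pair & !is.na(aln$tlen) & aln$tlen > 0, ]
  fw <- fw[fw$tlen >= min_outer & fw$tlen <= max_outer, ]
  tibble::tibble(qname = fw$qname, contig = fw$contig, start = fw$pos,
                 end = fw$pos + fw$tlen, outer = fw$tlen)
}

#' Count reads (or fragments) per IES with a minimum-overlap rule
#'
#' A unit counts toward an IES when at least `min_overlap` of its aligned
#' (non-gap) bases fall inside the IES interval; a unit may count toward
#' several IESs. For alignment tibbles the aligned CIGAR blocks are used, so
#' a read whose deletion spans an IES contributes nothing to it; fragment
#' tibbles (from [filter_nucleosomal_pairs()]) use the outer interval.
#'
#' @param x alignment tibble (has a `cigar` column) or fragment tibble.
#' @param annotations IES annotation tibble.
#' @param min_overlap minimum overlapping aligned bases (bp).
#' @return tibble `ies_id`, `count`, with attribute `n_total` = number of
#'   units supplied.
#' @export
count_ies_reads <- function(x, annotations, min_overlap = 9) {
  if ("cigar" %in% names(x)) {
    bl <- aligned_blocks(x)
    units <- tibble::tibble(unit = bl$read_idx, contig = bl$contig,
                            start = bl$start, end = bl$end)
    n_total <- nrow(x)
  } else {
    units <- tibble::tibble(unit = seq_len(nrow(x)), contig = x$contig,
                            start = x$start, end = x$end)
    n_total <- nrow(x)
  }
  res <- list()
  for (ct in unique(annotations$contig)) {
    d <- annotations[annotations$contig == ct, ]
    u <- units[units$contig == ct, ]
    if (nrow(u) == 0) next
    ir_u <- IRanges::IRanges(u$start + 1L, u$end)
    ir_i <- IRanges::IRanges(d$start + 1L, d$end)
    hits <- IRanges::findOverlaps(ir_u, ir_i)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ovl <- IRanges::width(IRanges::pintersect(ir_u[qh], ir_i[sh]))
    res[[ct]] <- tibble::tibble(ies_id = d$ies_id[sh], unit = u$unit[qh],
                                ovl = ovl) |>
      dplyr::group_by(.data$ies_id, .data$unit) |>
      dplyr::summarise(ovl = sum(.data$ovl), .groups = "drop") |>
      dplyr::filter(.data$ovl >= min_overlap) |>
      dplyr::count(.data$ies_id, name = "count")
  }
  counts <- dplyr::bind_rows(res)
  out <- tibble::tibble(ies_id = annotations$ies_id) |>
    dplyr::left_join(counts, by = "ies_id") |>
    tidyr::replace_na(list(count = 0L))
  attr(out, "n_total") <- n_total
  out
}

#' Bernoulli downsampling of a library, pair-coherent
#'
#' Each read is kept independently with probability `fraction`; both mates of
#' a pair share the keep decision. Deterministic given `seed`.
#'
#' @param aln alignment tibble.
#' @param fraction keep probability in `(0, 1]`.
#' @param seed integer seed.
#' @return the subsampled alignment tibble.
#' @export
downsample_reads <- function(aln, fraction, seed) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1], got ", fraction)
  }
  if (fraction == 1) return(aln)
  qn <- unique(aln$qname)
  keep <- withr::with_seed(seed, stats::runif(length(qn)) < fraction)
  aln[aln$qname %in% qn[keep], ]
}

#' Normalized nucleosome density
#'
#' `r = (n / N) / (d / D)`: per-IES nucleosomal reads as a fraction of the
#' nucleosomal library, divided by per-IES DNA-seq reads as a fraction of
#' the DNA-seq library. Missing where `d = 0`.
#'
#' @param n,d per-IES nucleosomal and DNA read counts (vectors).
#' @param N,D total mapped nucleosomal and DNA library sizes (scalars > 0).
#' @return numeric vector of densities, `NA` where `d == 0`.
#' @export
normalized_density <- function(n, N, d, D) {
  if (is.na(N) || is.na(D) || N <= 0 || D <= 0) {
    stop("library totals N and D must be positive")
  }
  ifelse(d > 0, (n / N) / (d / D), NA_real_)
}

#' Per-IES density records for one condition
#'
#' Applies the mononucleosome filter to the nucleosomal library, counts both
#' libraries per IES under the minimum-overlap rule, and forms the
#' normalized density. DNA-seq reads are counted unfiltered.
#'
#' @param annotations IES annotation tibble.
#' @param nucleosomal,dna alignment tibbles (or SAM/BAM paths).
#' @param min_outer,max_outer mononucleosome outer-distance bounds.
#' @param min_overlap minimum aligned-base overlap per IES.
#' @return tibble `ies_id`, `n`, `d`, `r`, with attributes `N` and `D`
#'   (library totals used for normalization).
#' @export
density_records <- function(annotations, nucleosomal, dna,
                            min_outer = 100, max_outer = 175,
                            min_overlap = 9) {
  if (is.character(nucleosomal)) nucleosomal <- read_alignments(nucleosomal)
  if (is.character(dna)) dna <- read_alignments(dna)
  frags <- filter_nucleosomal_pairs(nucleosomal, min_outer, max_outer)
  nc <- count_ies_reads(frags, annotations, min_overlap)
  dc <- count_ies_reads(dna, annotations, min_overlap)
  N <- nrow(frags)
  D <- attr(dc, "n_total")
  out <- tibble::tibble(ies_id = annotations$ies_id,
                        n = nc$count[match(annotations$ies_id, nc$ies_id)],
                        d = dc$count[match(annotations$ies_id, dc$ies_id)])
  out$r <- normalized_density(out$n, N, out$d, D)
  attr(out, "N") <- N
  attr(out, "D") <- D
  out
}

#' Stratify densities by retention score and IES length
#'
#' Groups IESs into weak (`irs < irs_threshold`) and strong
#' (`irs >= irs_threshold`) retention within length strata (all lengths,
#' first length peak, first non-periodic lengths by default), excluding
#' missing densities, and reports the two-sample Kolmogorov-Smirnov
#' comparison per stratum.
#'
#' @param density tibble from [density_records()] (`ies_id`, `r`).
#' @param annotations IES annotation tibble.
#' @param irs retention scores aligned with `annotations` rows (or a tibble
#'   with `ies_id` and `irs`).
#' @param irs_threshold weak/strong boundary on the retention score.
#' @param length_strata named list of inclusive length ranges (`NULL` =
#'   all lengths).
#' @return list: `values` (tibble `stratum`, `group`, `ies_id`, `r`) and
#'   `ks` (tibble `stratum`, `n_weak`, `n_strong`, `D`, `p_value`).
#' @export
stratified_density_distributions <- function(density, annotations, irs,
                                             irs_threshold = 0.2,
                                             length_strata = list(
                                               all = NULL,
                                               peak1 = c(26, 31),
                                               long = c(150, 200)
                                             )) {
  if (is.data.frame(irs)) {
    irs <- irs$irs[match(annotations$ies_id, irs$ies_id)]
  }
  stopifnot(length(irs) == nrow(annotations))
  base <- tibble::tibble(
    ies_id = annotations$ies_id, length = annotations$length, irs = irs
  ) |>
    dplyr::inner_join(density[, c("ies_id", "r")], by = "ies_id") |>
    dplyr::filter(!is.na(.data$r), !is.na(.data$irs)) |>
    dplyr::mutate(group = ifelse(.data$irs < irs_threshold,
                                 "weak", "strong"))
  values <- list(); ks <- list()
  for (nm in names(length_strata)) {
    rng <- length_strata[[nm]]
    d <- if (is.null(rng)) base else {
      base[base$length >= rng[1] & base$length <= rng[2], ]
    }
    values[[nm]] <- dplyr::mutate(
      d[, c("ies_id", "group", "r")], stratum = nm, .before = 1
    )
    x <- d$r[d$group == "weak"]; y <- d$r[d$group == "strong"]
    ks[[nm]] <- tibble::tibble(
      stratum = nm, n_weak = length(x), n_strong = length(y),
      D = NA_real_, p_value = NA_real_
    )
    if (length(x) >= 1 && length(y) >= 1) {
      kt <- ks_two_sample(x, y)
      ks[[nm]]$D <- kt$D
      ks[[nm]]$p_value <- kt$p_value
    }
  }
  list(values = dplyr::bind_rows(values), ks = dplyr::bind_rows(ks))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the maximum absolute difference between the two empirical CDFs;
#' the p-value uses the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_eff) * D` with effective size `n_eff = m*n/(m+n)`.
#'
#' @param x,y numeric samples (each nonempty).
#' @return one-row tibble `D`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be nonempty")
  pts <- sort(unique(c(x, y)))
  ex <- stats::ecdf(x)(pts)
  ey <- stats::ecdf(y)(pts)
  D <- max(abs(ex - ey))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  tibble::tibble(D = D, p_value = p, n_x = length(x), n_y = length(y))
}

# Survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(q, 0), 1)
}

#' Histogram of paired-end outer distances (1-bp bins)
#'
#' One entry per proper pair, counted from the forward-oriented record.
#'
#' @param aln alignment tibble.
#' @param max_len maximum outer distance tabulated.
#' @return tibble `outer` (1..`max_len`), `count`, `density`
#'   (count / total).
#' @export
fragment_length_histogram <- function(aln, max_len = 500) {
  if (!any(aln$paired)) stop("paired-end alignments required")
  fw <- aln[aln$paired & aln$proper_pair & !is.na(aln$tlen) & aln$tlen > 0, ]
  sizes <- fw$tlen[fw$tlen >= 1 & fw$tlen <= max_len]
  counts <- tabulate(sizes, nbins = max_len)
  tibble::tibble(outer = seq_len(max_len), count = counts,
                 density = if (sum(counts) > 0) counts / sum(counts) else 0)
}
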