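#' Run the full synthetic-data generator and write a dataset directory
#'
#' Generates a MAC+IES genome with annotations, ground-truth excision
#' parameters, anlagen DNA-seq reads and nucleosomal fragments, and writes
#' the standard file formats (FASTA, GFF3, coordinate-sorted SAM, FASTQ,
#' truth TSVs) plus a manifest with the seeds and parameters used.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created); `NULL` keeps everything in memory.
#' @param truth_params list of arguments for [simulate_truth()].
#' @param nucleosomal also simulate nucleosomal fragments.
#' @return an `ies_simulation` list: `cfg`, `genome`, `annotations`,
#'   `truth`, `dna` (alignments + read truth), `nuc` (or `NULL`), `paths`
#'   (when written).
#' @export
run_simulation <- function(cfg, dir = NULL, truth_params = list(),
                           nucleosomal = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_ies == 0) stop("n_ies must be positive")
  gen <- generate_genome(cfg)
  truth <- do.call(simulate_truth, c(list(gen$annotations), truth_params))
  dna <- simulate_dna_reads(gen$mac_plus_ies, gen$annotations, truth, cfg)
  nuc <- if (nucleosomal) {
    simulate_nucleosomal_fragments(gen$mac_plus_ies, gen$annotations, truth,
                                   cfg)
  }
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      mac_plus_ies_fasta = file.path(dir, "mac_plus_ies.fasta"),
      mac_fasta = file.path(dir, "mac.fasta"),
      annotations_gff3 = file.path(dir, "ies_annotations.gff3"),
      dna_sam = file.path(dir, "dna.sam"),
      nuc_sam = if (nucleosomal) file.path(dir, "nucleosomal.sam"),
      truth_tsv = file.path(dir, "truth_ies.tsv"),
      read_truth_tsv = file.path(dir, "truth_reads.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_genome_fasta(gen$mac_plus_ies, paths$mac_plus_ies_fasta)
    write_genome_fasta(gen$mac, paths$mac_fasta)
    write_ies_gff3(gen$annotations, paths$annotations_gff3)
    write_sam(dna$alignments, paths$dna_sam, gen$mac_plus_ies)
    write_fastq(dna$alignments, file.path(dir, "dna"))
    if (nucleosomal) {
      write_sam(nuc$alignments, paths$nuc_sam, gen$mac_plus_ies)
    }
    readr::write_tsv(
      dplyr::mutate(truth, cryptic_rate = attr(truth, "cryptic_rate")),
      paths$truth_tsv
    )
    readr::write_tsv(dna$read_truth, paths$read_truth_tsv)
    jsonlite::write_json(
      list(seed = cfg$seed, config = unclass(cfg),
           n_ies = nrow(gen$annotations),
           n_dna_reads = nrow(dna$alignments),
           n_nuc_records = if (nucleosomal) nrow(nuc$alignments) else 0L),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE
    )
  }
  structure(list(cfg = cfg, genome = gen$mac_plus_ies, mac = gen$mac,
                 annotations = gen$annotations, truth = truth, dna = dna,
                 nuc = nuc, paths = paths),
            class = "ies_simulation")
}

#' Run the analysis pipeline on one DNA-seq sample
#'
#' Chains event calling, retention scoring and the excision summary; when a
#' nucleosomal sample is given, adds mononucleosome-filtered per-IES density
#' records and retention-stratified Kolmogorov-Smirnov comparisons.
#'
#' @param dna alignment tibble or SAM/BAM path (anlagen DNA-seq on the
#'   MAC+IES reference).
#' @param annotations IES annotation tibble.
#' @param genome the MAC+IES `genome_assembly`.
#' @param nucleosomal optional nucleosomal alignment tibble or path.
#' @param min_gap,min_anchor,min_mapq,min_flank stage parameters (see
#'   [extract_gaps()], [read_alignments()], [score_retention()]).
#' @param min_outer,max_outer,min_overlap density-stage parameters.
#' @param irs_threshold weak/strong retention boundary for stratification.
#' @param forbidden_window length window for [forbidden_peak_mass()].
#' @return an `ies_analysis` list: `events`, `retention`, `excision`,
#'   `density`, `strata`, `fragment_lengths`, `params`.
#' @export
run_analysis <- function(dna, annotations, genome, nucleosomal = NULL,
                         min_gap = 20, min_anchor = 10, min_mapq = 10,
                         min_flank = 5, min_outer = 100, max_outer = 175,
                         min_overlap = 9, irs_threshold = 0.2,
                         forbidden_window = c(32, 38)) {
  if (is.character(dna)) dna <- read_alignments(dna, min_mapq = min_mapq)
  events <- call_excision_events(dna, annotations, genome,
                                 min_gap = min_gap, min_anchor = min_anchor)
  retention <- score_retention(dna, annotations, min_flank = min_flank)
  excision <- summarize_excision(events, annotations,
                                 forbidden_window = forbidden_window)
  density <- strata <- fragment_lengths <- NULL
  if (!is.null(nucleosomal)) {
    if (is.character(nucleosomal)) {
      nucleosomal <- read_alignments(nucleosomal, min_mapq = min_mapq)
    }
    density <- density_records(annotations, nucleosomal, dna,
                               min_outer = min_outer, max_outer = max_outer,
                               min_overlap = min_overlap)
    strata <- stratified_density_distributions(density, annotations,
                                               retention,
                                               irs_threshold = irs_threshold)
    fragment_lengths <- fragment_length_histogram(nucleosomal)
  } else {
    message("no nucleosomal sample supplied; skipping density analysis")
  }
  structure(list(
    events = events, retention = retention, excision = excision,
    density = density, strata = strata, fragment_lengths = fragment_lengths,
    params = list(min_gap = min_gap, min_anchor = min_anchor,
                  min_mapq = min_mapq, min_flank = min_flank,
                  min_outer = min_outer, max_outer = max_outer,
                  min_overlap = min_overlap, irs_threshold = irs_threshold,
                  forbidden_window = forbidden_window,
                  n_reads = attr(events, "n_reads"))
  ), class = "ies_analysis")
}

#' @export
print.ies_analysis <- function(x, ...) {
  cat(sprintf("<ies_analysis> %d IESs, %d events, %d mapped reads\n",
              nrow(x$retention), nrow(x$events), x$params$n_reads))
  print(x$excision)
  if (!is.null(x$strata)) {
    cat("  density strata (weak vs strong retention):\n")
    print(x$strata$ks)
  }
  invisible(x)
}

#' Write analysis outputs as a report directory
#'
#' Emits the retention table (TSV), the event calls (GFF3), length and
#' offset histograms (TSV), the per-IES density table (TSV, when present),
#' and a machine-readable summary (JSON).
#'
#' @param analysis an `ies_analysis` from [run_analysis()].
#' @param dir output directory (created).
#' @return named list of written paths, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ies_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    retention = file.path(dir, "retention.tsv"),
    events = file.path(dir, "events.gff3"),
    histograms = file.path(dir, "length_histograms.tsv"),
    offsets = file.path(dir, "length_offsets.tsv"),
    summary = file.path(dir, "summary.json")
  )
  write_retention_tsv(analysis$retention, paths$retention)
  write_events_gff3(analysis$events, paths$events)
  readr::write_tsv(analysis$excision$histograms, paths$histograms)
  readr::write_tsv(analysis$excision$offsets$length_offset, paths$offsets)
  if (!is.null(analysis$density)) {
    paths$density <- file.path(dir, "density.tsv")
    readr::write_tsv(analysis$density, paths$density)
    paths$ks <- file.path(dir, "ks_report.json")
    jsonlite::write_json(analysis$strata$ks, paths$ks, auto_unbox = FALSE,
                         pretty = TRUE, digits = NA)
    paths$fragment_lengths <- file.path(dir, "fragment_lengths.tsv")
    readr::write_tsv(analysis$fragment_lengths, paths$fragment_lengths)
  }
  jsonlite::write_json(glance(analysis), paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-IES tidy view of an analysis
#'
#' One row per annotated IES: boundary counts, retention score, correct and
#' alternative read support, and (when computed) density columns.
#'
#' @param x an `ies_analysis`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.ies_analysis <- function(x, ...) {
  out <- dplyr::left_join(x$retention, x$excision$per_ies, by = "ies_id")
  if (!is.null(x$density)) {
    out <- dplyr::left_join(out, x$density, by = "ies_id")
  }
  out
}

#' One-row summary of an analysis
#'
#' @param x an `ies_analysis`.
#' @param ... unused.
#' @return a one-row tibble with the headline statistics.
#' @export
glance.ies_analysis <- function(x, ...) {
  tibble::tibble(
    n_ies = nrow(x$retention),
    n_reads = x$params$n_reads,
    n_events = nrow(x$events),
    mean_irs = mean(x$retention$irs, na.rm = TRUE),
    global_alt_percent = x$excision$global_alt_percent,
    fraction_ies_with_alt = x$excision$fraction_ies_with_alt,
    median_alt_percent = x$excision$alt_summary$median_alt_percent %||% NA_real_,
    mean_alt_percent = x$excision$alt_summary$mean_alt_percent %||% NA_real_,
    cryptic_percent = x$excision$cryptic_percent,
    forbidden_mass = x$excision$forbidden_mass,
    offset_fraction_within_20 = x$excision$offsets$fraction_within,
    ks_D_all = if (!is.null(x$strata)) {
      x$strata$ks$D[x$strata$ks$stratum == "all"]
    } else NA_real_,
    ks_p_all = if (!is.null(x$strata)) {
      x$strata$ks$p_value[x$strata$ks$stratum == "all"]
    } else NA_real_
  )
}
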