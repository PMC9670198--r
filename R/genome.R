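#' Genome assemblies and IES annotations
#'
#' A `genome_assembly` is a thin S3 wrapper around a
#' [Biostrings::DNAStringSet] carrying a `flavor` attribute that records
#' which coordinate system the sequences live in: `"MAC_PLUS_IES"` for the
#' germline-inclusive reference (somatic sequence with IESs inserted) or
#' `"MAC"` for the somatic product after excision.
#'
#' All coordinates inside the package are 0-based half-open; GFF3 input and
#' output convert to and from the 1-based inclusive convention at the file
#' boundary.
#'
#' @param contigs a named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences (alphabet `A`, `C`, `G`, `T`, `N`).
#' @param flavor `"MAC_PLUS_IES"` or `"MAC"`.
#' @return a `genome_assembly` object.
#' @export
genome_assembly <- function(contigs, flavor = c("MAC_PLUS_IES", "MAC")) {
  flavor <- match.arg(flavor)
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(toupper(contigs))
  }
  stopifnot(methods::is(contigs, "DNAStringSet"))
  nm <- names(contigs)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("every contig must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate contig names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  freq <- Biostrings::alphabetFrequency(contigs)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(extra > 0)) {
    stop("contig(s) contain characters outside {A,C,G,T,N}: ",
         paste(nm[extra > 0], collapse = ", "))
  }
  structure(list(contigs = contigs, flavor = flavor),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> flavor=%s, %d contig(s), %s bp total\n",
              x$flavor, length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' @export
length.genome_assembly <- function(x) length(x$contigs)

contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$contigs), names(genome$contigs))
}

contig_string <- function(genome, contig) {
  if (!contig %in% names(genome$contigs)) {
    stop("unknown contig: ", contig)
  }
  as.character(genome$contigs[[contig]])
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on load; `N` is allowed; contig order in the file
#' is preserved.
#'
#' @param path path to a FASTA file.
#' @inheritParams genome_assembly
#' @return a `genome_assembly`.
#' @export
load_genome <- function(path, flavor = c("MAC_PLUS_IES", "MAC")) {
  flavor <- match.arg(flavor)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("FASTA file contains no sequences: ", path)
  # FASTA descriptions: keep the first whitespace-delimited token as the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(Biostrings::DNAStringSet(toupper(seqs)), flavor)
}

#' Write a genome assembly to FASTA (80-column wrapped)
#'
#' @param genome a `genome_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$contigs, path, width = 80)
  invisible(path)
}

#' Read IES annotations from GFF3
#'
#' Features are converted from GFF3's 1-based inclusive coordinates to the
#' package-internal 0-based half-open convention, validated against the
#' reference and returned sorted by contig then start.
#'
#' @param path path to a GFF3 file of IES features (attribute `ID` used as
#'   the IES identifier).
#' @param genome the MAC+IES `genome_assembly` the annotations refer to.
#' @return a tibble with columns `ies_id`, `contig`, `start`, `end`
#'   (0-based half-open) and `length`.
#' @export
load_ies_annotations <- function(path, genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  if (genome$flavor != "MAC_PLUS_IES") {
    stop("IES annotations must be loaded against a MAC_PLUS_IES genome")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("every IES feature needs an ID attribute")
  }
  ann <- tibble::tibble(
    ies_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr)
  )
  ann$length <- ann$end - ann$start
  validate_annotations(ann, genome)
}

validate_annotations <- function(ann, genome) {
  if (anyDuplicated(ann$ies_id)) {
    stop("duplicate IES IDs: ",
         paste(unique(ann$ies_id[duplicated(ann$ies_id)]), collapse = ", "))
  }
  clen <- contig_lengths(genome)
  unknown <- setdiff(ann$contig, names(clen))
  if (length(unknown)) stop("annotation on unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  bad <- ann$start < 0 | ann$end <= ann$start | ann$end > clen[ann$contig]
  if (any(bad)) {
    stop("IES interval(s) outside contig bounds: ",
         paste(ann$ies_id[bad], collapse = ", "))
  }
  if (any(ann$length < 20)) {
    warning(sum(ann$length < 20), " IES(s) shorter than 20 bp")
  }
  dplyr::arrange(ann, .data$contig, .data$start)
}

#' Write IES annotations as GFF3
#'
#' @param annotations IES annotation tibble (0-based half-open coordinates).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_ies_gff3 <- function(annotations, path, source = "iestools") {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\t%s\tinternal_eliminated_sequence\t%d\t%d\t.\t+\t.\tID=%s",
            annotations$contig, source,
            annotations$start + 1L, annotations$end,
            annotations$ies_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Check that annotated IESs carry the canonical TA boundary structure
#'
#' An IES passes when its interval begins with `TA` and the reference carries
#' a second `TA` immediately downstream of the interval (the copy retained at
#' the somatic junction after excision). Failures are reported, never raised.
#'
#' @param genome the MAC+IES `genome_assembly`.
#' @param annotations IES annotation tibble.
#' @return a tibble `ies_id`, `pass`, `reason` (`""` when passing; otherwise
#'   `"no left TA"`, `"no right TA"` or `"truncated"`).
#' @export
validate_ta_boundaries <- function(genome, annotations) {
  stopifnot(genome$flavor == "MAC_PLUS_IES")
  clen <- contig_lengths(genome)
  purrr::pmap_dfr(
    annotations[, c("ies_id", "contig", "start", "end")],
    function(ies_id, contig, start, end) {
      seq <- contig_string(genome, contig)
      if (end + 2L > clen[[contig]]) {
        return(tibble::tibble(ies_id = ies_id, pass = FALSE,
                              reason = "truncated"))
      }
      left  <- substr(seq, start + 1L, start + 2L)
      right <- substr(seq, end + 1L, end + 2L)
      reason <- if (left != "TA") "no left TA"
        else if (right != "TA") "no right TA"
        else ""
      tibble::tibble(ies_id = ies_id, pass = reason == "", reason = reason)
    }
  )
}

#' Write a TA-boundary validation report as TSV
#'
#' @param report tibble from [validate_ta_boundaries()].
#' @param path output path.
#' @export
write_validation_tsv <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}

#' Enumerate TA dinucleotide sites in a window
#'
#' Returns every 0-based position `p` inside the window with
#' `sequence[p:p+2] == "TA"`. `N` bases never match.
#'
#' @param genome a `genome_assembly`.
#' @param contig contig name.
#' @param window_start,window_end 0-based half-open window; defaults to the
#'   whole contig.
#' @return sorted integer vector of 0-based site positions.
#' @export
enumerate_ta_sites <- function(genome, contig, window_start = 0L,
                               window_end = NULL) {
  seq <- contig_string(genome, contig)
  n <- nchar(seq)
  if (is.null(window_end)) window_end <- n
  if (window_start < 0 || window_end > n || window_start > window_end) {
    stop("window [", window_start, ",", window_end, ") out of bounds for ",
         contig, " (length ", n, ")")
  }
  if (window_end - window_start < 2L) return(integer(0))
  sub <- substr(seq, window_start + 1L, window_end)
  hits <- Biostrings::matchPattern("TA", Biostrings::DNAString(sub),
                                   fixed = TRUE)
  sort(unique(as.integer(IRanges::start(hits)) - 1L + window_start))
}

#' Build a coordinate map between MAC+IES and MAC coordinates
#'
#' @param annotations IES annotation tibble on the MAC+IES assembly.
#' @return a `coordinate_map` object (per-contig sorted IES intervals with
#'   cumulative deleted lengths).
#' @export
coordinate_map <- function(annotations) {
  by_contig <- lapply(
    split(annotations, annotations$contig),
    function(d) {
      d <- dplyr::arrange(d, .data$start)
      d$cum_before <- cumsum(dplyr::lag(d$length, default = 0L))
      d
    }
  )
  structure(list(ies = by_contig), class = "coordinate_map")
}

#' Project MAC+IES positions to MAC coordinates
#'
#' Positions strictly inside an IES interval have no somatic image; they are
#' returned as `NA` (or raise an error with `strict = TRUE`) rather than
#' being clamped.
#'
#' @param cm a `coordinate_map`.
#' @param contig contig name (recycled against `pos`).
#' @param pos integer vector of 0-based MAC+IES positions.
#' @param strict error on IES-internal positions instead of returning `NA`.
#' @return integer vector of 0-based MAC positions, `NA` where undefined.
#' @export
project_to_mac <- function(cm, contig, pos, strict = FALSE) {
  stopifnot(inherits(cm, "coordinate_map"))
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n)
  pos <- rep_len(as.integer(pos), n)
  out <- integer(n)
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    d <- cm$ies[[ct]]
    if (is.null(d) || nrow(d) == 0) {
      out[idx] <- pos[idx]
      next
    }
    # index of the last IES starting at or before pos
    k <- findInterval(pos[idx], d$start)
    k1 <- pmax(k, 1L)
    inside <- k > 0 & pos[idx] >= d$start[k1] & pos[idx] < d$end[k1]
    # total IES length strictly upstream of pos
    upstream <- ifelse(k == 0, 0L,
                       d$cum_before[k1] +
                         ifelse(pos[idx] >= d$end[k1], d$length[k1], 0L))
    mac <- pos[idx] - upstream
    mac[inside] <- NA_integer_
    out[idx] <- mac
  }
  if (strict && anyNA(out)) {
    stop("position(s) inside an IES have no MAC coordinate")
  }
  out
}
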