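#' Read gapped alignments from SAM or BAM into a tibble
#'
#' Secondary, supplementary and unmapped records are dropped, as are records
#' below the mapping-quality cutoff. SAM input is converted to BAM
#' internally (via [Rsamtools::asBam()]); positions are returned 0-based.
#'
#' @param path path to a SAM or BAM file.
#' @param min_mapq minimum mapping quality (records with unavailable mapping
#'   quality, 255, are kept).
#' @return a tibble with one row per primary mapped record: `qname`, `flag`,
#'   `contig`, `pos` (0-based leftmost), `cigar`, `mapq`, `tlen`, `paired`,
#'   `proper_pair`, `mate` (1/2; 1 for single-end).
#' @export
read_alignments <- function(path, min_mapq = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq", "isize"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- is.na(res$mapq) | res$mapq == 255L | res$mapq >= min_mapq
  tibble::tibble(
    qname = res$qname[keep],
    flag = res$flag[keep],
    contig = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L,
    cigar = res$cigar[keep],
    mapq = res$mapq[keep],
    tlen = res$isize[keep],
    paired = bitwAnd(res$flag[keep], 1L) > 0L,
    proper_pair = bitwAnd(res$flag[keep], 2L) > 0L,
    mate = dplyr::if_else(bitwAnd(res$flag[keep], 128L) > 0L, 2L, 1L)
  )
}

#' Aligned reference blocks of each read
#'
#' Expands CIGAR strings into per-read aligned (M/=/X) reference intervals,
#' excluding deletions and skips.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @return a tibble `read_idx` (row index into `aln`), `qname`, `contig`,
#'   `start`, `end` (0-based half-open aligned block).
#' @export
aligned_blocks <- function(aln) {
  if (nrow(aln) == 0) {
    return(tibble::tibble(read_idx = integer(0), qname = character(0),
                          contig = character(0), start = integer(0),
                          end = integer(0)))
  }
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos + 1L, ops = c("M", "=", "X"),
    reduce.ranges = TRUE
  )
  n <- S4Vectors::elementNROWS(rl)
  flat <- unlist(rl, use.names = FALSE)
  idx <- rep(seq_len(nrow(aln)), n)
  tibble::tibble(
    read_idx = idx,
    qname = aln$qname[idx],
    contig = aln$contig[idx],
    start = IRanges::start(flat) - 1L,
    end = IRanges::end(flat)
  )
}
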