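# Per-base coverage of unique-mapping reads from SAM/BAM alignments,
# and NPKM (nucleotide activity per kilobase per million mapped
# nucleotides) normalization.

#' Per-base coverage profile from a SAM/BAM file
#'
#' Reads a read mapping and accumulates per-base depth over each read's
#' aligned reference positions (CIGAR `M`/`=`/`X` consume the
#' reference; insertions and clips do not). Only uniquely placed reads
#' contribute to depth: records flagged secondary or supplementary, or
#' with mapping quality 0 (the usual multi-mapper convention), are
#' excluded. Unmapped reads are counted but never contribute.
#'
#' @param path SAM (text) or BAM file. SAM input must carry a `@SQ`
#'   header line.
#' @param genome A [pp_genome()]; the header's sequence name and length
#'   must match.
#' @return A `pp_coverage` list: `genome_id`, `depth` (an
#'   [S4Vectors::Rle] of length `genome$length`), `total_aligned_nt`,
#'   `n_mapped` (primary mapped records), `n_unique` (records
#'   contributing to depth), `n_unmapped`.
#' @export
coverage_from_sam <- function(path, genome) {
  stopifnot(inherits(genome, "pp_genome"), file.exists(path))
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hdr) != 1L) stop("expected exactly one reference sequence in SAM header")
  if (names(hdr)[1L] != genome$id || unname(hdr[1L]) != genome$length) {
    stop(sprintf("SAM header (%s, %d bp) does not match genome (%s, %d bp)",
                 names(hdr)[1L], hdr[1L], genome$id, genome$length))
  }
  cnt <- function(flag, mapq = NA_integer_) {
    Rsamtools::countBam(bam, param = Rsamtools::ScanBamParam(
      flag = flag, mapqFilter = mapq))$records
  }
  n_unmapped <- cnt(Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  primary <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
  n_mapped <- cnt(primary)
  galn <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = primary, mapqFilter = 1L))
  cvg <- GenomicAlignments::coverage(galn)[[genome$id]]
  if (length(cvg) != genome$length) {
    cvg <- c(cvg, S4Vectors::Rle(0L, genome$length - length(cvg)))
  }
  structure(
    list(genome_id = genome$id, depth = cvg, length = genome$length,
         total_aligned_nt = sum(as.numeric(S4Vectors::runLength(cvg)) *
                                  as.numeric(S4Vectors::runValue(cvg))),
         n_mapped = n_mapped, n_unique = length(galn),
         n_unmapped = n_unmapped),
    class = "pp_coverage")
}

#' @export
print.pp_coverage <- function(x, ...) {
  cat(sprintf("<pp_coverage> %s: %s bp, %s aligned nt (mean depth %.2f), %s mapped / %s unmapped reads\n",
              x$genome_id, format(x$length, big.mark = ","),
              format(x$total_aligned_nt, big.mark = ","),
              x$total_aligned_nt / x$length,
              format(x$n_mapped, big.mark = ","),
              format(x$n_unmapped, big.mark = ",")))
  invisible(x)
}

# Sum of depth over a 1-based inclusive interval.
depth_sum <- function(profile, start, end) {
  v <- S4Vectors::window(profile$depth, start, end)
  sum(as.numeric(S4Vectors::runLength(v)) * as.numeric(S4Vectors::runValue(v)))
}

#' NPKM of a region
#'
#' NPKM (nucleotide activity per kilobase per million mapped
#' nucleotides) normalizes a region's coverage for region length and
#' sequencing depth:
#' `NPKM = (aligned nt in region / region length in kb) /
#'         (total aligned nt / 1e6)`.
#' A region on a uniformly covered genome gets the same NPKM whatever
#' its size.
#'
#' @param profile A `pp_coverage` from [coverage_from_sam()].
#' @param start,end Region coordinates, 1-based inclusive.
#' @return The NPKM value (numeric scalar).
#' @export
npkm <- function(profile, start, end) {
  stopifnot(inherits(profile, "pp_coverage"))
  if (profile$total_aligned_nt <= 0) stop("no aligned nucleotides in profile")
  if (start < 1L || end > profile$length || start > end) {
    stop("invalid region coordinates")
  }
  nt <- depth_sum(profile, start, end)
  (nt / ((end - start + 1) / 1000)) / (profile$total_aligned_nt / 1e6)
}

#' Windowed NPKM track
#'
#' Tiles the genome with non-overlapping windows from base 1 and
#' computes each window's NPKM; the final partial window keeps its true
#' length in the kilobase normalization. The kb-length-weighted sum of
#' all window NPKMs is exactly 1e6.
#'
#' @param profile A `pp_coverage`.
#' @param window Window size in bp (>= 100); default 1000.
#' @return Data frame with columns `start`, `end`, `npkm`; attribute
#'   `window` carries the window size.
#' @export
windowed_npkm <- function(profile, window = 1000L) {
  stopifnot(inherits(profile, "pp_coverage"))
  window <- as.integer(window)
  if (window < 100L) stop("window must be >= 100 bp")
  if (profile$total_aligned_nt <= 0) stop("no aligned nucleotides in profile")
  L <- profile$length
  starts <- seq.int(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  depth <- as.numeric(profile$depth)
  cs <- c(0, cumsum(depth))
  nt <- cs[ends + 1L] - cs[starts]
  vals <- (nt / ((ends - starts + 1) / 1000)) / (profile$total_aligned_nt / 1e6)
  structure(data.frame(start = starts, end = ends, npkm = vals),
            window = window)
}

#' Write an NPKM track as bedGraph
#'
#' @param track Data frame from [windowed_npkm()].
#' @param genome_id Reference name for the bedGraph chrom column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, genome_id, path) {
  lines <- sprintf("%s\t%d\t%d\t%.6g", genome_id, track$start - 1L,
                   track$end, track$npkm)
  writeLines(c("track type=bedGraph name=NPKM", lines), path)
  invisible(path)
}
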