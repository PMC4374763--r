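#' Find direct repeats flanking a putative prophage region
#'
#' Integration of a temperate phage by site-specific recombination
#' leaves direct repeats (attL/attR) at the prophage boundaries. This
#' scans a window of `flank` bp on each side of the region boundaries
#' (positions `start-flank .. start+flank-1` and
#' `end-flank .. end+flank-1`, clipped to the genome) for the best
#' ungapped match: among equal-length substring pairs that begin and
#' end with a matching position (trimmed-alignment convention) and have
#' at most `max_mismatch_frac` mismatching positions, the pair with
#' the most matches wins; ties go to fewer mismatches, then position.
#'
#' @param genome A [pp_genome()].
#' @param start,end Region coordinates, 1-based inclusive.
#' @param flank Window half-width in bp; default 500.
#' @param min_len Minimum repeat length; default 15.
#' @param max_mismatch_frac Maximum mismatch fraction; default 0.10.
#' @return `NULL` when no qualifying match; otherwise a list with
#'   `length`, `mismatches`, `left_start`, `right_start` (genome
#'   coordinates of the two copies) and `notation` in the conventional
#'   form `"18 bp"` / `"61 -6 bp"` (length, then mismatch count).
#' @export
find_flanking_repeats <- function(genome, start, end, flank = 500L,
                                  min_len = 15L, max_mismatch_frac = 0.10) {
  stopifnot(inherits(genome, "pp_genome"))
  flank <- as.integer(flank)
  L <- genome$length
  a1 <- max(1L, start - flank); a2 <- min(L, start + flank - 1L)
  b1 <- max(1L, end - flank); b2 <- min(L, end + flank - 1L)
  if ((a1 > start - flank || a2 < start + flank - 1L ||
       b1 > end - flank || b2 < end + flank - 1L)) {
    warning("flank windows clipped at genome boundary")
  }
  wa <- extract_region(genome, a1, a2)
  wb <- extract_region(genome, b1, b2)
  hit <- .best_repeat_cpp(wa, wb, as.integer(min_len), max_mismatch_frac)
  if (hit[3L] == 0L) return(NULL)
  list(length = hit[3L], mismatches = hit[4L],
       left_start = a1 + hit[1L] - 1L, right_start = b1 + hit[2L] - 1L,
       notation = if (hit[4L] == 0L) sprintf("%d bp", hit[3L]) else
         sprintf("%d -%d bp", hit[3L], hit[4L]))
}
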