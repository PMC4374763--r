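#' Call open reading frames on both strands
#'
#' Scans all six reading frames for maximal ORFs using the bacterial
#' convention: start codons `ATG`, `GTG`, `TTG`; stop codons `TAA`,
#' `TAG`, `TGA`; translation table 11 (alternative starts reported as
#' `M`). For each stop codon the longest ORF (earliest in-frame start
#' after the previous stop) is reported.
#'
#' @param genome A [pp_genome()].
#' @param min_aa Minimum protein length in amino acids (stop excluded);
#'   default 50, minimum 30.
#' @return A data frame with columns `orf_id`, `start`, `end` (1-based
#'   inclusive genome coordinates, `start < end` on both strands),
#'   `strand`, `protein`, sorted by `start`.
#' @export
call_orfs <- function(genome, min_aa = 50L) {
  stopifnot(inherits(genome, "pp_genome"))
  min_aa <- as.integer(min_aa)
  if (min_aa < 30L) stop("min_aa must be >= 30")
  L <- genome$length
  fwd <- as.character(genome$seq)
  rev <- as.character(Biostrings::reverseComplement(genome$seq))

  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 0:2) {
      starts_bp <- seq.int(frame + 1L, L - 2L, by = 3L)
      if (length(starts_bp) == 0L) next
      codons <- substring(s, starts_bp, starts_bp + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_start <- codons %in% c("ATG", "GTG", "TTG")
      stop_idx <- which(is_stop)
      if (length(stop_idx) == 0L) next
      prev_stop <- c(0L, stop_idx[-length(stop_idx)])
      start_idx <- which(is_start)
      for (k in seq_along(stop_idx)) {
        cand <- start_idx[start_idx > prev_stop[k] & start_idx < stop_idx[k]]
        if (length(cand) == 0L) next
        i1 <- cand[1L]; i2 <- stop_idx[k]
        n_aa <- i2 - i1            # codons before the stop
        if (n_aa < min_aa) next
        aa <- Biostrings::GENETIC_CODE[codons[i1:(i2 - 1L)]]
        aa[1L] <- "M"
        bp1 <- starts_bp[i1]; bp2 <- starts_bp[i2] + 2L
        if (strand == "+") {
          coords <- c(bp1, bp2)
        } else {
          coords <- c(L - bp2 + 1L, L - bp1 + 1L)
        }
        out[[length(out) + 1L]] <- list(
          start = coords[1L], end = coords[2L], strand = strand,
          protein = paste(aa, collapse = ""))
      }
    }
    out
  }

  orfs <- c(scan_strand(fwd, "+"), scan_strand(rev, "-"))
  if (length(orfs) == 0L) {
    return(data.frame(orf_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    start = vapply(orfs, `[[`, integer(1), "start"),
    end = vapply(orfs, `[[`, integer(1), "end"),
    strand = vapply(orfs, `[[`, character(1), "strand"),
    protein = vapply(orfs, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  df <- cbind(orf_id = sprintf("orf_%05d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
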