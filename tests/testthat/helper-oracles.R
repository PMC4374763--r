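# Independent oracles, deliberately written differently from the
# package implementations they check.

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Affine-gap global alignment score by memoized recursion over suffix
# pairs; state encodes whether the previous column was a gap (and in
# which sequence), so gap opening is charged exactly once per gap.
oracle_align_score <- function(a, b, sub = blosum62_matrix,
                               open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, sub[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(A)) {
      cost <- if (state == 1L) ext else open + ext
      best <- max(best, rec(i + 1L, j, 1L) - cost)
    }
    if (j <= length(B)) {
      cost <- if (state == 2L) ext else open + ext
      best <- max(best, rec(i, j + 1L, 2L) - cost)
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# Exhaustive substring-pair search for the best ungapped repeat match:
# every (start_a, start_b, length) triple is scored directly.
oracle_best_repeat <- function(a, b, min_len = 15L,
                               max_mismatch_frac = 0.10) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  best <- NULL
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      maxL <- min(length(A) - i, length(B) - j) + 1L
      if (maxL < min_len) next
      for (L in min_len:maxL) {
        x <- A[i:(i + L - 1L)]
        y <- B[j:(j + L - 1L)]
        if (x[1L] != y[1L] || x[L] != y[L]) next
        mm <- sum(x != y)
        if (mm / L > max_mismatch_frac) next
        cand <- c(match = L - mm, mm = mm, i = i, j = j, len = L)
        if (is.null(best) ||
            cand["match"] > best["match"] ||
            (cand["match"] == best["match"] &&
             (cand["mm"] < best["mm"] ||
              (cand["mm"] == best["mm"] &&
               (cand["i"] < best["i"] ||
                (cand["i"] == best["i"] && cand["j"] < best["j"])))))) {
          best <- cand
        }
      }
    }
  }
  best
}

# Brute-force in-silico PCR: every (forward site, reverse site) pair on
# both strands, checked by direct substring comparison.
oracle_pcr <- function(seq, fwd, rev, max_product = 5000L) {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  scan <- function(template) {
    lens <- integer(0)
    lf <- nchar(fwd); lr <- nchar(rev)
    site <- rc(rev)
    n <- nchar(template)
    for (p in seq_len(n - lf + 1L)) {
      if (substr(template, p, p + lf - 1L) != fwd) next
      for (q in seq_len(n - lr + 1L)) {
        if (substr(template, q, q + lr - 1L) != site) next
        len <- (q + lr - 1L) - p + 1L
        if (len >= lf && len >= lr && len <= max_product) {
          lens <- c(lens, len)
        }
      }
    }
    lens
  }
  sort(c(scan(seq), scan(rc(seq))))
}

random_protein <- function(n) {
  paste(c("M", sample(prophactr:::AA20, n - 1L, replace = TRUE)),
        collapse = "")
}

random_dna_str <- function(n, gc = 50) {
  p <- c(gc, 100 - gc)
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(p[1], p[1], p[2], p[2]) / 200),
        collapse = "")
}

# Minimal hand-written SAM file from a record table.
write_test_sam <- function(path, genome_id, genome_len, records) {
  lines <- c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", genome_id, genome_len),
    vapply(records, function(r) {
      seq <- if (is.null(r$seq)) strrep("A", r$len) else r$seq
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
              r$qname, r$flag,
              if (bitwAnd(r$flag, 4L) > 0L) "*" else genome_id,
              if (bitwAnd(r$flag, 4L) > 0L) 0L else r$pos,
              if (is.null(r$mapq)) 42L else r$mapq,
              if (bitwAnd(r$flag, 4L) > 0L) "*" else r$cigar,
              seq, strrep("I", nchar(seq)))
    }, character(1)))
  writeLines(lines, path)
  path
}

# Coverage profile built directly from a depth vector (for formula
# tests that do not need a SAM round trip).
profile_from_depth <- function(depth, genome_id = "g") {
  structure(
    list(genome_id = genome_id, depth = S4Vectors::Rle(as.integer(depth)),
         length = length(depth),
         total_aligned_nt = sum(depth),
         n_mapped = NA_integer_, n_unique = NA_integer_,
         n_unmapped = 0L),
    class = "pp_coverage")
}
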