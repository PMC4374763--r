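# Global protein alignment and best-hit classification.
#
# The alignment currency throughout the package is the EMBOSS-needle
# style pair (identity, similarity) computed on a full-length global
# alignment: identity = % of alignment columns with identical residues,
# similarity = % of columns whose residue pair has a positive
# substitution-matrix score. Classification keeps only hits with
# similarity >= 30% on the full-length alignment.

the_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(the_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the_cache$BLOSUM62 <- e$BLOSUM62
  }
  the_cache$BLOSUM62
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' End-to-end alignment of two amino-acid sequences under BLOSUM62 with
#' affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`), including end gaps, via the Gotoh
#' three-state dynamic program.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param gap_open,gap_extend Gap penalties; defaults 10 and 0.5.
#' @param matrix Substitution matrix with residue dimnames; default
#'   BLOSUM62.
#' @return A `pp_alignment` list: `score`, `identity` (%), `similarity`
#'   (% of columns with positive substitution score), `aligned_length`,
#'   `full_length` (always `TRUE` for global alignment), and the two
#'   gapped strings `aligned_a`, `aligned_b`.
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         matrix = NULL) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (is.null(matrix)) matrix <- blosum62()
  alphabet <- paste(rownames(matrix), collapse = "")
  # canonical argument order: co-optimal alignments are resolved by a
  # fixed traceback preference, so orienting the pair makes identity
  # and similarity exactly symmetric in (a, b)
  swapped <- a > b
  res <- if (swapped) {
    r <- .gotoh_align_cpp(b, a, matrix, alphabet, gap_open, gap_extend)
    list(score = r$score, aligned_a = r$aligned_b, aligned_b = r$aligned_a)
  } else {
    .gotoh_align_cpp(a, b, matrix, alphabet, gap_open, gap_extend)
  }
  ca <- strsplit(res$aligned_a, "")[[1L]]
  cb <- strsplit(res$aligned_b, "")[[1L]]
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- sum(both & ca == cb)
  simil <- sum(matrix[cbind(ca[both], cb[both])] > 0)
  structure(
    list(score = res$score,
         identity = 100 * ident / len,
         similarity = 100 * simil / len,
         aligned_length = len,
         full_length = TRUE,
         aligned_a = res$aligned_a,
         aligned_b = res$aligned_b),
    class = "pp_alignment")
}

#' @export
print.pp_alignment <- function(x, ...) {
  cat(sprintf("<pp_alignment> score %.1f, identity %.1f%%, similarity %.1f%%, length %d\n",
              x$score, x$identity, x$similarity, x$aligned_length))
  invisible(x)
}

#' Similarity score classes
#'
#' Bins percent-similarity scores into the four reporting classes used
#' for inter-region protein comparison: `none` (0-25], `low` (25-50],
#' `medium` (50-75], `high` (75-100]. A score of exactly 25 is `none`,
#' 50 is `low`, 75 is `medium`.
#'
#' @param score Numeric vector of percent similarities in \[0, 100\].
#' @return Factor with levels `none`, `low`, `medium`, `high`.
#' @export
similarity_class <- function(score) {
  cut(score, breaks = c(-Inf, 25, 50, 75, Inf),
      labels = c("none", "low", "medium", "high"), right = TRUE)
}

# Best surviving database hit for one protein. Ties on similarity are
# broken by raw score, then subject length, then lexicographic id, so
# the result is invariant under database record order.
best_hit_for <- function(protein, db, index, min_similarity,
                         gap_open = 10, gap_extend = 0.5, k = 4L,
                         min_seeds = 2L) {
  cand <- seed_candidates(protein, index, k = k, min_seeds = min_seeds)
  if (length(cand) == 0L) return(NULL)
  hits <- lapply(cand, function(i) {
    al <- global_align(protein, db$seq[i], gap_open, gap_extend)
    list(i = i, similarity = al$similarity, score = al$score)
  })
  sim <- vapply(hits, `[[`, numeric(1), "similarity")
  keep <- sim >= min_similarity
  if (!any(keep)) return(NULL)
  hits <- hits[keep]
  sim <- sim[keep]
  sc <- vapply(hits, `[[`, numeric(1), "score")
  ii <- vapply(hits, `[[`, integer(1), "i")
  ord <- order(-sim, -sc, -nchar(db$seq[ii]), db$id[ii])
  best <- ord[1L]
  list(db_index = ii[best], similarity = sim[best], score = sc[best])
}

#' Classify a prophage region by best-hit voting
#'
#' Each region protein is searched against the phage protein database
#' (k-mer seeded, then globally aligned); hits with full-length
#' similarity below `min_similarity` are discarded. The best surviving
#' hit per protein votes for its source phage; the region is assigned
#' to the phage with the most votes. The top fraction is computed over
#' *all* region proteins, including those without a surviving hit.
#'
#' @param region_proteins Named character vector of amino-acid
#'   sequences (names are protein ids).
#' @param db Phage protein database ([read_phage_db()]).
#' @param min_similarity Percent similarity cutoff; default 30.
#' @param region_label Label carried into the result.
#' @param gap_open,gap_extend Alignment penalties, see [global_align()].
#' @return A `pp_region_classification` list: `region_label`,
#'   `top_phage` (`"unclassified"` when no protein has a surviving
#'   hit), `top_fraction` (%), `family_votes` (named integer vector),
#'   and `best_hits` (one row per protein with a surviving hit).
#' @export
classify_region <- function(region_proteins, db, min_similarity = 30,
                            region_label = "region",
                            gap_open = 10, gap_extend = 0.5) {
  if (length(region_proteins) == 0L) stop("empty protein list")
  if (is.null(names(region_proteins))) {
    names(region_proteins) <- sprintf("p%03d", seq_along(region_proteins))
  }
  index <- kmer_index(db$seq)
  rows <- list()
  for (qid in names(region_proteins)) {
    bh <- best_hit_for(region_proteins[[qid]], db, index, min_similarity,
                       gap_open, gap_extend)
    if (is.null(bh)) next
    i <- bh$db_index
    rows[[qid]] <- data.frame(
      query_id = qid, subject_id = db$id[i], subject_phage = db$phage[i],
      subject_family = db$family[i], similarity = bh$similarity,
      score = bh$score, stringsAsFactors = FALSE)
  }
  best_hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), subject_id = character(0),
               subject_phage = character(0), subject_family = character(0),
               similarity = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  rownames(best_hits) <- NULL
  n_total <- length(region_proteins)
  if (nrow(best_hits) == 0L) {
    top_phage <- "unclassified"; top_fraction <- 0
    family_votes <- integer(0)
  } else {
    votes <- table(best_hits$subject_phage)
    # ties on vote count resolved lexicographically for reproducibility
    votes <- votes[order(-as.integer(votes), names(votes))]
    top_phage <- names(votes)[1L]
    top_fraction <- 100 * as.integer(votes)[1L] / n_total
    fv <- table(best_hits$subject_family)
    family_votes <- stats::setNames(as.integer(fv), names(fv))
  }
  structure(
    list(region_label = region_label, top_phage = top_phage,
         top_fraction = top_fraction, family_votes = family_votes,
         n_proteins = n_total, best_hits = best_hits),
    class = "pp_region_classification")
}

#' @export
print.pp_region_classification <- function(x, ...) {
  cat(sprintf("<region classification> %s: top phage %s (%.1f%% of %d proteins)\n",
              x$region_label, x$top_phage, x$top_fraction, x$n_proteins))
  invisible(x)
}

#' All-against-all protein comparison between prophage regions
#'
#' For every protein of every region, finds the best-matching protein
#' in each *other* region (k-mer seed gate, then global alignment) and
#' reports its percent similarity with the four-class binning of
#' [similarity_class()]. The comparison is directional: paralogs can
#' make A-vs-B differ from B-vs-A. Scores above 30 are flagged
#' significant.
#'
#' @param regions Named list; each element a named character vector of
#'   protein sequences for one region.
#' @param gap_open,gap_extend Alignment penalties.
#' @return Data frame with columns `region_a`, `protein_a`, `region_b`,
#'   `protein_b` (`NA` when no alignment was attempted), `score`,
#'   `class`, `significant`.
#' @export
compare_regions <- function(regions, gap_open = 10, gap_extend = 0.5) {
  if (length(regions) < 2L) stop("need at least 2 regions")
  if (is.null(names(regions))) {
    names(regions) <- sprintf("region_%d", seq_along(regions))
  }
  regions <- lapply(regions, function(p) {
    if (is.null(names(p))) names(p) <- sprintf("p%03d", seq_along(p))
    p
  })
  out <- list()
  for (ra in names(regions)) {
    for (rb in setdiff(names(regions), ra)) {
      db <- data.frame(id = names(regions[[rb]]),
                       seq = unname(regions[[rb]]),
                       stringsAsFactors = FALSE)
      index <- kmer_index(db$seq)
      for (qid in names(regions[[ra]])) {
        bh <- best_hit_for(regions[[ra]][[qid]], db, index,
                           min_similarity = 0,
                           gap_open, gap_extend)
        score <- if (is.null(bh)) 0 else bh$similarity
        pb <- if (is.null(bh)) NA_character_ else db$id[bh$db_index]
        out[[length(out) + 1L]] <- data.frame(
          region_a = ra, protein_a = qid, region_b = rb, protein_b = pb,
          score = score, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  df$class <- similarity_class(df$score)
  df$significant <- df$score > 30
  rownames(df) <- NULL
  df
}
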