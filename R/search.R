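# Candidate prophage prediction: seeded homology search of called ORFs
# against a phage protein database, then genomic clustering of hits.
# The k-mer seed gate (shared exact 4-mers) stands in for a BLASTP
# prefilter: only seeded pairs are globally aligned, and the paper's
# downstream cutoff (full-length similarity >= 30%) decides which hits
# survive.

# Hash index: amino-acid k-mer -> integer indices of database records.
kmer_index <- function(seqs, k = 4L) {
  env <- new.env(parent = emptyenv(), size = max(16L, 4L * length(seqs)))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1L), k:n))
    for (km in kmers) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  attr(env, "k") <- k
  env
}

# Database records sharing >= min_seeds distinct k-mers with the query.
seed_candidates <- function(query, index, k = 4L, min_seeds = 2L) {
  n <- nchar(query)
  if (n < k) return(integer(0))
  kmers <- unique(substring(query, 1:(n - k + 1L), k:n))
  hit_lists <- lapply(kmers, function(km) index[[km]])
  counts <- table(unlist(hit_lists))
  as.integer(names(counts)[counts >= min_seeds])
}

#' Search called ORFs against a phage protein database
#'
#' Candidate pairs are found by shared amino-acid 4-mers (at least two
#' distinct seeds) and then globally aligned ([global_align()]); hits
#' whose full-length similarity falls below `min_similarity` are
#' discarded. All surviving hits are returned.
#'
#' @param orfs ORF data frame from [call_orfs()].
#' @param db Phage protein database ([read_phage_db()]).
#' @param min_similarity Percent similarity cutoff; default 30.
#' @param gap_open,gap_extend Alignment penalties.
#' @return Data frame with one row per surviving (ORF, record) pair:
#'   `orf_id`, `orf_start`, `orf_end`, `midpoint` (floor of the ORF
#'   coordinate mean), `db_id`, `phage`, `family`, `similarity`,
#'   `score`.
#' @export
search_phage_proteins <- function(orfs, db, min_similarity = 30,
                                  gap_open = 10, gap_extend = 0.5) {
  if (nrow(db) == 0L) stop("empty phage protein database")
  empty <- data.frame(orf_id = character(0), orf_start = integer(0),
                      orf_end = integer(0), midpoint = integer(0),
                      db_id = character(0), phage = character(0),
                      family = character(0), similarity = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(orfs) == 0L) return(empty)
  index <- kmer_index(db$seq)
  out <- list()
  for (r in seq_len(nrow(orfs))) {
    cand <- seed_candidates(orfs$protein[r], index)
    if (length(cand) == 0L) next
    for (i in cand) {
      al <- global_align(orfs$protein[r], db$seq[i], gap_open, gap_extend)
      if (al$similarity < min_similarity) next
      out[[length(out) + 1L]] <- data.frame(
        orf_id = orfs$orf_id[r], orf_start = orfs$start[r],
        orf_end = orfs$end[r],
        midpoint = (orfs$start[r] + orfs$end[r]) %/% 2L,
        db_id = db$id[i], phage = db$phage[i], family = db$family[i],
        similarity = al$similarity, score = al$score,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  df <- do.call(rbind, out)
  df <- df[order(df$midpoint, df$db_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cluster protein hits into candidate prophage regions
#'
#' Hits are sorted by genomic midpoint and chained greedily while the
#' gap between consecutive midpoints is at most `max_spacing`; chains
#' with at least `min_hits` hits become candidates spanning the first
#' to the last hit ORF. Clustering is strand-agnostic.
#'
#' @param hits Hit data frame from [search_phage_proteins()].
#' @param max_spacing Maximum midpoint-to-midpoint gap in bp; default
#'   5500.
#' @param min_hits Minimum hits per candidate; default 5.
#' @return Region data frame with columns `label`, `start`, `end`,
#'   `n_hits`, `hit_ids` (comma-separated ORF ids).
#' @export
cluster_hits <- function(hits, max_spacing = 5500L, min_hits = 5L) {
  empty <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), n_hits = integer(0),
                      hit_ids = character(0), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$midpoint), , drop = FALSE]
  gap <- c(0L, diff(hits$midpoint))
  chain <- cumsum(gap > max_spacing)
  out <- list()
  for (cid in unique(chain)) {
    part <- hits[chain == cid, , drop = FALSE]
    if (nrow(part) < min_hits) next
    out[[length(out) + 1L]] <- data.frame(
      start = min(part$orf_start), end = max(part$orf_end),
      n_hits = nrow(part),
      hit_ids = paste(unique(part$orf_id), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  df <- cbind(label = sprintf("candidate_%d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Predict candidate prophage regions in a genome
#'
#' End-to-end prediction: ORF calling, seeded phage-protein homology
#' search, and genomic clustering. To keep the hit count per locus
#' interpretable as "phage genes with database support", only the best
#' database hit per ORF enters the clustering step.
#'
#' @param genome A [pp_genome()].
#' @param db Phage protein database ([read_phage_db()]).
#' @param min_aa Minimum ORF protein length; default 50.
#' @param min_similarity Percent similarity cutoff; default 30.
#' @param max_spacing Maximum hit spacing in bp; default 5500.
#' @param min_hits Minimum hits per candidate; default 5.
#' @return Candidate region data frame, see [cluster_hits()].
#' @export
predict_prophages <- function(genome, db, min_aa = 50L,
                              min_similarity = 30, max_spacing = 5500L,
                              min_hits = 5L) {
  orfs <- call_orfs(genome, min_aa = min_aa)
  hits <- search_phage_proteins(orfs, db, min_similarity = min_similarity)
  if (nrow(hits) > 0L) {
    # best hit per ORF: highest similarity, ties by score then id
    ord <- order(hits$orf_id, -hits$similarity, -hits$score, hits$db_id)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$orf_id), , drop = FALSE]
  }
  cluster_hits(hits, max_spacing = max_spacing, min_hits = min_hits)
}
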