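#' Read a phage protein database
#'
#' The database is a protein FASTA whose headers carry three
#' pipe-separated fields: `id|phage_name|family` (family from the
#' standard phage taxonomy vocabulary, e.g. `Siphoviridae`,
#' `Myoviridae`, `Podoviridae`).
#'
#' @param path Protein FASTA file.
#' @return A data frame with columns `id`, `phage`, `family`, `seq`.
#' @export
read_phage_db <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty phage protein database: ", path)
  parts <- strsplit(sub("\\s.*$", "", names(set)), "|", fixed = TRUE)
  db <- data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    phage = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1)),
    family = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, character(1)),
    seq = as.character(set),
    stringsAsFactors = FALSE)
  if (anyDuplicated(db$id)) stop("duplicate record ids in phage database")
  rownames(db) <- NULL
  db
}

#' Write a phage protein database
#'
#' @param db Data frame with columns `id`, `phage`, `family`, `seq`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_phage_db <- function(db, path) {
  stopifnot(all(c("id", "phage", "family", "seq") %in% names(db)))
  set <- Biostrings::AAStringSet(db$seq)
  names(set) <- paste(db$id, db$phage, db$family, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
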