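#' Construct a genome object
#'
#' A genome is a single named nucleotide sequence, optionally circular.
#' Coordinates everywhere in this package are 1-based and fully closed
#' (GenBank convention), so a region `start..end` has length
#' `end - start + 1`.
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string over the alphabet `A,C,G,T,N`
#'   (lower case accepted, stored upper case).
#' @param circular Is the molecule circular? Bacterial chromosomes
#'   usually are; wrap-around regions are only valid when `TRUE`.
#' @return An object of class `pp_genome` with elements `id`, `seq`
#'   (a [Biostrings::DNAString]), `circular` and `length`.
#' @export
pp_genome <- function(id, sequence, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (methods::is(sequence, "DNAString")) {
    seq <- Biostrings::DNAString(toupper(as.character(sequence)))
  } else {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad)) {
      stop("sequence contains characters outside {A,C,G,T,N}: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
    }
    seq <- Biostrings::DNAString(sequence)
  }
  if (length(seq) == 0L) stop("empty sequence")
  structure(
    list(id = id, seq = seq, circular = isTRUE(circular),
         length = length(seq)),
    class = "pp_genome"
  )
}

#' @export
print.pp_genome <- function(x, ...) {
  cat(sprintf("<pp_genome> %s: %s bp, %s, GC %.2f%%\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              gc_content(as.character(x$seq))))
  invisible(x)
}

#' Load a genome from FASTA or GenBank
#'
#' Reads exactly one sequence record. Multi-record files are rejected:
#' the workflow operates on a single bacterial chromosome.
#'
#' @param path Path to a FASTA file or a GenBank flat file (format
#'   auto-detected from content).
#' @param circular Mark the genome as circular. For GenBank input the
#'   LOCUS line topology is used when `circular` is `NULL`.
#' @return A [pp_genome()] object.
#' @export
load_genome <- function(path, circular = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (startsWith(first, "LOCUS")) {
    rec <- read_genbank_seq(path)
    if (is.null(circular)) circular <- rec$circular
    pp_genome(rec$id, rec$sequence, circular = isTRUE(circular))
  } else if (startsWith(first, ">")) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("no sequence records in ", path)
    if (length(set) > 1L) {
      stop("expected exactly one sequence record, found ", length(set))
    }
    id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
    pp_genome(id, as.character(set[[1L]]), circular = isTRUE(circular))
  } else {
    stop("unrecognized file format (expected FASTA or GenBank): ", path)
  }
}

# Minimal GenBank flat-file sequence reader: LOCUS line for id/topology,
# ORIGIN block for the sequence. Feature annotation is ignored.
read_genbank_seq <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0L) stop("no LOCUS line in ", path)
  if (length(locus) > 1L) stop("expected exactly one GenBank record")
  fields <- strsplit(trimws(lines[locus]), "\\s+")[[1L]]
  id <- fields[2L]
  circular <- any(tolower(fields) == "circular")
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1L) stop("expected exactly one ORIGIN block")
  end <- grep("^//", lines)
  end <- end[end > ori][1L]
  if (is.na(end)) stop("unterminated ORIGIN block")
  body <- lines[seq.int(ori + 1L, end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  list(id = id, sequence = seq, circular = circular)
}

#' Extract a region's sequence
#'
#' Coordinates are 1-based inclusive. On circular genomes a wrapping
#' region (`start > end`) runs through the origin; on linear genomes it
#' is an error.
#'
#' @param genome A [pp_genome()].
#' @param start,end 1-based inclusive coordinates.
#' @return The region's nucleotide sequence as a character string.
#' @export
extract_region <- function(genome, start, end) {
  stopifnot(inherits(genome, "pp_genome"))
  start <- as.integer(start); end <- as.integer(end)
  L <- genome$length
  if (is.na(start) || is.na(end) || start < 1L || end < 1L ||
      start > L || end > L) {
    stop("region coordinates out of range [1, ", L, "]")
  }
  if (start <= end) {
    as.character(Biostrings::subseq(genome$seq, start, end))
  } else {
    if (!genome$circular) {
      stop("wrap-around region (start > end) on a linear genome")
    }
    paste0(as.character(Biostrings::subseq(genome$seq, start, L)),
           as.character(Biostrings::subseq(genome$seq, 1L, end)))
  }
}

#' Length of a 1-based inclusive region
#'
#' @param start,end Coordinates (vectors recycle).
#' @param genome_length Needed only for wrapping regions (`start > end`).
#' @return Integer region length(s), `end - start + 1` in the
#'   non-wrapping case.
#' @export
region_length <- function(start, end, genome_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  len <- end - start + 1L
  wrap <- start > end
  if (any(wrap)) {
    if (is.null(genome_length)) stop("genome_length required for wrapping regions")
    len[wrap] <- genome_length - start[wrap] + 1L + end[wrap]
  }
  len
}

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`. `N` bases are excluded from both
#' numerator and denominator, so assembly gaps do not bias the value.
#'
#' @param seq Nucleotide string (or `DNAString`).
#' @return GC percentage in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  s <- if (methods::is(seq, "DNAString")) seq else {
    s <- toupper(as.character(seq))
    if (!nzchar(s)) stop("empty sequence")
    Biostrings::DNAString(s)
  }
  counts <- Biostrings::alphabetFrequency(s)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence contains no A/C/G/T bases")
  100 * sum(counts[c("G", "C")]) / denom
}

#' In-silico PCR with exact primer matching
#'
#' Scans both strands of the template for exact occurrences of the
#' forward primer followed, within `max_product`, by an exact occurrence
#' of the reverse complement of the reverse primer. The product length
#' spans from the forward primer's 5' start to the reverse primer's 5'
#' start inclusive of both primers -- the usual amplicon length.
#'
#' @param genome A [pp_genome()] template.
#' @param forward,reverse Primer sequences, 5'->3', length >= 10.
#' @param max_product Maximum product size in bp (default 5000).
#' @return Integer vector of product lengths (empty when no product).
#' @export
in_silico_pcr <- function(genome, forward, reverse, max_product = 5000L) {
  stopifnot(inherits(genome, "pp_genome"))
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    stop("primers must be at least 10 nt")
  }
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    stop("primers must be over the alphabet {A,C,G,T}")
  }
  template <- genome$seq
  products <- integer(0)
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") template else Biostrings::reverseComplement(template)
    f_starts <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(forward), subj))
    r_site <- Biostrings::reverseComplement(Biostrings::DNAString(reverse))
    r_starts <- Biostrings::start(
      Biostrings::matchPattern(r_site, subj))
    if (length(f_starts) == 0L || length(r_starts) == 0L) next
    # 5' start of the bound reverse primer = 3' end of its site
    r_5prime <- r_starts + nchar(reverse) - 1L
    for (f in f_starts) {
      len <- r_5prime - f + 1L
      ok <- len >= nchar(forward) & len >= nchar(reverse) & len <= max_product
      products <- c(products, len[ok])
    }
  }
  sort(products)
}
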