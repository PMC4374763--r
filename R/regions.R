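#' Region tables
#'
#' Genomic regions travel as plain data frames with columns `label`,
#' `start`, `end` (1-based inclusive) and optionally `strand`. Two
#' on-disk formats are supported: a 4-column TSV in the native 1-based
#' inclusive convention, and BED (0-based half-open), converted on read
#' and write.
#'
#' @param label Character labels.
#' @param start,end 1-based inclusive coordinates.
#' @param strand Optional strand (`+`/`-`/`*`).
#' @return A `data.frame` with columns `label`, `start`, `end`, `strand`.
#' @export
regions_df <- function(label, start, end, strand = "*") {
  df <- data.frame(label = as.character(label),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(strand, length(label)),
                   stringsAsFactors = FALSE)
  if (any(df$start < 1L)) stop("region start must be >= 1")
  if (any(df$end < df$start)) stop("region end must be >= start")
  df
}

#' Read a region table (TSV or BED)
#'
#' @param path File path. Files ending in `.bed` are parsed as BED3+
#'   (0-based half-open, name in column 4); anything else as TSV with
#'   columns `label`, `start`, `end`\[, `strand`\], 1-based inclusive,
#'   with or without a header line.
#' @return A region data frame (see [regions_df()]).
#' @export
read_regions <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    label <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else
      paste0("region_", seq_len(nrow(tab)))
    # BED: 0-based half-open -> 1-based inclusive
    regions_df(label, as.integer(tab[[2L]]) + 1L, as.integer(tab[[3L]]))
  } else {
    first <- readLines(path, n = 1L)
    header <- grepl("label", first, ignore.case = TRUE)
    tab <- utils::read.table(path, sep = "\t", header = header,
                             stringsAsFactors = FALSE, comment.char = "#")
    strand <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else "*"
    regions_df(as.character(tab[[1L]]), tab[[2L]], tab[[3L]], strand)
  }
}

#' Write a region table
#'
#' @param regions A region data frame.
#' @param path Output path; `format = "bed"` writes BED
#'   (0-based half-open), otherwise native 1-based TSV with header.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(chrom = if ("genome_id" %in% names(regions))
      regions$genome_id else "genome",
      start = regions$start - 1L, end = regions$end,
      name = regions$label)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    out <- regions[, intersect(c("label", "start", "end", "strand"),
                               names(regions)), drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

# Regions -> IRanges (merged, i.e. overlapping/adjacent intervals united)
regions_to_ranges <- function(regions, reduce = TRUE) {
  ir <- IRanges::IRanges(start = regions$start, end = regions$end)
  if (reduce) IRanges::reduce(ir) else ir
}

# Complement of a region set on [1, genome_length]
complement_ranges <- function(regions, genome_length) {
  ir <- regions_to_ranges(regions)
  IRanges::setdiff(IRanges::IRanges(1L, genome_length), ir)
}
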