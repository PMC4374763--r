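#' Per-region evaluation report
#'
#' Merges the evidence the workflow collects for each candidate
#' prophage region: GC content (against the genome average), flanking
#' direct repeats, optional protein-based classification, and -- when a
#' coverage profile is supplied -- NPKM, enrichment and the
#' active-region call.
#'
#' @param genome A [pp_genome()].
#' @param regions Region data frame (`label`, `start`, `end`).
#' @param profile Optional `pp_coverage` from [coverage_from_sam()].
#' @param db Optional phage protein database; when given together with
#'   `orfs`, each region's proteins are classified by best-hit voting.
#' @param orfs Optional ORF table from [call_orfs()] (needed for
#'   classification).
#' @param flank Flank width for repeat search; default 500.
#' @param enrichment_threshold,noise_flag_threshold See
#'   [call_active_regions()].
#' @return A `pp_report` list: `regions` (one row per region with all
#'   evidence columns), `genome_gc`, `signal_noise` (a
#'   `pp_signal_noise` or `NULL`).
#' @export
region_report <- function(genome, regions, profile = NULL, db = NULL,
                          orfs = NULL, flank = 500L,
                          enrichment_threshold = 10,
                          noise_flag_threshold = 20) {
  stopifnot(inherits(genome, "pp_genome"))
  out <- regions[, c("label", "start", "end")]
  out$span_bp <- region_length(out$start, out$end, genome$length)
  out$gc <- vapply(seq_len(nrow(out)), function(i)
    gc_content(extract_region(genome, out$start[i], out$end[i])),
    numeric(1))
  out$insertion_repeat <- vapply(seq_len(nrow(out)), function(i) {
    rep <- suppressWarnings(
      find_flanking_repeats(genome, out$start[i], out$end[i], flank = flank))
    if (is.null(rep)) NA_character_ else rep$notation
  }, character(1))

  if (!is.null(db) && !is.null(orfs)) {
    out$top_phage <- NA_character_
    out$top_fraction <- NA_real_
    for (i in seq_len(nrow(out))) {
      inside <- orfs$start >= out$start[i] & orfs$end <= out$end[i]
      if (!any(inside)) next
      prot <- stats::setNames(orfs$protein[inside], orfs$orf_id[inside])
      cls <- classify_region(prot, db, region_label = out$label[i])
      out$top_phage[i] <- cls$top_phage
      out$top_fraction[i] <- cls$top_fraction
    }
  }

  sn <- NULL
  if (!is.null(profile)) {
    out$npkm <- vapply(seq_len(nrow(out)), function(i)
      npkm(profile, out$start[i], out$end[i]), numeric(1))
    calls <- call_active_regions(profile, regions,
                                 enrichment_threshold = enrichment_threshold,
                                 noise_flag_threshold = noise_flag_threshold)
    out$mean_depth <- calls$mean_depth
    out$enrichment <- calls$enrichment
    out$active <- calls$active
    out$mode_flag <- calls$mode_flag
    sn <- tryCatch(suppressWarnings(signal_to_noise(profile, regions)),
                   error = function(e) NULL)
  }
  structure(list(regions = out,
                 genome_gc = gc_content(genome$seq),
                 signal_noise = sn),
            class = "pp_report")
}

#' @export
print.pp_report <- function(x, ...) {
  cat(sprintf("<pp_report> %d regions, genome GC %.2f%%\n",
              nrow(x$regions), x$genome_gc))
  print(x$regions)
  if (!is.null(x$signal_noise)) print(x$signal_noise)
  invisible(x)
}

#' Write a report as TSV + JSON
#'
#' @param report A `pp_report` from [region_report()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Named list of the written paths.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "pp_report"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(report$regions, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  payload <- list(genome_gc = report$genome_gc,
                  regions = report$regions)
  if (!is.null(report$signal_noise)) {
    payload$signal_noise <- unclass(report$signal_noise)
  }
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  list(tsv = tsv, json = json)
}
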