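# Signal-to-noise statistics and enrichment-based active-region calling
# for particle-protected DNA read mappings.

#' Signal-to-noise arithmetic from average base coverages
#'
#' Given the average base coverage inside prophage regions (signal) and
#' outside them (noise), computes the signal-to-noise ratio
#' (`signal / noise`) and the relative noise percentage
#' (`100 * noise / signal`, i.e. the noise with the signal set to
#' 100%). Before rounding, `noise_pct * ratio == 100` identically.
#'
#' @param signal,noise Mean depths in reads per base (non-negative).
#' @return A `pp_signal_noise` list: `signal`, `noise`, `ratio`,
#'   `noise_pct`.
#' @export
signal_noise_stats <- function(signal, noise) {
  if (signal < 0 || noise < 0) stop("coverages must be non-negative")
  if (signal == 0) stop("signal is zero; no coverage in prophage regions")
  if (noise == 0) {
    warning("noise is zero; ratio reported as infinite")
    ratio <- Inf; noise_pct <- 0
  } else {
    ratio <- signal / noise
    noise_pct <- 100 * noise / signal
  }
  structure(list(signal = signal, noise = noise, ratio = ratio,
                 noise_pct = noise_pct),
            class = "pp_signal_noise")
}

#' @export
print.pp_signal_noise <- function(x, ...) {
  cat(sprintf("<signal/noise> signal %.1f, noise %.1f, ratio %.1f, noise %.1f%%\n",
              x$signal, x$noise, x$ratio, x$noise_pct))
  invisible(x)
}

#' Signal-to-noise report for a prophage region set
#'
#' The signal is the mean per-base depth over the union of the prophage
#' regions, the noise the mean depth over their complement; overlapping
#' regions are merged first. See [signal_noise_stats()] for the derived
#' ratio and relative noise.
#'
#' @param profile A `pp_coverage` from [coverage_from_sam()].
#' @param regions Region data frame (columns `start`, `end`).
#' @return A `pp_signal_noise` list.
#' @export
signal_to_noise <- function(profile, regions) {
  stopifnot(inherits(profile, "pp_coverage"))
  if (nrow(regions) == 0L) stop("empty region set")
  if (any(regions$end > profile$length)) stop("region beyond genome end")
  inside <- regions_to_ranges(regions)
  outside <- complement_ranges(regions, profile$length)
  if (sum(IRanges::width(outside)) == 0L) {
    stop("region set covers the whole genome; complement is empty")
  }
  sum_over <- function(ir) {
    sum(vapply(seq_along(ir), function(i)
      depth_sum(profile, IRanges::start(ir)[i], IRanges::end(ir)[i]),
      numeric(1)))
  }
  signal <- sum_over(inside) / sum(IRanges::width(inside))
  noise <- sum_over(outside) / sum(IRanges::width(outside))
  signal_noise_stats(signal, noise)
}

#' Call active prophage regions from coverage enrichment
#'
#' The background depth is the median of per-window mean depths over
#' windows not overlapping any candidate region (median, not mean, so
#' origin-proximal coverage bias does not inflate it). A region is
#' called active when its mean depth is at least
#' `enrichment_threshold` times the background. When the genome-wide
#' relative noise exceeds `noise_flag_threshold` percent, all calls are
#' flagged `random_packaging_suspected` -- the coverage pattern of a
#' PBSX-like phage packaging random chromosomal fragments; otherwise
#' active regions are flagged `specific` and inactive ones `none`.
#'
#' @param profile A `pp_coverage`.
#' @param regions Region data frame (columns `label`, `start`, `end`).
#' @param enrichment_threshold Fold enrichment over background for an
#'   active call; default 10.
#' @param noise_flag_threshold Genome-wide relative noise (%) above
#'   which random packaging is suspected; default 20.
#' @param window Window size for the background estimate; default 1000.
#' @return Data frame with columns `label`, `start`, `end`,
#'   `mean_depth`, `enrichment`, `active`, `mode_flag`.
#' @export
call_active_regions <- function(profile, regions,
                                enrichment_threshold = 10,
                                noise_flag_threshold = 20,
                                window = 1000L) {
  stopifnot(inherits(profile, "pp_coverage"))
  empty_flag <- profile$total_aligned_nt <= 0
  mean_depth <- vapply(seq_len(nrow(regions)), function(i)
    depth_sum(profile, regions$start[i], regions$end[i]) /
      (regions$end[i] - regions$start[i] + 1), numeric(1))
  if (empty_flag) {
    enrichment <- rep(0, nrow(regions))
    active <- rep(FALSE, nrow(regions))
    mode_flag <- rep("none", nrow(regions))
  } else {
    track <- windowed_npkm(profile, window = window)
    win_ir <- IRanges::IRanges(track$start, track$end)
    reg_ir <- regions_to_ranges(regions)
    outside <- IRanges::countOverlaps(win_ir, reg_ir) == 0L
    depth <- as.numeric(profile$depth)
    cs <- c(0, cumsum(depth))
    win_mean <- (cs[track$end + 1L] - cs[track$start]) /
      (track$end - track$start + 1)
    background <- if (any(outside)) stats::median(win_mean[outside]) else 0
    enrichment <- if (background > 0) mean_depth / background else
      ifelse(mean_depth > 0, Inf, 0)
    active <- enrichment >= enrichment_threshold
    sn <- tryCatch(suppressWarnings(signal_to_noise(profile, regions)),
                   error = function(e) NULL)
    noisy <- !is.null(sn) && is.finite(sn$noise_pct) &&
      sn$noise_pct > noise_flag_threshold
    mode_flag <- if (noisy) rep("random_packaging_suspected", nrow(regions))
      else ifelse(active, "specific", "none")
  }
  data.frame(label = regions$label, start = regions$start,
             end = regions$end, mean_depth = mean_depth,
             enrichment = enrichment, active = active,
             mode_flag = mode_flag, stringsAsFactors = FALSE)
}
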