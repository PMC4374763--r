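# Reference simulation scenarios: desk-scale study conditions used to
# validate the activity caller against known ground truth. Both are
# 500 kb chromosomes sequenced to 50,000 single-end 100 nt reads with
# a 1% substitution error rate and 5% free host DNA carry-over.

#' Reference scenario: specific packaging of one prophage locus
#'
#' One 40 kb prophage (GC 40%) on a 500 kb chromosome whose particles
#' package the prophage's own genome: the situation of an induced
#' active siphovirus-like prophage. The expected outcome is a single
#' strongly enriched locus and low genome-wide relative noise.
#'
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
specific_packaging_config <- function(seed = 1L) {
  simulation_config(
    genome_length = 500000L,
    prophages = list(prophage_spec(230001L, 40000L, gc = 40)),
    packaging_mode = "specific",
    n_reads = 50000L, error_rate = 0.01,
    background_dna_fraction = 0.05, seed = seed)
}

#' Reference scenario: PBSX-like random packaging
#'
#' Seven prophage-like loci of 31 kb clustered in the origin-proximal
#' 46% of a 500 kb chromosome, packaged in the PBSX mode: ~13 kb
#' fragments drawn genome-wide with a 4-fold linear origin-proximity
#' bias. By construction roughly 40% of packaged DNA originates
#' outside the prophage loci, so the expected signal-to-noise ratio is
#' modest (about 1.8) and the genome-wide relative noise is far above
#' the random-packaging flag threshold -- the coverage signature of a
#' defective phage packaging host DNA.
#'
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
random_packaging_config <- function(seed = 1L) {
  starts <- 1L + (0:6) * 33000L
  simulation_config(
    genome_length = 500000L,
    prophages = lapply(starts, function(s)
      prophage_spec(s, 31000L, gc = 40)),
    packaging_mode = "random_13kb",
    origin_bias = 4,
    n_reads = 50000L, error_rate = 0.01,
    background_dna_fraction = 0.05, seed = seed)
}

#' Decoy regions for specificity evaluation
#'
#' Six 40 kb intervals spread over the reference 500 kb chromosome,
#' none overlapping the planted prophage of
#' [specific_packaging_config()]; an activity caller with perfect
#' specificity calls none of them active.
#'
#' @return A region data frame.
#' @export
decoy_regions <- function() {
  starts <- c(10001L, 60001L, 110001L, 160001L, 310001L, 400001L)
  regions_df(sprintf("decoy_%d", seq_along(starts)), starts,
             starts + 39999L)
}

#' Run one reference scenario end to end
#'
#' Simulates genome and reads, writes the truth SAM to a temporary
#' file, computes the coverage profile and evaluates the region set
#' (planted regions plus, for the specific scenario, the decoys).
#'
#' @param config A [simulation_config()] from one of the scenario
#'   constructors.
#' @param decoys Optional extra regions appended to the evaluated set.
#' @return List with `truth`, `profile`, `calls` (from
#'   [call_active_regions()] at default thresholds), and `sn`
#'   (genome-wide [signal_to_noise()] over the planted regions).
#' @export
run_scenario <- function(config, decoys = NULL) {
  truth <- simulate_genome(config)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  simulate_particle_reads(truth, sam = sam)
  profile <- coverage_from_sam(sam, truth$genome)
  regions <- truth$regions[, c("label", "start", "end")]
  if (!is.null(decoys)) regions <- rbind(regions, decoys[, c("label", "start", "end")])
  calls <- call_active_regions(profile, regions)
  sn <- suppressWarnings(signal_to_noise(profile, truth$regions))
  list(truth = truth, profile = profile, calls = calls, sn = sn)
}
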