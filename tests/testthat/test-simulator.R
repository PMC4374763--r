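# Synthetic genome and particle-read generator, and the flanking
# direct-repeat finder.

test_that("genome simulation is deterministic and GC-faithful", {
  cfg <- simulation_config(genome_length = 40000L,
                           prophages = list(prophage_spec(15001L, 12000L,
                                                          gc = 38)),
                           seed = 31L)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(as.character(t1$genome$seq), as.character(t2$genome$seq))
  expect_identical(t1$regions, t2$regions)

  # planted interval resampled at its own GC (binomial bound at 12 kb)
  reg_gc <- gc_content(extract_region(t1$genome, 15001L, 27000L))
  expect_lt(abs(reg_gc - 38), 1.5)
  # background stays near the host GC
  bg_gc <- gc_content(extract_region(t1$genome, 1L, 15000L))
  expect_lt(abs(bg_gc - 46.2), 1.5)

  expect_error(simulation_config(
    genome_length = 10000L,
    prophages = list(prophage_spec(1000L, 5000L),
                     prophage_spec(3000L, 5000L))), "overlap")
  expect_error(simulation_config(error_rate = 0.05), "error_rate")
})

test_that("planted flanking repeats are recovered with their mismatch count", {
  cfg <- simulation_config(genome_length = 30000L,
                           prophages = list(prophage_spec(10001L, 8000L,
                                                          gc = 40,
                                                          repeat_length = 30L,
                                                          repeat_mismatches = 2L)),
                           seed = 32L)
  truth <- simulate_genome(cfg)
  rep <- find_flanking_repeats(truth$genome, 10001L, 18000L)
  expect_false(is.null(rep))
  expect_gte(rep$length, 30L)
  expect_lte(rep$mismatches / rep$length, 0.10)
  # both copies sit at the planted boundaries
  expect_lt(abs(rep$left_start - 10001L), 10L)
  expect_lt(abs(rep$right_start - (18000L - 30L + 1L)), 10L)
})

test_that("repeat finder reports exact lengths on controlled constructions", {
  # homopolymer surroundings chosen so the two flank windows share
  # nothing but the planted repeat and can never extend it
  rep18 <- "ACGTTGCAATCGGATCGT"
  g <- pp_genome("g", paste0(strrep("A", 500), rep18, strrep("G", 2245),
                             strrep("T", 2245), rep18, strrep("C", 500)))
  hit <- find_flanking_repeats(g, 501L, 5026L, flank = 500L)
  expect_equal(hit$length, 18L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$notation, "18 bp")
  expect_equal(hit$left_start, 501L)
  expect_equal(hit$right_start, 5009L)

  # 61-mer with 6 substitutions in the right copy -> "61 -6 bp"
  set.seed(33)
  rep61 <- random_dna_str(61, gc = 50)
  right <- strsplit(rep61, "")[[1L]]
  at <- seq(6L, 56L, by = 10L)
  for (i in at) right[i] <- setdiff(c("A", "C", "G", "T"), right[i])[1L]
  right <- paste(right, collapse = "")
  g2 <- pp_genome("g", paste0(strrep("A", 500), rep61, strrep("G", 2200),
                              strrep("T", 2200), right, strrep("C", 500)))
  hit2 <- find_flanking_repeats(g2, 501L, 5022L, flank = 500L)
  expect_equal(hit2$length, 61L)
  expect_equal(hit2$mismatches, 6L)
  expect_equal(hit2$notation, "61 -6 bp")

  # nothing to find between poly-A and poly-C flanks
  g3 <- pp_genome("g", paste0(strrep("A", 1000), strrep("C", 1000)))
  expect_null(find_flanking_repeats(g3, 501L, 1500L, flank = 500L))
})

test_that("repeat finder agrees with the exhaustive substring-pair oracle", {
  set.seed(34)
  for (i in 1:15) {
    a <- random_dna_str(sample(30:60, 1), gc = 50)
    b <- random_dna_str(sample(30:60, 1), gc = 50)
    if (i %% 3 == 0) {
      # plant a shared 16-24 mer so matches exist in some cases
      core <- random_dna_str(sample(16:24, 1), gc = 50)
      pa <- sample(nchar(a) - nchar(core), 1)
      pb <- sample(nchar(b) - nchar(core), 1)
      substr(a, pa, pa + nchar(core) - 1L) <- core
      substr(b, pb, pb + nchar(core) - 1L) <- core
    }
    got <- prophactr:::.best_repeat_cpp(a, b, 15L, 0.10)
    want <- oracle_best_repeat(a, b, 15L, 0.10)
    if (is.null(want)) {
      expect_equal(got[3L], 0L)
    } else {
      expect_equal(got[1L], unname(want["i"]))
      expect_equal(got[2L], unname(want["j"]))
      expect_equal(got[3L], unname(want["len"]))
      expect_equal(got[4L], unname(want["mm"]))
    }
  }
})

test_that("specific packaging confines read origins to the designated region", {
  cfg <- simulation_config(genome_length = 60000L,
                           prophages = list(prophage_spec(20001L, 15000L)),
                           n_reads = 3000L,
                           error_rate = 0,
                           background_dna_fraction = 0,
                           seed = 35L)
  truth <- simulate_genome(cfg)
  fq <- tempfile(fileext = ".fastq")
  sam <- tempfile(fileext = ".sam")
  reads <- simulate_particle_reads(truth, fastq = fq, sam = sam)
  expect_equal(reads$n_reads, 3000L)
  expect_true(all(reads$origins$start >= 20001L))
  expect_true(all(reads$origins$end <= 35000L))
  # FASTQ holds one record per read; truth SAM reconciles with counts
  expect_equal(length(readLines(fq)), 4L * 3000L)
  prof <- coverage_from_sam(sam, truth$genome)
  expect_equal(prof$n_mapped, 3000L)
  expect_equal(prof$n_unmapped, 0L)
  # zero error rate: read sequences equal their genomic origin
  expect_equal(sum(as.numeric(prof$depth)), prof$total_aligned_nt)
  i <- 17L
  expect_equal(reads$reads[i],
               extract_region(truth$genome, reads$origins$start[i],
                              reads$origins$end[i]))
})

test_that("substitution errors appear at the configured rate", {
  cfg <- simulation_config(genome_length = 50000L, prophages = list(),
                           packaging_mode = "random_13kb",
                           n_reads = 10000L, error_rate = 0.01,
                           background_dna_fraction = 0, seed = 36L)
  truth <- simulate_genome(cfg)
  reads <- simulate_particle_reads(truth)
  ref <- vapply(seq_len(1000L), function(i)
    extract_region(truth$genome, reads$origins$start[i],
                   reads$origins$end[i]), character(1))
  mm <- sum(vapply(seq_len(1000L), function(i) {
    sum(strsplit(reads$reads[i], "")[[1L]] != strsplit(ref[i], "")[[1L]])
  }, numeric(1)))
  rate <- mm / (1000L * cfg$read_length)
  expect_lt(abs(rate - 0.01), 0.002)
})

test_that("origin bias tilts coverage toward the replication origin", {
  cfg <- simulation_config(genome_length = 100000L, prophages = list(),
                           packaging_mode = "random_13kb",
                           fragment_mean = 2000L, fragment_sd = 200L,
                           origin_bias = 2, n_reads = 100000L,
                           error_rate = 0, background_dna_fraction = 0,
                           seed = 37L)
  truth <- simulate_genome(cfg)
  reads <- simulate_particle_reads(truth)
  first <- sum(reads$origins$start <= 10000L)
  last <- sum(reads$origins$start > 90000L)
  expect_gt(first / last, 2 * 0.8)
  expect_lt(first / last, 2 * 1.2)
})

test_that("reads round-trip deterministically from config and seed", {
  cfg <- simulation_config(genome_length = 30000L,
                           prophages = list(prophage_spec(10001L, 8000L)),
                           n_reads = 500L, seed = 38L)
  truth <- simulate_genome(cfg)
  r1 <- simulate_particle_reads(truth)
  r2 <- simulate_particle_reads(truth)
  expect_identical(r1$origins, r2$origins)
  expect_identical(r1$reads, r2$reads)
})
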