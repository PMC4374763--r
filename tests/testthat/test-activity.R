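# Coverage from SAM, NPKM normalization, signal-to-noise statistics,
# and the active-region caller.

test_that("SAM coverage counts unique-mapping reads only", {
  g <- pp_genome("chr", strrep("ACGT", 250))   # 1,000 bp
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, "chr", 1000L, list(
    list(qname = "r1", flag = 0L, pos = 1L, cigar = "100M", len = 100L),
    list(qname = "r2", flag = 16L, pos = 501L, cigar = "100M", len = 100L)))
  prof <- coverage_from_sam(sam, g)
  expect_equal(prof$total_aligned_nt, 200)
  expect_equal(prof$total_aligned_nt / prof$length, 0.2)
  expect_equal(prof$n_mapped, 2L)
  expect_equal(prof$n_unmapped, 0L)
  expect_equal(sum(as.numeric(prof$depth)), prof$total_aligned_nt)
  expect_equal(as.numeric(prof$depth)[1:100], rep(1, 100))

  # an unmapped read is counted but adds no depth
  write_test_sam(sam, "chr", 1000L, list(
    list(qname = "r1", flag = 4L, pos = 0L, cigar = "*", len = 100L)))
  prof2 <- coverage_from_sam(sam, g)
  expect_equal(prof2$n_unmapped, 1L)
  expect_equal(prof2$total_aligned_nt, 0)

  # a duplicate placement flagged secondary is counted once
  write_test_sam(sam, "chr", 1000L, list(
    list(qname = "r1", flag = 0L, pos = 1L, cigar = "100M", len = 100L),
    list(qname = "r1", flag = 256L, pos = 501L, cigar = "100M", len = 100L)))
  prof3 <- coverage_from_sam(sam, g)
  expect_equal(prof3$total_aligned_nt, 100)
  expect_equal(sum(as.numeric(prof3$depth)[501:600]), 0)

  # mapping quality 0 marks a multi-mapper: excluded from depth
  write_test_sam(sam, "chr", 1000L, list(
    list(qname = "r1", flag = 0L, pos = 1L, cigar = "100M", len = 100L,
         mapq = 0L)))
  expect_equal(coverage_from_sam(sam, g)$total_aligned_nt, 0)

  # clips and insertions do not consume reference positions
  write_test_sam(sam, "chr", 1000L, list(
    list(qname = "r1", flag = 0L, pos = 1L, cigar = "10S40M5I45M",
         len = 100L)))
  expect_equal(coverage_from_sam(sam, g)$total_aligned_nt, 85)

  # header/genome mismatch is an error
  g2 <- pp_genome("other", strrep("ACGT", 250))
  expect_error(coverage_from_sam(sam, g2), "does not match")
})

test_that("NPKM normalizes out region length and sequencing depth", {
  # uniform coverage: every region has the same NPKM
  prof <- profile_from_depth(rep(5L, 10000L))
  v <- c(npkm(prof, 1, 1000), npkm(prof, 2001, 9000), npkm(prof, 1, 10000))
  expect_equal(v, rep(v[1], 3))

  # 10 kb genome, 1 kb region holding 2,000 of 10,000 aligned nt
  depth <- rep(0L, 10000L)
  depth[1001:2000] <- 2L
  depth[5001:9000] <- 2L
  prof2 <- profile_from_depth(depth)
  expect_equal(prof2$total_aligned_nt, 10000)
  expect_equal(npkm(prof2, 1001, 2000), (2000 / 1) / (10000 / 1e6))
  expect_equal(npkm(prof2, 3001, 4000), 0)
  # scaling depth leaves NPKM unchanged
  prof3 <- profile_from_depth(depth * 7L)
  expect_equal(npkm(prof3, 1001, 2000), npkm(prof2, 1001, 2000))
  expect_error(npkm(profile_from_depth(rep(0L, 100L)), 1, 10), "aligned")
})

test_that("windowed NPKM tiles the genome and conserves total signal", {
  depth <- rep(0L, 3500L)
  depth[1201:1300] <- 10L
  prof <- profile_from_depth(depth)
  track <- windowed_npkm(prof, window = 1000L)
  expect_equal(nrow(track), 4L)
  expect_equal(track$start, c(1L, 1001L, 2001L, 3001L))
  expect_equal(track$end, c(1000L, 2000L, 3000L, 3500L))
  expect_equal(track$end[4] - track$start[4] + 1L, 500L)
  # all signal in window 2: unique maximum
  expect_equal(which.max(track$npkm), 2L)
  expect_true(all(track$npkm[-2] == 0))
  # kb-length-weighted sum is exactly 1e6
  expect_equal(sum(track$npkm * (track$end - track$start + 1) / 1000), 1e6)
  expect_error(windowed_npkm(prof, window = 50L), ">= 100")
})

test_that("signal-to-noise statistics follow the published arithmetic", {
  sn <- signal_noise_stats(82.7, 31.5)
  expect_equal(round(sn$ratio, 1), 2.6)
  expect_equal(round(sn$noise_pct, 1), 38.1)
  sn2 <- signal_noise_stats(664.6, 5.4)
  expect_equal(round(sn2$ratio, 1), 123.1)
  expect_equal(round(sn2$noise_pct, 1), 0.8)

  # uniform coverage: ratio 1, noise 100%
  prof <- profile_from_depth(rep(3L, 5000L))
  regions <- regions_df("r", 1001L, 2000L)
  snu <- signal_to_noise(prof, regions)
  expect_equal(snu$ratio, 1)
  expect_equal(snu$noise_pct, 100)

  # identity noise_pct * ratio == 100 on random profiles
  set.seed(201)
  for (i in 1:10) {
    prof_i <- profile_from_depth(rpois(4000L, 2) + 1L)
    sn_i <- signal_to_noise(prof_i, regions_df("r", 501L, 1500L))
    expect_equal(sn_i$noise_pct * sn_i$ratio, 100)
  }

  # zero noise: infinite ratio with a warning
  d <- rep(0L, 2000L); d[101:200] <- 5L
  expect_warning(snz <- signal_to_noise(profile_from_depth(d),
                                        regions_df("r", 1L, 500L)),
                 "infinite")
  expect_equal(snz$ratio, Inf)
  expect_error(signal_to_noise(profile_from_depth(d),
                               regions_df("r", 1L, 2000L)), "complement")
})

test_that("scaling all depths leaves ratio, noise and enrichment unchanged", {
  set.seed(202)
  depth <- rpois(20000L, 1)
  depth[5001:7000] <- depth[5001:7000] + 40L
  regions <- regions_df("r", 5001L, 7000L)
  p1 <- profile_from_depth(depth)
  p2 <- profile_from_depth(depth * 5L)
  s1 <- signal_to_noise(p1, regions); s2 <- signal_to_noise(p2, regions)
  expect_equal(s1$ratio, s2$ratio)
  expect_equal(s1$noise_pct, s2$noise_pct)
  c1 <- call_active_regions(p1, regions)
  c2 <- call_active_regions(p2, regions)
  expect_equal(c1$enrichment, c2$enrichment)
  expect_equal(c1$active, c2$active)
})

test_that("the active caller flags enriched regions and random packaging", {
  # specific-packaging shape: one region dominating the coverage
  set.seed(203)
  depth <- rpois(50000L, 0.5)
  depth[20001:30000] <- depth[20001:30000] + 60L
  regions <- regions_df(c("hot", "cold"), c(20001L, 40001L),
                        c(30000L, 45000L))
  calls <- call_active_regions(profile_from_depth(depth), regions)
  expect_equal(calls$active, c(TRUE, FALSE))
  expect_equal(calls$mode_flag, c("specific", "none"))

  # random-packaging shape: flat-ish coverage everywhere
  flat <- rpois(50000L, 3) + 1L
  calls2 <- call_active_regions(profile_from_depth(flat), regions)
  expect_false(any(calls2$active))
  expect_true(all(calls2$mode_flag == "random_packaging_suspected"))

  # empty profile: nothing active
  calls3 <- call_active_regions(profile_from_depth(rep(0L, 50000L)), regions)
  expect_false(any(calls3$active))
  expect_true(all(calls3$mode_flag == "none"))
})
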