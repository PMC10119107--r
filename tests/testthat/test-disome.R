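test_that("disome records map to the leading ribosome's codon", {
  tx <- ref_tx(n_codons = 40L, utr = 30L)
  # 60-nt record with 5' end at the CDS start: A-site nt 45 -> codon 15
  fp <- tibble::tibble(transcript_id = tx$transcript_id,
                       five_prime_pos = tx$cds_start,
                       length = 60L, count = 2L)
  prof <- build_disome_profiles(fp, tx)
  expect_equal(prof$codon_index[prof$count > 0], 15L)
  # trailing convention instead uses 5' + 15 -> codon 5
  prof_tr <- build_disome_profiles(fp, tx, offset_rule = "trailing")
  expect_equal(prof_tr$codon_index[prof_tr$count > 0], 5L)
  # empty library: empty profile
  empty <- build_disome_profiles(fp[0, ], tx, total_count = 1)
  expect_true(all(empty$count == 0))
})

test_that("peak calling follows the declared fold-over-median rule", {
  flat <- toy_profile("t1", rep("AAA", 30), rep(5, 30))
  dflat <- dplyr::transmute(flat, transcript_id, codon_index, codon,
                            rpm = a_rpm, count = 10)
  expect_equal(nrow(call_disome_peaks(dflat)), 0L)

  spiked <- dflat
  spiked$rpm[10] <- 100
  spiked$count[10] <- 50
  pk <- call_disome_peaks(spiked)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, spiked$codon_index[10])
  expect_equal(pk$intensity, 100)

  # two spikes one codon apart merge into a single peak
  twin <- dflat
  twin$rpm[c(10, 12)] <- 100
  twin$count[c(10, 12)] <- 50
  pk2 <- call_disome_peaks(twin, merge_gap = 1L)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$codon_end - pk2$codon_start,
               twin$codon_index[12] - twin$codon_index[10] + 1L)

  # scaling the library leaves the calls unchanged
  scaled <- dplyr::mutate(spiked, rpm = rpm * 7)
  pk3 <- call_disome_peaks(scaled)
  expect_equal(pk3[, c("transcript_id", "codon_start", "codon_end", "summit")],
               pk[, c("transcript_id", "codon_start", "codon_end", "summit")])

  # short transcripts are skipped
  short <- dplyr::filter(spiked, codon_index <= 15)
  expect_equal(nrow(call_disome_peaks(short)), 0L)
})

test_that("peak matching yields consistent Venn decompositions", {
  mk_peaks <- function(tx, summits) {
    tibble::tibble(transcript_id = tx, codon_start = summits - 1L,
                   codon_end = summits + 2L, summit = summits,
                   intensity = 10)
  }
  a <- mk_peaks("t1", c(10L, 50L, 90L))
  expect_equal(glance(match_peaks(a, a))$common, 3L)

  b <- mk_peaks("t2", c(10L, 50L))
  m <- match_peaks(a, b)
  expect_equal(m$counts$common, 0L)
  expect_equal(m$counts$union, 5L)

  # tolerance-1 matching with an offset summit
  b2 <- mk_peaks("t1", c(11L, 50L, 200L))
  m2 <- match_peaks(a, b2, tolerance = 1L)
  expect_equal(m2$counts$common, 2L)
  expect_equal(m2$counts$common + m2$counts$only_a, nrow(a))
  expect_equal(m2$counts$common + m2$counts$only_b, nrow(b2))
  u <- union_peaks(m2)
  expect_equal(nrow(u), m2$counts$union)
})

test_that("peak fold changes track planted intensity ratios", {
  codons <- rep("AAA", 30)
  base <- toy_profile("t1", codons, c(rep(1, 9), 50, rep(1, 20)))
  dprof <- function(scale) {
    dplyr::transmute(base, transcript_id, codon_index, codon,
                     rpm = a_rpm * scale, count = round(a_rpm))
  }
  peaks <- call_disome_peaks(dprof(1))
  # identical conditions: log2FC = 0
  fc0 <- peak_fold_change(peaks, list(dprof(1)), list(dprof(1)))
  expect_true(all(fc0$log2fc == 0))
  # doubled intensities: log2FC near 1 (pseudocount-small regime)
  fc2 <- peak_fold_change(peaks, list(dprof(1)), list(dprof(2)),
                          pseudocount = 0.5)
  expect_equal(fc2$log2fc, log2((2 * fc2$intensity_a + 0.5) /
                                  (fc2$intensity_a + 0.5)))
  expect_equal(fc2$log2fc, 1, tolerance = 0.02)
})

test_that("codon/peak overlap equals brute-force interval containment", {
  set.seed(151)
  peaks <- tibble::tibble(transcript_id = sample(paste0("t", 1:5), 20,
                                                 replace = TRUE),
                          codon_start = sample(10:200, 20)) |>
    dplyr::mutate(codon_end = codon_start + sample(1:5, 20, replace = TRUE),
                  summit = codon_start, intensity = 1)
  queries <- tibble::tibble(transcript_id = sample(paste0("t", 1:5), 50,
                                                   replace = TRUE),
                            codon_index = sample(1:220, 50, replace = TRUE))
  ov <- codons_in_peaks(queries, peaks, tolerance = 1L)
  brute <- sum(vapply(seq_len(50), function(i) {
    any(peaks$transcript_id == queries$transcript_id[i] &
          queries$codon_index[i] >= peaks$codon_start - 1L &
          queries$codon_index[i] < peaks$codon_end + 1L)
  }, logical(1)))
  expect_equal(ov$n_in_peaks, brute)
  expect_equal(ov$n_in_peaks + ov$n_outside, 50L)
  expect_equal(codons_in_peaks(queries, peaks[0, ])$n_in_peaks, 0L)
  at_summit <- dplyr::transmute(peaks, transcript_id, codon_index = summit)
  expect_equal(codons_in_peaks(at_summit, peaks)$n_in_peaks, nrow(peaks))
})

test_that("planted stalls dominate disome profiles at p_stall = 1", {
  cfg <- sim_config(n_transcripts = 3L, cds_length_range = c(60L, 60L),
                    seed = 161L)
  tx <- generate_transcriptome(cfg)
  stalls <- tibble::tibble(transcript_id = tx$transcript_id[1],
                           codon_index = 30L)
  fp <- simulate_disome_footprints(tx, stalls, cfg, p_stall = 1, depth = 5e3)
  prof <- build_disome_profiles(fp, tx)
  expect_equal(sum(prof$count[prof$codon_index == 30L &
                                prof$transcript_id == tx$transcript_id[1]]),
               sum(prof$count))
})
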