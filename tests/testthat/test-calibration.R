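test_that("frame scores are modal-frame fractions", {
  tx <- ref_tx()
  # all 5' ends in frame 0
  fp0 <- tibble::tibble(transcript_id = tx$transcript_id,
                        five_prime_pos = tx$cds_start + c(0L, 3L, 9L),
                        length = 28L, count = c(10L, 5L, 5L))
  s0 <- frame_score_by_length(fp0, tx)
  expect_equal(s0$score, 1)
  expect_equal(s0$modal_frame, 0L)

  # frame counts (60, 30, 10) -> score 0.6
  fp <- tibble::tibble(transcript_id = tx$transcript_id,
                       five_prime_pos = tx$cds_start + c(0L, 1L, 2L),
                       length = 29L, count = c(60L, 30L, 10L))
  s <- frame_score_by_length(fp, tx)
  expect_equal(s$score, 0.6)
  expect_equal(s$frame0, 60)

  # uniform frames -> score 1/3
  fpu <- dplyr::mutate(fp, count = 10L)
  expect_equal(frame_score_by_length(fpu, tx)$score, 1 / 3)
})

test_that("length selection combines score, exclusion and offset domain", {
  scores <- tibble::tibble(length = c(28L, 29L, 21L, 33L),
                           score = c(0.8, 0.7, 0.9, 0.4))
  expect_equal(select_lengths(scores), c(28L, 29L))
  # threshold 0 keeps the offset-table domain minus exclusions
  scores_all <- tibble::tibble(length = 17:34, score = 0.4)
  expect_equal(select_lengths(scores_all, threshold = 0), 28:30)
  expect_warning(sel <- select_lengths(dplyr::mutate(scores, score = 0.1)),
                 "No read length")
  expect_length(sel, 0L)
})

test_that("A-site assignment follows the 15-nt rule with edge exclusion", {
  tx <- ref_tx(n_codons = 40L)
  # 28-nt read starting at the CDS start: A-site codon 15/3 = 5, retained
  fp <- tibble::tibble(transcript_id = tx$transcript_id,
                       five_prime_pos = tx$cds_start,
                       length = 28L, count = 1L)
  asg <- assign_sites(rpm(fp), tx)
  expect_equal(asg$a_codon, 5L)
  expect_equal(asg$p_codon, 4L)
  expect_equal(asg$e_codon, 3L)
  expect_true(asg$in_frame)

  # 29-nt read at cds_start + 1: A-site offset 16 nt, out of frame
  fp2 <- tibble::tibble(transcript_id = tx$transcript_id,
                        five_prime_pos = tx$cds_start + 1L,
                        length = 29L, count = 1L)
  asg2 <- assign_sites(rpm(fp2), tx)
  expect_false(asg2$in_frame)
  expect_equal(asg2$a_codon, 5L)

  # a_codon 3 falls in the excluded leading window -> dropped
  fp3 <- tibble::tibble(transcript_id = tx$transcript_id,
                        five_prime_pos = tx$cds_start - 6L,
                        length = 28L, count = 4L)
  asg3 <- assign_sites(rpm(fp3), tx)
  expect_equal(nrow(asg3), 0L)
  dropped <- attr(asg3, "dropped")
  expect_equal(dropped$n[dropped$reason == "outside_codon_window"], 4)
})

test_that("profiles place single reads at shifted P/E positions", {
  tx <- ref_tx(n_codons = 40L)
  fp <- tibble::tibble(transcript_id = tx$transcript_id,
                       five_prime_pos = tx$cds_start + 30L - 15L,
                       length = 28L, count = 1L)  # A-site codon 10
  prof <- build_profiles(fp, tx)
  expect_equal(prof$codon_index[prof$a_rpm > 0], 10L)
  expect_equal(prof$codon_index[prof$p_rpm > 0], 9L)
  expect_equal(prof$codon_index[prof$e_rpm > 0], 8L)
  expect_error(build_profiles(fp, tx, usable_lengths = integer(0)), "empty")
})

test_that("profile mass balances and P/E are exact shifts of A", {
  sim <- quick_sim(seed = 71L, depth = 5e4, offframe_noise = 0)
  filtered <- filter_by_length(sim$fp, keep = c(28L, 30L), exclude = NULL)
  prof <- build_profiles(sim$fp, sim$tx)
  # no mass created or lost: retained RPM equals the A-profile sum
  asg <- assign_sites(rpm(filtered), sim$tx)
  expect_equal(sum(prof$a_rpm), sum(asg$rpm), tolerance = 1e-9)
  shifted <- prof |>
    dplyr::mutate(a_next = dplyr::lead(.data$a_rpm),
                  a_next2 = dplyr::lead(.data$a_rpm, 2),
                  last_idx = max(.data$codon_index),
                  .by = "transcript_id") |>
    dplyr::filter(.data$codon_index <= .data$last_idx - 2L)
  expect_equal(shifted$p_rpm, shifted$a_next, tolerance = 1e-12)
  expect_equal(shifted$e_rpm, shifted$a_next2, tolerance = 1e-12)
})

test_that("planted A-sites are recovered exactly without off-frame noise", {
  cfg <- sim_config(n_transcripts = 3L, cds_length_range = c(60L, 60L),
                    depth = 2e4, offframe_noise = 0, seed = 81L)
  tx <- generate_transcriptome(cfg)
  sim <- simulate_monosome_footprints(tx, dwell_spec(), cfg)
  # frame purity: every length scores exactly 1
  scores <- frame_score_by_length(sim$footprints, tx)
  expect_true(all(scores$score == 1))
  # planted counts at 28-30 nt equal recovered per-codon counts
  prof <- build_profiles(sim$footprints, tx)
  planted <- sim$footprints |>
    dplyr::filter(.data$length %in% 28:30) |>
    dplyr::inner_join(tx[, c("transcript_id", "cds_start")],
                      by = "transcript_id") |>
    dplyr::mutate(codon_index = (.data$five_prime_pos + 15L -
                                   .data$cds_start) %/% 3L) |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("transcript_id", "codon_index"))
  joined <- dplyr::left_join(prof, planted,
                             by = c("transcript_id", "codon_index")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
  expect_equal(joined$a_count, as.numeric(joined$count))
})
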