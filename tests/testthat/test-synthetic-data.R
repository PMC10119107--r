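test_that("generated transcriptomes honour the configuration contract", {
  cfg <- sim_config(n_transcripts = 1L, cds_length_range = c(30L, 30L),
                    seed = 7L)
  tx <- generate_transcriptome(cfg)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$cds_end - tx$cds_start, 90L)
  cds <- substr(tx$sequence, tx$cds_start + 1, tx$cds_end)
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, 88, 90) %in% c("TAA", "TAG", "TGA"))

  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx, tx2)

  expect_error(sim_config(cds_length_range = c(20L, 40L)), "30 codons")
})

test_that("codon usage of generated CDSs matches the sampling weights", {
  cfg <- sim_config(n_transcripts = 100L, cds_length_range = c(100L, 1000L),
                    seed = 13L)
  tx <- generate_transcriptome(cfg)
  # interior codons are drawn uniformly from the 61 sense codons
  interior <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    cds <- substr(tx$sequence[i], tx$cds_start[i] + 1, tx$cds_end[i])
    cods <- substring(cds, seq(4, nchar(cds) - 5, 3), seq(6, nchar(cds) - 3, 3))
    cods
  }))
  obs <- table(factor(interior, levels = sense_codons()))
  n <- sum(obs)
  expected <- n / 61
  se <- sqrt(n * (1 / 61) * (1 - 1 / 61))
  expect_true(all(abs(obs - expected) < 3.5 * se))
  chi <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, df = 60, lower.tail = FALSE), 0.001)
})

test_that("monosome sampling follows the planted dwell structure", {
  # uniform dwell: per-codon A-site counts uniform within Poisson error
  cfg <- sim_config(n_transcripts = 5L, cds_length_range = c(80L, 80L),
                    depth = 1e6, offframe_noise = 0,
                    length_distribution = c(`28` = 1), seed = 17L)
  tx <- generate_transcriptome(cfg)
  tx$abundance <- rep(1 / 5, 5)  # equal abundance isolates the dwell term
  sim <- simulate_monosome_footprints(tx, dwell_spec(), cfg)
  prof <- build_profiles(sim$footprints, tx)
  lambda <- 1e6 / nrow(prof)
  z <- (prof$a_count - lambda) / sqrt(lambda)
  expect_lt(max(abs(z)), 5)

  # planted CCG x3: closed-form multinomial expectation
  sim3 <- simulate_monosome_footprints(
    tx, dwell_spec(codon_multipliers = c(CCG = 3)), cfg, seed = 18L)
  prof3 <- build_profiles(sim3$footprints, tx)
  ratio <- mean(prof3$a_count[prof3$codon == "CCG"]) / mean(prof3$a_count)
  n_ccg <- sum(prof3$codon == "CCG")
  n_all <- nrow(prof3)
  expected <- 3 / ((n_ccg * 3 + (n_all - n_ccg)) / n_all)
  expect_equal(ratio, expected, tolerance = 0.1)
})

test_that("off-frame noise controls the frame of simulated 5' ends", {
  sim <- quick_sim(seed = 31L, depth = 2e4, offframe_noise = 0)
  asg <- assign_sites(rpm(sim$fp), sim$tx)
  expect_true(all(asg$in_frame))

  # all profile mass comes from the offset-table lengths, none is lost
  prof <- build_profiles(sim$fp, sim$tx)
  in_domain <- sim$fp$count[sim$fp$length %in% 28:30]
  expect_equal(sum(prof$a_count), sum(in_domain))
})

test_that("disome simulation places reads at stall sites", {
  cfg <- sim_config(n_transcripts = 4L, cds_length_range = c(80L, 80L),
                    seed = 41L)
  tx <- generate_transcriptome(cfg)
  stalls <- tibble::tibble(transcript_id = tx$transcript_id[1:2],
                           codon_index = c(20L, 40L))
  fp <- simulate_disome_footprints(tx, stalls, cfg, p_stall = 1, depth = 1e4)
  expect_true(all(fp$length >= 50 & fp$length <= 80))
  prof <- build_disome_profiles(fp, tx)
  hit <- prof[prof$rpm > 0, c("transcript_id", "codon_index")]
  expect_equal(dplyr::arrange(tibble::as_tibble(hit), transcript_id),
               dplyr::arrange(stalls, transcript_id), ignore_attr = TRUE)

  # p_stall = 0: uniform over the allowed codons of each transcript,
  # checked against the sampler's own null (goodness of fit per transcript)
  fp0 <- simulate_disome_footprints(tx, stalls, cfg, p_stall = 0, depth = 1e5)
  prof0 <- build_disome_profiles(fp0, tx)
  tx1 <- prof0[prof0$transcript_id == tx$transcript_id[1], ]
  gof <- stats::chisq.test(tx1$count)
  expect_gt(gof$p.value, 0.01)

  # seed contract: distinct but equal-size background libraries
  fpA <- simulate_disome_footprints(tx, stalls, cfg, seed = 1L, p_stall = 0,
                                    depth = 1e4)
  fpB <- simulate_disome_footprints(tx, stalls, cfg, seed = 2L, p_stall = 0,
                                    depth = 1e4)
  expect_equal(library_size(fpA), library_size(fpB))
  expect_false(identical(fpA, fpB))
})

test_that("condition pairs carry truth and honour dispersion", {
  cfg <- sim_config(n_transcripts = 4L, cds_length_range = c(60L, 80L),
                    depth = 2e4, n_replicates = 2L, dispersion = 0,
                    seed = 51L)
  tx <- generate_transcriptome(cfg)
  pro <- codons_for("P")
  pair <- simulate_condition_pair(
    tx, dwell_spec(),
    dwell_spec(codon_multipliers = setNames(rep(2, 4), pro)), cfg)
  expect_setequal(pair$truth$planted_codons$codon, pro)
  expect_equal(pair$truth$planted_codons$mult_b /
                 pair$truth$planted_codons$mult_a, rep(2, 4))
  # dispersion = 0: all library depths equal
  depths <- vapply(c(pair$footprints$a, pair$footprints$b), library_size, 1)
  expect_true(all(depths == depths[1]))
  expect_length(pair$rna$a, 2L)

  cfg1 <- sim_config(n_replicates = 1L, seed = 52L)
  expect_error(simulate_condition_pair(tx, dwell_spec(), dwell_spec(), cfg1),
               "2")
})

test_that("simulation bookkeeping conserves counts and abundances", {
  sim <- quick_sim(seed = 61L, depth = 12345)
  expect_equal(library_size(sim$fp), 12345L)
  expect_equal(sum(sim$truth$positions$prob), 1, tolerance = 1e-12)
  expect_equal(sum(sim$tx$abundance), 1, tolerance = 1e-12)
})
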