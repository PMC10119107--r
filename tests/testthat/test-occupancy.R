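test_that("relative occupancy matches hand-computed toy values", {
  # flat profile: rho = 1 for every codon present
  flat <- toy_profile("t1", c("AAA", "CCA", "GGG", "TTT"), rep(2, 4))
  occ <- relative_codon_occupancy(flat)
  expect_true(all(occ$rho == 1))

  # 10-codon toy: CCA at 2 positions with RPM 4, 8 others RPM 1
  codons <- c("CCA", "AAA", "GAA", "CCA", "GGA", "TTG", "CAA", "GCT",
              "ATG", "TGG")
  vals <- ifelse(codons == "CCA", 4, 1)
  occ2 <- relative_codon_occupancy(toy_profile("t1", codons, vals))
  expect_equal(occ2$rho[occ2$codon == "CCA"], 2.5)
  expect_equal(occ2$rho[occ2$codon == "AAA"], 0.625)
  expect_equal(occ2$mean_rpm[occ2$codon == "CCA"], 4)

  # normalization identity holds by construction
  expect_equal(sum(occ2$n * occ2$rho) / sum(occ2$n), 1, tolerance = 1e-9)
  expect_error(relative_codon_occupancy(flat, min_codons = 100),
               "coverage gate")
})

test_that("occupancy recovers planted multipliers and is scale-invariant", {
  sim <- quick_sim(seed = 91L, depth = 1e6,
                   dwell = dwell_spec(codon_multipliers = c(GCT = 2)),
                   n_transcripts = 20L, cds_range = c(100L, 200L))
  prof <- build_profiles(sim$fp, sim$tx)
  occ <- relative_codon_occupancy(prof)
  bg <- median(occ$rho[occ$codon != "GCT"])
  expect_equal(occ$rho[occ$codon == "GCT"] / bg, 2, tolerance = 0.1)

  # multiplying the library by a constant leaves rho unchanged
  prof10 <- dplyr::mutate(prof, a_rpm = a_rpm * 10)
  occ10 <- relative_codon_occupancy(prof10)
  expect_equal(occ10$rho, occ$rho, tolerance = 1e-12)

  # the planted codon tops the occupancy ranking
  expect_equal(occ$codon[which.max(occ$rho)], "GCT")
})

test_that("amino-acid aggregation is occurrence-weighted", {
  occ <- tibble::tibble(codon = c("CCA", "CCG", "ATG", "TGG"),
                        amino_acid = c("P", "P", "M", "W"),
                        n = c(10L, 5L, 3L, 2L),
                        mean_rpm = 1,
                        rho = c(2, 4, 1.5, 0.7))
  aa <- aggregate_amino_acid(occ)
  expect_equal(aa$rho[aa$amino_acid == "P"], (10 * 2 + 5 * 4) / 15)
  # single-codon amino acids keep their codon's rho
  expect_equal(aa$rho[aa$amino_acid == "M"], 1.5)
  expect_equal(aa$rho[aa$amino_acid == "W"], 0.7)

  flat <- dplyr::mutate(occ, rho = 1)
  expect_true(all(aggregate_amino_acid(flat)$rho == 1))
})

test_that("RUST ratios match the binarisation walk-through", {
  # 10 codons, positions {2, 5} carry CAA with RPM 10, others RPM 1
  codons <- c("AAA", "GGG", "CAA", "TTT", "GAT", "CAA", "CTG", "TGC",
              "ATG", "TGG")
  vals <- ifelse(codons == "CAA", 10, 1)
  ru <- rust_metafootprint(toy_profile("t1", codons, vals))
  expect_equal(ru$observed[ru$codon == "CAA"], 1)
  expect_equal(ru$expected[ru$codon == "CAA"], 0.2)
  expect_equal(ru$rust_ratio[ru$codon == "CAA"], 5)

  # a constant profile has no above-mean positions
  expect_error(rust_metafootprint(toy_profile("t1", codons, rep(1, 10))),
               "above-mean")

  # simulated Ala stalling elevates the ratio at all four Ala codons
  ala <- codons_for("A")
  sim <- quick_sim(seed = 101L, depth = 5e5,
                   dwell = dwell_spec(codon_multipliers =
                                        setNames(rep(2, 4), ala)),
                   n_transcripts = 15L, cds_range = c(100L, 200L))
  ru2 <- rust_metafootprint(build_profiles(sim$fp, sim$tx))
  expect_true(all(ru2$rust_ratio[ru2$codon %in% ala] > 1))
  expect_gt(mean(ru2$rust_ratio[ru2$codon %in% ala]),
            mean(ru2$rust_ratio[!ru2$codon %in% ala]))
})

test_that("transcript CV matches hand arithmetic and sampling behaviour", {
  expect_equal(transcript_cv(toy_profile("t1", rep("AAA", 4), rep(3, 4)))$cv,
               0)
  cv2 <- transcript_cv(toy_profile("t1", c("AAA", "CCC"), c(1, 3)))
  expect_equal(cv2$cv, sqrt(2) / 2, tolerance = 1e-12)

  # homogeneous dwell: CV shrinks as per-codon coverage grows (~1/sqrt(mean))
  cvs <- vapply(c(2e4, 2e5, 2e6), function(d) {
    sim <- quick_sim(seed = 111L, depth = d, n_transcripts = 5L,
                     cds_range = c(80L, 80L))
    median(transcript_cv(build_profiles(sim$fp, sim$tx))$cv)
  }, 1)
  expect_true(all(diff(cvs) < 0))
})

test_that("translation efficiency is a density ratio, invariant to depth", {
  tx <- toy_transcripts(c(t1 = strrep("A", 400), t2 = strrep("A", 700)),
                        cds_start = c(50L, 50L), cds_end = c(350L, 650L))
  ribo <- tibble::tibble(transcript_id = c("t1", "t2"), count = c(10L, 10L))
  rna <- tibble::tibble(transcript_id = c("t1", "t2"), count = c(5L, 15L))
  te <- translation_efficiency(ribo, rna, tx)
  # equal library sizes: te = (ribo/cds)/(rna/cds) x (rna_total/ribo_total)
  expect_equal(te$te[te$transcript_id == "t1"], 2)
  expect_equal(te$te[te$transcript_id == "t2"], 2 / 3)

  te2 <- translation_efficiency(dplyr::mutate(ribo, count = count * 2L),
                                rna, tx)
  expect_equal(te2$te, te$te)

  rna0 <- tibble::tibble(transcript_id = c("t1", "t2"), count = c(5L, 0L))
  te3 <- translation_efficiency(ribo, rna0, tx)
  expect_true(is.na(te3$te[te3$transcript_id == "t2"]))
})
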