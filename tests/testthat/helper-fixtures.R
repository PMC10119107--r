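# Shared fixtures: all built in code at test time.

# A transcript tibble from explicit sequences and CDS bounds.
toy_transcripts <- function(seqs, cds_start, cds_end) {
  tx <- tibble::tibble(transcript_id = names(seqs),
                       sequence = unname(seqs),
                       length = nchar(seqs),
                       cds_start = as.integer(cds_start),
                       cds_end = as.integer(cds_end))
  dplyr::mutate(tx, cds_codons = (cds_end - cds_start) %/% 3L)
}

# A deterministic single-transcript reference: 40-codon CDS flanked by 30-nt
# UTRs, with known codon identities.
ref_tx <- function(n_codons = 40L, utr = 30L, seed = 11L) {
  cfg <- sim_config(n_transcripts = 1L,
                    cds_length_range = c(n_codons, n_codons),
                    utr_length = utr, seed = seed)
  generate_transcriptome(cfg)
}

# A profile tibble built directly from per-codon values (bypassing reads),
# for arithmetic oracles.
toy_profile <- function(transcript_id, codons, a_rpm,
                        codon_index = seq_along(codons) + 4L,
                        a_count = round(a_rpm)) {
  out <- tibble::tibble(transcript_id = transcript_id,
                        codon_index = as.integer(codon_index),
                        codon = codons,
                        a_rpm = a_rpm,
                        p_rpm = dplyr::lead(a_rpm, default = 0),
                        e_rpm = dplyr::lead(a_rpm, n = 2, default = 0),
                        a_count = a_count)
  class(out) <- c("ribodyn_profiles", class(out))
  out
}

# A small simulated library plus its profiles, reused across tests.
quick_sim <- function(seed = 5L, depth = 1e5, n_transcripts = 8L,
                      dwell = dwell_spec(), offframe_noise = 0,
                      cds_range = c(60L, 120L)) {
  cfg <- sim_config(n_transcripts = n_transcripts,
                    cds_length_range = cds_range,
                    depth = depth, offframe_noise = offframe_noise,
                    seed = seed)
  tx <- generate_transcriptome(cfg)
  sim <- simulate_monosome_footprints(tx, dwell, cfg, seed = seed + 1L)
  list(cfg = cfg, tx = tx, fp = sim$footprints, truth = sim$truth)
}
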