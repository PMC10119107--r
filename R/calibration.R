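# 3-nt periodicity scoring, usable-length selection and A-/P-/E-site codon
# assignment. The A-site of a 28-30-nt footprint sits 15 nt downstream of
# its 5' end; the periodicity score of a read length is the modal-frame
# fraction of its CDS-internal 5' ends, and lengths scoring >= 0.5 enter the
# analysis.

#' Default A-site offset table
#'
#' @return Tibble `length`, `offset`: 15 nt for 28–30-nt reads. Only lengths
#'   present in the offset table contribute to occupancy profiles.
#' @export
default_offsets <- function() {
  tibble(length = 28:30, offset = 15L)
}

#' Score 3-nt periodicity per read length
#'
#' For each read length, 5' ends falling inside an annotated CDS are tallied
#' by frame (`(five_prime_pos - cds_start) mod 3`) and the score is the modal
#' frame's fraction of reads. Ties go to the lower frame index; lengths with
#' no CDS-internal reads get an `NA` score.
#'
#' @param footprints A footprint tibble.
#' @param transcripts A transcript tibble.
#' @return Tibble `length`, `frame0`, `frame1`, `frame2`, `n`, `modal_frame`,
#'   `score`, one row per read length present in the library.
#' @export
frame_score_by_length <- function(footprints, transcripts) {
  cds <- select(transcripts, "transcript_id", "cds_start", "cds_end")
  tallies <- footprints |>
    inner_join(cds, by = "transcript_id") |>
    filter(.data$five_prime_pos >= .data$cds_start,
           .data$five_prime_pos < .data$cds_end) |>
    mutate(frame = (.data$five_prime_pos - .data$cds_start) %% 3L) |>
    summarise(n = sum(.data$count), .by = c("length", "frame"))
  out <- tidyr::expand_grid(length = sort(unique(footprints$length)),
                            frame = 0:2) |>
    left_join(tallies, by = c("length", "frame")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "frame", values_from = "n",
                       names_prefix = "frame") |>
    mutate(n = .data$frame0 + .data$frame1 + .data$frame2)
  mx <- pmax(out$frame0, out$frame1, out$frame2)
  out |>
    mutate(modal_frame = ifelse(.data$n > 0,
                                max.col(cbind(.data$frame0, .data$frame1,
                                              .data$frame2),
                                        ties.method = "first") - 1L,
                                NA_integer_),
           score = ifelse(.data$n > 0, mx / .data$n, NA_real_))
}

#' Select usable read lengths
#'
#' Lengths whose periodicity score reaches `threshold`, excluding the
#' open-A-site length class and intersected with the offset-table domain.
#'
#' @param scores Output of [frame_score_by_length()].
#' @param threshold Minimum score (scores exactly at the threshold are kept).
#' @param exclude Inclusive length range to drop (default 20–22 nt), or
#'   `NULL`.
#' @param offsets An offset table; only its lengths can be selected.
#' @return Integer vector of usable read lengths (warns when empty).
#' @export
select_lengths <- function(scores, threshold = 0.5, exclude = c(20L, 22L),
                           offsets = default_offsets()) {
  keep <- scores |>
    filter(!is.na(.data$score), .data$score >= threshold)
  lens <- keep$length
  if (!is.null(exclude)) {
    lens <- lens[lens < exclude[1] | lens > exclude[2]]
  }
  lens <- sort(intersect(lens, offsets$length))
  if (length(lens) == 0) {
    warn("No read length passed periodicity selection")
  }
  as.integer(lens)
}

#' Assign A-/P-/E-site codons to footprints
#'
#' The A-site nucleotide is `five_prime_pos + offset(length)`; its codon
#' index is `floor((A - cds_start) / 3)` and the P- and E-site codons sit one
#' and two codons upstream. Records whose A-site codon lies outside the
#' analyzed window (codons 5 to L-6; the first and last five codons are
#' excluded) or whose length has no offset are dropped, with a tally kept in
#' the `"dropped"` attribute.
#'
#' @param footprints A footprint tibble (optionally with an `rpm` column).
#' @param transcripts A transcript tibble.
#' @param offsets Offset table (`length`, `offset`).
#' @return The footprint tibble with `a_nt`, `a_codon`, `p_codon`, `e_codon`
#'   and `in_frame` columns; attribute `dropped` tallies discarded reads by
#'   reason.
#' @export
assign_sites <- function(footprints, transcripts, offsets = default_offsets()) {
  n0 <- sum(footprints$count)
  x <- footprints |>
    inner_join(offsets, by = "length") |>
    inner_join(select(transcripts, "transcript_id", "cds_start", "cds_end",
                      "cds_codons"),
               by = "transcript_id") |>
    mutate(a_nt = .data$five_prime_pos + .data$offset,
           rel = .data$a_nt - .data$cds_start,
           a_codon = .data$rel %/% 3L,
           in_frame = .data$rel %% 3L == 0L,
           p_codon = .data$a_codon - 1L,
           e_codon = .data$a_codon - 2L)
  no_offset <- n0 - sum(x$count)
  kept <- filter(x, .data$a_codon >= 5L, .data$a_codon <= .data$cds_codons - 6L)
  out_of_window <- sum(x$count) - sum(kept$count)
  kept <- select(kept, -"rel", -"offset", -"cds_start", -"cds_end",
                 -"cds_codons")
  attr(kept, "dropped") <- tibble(
    reason = c("no_offset_for_length", "outside_codon_window"),
    n = c(no_offset, out_of_window))
  kept
}

#' Build per-transcript codon profiles
#'
#' RPM-weighted A-, P- and E-site densities on the analyzed codon grid
#' (codons 5 to L-6) of every transcript. By default the RPM denominator is
#' the library size after restricting to `usable_lengths` (post-filter
#' normalisation) and out-of-frame reads are excluded, since the A-site codon
#' identity is ill-defined off frame.
#'
#' @param footprints A footprint tibble.
#' @param transcripts A transcript tibble.
#' @param offsets Offset table.
#' @param usable_lengths Read lengths to use (e.g. from [select_lengths()]);
#'   must be non-empty.
#' @param total_count RPM denominator; defaults to the post-filter library
#'   size.
#' @param keep_offframe Keep out-of-frame reads (assigned to the codon
#'   containing their A-site nucleotide)?
#' @return A tibble `transcript_id`, `codon_index`, `codon`, `a_rpm`,
#'   `p_rpm`, `e_rpm`, `a_count` covering the full analyzed grid of every
#'   transcript with at least 11 CDS codons (class `ribodyn_profiles`).
#' @export
build_profiles <- function(footprints, transcripts,
                           offsets = default_offsets(),
                           usable_lengths = offsets$length,
                           total_count = NULL,
                           keep_offframe = FALSE) {
  if (length(usable_lengths) == 0) {
    abort("`usable_lengths` is empty; no footprints can be assigned")
  }
  fp <- filter(footprints, .data$length %in% usable_lengths)
  fp <- rpm(fp, total_count = total_count)
  asg <- assign_sites(fp, transcripts, offsets)
  if (!keep_offframe) asg <- filter(asg, .data$in_frame)
  grid <- profile_grid(transcripts)
  site_sum <- function(col, value_col) {
    asg |>
      summarise(v = sum(.data[[value_col]]),
                .by = c("transcript_id", all_of(col))) |>
      rename(codon_index = all_of(col))
  }
  out <- grid |>
    left_join(rename(site_sum("a_codon", "rpm"), a_rpm = "v"),
              by = c("transcript_id", "codon_index")) |>
    left_join(rename(site_sum("p_codon", "rpm"), p_rpm = "v"),
              by = c("transcript_id", "codon_index")) |>
    left_join(rename(site_sum("e_codon", "rpm"), e_rpm = "v"),
              by = c("transcript_id", "codon_index")) |>
    left_join(rename(site_sum("a_codon", "count"), a_count = "v"),
              by = c("transcript_id", "codon_index")) |>
    mutate(across(c("a_rpm", "p_rpm", "e_rpm", "a_count"),
                  ~ tidyr::replace_na(.x, 0)))
  class(out) <- c("ribodyn_profiles", class(out))
  out
}

# Analyzed-codon grid with codon identities for all usable transcripts.
profile_grid <- function(transcripts) {
  tx <- filter(transcripts, .data$cds_codons >= 11L)
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    idx <- analysis_window(tx$cds_codons[i])
    tibble(transcript_id = tx$transcript_id[i],
           codon_index = idx,
           codon = codon_at(tx$sequence[i], tx$cds_start[i], idx))
  })
}

#' Calibration report
#'
#' One row per read length: frame tallies, periodicity score, whether the
#' length was retained, and its A-site offset.
#'
#' @param scores Output of [frame_score_by_length()].
#' @param usable_lengths Output of [select_lengths()].
#' @param offsets Offset table.
#' @return A tibble ready to write as TSV.
#' @export
calibration_report <- function(scores, usable_lengths,
                               offsets = default_offsets()) {
  scores |>
    left_join(offsets, by = "length") |>
    mutate(retained = .data$length %in% usable_lengths)
}
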