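# Disome (collided-ribosome) footprint processing: codon-level profiles,
# collision peak calling, cross-condition peak matching, and peak intensity
# fold changes.

#' Codon-level disome profiles
#'
#' Maps each 50–80-nt disome record to a codon: under the default
#' `"leading"` convention the leading (downstream, stalled) ribosome's
#' A-site nucleotide is `five_prime_pos + length - 15`, mirroring the
#' monosome 15-nt rule applied from the fragment's 3' end; `"trailing"`
#' instead uses `five_prime_pos + 15` (the upstream, collided ribosome).
#' Records mapping outside the analyzed codon window are dropped with a
#' tally.
#'
#' @param footprints A disome footprint tibble (lengths within
#'   `length_range` are kept; others are dropped with a tally).
#' @param transcripts A transcript tibble.
#' @param offset_rule `"leading"` or `"trailing"`.
#' @param length_range Allowed fragment lengths in nt.
#' @param total_count RPM denominator; defaults to the retained library size.
#' @return A tibble `transcript_id`, `codon_index`, `codon`, `rpm`, `count`
#'   on the full analyzed grid; attribute `dropped` tallies discarded reads.
#' @export
build_disome_profiles <- function(footprints, transcripts,
                                  offset_rule = c("leading", "trailing"),
                                  length_range = c(50L, 80L),
                                  total_count = NULL) {
  offset_rule <- match.arg(offset_rule)
  n0 <- sum(footprints$count)
  fp <- filter(footprints, .data$length >= length_range[1],
               .data$length <= length_range[2])
  bad_length <- n0 - sum(fp$count)
  fp <- rpm(fp, total_count = total_count)
  x <- fp |>
    inner_join(select(transcripts, "transcript_id", "cds_start",
                      "cds_codons"),
               by = "transcript_id") |>
    mutate(a_nt = if (offset_rule == "leading") {
      .data$five_prime_pos + .data$length - 15L
    } else {
      .data$five_prime_pos + 15L
    },
    codon_index = (.data$a_nt - .data$cds_start) %/% 3L)
  kept <- filter(x, .data$codon_index >= 5L,
                 .data$codon_index <= .data$cds_codons - 6L)
  out_of_window <- sum(x$count) - sum(kept$count)
  sums <- kept |>
    summarise(rpm = sum(.data$rpm), count = sum(.data$count),
              .by = c("transcript_id", "codon_index"))
  out <- profile_grid(transcripts) |>
    left_join(sums, by = c("transcript_id", "codon_index")) |>
    mutate(rpm = tidyr::replace_na(.data$rpm, 0),
           count = tidyr::replace_na(.data$count, 0))
  attr(out, "dropped") <- tibble(
    reason = c("length_out_of_range", "outside_codon_window"),
    n = c(bad_length, out_of_window))
  out
}

#' Call disome peaks
#'
#' A codon is a peak candidate when its disome density reaches `k_fold`
#' times the transcript's median density over non-zero codons and its raw
#' count reaches `min_count`. Candidates within `merge_gap` intervening
#' codons are merged into one peak whose summit is the densest codon and
#' whose intensity is the summed RPM of the interval. Transcripts with fewer
#' than `min_transcript_codons` analyzed codons are skipped. The rule is
#' scale-invariant: multiplying the whole library by a constant leaves the
#' calls unchanged.
#'
#' @param profiles Output of [build_disome_profiles()].
#' @param k_fold Enrichment threshold over the transcript median.
#' @param min_count Minimum raw count at a candidate codon.
#' @param merge_gap Maximum intervening codons between merged candidates.
#' @param min_transcript_codons Minimum analyzed codons per transcript.
#' @return A peak tibble (class `ribodyn_peaks`): `transcript_id`,
#'   `codon_start`, `codon_end` (half-open, codons), `summit`, `intensity`.
#' @export
call_disome_peaks <- function(profiles, k_fold = 4, min_count = 5,
                              merge_gap = 1L, min_transcript_codons = 20L) {
  out <- profiles |>
    group_by(.data$transcript_id) |>
    group_modify(function(d, key) {
      if (nrow(d) < min_transcript_codons) return(tibble())
      nz <- d$rpm[d$rpm > 0]
      if (length(nz) == 0) return(tibble())
      med <- median(nz)
      cand <- d |>
        filter(.data$rpm >= k_fold * med, .data$count >= min_count) |>
        arrange(.data$codon_index)
      if (nrow(cand) == 0) return(tibble())
      grp <- cumsum(c(1L, diff(cand$codon_index) > merge_gap + 1L))
      cand |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(codon_start = min(.data$codon_index),
                  codon_end = max(.data$codon_index) + 1L,
                  summit = .data$codon_index[which.max(.data$rpm)],
                  .groups = "drop") |>
        select(-".grp") |>
        mutate(intensity = purrr::map2_dbl(
          .data$codon_start, .data$codon_end,
          ~ sum(d$rpm[d$codon_index >= .x & d$codon_index < .y])))
    }) |>
    ungroup()
  if (nrow(out) == 0) {
    out <- tibble(transcript_id = character(0), codon_start = integer(0),
                  codon_end = integer(0), summit = integer(0),
                  intensity = numeric(0))
  }
  class(out) <- c("ribodyn_peaks", class(out))
  out
}

#' Match peak sets between two conditions
#'
#' Greedy nearest-summit matching within `tolerance` codons on the same
#' transcript: candidate pairs are ranked by summit distance and matched one
#' to one; leftovers are condition-specific. The Venn identity
#' `common + only_a + only_b = |union|` holds by construction.
#'
#' @param peaks_a,peaks_b Peak tibbles from [call_disome_peaks()].
#' @param tolerance Maximum summit distance in codons.
#' @return A list of class `ribodyn_peak_match`: `pairs` (matched index
#'   pairs with distances), `counts` (`common`, `only_a`, `only_b`, `union`),
#'   and the input peak sets.
#' @export
match_peaks <- function(peaks_a, peaks_b, tolerance = 1L) {
  pa <- mutate(as_tibble(peaks_a), .ia = dplyr::row_number())
  pb <- mutate(as_tibble(peaks_b), .ib = dplyr::row_number())
  cand <- inner_join(select(pa, "transcript_id", ".ia", summit_a = "summit"),
                     select(pb, "transcript_id", ".ib", summit_b = "summit"),
                     by = "transcript_id",
                     relationship = "many-to-many") |>
    mutate(distance = abs(.data$summit_a - .data$summit_b)) |>
    filter(.data$distance <= tolerance) |>
    arrange(.data$distance)
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$.ia[i]; ib <- cand$.ib[i]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  pairs <- cand[keep, ]
  counts <- list(common = nrow(pairs),
                 only_a = nrow(pa) - nrow(pairs),
                 only_b = nrow(pb) - nrow(pairs))
  counts$union <- counts$common + counts$only_a + counts$only_b
  structure(list(pairs = pairs, counts = counts,
                 peaks_a = pa, peaks_b = pb),
            class = "ribodyn_peak_match")
}

#' @export
print.ribodyn_peak_match <- function(x, ...) {
  cat("Peak match:", x$counts$common, "common,", x$counts$only_a,
      "A-only,", x$counts$only_b, "B-only (union",
      paste0(x$counts$union, ")"), "\n")
  invisible(x)
}

#' Union of two matched peak sets
#'
#' Matched pairs are merged into a single peak spanning both intervals;
#' unmatched peaks are carried over unchanged.
#'
#' @param match A `ribodyn_peak_match` from [match_peaks()].
#' @return A peak tibble over the union.
#' @export
union_peaks <- function(match) {
  pa <- match$peaks_a; pb <- match$peaks_b
  merged <- match$pairs |>
    left_join(select(pa, ".ia", a_start = "codon_start", a_end = "codon_end",
                     a_int = "intensity"), by = ".ia") |>
    left_join(select(pb, ".ib", b_start = "codon_start", b_end = "codon_end"),
              by = ".ib") |>
    transmute(transcript_id = .data$transcript_id,
              codon_start = pmin(.data$a_start, .data$b_start),
              codon_end = pmax(.data$a_end, .data$b_end),
              summit = .data$summit_a,
              intensity = .data$a_int)
  only_a <- anti_join(pa, match$pairs, by = ".ia")
  only_b <- anti_join(pb, match$pairs, by = ".ib")
  out <- bind_rows(merged,
                   select(only_a, -".ia"),
                   select(only_b, -".ib")) |>
    arrange(.data$transcript_id, .data$codon_start)
  class(out) <- c("ribodyn_peaks", class(out))
  out
}

#' Peak intensity fold changes between conditions
#'
#' Per peak, the replicate-mean RPM summed over the peak interval is
#' computed for each condition and the log2 ratio reported with a
#' pseudocount, so condition-specific peaks receive finite values.
#'
#' @param peaks A peak tibble (typically [union_peaks()] of both
#'   conditions).
#' @param profiles_a,profiles_b Lists of replicate disome profile tibbles.
#' @param pseudocount Added to both intensities (RPM).
#' @return `peaks` with `intensity_a`, `intensity_b` and `log2fc` columns.
#' @export
peak_fold_change <- function(peaks, profiles_a, profiles_b,
                             pseudocount = 0.5) {
  peak_intensity <- function(profiles) {
    per_rep <- purrr::map(profiles, function(prof) {
      purrr::pmap_dbl(list(peaks$transcript_id, peaks$codon_start,
                           peaks$codon_end),
                      function(tx, s, e) {
                        sum(prof$rpm[prof$transcript_id == tx &
                                       prof$codon_index >= s &
                                       prof$codon_index < e])
                      })
    })
    rowMeans(do.call(cbind, per_rep))
  }
  peaks |>
    as_tibble() |>
    mutate(intensity_a = peak_intensity(profiles_a),
           intensity_b = peak_intensity(profiles_b),
           log2fc = log2((.data$intensity_b + pseudocount) /
                           (.data$intensity_a + pseudocount)))
}

#' Overlap of codon positions with peaks
#'
#' Counts query codons lying within a peak interval widened by `tolerance`
#' codons on each side.
#'
#' @param positions Tibble `transcript_id`, `codon_index` (e.g. significant
#'   pause sites).
#' @param peaks A peak tibble.
#' @param tolerance Interval widening in codons.
#' @return A list: `n_query`, `n_in_peaks`, `n_outside`, and `hits`, the
#'   positions annotated with a logical `in_peak`.
#' @export
codons_in_peaks <- function(positions, peaks, tolerance = 1L) {
  pk <- as_tibble(peaks)
  in_peak <- purrr::map2_lgl(positions$transcript_id, positions$codon_index,
                             function(tx, ci) {
                               any(pk$transcript_id == tx &
                                     ci >= pk$codon_start - tolerance &
                                     ci < pk$codon_end + tolerance)
                             })
  list(n_query = nrow(positions),
       n_in_peaks = sum(in_peak),
       n_outside = sum(!in_peak),
       hits = mutate(positions, in_peak = in_peak))
}
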