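# Relative codon occupancy, amino-acid aggregation, RUST metafootprint
# enrichment, per-transcript CV and translation efficiency.
#
# Relative occupancy rho_c of a codon identity is the mean RPM over all
# analyzed positions carrying that codon divided by the mean RPM over all
# analyzed positions; rho_c > 1 marks slow decoding (ribosomes dwell with
# codon c in the chosen site).

site_column <- function(site) {
  site <- match.arg(tolower(site), c("a", "p", "e"))
  paste0(site, "_rpm")
}

# Transcripts passing the coverage gate for a given site column.
qualifying_transcripts <- function(profiles, col, min_mean_rpm, min_codons) {
  profiles |>
    summarise(n_codons = dplyr::n(),
              mean_rpm = mean(.data[[col]]),
              .by = "transcript_id") |>
    filter(.data$mean_rpm >= min_mean_rpm, .data$n_codons >= min_codons)
}

#' Relative codon occupancy
#'
#' Restricts to transcripts with mean RPM at least `min_mean_rpm` over at
#' least `min_codons` analyzed codons, pools all their codon positions, and
#' reports per codon identity the occurrence count, mean RPM, and relative
#' occupancy `rho = mean RPM at the codon / mean RPM over all positions`.
#' The occurrence-weighted mean of `rho` is 1 by construction.
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @param site Ribosomal site: `"a"`, `"p"` or `"e"`.
#' @param min_mean_rpm,min_codons Per-transcript coverage gates (for real
#'   libraries a mean raw count of about 1 per codon and at least 100 codons
#'   are reasonable; defaults are permissive so small examples work).
#' @return A tibble `codon`, `amino_acid`, `n`, `mean_rpm`, `rho` (class
#'   `ribodyn_occupancy`), with attributes `site` and `overall_mean`.
#' @export
relative_codon_occupancy <- function(profiles, site = "a",
                                     min_mean_rpm = 0, min_codons = 1) {
  col <- site_column(site)
  ok <- qualifying_transcripts(profiles, col, min_mean_rpm, min_codons)
  if (nrow(ok) == 0) abort("No transcript passes the coverage gate")
  pooled <- semi_join(profiles, ok, by = "transcript_id")
  overall <- mean(pooled[[col]])
  if (overall <= 0) abort("Library carries no signal at the requested site")
  out <- pooled |>
    summarise(n = dplyr::n(), mean_rpm = mean(.data[[col]]), .by = "codon") |>
    mutate(rho = .data$mean_rpm / overall) |>
    left_join(codon_table(), by = "codon") |>
    select("codon", "amino_acid", "n", "mean_rpm", "rho") |>
    arrange(.data$codon)
  attr(out, "site") <- tolower(site)
  attr(out, "overall_mean") <- overall
  class(out) <- c("ribodyn_occupancy", class(out))
  out
}

#' Aggregate codon occupancy per amino acid
#'
#' Occurrence-weighted mean of `rho` over the synonymous codons of each
#' amino acid.
#'
#' @param occupancy An occupancy table from [relative_codon_occupancy()].
#' @return A tibble `amino_acid`, `n`, `rho`.
#' @export
aggregate_amino_acid <- function(occupancy) {
  occupancy |>
    as_tibble() |>
    summarise(rho = sum(.data$n * .data$rho) / sum(.data$n),
              n = sum(.data$n),
              .by = "amino_acid") |>
    select("amino_acid", "n", "rho") |>
    arrange(.data$amino_acid)
}

#' RUST metafootprint codon enrichment
#'
#' Coverage-robust codon enrichment: each transcript profile is binarised at
#' its own mean (1 where the value strictly exceeds the mean), the codon
#' identity frequencies among above-mean positions are pooled across
#' transcripts (observed), and divided by the codon frequencies among all
#' analyzed positions of the contributing transcripts (expected). Transcripts
#' with no above-mean position (e.g. zero variance) contribute nothing.
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @param site Ribosomal site.
#' @param min_codons Minimum analyzed codons per transcript.
#' @return A tibble `codon`, `amino_acid`, `observed`, `expected` (pooled
#'   frequencies) and `rust_ratio = observed / expected`.
#' @export
rust_metafootprint <- function(profiles, site = "a", min_codons = 1) {
  col <- site_column(site)
  x <- profiles |>
    mutate(above = .data[[col]] > mean(.data[[col]]),
           n_above = sum(.data$above),
           n_codons = dplyr::n(),
           .by = "transcript_id") |>
    filter(.data$n_above > 0, .data$n_codons >= min_codons)
  if (nrow(x) == 0) abort("No transcript has above-mean positions")
  tot_above <- sum(x$above)
  tot_all <- nrow(x)
  x |>
    summarise(observed = sum(.data$above) / tot_above,
              expected = dplyr::n() / tot_all,
              .by = "codon") |>
    mutate(rust_ratio = .data$observed / .data$expected) |>
    left_join(codon_table(), by = "codon") |>
    select("codon", "amino_acid", "observed", "expected", "rust_ratio") |>
    arrange(.data$codon)
}

#' Per-transcript coefficient of variation of occupancy
#'
#' Sample standard deviation (n-1 denominator) over the mean of the
#' per-codon density of each qualifying transcript. A wider spread of
#' elongation rates along a transcript raises its CV.
#'
#' @param profiles A profile tibble.
#' @param site Ribosomal site (A by default, the decoded codon).
#' @param min_mean_rpm,min_codons Coverage gates; transcripts with zero mean
#'   are omitted.
#' @return A tibble `transcript_id`, `n_codons`, `mean_rpm`, `cv`.
#' @export
transcript_cv <- function(profiles, site = "a",
                          min_mean_rpm = 0, min_codons = 2) {
  col <- site_column(site)
  profiles |>
    summarise(n_codons = dplyr::n(),
              mean_rpm = mean(.data[[col]]),
              cv = sd(.data[[col]]) / mean(.data[[col]]),
              .by = "transcript_id") |>
    filter(.data$mean_rpm > 0, .data$mean_rpm >= min_mean_rpm,
           .data$n_codons >= min_codons)
}

#' Translation efficiency
#'
#' Footprint density over mRNA density per transcript: each library is
#' normalised to reads per million, densities are expressed per CDS kilobase,
#' and `te = ribo_density / rna_density` (undefined where the RNA density is
#' zero). Doubling either library uniformly leaves TE unchanged.
#'
#' @param ribo_counts,rna_counts Tibbles `transcript_id`, `count` (e.g. from
#'   [footprint_counts()]).
#' @param transcripts A transcript tibble (for CDS lengths).
#' @return A tibble `transcript_id`, `ribo_density`, `rna_density`, `te`.
#' @export
translation_efficiency <- function(ribo_counts, rna_counts, transcripts) {
  ribo_total <- sum(ribo_counts$count)
  rna_total <- sum(rna_counts$count)
  if (ribo_total <= 0 || rna_total <= 0) abort("Empty count table")
  transcripts |>
    transmute(transcript_id = .data$transcript_id,
              cds_kb = (.data$cds_end - .data$cds_start) / 1000) |>
    inner_join(rename(ribo_counts, ribo = "count"), by = "transcript_id") |>
    inner_join(rename(rna_counts, rna = "count"), by = "transcript_id") |>
    mutate(ribo_density = .data$ribo * 1e6 / ribo_total / .data$cds_kb,
           rna_density = .data$rna * 1e6 / rna_total / .data$cds_kb,
           te = ifelse(.data$rna_density > 0,
                       .data$ribo_density / .data$rna_density, NA_real_)) |>
    select("transcript_id", "ribo_density", "rna_density", "te")
}
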