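# Between-condition comparisons: codon-level occupancy fold changes,
# per-codon-position differential pause testing with BH adjustment inside
# each amino-acid family, cross-experiment fold-change correlation, and
# metagene profiles around anchor codons.

#' Codon-level occupancy fold changes between conditions
#'
#' Averages relative occupancy over replicates within each condition and
#' reports `log2(mean_b / mean_a)` per codon identity (or per amino acid
#' after occurrence-weighted aggregation). Identities absent or zero in
#' either condition are omitted and listed in the `"omitted"` attribute.
#'
#' @param tables_a,tables_b Lists of replicate occupancy tables from
#'   [relative_codon_occupancy()] (amino-acid tables from
#'   [aggregate_amino_acid()] when `level = "amino_acid"`).
#' @param level `"codon"` or `"amino_acid"`.
#' @return A tibble with the identity column, `mean_rho_a`, `mean_rho_b`,
#'   `log2fc`.
#' @export
codon_fold_change <- function(tables_a, tables_b, level = c("codon",
                                                            "amino_acid")) {
  level <- match.arg(level)
  key <- if (level == "codon") "codon" else "amino_acid"
  cond_mean <- function(tables, nm) {
    purrr::map_dfr(tables, ~ as_tibble(.x)[, c(key, "rho")]) |>
      summarise("{nm}" := mean(.data$rho), .by = all_of(key))
  }
  a <- cond_mean(tables_a, "mean_rho_a")
  b <- cond_mean(tables_b, "mean_rho_b")
  joined <- full_join(a, b, by = key)
  ok <- !is.na(joined$mean_rho_a) & !is.na(joined$mean_rho_b) &
    joined$mean_rho_a > 0 & joined$mean_rho_b > 0
  out <- joined[ok, ] |>
    mutate(log2fc = log2(.data$mean_rho_b / .data$mean_rho_a)) |>
    arrange(.data[[key]])
  attr(out, "omitted") <- joined[[key]][!ok]
  out
}

#' Per-codon-position differential occupancy test
#'
#' For every analyzed codon position, per-replicate occupancy is normalised
#' as position RPM divided by the transcript's mean RPM in that replicate
#' (removing transcript-abundance differences between conditions), and the
#' two groups are compared with a two-sided pooled-variance Student's t
#' test. Positions enter testing when their mean raw A-site count across
#' replicates reaches `min_mean_count` in at least one group. q values are
#' BH-adjusted within each amino-acid family of the tested codons, so e.g.
#' Pro and Ala positions form separate multiple-testing families.
#'
#' @param profiles_a,profiles_b Lists of replicate profile tibbles from
#'   [build_profiles()] (same transcriptome; at least 2 replicates each).
#' @param codon_filter Optional codon identities to test (e.g.
#'   `codons_for(c("P", "A"))`); default all sense codons.
#' @param min_mean_count Coverage gate on the mean raw count per position.
#' @param alpha Significance level applied to `q`.
#' @return A tibble of class `ribodyn_postest`: `transcript_id`,
#'   `codon_index`, `codon`, `amino_acid`, `mean_a`, `mean_b`, `log2fc`,
#'   `t`, `df`, `p`, `q`, `degenerate`, `significant`.
#' @export
position_differential <- function(profiles_a, profiles_b, codon_filter = NULL,
                                  min_mean_count = 5, alpha = 0.05) {
  if (length(profiles_a) < 2 || length(profiles_b) < 2) {
    abort("At least 2 replicates per group are required")
  }
  norm_one <- function(prof, nm) {
    prof |>
      mutate(tx_mean = mean(.data$a_rpm), .by = "transcript_id") |>
      transmute(transcript_id = .data$transcript_id,
                codon_index = .data$codon_index,
                codon = .data$codon,
                "{nm}" := ifelse(.data$tx_mean > 0,
                                 .data$a_rpm / .data$tx_mean, NA_real_),
                "cnt_{nm}" := .data$a_count)
  }
  bind_reps <- function(profiles, prefix) {
    tabs <- purrr::imap(profiles,
                        ~ norm_one(.x, paste0(prefix, .y)))
    purrr::reduce(tabs, inner_join,
                  by = c("transcript_id", "codon_index", "codon"))
  }
  wide <- inner_join(bind_reps(profiles_a, "a"), bind_reps(profiles_b, "b"),
                     by = c("transcript_id", "codon_index", "codon"))
  if (!is.null(codon_filter)) {
    wide <- filter(wide, .data$codon %in% codon_filter)
  }
  na_cols <- paste0("a", seq_along(profiles_a))
  nb_cols <- paste0("b", seq_along(profiles_b))
  amat <- as.matrix(wide[, na_cols])
  bmat <- as.matrix(wide[, nb_cols])
  ca <- as.matrix(wide[, paste0("cnt_", na_cols)])
  cb <- as.matrix(wide[, paste0("cnt_", nb_cols)])
  covered <- (rowMeans(ca) >= min_mean_count | rowMeans(cb) >= min_mean_count) &
    stats::complete.cases(amat) & stats::complete.cases(bmat)
  wide <- wide[covered, ]
  amat <- amat[covered, , drop = FALSE]
  bmat <- bmat[covered, , drop = FALSE]
  if (nrow(wide) == 0) abort("No position passes the coverage gate")
  tt <- row_pooled_t(amat, bmat)
  out <- wide |>
    select("transcript_id", "codon_index", "codon") |>
    left_join(codon_table(), by = "codon") |>
    bind_cols(tt) |>
    mutate(log2fc = log2(.data$mean_b / .data$mean_a)) |>
    mutate(q = bh_adjust(.data$p), .by = "amino_acid") |>
    mutate(significant = .data$q < alpha) |>
    select("transcript_id", "codon_index", "codon", "amino_acid",
           "mean_a", "mean_b", "log2fc", "t", "df", "p", "q",
           "degenerate", "significant")
  class(out) <- c("ribodyn_postest", class(out))
  out
}

#' Spearman correlation of codon fold changes between two experiments
#'
#' @param fc_1,fc_2 Fold-change tables from [codon_fold_change()] on a shared
#'   codon (or amino-acid) universe; at least 4 shared identities.
#' @param family_size Bonferroni family size (default 3: the A-, P- and
#'   E-site comparisons form one family).
#' @return A `ribodyn_cor` object (see [spearman_cor()]).
#' @export
spearman_fc_correlation <- function(fc_1, fc_2, family_size = 3L) {
  key <- intersect(c("codon", "amino_acid"), intersect(names(fc_1),
                                                       names(fc_2)))[1]
  if (is.na(key)) abort("Fold-change tables share no identity column")
  joined <- inner_join(as_tibble(fc_1)[, c(key, "log2fc")],
                       as_tibble(fc_2)[, c(key, "log2fc")],
                       by = key, suffix = c("_1", "_2"))
  if (nrow(joined) < 4) abort("Fewer than 4 shared identities")
  spearman_cor(joined$log2fc_1, joined$log2fc_2, family_size = family_size)
}

#' Metagene profile around anchor codons
#'
#' For each anchor (transcript, codon index), the density over offsets
#' `-window..window` codons is extracted, normalised by its own window mean,
#' and averaged over anchors; replicate profiles are then averaged. Anchors
#' whose window leaves the analyzed codon range (or with zero window mean)
#' are skipped and tallied in the `"skipped"` attribute.
#'
#' @param profiles A profile tibble or a list of replicate profile tibbles.
#' @param anchors Tibble `transcript_id`, `codon_index`.
#' @param window Half-width in codons.
#' @param site Ribosomal site.
#' @return A tibble of class `ribodyn_metagene`: `offset`, `density`,
#'   `n_anchors`.
#' @export
metagene <- function(profiles, anchors, window = 15L, site = "a") {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  col <- site_column(site)
  per_rep <- purrr::map(profiles, function(prof) {
    vals <- prof |>
      select("transcript_id", "codon_index", value = all_of(col))
    win <- anchors |>
      mutate(anchor = dplyr::row_number()) |>
      tidyr::expand_grid(offset = seq.int(-window, window)) |>
      mutate(codon_index = .data$codon_index + .data$offset) |>
      inner_join(vals, by = c("transcript_id", "codon_index"))
    full <- win |>
      mutate(n_off = dplyr::n(), wmean = mean(.data$value), .by = "anchor") |>
      filter(.data$n_off == 2L * window + 1L, .data$wmean > 0)
    skipped <- nrow(anchors) - dplyr::n_distinct(full$anchor)
    prof_out <- full |>
      mutate(norm = .data$value / .data$wmean) |>
      summarise(density = mean(.data$norm), .by = "offset")
    list(profile = prof_out, skipped = skipped,
         n_anchors = dplyr::n_distinct(full$anchor))
  })
  out <- purrr::map_dfr(per_rep, "profile") |>
    summarise(density = mean(.data$density), .by = "offset") |>
    arrange(.data$offset) |>
    mutate(n_anchors = per_rep[[1]]$n_anchors)
  attr(out, "skipped") <- purrr::map_int(per_rep, "skipped")
  class(out) <- c("ribodyn_metagene", class(out))
  out
}
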