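# Seeded generator for synthetic transcriptomes, monosome/disome footprint
# libraries and matched RNA-seq counts, with a ground-truth ledger. The
# generator is the inverse of the analysis: A-site codons are drawn with
# probability proportional to transcript abundance times per-codon dwell
# time, the 5' end of an in-frame monosome read sits 15 nt upstream of its
# A-site, and disome reads place the leading ribosome's A-site at planted
# collision sites.

#' Simulation configuration
#'
#' @param n_transcripts Number of transcripts to generate.
#' @param cds_length_range Length-2 vector: CDS length range in codons
#'   (start and stop codons included). Must be at least 30 codons so that
#'   excluding the first/last five codons leaves at least 20 analyzable ones.
#' @param length_distribution Named numeric vector of read-length
#'   probabilities over 17–34 nt; must sum to 1 (default concentrates mass on
#'   28–30 nt, as in rodent heart monosome libraries).
#' @param offframe_noise Fraction of reads shifted by +/-1 nt off frame.
#' @param depth Expected footprints per library.
#' @param n_replicates Libraries per condition.
#' @param dispersion Log-normal sigma of multiplicative replicate noise,
#'   applied both to library depth and to per-position means.
#' @param utr_length 5'/3' UTR length in nt (>= 18 so 15-nt offsets never
#'   underflow; the default 60 also accommodates 80-nt disome fragments).
#' @param codon_weights Optional named weights over the 61 sense codons used
#'   when sampling CDS codons; default uniform, so codon usage does not
#'   confound occupancy estimates in tests.
#' @param seed Integer seed; every stochastic operation is deterministic
#'   given the seed it receives.
#' @return A list of class `ribodyn_sim_config`.
#' @export
sim_config <- function(n_transcripts = 50L,
                       cds_length_range = c(100L, 400L),
                       length_distribution = default_length_distribution(),
                       offframe_noise = 0.05,
                       depth = 1e6,
                       n_replicates = 4L,
                       dispersion = 0.1,
                       utr_length = 60L,
                       codon_weights = NULL,
                       seed = 1L) {
  cds_length_range <- unlist(cds_length_range)
  length_distribution <- unlist(length_distribution)
  if (!is.null(codon_weights)) codon_weights <- unlist(codon_weights)
  if (length(cds_length_range) != 2 || cds_length_range[1] > cds_length_range[2]) {
    abort("`cds_length_range` must be c(min, max) in codons")
  }
  if (cds_length_range[1] < 30L) {
    abort("`cds_length_range` must be at least 30 codons")
  }
  lens <- as.integer(names(length_distribution))
  if (anyNA(lens) || any(lens < 17L) || any(lens > 34L)) {
    abort("`length_distribution` names must be read lengths in 17..34")
  }
  if (abs(sum(length_distribution) - 1) > 1e-9) {
    abort("`length_distribution` must sum to 1")
  }
  if (offframe_noise < 0 || offframe_noise >= 1) {
    abort("`offframe_noise` must lie in [0, 1)")
  }
  if (depth <= 0) abort("`depth` must be positive")
  if (utr_length < 18L) abort("`utr_length` must be at least 18 nt")
  if (!is.null(codon_weights)) {
    if (!setequal(names(codon_weights), sense_codons()) || any(codon_weights <= 0)) {
      abort("`codon_weights` must be positive and named by the 61 sense codons")
    }
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 cds_length_range = as.integer(cds_length_range),
                 length_distribution = length_distribution,
                 offframe_noise = offframe_noise,
                 depth = depth,
                 n_replicates = as.integer(n_replicates),
                 dispersion = dispersion,
                 utr_length = as.integer(utr_length),
                 codon_weights = codon_weights,
                 seed = as.integer(seed)),
            class = "ribodyn_sim_config")
}

#' Default monosome read-length distribution
#'
#' 80% of the mass on 28–30 nt (the lengths carrying the 15-nt A-site
#' offset), the remainder spread evenly over the other lengths of the
#' 17–34-nt size-selection window.
#'
#' @return Named probability vector over lengths 17–34.
#' @export
default_length_distribution <- function() {
  lens <- 17:34
  p <- setNames(rep(0, length(lens)), lens)
  p["28"] <- 0.35; p["29"] <- 0.30; p["30"] <- 0.15
  rest <- setdiff(as.character(lens), c("28", "29", "30"))
  p[rest] <- 0.20 / length(rest)
  p / sum(p)
}

#' Dwell-time specification
#'
#' Per-codon dwell times drive the A-site sampling probabilities: a codon
#' with multiplier m is decoded m times more slowly, so ribosomes are
#' observed there m times more often.
#'
#' @param base_dwell Baseline dwell per codon (arbitrary time units).
#' @param codon_multipliers Named positive multipliers for a subset of the 61
#'   sense codons (unnamed codons keep multiplier 1).
#' @param site_multipliers Optional tibble `transcript_id`, `codon_index`,
#'   `multiplier` of site-specific stalls.
#' @return A list of class `ribodyn_dwell_spec`.
#' @export
dwell_spec <- function(base_dwell = 1,
                       codon_multipliers = numeric(0),
                       site_multipliers = NULL) {
  codon_multipliers <- unlist(codon_multipliers) %||% numeric(0)
  if (base_dwell <= 0) abort("`base_dwell` must be positive")
  if (length(codon_multipliers) > 0) {
    bad <- setdiff(names(codon_multipliers), sense_codons())
    if (length(bad) > 0) {
      abort(paste0("Not sense codons: ", paste(bad, collapse = ", ")))
    }
    if (any(codon_multipliers <= 0)) abort("Multipliers must be positive")
  }
  if (!is.null(site_multipliers)) {
    stopifnot(all(c("transcript_id", "codon_index", "multiplier") %in%
                    names(site_multipliers)))
    if (any(site_multipliers$multiplier <= 0)) {
      abort("Site multipliers must be positive")
    }
  }
  structure(list(base_dwell = base_dwell,
                 codon_multipliers = codon_multipliers,
                 site_multipliers = site_multipliers),
            class = "ribodyn_dwell_spec")
}

# Full 61-codon multiplier vector implied by a dwell spec.
dwell_multipliers <- function(dwell) {
  m <- setNames(rep(1, 61), sense_codons())
  m[names(dwell$codon_multipliers)] <- dwell$codon_multipliers
  m * dwell$base_dwell
}

#' Generate a synthetic transcriptome
#'
#' Each transcript is an ATG-initiated CDS of random sense codons ending in a
#' random stop codon, flanked by random UTRs. Transcript abundances are drawn
#' log-normally and normalised to sum to 1.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A transcript tibble with an extra `abundance` column.
#' @export
generate_transcriptome <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n_transcripts
  ids <- sprintf("t%04d", seq_len(n))
  codons <- sense_codons()
  w <- if (is.null(cfg$codon_weights)) rep(1, 61) else cfg$codon_weights[codons]
  stops <- c("TAA", "TAG", "TGA")
  nt <- c("A", "C", "G", "T")
  len_choices <- seq.int(cfg$cds_length_range[1], cfg$cds_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    body <- sample(codons, L - 2L, replace = TRUE, prob = w)
    utr5 <- paste(sample(nt, cfg$utr_length, replace = TRUE), collapse = "")
    utr3 <- paste(sample(nt, cfg$utr_length, replace = TRUE), collapse = "")
    paste0(utr5, "ATG", paste(body, collapse = ""), sample(stops, 1L), utr3)
  }, character(1))
  abundance <- rlnorm(n, meanlog = 0, sdlog = 1)
  tibble(transcript_id = ids,
         sequence = seqs,
         length = nchar(seqs),
         cds_start = cfg$utr_length,
         cds_end = cfg$utr_length + 3L * lens,
         cds_codons = lens,
         abundance = abundance / sum(abundance))
}

# Position table over analyzed codons of all transcripts: one row per
# (transcript, codon index) with codon identity and abundance.
position_table <- function(transcripts) {
  ok <- transcripts$cds_codons >= 11L
  tx <- transcripts[ok, ]
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    idx <- analysis_window(tx$cds_codons[i])
    tibble(transcript_id = tx$transcript_id[i],
           codon_index = idx,
           codon = codon_at(tx$sequence[i], tx$cds_start[i], idx),
           cds_start = tx$cds_start[i],
           abundance = tx$abundance[i])
  })
}

#' Simulate a monosome footprint library
#'
#' A-site codon positions are drawn multinomially with probability
#' proportional to `abundance x dwell(codon) x site multiplier`, restricted
#' to the analyzed codon window. Read lengths follow
#' `cfg$length_distribution`; in-frame reads start 15 nt upstream of the
#' A-site and a fraction `cfg$offframe_noise` are shifted by +/-1 nt.
#'
#' @param transcripts Transcript tibble with `abundance` (from
#'   [generate_transcriptome()]).
#' @param dwell A [dwell_spec()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param depth Number of footprints to draw (defaults to `cfg$depth`).
#' @param position_noise_sd Log-normal sigma of per-position multiplicative
#'   noise (0 = pure multinomial sampling).
#' @return A list with `footprints` (footprint tibble) and `truth` (list:
#'   `positions` with sampling probabilities, `codon_multipliers`,
#'   `site_multipliers`, `abundance`, `skipped` transcripts).
#' @export
simulate_monosome_footprints <- function(transcripts, dwell, cfg,
                                         seed = cfg$seed,
                                         depth = cfg$depth,
                                         position_noise_sd = 0) {
  set.seed(seed)
  skipped <- transcripts$transcript_id[transcripts$cds_codons < 11L]
  if (length(skipped) > 0) {
    warn(paste0("Skipping transcripts shorter than the exclusion window: ",
                paste(skipped, collapse = ", ")))
  }
  pos <- position_table(transcripts)
  mult <- dwell_multipliers(dwell)
  w <- pos$abundance * mult[pos$codon]
  if (!is.null(dwell$site_multipliers)) {
    sm <- dwell$site_multipliers
    key <- paste(pos$transcript_id, pos$codon_index)
    site_key <- paste(sm$transcript_id, sm$codon_index)
    hit <- match(key, site_key)
    w <- w * ifelse(is.na(hit), 1, sm$multiplier[hit])
  }
  prob <- w / sum(w)
  w_draw <- if (position_noise_sd > 0) {
    w * rlnorm(length(w), 0, position_noise_sd)
  } else w
  counts <- as.vector(rmultinom(1, size = round(depth), prob = w_draw))
  keep <- counts > 0
  reads <- tibble(transcript_id = pos$transcript_id[keep],
                  a_nt = pos$cds_start[keep] + 3L * pos$codon_index[keep],
                  n = counts[keep])
  # split each position's reads over lengths, then over frame shifts
  ld <- cfg$length_distribution
  lens <- as.integer(names(ld))
  len_counts <- vapply(reads$n, function(n) {
    as.vector(rmultinom(1, n, ld))
  }, numeric(length(lens)))
  fp <- tibble(transcript_id = rep(reads$transcript_id, each = length(lens)),
               a_nt = rep(reads$a_nt, each = length(lens)),
               length = rep(lens, times = nrow(reads)),
               n = as.vector(len_counts)) |>
    filter(.data$n > 0)
  f <- cfg$offframe_noise
  shift_counts <- vapply(fp$n, function(n) {
    as.vector(rmultinom(1, n, c(1 - f, f / 2, f / 2)))
  }, numeric(3))
  shifts <- c(0L, -1L, 1L)
  fp <- tibble(transcript_id = rep(fp$transcript_id, each = 3L),
               five_prime_pos = rep(fp$a_nt - 15L, each = 3L) +
                 rep(shifts, times = nrow(fp)),
               length = rep(fp$length, each = 3L),
               count = as.vector(shift_counts)) |>
    filter(.data$count > 0) |>
    summarise(count = sum(.data$count),
              .by = c("transcript_id", "five_prime_pos", "length")) |>
    arrange(.data$transcript_id, .data$five_prime_pos, .data$length)
  truth <- list(positions = mutate(pos, prob = prob),
                codon_multipliers = mult,
                site_multipliers = dwell$site_multipliers,
                abundance = select(transcripts, "transcript_id", "abundance"),
                skipped = skipped)
  list(footprints = fp, truth = truth)
}

#' Simulate a disome footprint library
#'
#' Fragments of 50–80 nt protected by two collided ribosomes. With
#' probability `p_stall` a read's leading-ribosome A-site falls on a planted
#' collision site; otherwise it falls uniformly (abundance-weighted) over
#' the analyzed codons. The 5' end is `A-site nt + 15 - fragment length`,
#' mirroring the monosome offset applied to the downstream (leading)
#' ribosome.
#'
#' @param transcripts Transcript tibble with `abundance`.
#' @param stall_sites Tibble `transcript_id`, `codon_index` of collision
#'   sites (may have a `weight` column; default equal weights).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param p_stall Probability a read originates from a stall site.
#' @param depth Number of disome footprints.
#' @param length_range Fragment length range in nt.
#' @return A footprint tibble (50–80-nt records).
#' @export
simulate_disome_footprints <- function(transcripts, stall_sites, cfg,
                                       seed = cfg$seed,
                                       p_stall = 0.8,
                                       depth = 1e5,
                                       length_range = c(50L, 80L)) {
  set.seed(seed)
  pos <- position_table(transcripts)
  if (!is.null(stall_sites) && nrow(stall_sites) > 0) {
    key <- paste(pos$transcript_id, pos$codon_index)
    sk <- paste(stall_sites$transcript_id, stall_sites$codon_index)
    if (!all(sk %in% key)) {
      abort("Stall sites must lie within the analyzed codon window")
    }
    sw <- if ("weight" %in% names(stall_sites)) {
      stall_sites$weight
    } else {
      rep(1, nrow(stall_sites))
    }
  } else {
    p_stall <- 0
  }
  n_stall <- rbinom(1, round(depth), p_stall)
  draws <- list()
  if (n_stall > 0) {
    i <- match(sk, key)
    cnt <- as.vector(rmultinom(1, n_stall, sw))
    draws$stall <- tibble(transcript_id = pos$transcript_id[i],
                          a_nt = pos$cds_start[i] + 3L * pos$codon_index[i],
                          n = cnt)
  }
  n_bg <- round(depth) - n_stall
  if (n_bg > 0) {
    cnt <- as.vector(rmultinom(1, n_bg, pos$abundance))
    draws$bg <- tibble(transcript_id = pos$transcript_id,
                       a_nt = pos$cds_start + 3L * pos$codon_index,
                       n = cnt)
  }
  reads <- bind_rows(draws) |> filter(.data$n > 0)
  lens <- seq.int(length_range[1], length_range[2])
  len_counts <- vapply(reads$n, function(n) {
    as.vector(rmultinom(1, n, rep(1 / length(lens), length(lens))))
  }, numeric(length(lens)))
  tx_len <- setNames(transcripts$length, transcripts$transcript_id)
  fp <- tibble(transcript_id = rep(reads$transcript_id, each = length(lens)),
               a_nt = rep(reads$a_nt, each = length(lens)),
               length = rep(lens, times = nrow(reads)),
               count = as.vector(len_counts)) |>
    filter(.data$count > 0) |>
    mutate(five_prime_pos = .data$a_nt + 15L - .data$length) |>
    filter(.data$five_prime_pos >= 0,
           .data$five_prime_pos + .data$length <=
             tx_len[.data$transcript_id]) |>
    select("transcript_id", "five_prime_pos", "length", "count") |>
    summarise(count = sum(.data$count),
              .by = c("transcript_id", "five_prime_pos", "length")) |>
    arrange(.data$transcript_id, .data$five_prime_pos, .data$length)
  fp
}

#' Simulate matched replicate groups for two conditions
#'
#' Generates `cfg$n_replicates` monosome libraries per condition from the
#' same transcriptome, with library depth and per-position means jittered
#' log-normally (`sigma = cfg$dispersion`), plus matched RNA-seq count
#' tables drawn from the transcript abundances.
#'
#' @param transcripts Transcript tibble with `abundance`.
#' @param dwell_a,dwell_b [dwell_spec()] for each condition.
#' @param cfg A [sim_config()] (`n_replicates >= 2`).
#' @param seed Integer seed.
#' @param rna_depth RNA-seq reads per library (defaults to `cfg$depth`).
#' @return A list with `footprints` (`$a`, `$b`: lists of footprint tibbles),
#'   `rna` (`$a`, `$b`: lists of count tibbles), and `truth` (including
#'   `planted_codons`, codon identities whose multiplier differs between
#'   conditions, and `planted_sites`, site-specific stalls differing between
#'   conditions).
#' @export
simulate_condition_pair <- function(transcripts, dwell_a, dwell_b, cfg,
                                    seed = cfg$seed, rna_depth = cfg$depth) {
  if (cfg$n_replicates < 2L) {
    abort("`n_replicates` must be >= 2 for differential testing")
  }
  n <- cfg$n_replicates
  set.seed(seed)
  depths <- round(cfg$depth * rlnorm(2L * n, 0, cfg$dispersion))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  sim_one <- function(dwell, k, depth_k) {
    simulate_monosome_footprints(transcripts, dwell, cfg,
                                 seed = rep_seeds[k], depth = depth_k,
                                 position_noise_sd = cfg$dispersion)
  }
  libs_a <- purrr::map(seq_len(n), function(k) sim_one(dwell_a, k, depths[k]))
  libs_b <- purrr::map(seq_len(n), function(k) sim_one(dwell_b, n + k,
                                                       depths[n + k]))
  set.seed(seed + 1L)
  rna <- purrr::map(seq_len(2L * n), function(k) {
    cnt <- as.vector(rmultinom(1, round(rna_depth), transcripts$abundance))
    tibble(transcript_id = transcripts$transcript_id, count = cnt)
  })
  ma <- dwell_multipliers(dwell_a)
  mb <- dwell_multipliers(dwell_b)
  planted_codons <- tibble(codon = sense_codons(),
                           mult_a = unname(ma), mult_b = unname(mb)) |>
    filter(abs(log(.data$mult_b / .data$mult_a)) > 1e-12)
  planted_sites <- site_diff(dwell_a$site_multipliers, dwell_b$site_multipliers)
  list(footprints = list(a = purrr::map(libs_a, "footprints"),
                         b = purrr::map(libs_b, "footprints")),
       rna = list(a = rna[seq_len(n)], b = rna[n + seq_len(n)]),
       truth = list(planted_codons = planted_codons,
                    planted_sites = planted_sites,
                    depths = depths,
                    abundance = select(transcripts, "transcript_id",
                                       "abundance"),
                    truth_a = libs_a[[1]]$truth,
                    truth_b = libs_b[[1]]$truth))
}

site_diff <- function(sa, sb) {
  empty <- tibble(transcript_id = character(0), codon_index = integer(0),
                  mult_a = numeric(0), mult_b = numeric(0))
  if (is.null(sa) && is.null(sb)) return(empty)
  full_join(
    if (is.null(sa)) tibble(transcript_id = character(0),
                            codon_index = integer(0), mult_a = numeric(0))
    else select(sa, "transcript_id", "codon_index", mult_a = "multiplier"),
    if (is.null(sb)) tibble(transcript_id = character(0),
                            codon_index = integer(0), mult_b = numeric(0))
    else select(sb, "transcript_id", "codon_index", mult_b = "multiplier"),
    by = c("transcript_id", "codon_index")) |>
    mutate(mult_a = tidyr::replace_na(.data$mult_a, 1),
           mult_b = tidyr::replace_na(.data$mult_b, 1)) |>
    filter(abs(log(.data$mult_b / .data$mult_a)) > 1e-12)
}
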