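# On-disk formats and library-level filtering/normalisation.
#
# Coordinates are transcript-relative, 0-based and half-open throughout: a
# footprint record is (transcript_id, five_prime_pos, length, count) and the
# CDS annotation is (transcript_id, cds_start, cds_end) in nucleotides.

#' Read a transcriptome (FASTA + CDS annotation)
#'
#' @param fasta_path Path to a transcript FASTA file.
#' @param annotation_path Path to a tab-delimited annotation with a header and
#'   columns `transcript_id`, `cds_start`, `cds_end` (0-based, half-open,
#'   nucleotide coordinates).
#' @return A tibble with one row per transcript: `transcript_id`, `sequence`,
#'   `length`, `cds_start`, `cds_end` and `cds_codons` (CDS length in codons,
#'   stop codon included).
#' @export
read_transcriptome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate transcript ids in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = readr::col_character(),
                           cds_start = readr::col_integer(),
                           cds_end = readr::col_integer()))
  if (anyDuplicated(ann$transcript_id)) {
    abort("Duplicate transcript ids in annotation")
  }
  missing <- setdiff(ann$transcript_id, ids)
  if (length(missing) > 0) {
    abort(paste0("Annotation references transcripts absent from FASTA: ",
                 paste(missing, collapse = ", ")))
  }
  seq_chr <- as.character(seqs)
  names(seq_chr) <- ids
  out <- ann |>
    mutate(sequence = unname(seq_chr[.data$transcript_id]),
           length = nchar(.data$sequence)) |>
    select("transcript_id", "sequence", "length", "cds_start", "cds_end")
  validate_transcripts(out)
}

validate_transcripts <- function(tx) {
  bad_alpha <- grepl("[^ACGTN]", tx$sequence)
  if (any(bad_alpha)) {
    abort(paste0("Sequences contain characters outside {A,C,G,T,N}: ",
                 paste(tx$transcript_id[bad_alpha], collapse = ", ")))
  }
  cds_len <- tx$cds_end - tx$cds_start
  bad_frame <- cds_len %% 3L != 0L
  if (any(bad_frame)) {
    abort(paste0("CDS length not divisible by 3: ",
                 paste0(tx$transcript_id[bad_frame], " (CDS length ",
                        cds_len[bad_frame], ")", collapse = "; ")))
  }
  bad_bounds <- tx$cds_start < 0L | tx$cds_end > tx$length |
    tx$cds_end <= tx$cds_start
  if (any(bad_bounds)) {
    abort(paste0("CDS outside sequence bounds: ",
                 paste(tx$transcript_id[bad_bounds], collapse = ", ")))
  }
  mutate(tx, cds_codons = (.data$cds_end - .data$cds_start) %/% 3L)
}

#' Write a transcriptome as FASTA + annotation TSV
#'
#' @param transcripts A transcript tibble as returned by
#'   [read_transcriptome()] or [generate_transcriptome()].
#' @param fasta_path,annotation_path Output paths.
#' @return `transcripts`, invisibly.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                            transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(select(transcripts, "transcript_id", "cds_start", "cds_end"),
                   annotation_path)
  invisible(transcripts)
}

#' Read a footprint library
#'
#' Reads a tab-delimited footprint table (header line; columns
#' `transcript_id`, `five_prime_pos`, `length`, `count`). Rows describing the
#' same (transcript, position, length) are merged by summing counts, and the
#' result is returned in canonical sort order (transcript, position, length).
#'
#' @param path Path to the TSV.
#' @return A footprint tibble.
#' @export
read_footprints <- function(path) {
  fp <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          transcript_id = readr::col_character(),
                          five_prime_pos = readr::col_integer(),
                          length = readr::col_integer(),
                          count = readr::col_integer()))
  probs <- readr::problems(fp)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed footprint rows at line(s) ",
                 paste(unique(probs$row + 1L), collapse = ", "), " of ", path))
  }
  bad <- which(is.na(fp$five_prime_pos) | is.na(fp$count) | is.na(fp$length) |
                 fp$five_prime_pos < 0L | fp$count < 1L | fp$length < 1L)
  if (length(bad) > 0) {
    abort(paste0("Invalid footprint records (negative position, zero count ",
                 "or missing field) at line(s) ",
                 paste(bad + 1L, collapse = ", "), " of ", path))
  }
  fp |>
    summarise(count = sum(.data$count),
              .by = c("transcript_id", "five_prime_pos", "length")) |>
    arrange(.data$transcript_id, .data$five_prime_pos, .data$length)
}

#' Write a footprint library
#'
#' Records are written in canonical sort order so that read/write round-trips
#' are byte-identical.
#'
#' @param footprints A footprint tibble.
#' @param path Output path.
#' @return `footprints`, invisibly.
#' @export
write_footprints <- function(footprints, path) {
  footprints |>
    summarise(count = sum(.data$count),
              .by = c("transcript_id", "five_prime_pos", "length")) |>
    arrange(.data$transcript_id, .data$five_prime_pos, .data$length) |>
    mutate(across(c("five_prime_pos", "length", "count"), as.integer)) |>
    readr::write_tsv(path)
  invisible(footprints)
}

#' Filter footprints by read length
#'
#' Retains records with length inside `keep` and outside `exclude`. The
#' default reproduces a standard monosome analysis set: 17–34-nt fragments
#' with the 20–22-nt class (footprints of ribosomes with open A-sites, which
#' lack 3-nt periodicity) removed.
#'
#' @param footprints A footprint tibble.
#' @param keep Length-2 integer vector, inclusive keep range in nt.
#' @param exclude Length-2 integer vector or `NULL`, inclusive exclusion
#'   range in nt.
#' @return The filtered footprint tibble.
#' @export
filter_by_length <- function(footprints, keep = c(17L, 34L),
                             exclude = c(20L, 22L)) {
  if (length(keep) != 2 || keep[1] > keep[2]) {
    abort("`keep` must be c(min, max) with min <= max")
  }
  if (!is.null(exclude) && (length(exclude) != 2 || exclude[1] > exclude[2])) {
    abort("`exclude` must be NULL or c(min, max) with min <= max")
  }
  out <- filter(footprints, .data$length >= keep[1], .data$length <= keep[2])
  if (!is.null(exclude)) {
    out <- filter(out, .data$length < exclude[1] | .data$length > exclude[2])
  }
  out
}

#' Total footprint count of a library
#'
#' @param footprints A footprint tibble.
#' @return Integer sum of counts (the RPM denominator).
#' @export
library_size <- function(footprints) sum(footprints$count)

#' Reads-per-million weights
#'
#' Adds an `rpm` column: `count * 1e6 / total_count`. By default the
#' denominator is the library size of `footprints` itself (post-filter
#' normalisation); pass a pre-filter `total_count` to normalise against the
#' unfiltered library instead.
#'
#' @param footprints A footprint tibble.
#' @param total_count RPM denominator; defaults to `sum(count)`.
#' @return `footprints` with an `rpm` column; the weights sum to 1e6 when
#'   `total_count` is the default.
#' @export
rpm <- function(footprints, total_count = NULL) {
  total_count <- total_count %||% library_size(footprints)
  if (total_count <= 0) abort("Cannot compute RPM for an empty library")
  mutate(footprints, rpm = .data$count * 1e6 / total_count)
}

#' Per-transcript footprint counts
#'
#' @param footprints A footprint tibble.
#' @return Tibble `transcript_id`, `count`.
#' @export
footprint_counts <- function(footprints) {
  summarise(footprints, count = sum(.data$count), .by = "transcript_id")
}
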