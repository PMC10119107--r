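# Configuration-driven orchestration: simulate (optional) -> calibrate ->
# occupancy -> differential -> disome -> integrate, writing every table as
# TSV together with a run manifest (config fingerprint, stage timings,
# dropped-read tallies, package version). Deterministic stages are
# bit-identical across reruns of the same config.

#' Demo pipeline configuration
#'
#' A small fully-simulated two-condition study: condition B slows Pro and
#' Ala codons 1.5-fold and speeds Lys and Asn codons (x0.8), with a handful
#' of planted collision sites.
#'
#' @param seed Integer seed.
#' @param depth Footprints per monosome library.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, depth = 2e5) {
  list(
    seed = seed,
    simulate = list(n_transcripts = 20L, cds_length_range = c(100L, 250L),
                    depth = depth, n_replicates = 2L, dispersion = 0.05,
                    offframe_noise = 0.05,
                    codon_multipliers_b = c(
                      setNames(rep(1.5, 4), codons_for("P")),
                      setNames(rep(1.5, 4), codons_for("A")),
                      setNames(rep(0.8, 2), codons_for("K")),
                      setNames(rep(0.8, 2), codons_for("N"))),
                    n_stall_sites = 5L, p_stall = 0.7, disome_depth = 5e4),
    calibration = list(threshold = 0.5, exclude = c(20L, 22L)),
    occupancy = list(min_mean_rpm = 0, min_codons = 20L),
    differential = list(alpha = 0.05, min_mean_count = 5,
                        codon_families = c("P", "A")),
    disome = list(k_fold = 4, min_count = 5, merge_gap = 1L)
  )
}

#' Run the full analysis pipeline
#'
#' @param config A config list (see [demo_config()]) or path to a YAML file
#'   with the same structure. When `config$simulate` is present the input
#'   libraries are generated in `out_dir`; otherwise
#'   `config$paths$transcriptome`, `config$paths$annotation` and
#'   `config$paths$libraries` (`$a`, `$b`: footprint TSV paths) are read,
#'   with optional `config$paths$disome` and `config$paths$protein_fc`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.numeric(config$seed %||% 1)) abort("`seed` must be an integer")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$simulate)) {
    for (p in unlist(config$paths)) {
      if (!file.exists(p)) {
        abort(paste0("Configured input path does not exist: ", p),
              class = "ribodyn_config_error")
      }
    }
  }
  manifest <- list(fingerprint = rlang::hash(config),
                   version = as.character(packageVersion("ribodyn")),
                   stages = list())
  results <- list()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste("failed at stage:", name),
                 file.path(out_dir, "FAILED"))
      abort(paste0("Pipeline failed at stage '", name, "': ",
                   conditionMessage(e)), parent = e)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    res
  }

  results$inputs <- stage("inputs", function() {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      cfg <- sim_config(n_transcripts = sc$n_transcripts %||% 20L,
                        cds_length_range = sc$cds_length_range %||% c(100L, 250L),
                        depth = sc$depth %||% 2e5,
                        n_replicates = sc$n_replicates %||% 2L,
                        dispersion = sc$dispersion %||% 0.05,
                        offframe_noise = sc$offframe_noise %||% 0.05,
                        seed = config$seed %||% 1L)
      tx <- generate_transcriptome(cfg)
      write_transcriptome(tx, file.path(out_dir, "transcriptome.fa"),
                          file.path(out_dir, "annotation.tsv"))
      pair <- simulate_condition_pair(tx, dwell_spec(),
                                      dwell_spec(codon_multipliers =
                                                   sc$codon_multipliers_b),
                                      cfg)
      for (cond in c("a", "b")) {
        for (k in seq_along(pair$footprints[[cond]])) {
          write_footprints(pair$footprints[[cond]][[k]],
                           file.path(out_dir, sprintf("ribo_%s_rep%d.tsv",
                                                      cond, k)))
          readr::write_tsv(pair$rna[[cond]][[k]],
                           file.path(out_dir, sprintf("rna_%s_rep%d.tsv",
                                                      cond, k)))
        }
      }
      # disome libraries: planted stalls, stronger stalling in condition b
      set.seed(config$seed %||% 1L)
      grid <- profile_grid(tx)
      stall_idx <- sample(nrow(grid), sc$n_stall_sites %||% 5L)
      stalls <- grid[stall_idx, c("transcript_id", "codon_index")]
      disome <- purrr::map(c(a = 1, b = 2), function(i) {
        purrr::map(seq_len(cfg$n_replicates), function(k) {
          simulate_disome_footprints(
            tx, stalls, cfg, seed = (config$seed %||% 1L) + 1000L * i + k,
            p_stall = (sc$p_stall %||% 0.7) * if (i == 2) 1.2 else 1,
            depth = sc$disome_depth %||% 5e4)
        })
      })
      readr::write_tsv(stalls, file.path(out_dir, "truth_stall_sites.tsv"))
      readr::write_tsv(pair$truth$planted_codons,
                       file.path(out_dir, "truth_planted_codons.tsv"))
      list(transcripts = tx, footprints = pair$footprints, rna = pair$rna,
           disome = disome, truth = pair$truth)
    } else {
      tx <- read_transcriptome(config$paths$transcriptome,
                               config$paths$annotation)
      fps <- purrr::map(config$paths$libraries,
                        ~ purrr::map(.x, read_footprints))
      dis <- if (!is.null(config$paths$disome)) {
        purrr::map(config$paths$disome, ~ purrr::map(.x, read_footprints))
      }
      list(transcripts = tx, footprints = fps, disome = dis)
    }
  })

  tx <- results$inputs$transcripts
  results$calibration <- stage("calibrate", function() {
    cal <- config$calibration %||% list()
    purrr::imap(results$inputs$footprints, function(reps, cond) {
      purrr::imap(reps, function(fp, k) {
        fp <- filter_by_length(fp, keep = c(17L, 34L), exclude = NULL)
        scores <- frame_score_by_length(fp, tx)
        usable <- select_lengths(scores, threshold = cal$threshold %||% 0.5,
                                 exclude = cal$exclude %||% c(20L, 22L))
        report <- calibration_report(scores, usable)
        readr::write_tsv(report,
                         file.path(out_dir, sprintf("calibration_%s_rep%d.tsv",
                                                    cond, k)))
        list(scores = scores, usable = usable,
             profiles = build_profiles(fp, tx, usable_lengths = usable))
      })
    })
  })

  profiles <- purrr::map(results$calibration,
                         ~ purrr::map(.x, "profiles"))
  results$occupancy <- stage("occupancy", function() {
    oc <- config$occupancy %||% list()
    occ <- purrr::imap(profiles, function(reps, cond) {
      purrr::imap(reps, function(prof, k) {
        tab <- relative_codon_occupancy(prof,
                                        min_mean_rpm = oc$min_mean_rpm %||% 0,
                                        min_codons = oc$min_codons %||% 1)
        readr::write_tsv(as_tibble(tab),
                         file.path(out_dir, sprintf("occupancy_%s_rep%d.tsv",
                                                    cond, k)))
        tab
      })
    })
    cv <- purrr::map(profiles, function(reps) {
      purrr::map_dfr(reps, ~ transcript_cv(.x, min_codons =
                                             oc$min_codons %||% 2))
    })
    purrr::iwalk(cv, ~ readr::write_tsv(.x,
                                        file.path(out_dir,
                                                  paste0("cv_", .y, ".tsv"))))
    list(tables = occ, cv = cv)
  })

  results$differential <- stage("differential", function() {
    dc <- config$differential %||% list()
    fc <- codon_fold_change(results$occupancy$tables$a,
                            results$occupancy$tables$b)
    readr::write_tsv(fc, file.path(out_dir, "codon_fold_change.tsv"))
    fams <- dc$codon_families %||% c("P", "A")
    test <- position_differential(profiles$a, profiles$b,
                                  codon_filter = codons_for(fams),
                                  min_mean_count = dc$min_mean_count %||% 5,
                                  alpha = dc$alpha %||% 0.05)
    readr::write_tsv(as_tibble(test),
                     file.path(out_dir, "position_differential.tsv"))
    list(fold_change = fc, positions = test)
  })

  results$disome <- stage("disome", function() {
    if (is.null(results$inputs$disome)) return(NULL)
    dp <- config$disome %||% list()
    dprof <- purrr::map(results$inputs$disome,
                        ~ purrr::map(.x, build_disome_profiles,
                                     transcripts = tx))
    pooled <- purrr::map(dprof, function(reps) {
      purrr::reduce(purrr::map(reps, ~ select(.x, "transcript_id",
                                              "codon_index", "codon",
                                              "rpm", "count")),
                    function(x, y) {
                      mutate(x, rpm = .data$rpm + y$rpm,
                             count = .data$count + y$count)
                    }) |>
        mutate(rpm = .data$rpm / length(reps))
    })
    peaks <- purrr::map(pooled, call_disome_peaks,
                        k_fold = dp$k_fold %||% 4,
                        min_count = dp$min_count %||% 5,
                        merge_gap = dp$merge_gap %||% 1L)
    purrr::iwalk(peaks, ~ readr::write_tsv(as_tibble(.x),
                                           file.path(out_dir,
                                                     paste0("disome_peaks_",
                                                            .y, ".tsv"))))
    mtc <- match_peaks(peaks$a, peaks$b)
    fc <- peak_fold_change(union_peaks(mtc), dprof$a, dprof$b)
    readr::write_tsv(fc, file.path(out_dir, "disome_peak_fold_change.tsv"))
    readr::write_tsv(tidy(mtc), file.path(out_dir, "disome_peak_venn.tsv"))
    list(profiles = dprof, peaks = peaks, match = mtc, fold_change = fc)
  })

  results$integration <- stage("integrate", function() {
    if (is.null(config$paths$protein_fc)) return(NULL)
    prot <- readr::read_tsv(config$paths$protein_fc, show_col_types = FALSE)
    sig_genes <- unique(results$differential$positions$transcript_id[
      results$differential$positions$significant])
    if (length(sig_genes) == 0) return(NULL)
    cmp <- cumulative_fraction_compare(prot, sig_genes)
    readr::write_tsv(glance(cmp), file.path(out_dir, "cumulative_fraction.tsv"))
    cmp
  })

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}
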