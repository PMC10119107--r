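# Gene-set integration: Venn decomposition of 2-4 gene sets and
# cumulative-fraction (ECDF) comparison of protein fold changes for a
# flagged gene subset against the full proteome.

#' Venn region decomposition of 2–4 gene sets
#'
#' Counts the `2^k - 1` disjoint regions of up to four sets, with
#' memberships. Region counts sum to the size of the union.
#'
#' @param sets A named list of 2–4 character vectors of gene ids (duplicates
#'   within a set are collapsed).
#' @return A tibble `region` (set names joined by `&`), `n`, `ids`
#'   (list-column).
#' @export
#' @examples
#' venn_regions(list(a = c("1", "2", "3"), b = c("2", "3", "4")))
venn_regions <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) abort("Between 2 and 4 sets are supported")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = k,
                   dimnames = list(universe, names(sets)))
  pattern <- apply(member, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  all_patterns <- unlist(purrr::map(seq_len(k), function(m) {
    apply(combn(names(sets), m), 2, paste, collapse = "&")
  }))
  tibble(region = all_patterns) |>
    mutate(ids = purrr::map(.data$region, ~ universe[pattern == .x]),
           n = lengths(.data$ids)) |>
    select("region", "n", "ids")
}

#' Cumulative-fraction comparison of fold changes for a gene subset
#'
#' Compares the distribution of (protein) log2 fold changes of a gene subset
#' against a background — by default all genes in the table, subset
#' included, as in proteome-wide cumulative-fraction plots — with a
#' two-tailed Mann-Whitney U test. Subset ids absent from the table are
#' tallied, mirroring the common situation where only part of a gene set is
#' detected by MS.
#'
#' @param fc_table Tibble with gene id and log2 fold-change columns.
#' @param subset_ids Character vector of gene ids.
#' @param gene_col,fc_col Column names in `fc_table`.
#' @param background `"all"` (inclusive, default) or `"complement"`.
#' @return A list of class `ribodyn_ecdf_cmp`: `background`, `subset`
#'   (values), `missing_ids`, `mwu` (the test), `median_difference`
#'   (subset minus background), `n_background`, `n_subset`.
#' @export
cumulative_fraction_compare <- function(fc_table, subset_ids,
                                        gene_col = "gene_id",
                                        fc_col = "log2fc",
                                        background = c("all", "complement")) {
  background <- match.arg(background)
  genes <- fc_table[[gene_col]]
  vals <- fc_table[[fc_col]]
  keep <- !is.na(vals)
  genes <- genes[keep]; vals <- vals[keep]
  in_subset <- genes %in% subset_ids
  missing_ids <- setdiff(subset_ids, genes)
  subset <- vals[in_subset]
  if (length(subset) == 0) {
    abort("No subset gene is present in the fold-change table")
  }
  bg <- if (background == "all") vals else vals[!in_subset]
  mwu <- mann_whitney(subset, bg)
  structure(list(background = bg, subset = subset,
                 missing_ids = missing_ids, mwu = mwu,
                 median_difference = median(subset) - median(bg),
                 n_background = length(bg), n_subset = length(subset)),
            class = "ribodyn_ecdf_cmp")
}

#' @export
print.ribodyn_ecdf_cmp <- function(x, ...) {
  cat("Cumulative-fraction comparison: n =", x$n_subset, "subset vs",
      x$n_background, "background\n")
  cat("median difference =", round(x$median_difference, 4),
      " MWU p =", format.pval(x$mwu$p.value), "\n")
  if (length(x$missing_ids) > 0) {
    cat(length(x$missing_ids), "subset id(s) not detected\n")
  }
  invisible(x)
}

#' ECDF curves of a cumulative-fraction comparison
#'
#' @param x A `ribodyn_ecdf_cmp`.
#' @return A tibble `group`, `log2fc`, `cumulative_fraction` (each curve
#'   rising from its minimum to exactly 1).
#' @export
ecdf_curves <- function(x) {
  one <- function(v, g) {
    v <- sort(v)
    tibble(group = g, log2fc = v, cumulative_fraction = ecdf(v)(v))
  }
  bind_rows(one(x$background, "background"), one(x$subset, "subset"))
}
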