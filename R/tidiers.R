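# broom-style tidy()/glance() methods for result objects.

#' @rdname ribodyn-tidiers
#' @title Tidy and glance methods for ribodyn results
#' @description One-row (`glance`) and per-component (`tidy`) tibble
#'   summaries of test-like objects, in the broom idiom.
#' @param x A ribodyn result object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ribodyn_mwu
#' @export
tidy.ribodyn_mwu <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         n_x = x$n_x, n_y = x$n_y)
}

#' @rdname ribodyn-tidiers
#' @method glance ribodyn_mwu
#' @export
glance.ribodyn_mwu <- function(x, ...) tidy.ribodyn_mwu(x)

#' @rdname ribodyn-tidiers
#' @method tidy ribodyn_cor
#' @export
tidy.ribodyn_cor <- function(x, ...) {
  tibble(estimate = x$r, n = x$n, p.value = x$p.value,
         p.adjusted = x$p.adjusted, family_size = x$family_size,
         method = "spearman")
}

#' @rdname ribodyn-tidiers
#' @method glance ribodyn_cor
#' @export
glance.ribodyn_cor <- function(x, ...) tidy.ribodyn_cor(x)

#' @rdname ribodyn-tidiers
#' @method tidy ribodyn_peak_match
#' @export
tidy.ribodyn_peak_match <- function(x, ...) {
  tibble(category = c("common", "only_a", "only_b", "union"),
         n = c(x$counts$common, x$counts$only_a, x$counts$only_b,
               x$counts$union))
}

#' @rdname ribodyn-tidiers
#' @method glance ribodyn_peak_match
#' @export
glance.ribodyn_peak_match <- function(x, ...) {
  tibble(common = x$counts$common, only_a = x$counts$only_a,
         only_b = x$counts$only_b, union = x$counts$union)
}

#' @rdname ribodyn-tidiers
#' @method tidy ribodyn_ecdf_cmp
#' @export
tidy.ribodyn_ecdf_cmp <- function(x, ...) ecdf_curves(x)

#' @rdname ribodyn-tidiers
#' @method glance ribodyn_ecdf_cmp
#' @export
glance.ribodyn_ecdf_cmp <- function(x, ...) {
  tibble(n_subset = x$n_subset, n_background = x$n_background,
         n_missing = length(x$missing_ids),
         median_difference = x$median_difference,
         statistic = x$mwu$statistic, p.value = x$mwu$p.value)
}
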