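#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an informativeness regression fit
#'
#' @param x An `informativeness_fit`.
#' @param ... Passed on.
#' @return Tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy informativeness_fit
#' @export
tidy.informativeness_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname tidy.informativeness_fit
#' @return `glance()`: one-row tibble with `a`, `b`, `r.squared`, `n`.
#' @method glance informativeness_fit
#' @export
glance.informativeness_fit <- function(x, ...) {
  tibble(
    a = x$a, b = x$b, r.squared = x$r_squared,
    n = length(stats::fitted(x$model))
  )
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Passed on.
#' @return One-row tibble with `estimate` (r), `p.value`, `n_perm`,
#'   `n_sites`.
#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(
    estimate = x$r, p.value = x$p_value, n_perm = x$n_perm, n_sites = x$n_sites
  )
}

#' @rdname tidy.mantel_result
#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x, ...)

#' Summarise an outlier scan
#'
#' @param x An `outlier_scan`.
#' @param ... Passed on.
#' @return One-row tibble with the locus counts and flagged fraction.
#' @method glance outlier_scan
#' @export
glance.outlier_scan <- function(x, ...) {
  tibble(
    n_loci = nrow(x), n_outliers = sum(x$outlier),
    frac_outliers = mean(x$outlier),
    envelope = attr(x, "envelope_mass"), n_bins = attr(x, "n_bins")
  )
}

#' Summarise a panel selection
#'
#' @param x A [panel_selection()].
#' @param ... Passed on.
#' @return One-row tibble with marker counts by class, linkage-group
#'   coverage, the design spacing and provenance sizes.
#' @method glance panel_selection
#' @export
glance.panel_selection <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_markers = nrow(tb),
    n_snp = sum(tb$marker_class == "snp"),
    n_mitochondrial = sum(tb$marker_class == "mitochondrial"),
    n_linkage_groups = dplyr::n_distinct(tb$linkage_group[!is.na(tb$linkage_group)]),
    min_spacing_cM = attr(x, "min_spacing_cM"),
    n_removed = length(attr(x, "removed_ids")),
    n_spacing_violations = nrow(attr(x, "spacing_violations"))
  )
}
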