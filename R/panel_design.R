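#' Construct a panel selection
#'
#' A panel selection is a tibble of chosen markers (one row per marker:
#' `marker_id`, `linkage_group`, `position_cM`, optional `maf`,
#' `marker_class`) ordered by linkage group, position, then id, carrying its
#' design provenance as attributes: the minimum spacing used, the seed and
#' removed ids of any down-sampling step, and any logged spacing violations.
#'
#' @param data Data frame of selected markers.
#' @param min_spacing_cM Minimum consecutive spacing (cM) the selection was
#'   designed to, or `NA`.
#' @param seed,removed_ids,spacing_violations Provenance fields.
#' @return A tibble of class `panel_selection`.
#' @export
panel_selection <- function(data, min_spacing_cM = NA_real_, seed = NA_integer_,
                            removed_ids = character(),
                            spacing_violations = NULL) {
  data <- as_tibble(data)
  if (!"marker_id" %in% names(data)) abort("panel_selection requires a marker_id column")
  if (anyDuplicated(data$marker_id) > 0) abort("duplicate marker ids in panel")
  if (!"marker_class" %in% names(data)) data$marker_class <- "snp"
  for (col in c("linkage_group", "position_cM", "maf")) {
    if (!col %in% names(data)) data[[col]] <- NA
  }
  data <- data %>%
    mutate(position_cM = as.numeric(.data$position_cM)) %>%
    arrange(.data$linkage_group, .data$position_cM, .data$marker_id)
  structure(data,
    class = c("panel_selection", class(tibble())),
    min_spacing_cM = min_spacing_cM, seed = seed, removed_ids = removed_ids,
    spacing_violations = spacing_violations %||%
      tibble(marker_id = character(), neighbour_id = character(), gap_cM = numeric())
  )
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf(
    "# Panel selection: %d markers, min spacing %s cM\n", nrow(x),
    format(attr(x, "min_spacing_cM"))
  ))
  NextMethod()
}

#' Greedy minimum-spacing marker selection on a linkage map
#'
#' Selects an evenly spread marker panel: within each linkage group the
#' position-sorted candidates are scanned left to right, keeping the first
#' marker and then every candidate at least `min_spacing_cM` from the last
#' kept one.  Candidates at identical positions are ordered by decreasing
#' MAF (more informative first) and then id, so the selection is
#' deterministic.
#'
#' @param candidates Data frame with columns `marker_id`, `linkage_group`,
#'   `position_cM` and optionally `maf` (used for tie-breaks) and
#'   `marker_class`.  Every candidate must be mapped.
#' @param min_spacing_cM Minimum spacing between consecutive selected markers
#'   within a linkage group, in cM (default 3.5).
#' @return A [panel_selection()].
#' @export
select_spaced_markers <- function(candidates, min_spacing_cM = 3.5) {
  candidates <- as_tibble(candidates)
  if (min_spacing_cM <= 0) abort("min_spacing_cM must be positive")
  req <- c("marker_id", "linkage_group", "position_cM")
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols) > 0) {
    abort(paste0("candidates need columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(candidates$position_cM)) || any(is.na(candidates$linkage_group))) {
    abort("every candidate must have a linkage group and cM position")
  }
  if (!"maf" %in% names(candidates)) candidates$maf <- NA_real_

  kept <- candidates %>%
    arrange(
      .data$linkage_group, .data$position_cM,
      desc(tidyr::replace_na(.data$maf, -Inf)), .data$marker_id
    ) %>%
    group_by(.data$linkage_group) %>%
    filter(greedy_keep(.data$position_cM, min_spacing_cM)) %>%
    ungroup()
  panel_selection(kept, min_spacing_cM = min_spacing_cM)
}

# greedy scan over sorted positions: keep first, then every position at least
# `spacing` beyond the last kept one
greedy_keep <- function(pos, spacing) {
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= spacing || is.infinite(last)) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  keep
}

#' Randomly down-sample a panel to a target size
#'
#' Draws a uniform subset without replacement, reproducibly for a given seed;
#' removed marker ids are recorded in the result's provenance.
#'
#' @param panel A [panel_selection()] (or marker tibble).
#' @param target_size Number of markers to retain.
#' @param seed Integer seed.
#' @return A [panel_selection()] of `target_size` markers.
#' @export
downsample_panel <- function(panel, target_size, seed = 1L) {
  panel <- as_tibble(panel)
  if (target_size > nrow(panel)) {
    abort(sprintf("target_size (%d) exceeds panel size (%d)", target_size, nrow(panel)))
  }
  removed <- withr::with_seed(seed, {
    sample(panel$marker_id, nrow(panel) - target_size)
  })
  panel_selection(
    panel %>% filter(!.data$marker_id %in% removed),
    min_spacing_cM = attr(panel, "min_spacing_cM") %||% NA_real_,
    seed = seed, removed_ids = as.character(removed)
  )
}

#' Append fixed (ancestry-informative and mitochondrial) markers
#'
#' Adds externally chosen markers -- typically lineage-diagnostic nuclear SNPs
#' and mitochondrial SNPs -- to a designed panel.  Added ids must be disjoint
#' from the panel and from each other.
#'
#' @param panel A [panel_selection()].
#' @param nuclear_aims Data frame (or character vector of ids) of
#'   ancestry-informative nuclear markers; `marker_class` defaults to
#'   `"snp"`.
#' @param mito_markers Data frame (or character vector of ids) of
#'   mitochondrial markers; `marker_class` is forced to `"mitochondrial"`.
#' @return A [panel_selection()] of size `nrow(panel) + |aims| + |mito|`.
#' @export
append_fixed_markers <- function(panel, nuclear_aims = NULL, mito_markers = NULL) {
  panel_tb <- as_tibble(panel)
  as_marker_tbl <- function(x, class) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- tibble(marker_id = x)
    x <- as_tibble(x)
    x$marker_class <- class
    x
  }
  add <- bind_rows(
    as_marker_tbl(nuclear_aims, "snp"),
    as_marker_tbl(mito_markers, "mitochondrial")
  )
  if (is.null(add) || nrow(add) == 0) {
    return(panel_selection(panel_tb,
      min_spacing_cM = attr(panel, "min_spacing_cM") %||% NA_real_,
      seed = attr(panel, "seed") %||% NA_integer_,
      removed_ids = attr(panel, "removed_ids") %||% character()
    ))
  }
  all_ids <- c(panel_tb$marker_id, add$marker_id)
  if (anyDuplicated(all_ids) > 0) {
    dups <- unique(all_ids[duplicated(all_ids)])
    abort(paste0("marker id collision: ", paste(dups, collapse = ", ")))
  }
  panel_selection(bind_rows(panel_tb, add),
    min_spacing_cM = attr(panel, "min_spacing_cM") %||% NA_real_,
    seed = attr(panel, "seed") %||% NA_integer_,
    removed_ids = attr(panel, "removed_ids") %||% character()
  )
}

#' Spacing statistics of a panel on its linkage map
#'
#' Summarises how evenly a panel covers the map: per-linkage-group and global
#' mean and SD of consecutive marker spacings, the largest gap per group, and
#' the coarse panel density `total map length / marker count` (cM per
#' marker).
#'
#' @param panel A [panel_selection()] with mapped positions.
#' @param total_length_cM Total map length in cM; taken from `map` if given.
#' @param map Optional [linkage_map()] supplying the total length.
#' @return List with elements `per_lg` (tibble: `linkage_group`, `n_markers`,
#'   `mean_spacing_cM`, `sd_spacing_cM`, `max_gap_cM`) and `global` (one-row
#'   tibble: `n_markers`, `mean_spacing_cM`, `sd_spacing_cM`, `max_gap_cM`,
#'   `density_cM_per_marker`).
#' @export
panel_spacing_stats <- function(panel, total_length_cM = NULL, map = NULL) {
  panel <- as_tibble(panel)
  if (any(is.na(panel$position_cM))) {
    mapped <- panel %>% filter(!is.na(.data$position_cM))
  } else {
    mapped <- panel
  }
  total_length_cM <- total_length_cM %||%
    (if (!is.null(map)) map_total_length(map) else NA_real_)
  spacings <- mapped %>%
    arrange(.data$linkage_group, .data$position_cM) %>%
    group_by(.data$linkage_group) %>%
    mutate(spacing = .data$position_cM - lag(.data$position_cM)) %>%
    ungroup()
  per_lg <- spacings %>%
    group_by(.data$linkage_group) %>%
    summarise(
      n_markers = dplyr::n(),
      mean_spacing_cM = mean(.data$spacing, na.rm = TRUE),
      sd_spacing_cM = stats::sd(.data$spacing[!is.na(.data$spacing)]),
      max_gap_cM = if (all(is.na(.data$spacing))) NA_real_ else max(.data$spacing, na.rm = TRUE),
      .groups = "drop"
    )
  gaps <- spacings$spacing[!is.na(spacings$spacing)]
  global <- tibble(
    n_markers = nrow(panel),
    mean_spacing_cM = if (length(gaps)) mean(gaps) else NA_real_,
    sd_spacing_cM = if (length(gaps) > 1) stats::sd(gaps) else NA_real_,
    max_gap_cM = if (length(gaps)) max(gaps) else NA_real_,
    density_cM_per_marker = total_length_cM / nrow(panel)
  )
  list(per_lg = per_lg, global = global)
}

#' Replace failed assay markers from a reserve pool
#'
#' Markers that failed genotyping (e.g. did not amplify) are removed and
#' replaced from a reserve candidate list, preferring an unused reserve on the
#' same linkage group with the nearest cM position (ties to the smaller id);
#' when no same-group reserve remains, a seeded uniform draw from the unused
#' reserves is used.  The minimum-spacing constraint is re-checked and
#' violations are reported in the provenance, not silently dropped.
#'
#' @param panel A [panel_selection()].
#' @param failed_ids Character vector of failed marker ids.
#' @param reserves Data frame of reserve candidates (`marker_id`,
#'   `linkage_group`, `position_cM`, optional `maf`); they should already have
#'   passed the assay filter and be mapped.
#' @param min_spacing_cM Spacing used for the violation check; defaults to the
#'   panel's design spacing.
#' @param seed Seed for the fallback random draw.
#' @return A [panel_selection()]; unreplaced markers (reserve shortfall) are
#'   listed in `attr(, "shortfall")`.
#' @export
replace_failed_markers <- function(panel, failed_ids, reserves,
                                   min_spacing_cM = NULL, seed = 1L) {
  panel_tb <- as_tibble(panel)
  reserves <- as_tibble(reserves)
  min_spacing_cM <- min_spacing_cM %||% attr(panel, "min_spacing_cM") %||% NA_real_
  failed_ids <- intersect(failed_ids, panel_tb$marker_id)
  kept <- panel_tb %>% filter(!.data$marker_id %in% failed_ids)
  pool <- reserves %>% filter(!.data$marker_id %in% panel_tb$marker_id)

  replacements <- list()
  shortfall <- character()
  rng_seq <- withr::with_seed(seed, sample.int(.Machine$integer.max, length(failed_ids)))
  for (i in seq_along(sort(failed_ids))) {
    fid <- sort(failed_ids)[i]
    frow <- panel_tb %>% filter(.data$marker_id == fid)
    if (nrow(pool) == 0) {
      shortfall <- c(shortfall, fid)
      next
    }
    same_lg <- pool %>% filter(.data$linkage_group %in% frow$linkage_group)
    if (nrow(same_lg) > 0 && !is.na(frow$position_cM[1])) {
      same_lg <- same_lg %>%
        mutate(d = abs(.data$position_cM - frow$position_cM[1])) %>%
        arrange(.data$d, .data$marker_id)
      chosen <- same_lg$marker_id[1]
    } else {
      chosen <- withr::with_seed(rng_seq[i], sample(pool$marker_id, 1))
    }
    replacements[[fid]] <- pool %>% filter(.data$marker_id == chosen)
    pool <- pool %>% filter(.data$marker_id != chosen)
  }
  new_panel <- bind_rows(kept, bind_rows(replacements))

  violations <- spacing_violations(new_panel, min_spacing_cM)
  out <- panel_selection(new_panel,
    min_spacing_cM = min_spacing_cM, seed = seed,
    removed_ids = failed_ids, spacing_violations = violations
  )
  attr(out, "shortfall") <- shortfall
  out
}

# consecutive within-group pairs closer than the minimum spacing
spacing_violations <- function(panel, min_spacing_cM) {
  if (is.na(min_spacing_cM)) {
    return(tibble(marker_id = character(), neighbour_id = character(), gap_cM = numeric()))
  }
  as_tibble(panel) %>%
    filter(!is.na(.data$position_cM)) %>%
    arrange(.data$linkage_group, .data$position_cM) %>%
    group_by(.data$linkage_group) %>%
    mutate(
      gap_cM = .data$position_cM - lag(.data$position_cM),
      neighbour_id = lag(.data$marker_id)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$gap_cM), .data$gap_cM < min_spacing_cM) %>%
    select("marker_id", "neighbour_id", "gap_cM")
}
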