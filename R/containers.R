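#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

MISSING_CLASSES <- c("snp", "microsatellite", "mitochondrial")

#' Construct a tidy genotype table
#'
#' The package's central container is a long, tidy genotype table: one row per
#' (individual, locus) with the unordered allele pair of the call.  The same
#' shape holds biallelic SNPs, multiallelic microsatellites and haploid
#' mitochondrial markers, so every downstream statistic operates on one call
#' shape.  Mitochondrial calls are stored as homozygous pairs but contribute a
#' single gene copy to every frequency computation.
#'
#' @param data A data frame with columns `individual_id`, `locus_id`,
#'   `allele1`, `allele2` and optionally `marker_class` (one of `"snp"`,
#'   `"microsatellite"`, `"mitochondrial"`; default `"snp"`).  A missing call
#'   has `NA` in both allele columns.
#' @param complete If `TRUE` (default), absent (individual, locus)
#'   combinations are filled in as missing calls so the table is a complete
#'   grid.
#' @return A tibble of class `geno_tbl` with columns `individual_id`,
#'   `locus_id`, `allele1`, `allele2`, `marker_class`.
#' @export
geno_tbl <- function(data, complete = TRUE) {
  data <- as_tibble(data)
  req <- c("individual_id", "locus_id", "allele1", "allele2")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("geno_tbl requires columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"marker_class" %in% names(data)) data$marker_class <- "snp"
  bad_class <- setdiff(unique(data$marker_class), MISSING_CLASSES)
  if (length(bad_class) > 0) {
    abort(paste0("unknown marker_class: ", paste(bad_class, collapse = ", ")))
  }
  data <- data %>%
    mutate(
      individual_id = as.character(.data$individual_id),
      locus_id = as.character(.data$locus_id),
      allele1 = as.character(.data$allele1),
      allele2 = as.character(.data$allele2)
    )
  half <- xor(is.na(data$allele1), is.na(data$allele2))
  if (any(half)) {
    abort("calls must have both alleles present or both missing")
  }
  if (anyDuplicated(data[c("individual_id", "locus_id")]) > 0) {
    abort("duplicate (individual_id, locus_id) rows")
  }
  mito <- data$marker_class == "mitochondrial" & !is.na(data$allele1)
  if (any(data$allele1[mito] != data$allele2[mito])) {
    abort("mitochondrial (haploid) calls must be stored as homozygous pairs")
  }
  if (complete) {
    class_map <- data %>% distinct(.data$locus_id, .data$marker_class)
    if (anyDuplicated(class_map$locus_id) > 0) {
      abort("a locus may not carry more than one marker_class")
    }
    data <- data %>%
      select(-"marker_class") %>%
      tidyr::complete(
        individual_id = unique(.data$individual_id),
        locus_id = unique(.data$locus_id)
      ) %>%
      left_join(class_map, by = "locus_id")
  }
  new_geno_tbl(data[c("individual_id", "locus_id", "allele1", "allele2", "marker_class")])
}

new_geno_tbl <- function(data) {
  structure(data, class = c("geno_tbl", class(tibble())))
}

#' @export
print.geno_tbl <- function(x, ...) {
  n_ind <- dplyr::n_distinct(x$individual_id)
  n_loc <- dplyr::n_distinct(x$locus_id)
  cat(sprintf("# Genotype table: %d individuals x %d loci\n", n_ind, n_loc))
  NextMethod()
}

#' @rdname geno_tbl
#' @param x A `geno_tbl`.
#' @export
geno_individuals <- function(x) unique(x$individual_id)

#' @rdname geno_tbl
#' @export
geno_loci <- function(x) unique(x$locus_id)

# gene copies contributed by one call: 2 for diploid classes, 1 for mitochondrial
copies_per_call <- function(marker_class) ifelse(marker_class == "mitochondrial", 1L, 2L)

assert_geno <- function(x, arg = "genotypes") {
  if (!inherits(x, "geno_tbl")) {
    if (is.data.frame(x)) return(geno_tbl(x))
    abort(paste0("`", arg, "` must be a geno_tbl or data frame"))
  }
  x
}

#' Construct a linkage map table
#'
#' A linkage map is a tibble of mapped markers: `marker_id`, `linkage_group`,
#' `position_cM` and optionally `recomb_rate` (a local recombination-rate
#' estimate).  Rows are ordered by linkage group and position.  The estimated
#' total map length (in centimorgans) is carried as an attribute; by default it
#' is the sum over groups of the largest mapped position.
#'
#' @param data Data frame with columns `marker_id`, `linkage_group`,
#'   `position_cM`, optional `recomb_rate`.
#' @param total_length_cM Total map length in cM; defaults to the sum of
#'   per-group maxima.  Must be at least the largest position of any group.
#' @return A tibble of class `linkage_map`.
#' @export
linkage_map <- function(data, total_length_cM = NULL) {
  data <- as_tibble(data)
  req <- c("marker_id", "linkage_group", "position_cM")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("linkage_map requires columns: ", paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(data), c(req, "recomb_rate"))
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown linkage map columns: ", paste(extra, collapse = ", ")))
  }
  if (!"recomb_rate" %in% names(data)) data$recomb_rate <- NA_real_
  data <- data %>%
    mutate(
      marker_id = as.character(.data$marker_id),
      position_cM = as.numeric(.data$position_cM),
      recomb_rate = as.numeric(.data$recomb_rate)
    ) %>%
    select("marker_id", "linkage_group", "position_cM", "recomb_rate")
  if (anyDuplicated(data$marker_id) > 0) {
    dups <- unique(data$marker_id[duplicated(data$marker_id)])
    abort(paste0("duplicate marker ids: ", paste(utils::head(dups, 5), collapse = ", ")))
  }
  if (any(is.na(data$position_cM)) || any(data$position_cM < 0)) {
    abort("position_cM must be nonnegative and non-missing")
  }
  data <- data %>% arrange(.data$linkage_group, .data$position_cM, .data$marker_id)
  if (nrow(data) > 0) {
    group_max <- data %>%
      group_by(.data$linkage_group) %>%
      summarise(len = max(.data$position_cM), .groups = "drop")
    default_total <- sum(group_max$len)
    max_pos <- max(group_max$len)
  } else {
    default_total <- 0
    max_pos <- 0
  }
  total_length_cM <- total_length_cM %||% default_total
  if (total_length_cM < max_pos) {
    abort("total_length_cM must be >= the largest mapped position")
  }
  structure(data,
    class = c("linkage_map", class(tibble())),
    total_length_cM = total_length_cM
  )
}

#' @rdname linkage_map
#' @param map A `linkage_map`.
#' @export
map_total_length <- function(map) attr(map, "total_length_cM")

#' Construct a RAD tag table
#'
#' One row per RAD tag: the tag's reference sequence, the 0-based offsets of
#' the SNPs it carries (with their ref/alt bases) as list-columns, and the
#' tag's position on the linkage map when anchored (`NA` when unmapped).
#'
#' @param data Data frame with columns `tag_id`, `sequence`, list-columns
#'   `snp_offsets` (integer vectors, 0-based, strictly increasing), `ref`,
#'   `alt` (character vectors parallel to `snp_offsets`), and optional
#'   `linkage_group`, `position_cM`, `recomb_rate`.
#' @return A tibble of class `rad_tbl`.
#' @export
rad_tbl <- function(data) {
  data <- as_tibble(data)
  req <- c("tag_id", "sequence", "snp_offsets", "ref", "alt")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("rad_tbl requires columns: ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("linkage_group", "position_cM", "recomb_rate")) {
    if (!col %in% names(data)) data[[col]] <- NA
  }
  data <- data %>% mutate(
    tag_id = as.character(.data$tag_id),
    sequence = toupper(as.character(.data$sequence)),
    position_cM = as.numeric(.data$position_cM),
    recomb_rate = as.numeric(.data$recomb_rate)
  )
  if (anyDuplicated(data$tag_id) > 0) abort("duplicate tag ids")
  if (any(grepl("[^ACGTN]", data$sequence))) {
    abort("sequences may contain only A, C, G, T, N")
  }
  purrr::pwalk(
    list(data$tag_id, data$sequence, data$snp_offsets, data$ref, data$alt),
    function(id, seq, off, ref, alt) {
      off <- as.integer(off)
      if (length(off) != length(ref) || length(off) != length(alt)) {
        abort(paste0("tag ", id, ": snp_offsets, ref, alt lengths differ"))
      }
      if (length(off) == 0) return(invisible())
      if (any(off < 0) || any(off >= nchar(seq))) {
        abort(paste0("tag ", id, ": SNP offset outside sequence"))
      }
      if (is.unsorted(off, strictly = TRUE)) {
        abort(paste0("tag ", id, ": offsets must be strictly increasing"))
      }
      if (any(ref == alt)) abort(paste0("tag ", id, ": ref and alt must differ"))
      base <- substring(seq, off + 1, off + 1)
      ok <- base == ref | base == "N"
      if (!all(ok)) {
        abort(paste0("tag ", id, ": sequence base at offset disagrees with ref allele"))
      }
    }
  )
  data$snp_offsets <- purrr::map(data$snp_offsets, as.integer)
  structure(data, class = c("rad_tbl", class(tibble())))
}

#' SNP loci carried by a RAD tag table
#'
#' Expands a `rad_tbl` to one row per SNP, with locus ids of the form
#' `"<tag_id>:<offset>"` used throughout the package to link genotype loci to
#' their source tags.
#'
#' @param rads A [rad_tbl()].
#' @return Tibble with columns `locus_id`, `tag_id`, `offset`, `ref`, `alt`,
#'   `linkage_group`, `position_cM`.
#' @export
snp_loci <- function(rads) {
  rads <- as_tibble(rads)
  tidyr::unnest(
    rads[c("tag_id", "snp_offsets", "ref", "alt", "linkage_group", "position_cM")],
    cols = c("snp_offsets", "ref", "alt")
  ) %>%
    rename(offset = "snp_offsets") %>%
    mutate(locus_id = paste0(.data$tag_id, ":", .data$offset), .before = 1)
}

#' Validate a population assignment table
#'
#' @param data Data frame with columns `individual_id`, `population` and
#'   optionally `lineage`.
#' @param individuals Optional character vector; every listed individual must
#'   have exactly one population label.
#' @return A tibble with one row per individual.
#' @export
population_table <- function(data, individuals = NULL) {
  data <- as_tibble(data)
  req <- c("individual_id", "population")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("population_table requires columns: ", paste(missing_cols, collapse = ", ")))
  }
  data <- data %>% mutate(
    individual_id = as.character(.data$individual_id),
    population = as.character(.data$population)
  )
  if (anyDuplicated(data$individual_id) > 0) {
    abort("an individual may not carry more than one population label")
  }
  if (!is.null(individuals)) {
    orphans <- setdiff(individuals, data$individual_id)
    if (length(orphans) > 0) {
      abort(paste0(
        "individuals without a population label: ",
        paste(utils::head(orphans, 5), collapse = ", "),
        if (length(orphans) > 5) " ..." else ""
      ))
    }
  }
  data
}

#' Validate a symmetric distance matrix
#'
#' @param m A square numeric matrix with identical row and column labels,
#'   zero diagonal and symmetric entries (tolerance `1e-9`).
#' @return The matrix, invisibly validated.
#' @export
validate_distance_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) abort("distance matrix must be numeric")
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
    !identical(rownames(m), colnames(m))) {
    abort("distance matrix must have identical row and column labels")
  }
  if (any(abs(diag(m)) > 1e-9)) abort("distance matrix diagonal must be zero")
  if (any(abs(m - t(m)) > 1e-9)) abort("distance matrix must be symmetric")
  if (any(m < -1e-9)) abort("distances must be nonnegative")
  invisible(m)
}

#' Per-locus, per-population allele frequencies
#'
#' Computes the allele-frequency table that underlies heterozygosity, Fst and
#' informativeness computations: for every locus and population the relative
#' frequency of each observed allele among non-missing gene copies.
#' Mitochondrial loci contribute one gene copy per individual; diploid loci
#' two.
#'
#' @param genotypes A [geno_tbl()] (or coercible data frame).
#' @param populations A [population_table()] assigning every individual to a
#'   population.
#' @return A tibble of class `allele_freq_tbl` with columns `locus_id`,
#'   `population`, `allele`, `freq`, `n_copies` (non-missing gene copies for
#'   that locus-population cell).
#' @export
allele_frequencies <- function(genotypes, populations) {
  genotypes <- assert_geno(genotypes)
  populations <- population_table(populations, geno_individuals(genotypes))

  long <- genotypes %>%
    filter(!is.na(.data$allele1)) %>%
    left_join(populations[c("individual_id", "population")], by = "individual_id")

  if (nrow(long) == 0) abort("no non-missing calls")

  # every (locus, pop) cell must have at least one call
  grid <- tidyr::expand_grid(
    locus_id = geno_loci(genotypes),
    population = unique(populations$population[
      populations$individual_id %in% geno_individuals(genotypes)
    ])
  )
  seen <- long %>% distinct(.data$locus_id, .data$population)
  empty <- anti_join(grid, seen, by = c("locus_id", "population"))
  if (nrow(empty) > 0) {
    abort(paste0(
      "undefined frequency: no non-missing calls for ",
      paste(paste0("(", empty$locus_id, ", ", empty$population, ")")[
        seq_len(min(3, nrow(empty)))
      ], collapse = ", "),
      if (nrow(empty) > 3) " ..." else ""
    ))
  }

  # mitochondrial calls are stored as homozygous pairs; count allele1 once
  counts <- long %>%
    mutate(a2 = dplyr::if_else(.data$marker_class == "mitochondrial",
      NA_character_, .data$allele2
    )) %>%
    tidyr::pivot_longer(c("allele1", "a2"), values_to = "allele") %>%
    filter(!is.na(.data$allele)) %>%
    count(.data$locus_id, .data$population, .data$allele, name = "count") %>%
    group_by(.data$locus_id, .data$population) %>%
    mutate(n_copies = sum(.data$count), freq = .data$count / .data$n_copies) %>%
    ungroup() %>%
    select("locus_id", "population", "allele", "freq", "n_copies") %>%
    arrange(.data$locus_id, .data$population, .data$allele)

  structure(counts, class = c("allele_freq_tbl", class(tibble())))
}

#' Unweighted across-population mean allele frequencies
#'
#' The mean frequency of each allele across the K populations, with alleles
#' unobserved in a population entering as frequency zero.
#'
#' @param freqs An `allele_freq_tbl` from [allele_frequencies()].
#' @return Tibble with columns `locus_id`, `allele`, `mean_freq`, `k_pops`.
#' @export
pooled_mean_frequencies <- function(freqs) {
  k <- dplyr::n_distinct(freqs$population)
  freqs %>%
    group_by(.data$locus_id, .data$allele) %>%
    summarise(mean_freq = sum(.data$freq) / k, .groups = "drop") %>%
    mutate(k_pops = k)
}
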