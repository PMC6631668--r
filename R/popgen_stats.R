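#' Expected heterozygosity from allele frequencies
#'
#' Nei's gene diversity `He = 1 - sum(p_j^2)` for one locus.
#'
#' @param freqs Numeric vector of allele frequencies (summing to 1).
#' @return He in `[0, 1 - 1/n_alleles]`.
#' @export
expected_heterozygosity <- function(freqs) {
  if (length(freqs) == 0 || any(is.na(freqs))) abort("He undefined: no frequencies")
  1 - sum(freqs^2)
}

#' Per-locus heterozygosity statistics
#'
#' For every locus (within each population when `populations` is given,
#' otherwise over the pooled sample) computes the expected heterozygosity
#' `He = 1 - sum(p_j^2)`, the observed heterozygosity `Ho` (fraction of
#' non-missing diploid calls that are heterozygous; `NA` for haploid
#' mitochondrial loci), and `Fis = 1 - Ho/He` (`NA` where `He = 0`).
#'
#' @param genotypes A [geno_tbl()].
#' @param populations Optional [population_table()]; when omitted all
#'   individuals form one pooled population labelled `"all"`.
#' @return Tibble with columns `population`, `locus_id`, `n` (individuals
#'   with a call), `n_alleles`, `He`, `Ho`, `Fis`.
#' @export
het_stats <- function(genotypes, populations = NULL) {
  genotypes <- assert_geno(genotypes)
  if (is.null(populations)) {
    populations <- tibble(
      individual_id = geno_individuals(genotypes), population = "all"
    )
  }
  freqs <- allele_frequencies(genotypes, populations)
  he <- freqs %>%
    group_by(.data$population, .data$locus_id) %>%
    summarise(
      n_alleles = dplyr::n(), He = 1 - sum(.data$freq^2), .groups = "drop"
    )
  ho <- genotypes %>%
    filter(!is.na(.data$allele1)) %>%
    left_join(population_table(populations)[c("individual_id", "population")],
      by = "individual_id"
    ) %>%
    group_by(.data$population, .data$locus_id) %>%
    summarise(
      n = dplyr::n(),
      Ho = if (all(.data$marker_class == "mitochondrial")) NA_real_ else
        mean(.data$allele1 != .data$allele2),
      .groups = "drop"
    )
  he %>%
    left_join(ho, by = c("population", "locus_id")) %>%
    mutate(Fis = ifelse(.data$He > 0, 1 - .data$Ho / .data$He, NA_real_)) %>%
    select("population", "locus_id", "n", "n_alleles", "He", "Ho", "Fis")
}

#' Site-uniqueness Fst
#'
#' The site-level uniqueness statistic `Fst = 1 - He_site / He_total`, where
#' `He_site` and `He_total` are multilocus mean expected heterozygosities of
#' the site and of the total (pooled) sample.
#'
#' @param he_site,he_total Multilocus mean expected heterozygosities.
#' @return `1 - he_site/he_total`.
#' @export
site_uniqueness_fst <- function(he_site, he_total) {
  if (any(he_total <= 0)) abort("site-uniqueness Fst undefined: He_total must be > 0")
  1 - he_site / he_total
}

#' Per-site multilocus summary
#'
#' The per-site summary table of a panel evaluation: sample size, multilocus
#' mean (and SD across loci) observed and expected heterozygosity, mean Fis,
#' the site-uniqueness Fst `1 - He_site/He_total`, and mean allelic richness
#' by rarefaction.
#'
#' @param genotypes A [geno_tbl()].
#' @param populations A [population_table()].
#' @param rarefaction_n Gene copies for the rarefaction; defaults to the
#'   smallest non-missing copy count over (locus, site) cells.
#' @param polymorphic_only Restrict to loci polymorphic in the analysed set
#'   (default `TRUE`).
#' @return Tibble with one row per site: `population`, `N`, `Ho`, `Ho_sd`,
#'   `He`, `He_sd`, `Fis`, `Fst`, `Ar`.
#' @export
site_summary <- function(genotypes, populations, rarefaction_n = NULL,
                         polymorphic_only = TRUE) {
  genotypes <- assert_geno(genotypes)
  populations <- population_table(populations, geno_individuals(genotypes))
  if (polymorphic_only) {
    poly <- locus_maf(genotypes) %>% filter(!is.na(.data$maf), .data$maf > 0)
    genotypes <- genotypes %>%
      filter(.data$locus_id %in% poly$locus_id) %>%
      geno_tbl()
  }
  per_locus <- het_stats(genotypes, populations)
  total <- het_stats(genotypes, populations = NULL)
  he_total <- mean(total$He)
  ar <- allelic_richness(genotypes, populations, n = rarefaction_n)
  sizes <- populations %>% count(.data$population, name = "N")

  per_locus %>%
    group_by(.data$population) %>%
    summarise(
      Ho_sd = stats::sd(.data$Ho[!is.na(.data$Ho)]),
      He_sd = stats::sd(.data$He),
      Ho = mean(.data$Ho, na.rm = TRUE),
      He = mean(.data$He),
      Fis = mean(.data$Fis, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(Fst = site_uniqueness_fst(.data$He, he_total)) %>%
    left_join(ar$per_population, by = "population") %>%
    left_join(sizes, by = "population") %>%
    select("population", "N", "Ho", "Ho_sd", "He", "He_sd", "Fis", "Fst", "Ar")
}

# per-locus Hs (weighted), Ht (pooled) for a set of populations
locus_hs_ht <- function(genotypes, populations) {
  freqs <- allele_frequencies(genotypes, populations)
  hs <- freqs %>%
    group_by(.data$locus_id, .data$population) %>%
    summarise(
      he = 1 - sum(.data$freq^2), n_copies = .data$n_copies[1], .groups = "drop"
    ) %>%
    group_by(.data$locus_id) %>%
    summarise(
      Hs = sum(.data$he * .data$n_copies) / sum(.data$n_copies), .groups = "drop"
    )
  ht <- freqs %>%
    mutate(count = .data$freq * .data$n_copies) %>%
    group_by(.data$locus_id, .data$allele) %>%
    summarise(count = sum(.data$count), .groups = "drop_last") %>%
    mutate(freq = .data$count / sum(.data$count)) %>%
    summarise(Ht = 1 - sum(.data$freq^2), .groups = "drop")
  left_join(hs, ht, by = "locus_id")
}

#' Pairwise Fst between populations
#'
#' Nei-style pairwise Fst: `Fst = (Ht - Hs)/Ht`, with `Hs` the
#' sample-size-weighted mean within-population expected heterozygosity and
#' `Ht` the expected heterozygosity of the pooled pair, both summed over loci
#' before taking the ratio (ratio of sums).  Negative estimates are returned
#' as computed.
#'
#' @param genotypes A [geno_tbl()].
#' @param populations A [population_table()].
#' @param pair Optional length-2 character vector naming one pair; by default
#'   all pairs are computed.
#' @return Tibble with columns `pop1`, `pop2`, `fst`, or a single number when
#'   `pair` is given.
#' @export
pairwise_fst <- function(genotypes, populations, pair = NULL) {
  genotypes <- assert_geno(genotypes)
  populations <- population_table(populations, geno_individuals(genotypes))
  pops <- sort(unique(populations$population))
  if (!is.null(pair)) {
    if (length(pair) != 2 || !all(pair %in% pops)) {
      abort("pair must name two populations present in the assignment table")
    }
    return(fst_one_pair(genotypes, populations, pair[1], pair[2]))
  }
  pairs <- utils::combn(pops, 2)
  tibble(
    pop1 = pairs[1, ], pop2 = pairs[2, ],
    fst = purrr::map2_dbl(
      pairs[1, ], pairs[2, ],
      ~ fst_one_pair(genotypes, populations, .x, .y)
    )
  )
}

fst_one_pair <- function(genotypes, populations, a, b) {
  keep <- populations %>% filter(.data$population %in% c(a, b))
  sub <- genotypes %>%
    filter(.data$individual_id %in% keep$individual_id) %>%
    geno_tbl()
  hh <- locus_hs_ht(sub, keep)
  if (sum(hh$Ht) <= 0) {
    abort(paste0("pairwise Fst undefined: ", a, " vs ", b, " monomorphic at every locus"))
  }
  (sum(hh$Ht) - sum(hh$Hs)) / sum(hh$Ht)
}

#' Pairwise Fst matrix
#'
#' Convenience wrapper returning the pairwise Fst values of [pairwise_fst()]
#' as a labelled symmetric matrix with zero diagonal, ready for
#' [mantel_test()].
#'
#' @inheritParams pairwise_fst
#' @return A symmetric numeric matrix.
#' @export
pairwise_fst_matrix <- function(genotypes, populations) {
  tb <- pairwise_fst(genotypes, populations)
  pops <- sort(unique(c(tb$pop1, tb$pop2)))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(nrow(tb))) {
    m[tb$pop1[i], tb$pop2[i]] <- tb$fst[i]
    m[tb$pop2[i], tb$pop1[i]] <- tb$fst[i]
  }
  m
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a random subsample of `n` gene
#' copies: per locus `Ar = sum_j (1 - choose(N - c_j, n)/choose(N, n))`,
#' where `c_j` is the copy count of allele `j` and `N` the total non-missing
#' copies of the (locus, population) cell.  At `n = N` this is the observed
#' allele count.
#'
#' @param genotypes A [geno_tbl()].
#' @param populations A [population_table()]; omit for one pooled population.
#' @param n Rarefaction size in gene copies (`>= 2`); defaults to the
#'   smallest copy count over (locus, population) cells so every cell is
#'   comparable.
#' @return List with `per_locus` (tibble `population`, `locus_id`, `Ar`),
#'   `per_population` (tibble `population`, `Ar` averaged over loci) and the
#'   `n` used.
#' @export
allelic_richness <- function(genotypes, populations = NULL, n = NULL) {
  genotypes <- assert_geno(genotypes)
  if (is.null(populations)) {
    populations <- tibble(
      individual_id = geno_individuals(genotypes), population = "all"
    )
  }
  freqs <- allele_frequencies(genotypes, populations)
  counts <- freqs %>% mutate(c = round(.data$freq * .data$n_copies))
  n <- n %||% min(counts$n_copies)
  if (n < 2) abort("rarefaction size n must be at least 2")
  if (n > min(counts$n_copies)) {
    abort(sprintf(
      "rarefaction size n = %d exceeds the smallest copy count (%d)",
      n, min(counts$n_copies)
    ))
  }
  per_locus <- counts %>%
    group_by(.data$population, .data$locus_id) %>%
    summarise(
      Ar = sum(1 - exp(lchoose(.data$n_copies - .data$c, n) - lchoose(.data$n_copies, n))),
      .groups = "drop"
    )
  per_population <- per_locus %>%
    group_by(.data$population) %>%
    summarise(Ar = mean(.data$Ar), .groups = "drop")
  list(per_locus = per_locus, per_population = per_population, n = n)
}

#' Genotyping quality control
#'
#' Per-individual and per-locus missingness and the polymorphic-locus count
#' (loci with at least two alleles observed at nonzero frequency).
#'
#' @param genotypes A [geno_tbl()].
#' @return List with `individuals` (tibble `individual_id`, `n_missing`,
#'   `prop_missing`), `loci` (tibble `locus_id`, `n_missing`, `prop_missing`,
#'   `n_alleles`, `polymorphic`) and `summary` (one-row tibble with
#'   mean/sd/min/max missing per individual and `n_polymorphic`).
#' @export
genotyping_qc <- function(genotypes) {
  genotypes <- assert_geno(genotypes)
  inds <- genotypes %>%
    group_by(.data$individual_id) %>%
    summarise(
      n_missing = sum(is.na(.data$allele1)),
      prop_missing = mean(is.na(.data$allele1)), .groups = "drop"
    )
  loci <- genotypes %>%
    group_by(.data$locus_id) %>%
    summarise(
      n_missing = sum(is.na(.data$allele1)),
      prop_missing = mean(is.na(.data$allele1)),
      n_alleles = dplyr::n_distinct(
        c(.data$allele1[!is.na(.data$allele1)], .data$allele2[!is.na(.data$allele2)])
      ),
      .groups = "drop"
    ) %>%
    mutate(polymorphic = .data$n_alleles >= 2)
  list(
    individuals = inds, loci = loci,
    summary = tibble(
      n_individuals = nrow(inds), n_loci = nrow(loci),
      mean_missing = mean(inds$n_missing), sd_missing = stats::sd(inds$n_missing),
      min_missing = min(inds$n_missing), max_missing = max(inds$n_missing),
      mean_prop_missing = mean(inds$prop_missing),
      n_polymorphic = sum(loci$polymorphic)
    )
  )
}

#' Drop individuals with excessive missing data
#'
#' Keeps an individual iff its fraction of missing calls is at most
#' `max_fraction` (strictly greater is removed).
#'
#' @param genotypes A [geno_tbl()].
#' @param max_fraction Largest tolerated missing fraction, in `(0, 1]`
#'   (default one third).
#' @return A filtered [geno_tbl()]; dropped ids in `attr(, "dropped")`.
#' @export
drop_high_missing_individuals <- function(genotypes, max_fraction = 1 / 3) {
  if (max_fraction <= 0 || max_fraction > 1) abort("max_fraction must be in (0, 1]")
  genotypes <- assert_geno(genotypes)
  qc <- genotyping_qc(genotypes)$individuals
  drop <- qc$individual_id[qc$prop_missing > max_fraction]
  out <- genotypes %>%
    filter(!.data$individual_id %in% drop) %>%
    geno_tbl()
  attr(out, "dropped") <- drop
  out
}

#' Fst-versus-heterozygosity outlier scan
#'
#' Flags loci whose global Fst falls outside an empirical envelope of the
#' Fst-versus-total-heterozygosity cloud, the usual graphical scan for loci
#' under (or linked to) selection.  Per-locus global Fst is the Nei estimator
#' `(Ht - Hs)/Ht` across all populations; loci are grouped into `n_bins`
#' equal-count bins of total expected heterozygosity, the
#' `(1 - envelope)/2` and `1 - (1 - envelope)/2` empirical Fst quantiles are
#' taken per bin, and the envelope is linearly interpolated between bin
#' midpoints.
#'
#' @param genotypes A [geno_tbl()] with at least 50 polymorphic loci.
#' @param populations A [population_table()].
#' @param envelope Envelope mass (default 0.95).
#' @param n_bins Number of equal-count heterozygosity bins (default 10).
#' @return A tibble of class `outlier_scan`: `locus_id`, `He`, `fst`,
#'   `lower`, `upper`, `outlier`; the binned envelope is in
#'   `attr(, "envelope")`.
#' @export
fst_outlier_scan <- function(genotypes, populations, envelope = 0.95, n_bins = 10) {
  genotypes <- assert_geno(genotypes)
  populations <- population_table(populations, geno_individuals(genotypes))
  poly <- locus_maf(genotypes) %>% filter(!is.na(.data$maf), .data$maf > 0)
  if (nrow(poly) < 50) {
    abort(sprintf(
      "outlier scan needs >= 50 polymorphic loci (got %d): envelope unreliable",
      nrow(poly)
    ))
  }
  sub <- genotypes %>%
    filter(.data$locus_id %in% poly$locus_id) %>%
    geno_tbl()
  hh <- locus_hs_ht(sub, populations) %>%
    mutate(fst = ifelse(.data$Ht > 0, (.data$Ht - .data$Hs) / .data$Ht, NA_real_)) %>%
    filter(!is.na(.data$fst))

  alpha <- (1 - envelope) / 2
  binned <- hh %>%
    mutate(bin = dplyr::ntile(.data$Ht, n_bins)) %>%
    group_by(.data$bin) %>%
    summarise(
      mid = mean(.data$Ht),
      lower = stats::quantile(.data$fst, alpha, names = FALSE),
      upper = stats::quantile(.data$fst, 1 - alpha, names = FALSE),
      .groups = "drop"
    ) %>%
    arrange(.data$mid)

  lo <- stats::approx(binned$mid, binned$lower, xout = hh$Ht, rule = 2)$y
  up <- stats::approx(binned$mid, binned$upper, xout = hh$Ht, rule = 2)$y
  out <- tibble(
    locus_id = hh$locus_id, He = hh$Ht, fst = hh$fst,
    lower = lo, upper = up,
    outlier = hh$fst < lo | hh$fst > up
  )
  structure(out,
    class = c("outlier_scan", class(tibble())),
    envelope = binned, envelope_mass = envelope, n_bins = n_bins
  )
}
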