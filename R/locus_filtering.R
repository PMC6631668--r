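#' Per-locus minor allele frequency
#'
#' The minor allele frequency (MAF) of each locus over the pooled set of
#' individuals, computed from non-missing gene copies: `min(p, 1 - p)` with
#' `p` the frequency of either allele at a biallelic locus (for loci with more
#' than two alleles the complement of the major-allele frequency is reported).
#' Mitochondrial loci contribute one copy per individual.
#'
#' @param genotypes A [geno_tbl()].
#' @return Tibble with columns `locus_id`, `maf`, `n_copies`.  Loci with no
#'   non-missing call get `maf = NA` and `n_copies = 0`.
#' @export
locus_maf <- function(genotypes) {
  genotypes <- assert_geno(genotypes)
  counts <- genotypes %>%
    filter(!is.na(.data$allele1)) %>%
    mutate(a2 = dplyr::if_else(.data$marker_class == "mitochondrial",
      NA_character_, .data$allele2
    )) %>%
    tidyr::pivot_longer(c("allele1", "a2"), values_to = "allele") %>%
    filter(!is.na(.data$allele)) %>%
    count(.data$locus_id, .data$allele, name = "count")
  obs <- if (nrow(counts) == 0) {
    tibble(locus_id = character(), n_copies = integer(), maf = numeric())
  } else {
    counts %>%
      group_by(.data$locus_id) %>%
      summarise(
        n_copies = sum(.data$count),
        maf = 1 - max(.data$count) / sum(.data$count),
        .groups = "drop"
      )
  }
  tibble(locus_id = geno_loci(genotypes)) %>%
    left_join(obs, by = "locus_id") %>%
    mutate(n_copies = tidyr::replace_na(.data$n_copies, 0L))
}

#' Minor allele frequency of a single locus
#'
#' @param allele1,allele2 Character vectors of calls (NA pairs = missing).
#' @param haploid If `TRUE` only `allele1` is counted (one gene copy per
#'   individual).
#' @return MAF in `[0, 0.5]` for biallelic data.  Errors when every call is
#'   missing.
#' @export
minor_allele_frequency <- function(allele1, allele2, haploid = FALSE) {
  copies <- c(allele1, if (!haploid) allele2)
  copies <- copies[!is.na(copies)]
  if (length(copies) == 0) abort("MAF undefined: all calls missing")
  counts <- table(copies)
  1 - max(counts) / sum(counts)
}

#' Filter loci on minor allele frequency
#'
#' A locus passes iff its pooled-sample MAF is at least `threshold`
#' (boundary inclusive).  Monomorphic loci (MAF 0) always fail for any
#' positive threshold; all-missing loci fail and are reported with `maf = NA`.
#'
#' @param genotypes A [geno_tbl()].
#' @param threshold MAF threshold in `[0, 0.5]` (default 0.05).
#' @return Tibble with columns `locus_id`, `maf`, `pass`.
#' @export
filter_by_maf <- function(genotypes, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5) abort("threshold must be in [0, 0.5]")
  locus_maf(genotypes) %>%
    mutate(pass = !is.na(.data$maf) & .data$maf >= threshold) %>%
    select("locus_id", "maf", "pass")
}

#' Filter RAD tags on sequence quality and mapping
#'
#' A tag survives iff it carries at most `max_snps` SNPs, every SNP offset
#' `o` satisfies `edge_bp <= o < length - edge_bp` (0-based; the first and
#' last `edge_bp` bases are excluded, the boundary offset `edge_bp` itself is
#' allowed), its sequence contains no undetermined (`N`) base when
#' `forbid_undetermined`, and it has a linkage-map position when
#' `require_mapped`.
#'
#' @param rads A [rad_tbl()].
#' @param max_snps Maximum SNPs per tag (default 2).
#' @param edge_bp Excluded window at each tag end in bp (default 30).
#' @param forbid_undetermined Drop tags containing `N` (default `TRUE`).
#' @param require_mapped Drop tags without a cM position (default `TRUE`).
#' @return Tibble with columns `tag_id`, `pass`, and logical columns
#'   `fail_max_snps`, `fail_edge`, `fail_n`, `fail_unmapped` recording which
#'   rules each tag violates.
#' @export
filter_rad_tags <- function(rads, max_snps = 2, edge_bp = 30,
                            forbid_undetermined = TRUE, require_mapped = TRUE) {
  rads <- as_tibble(rads)
  len <- nchar(rads$sequence)
  if (nrow(rads) > 0 && 2 * edge_bp >= min(len)) {
    abort("edge_bp windows cover an entire tag; reduce edge_bp")
  }
  fail_edge <- purrr::map2_lgl(rads$snp_offsets, len, function(off, l) {
    any(off < edge_bp | off >= l - edge_bp)
  })
  out <- tibble(
    tag_id = rads$tag_id,
    fail_max_snps = lengths(rads$snp_offsets) > max_snps,
    fail_edge = fail_edge,
    fail_n = if (forbid_undetermined) grepl("N", rads$sequence, fixed = TRUE) else FALSE,
    fail_unmapped = if (require_mapped) is.na(rads$position_cM) else FALSE
  )
  out %>%
    mutate(pass = !(.data$fail_max_snps | .data$fail_edge | .data$fail_n |
      .data$fail_unmapped), .after = "tag_id")
}

#' Filter tags for assay (primer) design
#'
#' Keeps tags suitable for allele-specific PCR assay design: exactly one SNP,
#' lying outside the primer design zones (`primer_zone_bp` bases at each end;
#' 0-based offsets in `[primer_zone_bp, length - primer_zone_bp)` are
#' allowed).
#'
#' @param rads A [rad_tbl()], normally already passed through
#'   [filter_rad_tags()].
#' @param primer_zone_bp Primer zone width at each end in bp (default 50).
#' @return Tibble with columns `tag_id`, `pass`.
#' @export
filter_for_assay <- function(rads, primer_zone_bp = 50) {
  rads <- as_tibble(rads)
  len <- nchar(rads$sequence)
  if (nrow(rads) > 0 && 2 * primer_zone_bp >= min(len)) {
    abort("primer zones cover an entire tag; reduce primer_zone_bp")
  }
  pass <- purrr::map2_lgl(rads$snp_offsets, len, function(off, l) {
    length(off) == 1 && off >= primer_zone_bp && off < l - primer_zone_bp
  })
  tibble(tag_id = rads$tag_id, pass = pass)
}

#' Run the candidate-locus filter cascade
#'
#' Applies the panel-design filters in order -- minor allele frequency, tag
#' sequence/mapping filters, then optionally the assay (primer zone) filter --
#' and returns a telescoping report.  Each filter is a predicate on the
#' original input, so the final candidate set is the intersection of the
#' per-filter pass sets and is independent of filter order.
#'
#' A tag passes the MAF step iff every SNP it carries reaches the threshold.
#' Genotype locus ids must follow the `"<tag_id>:<offset>"` convention of
#' [snp_loci()] (or equal the tag id for one-SNP tags).
#'
#' @param genotypes A [geno_tbl()] of the tags' SNP loci.
#' @param rads A [rad_tbl()].
#' @param maf_threshold MAF threshold (default 0.05).
#' @param max_snps,edge_bp,forbid_undetermined,require_mapped Passed to
#'   [filter_rad_tags()].
#' @param assay Apply [filter_for_assay()] as a final step (default `FALSE`).
#' @param primer_zone_bp Primer zone width when `assay = TRUE` (default 50).
#' @return A tibble of class `filter_report` with columns `step`, `n_in`,
#'   `n_out`, `n_removed` and list-column `removed_ids`; the final candidate
#'   tag ids are in `attr(, "final_ids")`.
#' @export
run_filter_cascade <- function(genotypes, rads, maf_threshold = 0.05,
                               max_snps = 2, edge_bp = 30,
                               forbid_undetermined = TRUE, require_mapped = TRUE,
                               assay = FALSE, primer_zone_bp = 50) {
  genotypes <- assert_geno(genotypes)
  rads_tb <- as_tibble(rads)
  loci <- snp_loci(rads)

  geno_loci_ids <- geno_loci(genotypes)
  known <- geno_loci_ids %in% loci$locus_id | geno_loci_ids %in% rads_tb$tag_id
  if (nrow(rads_tb) > 0 && !all(known)) {
    abort(paste0(
      "genotype loci without a matching RAD tag: ",
      paste(utils::head(geno_loci_ids[!known], 5), collapse = ", ")
    ))
  }

  if (nrow(rads_tb) == 0) {
    report <- tibble(
      step = character(), n_in = integer(), n_out = integer(),
      n_removed = integer(), removed_ids = list()
    )
    attr(report, "final_ids") <- character()
    class(report) <- c("filter_report", class(tibble()))
    return(report)
  }

  # MAF pass per tag: all of the tag's genotyped SNP loci reach the threshold
  maf <- filter_by_maf(genotypes, maf_threshold)
  locus_to_tag <- loci %>% select("locus_id", "tag_id")
  one_snp <- rads_tb$tag_id[lengths(rads_tb$snp_offsets) == 1]
  alias <- tibble(locus_id = one_snp, tag_id = one_snp)
  locus_to_tag <- bind_rows(locus_to_tag, alias) %>% distinct()
  maf_by_tag <- maf %>%
    inner_join(locus_to_tag, by = "locus_id") %>%
    group_by(.data$tag_id) %>%
    summarise(pass = all(.data$pass), .groups = "drop")
  maf_pass <- tibble(tag_id = rads_tb$tag_id) %>%
    left_join(maf_by_tag, by = "tag_id") %>%
    # tags with no genotyped SNP cannot demonstrate polymorphism: fail
    mutate(pass = tidyr::replace_na(.data$pass, FALSE))

  seq_pass <- filter_rad_tags(rads,
    max_snps = max_snps, edge_bp = edge_bp,
    forbid_undetermined = forbid_undetermined, require_mapped = require_mapped
  )

  steps <- list(maf = maf_pass$pass, rad_sequence = seq_pass$pass)
  if (assay) steps$assay <- filter_for_assay(rads, primer_zone_bp)$pass

  ids <- rads_tb$tag_id
  current <- rep(TRUE, length(ids))
  rows <- purrr::imap(steps, function(pass, name) {
    n_in <- sum(current)
    removed <- ids[current & !pass]
    current <<- current & pass
    tibble(
      step = name, n_in = n_in, n_out = sum(current),
      n_removed = length(removed), removed_ids = list(removed)
    )
  })
  report <- bind_rows(rows)
  attr(report, "final_ids") <- ids[current]
  class(report) <- c("filter_report", class(tibble()))
  report
}

#' @rdname run_filter_cascade
#' @param report A `filter_report`.
#' @export
retained_ids <- function(report) attr(report, "final_ids")
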