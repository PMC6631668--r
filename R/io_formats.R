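#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file and keeps biallelic SNP records only (single-base REF
#' and ALT); multiallelic and indel records are skipped and counted.  Missing
#' genotypes (`./.`) become missing calls; phase is discarded, so `0|1` and
#' `1/0` yield the same unordered allele pair.  Locus ids are taken from the
#' ID column when present, otherwise `CHROM:POS`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A list with elements `genotypes` (a [geno_tbl()] coded with the
#'   actual ref/alt bases), `loci` (tibble `locus_id`, `chrom`, `pos`, `ref`,
#'   `alt`) and `n_skipped` (records dropped as non-biallelic-SNP).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no usable biallelic SNP records")
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (!any(keep)) abort("VCF contains no usable biallelic SNP records")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
    paste0(fix$CHROM, ":", fix$POS), fix$ID
  )
  if (anyDuplicated(ids) > 0) abort("duplicate locus ids in VCF")
  rownames(gt) <- ids

  loci <- tibble(
    locus_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )

  long <- as_tibble(gt, rownames = "locus_id") %>%
    tidyr::pivot_longer(-"locus_id",
      names_to = "individual_id", values_to = "gt"
    ) %>%
    left_join(loci[c("locus_id", "ref", "alt")], by = "locus_id")

  codes <- stringr::str_split_fixed(gsub("\\|", "/", long$gt), "/", 2)
  decode <- function(code, ref, alt) {
    out <- rep(NA_character_, length(code))
    i0 <- !is.na(code) & code == "0"
    i1 <- !is.na(code) & code == "1"
    out[i0] <- ref[i0]
    out[i1] <- alt[i1]
    out
  }
  a1 <- decode(codes[, 1], long$ref, long$alt)
  a2 <- decode(codes[, 2], long$ref, long$alt)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  # unordered pair: store sorted
  swap <- !miss & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp

  geno <- geno_tbl(tibble(
    individual_id = long$individual_id, locus_id = long$locus_id,
    allele1 = a1, allele2 = a2, marker_class = "snp"
  ))
  list(genotypes = geno, loci = loci, n_skipped = n_skipped)
}

#' Write biallelic SNP genotypes as a minimal VCF
#'
#' Inverse of [read_variants()] for round-trip testing and interchange.
#'
#' @param genotypes A [geno_tbl()] of SNP calls coded with ref/alt bases.
#' @param loci Tibble with `locus_id`, `ref`, `alt` and optional `chrom`,
#'   `pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(genotypes, loci, path) {
  genotypes <- assert_geno(genotypes)
  loci <- as_tibble(loci)
  if (!"chrom" %in% names(loci)) loci$chrom <- "1"
  if (!"pos" %in% names(loci)) loci$pos <- seq_len(nrow(loci))
  inds <- geno_individuals(genotypes)

  code <- genotypes %>%
    left_join(loci[c("locus_id", "ref", "alt")], by = "locus_id") %>%
    mutate(
      c1 = dplyr::case_when(
        is.na(.data$allele1) ~ ".",
        .data$allele1 == .data$ref ~ "0",
        .data$allele1 == .data$alt ~ "1"
      ),
      c2 = dplyr::case_when(
        is.na(.data$allele2) ~ ".",
        .data$allele2 == .data$ref ~ "0",
        .data$allele2 == .data$alt ~ "1"
      )
    )
  if (any(is.na(code$c1) | is.na(code$c2))) {
    abort("genotype allele not matching the locus ref/alt")
  }
  code <- code %>%
    mutate(gt = paste(pmin(.data$c1, .data$c2), pmax(.data$c1, .data$c2), sep = "/")) %>%
    select("individual_id", "locus_id", "gt") %>%
    tidyr::pivot_wider(names_from = "individual_id", values_from = "gt")
  code <- code[match(loci$locus_id, code$locus_id), , drop = FALSE]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radpanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", inds), collapse = "\t")
  )
  body <- paste(
    loci$chrom, loci$pos, loci$locus_id, loci$ref, loci$alt, ".", "PASS", ".",
    "GT",
    apply(as.matrix(code[, inds, drop = FALSE]), 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a linkage map from a delimited table
#'
#' Expects columns `marker_id`, `linkage_group`, `position_cM` and optionally
#' `recomb_rate`; other columns are dropped with a warning.  Rows are sorted
#' by group and position; duplicate marker ids and negative positions are
#' rejected.
#'
#' @param path Path to a comma- or tab-delimited table with a header row.
#' @param total_length_cM Optional total map length (cM); defaults to the sum
#'   of per-group maxima.
#' @param delim Field delimiter; guessed from the file extension by default
#'   (`.csv` comma, otherwise tab).
#' @return A [linkage_map()].
#' @export
read_linkage_map <- function(path, total_length_cM = NULL, delim = NULL) {
  data <- read_delim_quiet(path, delim)
  linkage_map(data, total_length_cM = total_length_cM)
}

#' @rdname read_linkage_map
#' @param map A [linkage_map()] to serialize.
#' @export
write_linkage_map <- function(map, path, delim = NULL) {
  delim <- delim %||% delim_for(path)
  readr::write_delim(as_tibble(map), path, delim = delim, na = "NA")
  invisible(path)
}

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

read_delim_quiet <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  delim <- delim %||% delim_for(path)
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(decimal_mark = ".")
  )
}

#' Read a wide genotype table
#'
#' Reads delimited genotype tables as produced by genotyping services: the
#' first column holds individual ids, then either two columns per locus
#' (alleles 1 and 2) or one combined column per locus with calls written
#' `"A/B"`.  Missing calls are encoded by a configurable sentinel (both
#' columns, or the whole combined field).  Microsatellite allele sizes become
#' string allele identifiers.
#'
#' @param path Path to the delimited file (header row required).
#' @param marker_class Marker class for all loci in the file: `"snp"`,
#'   `"microsatellite"` or `"mitochondrial"`.
#' @param format `"combined"` (one `"A/B"` column per locus) or
#'   `"two_column"` (paired allele columns; an odd locus-column count is an
#'   error).  Two-column headers may name the pair `L_1`/`L_2` (or `L.1`,
#'   `L.2`); the shared stem becomes the locus id.
#' @param missing Sentinel string for missing calls (default `"NA"`).
#' @param delim Field delimiter; guessed from the extension by default.
#' @return A [geno_tbl()].
#' @export
read_genotype_table <- function(path, marker_class = "snp",
                                format = c("combined", "two_column"),
                                missing = "NA", delim = NULL) {
  format <- match.arg(format)
  delim <- delim %||% delim_for(path)
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  data <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()), na = character()
  )
  if (ncol(data) < 2) abort("genotype table needs an id column plus locus columns")
  inds <- data[[1]]
  if (anyDuplicated(inds) > 0) abort("duplicate individual ids")
  body <- data[-1]

  if (format == "combined") {
    long <- tibble(
      individual_id = rep(inds, times = ncol(body)),
      locus_id = rep(names(body), each = nrow(body)),
      value = unlist(body, use.names = FALSE)
    )
    parts <- stringr::str_split_fixed(long$value, "/", 2)
    a1 <- parts[, 1]; a2 <- parts[, 2]
    miss <- long$value == missing | a1 == missing | a2 == missing | a2 == ""
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
    calls <- tibble(
      individual_id = long$individual_id, locus_id = long$locus_id,
      allele1 = a1, allele2 = a2
    )
  } else {
    if (ncol(body) %% 2 != 0) {
      abort("two-column format requires an even number of locus columns")
    }
    i1 <- seq(1, ncol(body), by = 2)
    stems <- sub("[._]?[12]$", "", names(body)[i1])
    calls <- purrr::map2_dfr(i1, stems, function(i, stem) {
      tibble(
        individual_id = inds, locus_id = stem,
        allele1 = body[[i]], allele2 = body[[i + 1]]
      )
    })
    miss <- calls$allele1 == missing | calls$allele2 == missing
    calls$allele1[miss] <- NA_character_
    calls$allele2[miss] <- NA_character_
  }
  calls$marker_class <- marker_class
  geno_tbl(calls)
}

#' @rdname read_genotype_table
#' @param genotypes A [geno_tbl()] to serialize (single marker class per call
#'   shape; the class column itself is not written).
#' @export
write_genotype_table <- function(genotypes, path, format = c("combined", "two_column"),
                                 missing = "NA", delim = NULL) {
  genotypes <- assert_geno(genotypes)
  format <- match.arg(format)
  delim <- delim %||% delim_for(path)
  if (format == "combined") {
    wide <- genotypes %>%
      mutate(value = ifelse(is.na(.data$allele1), missing,
        paste0(.data$allele1, "/", .data$allele2)
      )) %>%
      select("individual_id", "locus_id", "value") %>%
      tidyr::pivot_wider(names_from = "locus_id", values_from = "value")
  } else {
    wide <- genotypes %>%
      mutate(
        allele1 = ifelse(is.na(.data$allele1), missing, .data$allele1),
        allele2 = ifelse(is.na(.data$allele2), missing, .data$allele2)
      ) %>%
      select("individual_id", "locus_id", "allele1", "allele2") %>%
      tidyr::pivot_wider(
        names_from = "locus_id", values_from = c("allele1", "allele2"),
        names_glue = "{locus_id}_{ifelse(.value == 'allele1', 1, 2)}"
      )
    # interleave allele columns locus by locus
    loci <- geno_loci(genotypes)
    wide <- wide[c("individual_id", as.vector(rbind(
      paste0(loci, "_1"), paste0(loci, "_2")
    )))]
  }
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Read and write population assignment tables
#'
#' @param path Delimited file with columns `individual_id`, `population`,
#'   optional `lineage`.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return [read_population_table()] returns a validated tibble.
#' @export
read_population_table <- function(path, delim = NULL) {
  population_table(read_delim_quiet(path, delim))
}

#' @rdname read_population_table
#' @param populations Table to serialize.
#' @export
write_population_table <- function(populations, path, delim = NULL) {
  delim <- delim %||% delim_for(path)
  readr::write_delim(population_table(populations), path, delim = delim)
  invisible(path)
}

#' Read and write square labelled distance matrices
#'
#' The on-disk form is a delimited table whose first column (`site`) holds row
#' labels and whose remaining column names repeat the site labels.  Distances
#' are validated as symmetric, nonnegative and zero on the diagonal.
#'
#' @param path File path.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return A labelled numeric matrix.
#' @export
read_distance_matrix <- function(path, delim = NULL) {
  data <- read_delim_quiet(path, delim)
  m <- as.matrix(data[-1])
  rownames(m) <- data[[1]]
  storage.mode(m) <- "double"
  validate_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param m Labelled symmetric matrix to serialize.
#' @export
write_distance_matrix <- function(m, path, delim = NULL) {
  validate_distance_matrix(m)
  delim <- delim %||% delim_for(path)
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(site = rownames(m)), out)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read and write RAD tag tables
#'
#' The combined tabular representation stores one row per tag with the SNP
#' offsets and their ref/alt bases joined by `";"`.
#'
#' @param path File path.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return [read_rad_tags()] returns a [rad_tbl()].
#' @export
read_rad_tags <- function(path, delim = NULL) {
  data <- read_delim_quiet(path, delim)
  split_int <- function(x) purrr::map(x, ~ if (is.na(.x) || .x == "") integer(0) else as.integer(strsplit(.x, ";")[[1]]))
  split_chr <- function(x) purrr::map(x, ~ if (is.na(.x) || .x == "") character(0) else strsplit(.x, ";")[[1]])
  rad_tbl(tibble(
    tag_id = as.character(data$tag_id),
    sequence = data$sequence,
    snp_offsets = split_int(as.character(data$snp_offsets)),
    ref = split_chr(as.character(data$ref)),
    alt = split_chr(as.character(data$alt)),
    linkage_group = if ("linkage_group" %in% names(data)) data$linkage_group else NA,
    position_cM = if ("position_cM" %in% names(data)) data$position_cM else NA_real_,
    recomb_rate = if ("recomb_rate" %in% names(data)) data$recomb_rate else NA_real_
  ))
}

#' @rdname read_rad_tags
#' @param rads A [rad_tbl()] to serialize.
#' @export
write_rad_tags <- function(rads, path, delim = NULL) {
  delim <- delim %||% delim_for(path)
  out <- as_tibble(rads) %>%
    mutate(
      snp_offsets = purrr::map_chr(.data$snp_offsets, paste, collapse = ";"),
      ref = purrr::map_chr(.data$ref, paste, collapse = ";"),
      alt = purrr::map_chr(.data$alt, paste, collapse = ";")
    )
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

#' Export a panel as an assay design table
#'
#' Produces the submission format used by allele-specific PCR genotyping
#' services (KASP-style): one row per panel marker with its flanking sequence
#' written `left-flank[REF/ALT]right-flank`, flanks truncated at the tag
#' boundaries.  Rows are ordered by linkage group, position, then id.
#'
#' @param panel A [panel_selection()] (or tibble with `marker_id`); marker ids
#'   follow the `"<tag_id>:<offset>"` convention of [snp_loci()].
#' @param rads The [rad_tbl()] providing sequence context.
#' @param path Optional output CSV path.
#' @param flank_bp Flank length in bp on each side (default 50).
#' @return Tibble with columns `marker_id`, `linkage_group`, `position_cM`,
#'   `assay_sequence`.
#' @export
write_panel_export <- function(panel, rads, path = NULL, flank_bp = 50) {
  panel <- as_tibble(panel)
  loci <- snp_loci(rads)
  rows <- panel %>%
    left_join(loci %>% select("locus_id", tag = "tag_id", "offset", "ref", "alt"),
      by = c(marker_id = "locus_id")
    )
  if (any(is.na(rows$tag))) {
    bad <- rows$marker_id[is.na(rows$tag)]
    abort(paste0(
      "no sequence context for marker(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  seqs <- rads$sequence[match(rows$tag, rads$tag_id)]
  left <- substr(seqs, pmax(1, rows$offset + 1 - flank_bp), rows$offset)
  right <- substr(seqs, rows$offset + 2, pmin(nchar(seqs), rows$offset + 1 + flank_bp))
  out <- tibble(
    marker_id = rows$marker_id,
    linkage_group = if ("linkage_group" %in% names(rows)) rows$linkage_group else NA,
    position_cM = if ("position_cM" %in% names(rows)) rows$position_cM else NA_real_,
    assay_sequence = paste0(left, "[", rows$ref, "/", rows$alt, "]", right)
  ) %>%
    arrange(.data$linkage_group, .data$position_cM, .data$marker_id)
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
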