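# small in-code fixtures shared across the suite

# genotype table from a compact spec: list(ind = c("A/A", "A/G", NA, ...))
# one entry per individual, loci named by the `loci` argument
tiny_geno <- function(calls, loci, marker_class = "snp") {
  rows <- purrr::imap_dfr(calls, function(genos, ind) {
    parts <- stringr::str_split_fixed(ifelse(is.na(genos), "NA/NA", genos), "/", 2)
    tibble::tibble(
      individual_id = ind, locus_id = loci,
      allele1 = ifelse(parts[, 1] == "NA", NA_character_, parts[, 1]),
      allele2 = ifelse(parts[, 2] == "NA", NA_character_, parts[, 2]),
      marker_class = marker_class
    )
  })
  geno_tbl(rows)
}

two_pops <- function(geno, pattern = "^p1") {
  ids <- geno_individuals(geno)
  population_table(tibble::tibble(
    individual_id = ids,
    population = ifelse(grepl(pattern, ids), "p1", "p2")
  ))
}

# one RAD tag row; offsets 0-based
make_tag <- function(tag_id, sequence, offsets, ref = NULL, alt = NULL,
                     linkage_group = 1, position_cM = 1) {
  ref <- ref %||% substring(sequence, offsets + 1, offsets + 1)
  alt <- alt %||% vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
    character(1), USE.NAMES = FALSE
  )
  tibble::tibble(
    tag_id = tag_id, sequence = sequence,
    snp_offsets = list(as.integer(offsets)),
    ref = list(unname(ref)), alt = list(unname(alt)),
    linkage_group = linkage_group, position_cM = position_cM
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# frequency table for hand-constructed populations:
# freqs = named list pop -> named list locus -> named numeric allele freqs
freq_tbl <- function(freqs, n_copies = 100) {
  purrr::imap_dfr(freqs, function(loci, pop) {
    purrr::imap_dfr(loci, function(f, locus) {
      tibble::tibble(
        locus_id = locus, population = pop,
        allele = names(f), freq = unname(f), n_copies = n_copies
      )
    })
  })
}

# independent term-by-term evaluation of the informativeness formula,
# deliberately written as explicit loops over populations and alleles
brute_informativeness <- function(freqs) {
  total <- 0
  for (locus in unique(freqs$locus_id)) {
    sub <- freqs[freqs$locus_id == locus, ]
    pops <- unique(freqs$population)
    k <- length(pops)
    alleles <- unique(sub$allele)
    for (al in alleles) {
      p_ij <- vapply(pops, function(pp) {
        row <- sub[sub$population == pp & sub$allele == al, ]
        if (nrow(row) == 0) 0 else row$freq
      }, numeric(1))
      pbar <- mean(p_ij)
      term <- 0
      if (pbar > 0) term <- term - pbar * log(pbar)
      for (p in p_ij) if (p > 0) term <- term + (p / k) * log(p)
      total <- total + term
    }
  }
  total
}
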