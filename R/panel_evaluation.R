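#' Informativeness for assignment
#'
#' Rosenberg's informativeness for assignment of a marker set over K
#' populations.  Per locus,
#' `In = sum_j ( -pbar_j * ln(pbar_j) + sum_i (p_ij / K) * ln(p_ij) )`,
#' with `pbar_j` the unweighted mean frequency of allele `j` across the K
#' populations, natural logarithms, and the convention `0 * ln 0 = 0`.  The
#' multi-locus statistic is the sum over loci.  It is nonnegative and zero
#' iff every population shares the same frequencies.
#'
#' @param freqs An `allele_freq_tbl` from [allele_frequencies()] covering at
#'   least two populations.
#' @param loci Optional character vector restricting the locus set.
#' @return Total In (a single nonnegative number).
#' @seealso [locus_informativeness()] for the per-locus values.
#' @export
informativeness <- function(freqs, loci = NULL) {
  sum(locus_informativeness(freqs, loci)$In)
}

#' @rdname informativeness
#' @return `locus_informativeness()`: tibble with columns `locus_id`, `In`.
#' @export
locus_informativeness <- function(freqs, loci = NULL) {
  freqs <- as_tibble(freqs)
  if (!is.null(loci)) freqs <- freqs %>% filter(.data$locus_id %in% loci)
  k <- dplyr::n_distinct(freqs$population)
  if (k < 2) abort("informativeness requires K >= 2 populations")
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  # alleles unobserved in a population have frequency zero and contribute 0
  freqs %>%
    group_by(.data$locus_id, .data$allele) %>%
    summarise(
      pbar = sum(.data$freq) / k,
      sum_term = sum(xlx(.data$freq)) / k,
      .groups = "drop"
    ) %>%
    group_by(.data$locus_id) %>%
    summarise(In = sum(-xlx(.data$pbar) + .data$sum_term), .groups = "drop")
}

#' Informativeness as a function of panel size
#'
#' Estimates the informativeness-for-assignment curve: for each requested
#' subset size, `replicates` uniform random locus subsets are drawn without
#' replacement and the mean and SD of the multi-locus In are recorded.  Only
#' loci polymorphic in the analysed set enter the pool.
#'
#' @param genotypes A [geno_tbl()].
#' @param populations A [population_table()].
#' @param sizes Strictly increasing integer subset sizes; the largest must
#'   not exceed the polymorphic locus count.
#' @param replicates Subsets per size (default 20).
#' @param seed Integer seed; the curve is reproducible given the seed.
#' @return A tibble of class `informativeness_curve`: `size`, `mean_In`,
#'   `sd_In`, `replicates`.
#' @export
informativeness_curve <- function(genotypes, populations, sizes,
                                  replicates = 20, seed = 1L) {
  genotypes <- assert_geno(genotypes)
  sizes <- sort(unique(as.integer(sizes)))
  poly <- locus_maf(genotypes) %>% filter(!is.na(.data$maf), .data$maf > 0)
  pool_geno <- genotypes %>%
    filter(.data$locus_id %in% poly$locus_id) %>%
    geno_tbl()
  freqs <- allele_frequencies(pool_geno, populations)
  per_locus <- locus_informativeness(freqs)
  pool <- per_locus$locus_id
  if (max(sizes) > length(pool)) {
    abort(sprintf(
      "largest size (%d) exceeds the polymorphic locus count (%d)",
      max(sizes), length(pool)
    ))
  }
  curve <- withr::with_seed(seed, {
    purrr::map_dfr(sizes, function(s) {
      vals <- purrr::map_dbl(seq_len(replicates), function(r) {
        sub <- if (s == length(pool)) pool else sample(pool, s)
        sum(per_locus$In[per_locus$locus_id %in% sub])
      })
      tibble(
        size = s, mean_In = mean(vals),
        sd_In = if (replicates > 1) stats::sd(vals) else 0,
        replicates = replicates
      )
    })
  })
  structure(curve,
    class = c("informativeness_curve", class(tibble())), seed = seed
  )
}

#' Fit the linear informativeness-versus-size regression
#'
#' Ordinary least squares of mean In on panel size, `I = a * N + b`, the
#' relation used to express a marker set's informativeness in units of
#' "equivalent markers".
#'
#' @param curve An [informativeness_curve()] (or tibble with `size`,
#'   `mean_In`) with at least 3 distinct sizes.
#' @return An object of class `informativeness_fit`: list with `a` (slope),
#'   `b` (intercept), `r_squared` and the underlying `lm` fit.
#' @export
fit_informativeness_regression <- function(curve) {
  curve <- as_tibble(curve)
  if (dplyr::n_distinct(curve$size) < 3) {
    abort("regression needs at least 3 distinct sizes")
  }
  fit <- stats::lm(mean_In ~ size, data = curve)
  co <- stats::coef(fit)
  # summary.lm warns on numerically perfect fits; the fit itself is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      a = unname(co["size"]), b = unname(co["(Intercept)"]),
      r_squared = r2, model = fit
    ),
    class = "informativeness_fit"
  )
}

#' @export
print.informativeness_fit <- function(x, ...) {
  cat(sprintf(
    "Informativeness regression: I = %.4g * N + %.4g (r^2 = %.3f)\n",
    x$a, x$b, x$r_squared
  ))
  invisible(x)
}

#' Equivalent marker count for a target informativeness
#'
#' Inverts the linear informativeness regression: the smallest integer panel
#' size N whose predicted informativeness `a*N + b` reaches the target.  Used
#' to express, e.g., a microsatellite panel's informativeness as an
#' equivalent number of SNPs.
#'
#' @param fit An [fit_informativeness_regression()] result, or a list/vector
#'   with elements `a` and `b`.
#' @param target_informativeness The informativeness to match.
#' @return The smallest integer `N >= 0` with `a*N + b >= target`.
#' @export
equivalent_marker_count <- function(fit, target_informativeness) {
  a <- fit[["a"]]
  b <- fit[["b"]]
  if (is.null(a) || is.null(b)) abort("fit must provide slope `a` and intercept `b`")
  if (a <= 0) abort("extrapolation requires a positive slope")
  n <- (target_informativeness - b) / a
  # guard against 108.000000001-style float error at exact integers
  n <- ceiling(round(n, 9))
  max(0L, as.integer(n))
}

#' Mantel test between two labelled distance matrices
#'
#' Permutation Mantel test of the correlation between two symmetric matrices
#' (e.g. pairwise Fst and riparian distance).  The statistic is the Pearson
#' correlation of the lower-triangle vectors; the null distribution is built
#' by jointly permuting the row/column labels of the second matrix, and the
#' one-tailed p-value is `(1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param m1,m2 Symmetric labelled matrices over the same site set (order may
#'   differ; `m2` is aligned to `m1`'s labels).
#' @param n_perm Number of permutations (default 1000, minimum 99).
#' @param seed Integer seed.
#' @return An object of class `mantel_result`: list with `r`, `p_value`,
#'   `n_perm`, `n_sites`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 1000, seed = 1L) {
  validate_distance_matrix_loose(m1)
  validate_distance_matrix_loose(m2)
  if (!setequal(rownames(m1), rownames(m2))) {
    abort("matrices must be labelled with the same sites")
  }
  if (n_perm < 99) abort("use at least 99 permutations")
  m2 <- m2[rownames(m1), rownames(m1)]
  low <- lower.tri(m1)
  x <- m1[low]
  y <- m2[low]
  r_obs <- stats::cor(x, y)
  n <- nrow(m1)
  r_perm <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      stats::cor(x, m2[idx, idx][low])
    })
  })
  structure(
    list(
      r = r_obs, p_value = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
      n_perm = n_perm, n_sites = n, seed = seed
    ),
    class = "mantel_result"
  )
}

# Fst matrices may hold (slightly) negative estimates; only shape is enforced
validate_distance_matrix_loose <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    abort("matrix must have identical row and column labels")
  }
  if (any(abs(m - t(m)) > 1e-9)) abort("matrix must be symmetric")
  invisible(m)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.3f, p = %.4g (%d sites, %d permutations)\n",
    x$r, x$p_value, x$n_sites, x$n_perm
  ))
  invisible(x)
}

#' Supervised admixture estimation between two reference gene pools
#'
#' A supervised maximum-likelihood stand-in for unsupervised Bayesian
#' clustering: given reference allele frequencies for a captive-bred and a
#' wild gene pool, each individual's ancestry proportion `q` toward the
#' captive-bred pool is the maximiser over `[0, 1]` of the binomial
#' log-likelihood `sum_loci log Binom(g | ploidy, q*f_cap + (1-q)*f_wild)`,
#' where `g` counts copies of the reference allele.  The likelihood is
#' concave in `q`, so the deterministic golden-section search of
#' [stats::optimize()] finds the global maximum.  Reference frequencies are
#' floored away from 0 and 1 by the pseudo-count `1/(n_copies + 1)`.
#'
#' Individuals are classified by the threshold rule: `captive_bred` iff
#' `q > threshold`, `wild` iff `1 - q > threshold`, otherwise `admixed`
#' (strict inequalities; `q` exactly at the threshold is admixed).
#'
#' @param genotypes A [geno_tbl()] of the individuals to classify.
#' @param ref_captive,ref_wild Reference frequencies: `allele_freq_tbl`s of a
#'   single population each, or tibbles with `locus_id`, `allele`, `freq` and
#'   optionally `n_copies`.
#' @param threshold Classification threshold (default 0.7).
#' @param freq_floor Optional fixed floor overriding the per-locus
#'   pseudo-count.
#' @return A tibble of class `admixture_result`: `individual_id`,
#'   `q_captive`, `n_loci` (scored loci; individuals with none get `NA`),
#'   `class`.  The estimator is identified in `attr(, "method")`.
#' @export
supervised_admixture <- function(genotypes, ref_captive, ref_wild,
                                 threshold = 0.7, freq_floor = NULL) {
  genotypes <- assert_geno(genotypes)
  ref <- prepare_reference(ref_captive, ref_wild, freq_floor)

  calls <- genotypes %>%
    filter(!is.na(.data$allele1)) %>%
    inner_join(ref, by = "locus_id") %>%
    mutate(
      ploidy = copies_per_call(.data$marker_class),
      g = (.data$allele1 == .data$allele) +
        ifelse(.data$ploidy == 2L, .data$allele2 == .data$allele, 0L)
    )

  all_ids <- geno_individuals(genotypes)
  fitted <- calls %>%
    group_by(.data$individual_id) %>%
    summarise(
      q_captive = fit_q(.data$g, .data$ploidy, .data$f_cap, .data$f_wild),
      n_loci = dplyr::n(), .groups = "drop"
    )
  out <- tibble(individual_id = all_ids) %>%
    left_join(fitted, by = "individual_id") %>%
    mutate(
      n_loci = tidyr::replace_na(.data$n_loci, 0L),
      class = dplyr::case_when(
        is.na(.data$q_captive) ~ NA_character_,
        .data$q_captive > threshold ~ "captive_bred",
        1 - .data$q_captive > threshold ~ "wild",
        TRUE ~ "admixed"
      )
    )
  structure(out,
    class = c("admixture_result", class(tibble())),
    threshold = threshold,
    method = "supervised maximum-likelihood two-reference binomial estimator"
  )
}

# align the two reference tables on one counted allele per locus and floor
# frequencies away from {0, 1}
prepare_reference <- function(ref_captive, ref_wild, freq_floor = NULL) {
  norm <- function(x, nm) {
    x <- as_tibble(x)
    if (!all(c("locus_id", "allele", "freq") %in% names(x))) {
      abort(paste0(nm, " must have columns locus_id, allele, freq"))
    }
    if ("population" %in% names(x) && dplyr::n_distinct(x$population) > 1) {
      abort(paste0(nm, " must describe a single reference population"))
    }
    if (!"n_copies" %in% names(x)) x$n_copies <- NA_real_
    x[c("locus_id", "allele", "freq", "n_copies")]
  }
  cap <- norm(ref_captive, "ref_captive")
  wil <- norm(ref_wild, "ref_wild")
  # counted allele: first (alphabetically) allele seen at the locus in either pool
  counted <- bind_rows(cap, wil) %>%
    group_by(.data$locus_id) %>%
    summarise(allele = min(.data$allele), .groups = "drop")
  pick <- function(ref) {
    counted %>%
      left_join(ref, by = c("locus_id", "allele")) %>%
      mutate(
        freq = tidyr::replace_na(.data$freq, 0),
        floor = freq_floor %||% (1 / (tidyr::replace_na(.data$n_copies, 99) + 1)),
        freq = pmin(pmax(.data$freq, .data$floor), 1 - .data$floor)
      ) %>%
      select("locus_id", "allele", "freq")
  }
  pick(cap) %>%
    rename(f_cap = "freq") %>%
    inner_join(pick(wil) %>% rename(f_wild = "freq"), by = c("locus_id", "allele"))
}

fit_q <- function(g, ploidy, f_cap, f_wild) {
  loglik <- function(q) {
    theta <- q * f_cap + (1 - q) * f_wild
    sum(stats::dbinom(g, ploidy, theta, log = TRUE))
  }
  opt <- stats::optimize(loglik, interval = c(0, 1), maximum = TRUE, tol = 1e-7)
  # the optimum can sit on a boundary that golden-section never touches exactly
  cand <- c(0, opt$maximum, 1)
  cand[which.max(vapply(cand, loglik, numeric(1)))]
}

#' Concordance of ancestry estimates between marker sets
#'
#' Spearman rank correlation between two per-individual ancestry estimates
#' (e.g. SNP-based versus microsatellite-based `q`), the appropriate test
#' when admixture proportions are far from normal.  Ties are mid-ranked.
#'
#' @param q_a,q_b Either [supervised_admixture()] results or named numeric
#'   vectors of per-individual `q`; they are joined on individual id (at
#'   least 3 shared individuals required).
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
ancestry_concordance <- function(q_a, q_b) {
  as_q <- function(x) {
    if (inherits(x, "admixture_result") || is.data.frame(x)) {
      x <- as_tibble(x)
      stats::setNames(x$q_captive, x$individual_id)
    } else if (!is.null(names(x))) {
      x
    } else {
      abort("q vectors must be named by individual or be admixture results")
    }
  }
  qa <- as_q(q_a)
  qb <- as_q(q_b)
  shared <- intersect(names(qa), names(qb))
  shared <- shared[!is.na(qa[shared]) & !is.na(qb[shared])]
  if (length(shared) < 3) abort("concordance needs at least 3 paired individuals")
  ct <- suppressWarnings(
    stats::cor.test(qa[shared], qb[shared], method = "spearman", exact = FALSE)
  )
  tibble(
    rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared)
  )
}
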