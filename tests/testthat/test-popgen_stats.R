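test_that("allele frequencies count gene copies, haploids once", {
  g <- tiny_geno(list(p1_a = "A/A", p1_b = "A/G"), "L1")
  f <- allele_frequencies(g, tibble::tibble(
    individual_id = c("p1_a", "p1_b"), population = "p1"
  ))
  expect_equal(f$freq[f$allele == "A"], 0.75)
  expect_equal(f$freq[f$allele == "G"], 0.25)
  expect_equal(unique(f$n_copies), 4)

  # mitochondrial: homozygous pair stored, one copy counted
  m <- tiny_geno(list(p1_a = "H/H", p1_b = "K/K"), "mt1", marker_class = "mitochondrial")
  fm <- allele_frequencies(m, tibble::tibble(
    individual_id = c("p1_a", "p1_b"), population = "p1"
  ))
  expect_equal(unique(fm$n_copies), 2)
  expect_equal(fm$freq, c(0.5, 0.5))

  # all-missing cell errors, naming the cell
  g2 <- tiny_geno(list(p1_a = "A/A", p2_a = NA), "L1")
  expect_error(
    allele_frequencies(g2, tibble::tibble(
      individual_id = c("p1_a", "p2_a"), population = c("p1", "p2")
    )),
    "L1, p2"
  )
})

test_that("allele frequencies equal brute-force copy counting on random data", {
  set.seed(31)
  for (rep in 1:10) {
    sim <- simulate_two_lineage_genotypes(
      n_pops = 2, n_per_pop = 15, n_loci = 20, missing_rate = 0.1,
      seed = 300 + rep
    )
    f <- allele_frequencies(sim$genotypes, sim$populations)
    tb <- tibble::as_tibble(sim$genotypes) %>%
      dplyr::left_join(sim$populations, by = "individual_id")
    locus <- sample(unique(tb$locus_id), 1)
    pop <- sample(unique(tb$population), 1)
    copies <- with(
      tb[tb$locus_id == locus & tb$population == pop & !is.na(tb$allele1), ],
      c(allele1, allele2)
    )
    got <- f[f$locus_id == locus & f$population == pop, ]
    for (al in unique(copies)) {
      expect_equal(got$freq[got$allele == al], mean(copies == al))
    }
  }
})

test_that("heterozygosity closed forms and Fis under Hardy-Weinberg", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(rep(0.25, 4)), 0.75)
  expect_error(expected_heterozygosity(numeric()), "undefined")

  # He = Ho in expectation under HWE: multilocus mean Fis near 0 at n = 500
  set.seed(52)
  n <- 500
  rows <- purrr::map_dfr(1:50, function(m) {
    p <- runif(1, 0.1, 0.9)
    a1 <- ifelse(runif(n) < p, "A", "G")
    a2 <- ifelse(runif(n) < p, "A", "G")
    tibble::tibble(
      individual_id = paste0("p1_", seq_len(n)), locus_id = sprintf("L%02d", m),
      allele1 = pmin(a1, a2), allele2 = pmax(a1, a2), marker_class = "snp",
      het = a1 != a2
    )
  })
  g <- geno_tbl(dplyr::select(rows, -het))
  hs <- het_stats(g)
  expect_lt(abs(mean(hs$Fis)), 0.05)
  # observed heterozygosity is the heterozygote fraction
  expect_equal(
    hs$Ho[order(hs$locus_id)],
    with(rows, tapply(het, locus_id, mean))[order(unique(rows$locus_id))],
    ignore_attr = TRUE
  )
})

test_that("site-uniqueness Fst is the He ratio complement", {
  expect_equal(site_uniqueness_fst(0.2, 0.2), 0)
  expect_equal(site_uniqueness_fst(0.18, 0.20), 0.1)
  expect_error(site_uniqueness_fst(0.1, 0), "He_total")

  sim <- simulate_two_lineage_genotypes(
    n_pops = 3, n_per_pop = 25, n_loci = 60, divergence_F = 0.1,
    missing_rate = 0, seed = 61
  )
  ss <- site_summary(sim$genotypes, sim$populations)
  per_locus <- het_stats(sim$genotypes, sim$populations)
  total <- het_stats(sim$genotypes)
  poly <- locus_maf(sim$genotypes)
  poly_ids <- poly$locus_id[poly$maf > 0]
  he_total <- mean(total$He[total$locus_id %in% poly_ids])
  for (pop in ss$population) {
    he_site <- mean(per_locus$He[per_locus$population == pop &
      per_locus$locus_id %in% poly_ids])
    expect_equal(ss$Fst[ss$population == pop], 1 - he_site / he_total)
  }
})

test_that("pairwise Fst hits its closed-form anchors", {
  # identical frequencies: Fst = 0
  g <- tiny_geno(
    list(p1_a = "A/G", p1_b = "A/A", p2_a = "A/G", p2_b = "A/A"), "L1"
  )
  expect_equal(pairwise_fst(g, two_pops(g), c("p1", "p2")), 0)

  # fixed difference: Hs = 0, Ht = 0.5, Fst = 1
  gf <- tiny_geno(list(p1_a = "A/A", p1_b = "A/A", p2_a = "G/G", p2_b = "G/G"), "L1")
  expect_equal(pairwise_fst(gf, two_pops(gf), c("p1", "p2")), 1)

  gm <- tiny_geno(list(p1_a = "A/A", p2_a = "A/A"), "L1")
  expect_error(pairwise_fst(gm, two_pops(gm), c("p1", "p2")), "monomorphic")
})

test_that("pairwise Fst is symmetric and invariant to allele relabelling", {
  sim <- simulate_two_lineage_genotypes(
    n_pops = 3, n_per_pop = 20, n_loci = 40, divergence_F = 0.1,
    missing_rate = 0.05, seed = 71
  )
  ab <- pairwise_fst(sim$genotypes, sim$populations, c("pop1", "pop2"))
  ba <- pairwise_fst(sim$genotypes, sim$populations, c("pop2", "pop1"))
  expect_equal(ab, ba)

  relabel <- tibble::as_tibble(sim$genotypes) %>%
    dplyr::mutate(
      tmp1 = ifelse(allele1 == "A", "T", "C"),
      tmp2 = ifelse(allele2 == "A", "T", "C"),
      allele1 = pmin(tmp1, tmp2), allele2 = pmax(tmp1, tmp2)
    ) %>%
    dplyr::select(-tmp1, -tmp2) %>%
    geno_tbl()
  expect_equal(
    pairwise_fst(relabel, sim$populations, c("pop1", "pop2")), ab
  )

  m <- pairwise_fst_matrix(sim$genotypes, sim$populations)
  expect_equal(m, t(m))
  expect_equal(m["pop1", "pop2"], ab)
})

test_that("pairwise Fst estimates track the Nei pooled-pair expectation under Balding-Nichols", {
  # For two demes each diverged from the ancestor by F, the Nei pooled-pair
  # Gst has expectation ~ (F/2)/(1 - F/2); at F = 0.10 that is ~0.053.
  f_target <- 0.1
  expectation <- (f_target / 2) / (1 - f_target / 2)
  ests <- vapply(1:10, function(i) {
    sim <- simulate_two_lineage_genotypes(
      n_pops = 2, n_per_pop = 100, n_loci = 50, divergence_F = f_target,
      missing_rate = 0, seed = 700 + i
    )
    pairwise_fst(sim$genotypes, sim$populations, c("pop1", "pop2"))
  }, numeric(1))
  expect_gt(mean(ests), expectation - 0.02)
  expect_lt(mean(ests), expectation + 0.03)
})

test_that("allelic richness matches its rarefaction identities and enumeration", {
  pops1 <- function(g) tibble::tibble(
    individual_id = geno_individuals(g), population = "p1"
  )
  # n = Ncopies: Ar equals the observed allele count
  g <- tiny_geno(list(a = "150/152", b = "154/154", c = "150/156"), "U1",
    marker_class = "microsatellite"
  )
  ar <- allelic_richness(g, pops1(g), n = 6)
  expect_equal(ar$per_locus$Ar, 4)

  mono <- tiny_geno(list(a = "A/A", b = "A/A"), "L1")
  expect_equal(allelic_richness(mono, pops1(mono), n = 2)$per_locus$Ar, 1)
  expect_error(allelic_richness(mono, pops1(mono), n = 1), "at least 2")
  expect_error(allelic_richness(mono, pops1(mono), n = 10), "exceeds")

  # 6-copy toy locus, n = 4: exhaustive enumeration over all C(6,4) subsamples
  copies <- c("a", "a", "a", "b", "b", "c")
  combos <- utils::combn(6, 4)
  brute <- mean(apply(combos, 2, function(idx) length(unique(copies[idx]))))
  g6 <- tiny_geno(list(i1 = "a/a", i2 = "a/b", i3 = "b/c"), "U2",
    marker_class = "microsatellite"
  )
  expect_equal(allelic_richness(g6, pops1(g6), n = 4)$per_locus$Ar, brute)

  # Ar is nondecreasing in n
  ar_n <- vapply(2:6, function(n) allelic_richness(g6, pops1(g6), n = n)$per_locus$Ar,
    numeric(1)
  )
  expect_true(all(diff(ar_n) >= 0))
})

test_that("genotyping QC reports missingness and polymorphic counts", {
  sim <- simulate_two_lineage_genotypes(
    n_pops = 1, n_per_pop = 20, n_loci = 162, missing_rate = 0, seed = 81
  )
  qc0 <- genotyping_qc(sim$genotypes)
  expect_true(all(qc0$individuals$n_missing == 0))

  # plant exactly one missing call in one individual
  tb <- tibble::as_tibble(sim$genotypes)
  tb$allele1[1] <- NA
  tb$allele2[1] <- NA
  qc1 <- genotyping_qc(geno_tbl(tb))
  hit <- qc1$individuals[qc1$individuals$individual_id == tb$individual_id[1], ]
  expect_equal(hit$prop_missing, 1 / 162)

  # planted missingness rate recovered within 3 SE
  rate <- 0.01
  simm <- simulate_two_lineage_genotypes(
    n_pops = 1, n_per_pop = 50, n_loci = 200, missing_rate = rate, seed = 82
  )
  qc <- genotyping_qc(simm$genotypes)
  n_calls <- 50 * 200
  se <- sqrt(rate * (1 - rate) / n_calls)
  expect_lt(abs(mean(qc$individuals$prop_missing) - rate), 3 * se)
})

test_that("high-missing individuals are dropped by the strict one-third rule", {
  n_loci <- 100
  make_ind <- function(id, n_miss) {
    calls <- c(rep(NA_character_, n_miss), rep("A/G", n_loci - n_miss))
    tibble::tibble(
      individual_id = id, locus_id = sprintf("L%03d", 1:n_loci),
      allele1 = ifelse(is.na(calls), NA, "A"),
      allele2 = ifelse(is.na(calls), NA, "G"), marker_class = "snp"
    )
  }
  g <- geno_tbl(dplyr::bind_rows(
    make_ind("clean", 0), make_ind("at34", 34), make_ind("at33", 33)
  ))
  out <- drop_high_missing_individuals(g, 1 / 3)
  expect_setequal(geno_individuals(out), c("clean", "at33"))
  expect_equal(attr(out, "dropped"), "at34")

  # random missingness equals the brute-force rule
  set.seed(91)
  sim <- simulate_two_lineage_genotypes(
    n_pops = 1, n_per_pop = 30, n_loci = 30, missing_rate = 0.3, seed = 92
  )
  kept <- geno_individuals(drop_high_missing_individuals(sim$genotypes, 1 / 3))
  brute <- tibble::as_tibble(sim$genotypes) %>%
    dplyr::group_by(individual_id) %>%
    dplyr::summarise(f = mean(is.na(allele1))) %>%
    dplyr::filter(f <= 1 / 3)
  expect_setequal(kept, brute$individual_id)
  expect_error(drop_high_missing_individuals(sim$genotypes, 0), "max_fraction")
})

test_that("the outlier scan flags engineered outliers and respects its floor", {
  small <- simulate_two_lineage_genotypes(
    n_pops = 2, n_per_pop = 10, n_loci = 10, missing_rate = 0, seed = 101
  )
  expect_error(
    fst_outlier_scan(small$genotypes, small$populations),
    ">= 50 polymorphic"
  )

  base <- simulate_two_lineage_genotypes(
    n_pops = 2, n_per_pop = 30, n_loci = 99, divergence_F = 0.02,
    missing_rate = 0, seed = 102
  )
  ids <- geno_individuals(base$genotypes)
  fixed <- tibble::tibble(
    individual_id = ids, locus_id = "fixed1",
    allele1 = ifelse(grepl("pop1", ids), "A", "G"),
    allele2 = ifelse(grepl("pop1", ids), "A", "G"),
    marker_class = "snp"
  )
  gg <- geno_tbl(dplyr::bind_rows(tibble::as_tibble(base$genotypes), fixed))
  scan <- fst_outlier_scan(gg, base$populations)
  expect_true(scan$outlier[scan$locus_id == "fixed1"])
  expect_true(all(scan$lower <= scan$upper))
  expect_equal(sum(scan$outlier), glance(scan)$n_outliers)
})

test_that("statistics are invariant to individual order and missing-aware counting is consistent", {
  sim <- simulate_two_lineage_genotypes(
    n_pops = 2, n_per_pop = 15, n_loci = 30, missing_rate = 0, seed = 111
  )
  shuffled <- withr::with_seed(1, {
    tb <- tibble::as_tibble(sim$genotypes)
    geno_tbl(tb[sample.int(nrow(tb)), ])
  })
  expect_equal(
    dplyr::arrange(het_stats(sim$genotypes, sim$populations), population, locus_id),
    dplyr::arrange(het_stats(shuffled, sim$populations), population, locus_id)
  )
  # with no missing data, missing-aware counting equals complete-data counting
  f <- allele_frequencies(sim$genotypes, sim$populations)
  expect_true(all(f$n_copies == 30))
})
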