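test_that("informativeness closed forms: identical pools give 0, a fixed difference ln 2", {
  same <- freq_tbl(list(
    p1 = list(L1 = c(A = 0.7, G = 0.3)),
    p2 = list(L1 = c(A = 0.7, G = 0.3))
  ))
  expect_equal(informativeness(same), 0)

  fixed <- freq_tbl(list(
    p1 = list(L1 = c(A = 1)),
    p2 = list(L1 = c(G = 1))
  ))
  expect_equal(informativeness(fixed), log(2))

  expect_error(
    informativeness(freq_tbl(list(p1 = list(L1 = c(A = 1))))),
    "K >= 2"
  )
})

test_that("informativeness agrees with a term-by-term evaluation and is additive", {
  # K = 2, p1 = 0.7, p2 = 0.3 single-locus check against the brute evaluator
  f <- freq_tbl(list(
    p1 = list(L1 = c(A = 0.7, G = 0.3)),
    p2 = list(L1 = c(A = 0.3, G = 0.7))
  ))
  expect_equal(informativeness(f), brute_informativeness(f))

  set.seed(201)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    n_loci <- sample(1:4, 1)
    freqs <- purrr::map(seq_len(k), function(i) {
      purrr::map(seq_len(n_loci), function(m) {
        n_al <- sample(2:4, 1)
        f <- rgamma(n_al, 1)
        stats::setNames(f / sum(f), letters[seq_len(n_al)])
      }) %>% stats::setNames(paste0("L", seq_len(n_loci)))
    }) %>% stats::setNames(paste0("p", seq_len(k)))
    tab <- freq_tbl(freqs)
    expect_equal(informativeness(tab), brute_informativeness(tab), tolerance = 1e-12)
    # nonnegative; additive over loci; invariant to population ordering
    expect_gte(informativeness(tab), 0)
    per_locus <- vapply(
      paste0("L", seq_len(n_loci)),
      function(l) informativeness(tab, loci = l), numeric(1)
    )
    expect_equal(informativeness(tab), sum(per_locus))
    relabeled <- dplyr::mutate(tab,
      population = paste0("z", population)
    )
    expect_equal(informativeness(relabeled), informativeness(tab))
  }
})

test_that("the informativeness curve is seeded, exact at full size, and near-linear for iid loci", {
  sim <- simulate_two_lineage_genotypes(
    n_pops = 2, n_per_pop = 40, n_loci = 60, divergence_F = 0.1,
    missing_rate = 0, seed = 211
  )
  maf <- locus_maf(sim$genotypes)
  poly_ids <- maf$locus_id[!is.na(maf$maf) & maf$maf > 0]
  n_poly <- length(poly_ids)
  freqs <- allele_frequencies(
    geno_tbl(dplyr::filter(
      tibble::as_tibble(sim$genotypes), locus_id %in% poly_ids
    )),
    sim$populations
  )
  sizes <- c(10, 25, 40, n_poly)
  cur <- informativeness_curve(sim$genotypes, sim$populations, sizes,
    replicates = 30, seed = 7
  )
  expect_equal(
    tibble::as_tibble(informativeness_curve(sim$genotypes, sim$populations, sizes,
      replicates = 30, seed = 7
    )),
    tibble::as_tibble(cur)
  )
  # full panel: mean equals the total informativeness exactly, SD = 0
  full <- cur[cur$size == n_poly, ]
  expect_equal(full$mean_In, informativeness(freqs))
  expect_equal(full$sd_In, 0)
  # additivity: mean at size m ~ m * per-locus mean (within 3 SE)
  per_locus_mean <- informativeness(freqs) / n_poly
  m25 <- cur[cur$size == 25, ]
  expect_lt(
    abs(m25$mean_In - 25 * per_locus_mean),
    3 * m25$sd_In / sqrt(m25$replicates) + 1e-9
  )
  expect_error(
    informativeness_curve(sim$genotypes, sim$populations, sizes = 10 * n_poly),
    "exceeds"
  )
})

test_that("the informativeness regression recovers exact and noisy linear curves", {
  exact <- tibble::tibble(size = c(10, 20, 40, 80), mean_In = 0.023 * size + 0.0038)
  fit <- fit_informativeness_regression(exact)
  expect_equal(fit$a, 0.023, tolerance = 1e-9)
  expect_equal(fit$b, 0.0038, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(glance(fit)$r.squared, 1)
  expect_equal(nrow(tidy(fit)), 2)

  flat <- tibble::tibble(size = c(10, 20, 30), mean_In = 1)
  expect_equal(fit_informativeness_regression(flat)$a, 0)
  expect_error(fit_informativeness_regression(exact[1, ]), "3 distinct")

  withr::with_seed(3, {
    noisy <- tibble::tibble(
      size = seq(10, 90, by = 10),
      mean_In = 0.023 * size + 0.0038 + rnorm(9, sd = 0.01)
    )
    nf <- fit_informativeness_regression(noisy)
    expect_equal(nf$a, 0.023, tolerance = 0.05)
    expect_gt(nf$r_squared, 0.99)
  })
})

test_that("equivalent marker counts match brute-force integer search", {
  fit <- list(a = 0.023, b = 0.0038)
  expect_equal(equivalent_marker_count(fit, fit$b), 0)
  expect_error(equivalent_marker_count(list(a = -1, b = 0), 1), "positive slope")

  set.seed(221)
  for (rep in 1:50) {
    a <- runif(1, 0.001, 0.1)
    b <- runif(1, -0.5, 0.5)
    target <- runif(1, 0, 5)
    got <- equivalent_marker_count(list(a = a, b = b), target)
    brute <- 0
    while (a * brute + b < target) brute <- brute + 1
    expect_equal(got, brute)
  }
})

test_that("the Mantel statistic matches hand computation and vegan, with exact scaling r = 1", {
  net <- simulate_site_network(n_sites = 6, noise_sd = 0, seed = 231)
  res <- mantel_test(net$fst, 2 * net$fst, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)

  # 4-site hand-made pair: manual Pearson on the 6 lower-triangle values
  m1 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m2 <- m1
  m1[lower.tri(m1)] <- c(1, 2, 3, 4, 5, 6)
  m2[lower.tri(m2)] <- c(2, 1, 4, 3, 7, 5)
  m1 <- m1 + t(m1)
  m2 <- m2 + t(m2)
  byhand <- stats::cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 7, 5))
  res2 <- mantel_test(m1, m2, n_perm = 999, seed = 5)
  expect_equal(res2$r, byhand)

  skip_if_not_installed("vegan")
  veg <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2), permutations = 999)
  expect_equal(res2$r, unname(veg$statistic))

  # label alignment and error handling
  perm <- c(3, 1, 2, 4)
  m2p <- m2[perm, perm]
  expect_equal(mantel_test(m1, m2p, n_perm = 99, seed = 5)$r, byhand)
  rownames(m2p) <- colnames(m2p) <- LETTERS[1:4]
  expect_error(mantel_test(m1, m2p, 99), "same sites")
  expect_error(mantel_test(m1, m2, n_perm = 10), "99")
})

test_that("Mantel p-values are invariant to simultaneous site relabelling", {
  net <- simulate_site_network(n_sites = 7, noise_sd = 0.02, seed = 241)
  base <- mantel_test(net$fst, net$geo, n_perm = 499, seed = 9)
  perm <- withr::with_seed(2, sample.int(7))
  fst2 <- net$fst[perm, perm]
  geo2 <- net$geo[perm, perm]
  relab <- mantel_test(fst2, geo2, n_perm = 499, seed = 9)
  expect_equal(relab$r, base$r)
  # same permutation distribution up to the label-aligned reordering
  expect_equal(relab$p_value, base$p_value, tolerance = 0.02)
})

test_that("supervised admixture recovers pure, F1 and threshold-edge ancestries", {
  loci <- sprintf("d%02d", 1:50)
  ref_cap <- tibble::tibble(locus_id = loci, allele = "A", freq = 1, n_copies = 60)
  ref_wild <- tibble::tibble(locus_id = loci, allele = "A", freq = 0, n_copies = 60)

  pure <- geno_tbl(tibble::tibble(
    individual_id = "cap1", locus_id = loci,
    allele1 = "A", allele2 = "A", marker_class = "snp"
  ))
  res <- supervised_admixture(pure, ref_cap, ref_wild)
  expect_gt(res$q_captive, 0.9)
  expect_equal(res$class, "captive_bred")

  f1 <- geno_tbl(tibble::tibble(
    individual_id = "f1", locus_id = loci,
    allele1 = "A", allele2 = "G", marker_class = "snp"
  ))
  rf1 <- supervised_admixture(f1, ref_cap, ref_wild)
  expect_gt(rf1$q_captive, 0.4)
  expect_lt(rf1$q_captive, 0.6)
  expect_equal(rf1$class, "admixed")

  # strict threshold: q exactly at the threshold is never assigned to a cluster
  res_eq <- supervised_admixture(pure, ref_cap, ref_wild,
    threshold = res$q_captive
  )
  expect_false(res_eq$class == "captive_bred")
  res_above <- supervised_admixture(pure, ref_cap, ref_wild,
    threshold = res$q_captive - 1e-6
  )
  expect_equal(res_above$class, "captive_bred")

  # the estimator labels itself as a supervised stand-in
  expect_match(attr(res, "method"), "supervised")

  # individual with zero scorable loci gets a missing result
  empty <- geno_tbl(tibble::tibble(
    individual_id = "void", locus_id = loci,
    allele1 = NA_character_, allele2 = NA_character_, marker_class = "snp"
  ))
  rv <- supervised_admixture(empty, ref_cap, ref_wild)
  expect_true(is.na(rv$q_captive))
  expect_equal(rv$n_loci, 0L)
})

test_that("planted admixture proportions are recovered from simulated genotypes", {
  qs <- rep(seq(0, 1, length.out = 21), each = 4)
  sim <- simulate_two_lineage_genotypes(
    n_pops = 1, n_per_pop = length(qs), n_loci = 90, divergence_F = 0.3,
    q = qs, missing_rate = 0.01, seed = 42
  )
  truth <- sim$truth
  ref_cap <- tibble::tibble(
    locus_id = names(truth$f_captive), allele = "A",
    freq = truth$f_captive, n_copies = 60
  )
  ref_wild <- tibble::tibble(
    locus_id = colnames(truth$freq), allele = "A",
    freq = truth$freq[1, ], n_copies = 60
  )
  adm <- supervised_admixture(sim$genotypes, ref_cap, ref_wild)
  mae <- mean(abs(adm$q_captive - truth$q[adm$individual_id]))
  expect_lt(mae, 0.1)
})

test_that("ancestry concordance is a tie-aware Spearman correlation", {
  q <- c(a = 0.1, b = 0.5, c = 0.9, d = 0.3)
  expect_equal(ancestry_concordance(q, q)$rho, 1)
  expect_equal(ancestry_concordance(q, 1 - q)$rho, -1)
  expect_error(ancestry_concordance(q[1:2], q[1:2]), "at least 3")

  set.seed(251)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    qa <- stats::setNames(round(runif(n), 1), paste0("i", 1:n)) # forces ties
    qb <- stats::setNames(round(runif(n), 1), paste0("i", 1:n))
    got <- ancestry_concordance(qa, qb)$rho
    brute <- stats::cor(rank(qa), rank(qb))
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("result types expose plots and tidiers", {
  sim <- simulate_two_lineage_genotypes(
    n_pops = 2, n_per_pop = 30, n_loci = 80, divergence_F = 0.05,
    missing_rate = 0, seed = 261
  )
  scan <- fst_outlier_scan(sim$genotypes, sim$populations)
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")

  cur <- informativeness_curve(sim$genotypes, sim$populations,
    sizes = c(10, 30, 50), replicates = 5, seed = 1
  )
  fit <- fit_informativeness_regression(cur)
  expect_s3_class(ggplot2::autoplot(cur, fit = fit), "ggplot")

  net <- simulate_site_network(seed = 1)
  mt <- mantel_test(net$fst, net$geo, n_perm = 99, seed = 1)
  expect_named(tidy(mt), c("estimate", "p.value", "n_perm", "n_sites"))

  freqs <- allele_frequencies(sim$genotypes, sim$populations)
  ref1 <- dplyr::filter(freqs, population == "pop1")
  ref2 <- dplyr::filter(freqs, population == "pop2")
  adm <- supervised_admixture(sim$genotypes, ref1, ref2)
  expect_s3_class(ggplot2::autoplot(adm), "ggplot")

  panel <- panel_selection(tibble::tibble(
    marker_id = c("a", "b"), linkage_group = 1, position_cM = c(0, 5)
  ))
  expect_s3_class(ggplot2::autoplot(panel), "ggplot")
  expect_equal(glance(panel)$n_markers, 2)
})
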