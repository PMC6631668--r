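#' Simulate a linkage map skeleton
#'
#' Draws linkage-group lengths as a Dirichlet-proportional split of the total
#' map length (gamma draws with a common concentration, normalised).  Marker
#' positions are assigned later by [simulate_rad_tags()], uniformly within
#' groups.  Defaults mirror a salmonid map: 40 groups totalling 1453 cM.
#'
#' @param n_groups Number of linkage groups (default 40).
#' @param total_cM Total map length in cM (default 1453).
#' @param concentration Dirichlet concentration for the split (default 5;
#'   larger is more even).
#' @param seed Integer seed.
#' @return Tibble of class `lg_skeleton` with columns `linkage_group`,
#'   `length_cM`; total length in `attr(, "total_length_cM")`.
#' @export
simulate_linkage_map <- function(n_groups = 40, total_cM = 1453,
                                 concentration = 5, seed = 1L) {
  if (n_groups < 1 || total_cM <= 0) abort("need n_groups >= 1 and total_cM > 0")
  lengths <- withr::with_seed(seed, {
    g <- stats::rgamma(n_groups, shape = concentration, rate = 1)
    total_cM * g / sum(g)
  })
  structure(
    tibble(linkage_group = seq_len(n_groups), length_cM = lengths),
    class = c("lg_skeleton", class(tibble())),
    total_length_cM = total_cM, seed = seed
  )
}

#' Simulate RAD tags with known filter-violation labels
#'
#' Generates a collection of RAD tag sequences whose SNPs are placed so that
#' each tag either passes every panel-design filter or violates exactly the
#' rules recorded in its truth label.  Clean tags carry their SNPs inside the
#' safe zone (`safe_zone_bp` from either end), contain no `N`, and are mapped
#' uniformly on a linkage group (chosen with probability proportional to
#' group length).  Violations are planted independently at the given rates:
#' an edge violation moves one SNP into the first or last `edge_bp` bases, an
#' `N` violation writes 1-3 undetermined bases, an unmapped violation clears
#' the map position; tags drawing 3+ SNPs from `snp_count_probs` violate the
#' per-tag SNP-count rule.
#'
#' @param map An [simulate_linkage_map()] skeleton (or tibble with
#'   `linkage_group`, `length_cM`).
#' @param n_tags Number of tags.
#' @param tag_length Tag length in bp (default 230).
#' @param snp_count_probs Named numeric vector of SNP-count probabilities
#'   (default `c("1" = 0.7, "2" = 0.3)`).
#' @param edge_violation_rate,n_rate,unmapped_rate Violation rates in
#'   `[0, 1]` (defaults 0).
#' @param edge_bp Edge window the violation targets (default 30).
#' @param safe_zone_bp Clean SNPs are placed at offsets in
#'   `[safe_zone_bp, tag_length - safe_zone_bp)` (default 50, the primer
#'   design zone, so clean one-SNP tags also pass the assay filter).
#' @param seed Integer seed.
#' @return List with `rads` (a [rad_tbl()]) and `truth` (tibble `tag_id`,
#'   `n_snps`, `viol_max_snps`, `viol_edge`, `viol_n`, `viol_unmapped`,
#'   `clean`).
#' @export
simulate_rad_tags <- function(map, n_tags, tag_length = 230,
                              snp_count_probs = c("1" = 0.7, "2" = 0.3),
                              edge_violation_rate = 0, n_rate = 0,
                              unmapped_rate = 0, edge_bp = 30,
                              safe_zone_bp = 50, seed = 1L) {
  if (2 * safe_zone_bp >= tag_length) {
    abort("tag_length too short for the safe zone")
  }
  rates <- c(edge_violation_rate, n_rate, unmapped_rate)
  if (any(rates < 0 | rates > 1)) abort("violation rates must be in [0, 1]")
  map <- as_tibble(map)
  bases <- c("A", "C", "G", "T")

  sim <- withr::with_seed(seed, {
    n_snps <- as.integer(sample(names(snp_count_probs), n_tags,
      replace = TRUE, prob = snp_count_probs
    ))
    viol_edge <- stats::runif(n_tags) < edge_violation_rate
    viol_n <- stats::runif(n_tags) < n_rate
    viol_unmapped <- stats::runif(n_tags) < unmapped_rate
    lg <- sample(map$linkage_group, n_tags, replace = TRUE, prob = map$length_cM)
    pos <- stats::runif(n_tags) * map$length_cM[match(lg, map$linkage_group)]

    tags <- purrr::map(seq_len(n_tags), function(i) {
      seq <- sample(bases, tag_length, replace = TRUE)
      k <- n_snps[i]
      safe <- seq(safe_zone_bp, tag_length - safe_zone_bp - 1)
      off <- sort(sample(safe, k))
      if (viol_edge[i]) {
        # move one SNP into the excluded edge window
        edge_positions <- c(seq(0, edge_bp - 1), seq(tag_length - edge_bp, tag_length - 1))
        off[1] <- sample(edge_positions, 1)
        off <- sort(unique(off))
        while (length(off) < k) off <- sort(unique(c(off, sample(safe, 1))))
      }
      if (viol_n[i]) {
        n_sites <- sample(setdiff(seq_len(tag_length) - 1, off), sample(1:3, 1))
        seq[n_sites + 1] <- "N"
      }
      ref <- seq[off + 1]
      alt <- vapply(ref, function(b) sample(setdiff(bases, c(b, "N")), 1),
        character(1), USE.NAMES = FALSE
      )
      list(seq = paste(seq, collapse = ""), off = off, ref = unname(ref), alt = alt)
    })
    list(
      n_snps = n_snps, viol_edge = viol_edge, viol_n = viol_n,
      viol_unmapped = viol_unmapped, lg = lg, pos = pos, tags = tags
    )
  })

  ids <- sprintf("tag%05d", seq_len(n_tags))
  rads <- rad_tbl(tibble(
    tag_id = ids,
    sequence = purrr::map_chr(sim$tags, "seq"),
    snp_offsets = purrr::map(sim$tags, "off"),
    ref = purrr::map(sim$tags, "ref"),
    alt = purrr::map(sim$tags, "alt"),
    linkage_group = ifelse(sim$viol_unmapped, NA, sim$lg),
    position_cM = ifelse(sim$viol_unmapped, NA_real_, sim$pos)
  ))
  truth <- tibble(
    tag_id = ids, n_snps = lengths(rads$snp_offsets),
    viol_max_snps = lengths(rads$snp_offsets) > 2,
    viol_edge = sim$viol_edge, viol_n = sim$viol_n,
    viol_unmapped = sim$viol_unmapped
  ) %>%
    mutate(clean = !(.data$viol_max_snps | .data$viol_edge | .data$viol_n |
      .data$viol_unmapped))
  list(rads = rads, truth = truth)
}

#' Simulate two-lineage genotypes under the Balding-Nichols model
#'
#' Emulates the sampling design of a hatchery-introgression study: a set of
#' wild populations and a captive-bred (hatchery) lineage.  Per locus the
#' ancestral frequency is drawn `Uniform(0.05, 0.95)`; each population's
#' frequency (and the captive lineage's) is Balding-Nichols,
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, around the ancestral `p` with divergence
#' `F`.  Each individual carries an admixture proportion `q` toward the
#' captive pool and draws genotypes `Binomial(2, q*f_cap + (1-q)*f_pop)`
#' per locus; calls are masked missing with probability `missing_rate`.
#' Outlier loci are planted by re-drawing their population frequencies with
#' divergence `outlier_F`.
#'
#' @param n_pops Number of wild populations (default 2).
#' @param n_per_pop Individuals per population (single number or vector).
#' @param n_loci Number of biallelic SNP loci (default 100).
#' @param divergence_F Balding-Nichols divergence in `(0, 1)` (default 0.3,
#'   a deep between-lineage split).
#' @param q Admixture toward the captive pool: a single number, one value per
#'   population, or one per individual (default 0, pure wild).
#' @param n_captive Individuals sampled from the captive lineage itself
#'   (population label `"captive"`, `q = 1`; default 0).
#' @param missing_rate Per-call missingness probability (default 0.01).
#' @param n_outliers Number of planted high-divergence loci (default 0).
#' @param outlier_F Divergence of planted outliers (default 0.8).
#' @param seed Integer seed.
#' @return List with `genotypes` ([geno_tbl()]), `populations`
#'   ([population_table()]) and `truth` (list: `p_ancestral`, `freq` matrix
#'   (pops x loci), `f_captive`, `q` per individual, `outlier_loci`, `seed`).
#' @export
simulate_two_lineage_genotypes <- function(n_pops = 2, n_per_pop = 30,
                                           n_loci = 100, divergence_F = 0.3,
                                           q = 0, n_captive = 0,
                                           missing_rate = 0.01,
                                           n_outliers = 0, outlier_F = 0.8,
                                           seed = 1L) {
  if (divergence_F <= 0 || divergence_F >= 1) abort("divergence_F must be in (0, 1)")
  if (missing_rate < 0 || missing_rate > 1) abort("missing_rate must be in [0, 1]")
  if (n_outliers > n_loci) abort("n_outliers cannot exceed n_loci")
  n_per_pop <- rep(n_per_pop, length.out = n_pops)
  loci <- sprintf("snp%04d", seq_len(n_loci))
  pops <- sprintf("pop%d", seq_len(n_pops))

  out <- withr::with_seed(seed, {
    p <- stats::runif(n_loci, 0.05, 0.95)
    bn <- function(p, F) stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
    freq <- t(vapply(seq_len(n_pops), function(i) bn(p, divergence_F), numeric(n_loci)))
    f_cap <- bn(p, divergence_F)
    outlier_loci <- character()
    if (n_outliers > 0) {
      idx <- sample.int(n_loci, n_outliers)
      outlier_loci <- loci[idx]
      for (i in seq_len(n_pops)) freq[i, idx] <- bn(p[idx], outlier_F)
      f_cap[idx] <- bn(p[idx], outlier_F)
    }
    dimnames(freq) <- list(pops, loci)
    names(f_cap) <- loci

    ind_pop <- c(rep(pops, times = n_per_pop), rep("captive", n_captive))
    n_ind <- length(ind_pop)
    ind_ids <- sprintf("%s_ind%03d", ind_pop, stats::ave(
      seq_len(n_ind), ind_pop, FUN = seq_along
    ))
    q_wild <- rep(q, length.out = if (length(q) %in% c(1, n_pops)) n_pops else sum(n_per_pop))
    q_ind <- if (length(q_wild) == n_pops) {
      q_wild[match(ind_pop[seq_len(sum(n_per_pop))], pops)]
    } else {
      q_wild
    }
    q_ind <- c(q_ind, rep(1, n_captive))

    f_pop <- rbind(freq, captive = f_cap)[ind_pop, , drop = FALSE]
    theta <- q_ind * matrix(f_cap, n_ind, n_loci, byrow = TRUE) + (1 - q_ind) * f_pop
    g <- matrix(stats::rbinom(n_ind * n_loci, 2, theta), n_ind, n_loci)
    miss <- matrix(stats::runif(n_ind * n_loci) < missing_rate, n_ind, n_loci)
    list(
      p = p, freq = freq, f_cap = f_cap, outlier_loci = outlier_loci,
      ind_ids = ind_ids, ind_pop = ind_pop, q_ind = q_ind, g = g, miss = miss
    )
  })

  g_vec <- as.vector(out$g)
  miss_vec <- as.vector(out$miss)
  calls <- tibble(
    individual_id = rep(out$ind_ids, times = n_loci),
    locus_id = rep(loci, each = length(out$ind_ids)),
    allele1 = ifelse(miss_vec, NA_character_, ifelse(g_vec >= 1, "A", "G")),
    allele2 = ifelse(miss_vec, NA_character_, ifelse(g_vec == 2, "A", "G")),
    marker_class = "snp"
  )
  genotypes <- geno_tbl(calls)
  populations <- population_table(tibble(
    individual_id = out$ind_ids, population = out$ind_pop
  ))
  truth <- list(
    p_ancestral = out$p, freq = out$freq, f_captive = out$f_cap,
    q = stats::setNames(out$q_ind, out$ind_ids),
    outlier_loci = out$outlier_loci, missing_rate = missing_rate, seed = seed
  )
  list(genotypes = genotypes, populations = populations, truth = truth)
}

#' Simulate multiallelic microsatellite genotypes
#'
#' Per locus, a base frequency vector over `k` alleles (`k` uniform on
#' `alleles_per_locus`) is drawn from a symmetric Dirichlet; each
#' population's frequencies are a Dirichlet perturbation of the base with
#' concentration `base * (1 - divergence)/divergence`, the multiallelic
#' analogue of the Balding-Nichols draw.  Allele identifiers resemble
#' fragment sizes (integers stepping by 2).
#'
#' @param n_loci Number of loci (default 13).
#' @param alleles_per_locus Integer range of allele counts (default `6:10`).
#' @param n_pops,n_per_pop Populations and individuals per population.
#' @param divergence Between-population divergence in `(0, 1)` (default
#'   0.05).
#' @param dirichlet_conc Concentration of the symmetric base Dirichlet
#'   (default 1.5).
#' @param missing_rate Per-call missingness probability (default 0.01).
#' @param seed Integer seed.
#' @return List with `genotypes` (a microsatellite [geno_tbl()]),
#'   `populations` and `truth` (per-locus, per-population frequencies).
#' @export
simulate_microsatellites <- function(n_loci = 13, alleles_per_locus = 6:10,
                                     n_pops = 2, n_per_pop = 30,
                                     divergence = 0.05, dirichlet_conc = 1.5,
                                     missing_rate = 0.01, seed = 1L) {
  # k = 1 is allowed as a degenerate monomorphic control
  if (min(alleles_per_locus) < 1) abort("alleles_per_locus must be >= 1")
  if (divergence <= 0 || divergence >= 1) abort("divergence must be in (0, 1)")
  n_per_pop <- rep(n_per_pop, length.out = n_pops)
  loci <- sprintf("usat%02d", seq_len(n_loci))
  pops <- sprintf("pop%d", seq_len(n_pops))

  rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }

  out <- withr::with_seed(seed, {
    per_locus <- purrr::map(seq_len(n_loci), function(m) {
      k <- if (length(alleles_per_locus) == 1) alleles_per_locus else sample(alleles_per_locus, 1)
      sizes <- as.character(seq(100 + 10 * m, by = 2, length.out = k))
      base <- rdirichlet(rep(dirichlet_conc, k))
      pop_freq <- purrr::map(seq_len(n_pops), function(i) {
        f <- rdirichlet(base * (1 - divergence) / divergence)
        stats::setNames(f, sizes)
      })
      names(pop_freq) <- pops
      list(sizes = sizes, pop_freq = pop_freq)
    })
    names(per_locus) <- loci

    ind_pop <- rep(pops, times = n_per_pop)
    ind_ids <- sprintf("%s_ind%03d", ind_pop, stats::ave(
      seq_along(ind_pop), ind_pop, FUN = seq_along
    ))
    calls <- purrr::map_dfr(loci, function(m) {
      info <- per_locus[[m]]
      purrr::map_dfr(seq_along(ind_ids), function(j) {
        f <- info$pop_freq[[ind_pop[j]]]
        pair <- sort(sample(info$sizes, 2, replace = TRUE, prob = f))
        if (stats::runif(1) < missing_rate) pair <- c(NA_character_, NA_character_)
        tibble(
          individual_id = ind_ids[j], locus_id = m,
          allele1 = pair[1], allele2 = pair[2],
          marker_class = "microsatellite"
        )
      })
    })
    list(per_locus = per_locus, ind_ids = ind_ids, ind_pop = ind_pop, calls = calls)
  })

  list(
    genotypes = geno_tbl(out$calls),
    populations = population_table(tibble(
      individual_id = out$ind_ids, population = out$ind_pop
    )),
    truth = list(frequencies = out$per_locus, seed = seed)
  )
}

#' Simulate a riparian site network with isolation by distance
#'
#' Places sites along a river, measures pairwise riparian distances in
#' meters, and builds a genetic differentiation matrix whose pairwise Fst
#' increases linearly with distance plus truncated Gaussian noise -- a truthy
#' positive case for [mantel_test()].  With zero noise the Mantel correlation
#' is exactly 1.
#'
#' @param n_sites Number of sites (minimum 4; default 7).
#' @param river_length_m River length in meters (default 15000).
#' @param ibd_slope_per_km Fst increase per km of riparian distance (default
#'   0.004).
#' @param noise_sd SD of the Gaussian noise on each pairwise Fst (default
#'   0.01); `0` gives a perfectly linear relation.
#' @param seed Integer seed.
#' @return List with `geo` (distance matrix, m), `fst` (Fst matrix),
#'   `positions` (tibble `site`, `position_m`) and the parameters used.
#' @export
simulate_site_network <- function(n_sites = 7, river_length_m = 15000,
                                  ibd_slope_per_km = 0.004, noise_sd = 0.01,
                                  seed = 1L) {
  if (n_sites < 4) abort("need at least 4 sites")
  sites <- sprintf("site%02d", seq_len(n_sites))
  out <- withr::with_seed(seed, {
    pos <- sort(stats::runif(n_sites, 0, river_length_m))
    geo <- abs(outer(pos, pos, "-"))
    fst <- ibd_slope_per_km * geo / 1000
    if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(n_sites^2, 0, noise_sd), n_sites)
      noise[upper.tri(noise)] <- t(noise)[upper.tri(noise)]
      fst <- pmax(fst + noise, 0)
    }
    diag(fst) <- 0
    list(pos = pos, geo = geo, fst = fst)
  })
  dimnames(out$geo) <- dimnames(out$fst) <- list(sites, sites)
  list(
    geo = out$geo, fst = out$fst,
    positions = tibble(site = sites, position_m = out$pos),
    ibd_slope_per_km = ibd_slope_per_km, noise_sd = noise_sd, seed = seed
  )
}

#' Simulate a complete small-river study bundle
#'
#' Convenience preset emulating a full panel-evaluation campaign on one small
#' river: 7 wild sites (~27 individuals each) plus a 30-fish hatchery sample,
#' genotyped at a polymorphic SNP panel and 13 microsatellites, with a site
#' network for isolation-by-distance testing.
#'
#' @param n_snps Number of SNP loci (default 92, a typical polymorphic count
#'   for a low-density array in one river).
#' @param seed Integer seed.
#' @return List with components `snps`, `usats` (each as returned by their
#'   simulator) and `network` (from [simulate_site_network()]).
#' @export
simulate_study_bundle <- function(n_snps = 92, seed = 1L) {
  snps <- simulate_two_lineage_genotypes(
    n_pops = 7, n_per_pop = 27, n_loci = n_snps, divergence_F = 0.05,
    q = 0, n_captive = 30, missing_rate = 0.01, seed = seed
  )
  usats <- simulate_microsatellites(
    n_loci = 13, n_pops = 7, n_per_pop = 27, divergence = 0.05,
    seed = seed + 1L
  )
  network <- simulate_site_network(n_sites = 7, seed = seed + 2L)
  list(snps = snps, usats = usats, network = network)
}
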