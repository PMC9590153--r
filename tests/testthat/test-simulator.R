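test_that("simulated crosses follow the gamete model closed forms", {
  # tetraploid duplex x homozygote, alpha = 0: offspring dosage classes at
  # marker 1 appear at 1/6, 2/3, 1/6; Monte-Carlo at 1e5 within 3 sigma
  n <- 1e5
  off <- simulate_cross(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L), n,
                        alpha = 0, seed = 40)
  d <- mrkdos_of_hapcomb(off, 1)
  freq <- tabulate(d + 1L, nbins = 3L) / n
  expected <- c(1 / 6, 2 / 3, 1 / 6)
  sigma <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) < 3 * sigma))
})

test_that("double-reduction gametes appear at the configured rate", {
  # fully heteroallelic parent: a DR offspring carries a duplicated code
  # from a parent; with alpha = 0.5 half the gametes are DR
  n <- 2e4
  off <- simulate_cross(c(1L, 2L, 4L, 8L), c(16L, 17L, 18L, 19L), n,
                        alpha = 0.5, seed = 41)
  is_dr <- vapply(seq_len(n), function(i) {
    g1 <- off[off[, i] < 16L, i]
    g2 <- off[off[, i] >= 16L, i]
    anyDuplicated(g1) > 0L || anyDuplicated(g2) > 0L
  }, logical(1L))
  # each gamete is DR with prob 0.5 -> at least one duplicated side at 75%
  p <- mean(is_dr)
  expect_true(abs(p - 0.75) < 3 * sqrt(0.75 * 0.25 / n))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_design_two_populations(family_size = 10, n_unrelated = 5,
                                    n_blocks = 3, markers_per_block = 3,
                                    seed = 42)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$dosages, s2$dosages)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_population(sim_design_two_populations(
    family_size = 10, n_unrelated = 5, n_blocks = 3,
    markers_per_block = 3, seed = 43))
  expect_false(identical(s1$dosages, s3$dosages))
})

test_that("error-free dosages are exactly consistent with the truth", {
  cfg <- sim_design_shared_parent(n_families = 2, family_size = 10,
                                  n_blocks = 4, markers_per_block = 2:4,
                                  seed = 44)
  sim <- simulate_population(cfg)
  for (b in names(sim$blocks)) {
    tr <- sim$truth[sim$truth$block == b, ]
    nmrk <- length(sim$blocks[[b]])
    for (i in seq_len(nrow(tr))) {
      expect_equal(unname(sim$dosages[sim$blocks[[b]], tr$indiv[i]]),
                   mrkdos_of_hapcomb(tr$ghap[[i]], nmrk))
      # and the truth is among the enumerated solutions of its dosages
      if (i <= 3) {
        sols <- comb_strings(enumerate_hapcombs(
          sim$dosages[sim$blocks[[b]], tr$indiv[i]], 4))
        expect_true(paste(tr$ghap[[i]], collapse = "+") %in% sols)
      }
    }
  }
})

test_that("offspring truth is gamete-decomposable from parental truth", {
  cfg <- sim_design_shared_parent(n_families = 3, family_size = 8,
                                  n_blocks = 3, markers_per_block = 3,
                                  alpha = 0.025, seed = 45)
  sim <- simulate_population(cfg)
  # feed the truth back as a perfect result and check every trio matches
  asn <- sim$truth
  asn$category <- "other"
  asn$stage <- "truth"
  asn$imputed <- FALSE
  asn$assigned <- TRUE
  res <- structure(list(assignments = asn,
                        inventory = tibble::tibble(),
                        families = tibble::tibble(),
                        blocks = tibble::tibble(block = names(sim$blocks),
                                                nmrk = lengths(sim$blocks),
                                                error = NA_character_),
                        ploidy = 4L, params = hap_params()),
                   class = "hap_result")
  rep <- check_parent_offspring(res, sim_pedigree(sim), alpha = 0.025)
  expect_true(all(rep$status == "match"))
})

test_that("founder draws achieve the configured haplotype diversity", {
  cfg <- sim_design_shared_parent(n_blocks = 6, markers_per_block = 6,
                                  n_founder_haps = 16, seed = 46)
  sim <- simulate_population(cfg)
  founders <- sim$truth[sim$truth$indiv %in% cfg$parents$indiv, ]
  for (b in names(sim$blocks)) {
    n_distinct <- length(unique(unlist(
      founders$ghap[founders$block == b])))
    expect_gte(n_distinct, 8L)
    expect_lte(n_distinct, 16L)
  }
})

test_that("two-population designs draw founders independently", {
  cfg <- sim_design_two_populations(family_size = 4, n_unrelated = 30,
                                    n_blocks = 4, markers_per_block = 6,
                                    seed = 47)
  sim <- simulate_population(cfg)
  u1 <- sprintf("U1_%02d", 1:30)
  u2 <- sprintf("U2_%02d", 1:30)
  shared <- vapply(names(sim$blocks), function(b) {
    tr <- sim$truth[sim$truth$block == b, ]
    h1 <- unique(unlist(tr$ghap[tr$indiv %in% u1]))
    h2 <- unique(unlist(tr$ghap[tr$indiv %in% u2]))
    length(intersect(h1, h2)) / length(union(h1, h2))
  }, numeric(1L))
  # pools are drawn independently: overlap well below identity
  expect_lt(mean(shared), 0.8)
})

test_that("dosage errors and missingness are applied at the set rates", {
  cfg <- sim_design_shared_parent(n_families = 3, family_size = 40,
                                  n_blocks = 6, markers_per_block = 4,
                                  epsilon_sim = 0.1, missing_rate = 0.2,
                                  seed = 48)
  sim <- simulate_population(cfg)
  expect_equal(mean(is.na(sim$dosages)), 0.2, tolerance = 0.03)
  # compare non-missing entries against the error-free truth
  nerr <- 0L; ntot <- 0L
  for (b in names(sim$blocks)) {
    tr <- sim$truth[sim$truth$block == b, ]
    nmrk <- length(sim$blocks[[b]])
    true_dos <- vapply(tr$ghap, mrkdos_of_hapcomb, integer(nmrk),
                       nmrk = nmrk)
    got <- sim$dosages[sim$blocks[[b]], tr$indiv]
    ok <- !is.na(got)
    nerr <- nerr + sum(got[ok] != true_dos[ok])
    ntot <- ntot + sum(ok)
  }
  expect_equal(nerr / ntot, 0.1, tolerance = 0.2)
  # errors are off by one
  expect_true(all(abs(got[ok] - true_dos[ok]) <= 1L))
})

test_that("scoring against truth counts correct multisets", {
  cfg <- sim_design_shared_parent(n_families = 1, family_size = 4,
                                  n_blocks = 1, markers_per_block = 2,
                                  seed = 49)
  sim <- simulate_population(cfg)
  tr <- sim$truth
  asn <- tr
  asn$category <- "other"; asn$stage <- "x"; asn$imputed <- FALSE
  asn$assigned <- TRUE
  # corrupt one assignment, unassign another
  asn$ghap[[1L]] <- if (all(asn$ghap[[1L]] == 0L)) c(0L, 0L, 0L, 1L)
                    else c(0L, 0L, 0L, 0L)
  asn$assigned[2L] <- FALSE
  asn$ghap[2L] <- list(NULL)
  res <- structure(list(assignments = asn, inventory = tibble::tibble(),
                        families = tibble::tibble(),
                        blocks = tibble::tibble(block = names(sim$blocks),
                                                nmrk = 2L,
                                                error = NA_character_),
                        ploidy = 4L, params = hap_params()),
                   class = "hap_result")
  sc <- score_against_truth(res, sim$truth)
  n <- nrow(tr)
  expect_equal(sc$by_block$n, n)
  expect_equal(sc$by_block$n_haplotyped, n - 1L)
  expect_lte(sc$by_block$n_correct, n - 2L)
  expect_equal(sc$overall$total_not_haplotyped, 1L)
})

test_that("perfect and empty assignments score 100% and 0%", {
  cfg <- sim_design_shared_parent(n_families = 1, family_size = 5,
                                  n_blocks = 2, markers_per_block = 2,
                                  seed = 50)
  sim <- simulate_population(cfg)
  asn <- sim$truth
  asn$category <- "other"; asn$stage <- "x"; asn$imputed <- FALSE
  asn$assigned <- TRUE
  res <- structure(list(assignments = asn, inventory = tibble::tibble(),
                        families = tibble::tibble(),
                        blocks = tibble::tibble(block = names(sim$blocks),
                                                nmrk = 2L,
                                                error = NA_character_),
                        ploidy = 4L, params = hap_params()),
                   class = "hap_result")
  sc <- score_against_truth(res, sim$truth)
  expect_equal(sc$overall$mean_pct_haplotyped, 100)
  expect_equal(sc$overall$mean_pct_correct, 100)
  asn2 <- asn
  asn2$assigned <- FALSE
  asn2$ghap <- rep(list(NULL), nrow(asn2))
  res$assignments <- asn2
  sc2 <- score_against_truth(res, sim$truth)
  expect_equal(sc2$overall$mean_pct_haplotyped, 0)
  expect_true(is.nan(sc2$overall$mean_pct_correct))
})

test_that("founder extraction covers parents and unrelated individuals", {
  cfg <- sim_design_two_populations(family_size = 3, n_unrelated = 4,
                                    n_blocks = 2, markers_per_block = 2,
                                    seed = 51)
  fo <- simulate_founders(cfg)
  expect_setequal(unique(fo$indiv),
                  c("P01", "P02", "P03", sprintf("U1_%02d", 1:4),
                    sprintf("U2_%02d", 1:4)))
  expect_true(all(lengths(fo$ghap) == 4L))
  # identical to the founder rows of the full simulation
  sim <- simulate_population(cfg)
  tr <- sim$truth[sim$truth$indiv %in% fo$indiv, ]
  expect_equal(fo, tr)
})
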